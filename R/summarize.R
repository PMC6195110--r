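#' Round half-up at a fixed number of decimals
#'
#' House rounding rule for printed percentages: exact halves round away
#' from zero, matching the precision conventions of the reported tables
#' (base R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param decimals Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, decimals = 0L) {
  p <- 10^decimals
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

#' Percentage with half-up rounding
#'
#' @param count Integer in `[0, total]`.
#' @param total Positive integer.
#' @param decimals Decimal places of the printed value.
#' @return `100 * count / total`, rounded half-up.
#' @examples
#' pct(81, 385, 2)   # 21.04
#' @export
pct <- function(count, total, decimals = 1L) {
  if (any(total <= 0)) stop("undefined ratio: total must be positive",
                            call. = FALSE)
  if (any(count < 0) || any(count > total)) {
    stop("'count' must lie in [0, total]", call. = FALSE)
  }
  round_half_up(100 * count / total, decimals)
}

#' Share of analysed nucleotides affected
#'
#' A problematic locus carries one questionable SNP, so `n_loci_affected`
#' variant positions are reported against `n_shared_loci *
#' locus_length_bp` analysed positions.  The printed value is rounded
#' half-up to one significant figure; the raw ratio is retained.
#'
#' @param n_loci_affected Number of affected loci.
#' @param n_shared_loci Number of loci analysed.
#' @param locus_length_bp Locus length in bp.
#' @return List with `raw` (exact percentage), `printed` (one significant
#'   figure) and `n_nt` (analysed nucleotides).
#' @examples
#' pct_of_nucleotides(385, 32913, 109)$printed   # 0.01
#' @export
pct_of_nucleotides <- function(n_loci_affected, n_shared_loci,
                               locus_length_bp) {
  if (n_shared_loci <= 0 || locus_length_bp <= 0) {
    stop("undefined ratio: denominator must be positive", call. = FALSE)
  }
  if (n_loci_affected < 0 || n_loci_affected > n_shared_loci) {
    stop("'n_loci_affected' must lie in [0, n_shared_loci]", call. = FALSE)
  }
  n_nt <- n_shared_loci * locus_length_bp
  raw <- 100 * n_loci_affected / n_nt
  printed <- if (raw == 0) 0 else {
    e <- floor(log10(raw))
    round_half_up(raw / 10^e, 0L) * 10^e
  }
  list(raw = raw, printed = printed, n_nt = n_nt)
}

#' Mean of a column of measurements, rounded half-up
#'
#' @param values Non-empty numeric vector.
#' @param decimals Decimal places of the reported mean.
#' @return The rounded arithmetic mean.
#' @examples
#' column_mean(c(500, 1048, 2393, 1128, 390, 226), 1)   # 947.5
#' @export
column_mean <- function(values, decimals = 1L) {
  if (!length(values)) stop("empty input", call. = FALSE)
  round_half_up(mean(values), decimals)
}

#' Summarize pairwise F1-versus-pool classifications across crosses
#'
#' Per cross, percentages of identical-homozygous, identical-heterozygous,
#' setup-explained and unexplained loci at one decimal, with the identical
#' and with-differences totals and the consistent-or-explained total.
#' Across crosses, means are taken over the *rounded per-cross
#' percentages* (each cross weighs equally regardless of its locus
#' count), with min/max.
#'
#' @param results A data frame from `classify_dataset(mode = "pair")`, or
#'   a named list of such data frames (one per cross).
#' @return An object of class `pair_summary`: list with `per_cross` (data
#'   frame) and `across` (data frame of mean/min/max per statistic).
#' @export
summarize_pairwise <- function(results) {
  if (is.data.frame(results)) results <- list(cross1 = results)
  if (!length(results)) stop("empty input: no pairwise results",
                             call. = FALSE)
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    names(results) <- paste0("cross", seq_along(results))
  }
  per <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    stopifnot(is.data.frame(r), "category" %in% names(r))
    n <- nrow(r)
    if (!n) stop("empty result table for cross ", nm, call. = FALSE)
    cnt <- table(factor(r$category, levels = PAIR_CATEGORIES))
    data.frame(
      cross = nm,
      n_shared_loci = n,
      pct_identical_hom = pct(cnt[["IDENTICAL_HOM"]], n, 1L),
      pct_identical_het = pct(cnt[["IDENTICAL_HET"]], n, 1L),
      pct_explained = pct(cnt[["EXPLAINED_BY_SETUP"]], n, 1L),
      pct_unexplained = pct(cnt[["UNEXPLAINED"]], n, 1L),
      pct_identical_total =
        pct(cnt[["IDENTICAL_HOM"]] + cnt[["IDENTICAL_HET"]], n, 1L),
      pct_with_differences =
        pct(cnt[["EXPLAINED_BY_SETUP"]] + cnt[["UNEXPLAINED"]], n, 1L),
      pct_consistent_or_explained =
        pct(cnt[["IDENTICAL_HOM"]] + cnt[["IDENTICAL_HET"]] +
              cnt[["EXPLAINED_BY_SETUP"]], n, 1L),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per) <- NULL
  stats <- setdiff(names(per), c("cross", "n_shared_loci"))
  across <- data.frame(
    statistic = stats,
    mean = vapply(stats, function(s) column_mean(per[[s]], 1L), numeric(1)),
    min = vapply(stats, function(s) min(per[[s]]), numeric(1)),
    max = vapply(stats, function(s) max(per[[s]]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(across) <- NULL
  structure(list(per_cross = per, across = across), class = "pair_summary")
}

#' @export
print.pair_summary <- function(x, ...) {
  cat("<pair_summary> ", nrow(x$per_cross), " cross(es)\n", sep = "")
  print(x$per_cross, row.names = FALSE)
  if (nrow(x$per_cross) > 1L) {
    cat("across crosses (mean of per-cross percentages):\n")
    print(x$across, row.names = FALSE)
  }
  invisible(x)
}

#' Summarize quartet classifications
#'
#' Counts consistent loci and, among the problematic (inconsistent) loci,
#' occurrences and percentage shares per culprit category (two decimals,
#' matching the printed occurrence table), the count of possible
#' allele-dropout cases (a missing allele for the F0 or F1 female) and
#' their share at one decimal, and the consistent percentage at one
#' decimal.
#'
#' @param results Data frame from `classify_dataset(mode = "quartet")`.
#' @param locus_length_bp Locus length used for the analysed-nucleotide
#'   shares (default 109).
#' @return An object of class `quartet_summary`.
#' @export
summarize_quartet <- function(results, locus_length_bp = 109L) {
  stopifnot(is.data.frame(results),
            all(c("category", "culprit") %in% names(results)))
  n <- nrow(results)
  if (!n) stop("empty input: no quartet results", call. = FALSE)
  n_prob <- sum(results$category == "INCONSISTENT")
  occ <- table(factor(results$culprit, levels = CULPRITS))
  culprits <- data.frame(
    culprit = CULPRITS,
    occurrences = as.integer(occ),
    pct_of_problematic = if (n_prob > 0)
      vapply(as.integer(occ), pct, numeric(1), total = n_prob,
             decimals = 2L) else rep(NA_real_, length(CULPRITS)),
    pct_of_nt = vapply(as.integer(occ), function(k)
      pct_of_nucleotides(k, n, locus_length_bp)$printed, numeric(1)),
    stringsAsFactors = FALSE
  )
  n_dropout <- sum(!is.na(results$dropout_candidate))
  structure(list(
    n_loci = n,
    n_consistent = n - n_prob,
    n_problematic = n_prob,
    pct_consistent = pct(n - n_prob, n, 1L),
    pct_problematic_nt = pct_of_nucleotides(n_prob, n,
                                            locus_length_bp)$printed,
    culprits = culprits,
    n_dropout_candidates = n_dropout,
    pct_dropout_of_problematic = if (n_prob > 0)
      pct(n_dropout, n_prob, 1L) else NA_real_
  ), class = "quartet_summary")
}

#' @export
print.quartet_summary <- function(x, ...) {
  cat("<quartet_summary> ", x$n_loci, " loci: ", x$pct_consistent,
      "% consistent, ", x$n_problematic, " problematic\n", sep = "")
  if (x$n_problematic > 0) {
    print(x$culprits, row.names = FALSE)
    cat("possible allele-dropout cases: ", x$n_dropout_candidates, " (",
        x$pct_dropout_of_problematic, "% of problematic loci)\n", sep = "")
  }
  invisible(x)
}

#' Write a summary as TSV and JSON twins
#'
#' @param summary A `pair_summary` or `quartet_summary`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Invisibly, the summary.
#' @export
write_summary <- function(summary, prefix) {
  if (inherits(summary, "pair_summary")) {
    tab <- summary$per_cross
    js <- list(per_cross = summary$per_cross, across = summary$across)
  } else if (inherits(summary, "quartet_summary")) {
    tab <- summary$culprits
    js <- unclass(summary)
  } else {
    stop("unsupported summary object", call. = FALSE)
  }
  write.table(tab, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(js, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(summary)
}
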