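#' Construct a per-sample haplotype call
#'
#' A haplotype call is the unordered set of haplotype strings observed for
#' one sample at one RAD locus, together with its stack depth (number of
#' reads supporting the call).  A haploid male carries one haplotype, a
#' diploid female one or two, and the F2 pool any number.  An empty allele
#' set marks a missing call.
#'
#' @param alleles Character vector of haplotype strings (uppercased on
#'   construction; empty strings dropped).  A single string containing
#'   `"/"` is split, so `hap_call("C/T")` equals `hap_call(c("C", "T"))`.
#' @param depth Non-negative integer stack depth.
#' @return An object of class `hap_call` with fields `alleles` (sorted
#'   unique character vector), `depth` and `missing`.
#' @examples
#' hap_call("C/T", depth = 25)
#' hap_call(character())          # a missing call
#' @export
hap_call <- function(alleles = character(), depth = 0L) {
  alleles <- parse_cell(paste(as.character(alleles), collapse = "/"))
  depth <- suppressWarnings(as.integer(depth)[1L])
  if (is.na(depth) || depth < 0L) {
    stop("'depth' must be a single non-negative integer", call. = FALSE)
  }
  structure(
    list(alleles = alleles, depth = depth, missing = length(alleles) == 0L),
    class = "hap_call"
  )
}

#' @export
print.hap_call <- function(x, ...) {
  cat("<hap_call> ", if (x$missing) "-" else paste(x$alleles, collapse = "/"),
      " (depth ", x$depth, ")\n", sep = "")
  invisible(x)
}

# Parse one matrix cell into a sorted allele set.  Dialect:
#   "-"          missing call
#   "consensus"  monomorphic locus sentinel
#   "X/Y/..."    haplotypes joined by "/"
parse_cell <- function(cell) {
  cell <- trimws(cell)
  if (!nzchar(cell) || identical(cell, "-")) return(character())
  if (tolower(cell) == "consensus") return(CONSENSUS_ALLELE)
  parts <- toupper(unlist(strsplit(cell, "/", fixed = TRUE), use.names = FALSE))
  parts <- parts[nzchar(parts)]
  bad <- !grepl("^[A-Z]+$", parts)
  if (any(bad)) {
    stop("invalid haplotype string(s): ", paste(parts[bad], collapse = ", "),
         call. = FALSE)
  }
  sort(unique(parts))
}

format_cell <- function(alleles) {
  if (length(alleles) == 0L) return("-")
  if (identical(alleles, CONSENSUS_ALLELE)) return("consensus")
  paste(sort(alleles), collapse = "/")
}

# Canonicalize a vector of raw cells ("-", "consensus", "a/g", ...) to the
# internal representation: "" for missing, sorted-"/"-joined otherwise.
# Deduplicates cell strings first: haplotype matrices are highly repetitive.
canonicalize_cells <- function(cells) {
  u <- unique(cells)
  mapped <- vapply(u, function(cell) {
    al <- parse_cell(cell)
    if (length(al) == 0L) "" else paste(al, collapse = "/")
  }, character(1))
  unname(mapped[match(cells, u)])
}

#' Assemble a cross dataset
#'
#' The in-memory container tying together sample metadata, the locus table
#' and the per-sample haplotype calls of one cross.  Calls are stored as a
#' character matrix of canonical cells (`""` = missing, otherwise sorted
#' alleles joined by `"/"`) plus a parallel integer depth matrix, both with
#' loci in rows and samples in columns.
#'
#' @param samples Data frame with columns `sample_id`, `role` (one of
#'   F0_MALE, F0_FEMALE, F1_FEMALE, F2_POOL), `cross_id`, `wga` (logical)
#'   and `input_dna_ng` (numeric, may be NA).
#' @param loci Data frame with columns `locus_id` (unique) and `length_bp`.
#' @param alleles Character matrix (loci x samples) of canonical cells.
#' @param depth Integer matrix of the same shape.
#' @param truth Optional list with elements `genotypes` and `events`
#'   (simulations only).
#' @return An object of class `cross_dataset`.
#' @export
cross_dataset <- function(samples, loci, alleles, depth, truth = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  req <- c("sample_id", "role", "cross_id", "wga", "input_dna_ng")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(samples$role), ROLES)
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(samples[c("cross_id", "role")])
  if (any(dup)) {
    stop("more than one sample per role within a cross: ",
         paste(samples$sample_id[dup], collapse = ", "), call. = FALSE)
  }
  samples$expected_ploidy <- ifelse(samples$role == "F0_MALE", "1",
                             ifelse(samples$role == "F2_POOL", "POOL", "2"))
  if (anyDuplicated(loci$locus_id)) {
    stop("duplicated locus_id(s): ",
         paste(unique(loci$locus_id[duplicated(loci$locus_id)]),
               collapse = ", "), call. = FALSE)
  }
  alleles <- as.matrix(alleles)
  mode(alleles) <- "character"
  depth <- as.matrix(depth)
  mode(depth) <- "integer"
  if (!identical(dim(alleles), dim(depth)) ||
      nrow(alleles) != nrow(loci) || ncol(alleles) != nrow(samples)) {
    stop("call matrices must be n_loci x n_samples and congruent",
         call. = FALSE)
  }
  dimnames(alleles) <- dimnames(depth) <-
    list(loci$locus_id, samples$sample_id)
  if (any(depth < 0L, na.rm = TRUE) || anyNA(depth)) {
    stop("depths must be non-negative integers", call. = FALSE)
  }
  check_haplotype_lengths(alleles, loci$locus_id)
  ds <- structure(
    list(samples = samples, loci = loci, alleles = alleles, depth = depth,
         truth = truth),
    class = "cross_dataset"
  )
  ds
}

# All non-missing, non-consensus haplotype strings within a locus must have
# one common length (they are the same concatenated SNP columns).
check_haplotype_lengths <- function(alleles, locus_ids) {
  u <- unique(as.vector(alleles))
  lens <- lapply(u, function(cell) {
    if (!nzchar(cell)) return(integer())
    parts <- strsplit(cell, "/", fixed = TRUE)[[1L]]
    parts <- setdiff(parts, CONSENSUS_ALLELE)
    unique(nchar(parts))
  })
  names(lens) <- u
  bad <- character()
  for (i in seq_along(locus_ids)) {
    ll <- unique(unlist(lens[alleles[i, ]], use.names = FALSE))
    if (length(ll) > 1L) bad <- c(bad, locus_ids[i])
  }
  if (length(bad)) {
    stop("mixed haplotype lengths within locus/loci: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.cross_dataset <- function(x, ...) {
  cat("<cross_dataset> ", nrow(x$loci), " loci x ", nrow(x$samples),
      " samples (cross ", paste(unique(x$samples$cross_id), collapse = ","),
      ")\n", sep = "")
  cat("  roles: ", paste(x$samples$role, collapse = ", "), "\n", sep = "")
  miss <- sum(x$alleles == "")
  cat("  missing calls: ", miss, " (",
      round(100 * miss / length(x$alleles), 1), "%)",
      if (!is.null(x$truth)) "; truth labels attached", "\n", sep = "")
  invisible(x)
}

#' Read a haplotype matrix and its sample metadata
#'
#' Reads the tab-separated haplotype-matrix dialect written by
#' [write_haplotype_matrix()]: a header row
#' `locus_id<TAB>length<TAB>S1<TAB>S1.depth<TAB>...`, one row per locus,
#' cells being `-` (missing), `consensus` (monomorphic sentinel) or
#' haplotypes joined by `/` (e.g. `AG/GG`).  Depth travels in the
#' companion `<sample>.depth` columns so the file is self-contained for
#' the depth filter.
#'
#' @param path Path to the haplotype matrix.
#' @param metadata_path Path to the tab-separated sample metadata with
#'   header `sample_id role cross_id wga input_dna_ng`.
#' @return A [cross_dataset()].
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines(c("locus_id\tlength\tA1\tA1.depth",
#'              "L1\t109\tC/T\t21"), file.path(dir, "h.tsv"))
#' writeLines(c("sample_id\trole\tcross_id\twga\tinput_dna_ng",
#'              "A1\tF1_FEMALE\tc1\tTRUE\t0.35"), file.path(dir, "m.tsv"))
#' read_haplotype_matrix(file.path(dir, "h.tsv"), file.path(dir, "m.tsv"))
#' @export
read_haplotype_matrix <- function(path, metadata_path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- read_sample_metadata(metadata_path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty haplotype matrix: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 4L || header[1L] != "locus_id" ||
      header[2L] != "length") {
    stop("malformed header: expected 'locus_id<TAB>length<TAB><sample>",
         "<TAB><sample>.depth...'", call. = FALSE)
  }
  body <- header[-(1:2)]
  if (length(body) %% 2L != 0L) {
    stop("header must interleave <sample> and <sample>.depth columns",
         call. = FALSE)
  }
  sample_cols <- body[seq(1L, length(body), by = 2L)]
  depth_cols <- body[seq(2L, length(body), by = 2L)]
  if (!identical(depth_cols, paste0(sample_cols, ".depth"))) {
    stop("each sample column must be followed by its '.depth' companion",
         call. = FALSE)
  }
  unknown <- setdiff(sample_cols, meta$sample_id)
  if (length(unknown)) {
    stop("sample(s) in header absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ncol_expect <- length(header)
  nfield <- lengths(fields)
  ragged <- which(nfield[-1L] != ncol_expect) + 1L
  if (length(ragged)) {
    stop("ragged row(s) at line(s) ", paste(ragged, collapse = ", "),
         ": expected ", ncol_expect, " tab-separated fields", call. = FALSE)
  }
  rows <- fields[-1L]
  m <- matrix(unlist(rows, use.names = FALSE), ncol = ncol_expect,
              byrow = TRUE)
  locus_id <- m[, 1L]
  length_bp <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(length_bp) || any(length_bp <= 0L)) {
    stop("locus lengths must be positive integers", call. = FALSE)
  }
  idx_call <- 2L + seq(1L, length(body), by = 2L)
  idx_depth <- idx_call + 1L
  alleles <- matrix(canonicalize_cells(as.vector(m[, idx_call, drop = FALSE])),
                    nrow = nrow(m))
  depth <- suppressWarnings(
    matrix(as.integer(m[, idx_depth, drop = FALSE]), nrow = nrow(m)))
  if (anyNA(depth)) {
    stop("non-integer depth value(s) in ", path, call. = FALSE)
  }
  meta_used <- meta[match(sample_cols, meta$sample_id), , drop = FALSE]
  rownames(meta_used) <- NULL
  cross_dataset(
    samples = meta_used,
    loci = data.frame(locus_id = locus_id, length_bp = length_bp,
                      stringsAsFactors = FALSE),
    alleles = alleles, depth = depth
  )
}

#' Read a sample metadata table
#'
#' @param path Tab-separated file with header
#'   `sample_id role cross_id wga input_dna_ng`.
#' @return Data frame with an `expected_ploidy` column derived from the role.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) {
    stop("no such metadata file: ", path, call. = FALSE)
  }
  meta <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "role", "cross_id", "wga", "input_dna_ng")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  meta$wga <- as.logical(meta$wga)
  meta$input_dna_ng <- suppressWarnings(as.numeric(meta$input_dna_ng))
  if (any(!is.na(meta$input_dna_ng) & meta$input_dna_ng < 0)) {
    stop("input_dna_ng must be non-negative", call. = FALSE)
  }
  bad <- setdiff(unique(meta$role), ROLES)
  if (length(bad)) {
    stop("unknown role(s) in metadata: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  meta$expected_ploidy <- ifelse(meta$role == "F0_MALE", "1",
                          ifelse(meta$role == "F2_POOL", "POOL", "2"))
  meta
}

#' Filter loci on stack depth and completeness
#'
#' Retains exactly the loci at which (when `require_all = TRUE`) every
#' sample has a call and every non-missing call has depth at least
#' `min_depth` -- the retention rule used when comparing WGA'd and
#' control libraries.  The input is unchanged; kept/dropped counts are
#' attached as the `"filter_counts"` attribute.
#'
#' @param ds A [cross_dataset()].
#' @param min_depth Minimum stack depth (default 10).
#' @param require_all Require a call in every sample (default TRUE).
#' @return A new, possibly smaller, `cross_dataset`.
#' @examples
#' cfg <- sim_config(n_loci = 50, seed = 1)
#' ds <- simulate_cross(cfg)
#' kept <- filter_loci(ds, min_depth = 10)
#' attr(kept, "filter_counts")
#' @export
filter_loci <- function(ds, min_depth = 10L, require_all = TRUE) {
  stopifnot(inherits(ds, "cross_dataset"))
  min_depth <- as.integer(min_depth)
  if (is.na(min_depth) || min_depth < 0L) {
    stop("'min_depth' must be a non-negative integer", call. = FALSE)
  }
  present <- ds$alleles != ""
  deep_enough <- !present | ds$depth >= min_depth
  keep <- rowSums(!deep_enough) == 0L
  if (isTRUE(require_all)) keep <- keep & rowSums(!present) == 0L
  out <- subset_loci(ds, keep)
  attr(out, "filter_counts") <- c(kept = sum(keep), dropped = sum(!keep))
  out
}

subset_loci <- function(ds, keep) {
  truth <- ds$truth
  if (!is.null(truth)) {
    ids <- ds$loci$locus_id[keep]
    truth$genotypes <- truth$genotypes[truth$genotypes$locus_id %in% ids, ,
                                       drop = FALSE]
    truth$events <- truth$events[truth$events$locus_id %in% ids, ,
                                 drop = FALSE]
    rownames(truth$genotypes) <- rownames(truth$events) <- NULL
  }
  cross_dataset(
    samples = ds$samples,
    loci = ds$loci[keep, , drop = FALSE],
    alleles = ds$alleles[keep, , drop = FALSE],
    depth = ds$depth[keep, , drop = FALSE],
    truth = truth
  )
}

#' Write a haplotype matrix
#'
#' Serializes a [cross_dataset()] to the tab-separated dialect read by
#' [read_haplotype_matrix()].  Output is deterministic (alleles sorted
#' within cells, LF newlines), so two writes of the same dataset are
#' byte-identical and `read(write(ds))` reproduces alleles, depths and
#' missingness exactly.
#'
#' @param ds A [cross_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_haplotype_matrix <- function(ds, path) {
  stopifnot(inherits(ds, "cross_dataset"))
  sample_ids <- ds$samples$sample_id
  header <- c("locus_id", "length",
              as.vector(rbind(sample_ids, paste0(sample_ids, ".depth"))))
  cells <- ds$alleles
  cells[cells == ""] <- "-"
  cells[cells == CONSENSUS_ALLELE] <- "consensus"
  n <- nrow(cells)
  body <- matrix("", nrow = n, ncol = length(header))
  body[, 1L] <- ds$loci$locus_id
  body[, 2L] <- as.character(ds$loci$length_bp)
  body[, 2L + 2L * seq_along(sample_ids) - 1L] <- cells
  body[, 2L + 2L * seq_along(sample_ids)] <- as.character(ds$depth)
  lines <- c(paste(header, collapse = "\t"),
             apply(body, 1L, paste, collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a sample metadata table
#'
#' @param samples The `samples` data frame of a [cross_dataset()] (or any
#'   data frame with the metadata columns).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_metadata <- function(samples, path) {
  cols <- c("sample_id", "role", "cross_id", "wga", "input_dna_ng")
  df <- samples[, cols, drop = FALSE]
  lines <- c(paste(cols, collapse = "\t"),
             apply(df, 1L, function(r) paste(trimws(r), collapse = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Extract one haplotype call from a dataset
#'
#' @param ds A [cross_dataset()].
#' @param locus_id Locus identifier.
#' @param sample_id Sample identifier.
#' @return A [hap_call()].
#' @export
get_call <- function(ds, locus_id, sample_id) {
  stopifnot(inherits(ds, "cross_dataset"))
  cell <- ds$alleles[locus_id, sample_id]
  hap_call(if (nzchar(cell)) strsplit(cell, "/", fixed = TRUE)[[1L]]
           else character(),
           depth = ds$depth[locus_id, sample_id])
}
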