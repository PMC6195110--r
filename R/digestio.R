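#' Scan a nucleotide sequence for restriction-site motif matches
#'
#' Case-insensitive exact matching of the recognition motif (default
#' `CTGCAG`, the PstI site used to build RAD libraries); windows
#' containing any non-ACGT character never match, and overlapping matches
#' are all reported.
#'
#' @param sequence A nucleotide string (IUPAC letters accepted; ambiguous
#'   letters never match).
#' @param motif Recognition motif over A/C/G/T only; ambiguity codes are
#'   rejected.
#' @return Integer vector of 0-based match start positions.
#' @examples
#' scan_cut_sites("ACTGCAGT")   # 1
#' scan_cut_sites("CTNCAG")     # integer(0)
#' @export
scan_cut_sites <- function(sequence, motif = "CTGCAG") {
  check_motif(motif)
  if (inherits(sequence, "DNAString")) {
    subj <- sequence
  } else {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (!nzchar(sequence)) return(integer())
    subj <- tryCatch(Biostrings::DNAString(toupper(sequence)),
                     error = function(e) {
                       stop("sequence contains non-nucleotide characters: ",
                            conditionMessage(e), call. = FALSE)
                     })
  }
  if (length(subj) < nchar(motif)) return(integer())
  hits <- Biostrings::matchPattern(Biostrings::DNAString(motif), subj,
                                   fixed = TRUE)
  as.integer(Biostrings::start(hits)) - 1L
}

check_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif)) {
    stop("'motif' must be a single non-empty string", call. = FALSE)
  }
  if (!grepl("^[ACGTacgt]+$", motif)) {
    stop("unsupported motif '", motif,
         "': only unambiguous A/C/G/T motifs are supported", call. = FALSE)
  }
  invisible(toupper(motif))
}

#' In-silico restriction digestion of a genome FASTA
#'
#' Counts recognition-site matches per sequence record and totals them.
#' Each cut site flanks two sequenceable RAD tags, so `n_tags` is exactly
#' `2 * n_sites`; no correction is applied for sites near chromosome
#' ends.
#'
#' @param path FASTA file (multi-record and wrapped lines supported;
#'   gzip-compressed input accepted).
#' @param motif Recognition motif (default PstI, `CTGCAG`).
#' @param cut_offset 0-based offset of the cut position within the motif
#'   (default 5: `CTGCA^G`); recorded in the report, not used in counts.
#' @return An object of class `digest_report`: a list with `per_sequence`
#'   (data frame `seq_id`, `length`, `n_sites`), `n_sites`, `n_tags`,
#'   `motif` and `cut_offset`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "AACTGCAGTT", ">chr2", "AAAA"), fa)
#' digest_fasta(fa)
#' @export
digest_fasta <- function(path, motif = "CTGCAG", cut_offset = 5L) {
  motif <- check_motif(motif)
  if (!file.exists(path)) stop("no such FASTA file: ", path, call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop("malformed FASTA '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (length(seqs) == 0L) {
    stop("malformed FASTA '", path, "': no records", call. = FALSE)
  }
  counts <- Biostrings::vcountPattern(motif, seqs, fixed = TRUE)
  per_seq <- data.frame(
    seq_id = sub("\\s.*$", "", names(seqs)),
    length = Biostrings::width(seqs),
    n_sites = as.integer(counts),
    stringsAsFactors = FALSE
  )
  n_sites <- sum(per_seq$n_sites)
  structure(
    list(per_sequence = per_seq, n_sites = n_sites,
         n_tags = expected_tag_count(n_sites), motif = motif,
         cut_offset = as.integer(cut_offset)),
    class = "digest_report"
  )
}

#' RAD tags expected from a cut-site count
#'
#' Every restriction site yields one sequenceable tag on each side, so a
#' genome with `n_sites` recognition sites is expected to produce
#' `2 * n_sites` RAD tags.
#'
#' @param n_sites Non-negative integer count of cut sites.
#' @return `2 * n_sites` as an integer (double if it would overflow).
#' @examples
#' expected_tag_count(59433)   # 118866
#' @export
expected_tag_count <- function(n_sites) {
  n_sites <- as.numeric(n_sites)
  if (length(n_sites) != 1L || is.na(n_sites) || n_sites < 0 ||
      n_sites != trunc(n_sites)) {
    stop("'n_sites' must be a single non-negative integer", call. = FALSE)
  }
  out <- 2 * n_sites
  if (out <= .Machine$integer.max) as.integer(out) else out
}

#' @export
print.digest_report <- function(x, ...) {
  cat("<digest_report> motif ", x$motif, " (cut offset ", x$cut_offset,
      "): ", nrow(x$per_sequence), " sequence(s), ", x$n_sites,
      " sites, ", x$n_tags, " tags\n", sep = "")
  invisible(x)
}

#' Write a digestion report
#'
#' Writes the per-sequence table as TSV and the totals as JSON.
#'
#' @param report A [digest_fasta()] report.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_digest_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "digest_report"))
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, open = "wb")
    lines <- c("seq_id\tlength\tn_sites",
               sprintf("%s\t%d\t%d", report$per_sequence$seq_id,
                       report$per_sequence$length,
                       report$per_sequence$n_sites))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    close(con)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(motif = report$motif, cut_offset = report$cut_offset,
           n_sites = report$n_sites, n_tags = report$n_tags),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
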