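# Shared fixtures and independent oracles for the test suite.

# --- worked genotype examples (quartets with their published category) ------
worked_quartets <- function() {
  rows <- list(
    list("A/G",  "G",     "G",     "G",     "F0_MALE"),
    list("TG",   "GA",    "GA",    "GA",    "F0_MALE"),
    list("C",    "C/T",   "C",     "C",     "F0_FEMALE"),
    list("A",    "A",     "A/G",   "A/G",   "F0_FEMALE"),
    list("G",    "A",     "G",     "G",     "F0_FEMALE"),
    list("C",    "C",     "A/C",   "C",     "F1_FEMALE"),
    list("T",    "C/T",   "C",     "C/T",   "F1_FEMALE"),
    list("GG",   "AG/GG", "GG/GT", "AG/GG", "F1_FEMALE"),
    list("T",    "A",     "A",     "A/T",   "F1_FEMALE"),
    list("T",    "T",     "T",     "C/T",   "F2_POOL"),
    list("A",    "A/G",   "A/G",   "A",     "F2_POOL"),
    list("AA",   "AA",    "AA",    "CC",    "F2_POOL"),
    list("C",    "T",     "C/T",   "C",     "F2_POOL"),
    list("C/G",  "C/G",   "C/G",   "C",     "COMBINATION")
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(m = r[[1]], f0 = r[[2]], f1 = r[[3]], pool = r[[4]],
               culprit = r[[5]], stringsAsFactors = FALSE)
  }))
}

# F1-versus-pool difference patterns with their published labels.
pair_patterns <- function() {
  data.frame(
    f1   = c("A",   "A/B",   "A", "A/B", "A/B", "C",   "A/C"),
    pool = c("A/B", "A/B/C", "B", "A",   "C",   "A/B", "A/B"),
    label = c("EXPLAINED_BY_SETUP", "EXPLAINED_BY_SETUP",
              "UNEXPLAINED", "UNEXPLAINED", "UNEXPLAINED",
              "UNEXPLAINED", "UNEXPLAINED"),
    stringsAsFactors = FALSE
  )
}

# --- brute-force attribution oracle ----------------------------------------
# Searches, for each role, EVERY non-empty allele subset of the supplied
# alphabet (which may contain alleles never observed in the quartet) and
# applies the published decision policy: minimum symmetric-difference cost,
# then prefer removal-only fixes on cross-role ties, else COMBINATION.
all_subsets <- function(alphabet) {
  out <- list()
  for (sz in seq_along(alphabet)) {
    cmb <- combn(alphabet, sz)
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- cmb[, j]
  }
  out
}

oracle_attribute <- function(m, f0, f1, pool, alphabet) {
  roles <- c("F0_MALE", "F0_FEMALE", "F1_FEMALE", "F2_POOL")
  obs <- list(F0_MALE = sort(unique(strsplit(m, "/")[[1]])),
              F0_FEMALE = sort(unique(strsplit(f0, "/")[[1]])),
              F1_FEMALE = sort(unique(strsplit(f1, "/")[[1]])),
              F2_POOL = sort(unique(strsplit(pool, "/")[[1]])))
  cand <- all_subsets(alphabet)
  fixes <- list()
  for (role in roles) {
    for (s in cand) {
      s <- sort(s)
      if (identical(s, obs[[role]])) next
      q <- obs
      q[[role]] <- s
      ok <- radmendel::quartet_consistent(q$F0_MALE, q$F0_FEMALE,
                                          q$F1_FEMALE, q$F2_POOL)
      if (!ok) next
      fixes[[length(fixes) + 1L]] <- list(
        role = role,
        cost = length(setdiff(s, obs[[role]])) +
               length(setdiff(obs[[role]], s)),
        removal = all(s %in% obs[[role]]),
        added = length(setdiff(s, obs[[role]]))
      )
    }
  }
  if (!length(fixes)) {
    return(list(culprit = "COMBINATION", dropout_candidate = NA_character_,
                fix_cost = NA_integer_))
  }
  costs <- vapply(fixes, `[[`, numeric(1), "cost")
  best <- fixes[costs == min(costs)]
  roles_best <- unique(vapply(best, `[[`, character(1), "role"))
  if (length(roles_best) > 1L) {
    rem <- best[vapply(best, `[[`, logical(1), "removal")]
    rroles <- unique(vapply(rem, `[[`, character(1), "role"))
    if (length(rem) == 0L || length(rroles) > 1L) {
      return(list(culprit = "COMBINATION", dropout_candidate = NA_character_,
                  fix_cost = as.integer(min(costs))))
    }
    best <- rem
    roles_best <- rroles
  }
  rem <- best[vapply(best, `[[`, logical(1), "removal")]
  chosen <- if (length(rem)) rem[[1L]] else best[[1L]]
  dropout <- NA_character_
  if (roles_best %in% c("F0_FEMALE", "F1_FEMALE") && !chosen$removal &&
      chosen$added == 1L && chosen$cost == 1L) {
    dropout <- roles_best
  }
  list(culprit = roles_best, dropout_candidate = dropout,
       fix_cost = as.integer(chosen$cost))
}

# --- naive digestion oracle -------------------------------------------------
# Character-by-character O(n*m) scan; windows with any non-ACGT letter
# never match.  0-based positions, overlapping matches reported.
naive_scan <- function(sequence, motif) {
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  n <- nchar(sequence)
  m <- nchar(motif)
  if (n < m) return(integer())
  hits <- integer()
  for (i in seq_len(n - m + 1L)) {
    window <- substr(sequence, i, i + m - 1L)
    if (!grepl("^[ACGT]+$", window)) next
    if (window == motif) hits <- c(hits, i - 1L)
  }
  hits
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", x), "")[[1]]),
        collapse = "")
}

# --- small file fixtures -----------------------------------------------------
write_toy_matrix <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  hap <- file.path(dir, "haplotypes.tsv")
  meta <- file.path(dir, "samples.tsv")
  writeLines(c(
    "locus_id\tlength\tM1\tM1.depth\tF1\tF1.depth\tD1\tD1.depth\tP1\tP1.depth",
    "L1\t109\tC\t20\tC/T\t15\tC\t12\tC/T\t30",
    "L2\t109\tconsensus\t25\tconsensus\t25\tconsensus\t25\tconsensus\t25",
    "L3\t109\tg\t9\ta/g\t18\t-\t0\tA/G\t22"
  ), hap)
  writeLines(c(
    "sample_id\trole\tcross_id\twga\tinput_dna_ng",
    "M1\tF0_MALE\tc1\tTRUE\t1.5",
    "F1\tF0_FEMALE\tc1\tTRUE\t0.39",
    "D1\tF1_FEMALE\tc1\tTRUE\t0.35",
    "P1\tF2_POOL\tc1\tFALSE\tNA"
  ), meta)
  list(hap = hap, meta = meta, dir = dir)
}

# Config used when a test needs noise-free Mendelian data quickly.
quiet_config <- function(n_loci, seed, ...) {
  sim_config(n_loci = n_loci, seed = seed, p_dropout = 0, p_spurious = 0,
             p_missing = 0, ...)
}
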