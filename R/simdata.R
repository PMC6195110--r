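#' Simulation configuration for a haplodiploid cross
#'
#' Bundles every parameter of the forward simulator with a seed.  The
#' defaults describe the benchmark cross design this package audits: one
#' haploid F0 male crossed to one diploid F0 female, several virgin F1
#' daughters each leaving haploid sons, all sons pooled into a single
#' WGA-free F2 library while the F0 pair and one F1 female are
#' whole-genome amplified before library construction.
#'
#' @param n_loci Number of RAD loci to simulate.
#' @param locus_length_bp Locus length in bp (default 109, the tag length
#'   of the benchmark libraries).
#' @param hap_length Number of concatenated variable positions per locus
#'   haplotype string (default 2; printed examples use 1-2 bases).
#' @param n_f1_females Number of F1 daughters contributing sons to the
#'   pool (default 20; the benchmark crosses reared up to 38).
#' @param n_f2_males Number of pooled F2 sons (default 933, the pool size
#'   of the most deeply sampled cross).
#' @param maternal_het_rate Probability the F0 female is heterozygous at
#'   a locus (default 0.012, calibrated so the noise-free fraction of
#'   heterozygous-identical F1-vs-pool loci matches the benchmark's 1.3%).
#' @param novel_paternal_rate Probability the F0 male allele differs from
#'   both maternal alleles (default 0.007; with the default
#'   `maternal_het_rate` this leaves about 0.6% of noise-free loci showing
#'   pool alleles absent from the genotyped F1 female).
#' @param p_dropout Per-heterozygous-call probability that WGA drops one
#'   allele.  Scalar, or a vector named by WGA'd role
#'   (`F0_MALE`, `F0_FEMALE`, `F1_FEMALE`).  Default 0.1.
#' @param p_spurious Per-call probability that WGA/PCR/sequencing error
#'   substitutes a mutated allele into a WGA'd call.  Scalar or named as
#'   for `p_dropout`.  Default 0.003.
#' @param p_missing Per-sample-locus probability that a WGA'd call is
#'   missing.  Scalar or named.  Default 0.02.
#' @param depth_mean,depth_dispersion Mean and dispersion (size) of the
#'   negative-binomial stack-depth distribution (defaults 40 and 8).
#' @param pool_detection_min Minimum number of F2 sons that must carry an
#'   allele for it to appear in the pool call (default 1).
#' @param dropout_dose Optional dose-dependent dropout model: a numeric
#'   vector `c(rate_at_1ng, slope_per_log2_ng)`.  When given, the dropout
#'   rate of a WGA'd role is `rate_at_1ng + slope_per_log2_ng *
#'   log2(input_dna_ng)`, clamped to `[0, 1]`, emulating the suspected
#'   dependence of WGA bias on input DNA mass.  Overrides `p_dropout`.
#' @param input_dna_ng Named vector of input DNA masses (ng) for the
#'   WGA'd samples; defaults to the benchmark cross (male 1.5 ng, F0
#'   female 0.39 ng, F1 female 0.35 ng).
#' @param cross_id Cross identifier written into the sample metadata.
#' @param seed Integer seed; a fixed seed yields byte-identical datasets.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(n_loci = 100, seed = 1)
#' @export
sim_config <- function(n_loci,
                       locus_length_bp = 109L,
                       hap_length = 2L,
                       n_f1_females = 20L,
                       n_f2_males = 933L,
                       maternal_het_rate = 0.012,
                       novel_paternal_rate = 0.007,
                       p_dropout = 0.1,
                       p_spurious = 0.003,
                       p_missing = 0.02,
                       depth_mean = 40,
                       depth_dispersion = 8,
                       pool_detection_min = 1L,
                       dropout_dose = NULL,
                       input_dna_ng = c(F0_MALE = 1.5, F0_FEMALE = 0.39,
                                        F1_FEMALE = 0.35),
                       cross_id = "sim",
                       seed = 1L) {
  cfg <- list(
    n_loci = as.integer(n_loci), locus_length_bp = as.integer(locus_length_bp),
    hap_length = as.integer(hap_length),
    n_f1_females = as.integer(n_f1_females),
    n_f2_males = as.integer(n_f2_males),
    maternal_het_rate = maternal_het_rate,
    novel_paternal_rate = novel_paternal_rate,
    p_dropout = p_dropout, p_spurious = p_spurious, p_missing = p_missing,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    pool_detection_min = as.integer(pool_detection_min),
    dropout_dose = dropout_dose,
    input_dna_ng = input_dna_ng, cross_id = as.character(cross_id),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("n_loci", "locus_length_bp", "hap_length", "n_f1_females",
           "n_f2_males", "pool_detection_min")
  for (nm in pos) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop("'", nm, "' must be a positive integer", call. = FALSE)
    }
  }
  if (cfg$n_f2_males < cfg$n_f1_females) {
    stop("'n_f2_males' must be at least 'n_f1_females' so that every F1 ",
         "female can leave sons", call. = FALSE)
  }
  probs <- c("maternal_het_rate", "novel_paternal_rate", "p_dropout",
             "p_spurious", "p_missing")
  for (nm in probs) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1)) {
      stop("'", nm, "' must be probability/probabilities in [0, 1]",
           call. = FALSE)
    }
    if (length(v) > 1L && !all(names(v) %in% WGA_ROLES)) {
      stop("per-role '", nm, "' must be named by WGA'd role", call. = FALSE)
    }
  }
  if (!is.null(cfg$dropout_dose) &&
      (!is.numeric(cfg$dropout_dose) || length(cfg$dropout_dose) != 2L)) {
    stop("'dropout_dose' must be c(rate_at_1ng, slope_per_log2_ng)",
         call. = FALSE)
  }
  if (cfg$depth_mean <= 0 || cfg$depth_dispersion <= 0) {
    stop("depth parameters must be positive", call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("'seed' must be an integer", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_loci, " loci, ", x$n_f1_females,
      " F1 females, ", x$n_f2_males, " pooled F2 males, seed ", x$seed,
      "\n  noise: dropout ", paste(signif(x$p_dropout, 3), collapse = "/"),
      ", spurious ", paste(signif(x$p_spurious, 3), collapse = "/"),
      ", missing ", paste(signif(x$p_missing, 3), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Unknown keys are rejected; omitted keys take [sim_config()] defaults.
#'
#' @param path YAML file of `sim_config` fields.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("p_dropout", "p_spurious", "p_missing", "input_dna_ng")) {
    if (is.list(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(sim_config, vals)
}

# Per-role noise rate lookup: scalar rates apply to every WGA'd role,
# named vectors fall back to 0 for unnamed roles.
role_rate <- function(p, role) {
  if (length(p) == 1L && is.null(names(p))) return(unname(p))
  if (role %in% names(p)) return(unname(p[[role]])) else return(0)
}

dropout_rate_for <- function(cfg, role) {
  if (!is.null(cfg$dropout_dose)) {
    ng <- cfg$input_dna_ng[[role]]
    r <- cfg$dropout_dose[1L] + cfg$dropout_dose[2L] * log2(ng)
    return(min(max(r, 0), 1))
  }
  role_rate(cfg$p_dropout, role)
}

#' Substitute one base of a haplotype string
#'
#' Returns a string equal to the input at all but exactly one position,
#' where the base is replaced by a different one drawn uniformly.  Uses
#' the session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param allele Non-empty haplotype string over A/C/G/T.
#' @return A mutated haplotype string at Hamming distance 1.
#' @examples
#' set.seed(1); allele_mutant("GA")
#' @export
allele_mutant <- function(allele) {
  if (!is.character(allele) || length(allele) != 1L || !nzchar(allele)) {
    stop("'allele' must be a single non-empty string", call. = FALSE)
  }
  mutate_haps(allele)
}

# Vectorized single-base substitution.  All strings must share one length.
mutate_haps <- function(haps) {
  bases <- c("A", "C", "G", "T")
  L <- unique(nchar(haps))
  stopifnot(length(L) == 1L)
  n <- length(haps)
  pos <- if (L == 1L) rep(1L, n) else sample.int(L, n, replace = TRUE)
  cur <- substr(haps, pos, pos)
  # row = current base, columns = the three alternatives
  alt <- matrix(c("C", "G", "T",
                  "A", "G", "T",
                  "A", "C", "T",
                  "A", "C", "G"), nrow = 4L, byrow = TRUE)
  pick <- sample.int(3L, n, replace = TRUE)
  new <- alt[cbind(match(cur, bases), pick)]
  substr(haps, pos, pos) <- new
  haps
}

#' Simulate a haplodiploid cross with WGA artifacts
#'
#' Forward-simulates one cross under arrhenotokous inheritance: per locus
#' the F0 male carries one allele and the F0 female two (heterozygous with
#' `maternal_het_rate`); every F1 daughter inherits the paternal allele
#' plus one maternal allele chosen uniformly; each F2 son is assigned an
#' F1 mother uniformly and inherits one of her two alleles uniformly; the
#' pool call is the set of alleles carried by at least
#' `pool_detection_min` sons.  Exactly one F1 female (the first) is
#' emitted as the genotyped sample.  WGA noise -- allele dropout on
#' heterozygous calls, spurious single-base substitution, missing calls --
#' is applied only to the F0 male, F0 female and genotyped F1 female; the
#' pool is the amplification-free control.  Stack depths are drawn from a
#' negative binomial.  Truth labels (pre-noise genotypes and injected
#' events) are attached.
#'
#' All randomness flows through one RNG stream seeded from `cfg$seed` in a
#' fixed internal draw order, so a fixed config reproduces the dataset
#' byte-for-byte.
#'
#' @param cfg A [sim_config()].
#' @return A [cross_dataset()] with four samples (`F0_male`, `F0_female`,
#'   `F1_female`, `F2_pool`) and a `truth` component.
#' @examples
#' ds <- simulate_cross(sim_config(n_loci = 200, seed = 42))
#' ds
#' @export
simulate_cross <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_loci
  k <- cfg$n_f1_females
  L <- cfg$hap_length
  bases <- c("A", "C", "G", "T")

  # -- founder genotypes ----------------------------------------------------
  # draw order: ancestral haplotypes, maternal het flags, maternal variant,
  # paternal novelty flags, paternal allele, F1 maternal choices, F2
  # mother/allele segregation, noise flags per role, depths.
  anc_mat <- matrix(sample(bases, n * L, replace = TRUE), nrow = n)
  anc <- do.call(paste0, as.data.frame(anc_mat, stringsAsFactors = FALSE))
  het <- runif(n) < cfg$maternal_het_rate
  variant <- mutate_haps(anc)
  mat1 <- anc
  mat2 <- ifelse(het, variant, anc)

  novel <- runif(n) < cfg$novel_paternal_rate
  pat <- mutate_haps(anc)
  clash <- novel & (pat == mat2)
  while (any(clash)) {           # redraw until the novel allele is novel
    pat[clash] <- mutate_haps(anc[clash])
    clash <- novel & (pat == mat2)
  }
  inherit_pick <- runif(n) < 0.5
  pat[!novel] <- ifelse(inherit_pick[!novel], mat1[!novel], mat2[!novel])

  # -- F1 daughters and the F2 pool ----------------------------------------
  # ch[j, i]: does F1 female j carry maternal allele 1 at locus i?
  ch <- matrix(runif(k * n) < 0.5, nrow = k)
  f1_mat <- ifelse(ch[1L, ], mat1, mat2)   # the genotyped daughter
  sons <- rmultinom(n, size = cfg$n_f2_males, prob = rep(1 / k, k))
  k_pat <- matrix(rbinom(k * n, as.vector(sons), 0.5), nrow = k)
  k_mat <- sons - k_pat
  cnt_pat <- colSums(k_pat)
  cnt_mat1 <- colSums(k_mat * ch)
  cnt_mat2 <- colSums(k_mat * !ch)

  pool_true <- character(n)
  pmin_ <- cfg$pool_detection_min
  for (i in seq_len(n)) {
    al <- c(pat[i], mat1[i], mat2[i])
    cnts <- c(cnt_pat[i], cnt_mat1[i], cnt_mat2[i])
    tot <- tapply(cnts, al, sum)
    pool_true[i] <- paste(sort(names(tot)[tot >= pmin_]), collapse = "/")
  }

  true_calls <- list(
    F0_MALE = pat,
    F0_FEMALE = join_pair(mat1, mat2),
    F1_FEMALE = join_pair(pat, f1_mat),
    F2_POOL = pool_true
  )

  # -- WGA noise on the amplified samples -----------------------------------
  obs <- true_calls
  events <- list()
  for (role in WGA_ROLES) {
    p_drop <- dropout_rate_for(cfg, role)
    p_spur <- role_rate(cfg$p_spurious, role)
    p_miss <- role_rate(cfg$p_missing, role)
    call <- obs[[role]]
    is_het <- grepl("/", call, fixed = TRUE)

    drop_flag <- runif(n) < p_drop & is_het
    drop_first <- runif(n) < 0.5
    if (any(drop_flag)) {
      parts <- strsplit(call[drop_flag], "/", fixed = TRUE)
      kept <- mapply(function(p, first) if (first) p[1L] else p[2L],
                     parts, drop_first[drop_flag])
      call[drop_flag] <- kept
      events[[length(events) + 1L]] <- data.frame(
        locus_id = locus_ids(n)[drop_flag], role = role, event = "DROPOUT",
        stringsAsFactors = FALSE)
    }

    spur_flag <- runif(n) < p_spur
    spur_slot <- runif(n) < 0.5
    if (any(spur_flag)) {
      idx <- which(spur_flag)
      parts <- strsplit(call[idx], "/", fixed = TRUE)
      mutated <- vapply(seq_along(idx), function(j) {
        p <- parts[[j]]
        slot <- if (length(p) == 1L) 1L else if (spur_slot[idx[j]]) 1L else 2L
        p[slot] <- mutate_haps(p[slot])
        paste(sort(unique(p)), collapse = "/")
      }, character(1))
      call[idx] <- mutated
      events[[length(events) + 1L]] <- data.frame(
        locus_id = locus_ids(n)[idx], role = role, event = "SPURIOUS",
        stringsAsFactors = FALSE)
    }

    miss_flag <- runif(n) < p_miss
    if (any(miss_flag)) {
      call[miss_flag] <- ""
      events[[length(events) + 1L]] <- data.frame(
        locus_id = locus_ids(n)[miss_flag], role = role, event = "MISSING",
        stringsAsFactors = FALSE)
    }
    obs[[role]] <- call
  }

  depth <- matrix(
    rnbinom(4L * n, size = cfg$depth_dispersion, mu = cfg$depth_mean),
    nrow = n)
  alleles <- cbind(obs$F0_MALE, obs$F0_FEMALE, obs$F1_FEMALE, obs$F2_POOL)
  depth[alleles == ""] <- 0L

  ids <- locus_ids(n)
  samples <- data.frame(
    sample_id = c("F0_male", "F0_female", "F1_female", "F2_pool"),
    role = ROLES,
    cross_id = cfg$cross_id,
    wga = c(TRUE, TRUE, TRUE, FALSE),
    input_dna_ng = c(cfg$input_dna_ng[["F0_MALE"]],
                     cfg$input_dna_ng[["F0_FEMALE"]],
                     cfg$input_dna_ng[["F1_FEMALE"]], NA_real_),
    stringsAsFactors = FALSE
  )
  truth <- list(
    genotypes = data.frame(
      locus_id = ids,
      F0_MALE = true_calls$F0_MALE, F0_FEMALE = true_calls$F0_FEMALE,
      F1_FEMALE = true_calls$F1_FEMALE, F2_POOL = true_calls$F2_POOL,
      stringsAsFactors = FALSE),
    events = if (length(events)) {
      ev <- do.call(rbind, events)
      ev[order(ev$locus_id, ev$role, ev$event), , drop = FALSE]
    } else {
      data.frame(locus_id = character(), role = character(),
                 event = character(), stringsAsFactors = FALSE)
    }
  )
  rownames(truth$events) <- NULL
  cross_dataset(
    samples = samples,
    loci = data.frame(locus_id = ids, length_bp = cfg$locus_length_bp,
                      stringsAsFactors = FALSE),
    alleles = alleles, depth = depth, truth = truth
  )
}

locus_ids <- function(n) sprintf("L%05d", seq_len(n))

join_pair <- function(a, b) {
  ifelse(a == b, a,
         paste(pmin(a, b), pmax(a, b), sep = "/"))
}

#' Write simulation truth labels
#'
#' Serializes the truth component of a simulated dataset as a
#' tab-separated sidecar: pre-noise genotypes per role plus the injected
#' WGA events, one `role:event` token list per locus.
#'
#' @param ds A simulated [cross_dataset()] carrying truth labels.
#' @param path Output path (conventionally `<prefix>.truth.tsv`).
#' @return Invisibly, `path`.
#' @export
write_truth_labels <- function(ds, path) {
  stopifnot(inherits(ds, "cross_dataset"))
  if (is.null(ds$truth)) stop("dataset carries no truth labels", call. = FALSE)
  g <- ds$truth$genotypes
  ev <- ds$truth$events
  tok <- vapply(g$locus_id, function(id) {
    rows <- ev[ev$locus_id == id, , drop = FALSE]
    if (!nrow(rows)) "." else
      paste(paste0(rows$role, ":", rows$event), collapse = ";")
  }, character(1))
  out <- cbind(g, events = tok)
  lines <- c(paste(names(out), collapse = "\t"),
             apply(out, 1L, paste, collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
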