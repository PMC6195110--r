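#' @name mendel
#' @title Haplodiploid Mendelian-consistency classification
#' @description
#' The classifiers compare haplotype calls of a genotyped F1 female, her
#' parents (haploid F0 male, diploid F0 female) and the pool of all F2
#' sons of the F1 generation against the expectations set by arrhenotokous
#' inheritance.  Calls may be given as [hap_call()] objects, character
#' vectors of alleles, or single `"A/G"`-style strings.
NULL

# Coerce any accepted call representation to a sorted allele vector.
call_alleles <- function(x) {
  if (inherits(x, "hap_call")) return(x$alleles)
  x <- as.character(x)
  x <- unlist(strsplit(x, "/", fixed = TRUE), use.names = FALSE)
  x <- toupper(x[!is.na(x) & nzchar(x)])
  sort(unique(x))
}

require_nonmissing <- function(...) {
  calls <- list(...)
  empty <- vapply(calls, function(a) length(a) == 0L, logical(1))
  if (any(empty)) {
    stop("missing call(s) for: ",
         paste(names(calls)[empty], collapse = ", "),
         "; filter loci (filter_loci) before classification", call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify one F1-versus-pool locus
#'
#' Compares the allele set of the genotyped F1 female with that of the F2
#' pool.  Because the pool contains sons of *all* F1 females while only
#' one F1 female is genotyped, extra pool alleles are expected
#' (`EXPLAINED_BY_SETUP`); an F1 allele absent from the pool is not
#' (`UNEXPLAINED`).
#'
#' @param f1,pool Haplotype calls (see [mendel]); both must be non-missing.
#' @return One of `"IDENTICAL_HOM"`, `"IDENTICAL_HET"`,
#'   `"EXPLAINED_BY_SETUP"`, `"UNEXPLAINED"`.
#' @examples
#' classify_pair("A", "A/B")      # extra pool allele from unsampled sisters
#' classify_pair("A/B", "A")      # pool lacks an F1 allele: unexplained
#' @export
classify_pair <- function(f1, pool) {
  f1 <- call_alleles(f1)
  pool <- call_alleles(pool)
  require_nonmissing(f1 = f1, pool = pool)
  if (identical(f1, pool)) {
    return(if (length(f1) == 1L) "IDENTICAL_HOM" else "IDENTICAL_HET")
  }
  if (all(f1 %in% pool)) return("EXPLAINED_BY_SETUP")
  "UNEXPLAINED"
}

# Core consistency predicate on plain allele vectors (no coercion).
#
#   C1  the F0 male is haploid;
#   C2  the F0 and F1 females carry at most two alleles;
#   C3  the F1 female is {paternal} + one maternal allele (a homozygous
#       F1 call h requires h = male allele and h in the F0 female);
#   C4  every pool allele descends from the founders ({m} union f0);
#   C5  the genotyped F1 female's alleles reach the pool via her sons;
#   C6  (pool_complete) every founder allele appears in the pool -- the
#       pool of all F2 sons is treated as the reference against which
#       F0/F1 alleles are corroborated.
quartet_ok <- function(m, f0, f1, pool, pool_complete = TRUE) {
  if (length(m) != 1L) return(FALSE)                       # C1
  if (length(f0) > 2L || length(f1) > 2L) return(FALSE)    # C2
  if (length(f1) == 1L) {                                  # C3
    if (f1 != m || !(f1 %in% f0)) return(FALSE)
  } else {
    if (!(m %in% f1)) return(FALSE)
    if (!all(setdiff(f1, m) %in% f0)) return(FALSE)
  }
  founders <- unique(c(m, f0))
  if (!all(pool %in% founders)) return(FALSE)              # C4
  if (!all(f1 %in% pool)) return(FALSE)                    # C5
  if (pool_complete && !all(founders %in% pool)) return(FALSE) # C6
  TRUE
}

#' Test a four-sample quartet for Mendelian consistency
#'
#' A locus is consistent when the haploid/diploid ploidies hold, the F1
#' female's genotype is one paternal plus one maternal allele, every pool
#' allele traces back to the founders, the genotyped F1 female's alleles
#' are present in the pool, and (with `pool_complete = TRUE`, the default)
#' every founder allele is corroborated by the pool of F2 sons.  The last
#' check treats the WGA-free pool as the reference: it assumes families
#' large enough that every founder allele segregates into at least one
#' son, which holds with high probability for pools of hundreds of males
#' from ten or more F1 females.
#'
#' @param m,f0,f1,pool Haplotype calls for the F0 male, F0 female,
#'   genotyped F1 female and F2 pool; all non-missing.
#' @param pool_complete Require founder alleles to appear in the pool.
#' @return `TRUE` or `FALSE`.
#' @examples
#' quartet_consistent("C", "C", "C", "C")        # monomorphic locus
#' quartet_consistent("A/G", "G", "G", "G")      # diploid male call
#' @export
quartet_consistent <- function(m, f0, f1, pool, pool_complete = TRUE) {
  m <- call_alleles(m); f0 <- call_alleles(f0)
  f1 <- call_alleles(f1); pool <- call_alleles(pool)
  require_nonmissing(m = m, f0 = f0, f1 = f1, pool = pool)
  quartet_ok(m, f0, f1, pool, pool_complete)
}

# Candidate replacement calls for a role, drawn from allele universe U:
# singletons for the haploid male, singletons and pairs for diploid
# females, every non-empty subset for the pool.
role_candidates <- function(role, U) {
  singles <- as.list(U)
  if (role == "F0_MALE") return(singles)
  pairs <- if (length(U) >= 2L) {
    cmb <- combn(U, 2L)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  } else list()
  if (role %in% c("F0_FEMALE", "F1_FEMALE")) return(c(singles, pairs))
  subsets <- list()
  for (sz in seq_along(U)) {
    cmb <- combn(U, sz)
    subsets <- c(subsets,
                 lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  subsets
}

# Enumerate consistent single-role replacements.  Shared by the public
# attribution and (with a caller-supplied universe) the brute-force
# oracle used in the tests.
enumerate_fixes <- function(obs, U, pool_complete = TRUE) {
  fixes <- list()
  for (role in ROLES) {
    o <- obs[[role]]
    for (cand in role_candidates(role, U)) {
      cand <- sort(cand)
      if (identical(cand, o)) next
      repl <- obs
      repl[[role]] <- cand
      if (!quartet_ok(repl$F0_MALE, repl$F0_FEMALE, repl$F1_FEMALE,
                      repl$F2_POOL, pool_complete)) next
      fixes[[length(fixes) + 1L]] <- list(
        role = role,
        replacement = cand,
        cost = length(setdiff(cand, o)) + length(setdiff(o, cand)),
        removal_only = all(cand %in% o),
        n_added = length(setdiff(cand, o))
      )
    }
  }
  fixes
}

# Shared decision policy: minimum cost, then prefer fixes that only
# remove alleles (blaming an observed spurious allele over positing
# dropout elsewhere); unresolved ties across roles give COMBINATION.
decide_culprit <- function(fixes) {
  if (!length(fixes)) {
    return(list(culprit = "COMBINATION", dropout_candidate = NA_character_,
                fix_cost = NA_integer_))
  }
  costs <- vapply(fixes, `[[`, numeric(1), "cost")
  best <- fixes[costs == min(costs)]
  roles <- unique(vapply(best, `[[`, character(1), "role"))
  if (length(roles) > 1L) {
    removals <- Filter(function(f) f$removal_only, best)
    if (!length(removals)) {
      return(list(culprit = "COMBINATION",
                  dropout_candidate = NA_character_,
                  fix_cost = as.integer(min(costs))))
    }
    rroles <- unique(vapply(removals, `[[`, character(1), "role"))
    if (length(rroles) > 1L) {
      return(list(culprit = "COMBINATION",
                  dropout_candidate = NA_character_,
                  fix_cost = as.integer(min(costs))))
    }
    best <- removals
    roles <- rroles
  }
  # within the winning role, prefer removal-only fixes (same policy)
  removals <- Filter(function(f) f$removal_only, best)
  chosen <- if (length(removals)) removals[[1L]] else best[[1L]]
  dropout <- NA_character_
  if (roles %in% c("F0_FEMALE", "F1_FEMALE") &&
      !chosen$removal_only && chosen$n_added == 1L &&
      chosen$cost == 1L) {
    dropout <- roles
  }
  list(culprit = roles, dropout_candidate = dropout,
       fix_cost = as.integer(chosen$cost))
}

#' Attribute an inconsistent quartet to a culprit sample
#'
#' Treats the F2 pool as the reference and searches for the cheapest
#' single-sample edit that restores consistency: for each role, every
#' alternative call with alleles drawn from the union of observed alleles
#' (singletons for the male, singletons/pairs for the females, any subset
#' for the pool).  Edit cost is the symmetric set difference (adding or
#' removing an allele costs 1, substituting costs 2).  Ties across roles
#' prefer the fix that only removes alleles -- blaming an observed
#' spurious allele over positing an unobserved dropout.  When no
#' single-role fix exists, or the tie cannot be resolved, the verdict is
#' `COMBINATION`.  A winning fix that adds exactly one allele to a female
#' flags that female as a possible allele-dropout case.
#'
#' @inheritParams quartet_consistent
#' @return An object of class `quartet_verdict`: a list with
#'   `consistent` (FALSE), `culprit`, `dropout_candidate` and `fix_cost`.
#' @examples
#' attribute_culprit("A/G", "G", "G", "G")       # diploid male: F0_MALE
#' attribute_culprit("T", "C/T", "C", "C/T")     # F1 dropout candidate
#' @export
attribute_culprit <- function(m, f0, f1, pool, pool_complete = TRUE) {
  obs <- list(F0_MALE = call_alleles(m), F0_FEMALE = call_alleles(f0),
              F1_FEMALE = call_alleles(f1), F2_POOL = call_alleles(pool))
  require_nonmissing(m = obs$F0_MALE, f0 = obs$F0_FEMALE,
                     f1 = obs$F1_FEMALE, pool = obs$F2_POOL)
  if (quartet_ok(obs$F0_MALE, obs$F0_FEMALE, obs$F1_FEMALE, obs$F2_POOL,
                 pool_complete)) {
    stop("quartet is consistent; attribute_culprit() expects an ",
         "inconsistent quartet", call. = FALSE)
  }
  U <- sort(unique(unlist(obs, use.names = FALSE)))
  verdict <- decide_culprit(enumerate_fixes(obs, U, pool_complete))
  structure(c(list(consistent = FALSE), verdict), class = "quartet_verdict")
}

#' @export
print.quartet_verdict <- function(x, ...) {
  cat("<quartet_verdict> culprit ", x$culprit,
      if (!is.na(x$dropout_candidate))
        paste0(" (dropout candidate: ", x$dropout_candidate, ")"),
      if (!is.na(x$fix_cost)) paste0(", fix cost ", x$fix_cost),
      "\n", sep = "")
  invisible(x)
}

#' Classify every locus of a cross dataset
#'
#' Applies [classify_pair()] (`mode = "pair"`: genotyped F1 female versus
#' F2 pool) or [quartet_consistent()] plus [attribute_culprit()]
#' (`mode = "quartet"`: all four samples) to each locus.  The dataset
#' should be depth-filtered first ([filter_loci()]); a missing call among
#' the required roles is an error.
#'
#' @param ds A [cross_dataset()].
#' @param mode `"pair"` or `"quartet"`.
#' @param pool_complete Passed to the quartet checks.
#' @return A data frame with one row per locus: `locus_id`, `category`,
#'   and for quartet mode `culprit`, `dropout_candidate`, `fix_cost`.
#'   Quartet categories are `CONSISTENT`/`INCONSISTENT`.
#' @examples
#' ds <- simulate_cross(sim_config(n_loci = 100, seed = 7))
#' res <- classify_dataset(filter_loci(ds), mode = "quartet")
#' table(res$category)
#' @export
classify_dataset <- function(ds, mode = c("pair", "quartet"),
                             pool_complete = TRUE) {
  stopifnot(inherits(ds, "cross_dataset"))
  mode <- match.arg(mode)
  need <- if (mode == "pair") c("F1_FEMALE", "F2_POOL") else ROLES
  have <- ds$samples$role
  absent <- setdiff(need, have)
  if (length(absent)) {
    stop("dataset lacks required role(s) for mode '", mode, "': ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  col_of <- function(role) ds$samples$sample_id[match(role, ds$samples$role)]
  cells <- lapply(need, function(r) ds$alleles[, col_of(r)])
  names(cells) <- need
  miss <- Reduce(`|`, lapply(cells, function(x) x == ""))
  if (any(miss)) {
    stop("missing call(s) among required roles at ", sum(miss),
         " locus/loci (e.g. ", ds$loci$locus_id[which(miss)[1L]],
         "); run filter_loci() first", call. = FALSE)
  }
  n <- nrow(ds$loci)
  sets <- lapply(cells, function(x) strsplit(x, "/", fixed = TRUE))

  if (mode == "pair") {
    f1c <- cells$F1_FEMALE; pc <- cells$F2_POOL
    category <- character(n)
    same <- f1c == pc
    category[same & !grepl("/", f1c, fixed = TRUE)] <- "IDENTICAL_HOM"
    category[same & grepl("/", f1c, fixed = TRUE)] <- "IDENTICAL_HET"
    for (i in which(!same)) {
      category[i] <- if (all(sets$F1_FEMALE[[i]] %in% sets$F2_POOL[[i]]))
        "EXPLAINED_BY_SETUP" else "UNEXPLAINED"
    }
    return(data.frame(locus_id = ds$loci$locus_id, category = category,
                      stringsAsFactors = FALSE))
  }

  consistent <- vapply(seq_len(n), function(i) {
    quartet_ok(sets$F0_MALE[[i]], sets$F0_FEMALE[[i]],
               sets$F1_FEMALE[[i]], sets$F2_POOL[[i]], pool_complete)
  }, logical(1))
  culprit <- rep(NA_character_, n)
  dropout <- rep(NA_character_, n)
  fix_cost <- rep(NA_integer_, n)
  for (i in which(!consistent)) {
    obs <- list(F0_MALE = sets$F0_MALE[[i]], F0_FEMALE = sets$F0_FEMALE[[i]],
                F1_FEMALE = sets$F1_FEMALE[[i]], F2_POOL = sets$F2_POOL[[i]])
    U <- sort(unique(unlist(obs, use.names = FALSE)))
    v <- decide_culprit(enumerate_fixes(obs, U, pool_complete))
    culprit[i] <- v$culprit
    dropout[i] <- v$dropout_candidate
    fix_cost[i] <- v$fix_cost
  }
  data.frame(locus_id = ds$loci$locus_id,
             category = ifelse(consistent, "CONSISTENT", "INCONSISTENT"),
             culprit = culprit, dropout_candidate = dropout,
             fix_cost = fix_cost, stringsAsFactors = FALSE)
}
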