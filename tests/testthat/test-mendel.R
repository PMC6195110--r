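test_that("pairwise classification follows the published patterns", {
  expect_equal(classify_pair("A", "A/B"), "EXPLAINED_BY_SETUP")
  expect_equal(classify_pair("A/B", "A"), "UNEXPLAINED")
  expect_equal(classify_pair("A", "A"), "IDENTICAL_HOM")
  expect_equal(classify_pair("A/C", "A/B"), "UNEXPLAINED")
  expect_equal(classify_pair("A/B", "B/A"), "IDENTICAL_HET")

  pat <- pair_patterns()
  for (i in seq_len(nrow(pat))) {
    expect_equal(classify_pair(pat$f1[i], pat$pool[i]), pat$label[i],
                 info = paste(pat$f1[i], "vs", pat$pool[i]))
  }

  expect_error(classify_pair(hap_call(character()), "A"), "missing")
})

test_that("pairwise categories are invariant under allele relabeling", {
  set.seed(77)
  letters_pool <- c("A", "B", "C", "D")
  for (i in 1:200) {
    f1 <- sample(letters_pool, sample(1:2, 1))
    pool <- sample(letters_pool, sample(1:3, 1))
    perm <- setNames(sample(letters_pool), letters_pool)
    expect_equal(classify_pair(unname(perm[f1]), unname(perm[pool])),
                 classify_pair(f1, pool))
  }
})

test_that("quartet consistency enforces ploidy and inheritance", {
  expect_true(quartet_consistent("C", "C", "C", "C"))
  expect_false(quartet_consistent("A/G", "G", "G", "G"))  # diploid male
  expect_false(quartet_consistent("G", "A", "G", "G"))    # maternal allele absent
  expect_false(quartet_consistent("T", "A", "A", "A/T"))  # hom F1 != male
  expect_true(quartet_consistent("T", "C/T", "C/T", "C/T"))
  expect_false(quartet_consistent("T", "C/T", "C/T", "T")) # C5: f1 not in pool

  # the pool-as-reference rule: an F0 allele unseen in the pool is suspect,
  # unless the completeness check is relaxed
  expect_false(quartet_consistent("C", "C/T", "C", "C"))
  expect_true(quartet_consistent("C", "C/T", "C", "C", pool_complete = FALSE))

  expect_error(quartet_consistent("A", "A", hap_call(character()), "A"),
               "missing")
})

test_that("worked quartet examples reproduce their published culprits", {
  wq <- worked_quartets()
  for (i in seq_len(nrow(wq))) {
    expect_false(quartet_consistent(wq$m[i], wq$f0[i], wq$f1[i], wq$pool[i]),
                 info = paste("row", i))
    v <- attribute_culprit(wq$m[i], wq$f0[i], wq$f1[i], wq$pool[i])
    expect_equal(v$culprit, wq$culprit[i],
                 info = paste(wq$m[i], wq$f0[i], wq$f1[i], wq$pool[i]))
  }
})

test_that("attribution details match the documented policy", {
  # minimal fix on the male, removal-only
  v <- attribute_culprit("A/G", "G", "G", "G")
  expect_equal(v$culprit, "F0_MALE")
  expect_equal(v$fix_cost, 1L)
  expect_true(is.na(v$dropout_candidate))

  # tie between removing the F0 female's T and adding T to the pool:
  # removal preferred
  v <- attribute_culprit("C", "C/T", "C", "C")
  expect_equal(v$culprit, "F0_FEMALE")
  expect_equal(v$fix_cost, 1L)
  expect_true(is.na(v$dropout_candidate))

  # adding T to the F1 female (cost 1) beats substituting the male (cost 2)
  v <- attribute_culprit("T", "C/T", "C", "C/T")
  expect_equal(v$culprit, "F1_FEMALE")
  expect_equal(v$dropout_candidate, "F1_FEMALE")
  expect_equal(v$fix_cost, 1L)

  # removing C from the pool preferred over adding C to the F0 female
  v <- attribute_culprit("T", "T", "T", "C/T")
  expect_equal(v$culprit, "F2_POOL")
  expect_equal(v$fix_cost, 1L)

  # a one-allele gap in the F0 female flags possible dropout
  v <- attribute_culprit("A", "A", "A/G", "A/G")
  expect_equal(v$culprit, "F0_FEMALE")
  expect_equal(v$dropout_candidate, "F0_FEMALE")

  # no single-sample fix restores consistency
  v <- attribute_culprit("C/G", "C/G", "C/G", "C")
  expect_equal(v$culprit, "COMBINATION")

  # a diploid call with three alleles blames that sample alone
  v <- attribute_culprit("A", "A/B/C", "A", "A")
  expect_equal(v$culprit, "F0_FEMALE")

  expect_error(attribute_culprit("C", "C", "C", "C"), "consistent")
})

test_that("attribution agrees with the brute-force oracle on random quartets", {
  set.seed(1234)
  alph <- c("A", "B", "C", "D")
  checked <- 0L
  while (checked < 150L) {
    m <- paste(sample(alph, sample(1:2, 1)), collapse = "/")
    f0 <- paste(sample(alph, sample(1:2, 1)), collapse = "/")
    f1 <- paste(sample(alph, sample(1:2, 1)), collapse = "/")
    pool <- paste(sample(alph, sample(1:3, 1)), collapse = "/")
    if (quartet_consistent(m, f0, f1, pool)) next
    got <- attribute_culprit(m, f0, f1, pool)
    # oracle alphabet includes an allele never observed in the quartet
    want <- oracle_attribute(m, f0, f1, pool, c(alph, "E"))
    expect_equal(got$culprit, want$culprit,
                 info = paste(m, f0, f1, pool))
    expect_equal(got$fix_cost, want$fix_cost, info = paste(m, f0, f1, pool))
    expect_equal(got$dropout_candidate, want$dropout_candidate,
                 info = paste(m, f0, f1, pool))
    checked <- checked + 1L
  }
})

test_that("dataset classification requires the roles of its mode", {
  ds <- simulate_cross(sim_config(n_loci = 30, seed = 14, p_missing = 0))
  pair_only <- ds
  pair_only$samples <- ds$samples[ds$samples$role != "F0_MALE", ]
  pair_only$alleles <- ds$alleles[, pair_only$samples$sample_id]
  pair_only$depth <- ds$depth[, pair_only$samples$sample_id]
  expect_error(classify_dataset(pair_only, mode = "quartet"), "F0_MALE")
  expect_silent(classify_dataset(pair_only, mode = "pair"))

  noisy <- simulate_cross(sim_config(n_loci = 200, seed = 15,
                                     p_missing = 0.2))
  expect_error(classify_dataset(noisy, mode = "quartet"), "filter_loci")
})

test_that("a hand-built locus fixture classifies into all five categories", {
  wq <- worked_quartets()
  pick <- c(1, 3, 7, 10, 13, 14)   # every culprit category represented
  n <- length(pick)
  samples <- data.frame(
    sample_id = c("m", "f0", "f1", "pool"),
    role = c("F0_MALE", "F0_FEMALE", "F1_FEMALE", "F2_POOL"),
    cross_id = "fix", wga = c(TRUE, TRUE, TRUE, FALSE),
    input_dna_ng = c(1.5, 0.39, 0.35, NA), stringsAsFactors = FALSE)
  ds <- cross_dataset(
    samples = samples,
    loci = data.frame(locus_id = paste0("T", seq_len(n)), length_bp = 109L),
    alleles = cbind(wq$m[pick], wq$f0[pick], wq$f1[pick], wq$pool[pick]),
    depth = matrix(20L, n, 4)
  )
  res <- classify_dataset(ds, mode = "quartet")
  expect_true(all(res$category == "INCONSISTENT"))
  expect_equal(res$culprit, wq$culprit[pick])
  expect_setequal(unique(res$culprit),
                  c("F0_MALE", "F0_FEMALE", "F1_FEMALE", "F2_POOL",
                    "COMBINATION"))

  # category counts partition the locus set
  expect_equal(sum(table(res$category)), n)
})

test_that("noise on one sample is attributed to that sample", {
  cfg <- sim_config(n_loci = 1000, seed = 55,
                    maternal_het_rate = 1, novel_paternal_rate = 1,
                    p_dropout = c(F1_FEMALE = 0.1), p_spurious = 0,
                    p_missing = 0)
  ds <- simulate_cross(cfg)
  res <- classify_dataset(ds, mode = "quartet")
  bad <- res[res$category == "INCONSISTENT", ]
  injected <- unique(ds$truth$events$locus_id[
    ds$truth$events$event == "DROPOUT"])
  expect_gt(nrow(bad), 50L)
  expect_true(all(bad$culprit == "F1_FEMALE"))
  expect_true(all(bad$dropout_candidate == "F1_FEMALE"))
  expect_setequal(bad$locus_id, injected)
})
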