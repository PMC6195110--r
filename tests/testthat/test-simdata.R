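test_that("configuration validation rejects invalid parameters", {
  expect_error(sim_config(n_loci = 100, p_dropout = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_loci = 100, maternal_het_rate = -0.1),
               "\\[0, 1\\]")
  expect_error(sim_config(n_loci = 0), "positive")
  expect_error(sim_config(n_loci = 10, n_f1_females = 20, n_f2_males = 5),
               "n_f2_males")
  expect_error(sim_config(n_loci = 10, dropout_dose = 0.1), "dropout_dose")
})

test_that("allele_mutant substitutes exactly one base", {
  set.seed(1)
  expect_true(allele_mutant("C") %in% c("A", "G", "T"))

  for (hap in c("GA", "ACGT", "TTTT")) {
    for (i in 1:20) {
      mut <- allele_mutant(hap)
      d <- sum(strsplit(mut, "")[[1]] != strsplit(hap, "")[[1]])
      expect_equal(d, 1L)
      expect_equal(nchar(mut), nchar(hap))
    }
  }

  set.seed(99); a <- allele_mutant("ACGTAC")
  set.seed(99); b <- allele_mutant("ACGTAC")
  expect_identical(a, b)
  expect_error(allele_mutant(""), "non-empty")
})

test_that("a fixed seed reproduces the dataset exactly", {
  cfg <- sim_config(n_loci = 400, seed = 123)
  d1 <- simulate_cross(cfg)
  d2 <- simulate_cross(cfg)
  expect_identical(d1$alleles, d2$alleles)
  expect_identical(d1$depth, d2$depth)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_cross(sim_config(n_loci = 400, seed = 124))
  expect_false(identical(d1$alleles, d3$alleles))
})

test_that("without spurious alleles every observed allele is a founder allele", {
  ds <- simulate_cross(sim_config(n_loci = 800, seed = 5, p_spurious = 0,
                                  p_dropout = 0.2, p_missing = 0.05,
                                  maternal_het_rate = 0.3,
                                  novel_paternal_rate = 0.2))
  g <- ds$truth$genotypes
  for (i in seq_len(nrow(g))) {
    founders <- unique(unlist(strsplit(c(g$F0_MALE[i], g$F0_FEMALE[i]), "/")))
    observed <- unlist(strsplit(ds$alleles[i, ], "/", fixed = TRUE))
    observed <- observed[nzchar(observed)]
    expect_true(all(observed %in% founders))
  }
})

test_that("noise-free crosses are fully Mendelian", {
  ds <- simulate_cross(quiet_config(n_loci = 1500, seed = 2,
                                    n_f1_females = 12,
                                    maternal_het_rate = 0.3,
                                    novel_paternal_rate = 0.1))
  q <- classify_dataset(ds, mode = "quartet")
  expect_true(all(q$category == "CONSISTENT"))
  p <- classify_dataset(ds, mode = "pair")
  expect_equal(sum(p$category == "UNEXPLAINED"), 0L)
  # the partition property: categories account for every locus
  expect_equal(sum(table(p$category)), nrow(ds$loci))
})

test_that("with one F1 female and a large pool the pool equals her genotype", {
  ds <- simulate_cross(quiet_config(n_loci = 600, seed = 9,
                                    n_f1_females = 1, n_f2_males = 500,
                                    maternal_het_rate = 0.5,
                                    novel_paternal_rate = 0.3))
  f1 <- ds$alleles[, "F1_female"]
  pool <- ds$alleles[, "F2_pool"]
  expect_identical(f1, pool)
  p <- classify_dataset(ds, mode = "pair")
  expect_equal(sum(p$category == "EXPLAINED_BY_SETUP"), 0L)
})

test_that("unsampled sister F1 females leave extra pool alleles", {
  ds <- simulate_cross(quiet_config(n_loci = 800, seed = 4,
                                    n_f1_females = 2,
                                    maternal_het_rate = 0.5,
                                    novel_paternal_rate = 0.2))
  p <- classify_dataset(ds, mode = "pair")
  expect_gt(sum(p$category == "EXPLAINED_BY_SETUP"), 0L)

  # frequency of setup-explained differences grows with the number of
  # unsampled sisters and vanishes with none
  explained <- vapply(c(1L, 2L, 8L), function(k) {
    d <- simulate_cross(quiet_config(n_loci = 1500, seed = 40 + k,
                                     n_f1_females = k,
                                     maternal_het_rate = 0.5,
                                     novel_paternal_rate = 0.2))
    sum(classify_dataset(d, mode = "pair")$category == "EXPLAINED_BY_SETUP")
  }, numeric(1))
  expect_equal(explained[1], 0)
  expect_true(all(diff(explained) > 0))
})

test_that("injected dropout events match an independent recount", {
  cfg <- sim_config(n_loci = 500, seed = 7, p_dropout = 0.2,
                    p_spurious = 0, p_missing = 0,
                    maternal_het_rate = 0.5, novel_paternal_rate = 0.3)
  ds <- simulate_cross(cfg)
  ev <- ds$truth$events
  expect_true(all(ev$event == "DROPOUT"))

  # recount: a dropout is the only way an observed WGA'd call can differ
  # from its true genotype in this configuration
  g <- ds$truth$genotypes
  col_of <- c(F0_MALE = "F0_male", F0_FEMALE = "F0_female",
              F1_FEMALE = "F1_female")
  recount <- 0L
  for (role in names(col_of)) {
    diff <- ds$alleles[, col_of[[role]]] != g[[role]]
    recount <- recount + sum(diff)
    # each difference is one lost allele of a heterozygote
    for (i in which(diff)) {
      true_al <- strsplit(g[[role]][i], "/")[[1]]
      obs_al <- strsplit(ds$alleles[i, col_of[[role]]], "/")[[1]]
      expect_length(true_al, 2L)
      expect_length(obs_al, 1L)
      expect_true(obs_al %in% true_al)
    }
  }
  expect_equal(nrow(ev), recount)

  # events are recorded against the right locus and role
  key_ev <- paste(ev$locus_id, ev$role)
  key_re <- unlist(lapply(names(col_of), function(role) {
    ids <- g$locus_id[ds$alleles[, col_of[[role]]] != g[[role]]]
    if (length(ids)) paste(ids, role) else character()
  }))
  expect_setequal(key_ev, key_re)
})

test_that("dose-dependent dropout tracks input DNA mass", {
  base <- list(n_loci = 3000, seed = 31, p_spurious = 0, p_missing = 0,
               maternal_het_rate = 1, novel_paternal_rate = 1)
  cfg <- do.call(sim_config, c(base, list(
    dropout_dose = c(0.3, -0.1),
    input_dna_ng = c(F0_MALE = 1, F0_FEMALE = 1, F1_FEMALE = 8))))
  ds <- simulate_cross(cfg)
  ev <- ds$truth$events
  n_f1 <- sum(ev$role == "F1_FEMALE" & ev$event == "DROPOUT")
  n_f0 <- sum(ev$role == "F0_FEMALE" & ev$event == "DROPOUT")
  # F1 female rate 0.3 - 0.1*log2(8) = 0; F0 female rate 0.3
  expect_equal(n_f1, 0L)
  expect_gt(n_f0, 0.2 * cfg$n_loci)
})

test_that("YAML configs round-trip through the reader", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_loci = 50, seed = 3, p_dropout = 0.25,
                        n_f1_females = 4), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_loci, 50L)
  expect_equal(cfg$p_dropout, 0.25)
  expect_equal(cfg$n_f1_females, 4L)

  yaml::write_yaml(list(n_loci = 50, bogus = 1), path)
  expect_error(read_sim_config(path), "bogus")
})
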