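test_that("sim_config validates its stated world", {
  expect_error(sim_config(h2_true = 1.2), "h2_true")
  expect_error(sim_config(w_true = -0.1), "w_true")
  expect_error(sim_config(se_range = c(0, 1)), "se_range")
  expect_error(sim_config(founder_freq_range = c(0.01, 0.9)), "founder_freq")
  expect_error(sim_config(n_founders = 2), "founders")
})

test_that("simulated pedigrees have the configured family structure", {
  cfg <- sim_config(n_families = 10L, sibs_per_family = 8L, seed = 21L)
  sp <- simulate_pedigree(cfg)
  expect_length(sp$line_ids, 80L)
  fams <- full_sib_families(sp$ped, sp$line_ids)
  expect_length(fams, 10L)
  expect_true(all(lengths(fams) == 8L))
  # impossible configuration: more families than distinct parent pairs
  expect_error(
    simulate_pedigree(sim_config(n_per_generation = 4L, n_families = 100L)),
    "impossible")
})

test_that("deeper pedigrees accumulate between-family relatedness", {
  mean_off <- function(gens, seed) {
    cfg <- sim_config(n_founders = 12L, n_generations = gens,
                      n_per_generation = 10L, n_families = 6L,
                      sibs_per_family = 4L, seed = seed)
    sp <- simulate_pedigree(cfg)
    A <- unclass(rel_subset(numerator_relationship_matrix(sp$ped),
                            sp$line_ids))
    fam <- rep(seq_len(6L), each = 4L)
    between <- outer(fam, fam, "!=")
    mean(A[between])
  }
  shallow <- vapply(1:20, function(s) mean_off(1L, 300 + s), 0)
  deep <- vapply(1:20, function(s) mean_off(8L, 300 + s), 0)
  expect_gt(mean(deep), mean(shallow))
})

test_that("gene dropping obeys Mendelian transmission", {
  # parents with dosage 0 x 0 give 0; 2 x 0 give obligate heterozygotes
  cfg <- sim_config(n_founders = 4L, n_generations = 1L,
                    n_per_generation = 4L, n_families = 2L,
                    sibs_per_family = 3L, n_markers = 60L,
                    missing_rate = 0, seed = 31L)
  sp <- simulate_pedigree(cfg)
  gd <- gene_drop(sp$ped, cfg, line_ids = sp$ped$id)
  d <- gd$geno_complete$dosages
  ped <- as.data.frame(sp$ped)
  kids <- ped[!is.na(ped$sire), ]
  for (i in seq_len(nrow(kids))) {
    s <- d[kids$sire[i], ]; m <- d[kids$dam[i], ]; o <- d[kids$id[i], ]
    expect_true(all(o[s == 0 & m == 0] == 0))
    expect_true(all(o[s == 2 & m == 2] == 2))
    expect_true(all(o[(s == 2 & m == 0) | (s == 0 & m == 2)] == 1))
  }
})

test_that("a 1x1 cross segregates 1:2:1 over many offspring", {
  n_off <- 4000L
  ped <- suppressMessages(pedigree(
    c("P1", "P2", sprintf("O%04d", seq_len(n_off))),
    c(NA, NA, rep("P1", n_off)), c(NA, NA, rep("P2", n_off))))
  cfg <- sim_config(n_markers = 30L, missing_rate = 0, seed = 33L)
  d <- gene_drop(ped, cfg, line_ids = ped$id)$geno_complete$dosages
  het <- which(d["P1", ] == 1 & d["P2", ] == 1)
  expect_gt(length(het), 3)
  off <- d[-(1:2), het]
  freqs <- c(mean(off == 0), mean(off == 1), mean(off == 2))
  expect_equal(freqs, c(0.25, 0.5, 0.25), tolerance = 0.04)
})

test_that("expected line dosage is twice the founder frequency", {
  # drift makes any single realization deviate; unbiasedness shows up as a
  # near-zero mean signed deviation across seeds
  devs <- vapply(1:15, function(s) {
    cfg <- sim_config(n_founders = 30L, n_generations = 2L,
                      n_per_generation = 20L, n_families = 10L,
                      sibs_per_family = 10L, n_markers = 150L,
                      missing_rate = 0, seed = 800 + s)
    sp <- simulate_pedigree(cfg)
    gd <- gene_drop(sp$ped, cfg, line_ids = sp$line_ids)
    mean(colMeans(gd$geno_complete$dosages) - 2 * gd$founder_freqs)
  }, 0)
  expect_equal(mean(devs), 0, tolerance = 0.03)

  # Mendelian sampling: full sibs differ
  cfg <- sim_config(n_founders = 30L, n_generations = 2L,
                    n_per_generation = 20L, n_families = 10L,
                    sibs_per_family = 10L, n_markers = 150L,
                    missing_rate = 0, seed = 35L)
  sp <- simulate_pedigree(cfg)
  gd <- gene_drop(sp$ped, cfg, line_ids = sp$line_ids)
  fams <- full_sib_families(sp$ped, sp$line_ids)
  sib_var <- vapply(fams, function(f)
    mean(apply(gd$geno_complete$dosages[f, ], 2, var)), 0)
  expect_true(all(sib_var > 0))
})

test_that("trait architecture degenerates correctly at w_true = 0 and 1", {
  base <- function(w) sim_config(n_founders = 14L, n_generations = 2L,
                                 n_per_generation = 10L, n_families = 6L,
                                 sibs_per_family = 5L, n_markers = 120L,
                                 w_true = w, missing_rate = 0, seed = 41L)
  sp <- simulate_pedigree(base(1))
  gd <- gene_drop(sp$ped, base(1), line_ids = sp$line_ids)
  ph1 <- simulate_phenotypes(sp$ped, gd$geno_complete, base(1))
  expect_equal(var(ph1$truth$m_true), 0)
  ph0 <- simulate_phenotypes(sp$ped, gd$geno_complete, base(0))
  expect_true(all(ph0$truth$a_true == 0))
  expect_equal(ph0$truth$g_true, ph0$truth$m_true)
})

test_that("the realized polygenic variance share tracks w_true", {
  shares <- vapply(1:20, function(s) {
    cfg <- sim_config(n_founders = 16L, n_generations = 2L,
                      n_per_generation = 12L, n_families = 10L,
                      sibs_per_family = 6L, n_markers = 250L,
                      w_true = 0.5, missing_rate = 0, seed = 500 + s)
    sim <- simulate_dataset(cfg)
    var(sim$truth$a_true) / var(sim$truth$g_true)
  }, 0)
  expect_equal(mean(shares), 0.5, tolerance = 0.1)
})

test_that("masking + imputation perturbs G by an amount that shrinks with missingness", {
  cfg0 <- sim_config(n_founders = 16L, n_generations = 2L,
                     n_per_generation = 12L, n_families = 8L,
                     sibs_per_family = 6L, n_markers = 300L,
                     missing_rate = 0, seed = 55L)
  sp <- simulate_pedigree(cfg0)
  complete <- gene_drop(sp$ped, cfg0, line_ids = sp$line_ids)$geno_complete
  G0 <- unclass(vanraden_g(complete))
  perturb <- vapply(c(0.02, 0.25), function(mr) {
    d <- complete$dosages
    set.seed(66)
    d[matrix(runif(length(d)) < mr, nrow(d))] <- NA
    gi <- impute_missing(geno_matrix(d), seed = 67L)
    mean(abs(unclass(vanraden_g(gi)) - G0))
  }, 0)
  expect_lt(perturb[1], perturb[2])
  expect_lt(perturb[1], 0.05)
})

test_that("simulate_dataset is reproducible given its seed", {
  cfg <- sim_config(n_founders = 10L, n_generations = 1L,
                    n_per_generation = 8L, n_families = 4L,
                    sibs_per_family = 4L, n_markers = 50L, seed = 71L)
  s1 <- simulate_dataset(cfg); s2 <- simulate_dataset(cfg)
  expect_identical(s1$geno$dosages, s2$geno$dosages)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$truth, s2$truth)
})
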