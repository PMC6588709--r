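test_that("qc_filter removes exactly the violating markers with reasons", {
  out <- qc_filter(qc_fixture())
  removed <- out$report$marker_id[nzchar(out$report$removed_reason)]
  expect_setequal(removed, c("M01", "M02", "M06", "M08", "M09", "M10"))
  expect_setequal(marker_ids(out$geno), c("M03", "M04", "M05", "M07"))
  rr <- setNames(out$report$removed_reason, out$report$marker_id)
  expect_equal(unname(rr["M01"]), "MAF")
  expect_equal(unname(rr["M06"]), "missingness")
  expect_error(qc_filter(out$geno, maf_min = 0.99), "every marker")
})

test_that("impute_missing is seeded, targeted and frequency-consistent", {
  g <- qc_filter(qc_fixture())$geno
  i1 <- impute_missing(g, seed = 3L)
  i2 <- impute_missing(g, seed = 3L)
  expect_identical(i1$dosages, i2$dosages)        # determinism
  expect_false(anyNA(i1$dosages))
  obs <- !is.na(g$dosages)
  expect_identical(i1$dosages[obs], g$dosages[obs])  # untouched cells
  expect_identical(impute_missing(i1, seed = 9L)$dosages, i1$dosages)

  # law of large numbers at p = 0.5: mean imputed dosage -> 1
  d <- matrix(c(rep(c(0, 2), 50), rep(NA, 10000)), ncol = 1)
  rownames(d) <- sprintf("L%05d", seq_len(nrow(d))); colnames(d) <- "M"
  imp <- impute_missing(geno_matrix(d), seed = 1L)
  expect_equal(mean(imp$dosages[101:10100, 1]), 1.0, tolerance = 0.03)

  # qc then impute is idempotent on its own output
  qi <- impute_missing(qc_filter(qc_fixture())$geno, seed = 2L)
  again <- impute_missing(qc_filter(qi)$geno, seed = 2L)
  expect_identical(again$dosages, qi$dosages)
})

test_that("vanraden_g matches the hand-computed two-line example", {
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("L1", "L2"), c("m1", "m2")))
  G <- unclass(vanraden_g(geno_matrix(d)))
  # p = (0.5, 0.5), W = [[-1,1],[1,-1]], denom = 1
  expect_equal(G, matrix(c(2, -2, -2, 2), 2,
                         dimnames = list(c("L1", "L2"), c("L1", "L2"))),
               ignore_attr = TRUE)
})

test_that("vanraden_g invariances: duplicates, zero grand mean, allele flip", {
  kin <- small_kinships()
  d <- kin$geno$dosages[1:30, ]
  d <- rbind(d, DUP = d[1, ])
  G <- unclass(vanraden_g(geno_matrix(d)))
  expect_equal(G["DUP", ], G[rownames(d)[1], ], ignore_attr = TRUE)
  expect_equal(mean(G), 0, tolerance = 1e-12)
  flip <- d; flip[, 1:50] <- 2 - flip[, 1:50]
  expect_equal(unclass(vanraden_g(geno_matrix(flip))), G, tolerance = 1e-12)
  mono <- matrix(2, 3, 2, dimnames = list(letters[1:3], c("m1", "m2")))
  expect_error(vanraden_g(geno_matrix(mono)), "monomorphic")
})

test_that("rescale_g solves the stated two-moment system", {
  mk <- function(dg, off, ids = c("a", "b"), kind = "G") {
    m <- matrix(off, 2, 2, dimnames = list(ids, ids)); diag(m) <- dg
    rel_matrix(m, kind = kind)
  }
  # mean(diag G)=0.9, mean(G)=0.1 => off-diag -0.7; mean(diag A)=1, mean(A)=0.5 => off 0
  G <- mk(0.9, -0.7)
  A <- mk(1.0, 0.0, kind = "A")
  rs <- rescale_g(G, A)
  expect_equal(rs$coef$scale_b, 0.625)
  expect_equal(rs$coef$offset_a, 0.4375)
  # identity case: already matched moments
  rs2 <- rescale_g(mk(1.0, 0.0), A)
  expect_equal(rs2$coef$scale_b, 1)
  expect_equal(rs2$coef$offset_a, 0)
  expect_equal(unclass(rs2$Gs), unclass(mk(1.0, 0.0)), ignore_attr = TRUE)
  # degenerate: mean(diag G) == mean(G)
  expect_error(rescale_g(mk(0.5, 0.5), A), "singular")

  # moment matching holds by construction on real data
  kin <- small_kinships()
  expect_equal(mean(diag(unclass(kin$Gs))), mean(diag(unclass(kin$A))),
               tolerance = 1e-10)
  expect_equal(mean(unclass(kin$Gs)), mean(unclass(kin$A)),
               tolerance = 1e-10)
  expect_equal(rel_kind(kin$Gs), "Gs")
})

test_that("blend endpoints, arithmetic and linearity", {
  kin <- small_kinships()
  expect_equal(unclass(blend(kin$A, kin$Gs, 0)), unclass(kin$Gs),
               ignore_attr = TRUE)
  expect_equal(unclass(blend(kin$A, kin$Gs, 1)), unclass(kin$A),
               ignore_attr = TRUE)
  ids <- c("x", "y")
  A <- rel_matrix(matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(ids, ids)), "A")
  Gs <- rel_matrix(matrix(c(1, 0.7, 0.7, 1), 2, dimnames = list(ids, ids)), "Gs")
  expect_equal(unclass(blend(A, Gs, 0.3))["x", "y"], 0.3 * 0.5 + 0.7 * 0.7)
  # linear in w: K(w1) + K(w2) = K(w1+w2) + K(0)
  for (w in list(c(0.2, 0.3), c(0.1, 0.6))) {
    lhs <- unclass(blend(kin$A, kin$Gs, w[1])) +
           unclass(blend(kin$A, kin$Gs, w[2]))
    rhs <- unclass(blend(kin$A, kin$Gs, sum(w))) +
           unclass(blend(kin$A, kin$Gs, 0))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  B <- rel_matrix(matrix(1, 1, 1, dimnames = list("z", "z")), "Gs")
  expect_error(blend(A, B, 0.5), "mismatch")
  expect_error(blend(A, Gs, 1.5), "0, 1")
})

test_that("ensure_pd repairs by diagonal loading only when needed", {
  ids <- c("a", "b")
  I2 <- rel_matrix(matrix(c(1, 0, 0, 1), 2, dimnames = list(ids, ids)), "K")
  expect_identical(unclass(ensure_pd(I2)), unclass(I2))
  ones <- rel_matrix(matrix(1, 2, 2, dimnames = list(ids, ids)), "K")
  fixed <- suppressMessages(ensure_pd(ones, eps = 1e-8))
  expect_equal(diag(unclass(fixed)), c(a = 1 + 1e-8, b = 1 + 1e-8))
  lmin <- min(eigen(unclass(fixed), only.values = TRUE)$values)
  expect_gte(lmin, 1e-8 - 1e-15)
})

test_that("genotype and relationship matrix files round-trip", {
  kin <- small_kinships()
  gpath <- withr::local_tempfile(fileext = ".csv")
  write_genotypes_csv(small_sim()$geno, gpath)
  back <- read_genotypes_csv(gpath)
  expect_identical(back$dosages, small_sim()$geno$dosages)

  apath <- withr::local_tempfile(fileext = ".csv")
  write_rel_matrix(kin$A, apath)
  A2 <- read_rel_matrix(apath, kind = "A")
  expect_equal(unclass(A2), unclass(kin$A), tolerance = 1e-12)
})

test_that("gene-dropped Gs tracks A more closely as marker count grows", {
  cfgs <- lapply(c(80L, 800L), function(m)
    sim_config(n_founders = 16L, n_generations = 2L, n_per_generation = 12L,
               n_families = 8L, sibs_per_family = 6L, n_markers = m,
               missing_rate = 0, seed = 99L))
  sp <- simulate_pedigree(cfgs[[1]])
  A <- rel_subset(numerator_relationship_matrix(sp$ped), sp$line_ids)
  corr <- vapply(cfgs, function(cfg) {
    g <- gene_drop(sp$ped, cfg, line_ids = sp$line_ids)$geno_complete
    Gs <- rescale_g(vanraden_g(g), A)$Gs
    lo <- lower.tri(unclass(A))
    cor(unclass(Gs)[lo], unclass(A)[lo])
  }, numeric(1))
  expect_gt(corr[2], corr[1])
  expect_gt(corr[2], 0.7)
})
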