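# Independent oracles and random-case generators shared across the suite.
# These deliberately share no code with the package internals they check.

# Path-counting oracle for the numerator relationship matrix.
# a_ij = sum over pairs of non-overlapping descent chains from a common
# ancestor A down to i and down to j of (1/2)^(L1+L2) * (1 + F_A);
# a_ii = 1 + F_i with F_i = (1/2) * a(sire_i, dam_i).
# Chains are enumerated per gamete slot, so selfing (sire == dam) yields two
# distinct single-link chains to the same parent, as it must.
oracle_A <- function(ped) {
  ped <- as.data.frame(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])

  # chains[[i]]: list of list(top = ancestor index, below = indices on the
  # chain strictly below the top (including i), len = number of links)
  chains <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- list(list(top = i, below = integer(0), len = 0L))
    for (p in c(si[i], di[i])) {      # one entry per gamete slot
      if (p == 0L) next
      for (ch in chains[[p]])
        cs[[length(cs) + 1L]] <- list(top = ch$top,
                                      below = c(i, ch$below),
                                      len = ch$len + 1L)
    }
    chains[[i]] <- cs
  }

  Fco <- numeric(n)   # inbreeding, filled in topological order
  pair_sum <- function(ci, cj, Fvec) {
    tot <- 0
    for (c1 in ci) for (c2 in cj) {
      if (c1$top != c2$top) next
      if (length(intersect(c1$below, c2$below))) next
      tot <- tot + 0.5^(c1$len + c2$len) * (1 + Fvec[c1$top])
    }
    tot
  }
  for (i in seq_len(n)) {
    if (si[i] > 0L && di[i] > 0L)
      Fco[i] <- 0.5 * pair_sum(chains[[si[i]]], chains[[di[i]]], Fco)
  }
  A <- diag(1 + Fco)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) A[i, j] <- A[j, i] <- pair_sum(chains[[i]], chains[[j]], Fco)
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# Random valid pedigree with founders, selfing and inbred loops.
rand_pedigree <- function(n, seed, p_founder = 0.3, p_self = 0.15) {
  set.seed(seed)
  id <- sprintf("I%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= 2 || runif(1) < p_founder) next
    s <- sample(id[seq_len(i - 1)], 1)
    d <- if (runif(1) < p_self) s else sample(id[seq_len(i - 1)], 1)
    sire[i] <- s; dam[i] <- d
  }
  pedigree(id, sire, dam)
}

# QC fixture: 10 markers with known MAF and missingness, built in code.
# Masked cells sit on the dosage-2 entries, so post-masking MAFs stay well
# above threshold for the missingness-only removals.
qc_fixture <- function() {
  n <- 100L
  make_col <- function(p, miss_n) {
    cnt <- round(2 * n * p)  # counted alleles among 2n
    x <- c(rep(2, cnt %/% 2), rep(1, cnt %% 2))
    x <- c(x, rep(0, n - length(x)))
    if (miss_n > 0) x[seq_len(miss_n)] <- NA
    x
  }
  cols <- cbind(
    M01 = make_col(0.01, 0),    # MAF 0.01 -> removed
    M02 = make_col(0.02, 0),    # MAF 0.02 -> removed
    M03 = make_col(0.025, 0),   # MAF exactly at threshold -> retained
    M04 = make_col(0.30, 5),    # retained (5% missing)
    M05 = make_col(0.50, 0),    # retained
    M06 = make_col(0.40, 25),   # 25% missing -> removed
    M07 = make_col(0.40, 20),   # exactly 20% missing -> retained
    M08 = make_col(0.99, 0),    # counted-allele freq 0.99, MAF 0.01 -> removed
    M09 = c(rep(NA, n)),        # entirely missing -> removed
    M10 = make_col(0.45, 30))   # 30% missing -> removed
  rownames(cols) <- sprintf("L%03d", seq_len(n))
  geno_matrix(cols)
}

# The 20-dataset simulation suite used by the heavy acceptance criteria
# (parameter recovery and weight-sweep shape): 60 families x 8 sibs = 480
# lines, 1,000 markers, h2 = 0.6, w_true = 0.5 — the generator defaults.
acceptance_suite <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(1:20, function(s) {
        sim <- simulate_dataset(sim_config(seed = s))
        geno <- impute_missing(qc_filter(sim$geno)$geno,
                               seed = kinblend:::derive_seed(s, "impute"))
        A <- rel_subset(numerator_relationship_matrix(sim$ped),
                        geno_ids(geno))
        rs <- rescale_g(vanraden_g(geno), A)
        list(sim = sim, geno = geno, A = A, Gs = rs$Gs)
      })
    cache
  }
})

# Small complete dataset used by several unit tests; cached per session.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(sim_config(
        n_founders = 20L, n_generations = 3L, n_per_generation = 15L,
        n_families = 12L, sibs_per_family = 6L, n_markers = 300L,
        seed = 42L))
    cache
  }
})

# Imputed genotypes + aligned A and Gs for the small dataset.
small_kinships <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      geno <- impute_missing(qc_filter(sim$geno)$geno, seed = 11L)
      A_gg <- rel_subset(numerator_relationship_matrix(sim$ped),
                         geno_ids(geno))
      G <- vanraden_g(geno)
      rs <- rescale_g(G, A_gg)
      cache <<- list(sim = sim, geno = geno, A = A_gg, G = G, Gs = rs$Gs,
                     coef = rs$coef)
    }
    cache
  }
})
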