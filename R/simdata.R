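#' Configuration for the synthetic breeding-program generator
#'
#' The defaults emulate a highly structured inbred-line breeding population
#' at roughly 70% of the scale of a typical parental-line program: about 500
#' ancestors feeding 60 full-sib families of 8 lines each (480 lines), with
#' 1,000 unlinked SNPs. The trait architecture splits the total additive
#' variance into a marker-captured share `1 - w_true` and a residual
#' polygenic share `w_true`; line BLUEs get heteroscedastic standard errors
#' drawn uniformly from `se_range`.
#'
#' @param n_founders number of pedigree founders.
#' @param n_generations intermediate generations of random mating between
#'   founders and the final family crosses.
#' @param n_per_generation individuals per intermediate generation.
#' @param n_families full-sib families in the line cohort.
#' @param sibs_per_family lines per family.
#' @param n_markers number of unlinked biallelic SNPs.
#' @param founder_freq_range range of founder allele frequencies (uniform).
#' @param w_true residual polygenic share of the additive variance.
#' @param h2_true narrow-sense heritability of line means.
#' @param mu_true trait mean.
#' @param se_range range of BLUE standard errors (uniform, trait units).
#' @param missing_rate fraction of genotype calls masked to missing.
#' @param selfing_generations generations of selfing applied to each line
#'   after the family cross (0 = F1 sibs).
#' @param seed integer seed; every downstream draw is derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_founders = 40L, n_generations = 5L,
                       n_per_generation = 30L, n_families = 60L,
                       sibs_per_family = 8L, n_markers = 1000L,
                       founder_freq_range = c(0.1, 0.9), w_true = 0.5,
                       h2_true = 0.6, mu_true = 0, se_range = c(0.8, 1.2),
                       missing_rate = 0.05, selfing_generations = 0L,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_founders < 4) stop2("need at least 4 founders")
  if (cfg$w_true < 0 || cfg$w_true > 1) stop2("w_true must lie in [0, 1]")
  if (cfg$h2_true <= 0 || cfg$h2_true >= 1)
    stop2("h2_true must lie strictly inside (0, 1)")
  if (cfg$se_range[1] <= 0) stop2("se_range lower bound must be positive")
  if (cfg$founder_freq_range[1] < 0.05 || cfg$founder_freq_range[2] > 0.95)
    stop2("founder_freq_range must lie within (0.05, 0.95)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop2("missing_rate must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-generation breeding pedigree
#'
#' Founders, `n_generations` of random matings producing intermediate
#' ancestors, then `n_families` distinct parent pairs each producing
#' `sibs_per_family` full-sib lines (the "line" cohort), optionally advanced
#' by selfing generations. Deterministic given `cfg$seed`.
#'
#' @param cfg a `sim_config`.
#' @return list with `ped` (a `pedigree`), `line_ids` (the final cohort) and
#'   `family_of` (named family key per line).
#' @export
simulate_pedigree <- function(cfg) {
  old <- local_seed(derive_seed(cfg$seed, "pedigree"))
  on.exit(restore_seed(old))
  id <- sprintf("FND%03d", seq_len(cfg$n_founders))
  sire <- dam <- rep(NA_character_, cfg$n_founders)
  prev <- id
  for (g in seq_len(cfg$n_generations)) {
    new_ids <- sprintf("G%d_%03d", g, seq_len(cfg$n_per_generation))
    for (i in seq_along(new_ids)) {
      pair <- sample(prev, 2L)
      id <- c(id, new_ids[i]); sire <- c(sire, pair[1]); dam <- c(dam, pair[2])
    }
    prev <- new_ids
  }
  n_parents <- length(prev)
  if (cfg$n_families > n_parents * (n_parents - 1) / 2)
    stop2("impossible configuration: ", cfg$n_families,
          " families exceed the ", n_parents * (n_parents - 1) / 2,
          " distinct parent pairs available")
  pairs <- t(utils::combn(prev, 2L))
  pairs <- pairs[sample(nrow(pairs), cfg$n_families), , drop = FALSE]
  line_ids <- character(0); family_of <- character(0)
  for (f in seq_len(cfg$n_families)) {
    fam_key <- paste(sort(pairs[f, ]), collapse = " x ")
    cross_id <- sprintf("FAM%02d_%d", f, seq_len(cfg$sibs_per_family))
    cur_s <- rep(pairs[f, 1], cfg$sibs_per_family)
    cur_d <- rep(pairs[f, 2], cfg$sibs_per_family)
    cur <- cross_id
    id <- c(id, cross_id); sire <- c(sire, cur_s); dam <- c(dam, cur_d)
    for (s in seq_len(cfg$selfing_generations)) {
      selfed <- sprintf("%s_S%d", cross_id, s)
      id <- c(id, selfed); sire <- c(sire, cur); dam <- c(dam, cur)
      cur <- selfed
    }
    line_ids <- c(line_ids, cur)
    family_of <- c(family_of, stats::setNames(rep(fam_key, length(cur)), cur))
  }
  list(ped = pedigree(id, sire, dam), line_ids = line_ids,
       family_of = family_of)
}

#' Gene-drop unlinked SNPs through a pedigree
#'
#' Founder allele frequencies are drawn uniformly from
#' `cfg$founder_freq_range`; founders get two independent Bernoulli alleles
#' per marker, and every offspring receives one allele sampled at random
#' from each parent's pair (true Mendelian transmission — the two alleles
#' are tracked, not just the dosage). Afterward a fraction `missing_rate` of
#' line-cohort calls is masked to `NA`.
#'
#' @param ped a `pedigree` (topologically sorted, as returned by
#'   [simulate_pedigree()]).
#' @param cfg a `sim_config`.
#' @param line_ids ids to report genotypes for (default all).
#' @return list with `geno` (a `geno_matrix`, possibly with missing calls),
#'   `geno_complete` (pre-masking truth) and `founder_freqs`.
#' @export
gene_drop <- function(ped, cfg, line_ids = ped$id) {
  old <- local_seed(derive_seed(cfg$seed, "genedrop"))
  on.exit(restore_seed(old))
  n <- nrow(ped); m <- cfg$n_markers
  p <- stats::runif(m, cfg$founder_freq_range[1], cfg$founder_freq_range[2])
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  a1 <- matrix(0L, n, m); a2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    # an unknown parent contributes a founder-population allele
    a1[i, ] <- if (si[i] == 0L) stats::rbinom(m, 1L, p) else
      ifelse(stats::runif(m) < 0.5, a1[si[i], ], a2[si[i], ])
    a2[i, ] <- if (di[i] == 0L) stats::rbinom(m, 1L, p) else
      ifelse(stats::runif(m) < 0.5, a1[di[i], ], a2[di[i], ])
  }
  dos <- a1 + a2
  dimnames(dos) <- list(ped$id, sprintf("SNP%04d", seq_len(m)))
  dos <- dos[line_ids, , drop = FALSE]
  storage.mode(dos) <- "double"
  complete <- geno_matrix(dos)
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(dos)) < cfg$missing_rate, nrow(dos))
    dos[mask] <- NA_real_
  }
  list(geno = geno_matrix(dos), geno_complete = complete, founder_freqs = p)
}

#' Simulate line phenotypes (BLUEs with standard errors)
#'
#' True additive values are `g = m + a`: the marker-captured part `m = W b`
#' with effects `b ~ N(0, (1 - w_true) * sigma2_g / (2 sum p(1-p)))` on the
#' column-centered dosages (pre-masking truth genotypes), and the residual
#' polygenic part `a ~ N(0, A * w_true * sigma2_g)` drawn through the
#' pedigree via a Cholesky factor of A restricted to the lines. The total
#' additive variance is set to `sigma2_g = h2/(1-h2) * mean(se^2)` so the
#' realized heritability of line means matches `h2_true` in expectation.
#' BLUEs are `mu + g + e` with `e ~ N(0, se_i^2)`,
#' `se_i ~ Uniform(se_range)`.
#'
#' @param ped a `pedigree` containing the lines.
#' @param geno a complete `geno_matrix` over the line cohort (pre-masking).
#' @param cfg a `sim_config`.
#' @return list with `pheno` (data frame `line_id`, `trait`, `blue`, `se`)
#'   and `truth` (data frame `line_id`, `g_true`, `m_true`, `a_true`, plus
#'   attributes `sigma2_g`, `marker_effects`).
#' @export
simulate_phenotypes <- function(ped, geno, cfg) {
  old <- local_seed(derive_seed(cfg$seed, "phenotypes"))
  on.exit(restore_seed(old))
  ids <- geno_ids(geno)
  d <- geno$dosages
  if (anyNA(d)) stop2("truth genotypes must be complete (pre-masking)")
  se <- stats::runif(length(ids), cfg$se_range[1], cfg$se_range[2])
  sigma2_g <- cfg$h2_true / (1 - cfg$h2_true) * mean(se^2)

  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  W <- sweep(d[, poly, drop = FALSE], 2, 2 * p[poly])
  beta <- stats::rnorm(ncol(W), 0, sqrt((1 - cfg$w_true) * sigma2_g / denom))
  m_true <- (W %*% beta)[, 1]

  if (cfg$w_true > 0) {
    A_ll <- unclass(rel_subset(numerator_relationship_matrix(ped), ids))
    ch <- chol(A_ll + diag(1e-10, length(ids)))
    a_true <- sqrt(cfg$w_true * sigma2_g) *
      (t(ch) %*% stats::rnorm(length(ids)))[, 1]
  } else a_true <- rep(0, length(ids))

  g_true <- m_true + a_true
  blue <- cfg$mu_true + g_true + stats::rnorm(length(ids), 0, se)
  truth <- data.frame(line_id = ids, g_true = g_true, m_true = m_true,
                      a_true = a_true, stringsAsFactors = FALSE)
  attr(truth, "sigma2_g") <- sigma2_g
  attr(truth, "marker_effects") <- beta
  list(pheno = data.frame(line_id = ids, trait = "sim_trait", blue = blue,
                          se = se, stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a complete synthetic breeding dataset
#'
#' Runs [simulate_pedigree()], [gene_drop()] and [simulate_phenotypes()] in
#' sequence.
#'
#' @param cfg a `sim_config`.
#' @return list with `ped`, `line_ids`, `families` (named list key -> line
#'   ids), `geno` (masked), `geno_complete`, `pheno`, `truth`, `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  sp <- simulate_pedigree(cfg)
  gd <- gene_drop(sp$ped, cfg, line_ids = sp$line_ids)
  ph <- simulate_phenotypes(sp$ped, gd$geno_complete, cfg)
  # group by the family key assigned at the cross (robust to selfing, where
  # the literal parent pair of a selfed line is a single individual)
  fams <- split(sp$line_ids, factor(sp$family_of[sp$line_ids],
                                    levels = unique(sp$family_of)))
  list(ped = sp$ped, line_ids = sp$line_ids, families = fams,
       geno = gd$geno, geno_complete = gd$geno_complete,
       pheno = ph$pheno, truth = ph$truth, cfg = cfg)
}
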