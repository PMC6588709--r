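#' VanRaden method-1 genomic relationship matrix
#'
#' `G = W W' / (2 * sum_j p_j (1 - p_j))` where `W` is the dosage matrix
#' column-centered by twice the observed allele frequency `p_j` of the
#' genotyped set. Using current observed frequencies sets the reference
#' population for G to the genotyped lines themselves, which is why a
#' rescaling step ([rescale_g()]) is needed before mixing G with a pedigree
#' matrix.
#'
#' @param geno a complete `geno_matrix` (no missing calls).
#' @return a `rel_matrix` of kind `"G"`.
#' @export
vanraden_g <- function(geno) {
  d <- geno$dosages
  if (anyNA(d)) stop2("genotypes contain missing calls; impute first")
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop2("all markers monomorphic: VanRaden denominator is zero")
  W <- sweep(d, 2, 2 * p)
  G <- tcrossprod(W) / denom
  rel_matrix(G, kind = "G", tol = 1e-8)
}

#' Rescale a genomic matrix to the pedigree base
#'
#' Finds `a`, `b` such that `Gs = a + b * G` matches the pedigree matrix on
#' the genotyped subset in two moments: mean diagonal (average inbreeding
#' level) and mean over all elements (overall relationship). Solves the 2x2
#' linear system
#' `a + b * mean(diag G) = mean(diag A_gg)` and
#' `a + b * mean(G) = mean(A_gg)`.
#'
#' @param G a `rel_matrix` of kind `"G"`.
#' @param A_gg the pedigree `rel_matrix` restricted to the same genotyped
#'   ids.
#' @param use_offdiag if `TRUE`, the second equation matches off-diagonal
#'   means instead of all-element means (alternative reading of "overall
#'   relationships"). Default `FALSE`.
#' @return list with `Gs` (a `rel_matrix` of kind `"Gs"`) and `coef`
#'   (list `offset_a`, `scale_b`).
#' @export
rescale_g <- function(G, A_gg, use_offdiag = FALSE) {
  A_gg <- rel_align(G, A_gg, "G", "A")
  g <- unclass(G); a <- unclass(A_gg)
  off <- function(m) (sum(m) - sum(diag(m))) / (length(m) - nrow(m))
  mg_all <- if (use_offdiag) off(g) else mean(g)
  ma_all <- if (use_offdiag) off(a) else mean(a)
  mg_d <- mean(diag(g)); ma_d <- mean(diag(a))
  if (abs(mg_d - mg_all) < 1e-12)
    stop2("singular rescaling system: mean(diag G) equals mean(G)")
  scale_b <- (ma_d - ma_all) / (mg_d - mg_all)
  offset_a <- ma_d - scale_b * mg_d
  if (scale_b <= 0)
    stop2(sprintf("rescaling produced non-positive scale b = %.4g", scale_b))
  Gs <- rel_matrix(offset_a + scale_b * g, kind = "Gs", tol = 1e-8)
  list(Gs = Gs, coef = list(offset_a = offset_a, scale_b = scale_b))
}

#' Blend pedigree and rescaled genomic relationship matrices
#'
#' `K = w * A + (1 - w) * Gs`. `w = 1` gives the pedigree-only matrix
#' (A-BLUP); `w = 0` gives the genomic matrix (G-BLUP); interior weights
#' split the additive variance between a marker-captured and a residual
#' polygenic part.
#'
#' @param A pedigree `rel_matrix` restricted to the genotyped lines.
#' @param Gs rescaled genomic `rel_matrix` on the same ids.
#' @param w blending weight in \[0, 1\] — the pedigree share.
#' @return a `rel_matrix` of kind `"K"` (kind `"A"`/`"Gs"` semantics are
#'   preserved numerically at the endpoints, tag is always `"K"`).
#' @export
blend <- function(A, Gs, w) {
  if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1)
    stop2("`w` must be a single value in [0, 1]")
  Gs <- rel_align(A, Gs, "A", "Gs")
  rel_matrix(w * unclass(A) + (1 - w) * unclass(Gs), kind = "K", tol = 1e-8)
}

#' Ensure positive definiteness by diagonal loading
#'
#' If the minimum eigenvalue is below `eps`, adds `eps - lambda_min` to the
#' diagonal and logs the repair magnitude. REML needs an invertible
#' covariance; diagonal loading is transparent and preserves off-diagonal
#' structure (eigenvalue truncation would not).
#'
#' @param K a `rel_matrix`.
#' @param eps target minimum eigenvalue.
#' @return a `rel_matrix` of the same kind with `lambda_min >= eps`.
#' @export
ensure_pd <- function(K, eps = 1e-8) {
  m <- unclass(K)
  lmin <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin >= eps) return(K)
  bump <- eps - lmin
  kb_log("kinship", sprintf("PD repair on %s matrix: diagonal += %.3g",
                            rel_kind(K), bump))
  rel_matrix(m + diag(bump, nrow(m)), kind = rel_kind(K))
}
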