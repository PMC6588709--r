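#' Read a line-level phenotype table
#'
#' Expects TSV with header `line_id  trait  blue  se`: one row per line and
#' trait, carrying the adjusted line mean (BLUE) and its standard error from
#' an upstream phenotypic analysis. The squared standard errors act as known
#' heteroscedastic residual weights in the prediction models.
#'
#' @param path TSV file.
#' @param trait trait name to select; if `NULL` and the file holds a single
#'   trait, that trait is used.
#' @return data frame with columns `line_id`, `blue`, `se`.
#' @export
read_phenotypes <- function(path, trait = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("line_id", "trait", "blue", "se")
  if (!all(need %in% names(df)))
    stop2("phenotype file must have columns: ", paste(need, collapse = ", "))
  if (is.null(trait)) {
    tr <- unique(df$trait)
    if (length(tr) > 1L)
      stop2("file holds traits ", paste(tr, collapse = ", "),
            "; pick one with `trait`")
    trait <- tr
  }
  df <- df[df$trait == trait, c("line_id", "blue", "se")]
  if (!nrow(df)) stop2("no records for trait '", trait, "'")
  validate_phenotypes(df)
}

validate_phenotypes <- function(pheno) {
  need <- c("line_id", "blue", "se")
  if (!all(need %in% names(pheno)))
    stop2("phenotypes must have columns: ", paste(need, collapse = ", "))
  pheno$line_id <- as.character(pheno$line_id)
  if (anyDuplicated(pheno$line_id))
    stop2("more than one phenotype record per line: ",
          paste(unique(pheno$line_id[duplicated(pheno$line_id)]),
                collapse = ", "))
  if (any(!is.finite(pheno$se) | pheno$se <= 0))
    stop2("every record needs a finite positive standard error")
  pheno[, need]
}

# -2 * restricted log-likelihood with no dropped constants:
# (n-p)*log(2*pi) + log|V| + log|X'V^-1 X| + y'Py, p = 1 (intercept).
# Keeping the constants makes likelihood-based comparisons across kinship
# matrices and across single-/two-kernel parameterizations valid.
neg2_reml <- function(y, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(crit = Inf))
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  xvx <- sum(Vi_1)                       # 1' V^-1 1
  mu <- sum(Vi_y) / xvx
  r <- y - mu
  Vi_r <- Vi_y - mu * Vi_1
  yPy <- sum(r * Vi_r)
  crit <- (n - 1) * log(2 * pi) + logdetV + log(xvx) + yPy
  list(crit = crit, mu = mu, Vi_r = Vi_r)
}

# Align phenotypes with a set of kinship ids; returns the training index
# machinery shared by the fitters.
blup_prepare <- function(pheno, ids) {
  pheno <- validate_phenotypes(pheno)
  miss <- setdiff(pheno$line_id, ids)
  if (length(miss))
    stop2("phenotyped line(s) absent from the kinship matrix: ",
          paste(miss, collapse = ", "))
  if (nrow(pheno) < 10)
    stop2("need at least 10 phenotyped lines, got ", nrow(pheno))
  train <- ids[ids %in% pheno$line_id]
  pheno <- pheno[match(train, pheno$line_id), ]
  list(pheno = pheno, train = train, y = pheno$blue, d = pheno$se^2)
}

#' Fit a single-kinship BLUP model by REML
#'
#' Model: `y = 1*mu + g + e` on the phenotyped lines, with
#' `g ~ N(0, K * sigma2_g)` and `e ~ N(0, sigma2_e * diag(se^2))` — the
#' squared standard errors of the line BLUEs enter as known relative
#' residual weights. By default a free residual scale `sigma2_e` is
#' estimated; `fixed_r = TRUE` pins `sigma2_e = 1` so the residual
#' covariance is exactly `diag(se^2)`.
#'
#' REML is computed by a one-time eigendecomposition of
#' `D^-1/2 K_TT D^-1/2` followed by Brent maximization of the profiled
#' restricted likelihood over the variance ratio. Predicted additive values
#' are returned for every id in `K`, phenotyped or not, via the joint
#' covariance (equivalent to the mixed-model equations with zero residual
#' precision on unphenotyped lines).
#'
#' @param pheno data frame `line_id`, `blue`, `se`.
#' @param K a `rel_matrix` (use [ensure_pd()] first if in doubt).
#' @param fixed_r if `TRUE`, fix `sigma2_e = 1` (residual covariance exactly
#'   the squared SEs).
#' @param fixed_vc optional list `sigma2_g`, `sigma2_e`: skip REML and BLUP
#'   at these components.
#' @param model_tag label stored in the fit; default derived from the kind
#'   of `K`.
#' @return a `blup_fit`: list with `mu`, `gebv` (named vector over all K
#'   ids), `vc` (`sigma2_g`, `sigma2_e`), `h2`, `reml_loglik`, `converged`,
#'   `boundary`, `model_tag`, `train_ids`.
#' @export
fit_single_kernel <- function(pheno, K, fixed_r = FALSE, fixed_vc = NULL,
                              model_tag = NULL) {
  ids <- rel_ids(K)
  prep <- blup_prepare(pheno, ids)
  y <- prep$y; d <- prep$d; train <- prep$train
  n <- length(y)
  Km <- unclass(K)
  Ktt <- Km[train, train, drop = FALSE]

  sd_half <- sqrt(d)
  S <- Ktt / tcrossprod(sd_half)          # D^-1/2 K D^-1/2
  eg <- eigen(S, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y / sd_half)[, 1]
  xt <- crossprod(eg$vectors, 1 / sd_half)[, 1]
  logdetD <- sum(log(d))
  vary <- stats::var(y)
  floor_v <- 1e-10 * vary

  # profiled -2 REML criterion as a function of the ratio sigma2_g/sigma2_e
  crit_ratio <- function(ratio) {
    v <- 1 + ratio * lam
    xvx <- sum(xt^2 / v)
    mu <- sum(xt * yt / v) / xvx
    rss <- sum((yt - mu * xt)^2 / v)
    s2e <- rss / (n - 1)
    (n - 1) * log(2 * pi) + logdetD + (n - 1) * log(s2e) + sum(log(v)) +
      log(xvx) + (n - 1)
  }
  # fixed-R: sigma2_e = 1, optimize sigma2_g directly
  crit_s2g <- function(s2g) {
    v <- 1 + s2g * lam
    xvx <- sum(xt^2 / v)
    mu <- sum(xt * yt / v) / xvx
    rss <- sum((yt - mu * xt)^2 / v)
    (n - 1) * log(2 * pi) + logdetD + sum(log(v)) + log(xvx) + rss
  }

  converged <- TRUE; boundary <- FALSE
  if (!is.null(fixed_vc)) {
    s2g <- fixed_vc$sigma2_g; s2e <- fixed_vc$sigma2_e
  } else if (fixed_r) {
    upper <- 1e4 * vary
    opt <- stats::optimize(crit_s2g, interval = c(0, upper), tol = 1e-10)
    s2g <- max(opt$minimum, floor_v); s2e <- 1
    boundary <- opt$minimum < floor_v || opt$minimum > 0.999 * upper
  } else {
    upper <- 1e7
    opt <- stats::optimize(crit_ratio, interval = c(0, upper), tol = 1e-10)
    ratio <- opt$minimum
    v <- 1 + ratio * lam
    xvx <- sum(xt^2 / v)
    mu0 <- sum(xt * yt / v) / xvx
    s2e <- sum((yt - mu0 * xt)^2 / v) / (n - 1)
    s2g <- ratio * s2e
    boundary <- s2g < floor_v
    s2g <- max(s2g, floor_v)
  }

  # final quantities at (s2g, s2e) on the common likelihood convention
  v <- s2g * lam + s2e
  xvx <- sum(xt^2 / v)
  mu <- sum(xt * yt / v) / xvx
  rt <- yt - mu * xt
  loglik <- -0.5 * ((n - 1) * log(2 * pi) + logdetD + sum(log(v)) +
                      log(xvx) + sum(rt^2 / v))
  # V^-1 (y - mu) back on the original scale
  Vi_r <- (eg$vectors %*% (rt / v))[, 1] / sd_half
  gebv <- s2g * (Km[, train, drop = FALSE] %*% Vi_r)[, 1]
  names(gebv) <- ids

  tag <- model_tag %||% switch(rel_kind(K), A = "A-BLUP", G = "G-BLUP",
                               Gs = "G-BLUP", K = "K-BLUP")
  structure(list(mu = mu, gebv = gebv,
                 vc = list(sigma2_g = s2g, sigma2_e = s2e),
                 h2 = s2g / (s2g + s2e),
                 reml_loglik = loglik, converged = converged,
                 boundary = boundary, model_tag = tag, train_ids = train),
            class = "blup_fit")
}

#' Fit the two-kinship (pedigree + genomic) BLUP model by REML
#'
#' Model: `y = 1*mu + m + a + e` with `m ~ N(0, Gs * sigma2_m)` (additive
#' effects captured by markers), `a ~ N(0, A * sigma2_a)` (residual
#' polygenic effects), `e ~ N(0, sigma2_e * diag(se^2))`. Total additive
#' effects are `g = m + a` with `sigma2_g = sigma2_m + sigma2_a`; the
#' implied pedigree weight is `w = sigma2_a / (sigma2_a + sigma2_m)`.
#'
#' REML maximizes over log-variances by a Nelder-Mead start followed by
#' average-information (AI) refinement with step halving; convergence when
#' the relative log-likelihood change drops below 1e-8. The log-likelihood
#' uses the same constant convention as [fit_single_kernel()] so the two are
#' directly comparable.
#'
#' @param pheno data frame `line_id`, `blue`, `se`.
#' @param A pedigree `rel_matrix` over the study lines.
#' @param Gs rescaled genomic `rel_matrix` on the same ids.
#' @param fixed_r if `TRUE`, fix `sigma2_e = 1`.
#' @param fixed_vc optional list `sigma2_m`, `sigma2_a`, `sigma2_e`: skip
#'   REML.
#' @param max_iter maximum AI iterations.
#' @return a `blup_fit` with additionally `vc$sigma2_m`, `vc$sigma2_a`,
#'   `w_implied`, and component predictions `m_hat`, `a_hat`
#'   (`gebv = m_hat + a_hat`).
#' @export
fit_two_kernel <- function(pheno, A, Gs, fixed_r = FALSE, fixed_vc = NULL,
                           max_iter = 200L) {
  Gs <- rel_align(A, Gs, "A", "Gs")
  ids <- rel_ids(A)
  prep <- blup_prepare(pheno, ids)
  y <- prep$y; d <- prep$d; train <- prep$train
  n <- length(y)
  Am <- unclass(A); Gm <- unclass(Gs)
  At <- Am[train, train, drop = FALSE]
  Gt <- Gm[train, train, drop = FALSE]
  Dt <- diag(d, n)
  vary <- stats::var(y)
  floor_v <- 1e-10 * vary

  build_V <- function(th) th[1] * Gt + th[2] * At + th[3] * Dt
  crit <- function(th) neg2_reml(y, build_V(th))$crit

  converged <- TRUE; boundary <- FALSE; iters <- 0L
  if (!is.null(fixed_vc)) {
    th <- c(fixed_vc$sigma2_m, fixed_vc$sigma2_a, fixed_vc$sigma2_e)
  } else {
    free <- if (fixed_r) 1:2 else 1:3
    th0 <- c(vary / 4, vary / 4, if (fixed_r) 1 else vary / 2)
    nm_fn <- function(lt) {
      th <- th0; th[free] <- exp(lt)
      crit(th)
    }
    nm <- stats::optim(log(th0[free]), nm_fn, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-10))
    th <- th0; th[free] <- exp(nm$par)

    # AI-REML refinement with step halving; log-likelihood must not decrease
    Vmats <- list(Gt, At, Dt)
    cur <- crit(th)
    for (it in seq_len(max_iter)) {
      iters <- it
      V <- build_V(th)
      ch <- chol(V)
      Vi <- chol2inv(ch)
      Vi1 <- Vi %*% rep(1, n)
      P <- Vi - tcrossprod(Vi1) / sum(Vi1)
      Py <- P %*% y
      score <- numeric(3); AI <- matrix(0, 3, 3)
      PVPy <- lapply(Vmats, function(M) P %*% (M %*% Py))
      for (i in free)
        score[i] <- -0.5 * (sum(P * Vmats[[i]]) -
                              crossprod(Py, Vmats[[i]] %*% Py))
      for (i in free) for (j in free)
        AI[i, j] <- 0.5 * crossprod(Py, Vmats[[i]] %*% PVPy[[j]])
      step <- numeric(3)
      sol <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                      error = function(e) NULL)
      if (is.null(sol)) break
      step[free] <- sol
      new_th <- th; accepted <- FALSE
      for (h in 0:10) {
        cand <- th + step / 2^h
        cand[free] <- pmax(cand[free], floor_v)
        val <- crit(cand)
        if (is.finite(val) && val <= cur + 1e-12) {
          new_th <- cand; accepted <- TRUE
          if (abs(cur - val) < 1e-8 * (abs(cur) + 1)) {
            th <- new_th; cur <- val
            it <- max_iter   # converged
          }
          break
        }
      }
      if (!accepted) break
      delta <- abs(cur - crit(new_th))
      th <- new_th; cur <- crit(th)
      if (delta < 1e-8 * (abs(cur) + 1)) break
      if (it == max_iter) converged <- FALSE
    }
    boundary <- any(th[free] <= floor_v * 1.0001)
  }

  V <- build_V(th)
  fin <- neg2_reml(y, V)
  mu <- fin$mu; Vi_r <- fin$Vi_r
  m_hat <- th[1] * (Gm[, train, drop = FALSE] %*% Vi_r)[, 1]
  a_hat <- th[2] * (Am[, train, drop = FALSE] %*% Vi_r)[, 1]
  gebv <- m_hat + a_hat
  names(gebv) <- names(m_hat) <- names(a_hat) <- ids
  s2g <- th[1] + th[2]
  structure(list(mu = mu, gebv = gebv, m_hat = m_hat, a_hat = a_hat,
                 vc = list(sigma2_g = s2g, sigma2_m = th[1],
                           sigma2_a = th[2], sigma2_e = th[3]),
                 w_implied = if (s2g > 0) th[2] / s2g else NA_real_,
                 h2 = s2g / (s2g + th[3]),
                 reml_loglik = -0.5 * fin$crit, converged = converged,
                 boundary = boundary, iterations = iters,
                 model_tag = "AG-BLUP", train_ids = train),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("<blup_fit %s: mu = %.4f, logLik = %.3f%s>\n", x$model_tag,
              x$mu, x$reml_loglik,
              if (!x$converged) ", NOT CONVERGED"
              else if (x$boundary) ", boundary" else ""))
  vc <- x$vc
  cat("  variance components:",
      paste(sprintf("%s = %.4g", names(vc), unlist(vc)), collapse = ", "),
      "\n")
  if (!is.null(x$w_implied))
    cat(sprintf("  w_implied (maxLL weight) = %.3f\n", x$w_implied))
  invisible(x)
}

#' Likelihood-based blending weight from a two-kernel fit
#'
#' The REML estimate of the residual polygenic share,
#' `w = sigma2_a / (sigma2_a + sigma2_m)` — the weight at which the blended
#' single-matrix model is equivalent to the two-kernel fit.
#'
#' @param fit a converged `blup_fit` from [fit_two_kernel()].
#' @return fraction in \[0, 1\].
#' @export
ml_weight_from_agblup <- function(fit) {
  if (is.null(fit$vc$sigma2_m) || is.null(fit$vc$sigma2_a))
    stop2("fit is not a two-kernel (AG-BLUP) fit")
  tot <- fit$vc$sigma2_a + fit$vc$sigma2_m
  if (tot <= 0) stop2("total additive variance is zero")
  fit$vc$sigma2_a / tot
}

#' Narrow-sense heritability of line means
#'
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)`; for a two-kernel fit,
#' `sigma2_g = sigma2_m + sigma2_a`. Note this uses the residual scale as
#' estimated; in fixed-R mode `sigma2_e = 1` and the BLUE standard errors
#' carry the residual variance, so interpret against `mean(se^2)`.
#'
#' @param vc list with `sigma2_g` (or `sigma2_m` + `sigma2_a`) and
#'   `sigma2_e`, e.g. the `vc` element of a `blup_fit`.
#' @return fraction in \[0, 1\].
#' @export
heritability <- function(vc) {
  s2g <- vc$sigma2_g %||% (vc$sigma2_m + vc$sigma2_a)
  s2e <- vc$sigma2_e
  if (s2g + s2e <= 0) stop2("both variance components are zero")
  s2g / (s2g + s2e)
}

#' Ridge-type SNP-BLUP (independent G-BLUP oracle)
#'
#' Estimates marker effects by ridge BLUP at fixed variance components —
#' effect variance `sigma2_g / (2 * sum p(1-p))` with the same centering and
#' denominator as [vanraden_g()] — and returns per-line predictions
#' `W %*% beta_hat`. At matched components these must equal single-kernel
#' G-BLUP predictions exactly; the function solves the marker-effect
#' mixed-model equations directly and shares no code with
#' [fit_single_kernel()].
#'
#' @param pheno data frame `line_id`, `blue`, `se`.
#' @param geno a complete `geno_matrix` containing all phenotyped lines.
#' @param sigma2_g,sigma2_e fixed variance components.
#' @return list with `mu`, `beta` (marker effects), `pred` (named per-line
#'   predictions for every genotyped line).
#' @export
snp_blup_oracle <- function(pheno, geno, sigma2_g, sigma2_e) {
  pheno <- validate_phenotypes(pheno)
  ids <- geno_ids(geno)
  miss <- setdiff(pheno$line_id, ids)
  if (length(miss))
    stop2("phenotyped line(s) not genotyped: ", paste(miss, collapse = ", "))
  dset <- geno$dosages
  p <- colMeans(dset) / 2
  denom <- 2 * sum(p * (1 - p))
  W <- sweep(dset, 2, 2 * p)
  Wt <- W[pheno$line_id, , drop = FALSE]
  m <- ncol(W)
  sigma2_b <- sigma2_g / denom
  di <- 1 / (pheno$se^2 * sigma2_e)        # residual precisions
  if (sigma2_b <= 0) {
    mu <- sum(di * pheno$blue) / sum(di)
    pred <- stats::setNames(rep(0, nrow(W)), ids)
    return(list(mu = mu, beta = rep(0, m), pred = pred))
  }
  # normal equations for (mu, beta) with ridge penalty 1/sigma2_b
  X <- cbind(1, Wt)
  C <- crossprod(X * di, X)
  diag(C)[-1] <- diag(C)[-1] + 1 / sigma2_b
  rhs <- crossprod(X * di, pheno$blue)
  sol <- solve(C, rhs)[, 1]
  mu <- unname(sol[1]); beta <- unname(sol[-1])
  pred <- (W %*% beta)[, 1]
  names(pred) <- ids
  list(mu = mu, beta = beta, pred = pred)
}

#' Serialize a BLUP fit
#'
#' Writes variance components, intercept, log-likelihood and convergence as
#' JSON and the per-line predicted additive values as TSV.
#'
#' @param fit a `blup_fit`.
#' @param json_path,tsv_path output files.
#' @export
write_blup_fit <- function(fit, json_path, tsv_path) {
  meta <- list(model_tag = fit$model_tag, mu = fit$mu, vc = fit$vc,
               h2 = fit$h2, w_implied = fit$w_implied,
               reml_loglik = fit$reml_loglik, converged = fit$converged,
               boundary = fit$boundary)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)], json_path,
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(line_id = names(fit$gebv), gebv = fit$gebv),
    tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(fit)
}
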