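#' Build a family-structured cross-validation fold plan
#'
#' Two schemes mirroring two selection scenarios:
#' * `"W-fam"` (within-family): each full-sib family's lines are shuffled
#'   and dealt round-robin across the `k` folds, so validation lines always
#'   have sibs in training. Every family with at least `k` members
#'   contributes to every fold; smaller families cover a random subset of
#'   folds (round-robin from a random offset).
#' * `"A-fam"` (among-family): whole families are shuffled and dealt
#'   round-robin to folds, so no family is ever split between a validation
#'   fold and its training complement.
#'
#' Deterministic given `(base_seed, scheme, replicate)`; the derived seed is
#' independent of the model or blending weight, so every model sees
#' identical folds.
#'
#' @param scheme `"W-fam"` or `"A-fam"`.
#' @param families named list mapping family key to line ids (see
#'   [full_sib_families()]).
#' @param k number of folds.
#' @param replicate replicate index (1-based).
#' @param base_seed integer base seed.
#' @return a `fold_plan`: list with `scheme`, `replicate`, `folds` (list of
#'   `k` disjoint id vectors partitioning all lines), `seed`.
#' @export
make_folds <- function(scheme = c("W-fam", "A-fam"), families, k = 5L,
                       replicate = 1L, base_seed = 1L) {
  scheme <- match.arg(scheme)
  if (k < 2) stop2("k must be >= 2")
  seed <- derive_seed(base_seed, scheme, replicate)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  folds <- vector("list", k)
  if (scheme == "A-fam") {
    if (length(families) < k)
      stop2("A-fam needs at least k = ", k, " families, got ",
            length(families))
    ord <- sample(length(families))
    for (i in seq_along(ord)) {
      f <- (i - 1L) %% k + 1L
      folds[[f]] <- c(folds[[f]], families[[ord[i]]])
    }
  } else {
    for (fam in families) {
      ids <- if (length(fam) > 1L) sample(fam) else fam
      offset <- sample.int(k, 1L) - 1L
      for (i in seq_along(ids)) {
        f <- (offset + i - 1L) %% k + 1L
        folds[[f]] <- c(folds[[f]], ids[i])
      }
    }
  }
  structure(list(scheme = scheme, replicate = as.integer(replicate),
                 folds = folds, seed = seed), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan %s replicate %d: %d folds of sizes %s>\n",
              x$scheme, x$replicate, length(x$folds),
              paste(lengths(x$folds), collapse = ", ")))
  invisible(x)
}

#' Export a fold plan as a tidy table
#' @param plan a `fold_plan`.
#' @return data frame `line_id`, `scheme`, `replicate`, `fold`.
#' @export
fold_plan_table <- function(plan) {
  data.frame(
    line_id = unlist(plan$folds),
    scheme = plan$scheme, replicate = plan$replicate,
    fold = rep(seq_along(plan$folds), lengths(plan$folds)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-validated sweep of the blending weight
#'
#' For each scheme and replicate, folds are built once and reused for every
#' blending weight and for the AG-BLUP comparator (same-seed contract). For
#' each fold, the model is fitted on the training lines only (validation
#' BLUEs withheld entirely), validation lines are predicted, predictions are
#' pooled across the `k` folds, and quality metrics are computed per
#' replicate on the pooled set.
#'
#' @param pheno data frame `line_id`, `blue`, `se`; lines without a
#'   phenotype are excluded from fold construction.
#' @param A pedigree `rel_matrix` over the study lines.
#' @param Gs rescaled genomic `rel_matrix`, same ids.
#' @param families named list from [full_sib_families()] (keys -> line ids);
#'   entries are intersected with the phenotyped lines.
#' @param grid numeric vector of blending weights in \[0, 1\].
#' @param schemes subset of `c("W-fam", "A-fam")`.
#' @param k folds per replicate.
#' @param n_reps number of replicates.
#' @param base_seed integer seed governing all fold randomness.
#' @param include_agblup also run the two-kernel AG-BLUP competitor, which
#'   re-estimates its variance components on every training set.
#' @param fixed_r passed to the fitters.
#' @return a `cv_sweep`: list with `results` (tidy data frame: `scheme`,
#'   `model`, `w`, `replicate`, `n`, `r_pa`, `bias_slope`, `msep`,
#'   `msep_resid`, `n_failed`), `predictions` (pooled per-replicate
#'   predictions per model), `realized`, `grid`, `schemes`, `k`, `n_reps`,
#'   `base_seed`, `fold_plans`.
#' @export
run_cv <- function(pheno, A, Gs, families, grid = seq(0, 1, 0.1),
                   schemes = c("W-fam", "A-fam"), k = 5L, n_reps = 20L,
                   base_seed = 1L, include_agblup = TRUE, fixed_r = FALSE) {
  if (any(grid < 0 | grid > 1)) stop2("grid weights must lie in [0, 1]")
  grid <- sort(unique(grid))
  schemes <- match.arg(schemes, c("W-fam", "A-fam"), several.ok = TRUE)
  pheno <- validate_phenotypes(pheno)
  Gs <- rel_align(A, Gs, "A", "Gs")
  lines <- intersect(rel_ids(A), pheno$line_id)
  pheno <- pheno[match(lines, pheno$line_id), ]
  fam_ph <- lapply(families, intersect, y = lines)
  fam_ph <- fam_ph[lengths(fam_ph) > 0L]
  if (!setequal(unlist(fam_ph), lines))
    stop2("families must cover every phenotyped line")
  realized <- stats::setNames(pheno$blue, pheno$line_id)

  Ks <- lapply(grid, function(w) ensure_pd(blend(A, Gs, w)))
  names(Ks) <- sprintf("w=%g", grid)
  A_pd <- ensure_pd(A); Gs_pd <- ensure_pd(Gs)
  model_keys <- c(names(Ks), if (include_agblup) "AG-BLUP")

  rows <- list(); preds <- list(); plans <- list()
  for (scheme in schemes) {
    preds[[scheme]] <- lapply(stats::setNames(nm = model_keys),
                              function(m) vector("list", n_reps))
    for (rep_i in seq_len(n_reps)) {
      plan <- make_folds(scheme, fam_ph, k = k, replicate = rep_i,
                         base_seed = base_seed)
      plans[[paste(scheme, rep_i)]] <- plan
      for (key in model_keys) {
        pooled <- numeric(0); n_failed <- 0L
        for (fold in plan$folds) {
          if (!length(fold)) next
          train_pheno <- pheno[!pheno$line_id %in% fold, ]
          fit <- tryCatch({
            if (key == "AG-BLUP")
              fit_two_kernel(train_pheno, A_pd, Gs_pd, fixed_r = fixed_r)
            else
              fit_single_kernel(train_pheno, Ks[[key]], fixed_r = fixed_r)
          }, error = function(e) NULL)
          if (is.null(fit) || !fit$converged) {
            n_failed <- n_failed + 1L
            next
          }
          pooled <- c(pooled, fit$gebv[fold])
        }
        preds[[scheme]][[key]][[rep_i]] <- pooled
        ok <- length(pooled) >= 3
        qm <- if (ok) quality_metrics(pooled, realized[names(pooled)])
              else data.frame(n = length(pooled), r_pa = NA_real_,
                              bias_slope = NA_real_, msep = NA_real_,
                              msep_resid = NA_real_)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(scheme = scheme, model = key,
                     w = if (key == "AG-BLUP") NA_real_
                         else grid[match(key, names(Ks))],
                     replicate = rep_i, stringsAsFactors = FALSE),
          qm, data.frame(n_failed = n_failed))
      }
    }
  }
  structure(list(results = do.call(rbind, rows), predictions = preds,
                 realized = realized, grid = grid, schemes = schemes,
                 k = k, n_reps = n_reps, base_seed = base_seed,
                 fold_plans = plans),
            class = "cv_sweep")
}

#' @export
print.cv_sweep <- function(x, ...) {
  cat(sprintf("<cv_sweep: %s; grid of %d weights%s; k = %d, %d replicates>\n",
              paste(x$schemes, collapse = " + "), length(x$grid),
              if ("AG-BLUP" %in% x$results$model) " + AG-BLUP" else "",
              x$k, x$n_reps))
  print(utils::head(summarize_sweep(x), 12))
  invisible(x)
}

#' Aggregate a sweep over replicates
#'
#' @param sweep a `cv_sweep`.
#' @return data frame with mean and SD of each metric per (scheme, model),
#'   plus the number of replicates with a computable metric.
#' @export
summarize_sweep <- function(sweep) {
  res <- sweep$results
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  out <- do.call(rbind, lapply(
    split(res, list(res$scheme, res$model), drop = TRUE), function(g) {
      data.frame(scheme = g$scheme[1], model = g$model[1], w = g$w[1],
                 n_reps_ok = sum(!is.na(g$r_pa)),
                 r_pa_mean = mean(g$r_pa, na.rm = TRUE),
                 r_pa_sd = stats::sd(g$r_pa, na.rm = TRUE),
                 bias_mean = mean(g$bias_slope, na.rm = TRUE),
                 bias_sd = stats::sd(g$bias_slope, na.rm = TRUE),
                 msep_mean = mean(g$msep, na.rm = TRUE),
                 msep_sd = stats::sd(g$msep, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$scheme, out$w, na.last = TRUE), ]
}

#' Select the grid weight maximizing mean predictive ability
#'
#' Ties are broken toward the smallest weight (the least pedigree-dependent
#' model among equals).
#'
#' @param sweep a `cv_sweep`.
#' @param scheme which scheme to select for.
#' @return the optimal weight (scalar from the grid).
#' @export
select_optimal_w <- function(sweep, scheme) {
  s <- summarize_sweep(sweep)
  s <- s[s$scheme == scheme & !is.na(s$w), ]
  if (nrow(s) < 2) stop2("need at least 2 grid points for scheme ", scheme)
  if (all(!is.finite(s$r_pa_mean)))
    stop2("all metrics missing for scheme ", scheme)
  s <- s[order(s$w), ]
  s$w[which.max(s$r_pa_mean)]
}

#' Compare two models' predictive abilities within a sweep
#'
#' Applies the Hotelling-Williams test per replicate to the pooled
#' validation predictions (the realized line values are the shared
#' variable), summarizes the replicate p-values by their median, and adds a
#' paired two-sided t test across the replicate-level predictive abilities
#' as a robustness companion. Replicates where either model failed are
#' dropped pairwise.
#'
#' @param sweep a `cv_sweep`.
#' @param model1,model2 model keys as in `sweep$results$model` (e.g. `"w=0"`,
#'   `"AG-BLUP"`).
#' @param scheme scheme to compare within.
#' @return one-row data frame: `model_1`, `model_2`, `scheme`,
#'   `mean_r_1`, `mean_r_2`, `t_median`, `df`, `p_median`,
#'   `p_paired`, `n_reps_used`.
#' @export
compare_models <- function(sweep, model1, model2, scheme) {
  p1 <- sweep$predictions[[scheme]][[model1]]
  p2 <- sweep$predictions[[scheme]][[model2]]
  if (is.null(p1) || is.null(p2))
    stop2("unknown model key; available: ",
          paste(names(sweep$predictions[[scheme]]), collapse = ", "))
  hw <- list(); r1 <- c(); r2 <- c()
  for (i in seq_len(sweep$n_reps)) {
    a <- p1[[i]]; b <- p2[[i]]
    shared <- intersect(names(a), names(b))
    if (length(shared) < 4) next
    y <- sweep$realized[shared]
    r12 <- stats::cor(y, a[shared]); r13 <- stats::cor(y, b[shared])
    r23 <- stats::cor(a[shared], b[shared])
    res <- tryCatch(hotelling_williams(r12, r13, r23, length(shared)),
                    error = function(e) NULL)
    if (!is.null(res)) hw[[length(hw) + 1L]] <- res
    r1 <- c(r1, r12); r2 <- c(r2, r13)
  }
  if (!length(hw)) stop2("no replicate allowed a comparison")
  pp <- if (length(r1) >= 2 && stats::sd(r1 - r2) > 0)
    stats::t.test(r1, r2, paired = TRUE)$p.value else NA_real_
  data.frame(model_1 = model1, model_2 = model2, scheme = scheme,
             mean_r_1 = mean(r1), mean_r_2 = mean(r2),
             t_median = stats::median(vapply(hw, `[[`, 0, "t_stat")),
             df = hw[[1]]$df,
             p_median = stats::median(vapply(hw, `[[`, 0, "p_value")),
             p_paired = pp, n_reps_used = length(hw),
             stringsAsFactors = FALSE)
}
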