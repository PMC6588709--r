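#' Predictive ability
#'
#' Pearson correlation between predicted additive values and realized line
#' values (the line BLUEs) in a validation set.
#'
#' @param predicted,realized aligned numeric vectors, length >= 3.
#' @return correlation in \[-1, 1\], or `NA` (with a logged cause) if either
#'   vector has zero variance.
#' @export
predictive_ability <- function(predicted, realized) {
  check_aligned(predicted, realized)
  if (stats::sd(predicted) == 0 || stats::sd(realized) == 0) {
    kb_log("evaluation", "zero variance: predictive ability undefined")
    return(NA_real_)
  }
  stats::cor(predicted, realized)
}

#' Empirical bias slope
#'
#' OLS slope of realized on predicted. A slope of 1 marks an empirically
#' unbiased predictor; a slope below 1 indicates inflated (over-dispersed)
#' predictions.
#'
#' @inheritParams predictive_ability
#' @return slope, or `NA` if the predictions have zero variance.
#' @export
bias_regression <- function(predicted, realized) {
  check_aligned(predicted, realized)
  vp <- stats::var(predicted)
  if (vp == 0) {
    kb_log("evaluation", "zero variance in predictions: bias slope undefined")
    return(NA_real_)
  }
  stats::cov(predicted, realized) / vp
}

#' Mean squared error of prediction
#'
#' Two definitions are supported. `"squared_difference"` (default) is
#' `mean((realized - predicted)^2)`, which penalizes both bias and
#' imprecision. `"regression_residual"` is the mean squared OLS residual of
#' realized on predicted, which removes location and slope bias.
#'
#' @inheritParams predictive_ability
#' @param definition which MSEP to compute.
#' @return non-negative scalar.
#' @export
msep <- function(predicted, realized,
                 definition = c("squared_difference", "regression_residual")) {
  definition <- match.arg(definition)
  check_aligned(predicted, realized)
  if (definition == "squared_difference")
    return(mean((realized - predicted)^2))
  b <- bias_regression(predicted, realized)
  if (is.na(b)) return(NA_real_)
  a <- mean(realized) - b * mean(predicted)
  mean((realized - a - b * predicted)^2)
}

check_aligned <- function(predicted, realized) {
  if (length(predicted) != length(realized))
    stop2("predicted and realized must have equal length")
  if (length(predicted) < 3)
    stop2("need at least 3 validation lines")
  if (anyNA(predicted) || anyNA(realized))
    stop2("NA values in metric inputs; filter non-converged folds first")
  invisible(TRUE)
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Tests whether two correlations `r12` and `r13` that share the common
#' variable 1 (here: the realized line values, correlated with two models'
#' predictions) differ. Uses Steiger's form of the Williams t statistic:
#' \deqn{t = (r12 - r13) \sqrt{\frac{(n-1)(1+r23)}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r23)^3}}}
#' with \eqn{|R| = 1 - r12^2 - r13^2 - r23^2 + 2 r12 r13 r23} and
#' \eqn{\bar r = (r12 + r13)/2}; two-sided p from Student t with `n - 3`
#' degrees of freedom.
#'
#' @param r12,r13 correlations of the common variable with predictor 2 and
#'   predictor 3.
#' @param r23 correlation between the two predictors.
#' @param n shared sample size (>= 4).
#' @return list with `r12`, `r13`, `r23`, `n`, `t_stat`, `df`, `p_value`.
#' @export
hotelling_williams <- function(r12, r13, r23, n) {
  if (n < 4) stop2("Hotelling-Williams test needs n >= 4")
  rs <- c(r12, r13, r23)
  if (any(!is.finite(rs)) || any(abs(rs) >= 1))
    stop2("correlations must lie strictly inside (-1, 1)")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= 0)
    stop2("degenerate correlation matrix (|R| <= 0)")
  rbar <- (r12 + r13) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3
  t_stat <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  df <- n - 3
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(r12 = r12, r13 = r13, r23 = r23, n = n, t_stat = t_stat, df = df,
       p_value = p)
}

#' Prediction-quality metrics for one validation set
#'
#' Convenience wrapper computing predictive ability, bias slope and both
#' MSEP definitions at once.
#'
#' @inheritParams predictive_ability
#' @return one-row data frame `n`, `r_pa`, `bias_slope`, `msep`,
#'   `msep_resid`.
#' @export
quality_metrics <- function(predicted, realized) {
  data.frame(
    n = length(predicted),
    r_pa = predictive_ability(predicted, realized),
    bias_slope = bias_regression(predicted, realized),
    msep = msep(predicted, realized, "squared_difference"),
    msep_resid = msep(predicted, realized, "regression_residual"))
}
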