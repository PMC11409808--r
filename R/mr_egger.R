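#' Inverse-variance-weighted MR estimate from summary statistics
#'
#' Weighted regression of per-instrument outcome effects on exposure
#' effects through the origin with weights 1/se_out^2 — equivalently the
#' weighted mean of the per-instrument Wald ratios with weights
#' `beta_exp^2 / se_out^2`.
#'
#' @param beta_exp,beta_out Per-instrument exposure and outcome effects.
#' @param se_out Outcome-effect standard errors.
#' @return List: `estimate`, `se` (fixed-effect).
#' @export
mr_ivw <- function(beta_exp, beta_out, se_out) {
  w <- 1 / se_out^2
  den <- sum(w * beta_exp^2)
  list(estimate = sum(w * beta_exp * beta_out) / den, se = sqrt(1 / den))
}

#' MR-Egger regression
#'
#' Weighted least squares of per-instrument outcome effects on exposure
#' effects with a free intercept (weights 1/se_out^2). A non-zero intercept
#' indicates directional pleiotropy; the slope is a pleiotropy-robust
#' causal estimate. Effect alleles are re-oriented so that all exposure
#' effects are non-negative (the standard identification requirement).
#' Standard errors use the regression's multiplicative overdispersion, and
#' the intercept p-value is from a t distribution on k - 2 degrees of
#' freedom.
#'
#' @param beta_exp,se_exp,beta_out,se_out Per-instrument summary
#'   statistics; at least 3 instruments.
#' @return An `egger_result`: slope, slope_se, slope_p, intercept,
#'   intercept_se, intercept_p, k.
#' @export
mr_egger <- function(beta_exp, se_exp, beta_out, se_out) {
  k <- length(beta_exp)
  if (k < 3) stop("MR-Egger needs at least 3 instruments")
  flip <- sign(beta_exp); flip[flip == 0] <- 1
  be <- beta_exp * flip; bo <- beta_out * flip
  w <- 1 / se_out^2
  fit <- stats::lm(bo ~ be, weights = w)
  co <- summary(fit)$coefficients
  structure(list(slope = co["be", "Estimate"], slope_se = co["be", "Std. Error"],
                 slope_p = co["be", "Pr(>|t|)"],
                 intercept = co["(Intercept)", "Estimate"],
                 intercept_se = co["(Intercept)", "Std. Error"],
                 intercept_p = 2 * stats::pt(-abs(co["(Intercept)", "t value"]),
                                             df = k - 2),
                 k = k),
            class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("MR-Egger (k = %d): slope %.4f (SE %.4f, p = %.3g); intercept %.4f (p = %.3g)\n",
              x$k, x$slope, x$slope_se, x$slope_p, x$intercept, x$intercept_p))
  invisible(x)
}
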