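#' Construct a hazard-ratio effect estimate
#'
#' Container for a hazard ratio with 95\% confidence interval on a stated
#' exposure increment; the CI is `exp(loghr +/- 1.96 se)` by construction.
#'
#' @param loghr,se Log hazard ratio per unit of exposure and its SE.
#' @param method Estimator label (`"2SLS-Cox"`, `"MR-Egger"`, `"MVMR"`,
#'   `"observational"`, ...).
#' @param increment Exposure increment the HR is reported per (default 1
#'   unit; e.g. 100 for "per 100 mL/day" when the trait is in mL/day).
#' @param subgroup Subgroup label (default `"all"`).
#' @param f F-statistic of the instrument, if any.
#' @param p_pleiotropy Pleiotropy diagnostic p-value, if any.
#' @param n,events Sample and event counts.
#' @return An `effect_estimate` list with `hr`, `ci_low`, `ci_high`.
#' @export
effect_estimate <- function(loghr, se, method, increment = 1,
                            subgroup = "all", f = NA_real_,
                            p_pleiotropy = NA_real_, n = NA_integer_,
                            events = NA_integer_) {
  b <- loghr * increment; s <- se * increment
  structure(list(hr = exp(b), ci_low = exp(b - 1.96 * s),
                 ci_high = exp(b + 1.96 * s), loghr = b, se = s,
                 increment = increment, method = method, subgroup = subgroup,
                 f = f, p_pleiotropy = p_pleiotropy, n = n, events = events),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s [%s]: HR = %.2f (95%% CI %.2f-%.2f) per %g unit(s); n = %s, events = %s\n",
              x$method, x$subgroup, x$hr, x$ci_low, x$ci_high, x$increment,
              x$n, x$events))
  if (is.finite(x$f)) cat(sprintf("  instrument F = %.1f\n", x$f))
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ...) {
  data.frame(method = x$method, subgroup = x$subgroup, hr = x$hr,
             ci_low = x$ci_low, ci_high = x$ci_high, loghr = x$loghr,
             se = x$se, increment = x$increment, f = x$f,
             p_pleiotropy = x$p_pleiotropy, n = x$n, events = x$events)
}

#' First stage of the two-stage estimator
#'
#' Regresses the exposure on its allele score (plus covariates) and returns
#' fitted exposure values for every sample with a non-missing score, along
#' with the instrument-strength diagnostics. Scores with F below `min_f`
#' are refused unless `allow_weak = TRUE`, the conventional weak-instrument
#' gate.
#'
#' @param trait Exposure values.
#' @param score Allele score.
#' @param covariates Optional covariates.
#' @param min_f Weak-instrument threshold (default 10).
#' @param allow_weak Override the gate.
#' @return List: `fitted` (NA where the score or covariates are missing),
#'   `diagnostics` (an `instrument_diagnostics`), `fit`.
#' @export
first_stage <- function(trait, score, covariates = NULL, min_f = 10,
                        allow_weak = FALSE) {
  if (stats::sd(score, na.rm = TRUE) == 0) stop("constant allele score")
  dat <- data.frame(trait = trait, score = score)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- stats::lm(trait ~ ., data = dat)
  diag <- f_statistic(fit)
  if (diag$F < min_f && !allow_weak) {
    stop(sprintf(paste("weak instrument: first-stage F = %.2f < %g;",
                       "set allow_weak = TRUE to override"), diag$F, min_f))
  }
  predictable <- !is.na(score)
  if (!is.null(covariates)) {
    predictable <- predictable & stats::complete.cases(covariates)
  }
  fitted <- rep(NA_real_, length(trait))
  fitted[predictable] <- stats::predict(
    fit, newdata = dat[predictable, setdiff(names(dat), "trait"), drop = FALSE])
  list(fitted = fitted, diagnostics = diag, fit = fit)
}

#' Second stage: age-scale Cox model on the fitted exposure
#'
#' Cox partial-likelihood fit with age as the time scale (delayed entry at
#' the recruitment age, Efron ties) of the outcome on the stage-1 fitted
#' exposure values. The default SE is the model-based Cox SE; see
#' [mr_fit()] for a bootstrap that propagates first-stage uncertainty.
#'
#' @param fitted Stage-1 fitted exposure values.
#' @param outcome An `outcome_table`.
#' @param covariates Optional covariates.
#' @param increment Exposure increment for reporting.
#' @param method,subgroup Labels passed to [effect_estimate()].
#' @param f Instrument F to attach.
#' @return An `effect_estimate`.
#' @export
second_stage_cox <- function(fitted, outcome, covariates = NULL,
                             increment = 1, method = "2SLS-Cox",
                             subgroup = "all", f = NA_real_) {
  keep <- !is.na(fitted)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  if (sum(outcome$event[keep]) < 1) stop("no events among rows with fitted values")
  dat <- data.frame(.x = fitted[keep])
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates)[keep, , drop = FALSE])
  dat$surv <- survival::Surv(outcome$entry_age[keep], outcome$exit_age[keep],
                             outcome$event[keep])
  fit <- survival::coxph(surv ~ ., data = dat, ties = "efron")
  co <- summary(fit)$coefficients
  effect_estimate(co[".x", "coef"], co[".x", "se(coef)"], method = method,
                  increment = increment, subgroup = subgroup, f = f,
                  n = sum(keep), events = sum(outcome$event[keep]))
}

#' One-sample MR by two-stage least squares with a Cox second stage
#'
#' Convenience wrapper running [first_stage()] and [second_stage_cox()],
#' optionally with a nonparametric bootstrap over individuals that re-runs
#' both stages to propagate first-stage uncertainty into the SE.
#'
#' @param trait Exposure values.
#' @param score Allele score.
#' @param outcome An `outcome_table`.
#' @param covariates Optional covariates (used in both stages).
#' @param increment Exposure increment for reporting.
#' @param bootstrap Number of bootstrap resamples (0 = model-based SE only).
#' @param seed Seed for the bootstrap.
#' @param min_f,allow_weak Weak-instrument gate, see [first_stage()].
#' @param subgroup Label.
#' @return An `effect_estimate`; when bootstrapped, the model-based
#'   estimate is kept and the SE (hence CI) is replaced by the bootstrap
#'   SE, with the model-based version attached as attribute
#'   `"model_based"`.
#' @export
mr_fit <- function(trait, score, outcome, covariates = NULL, increment = 1,
                   bootstrap = 0, seed = 1L, min_f = 10, allow_weak = FALSE,
                   subgroup = "all") {
  s1 <- first_stage(trait, score, covariates, min_f = min_f,
                    allow_weak = allow_weak)
  est <- second_stage_cox(s1$fitted, outcome, covariates,
                          increment = increment, subgroup = subgroup,
                          f = s1$diagnostics$F)
  if (bootstrap > 0) {
    set.seed(as.integer(seed))
    n <- length(trait)
    bs <- vapply(seq_len(bootstrap), function(b) {
      ix <- sample.int(n, n, replace = TRUE)
      out_b <- outcome[ix, , drop = FALSE]
      class(out_b) <- class(outcome)
      cov_b <- if (is.null(covariates)) NULL else
        as.data.frame(covariates)[ix, , drop = FALSE]
      fb <- tryCatch({
        s1b <- first_stage(trait[ix], score[ix], cov_b, allow_weak = TRUE)
        second_stage_cox(s1b$fitted, out_b, cov_b)$loghr
      }, error = function(e) NA_real_)
      fb
    }, 0)
    se_boot <- stats::sd(bs, na.rm = TRUE)
    boot_est <- effect_estimate(est$loghr / increment, se_boot,
                                method = "2SLS-Cox (bootstrap SE)",
                                increment = increment, subgroup = subgroup,
                                f = s1$diagnostics$F, n = est$n,
                                events = est$events)
    attr(boot_est, "model_based") <- est
    return(boot_est)
  }
  est
}

#' Wald ratio estimate for a single instrument
#'
#' The ratio of the variant-outcome to the variant-exposure association,
#' with a delta-method SE; algebraically identical to single-instrument
#' two-stage least squares with a linear second stage.
#'
#' @param beta_out Variant-outcome association (log-hazard scale).
#' @param beta_exp Variant-exposure association (trait units); must be
#'   non-zero.
#' @param se_out,se_exp Standard errors (exposure SE contributes the
#'   second-order delta term; default 0).
#' @return List: `estimate`, `se`.
#' @export
wald_ratio <- function(beta_out, beta_exp, se_out = NA_real_, se_exp = 0) {
  if (beta_exp == 0) stop("beta_exp must be non-zero")
  est <- beta_out / beta_exp
  se <- sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  list(estimate = est, se = se)
}

#' Re-run an estimator in sex and subsite subgroups
#'
#' Sex subgroups are sample subsets; subsite analyses keep the whole
#' sample and censor the competing subsite's events at their event age.
#'
#' @param outcome An `outcome_table`.
#' @param estimator Function `(outcome, rows)` returning an
#'   `effect_estimate`, where `rows` is the logical row filter to apply to
#'   sample-level inputs and `outcome` already carries the subsite
#'   censoring.
#' @param by Any of `"sex"`, `"subsite"`.
#' @return Data frame of estimates with a `subgroup` column.
#' @export
subgroup_run <- function(outcome, estimator, by = c("sex", "subsite")) {
  by <- match.arg(by, several.ok = TRUE)
  specs <- list(list(label = "all", rows = rep(TRUE, nrow(outcome)),
                     subsite = NULL))
  if ("sex" %in% by) {
    specs <- c(specs,
               list(list(label = "men", rows = outcome$sex == 0, subsite = NULL),
                    list(label = "women", rows = outcome$sex == 1, subsite = NULL)))
  }
  if ("subsite" %in% by) {
    specs <- c(specs,
               list(list(label = "colon", rows = rep(TRUE, nrow(outcome)),
                         subsite = "colon"),
                    list(label = "rectal", rows = rep(TRUE, nrow(outcome)),
                         subsite = "rectal")))
  }
  rows_out <- lapply(specs, function(sp) {
    if (!any(sp$rows)) stop("empty subgroup: ", sp$label)
    out <- outcome[sp$rows, , drop = FALSE]
    if (!is.null(sp$subsite)) {
      # censor competing subsite events at their event age
      competing <- out$event == 1 & out$subsite != sp$subsite
      out$event[competing] <- 0L
    }
    if (sum(out$event) < 1) stop("no events in subgroup: ", sp$label)
    class(out) <- c("outcome_table", "data.frame")
    est <- estimator(out, sp$rows)
    df <- as.data.frame(est)
    df$subgroup <- sp$label
    df
  })
  do.call(rbind, rows_out)
}
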