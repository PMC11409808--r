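#' Adjustment set for the observational Cox analysis
#'
#' The multivariable adjustment set comprises sex, family history of
#' colorectal cancer, household income, smoking, alcohol consumption
#' (dropped when alcohol itself is the exposure), body-mass index and
#' physical activity. The exposure is never allowed in its own adjustment
#' set.
#'
#' @param exposure Exposure trait label.
#' @param adjust Character vector of covariate names (default the full
#'   set above; `"alcohol"` refers to the alcohol trait column).
#' @param increment Exposure increment the HR is reported per (default 1).
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(exposure,
                           adjust = c("sex", "family_history", "income",
                                      "smoking", "alcohol", "bmi", "activity"),
                           increment = 1) {
  if (identical(exposure, "alcohol")) adjust <- setdiff(adjust, "alcohol")
  if (exposure %in% adjust) stop("exposure cannot appear in its own adjustment set")
  structure(list(exposure = exposure, adjust = adjust, increment = increment),
            class = "covariate_spec")
}

#' Observational Cox fit with age as the time scale
#'
#' Univariate or multivariable Cox proportional-hazards model of the
#' outcome on a continuous dietary exposure, with delayed entry at the
#' recruitment age and Efron tie handling, on complete cases of the
#' exposure and (for the multivariable mode) the adjustment set.
#'
#' @param exposure Numeric exposure values.
#' @param outcome An `outcome_table`.
#' @param covariates Data frame holding the adjustment-set columns (may
#'   also hold the alcohol trait column).
#' @param spec A `covariate_spec`.
#' @param mode `"univariate"` or `"multivariable"`.
#' @return An `effect_estimate` with method `"observational"`.
#' @export
cox_fit <- function(exposure, outcome, covariates = NULL,
                    spec = covariate_spec("exposure"),
                    mode = c("multivariable", "univariate")) {
  mode <- match.arg(mode)
  keep <- !is.na(exposure)
  adj <- NULL
  if (mode == "multivariable" && length(spec$adjust)) {
    present <- intersect(spec$adjust, names(covariates))
    adj <- as.data.frame(covariates)[, present, drop = FALSE]
    keep <- keep & stats::complete.cases(adj)
  }
  if (sum(outcome$event[keep]) < 1) stop("no events on analyzable rows")
  if (stats::sd(exposure[keep]) == 0) stop("exposure is constant on analyzable rows")
  dat <- data.frame(.x = exposure[keep])
  if (!is.null(adj)) dat <- cbind(dat, adj[keep, , drop = FALSE])
  dat$surv <- survival::Surv(outcome$entry_age[keep], outcome$exit_age[keep],
                             outcome$event[keep])
  fit <- survival::coxph(surv ~ ., data = dat, ties = "efron")
  if (any(!is.finite(fit$coefficients))) {
    stop("observational Cox fit did not converge (possible separation)")
  }
  co <- summary(fit)$coefficients
  effect_estimate(co[".x", "coef"], co[".x", "se(coef)"],
                  method = "observational", increment = spec$increment,
                  n = sum(keep), events = sum(outcome$event[keep]))
}

#' Screen candidate confounders by univariate Cox association
#'
#' Retains candidates associated with the outcome at `p < alpha` in a
#' univariate age-scale Cox model, and always returns the full decision
#' log.
#'
#' @param candidates Data frame of candidate covariates.
#' @param outcome An `outcome_table`.
#' @param alpha Selection threshold (default 0.05).
#' @return List: `selected` (character vector) and `log` (candidate, p,
#'   selected).
#' @export
confounder_screen <- function(candidates, outcome, alpha = 0.05) {
  if (is.null(candidates) || ncol(as.data.frame(candidates)) == 0) {
    return(list(selected = character(0),
                log = data.frame(candidate = character(0), p = numeric(0),
                                 selected = logical(0))))
  }
  candidates <- as.data.frame(candidates)
  surv <- survival::Surv(outcome$entry_age, outcome$exit_age, outcome$event)
  ps <- vapply(names(candidates), function(nm) {
    dat <- data.frame(.x = candidates[[nm]], surv = surv)
    fit <- tryCatch(survival::coxph(surv ~ .x, data = dat, ties = "efron"),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    summary(fit)$coefficients[".x", "Pr(>|z|)"]
  }, 0)
  log <- data.frame(candidate = names(candidates), p = unname(ps),
                    selected = !is.na(ps) & ps < alpha)
  list(selected = log$candidate[log$selected], log = log)
}
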