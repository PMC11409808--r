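#' Simulate a time-to-event colorectal-cancer outcome
#'
#' Event ages are drawn from a proportional-hazards model on the age scale
#' with an exponential baseline hazard and delayed entry at the recruitment
#' age: the linear predictor is the sum of each trait's causal log hazard
#' ratio times the (mean-centred) trait plus the latent confounder's
#' contribution, and follow-up is administratively censored at a fixed age.
#' Events are split into colon and rectal subsites at a configurable ratio
#' (default 2:1, the approximate case mix of a UK biobank-scale cohort).
#'
#' @param cohort A `synthetic_cohort` from [simulate_traits()].
#' @param arch The `true_architecture` used to build the cohort.
#' @param baseline_rate Exponential baseline hazard (events per person-year
#'   at the reference covariate level). The default 0.0055 yields roughly a
#'   10\% cumulative event fraction under administrative censoring at 75.
#' @param censor_age Administrative censoring age in years (default 75).
#' @param subsite_split Numeric `c(colon, rectal)` odds (default `c(2, 1)`).
#' @param seed Seed.
#' @return An `outcome_table` data frame: `entry_age`, `exit_age`, `event`
#'   (0/1), `subsite` (censored/colon/rectal), `sex`; the realized event
#'   fraction is attached as attribute `"event_fraction"`.
#' @export
simulate_outcome <- function(cohort, arch, baseline_rate = 0.0055,
                             censor_age = 75, subsite_split = c(2, 1),
                             seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(arch, "true_architecture"))
  if (any(is.na(unlist(cohort$traits)))) {
    stop("traits must be complete for outcome simulation")
  }
  entry <- cohort$covariates$age
  if (censor_age <= min(entry)) {
    stop("censoring age precedes all entry ages: empty risk set")
  }
  .set_seed(seed, 4L)
  n <- nrow(cohort$covariates)
  lp <- rep(0, n)
  for (tr in arch$traits) {
    b <- arch$log_hr[[tr]]
    if (b != 0) lp <- lp + b * (cohort$traits[[tr]] - mean(cohort$traits[[tr]]))
  }
  if (arch$confounder_log_hr != 0) {
    lp <- lp + arch$confounder_log_hr * cohort$truth$confounder
  }
  haz <- baseline_rate * exp(lp)
  if (all(haz == 0)) stop("all-zero hazard")
  # exponential hazard is memoryless: residual time after entry is Exp(haz)
  t_event <- entry + stats::rexp(n, haz)
  event <- as.integer(t_event <= censor_age)
  exit <- pmin(t_event, censor_age)
  subsite <- rep("censored", n)
  if (sum(event) > 0) {
    subsite[event == 1] <- sample(c("colon", "rectal"), sum(event),
                                  replace = TRUE,
                                  prob = subsite_split / sum(subsite_split))
  }
  out <- data.frame(entry_age = entry, exit_age = exit, event = event,
                    subsite = factor(subsite, c("censored", "colon", "rectal")),
                    sex = cohort$covariates$sex,
                    row.names = rownames(cohort$covariates))
  class(out) <- c("outcome_table", "data.frame")
  attr(out, "event_fraction") <- mean(event)
  out
}
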