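#' Declare the generating architecture of the synthetic cohort
#'
#' The architecture is the simulation ground truth: which variants are
#' causal for each dietary trait, their additive effects, the target
#' heritability, the variance shares of the family random effect and of a
#' latent confounder, and each trait's causal log hazard ratio on the
#' colorectal-cancer outcome. Traits sharing causal variants (with the same
#' effect sizes on the shared set) induce genetic correlation and cross-trait
#' pleiotropy.
#'
#' @param geno A `genotype_matrix` whose variants the causal sets index.
#' @param h2 Named numeric vector of target heritabilities, each in [0, 1).
#' @param n_causal Named integer vector: causal variants per trait (ignored
#'   for traits with an explicit `causal` entry).
#' @param causal Optional named list of causal variant ids per trait.
#' @param effects Optional named list of per-variant effects; by default
#'   drawn standard normal (shared variants keep one draw across traits, so
#'   the genetic correlation between two traits is approximately the shared
#'   fraction of their causal sets).
#' @param log_hr Named numeric: causal log hazard ratio per unit of each
#'   trait (default 0).
#' @param family_frac,confounder_frac Named numeric variance fractions of
#'   the family random effect and of the latent confounder (default 0).
#' @param confounder_log_hr Log hazard ratio of the latent confounder on the
#'   outcome (default 0).
#' @param trait_mean,trait_sd Marginal mean and sd of each trait (defaults
#'   3 and 1, a weekly-frequency-like scale).
#' @param seed Seed for effect-size draws and causal-set sampling.
#' @return A `true_architecture` object.
#' @export
make_architecture <- function(geno, h2, n_causal = NULL, causal = NULL,
                              effects = NULL, log_hr = NULL,
                              family_frac = NULL, confounder_frac = NULL,
                              confounder_log_hr = 0,
                              trait_mean = 3, trait_sd = 1, seed = 1L) {
  traits <- names(h2)
  if (is.null(traits)) stop("h2 must be a named vector (one entry per trait)")
  if (any(h2 < 0 | h2 >= 1)) stop("target h2 must lie in [0, 1)")
  .set_seed(seed, 2L)
  full <- function(x, default = 0) {
    out <- stats::setNames(rep(default, length(traits)), traits)
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  family_frac <- full(family_frac)
  confounder_frac <- full(confounder_frac)
  log_hr <- full(log_hr)
  ids <- geno$variants$id
  causal <- causal %||% list()
  effects <- effects %||% list()
  shared_pool <- character(0)
  for (tr in traits) {
    if (is.null(causal[[tr]])) {
      k <- n_causal[[tr]]
      if (is.null(k)) stop("no causal set or n_causal for trait '", tr, "'")
      causal[[tr]] <- sample(ids, k)
    }
    if (!all(causal[[tr]] %in% ids)) {
      stop("unknown causal variant id(s) for trait '", tr, "'")
    }
  }
  # one effect draw per variant, reused across traits so shared causal
  # variants have identical effects
  all_ids <- unique(unlist(causal))
  pool <- stats::setNames(stats::rnorm(length(all_ids)), all_ids)
  for (tr in traits) {
    if (is.null(effects[[tr]])) effects[[tr]] <- unname(pool[causal[[tr]]])
    if (length(effects[[tr]]) != length(causal[[tr]])) {
      stop("effects/causal length mismatch for trait '", tr, "'")
    }
  }
  noise <- 1 - h2 - family_frac - confounder_frac
  if (any(noise <= 0)) {
    stop("variance budget exhausted (h2 + family + confounder fractions must ",
         "stay below 1): realized h2 = 1 is outside the model")
  }
  shared <- outer(traits, traits, Vectorize(function(a, b)
    length(intersect(causal[[a]], causal[[b]]))))
  dimnames(shared) <- list(traits, traits)
  out <- list(traits = traits, h2 = h2, causal = causal, effects = effects,
              log_hr = log_hr, family_frac = family_frac,
              confounder_frac = confounder_frac,
              confounder_log_hr = confounder_log_hr,
              trait_mean = full(trait_mean, trait_mean[1]),
              trait_sd = full(trait_sd, trait_sd[1]),
              shared_causal = shared)
  class(out) <- "true_architecture"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate quantitative diet traits and covariates
#'
#' Builds each trait as genetic value + family random effect + latent
#' confounder + Gaussian noise, with components scaled so the realized
#' variance shares match the architecture's targets (the genetic value is
#' rescaled to its empirical sd, so the realized h2 tracks the target up to
#' sampling noise in the non-genetic parts). Covariates emulate a
#' biobank baseline: age at recruitment (years, mean 56.6, sd 8, range
#' 37-73), sex (1 = female, 53% as in the cohort), family history of
#' colorectal cancer, household income band (1-5), smoking status (0-2),
#' body-mass index and physical activity. The latent confounder is returned
#' only in the truth record: the observational arm cannot adjust for it.
#'
#' @param geno A `genotype_matrix`.
#' @param arch A `true_architecture`.
#' @param kin Optional `kinship_structure` providing family blocks.
#' @param seed Seed.
#' @return A `synthetic_cohort`: list with `traits` (data frame), a
#'   `covariates` data frame, and `truth` (genetic values, confounder,
#'   realized variance decomposition per trait).
#' @export
simulate_traits <- function(geno, arch, kin = NULL, seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(arch, "true_architecture"))
  .set_seed(seed, 3L)
  n <- length(geno$sample_ids)
  u <- stats::rnorm(n)
  fam_eff <- NULL
  if (!is.null(kin)) {
    fam_draw <- stats::rnorm(max(kin$family))
    fam_eff <- fam_draw[kin$family]
  }
  traits <- list(); gmat <- list(); decomp <- list()
  for (tr in arch$traits) {
    sdt <- arch$trait_sd[[tr]]
    g_raw <- as.numeric(geno$dosages[, arch$causal[[tr]], drop = FALSE] %*%
                          arch$effects[[tr]])
    h2 <- arch$h2[[tr]]
    g <- if (h2 > 0) {
      if (stats::sd(g_raw) == 0) stop("degenerate genetic value for '", tr, "'")
      (g_raw - mean(g_raw)) / stats::sd(g_raw) * sqrt(h2) * sdt
    } else rep(0, n)
    ff <- arch$family_frac[[tr]]; cf <- arch$confounder_frac[[tr]]
    fpart <- if (ff > 0) {
      if (is.null(fam_eff)) stop("family_frac > 0 requires a kinship structure")
      fam_eff * sqrt(ff) * sdt
    } else rep(0, n)
    cpart <- u * sqrt(cf) * sdt
    epart <- stats::rnorm(n, 0, sqrt(1 - h2 - ff - cf) * sdt)
    y <- arch$trait_mean[[tr]] + g + fpart + cpart + epart
    traits[[tr]] <- y; gmat[[tr]] <- g
    vt <- stats::var(y)
    decomp[[tr]] <- data.frame(trait = tr, var_total = vt,
                               frac_genetic = stats::var(g) / vt,
                               frac_family = stats::var(fpart) / vt,
                               frac_confounder = stats::var(cpart) / vt)
  }
  age <- pmin(pmax(stats::rnorm(n, 56.6, 8), 37), 73)
  covariates <- data.frame(
    age = age,
    sex = stats::rbinom(n, 1L, 0.533),
    family_history = stats::rbinom(n, 1L, 0.10),
    income = sample.int(5L, n, replace = TRUE),
    smoking = sample(0:2, n, replace = TRUE, prob = c(0.55, 0.35, 0.10)),
    bmi = stats::rnorm(n, 27.4, 4.7),
    activity = stats::rnorm(n),
    row.names = geno$sample_ids
  )
  out <- list(traits = as.data.frame(traits, row.names = geno$sample_ids),
              covariates = covariates,
              truth = list(genetic_values = as.data.frame(gmat),
                           confounder = u, family_effect = fam_eff,
                           decomposition = do.call(rbind, decomp)),
              kin = kin)
  class(out) <- "synthetic_cohort"
  out
}

#' Map quantitative frequencies back to FFQ categories
#'
#' Inverse of [convert_frequency()]: each non-negative weekly frequency is
#' assigned the response category whose numeric value is nearest, ties going
#' to the lower category, so that converting the simulated response back
#' recovers the category value exactly.
#'
#' @param x Non-negative numeric frequencies.
#' @param item_class `"meat"`, `"fish"`, `"cheese"` or `"alcohol"`.
#' @return Character vector of response labels.
#' @export
simulate_ffq <- function(x, item_class = "meat") {
  if (any(x < 0, na.rm = TRUE)) stop("frequencies must be non-negative")
  tab <- ffq_conversion_table()
  cls <- .resolve_class(item_class, tab)
  labs <- vapply(cls$levels, `[[`, "", "label")
  vals <- vapply(cls$levels, function(l) as.numeric(l$value), 0)
  o <- order(vals); labs <- labs[o]; vals <- vals[o]
  idx <- vapply(x, function(xi) {
    if (is.na(xi)) return(NA_integer_)
    d <- abs(xi - vals)
    which(d == min(d))[1L]  # first index = lower category on ties
  }, 1L)
  labs[idx]
}
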