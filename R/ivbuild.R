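#' Flag lead variants associated with multiple dietary traits
#'
#' Counts, for every lead variant across the per-trait locus lists, how many
#' traits it is significant for, and flags variants whose count reaches
#' `min_traits`. The default `min_traits = 2` excludes any variant
#' associated with more than one dietary phenotype; `min_traits = 3`
#' implements the looser "more than two traits" reading.
#'
#' @param loci_by_trait Named list of locus tables (see [select_loci()]).
#' @param min_traits Flag variants associated with at least this many traits.
#' @return Data frame: variant_id, n_traits, traits (comma-separated),
#'   flagged.
#' @export
cross_trait_flags <- function(loci_by_trait, min_traits = 2L) {
  pairs <- do.call(rbind, lapply(names(loci_by_trait), function(tr) {
    loci <- loci_by_trait[[tr]]
    if (nrow(loci) == 0) return(NULL)
    data.frame(variant_id = loci$lead_id, trait = tr)
  }))
  if (is.null(pairs)) {
    return(data.frame(variant_id = character(0), n_traits = integer(0),
                      traits = character(0), flagged = logical(0)))
  }
  agg <- lapply(split(pairs$trait, pairs$variant_id), unique)
  out <- data.frame(variant_id = names(agg),
                    n_traits = vapply(agg, length, 0L),
                    traits = vapply(agg, paste, "", collapse = ","),
                    row.names = NULL)
  out$flagged <- out$n_traits >= min_traits
  out
}

#' Construct an instrument set from a trait's loci
#'
#' Lead variants become instruments weighted by their trait-association
#' beta (internal weighting: weights estimated in the same sample carry a
#' winner's-curse caveat, which is surfaced as a warning attribute rather
#' than corrected).
#'
#' @param trait Trait label.
#' @param loci Locus table from [select_loci()].
#' @param geno A `genotype_matrix` containing the lead variants.
#' @return An `instrument_set`: trait, `variants` (id, weight, flag
#'   columns), and the per-sample allele `score`.
#' @export
build_instruments <- function(trait, loci, geno) {
  if (nrow(loci) == 0) stop("no loci for trait '", trait, "'")
  w <- stats::setNames(loci$beta, loci$lead_id)
  out <- list(trait = trait,
              variants = data.frame(variant_id = loci$lead_id,
                                    weight = unname(w),
                                    flag_pleiotropy = FALSE,
                                    flag_outcome = FALSE),
              score = allele_score(geno, w))
  class(out) <- "instrument_set"
  attr(out, "weighting") <- paste(
    "internal weights (same-sample GWAS betas); estimates may carry",
    "winner's-curse bias")
  out
}

#' Apply pleiotropy and outcome-association exclusions
#'
#' Removes instruments flagged for cross-trait pleiotropy and instruments
#' associated with the outcome at `p < p_cut` (the exclusion-restriction
#' screen), then recomputes the allele score on the reduced set.
#'
#' @param ivs An `instrument_set`.
#' @param flags Output of [cross_trait_flags()] (or `NULL` to skip).
#' @param outcome_stats `summary_stats` from [outcome_scan()] covering the
#'   instrument variants.
#' @param p_cut Outcome-association exclusion threshold (default 0.05).
#' @param geno The `genotype_matrix` used to rebuild the score.
#' @return The reduced `instrument_set`, with an `exclusion_log` attribute.
#' @export
apply_exclusions <- function(ivs, flags, outcome_stats, geno, p_cut = 0.05) {
  v <- ivs$variants
  if (!is.null(flags) && nrow(flags)) {
    v$flag_pleiotropy <- v$variant_id %in% flags$variant_id[flags$flagged]
  }
  if (!is.null(outcome_stats)) {
    m <- match(v$variant_id, outcome_stats$variant_id)
    if (anyNA(m)) stop("outcome stats do not cover all instrument variants")
    v$flag_outcome <- !is.na(outcome_stats$p[m]) & outcome_stats$p[m] < p_cut
  }
  keep <- !(v$flag_pleiotropy | v$flag_outcome)
  if (!any(keep)) {
    stop("all instruments excluded for trait '", ivs$trait,
         "'; review the pleiotropy / outcome-association thresholds")
  }
  out <- list(trait = ivs$trait, variants = v[keep, , drop = FALSE],
              score = allele_score(
                geno, stats::setNames(v$weight[keep], v$variant_id[keep])))
  class(out) <- "instrument_set"
  attr(out, "exclusion_log") <- data.frame(
    variant_id = v$variant_id, flag_pleiotropy = v$flag_pleiotropy,
    flag_outcome = v$flag_outcome, retained = keep)
  out
}

#' Weighted allele score
#'
#' Per-sample weighted sum of effect-allele dosages; missing dosages are
#' mean-imputed per variant before scoring, so no sample is dropped.
#'
#' @param geno A `genotype_matrix`.
#' @param weights Named numeric vector (names = variant ids).
#' @return Numeric score vector, one entry per sample.
#' @export
allele_score <- function(geno, weights) {
  if (length(weights) == 0) stop("empty weight set")
  ids <- names(weights)
  if (!all(ids %in% geno$variants$id)) stop("weight variants outside the panel")
  d <- .impute_dosages(geno$dosages[, ids, drop = FALSE])
  unname(drop(d %*% unname(weights)))
}

#' Instrument-strength F-statistic
#'
#' The F-statistic of an instrument is the squared first-stage estimate
#' divided by its variance, i.e. the squared t-statistic of the score
#' coefficient in the exposure-on-score regression; F below 10 is the
#' conventional weak-instrument signal.
#'
#' @param fit An `lm` fit of the exposure on the allele score (score
#'   coefficient named `score`), or pass `beta` and `se` directly.
#' @param beta,se First-stage estimate and standard error (alternative to
#'   `fit`).
#' @return An `instrument_diagnostics` list: `F`, `beta`, `se`, `n`.
#' @export
f_statistic <- function(fit = NULL, beta = NULL, se = NULL) {
  if (!is.null(fit)) {
    co <- summary(fit)$coefficients
    row <- if ("score" %in% rownames(co)) "score" else rownames(co)[2]
    beta <- co[row, "Estimate"]; se <- co[row, "Std. Error"]
    n <- length(stats::residuals(fit))
  } else {
    n <- NA_integer_
  }
  if (is.null(beta) || is.null(se)) stop("need a fit or beta and se")
  if (se <= 0) stop("zero variance of the first-stage estimate")
  structure(list(F = (beta / se)^2, beta = beta, se = se, n = n),
            class = "instrument_diagnostics")
}
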