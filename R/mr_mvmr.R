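#' Group traits for multivariable MR
#'
#' Traits are modelled jointly when their allele scores are substantially
#' correlated (|r| > `r_score`) or their genetic correlation is high
#' (|r_g| > `r_g`); grouping takes the connected components of the union
#' of the two adjacency relations.
#'
#' @param score_cor Trait-by-trait correlation matrix of allele scores.
#' @param rg_mat Optional genetic-correlation matrix (same trait order).
#' @param r_score,r_g Thresholds (defaults 0.10 and 0.30).
#' @return List of character vectors (one per group); singleton groups are
#'   traits that join nothing.
#' @export
mvmr_groups <- function(score_cor, rg_mat = NULL, r_score = 0.10, r_g = 0.30) {
  traits <- colnames(score_cor)
  adj <- abs(score_cor) > r_score
  if (!is.null(rg_mat)) adj <- adj | (abs(rg_mat) > r_g)
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, length(traits)); cur <- 0L
  for (i in seq_along(traits)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  unname(lapply(split(traits, comp), identity))
}

#' Multivariable Mendelian randomisation
#'
#' For each group of correlated traits, stage 1 regresses every trait in
#' the group on all of the group's allele scores jointly, and stage 2 fits
#' a single age-scale Cox model on all fitted exposures simultaneously,
#' giving each trait's direct effect. Groups are determined by
#' [mvmr_groups()]; singleton groups are skipped (ordinary univariable MR
#' covers them). Near-collinear fitted exposures are rejected by a
#' condition-number gate.
#'
#' @param traits Data frame of exposure traits (columns named by trait).
#' @param scores Data frame of allele scores, same column names.
#' @param outcome An `outcome_table`.
#' @param covariates Optional covariates for both stages.
#' @param rg_mat Optional genetic-correlation matrix for grouping.
#' @param r_score,r_g Grouping thresholds.
#' @param max_kappa Condition-number gate on the fitted-exposure block
#'   (default 1e8).
#' @return List with `groups` and `results` (one `effect_estimate` per
#'   trait analysed, method `"MVMR"`).
#' @export
multivariable_mr <- function(traits, scores, outcome, covariates = NULL,
                             rg_mat = NULL, r_score = 0.10, r_g = 0.30,
                             max_kappa = 1e8) {
  stopifnot(identical(sort(names(traits)), sort(names(scores))))
  if (ncol(traits) < 2) stop("multivariable MR needs at least 2 traits")
  sc <- stats::cor(as.matrix(scores))
  groups <- mvmr_groups(sc, rg_mat, r_score = r_score, r_g = r_g)
  results <- list()
  for (grp in groups) {
    if (length(grp) < 2) next
    S <- as.data.frame(scores)[, grp, drop = FALSE]
    names(S) <- paste0("s_", seq_along(grp))
    fitted <- sapply(grp, function(tr) {
      dat <- cbind(data.frame(.y = traits[[tr]]), S)
      if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
      stats::fitted(stats::lm(.y ~ ., data = dat))
    })
    cm <- stats::cor(fitted)
    if (anyNA(cm) || !all(is.finite(cm)) || kappa(cm, exact = TRUE) > max_kappa) {
      stop("collinear fitted exposures in group: ", paste(grp, collapse = ", "))
    }
    Fd <- as.data.frame(fitted)
    names(Fd) <- make.names(grp)
    dat <- Fd
    if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
    dat$surv <- survival::Surv(outcome$entry_age, outcome$exit_age, outcome$event)
    fit <- survival::coxph(surv ~ ., data = dat, ties = "efron")
    co <- summary(fit)$coefficients
    for (i in seq_along(grp)) {
      results[[grp[i]]] <- effect_estimate(
        co[make.names(grp[i]), "coef"], co[make.names(grp[i]), "se(coef)"],
        method = "MVMR", n = nrow(dat), events = sum(outcome$event))
    }
  }
  list(groups = groups, results = results)
}
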