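#' Principal-component covariates from the genotype panel
#'
#' Top-k principal-component scores of the column-standardized dosage
#' matrix, the usual adjustment for population stratification. Monomorphic
#' variants are dropped before standardization. The sign of each component
#' is fixed by making its largest-magnitude variant loading positive, so
#' results are deterministic.
#'
#' @param geno A `genotype_matrix`.
#' @param k Number of components (`k = 0` gives an empty covariate block).
#' @return n x k matrix of PC scores (columns `PC1..PCk`).
#' @export
pca_covariates <- function(geno, k = 6L) {
  d <- geno$dosages
  n <- nrow(d)
  if (k >= min(dim(d))) stop("k must be below both panel dimensions")
  if (k == 0) return(matrix(numeric(0), n, 0))
  sds <- apply(d, 2, stats::sd)
  poly <- sds > 0
  if (!any(poly)) stop("zero-variance panel: no polymorphic variants")
  z <- scale(d[, poly, drop = FALSE])
  sv <- svd(z, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k, k), 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(d)
  scores
}

# Mean-impute missing dosages per variant (keeps sample size for scans and
# allele scores).
.impute_dosages <- function(d) {
  if (!anyNA(d)) return(d)
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  d
}

.covar_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0) ||
      (is.matrix(covariates) && ncol(covariates) == 0)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  cbind(`(Intercept)` = 1, as.matrix(covariates))
}

# Vectorised per-variant OLS of y on each dosage column plus covariates,
# via Frisch-Waugh residualisation; identical to the full normal-equations
# solve variant by variant.
.scan_ols <- function(y, X, C) {
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("singular covariate matrix")
  yres <- qr.resid(qrC, y)
  Xres <- X - C %*% qr.coef(qrC, X)
  xx <- colSums(Xres^2)
  xy <- colSums(Xres * yres)
  beta <- xy / xx
  df <- length(y) - ncol(C) - 1L
  rss <- sum(yres^2) - beta * xy
  se <- sqrt(pmax(rss, 0) / df / xx)
  p <- 2 * stats::pt(-abs(beta / se), df)
  list(beta = beta, se = se, p = p, df = df)
}

#' Per-variant association scan for a quantitative trait
#'
#' Regresses the trait on each variant's dosage with covariate adjustment.
#' Without a kinship structure this is exact per-variant ordinary least
#' squares. With one, a two-step residual approach is used: the trait is
#' first fitted on the covariates plus a family random intercept (a
#' GRAMMAR-style approximation of a full linear mixed model), and the
#' conditional residuals are then scanned against each variant.
#'
#' @param trait Numeric trait vector.
#' @param geno A `genotype_matrix`.
#' @param covariates Optional data frame / matrix of covariates (no
#'   intercept column; one is added).
#' @param kin Optional `kinship_structure` for relatedness adjustment.
#' @return A `summary_stats` data frame: variant_id, chr, pos,
#'   effect_allele, other_allele, eaf, beta, se, p, n.
#' @export
association_scan <- function(trait, geno, covariates = NULL, kin = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- .impute_dosages(geno$dosages)
  n <- nrow(X)
  keep <- !is.na(trait)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  if (sum(keep) < 50) stop("fewer than 50 complete-case rows")
  y <- trait[keep]
  if (stats::sd(y) == 0) stop("trait is constant")
  X <- X[keep, , drop = FALSE]
  C <- .covar_matrix(if (is.null(covariates)) NULL else
    as.data.frame(covariates)[keep, , drop = FALSE], sum(keep))
  if (!is.null(kin)) {
    dat <- data.frame(.y = y, C[, -1, drop = FALSE],
                      .fam = factor(kin$family[keep]))
    form <- stats::as.formula(paste(
      ".y ~", if (ncol(C) > 1)
        paste(colnames(C)[-1], collapse = " + ") else "1", "+ (1 | .fam)"))
    fit <- lme4::lmer(form, data = dat, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    y <- stats::residuals(fit)
    C <- matrix(1, length(y), 1)
  }
  sc <- .scan_ols(y, X, C)
  out <- data.frame(variant_id = geno$variants$id, chr = geno$variants$chr,
                    pos = geno$variants$pos,
                    effect_allele = geno$variants$effect_allele,
                    other_allele = geno$variants$other_allele,
                    eaf = colMeans(X) / 2,
                    beta = unname(sc$beta), se = unname(sc$se),
                    p = unname(sc$p), n = sum(keep))
  class(out) <- c("summary_stats", "data.frame")
  attr(out, "adjusted_for_kinship") <- !is.null(kin)
  out
}

#' Per-variant Cox scan against the time-to-event outcome
#'
#' Fits an age-scale Cox proportional-hazards model (delayed entry at the
#' recruitment age) for each variant's dosage with covariate adjustment,
#' returning per-variant log hazard ratios. Non-converging fits are flagged
#' in the `converged` column rather than aborting the scan.
#'
#' @param outcome An `outcome_table`.
#' @param geno A `genotype_matrix`.
#' @param covariates Optional covariate data frame.
#' @return A `summary_stats` data frame on the log-hazard scale, with a
#'   `converged` flag per variant.
#' @export
outcome_scan <- function(outcome, geno, covariates = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (sum(outcome$event) < 1) stop("no events in outcome table")
  X <- .impute_dosages(geno$dosages)
  surv <- survival::Surv(outcome$entry_age, outcome$exit_age, outcome$event)
  base <- if (is.null(covariates)) data.frame(row.names = seq_len(nrow(X)))
          else as.data.frame(covariates)
  cv_terms <- if (ncol(base)) paste("+", paste(names(base), collapse = " + ")) else ""
  form <- stats::as.formula(paste("surv ~ .dos", cv_terms))
  M <- ncol(X)
  beta <- se <- p <- rep(NA_real_, M)
  conv <- logical(M)
  for (j in seq_len(M)) {
    dat <- base
    dat$.dos <- X[, j]
    dat$surv <- surv
    fit <- tryCatch(survival::coxph(form, data = dat, ties = "efron"),
                    error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && is.finite(fit$coefficients[".dos"])) {
      s <- summary(fit)$coefficients
      beta[j] <- s[".dos", "coef"]
      se[j] <- s[".dos", "se(coef)"]
      p[j] <- s[".dos", "Pr(>|z|)"]
      conv[j] <- TRUE
    }
  }
  out <- data.frame(variant_id = geno$variants$id, chr = geno$variants$chr,
                    pos = geno$variants$pos,
                    effect_allele = geno$variants$effect_allele,
                    other_allele = geno$variants$other_allele,
                    eaf = colMeans(X) / 2, beta = beta, se = se, p = p,
                    n = nrow(X), converged = conv)
  class(out) <- c("summary_stats", "data.frame")
  out
}
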