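#' @title Haseman-Elston heritability and genetic correlation
#' @description SNP heritability is estimated by Haseman-Elston regression:
#'   the products of (covariate-residualized, standardized) trait values for
#'   sample pairs are regressed on the corresponding genomic-relatedness
#'   entries over all off-diagonal pairs; the slope estimates h2. The
#'   bivariate form regresses cross-trait products to estimate the genetic
#'   covariance, normalized by the two heritabilities to give r_g. All pair
#'   sums are evaluated through identities in Z'Z and Z'y, so the n x n
#'   relatedness matrix is never formed; standard errors come from a
#'   delete-a-block jackknife over samples.
#' @name heritability
NULL

# Core sums for Haseman-Elston regression. ys: matrix of residualized,
# standardized trait columns.
.he_core <- function(geno, ys, n_blocks = 20L) {
  d <- .impute_dosages(geno$dosages)
  sds <- apply(d, 2, stats::sd)
  if (!any(sds > 0)) stop("degenerate relatedness: zero-variance panel")
  Z <- scale(d[, sds > 0, drop = FALSE])
  n <- nrow(Z); M <- ncol(Z)
  Zty <- crossprod(Z, ys)                    # M x T
  gdiag <- rowSums(Z^2) / M
  K <- crossprod(Z)                          # M x M
  Fsq <- sum(K^2) / M^2                      # ||G||_F^2
  q <- rowSums((Z %*% K) * Z) / M^2          # diag(G^2)
  Gy <- Z %*% Zty / M                        # n x T
  S_x <- -sum(gdiag) / 2
  S_xx <- (Fsq - sum(gdiag^2)) / 2
  P <- n * (n - 1) / 2
  denom_full <- S_xx - S_x^2 / P
  if (!is.finite(denom_full) || denom_full <= sqrt(.Machine$double.eps)) {
    stop("degenerate relatedness: off-diagonal relatedness has no variance")
  }
  blocks <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))

  slope <- function(a, b) {
    S_xy <- (sum(Zty[, a] * Zty[, b]) / M - sum(gdiag * ys[, a] * ys[, b])) / 2
    S_y <- -sum(ys[, a] * ys[, b]) / 2
    (S_xy - S_x * S_y / P) / denom_full
  }
  slope_delblock <- function(a, b, I) {
    m <- length(I)
    GII <- tcrossprod(Z[I, , drop = FALSE]) / M
    S_x_b <- (sum(GII) - (sum(gdiag) - sum(gdiag[I]))) / 2
    S_xx_b <- (Fsq - 2 * sum(q[I]) + sum(GII^2) -
                 (sum(gdiag^2) - sum(gdiag[I]^2))) / 2
    y1 <- ys[, a]; y2 <- ys[, b]
    quad <- sum(Zty[, a] * Zty[, b]) / M -
      sum(y1[I] * Gy[I, b]) - sum(y2[I] * Gy[I, a]) +
      drop(y1[I] %*% GII %*% y2[I])
    dterm <- sum(gdiag * y1 * y2) - sum(gdiag[I] * y1[I] * y2[I])
    S_xy_b <- (quad - dterm) / 2
    s12 <- sum(y1 * y2) - sum(y1[I] * y2[I])
    S_y_b <- ((-sum(y1[I])) * (-sum(y2[I])) - s12) / 2
    P_b <- (n - m) * (n - m - 1) / 2
    (S_xy_b - S_x_b * S_y_b / P_b) / (S_xx_b - S_x_b^2 / P_b)
  }
  list(slope = slope, slope_delblock = slope_delblock, blocks = blocks, n = n)
}

.residualize_std <- function(trait, covariates) {
  keep <- !is.na(trait)
  if (!all(keep)) stop("trait must be complete for heritability estimation")
  C <- .covar_matrix(covariates, length(trait))
  r <- qr.resid(qr(C), trait)
  r / stats::sd(r)
}

#' Estimate SNP heritability by Haseman-Elston regression
#'
#' @param geno A `genotype_matrix`.
#' @param trait Numeric trait vector (complete).
#' @param covariates Optional covariates residualized out first.
#' @param n_blocks Number of sample blocks for the jackknife SE.
#' @return A `heritability_estimate`: `h2` (clipped to [0, 1], with
#'   `clipped` flag and the `raw` value), `se`, and `method = "HE"`.
#' @export
estimate_h2 <- function(geno, trait, covariates = NULL, n_blocks = 20L) {
  if (length(trait) < 500) stop("heritability estimation needs n >= 500")
  y <- .residualize_std(trait, covariates)
  core <- .he_core(geno, cbind(y), n_blocks)
  est <- core$slope(1, 1)
  jk <- vapply(core$blocks, function(I) core$slope_delblock(1, 1, I), 0)
  B <- length(jk)
  se <- sqrt((B - 1) / B * sum((jk - mean(jk))^2))
  h2 <- min(max(est, 0), 1)
  structure(list(h2 = h2, raw = est, se = se, method = "HE",
                 clipped = !identical(h2, est), n = core$n),
            class = "heritability_estimate")
}

#' Genetic correlation between two traits (bivariate Haseman-Elston)
#'
#' @param geno A `genotype_matrix` (both traits measured on its samples).
#' @param trait_a,trait_b Numeric trait vectors.
#' @param covariates Optional covariates residualized out of both traits.
#' @param n_blocks Jackknife blocks.
#' @return A `genetic_correlation`: `rg` (clipped to [-1, 1] with flag),
#'   `se`, the two h2 slopes, and `defined` (FALSE when either h2 slope is
#'   non-positive, in which case `rg` is `NA`).
#' @export
genetic_correlation <- function(geno, trait_a, trait_b, covariates = NULL,
                                n_blocks = 20L) {
  if (length(trait_a) != length(trait_b)) {
    stop("traits must be measured on the same samples")
  }
  ys <- cbind(.residualize_std(trait_a, covariates),
              .residualize_std(trait_b, covariates))
  core <- .he_core(geno, ys, n_blocks)
  h2a <- core$slope(1, 1); h2b <- core$slope(2, 2); cg <- core$slope(1, 2)
  if (h2a <= 0 || h2b <= 0) {
    return(structure(list(rg = NA_real_, se = NA_real_, h2_a = h2a,
                          h2_b = h2b, defined = FALSE, clipped = FALSE),
                     class = "genetic_correlation"))
  }
  rg_raw <- cg / sqrt(h2a * h2b)
  jk <- vapply(core$blocks, function(I) {
    a <- core$slope_delblock(1, 1, I); b <- core$slope_delblock(2, 2, I)
    cc <- core$slope_delblock(1, 2, I)
    if (a <= 0 || b <= 0) return(NA_real_)
    cc / sqrt(a * b)
  }, 0)
  jk <- jk[is.finite(jk)]
  B <- length(jk)
  se <- if (B >= 2) sqrt((B - 1) / B * sum((jk - mean(jk))^2)) else NA_real_
  rg <- min(max(rg_raw, -1), 1)
  structure(list(rg = rg, raw = rg_raw, se = se, h2_a = h2a, h2_b = h2b,
                 defined = TRUE, clipped = !identical(rg, rg_raw)),
            class = "genetic_correlation")
}
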