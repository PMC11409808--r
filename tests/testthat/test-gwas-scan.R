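test_that("the association scan reproduces the explicit normal-equations solve", {
  set.seed(21)
  n <- 200
  g <- simulate_genotypes(n, 5, seed = 21)
  covs <- data.frame(age = rnorm(n, 55, 8), sex = rbinom(n, 1, 0.5))
  y <- 0.3 * g$dosages[, 2] + 0.05 * covs$age + rnorm(n)
  st <- association_scan(y, g, covs)
  for (j in 1:5) {
    A <- cbind(1, g$dosages[, j], covs$age, covs$sex)
    bhat <- solve(crossprod(A), crossprod(A, y))
    res <- y - A %*% bhat
    sig2 <- sum(res^2) / (n - ncol(A))
    se <- sqrt(sig2 * solve(crossprod(A))[2, 2])
    expect_equal(st$beta[j], bhat[2], tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(st$se[j], se, tolerance = 1e-8)
    expect_equal(st$p[j], 2 * pt(-abs(bhat[2] / se), n - 4), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("the scan is calibrated under the null and recovers injected effects", {
  g <- simulate_genotypes(5000, 500, seed = 31)
  set.seed(31)
  y <- rnorm(5000)
  st <- association_scan(y, g)
  frac <- mean(st$p < 0.05)
  expect_true(frac >= 0.03 && frac <= 0.07)

  hits <- vapply(1:20, function(s) {
    gg <- simulate_genotypes(2000, 20, seed = s)
    set.seed(s + 1000)
    yy <- 0.3 * gg$dosages[, 7] + rnorm(2000)
    ss <- association_scan(yy, gg)
    abs(ss$beta[7] - 0.3) <= 1.96 * ss$se[7]
  }, TRUE)
  expect_gte(sum(hits), 17)
})

test_that("degenerate scan inputs are rejected", {
  g <- simulate_genotypes(100, 5, seed = 1)
  expect_error(association_scan(rep(1, 100), g), "constant")
  expect_error(association_scan(c(rnorm(40), rep(NA, 60)), g), "50")
  covs <- data.frame(a = rnorm(100))
  covs$b <- covs$a * 2
  expect_error(association_scan(rnorm(100), g, covs), "singular")
})

test_that("the kinship-adjusted scan absorbs the family effect and stays calibrated", {
  n <- 2000
  g <- simulate_genotypes(n, 150, seed = 41)
  kin <- make_kinship(n, block_size = 4)
  arch <- make_architecture(g, h2 = c(t = 0), n_causal = c(t = 1),
                            family_frac = c(t = 0.4), seed = 41)
  coh <- simulate_traits(g, arch, kin = kin, seed = 41)
  st <- association_scan(coh$traits$t, g, coh$covariates[, c("age", "sex")],
                         kin = kin)
  expect_true(attr(st, "adjusted_for_kinship"))
  frac <- mean(st$p < 0.05)
  expect_true(frac >= 0.02 && frac <= 0.08)
})

test_that("principal components separate simulated subpopulations and honor k = 0", {
  g <- simulate_genotypes(400, 300, fst_shift = 0.2, seed = 51)
  pcs <- pca_covariates(g, 2)
  expect_gt(abs(cor(pcs[, 1], g$subpop)), 0.9)
  expect_equal(ncol(pca_covariates(g, 0)), 0)
  # unstructured panel: leading eigenvalue stays near the bulk
  g0 <- simulate_genotypes(1000, 200, seed = 52)
  z <- scale(g0$dosages)
  d <- svd(z, nu = 0, nv = 0)$d^2
  expect_lt(d[1] / median(d), 3)
  expect_error(pca_covariates(g, 400), "below")
})

test_that("the outcome scan is calibrated and recovers an injected log hazard", {
  g <- simulate_genotypes(1500, 300, seed = 61)
  set.seed(61)
  entry <- runif(1500, 45, 65)
  tt <- toy_surv_times(entry, rep(0, 1500), rate = 0.012)
  out <- toy_outcome(entry, tt$exit, tt$event)
  st <- outcome_scan(out, g)
  expect_true(all(st$converged))
  expect_gt(ks.test(st$p, "punif")$p.value, 0.01)

  gg <- simulate_genotypes(20000, 1, maf_range = c(0.3, 0.3), seed = 62)
  set.seed(62)
  entry <- runif(20000, 45, 65)
  dos <- gg$dosages[, 1]
  tt <- toy_surv_times(entry, 0.3 * (dos - mean(dos)), rate = 0.008)
  out <- toy_outcome(entry, tt$exit, tt$event)
  st <- outcome_scan(out, gg)
  expect_true(st$beta[1] >= 0.1 && st$beta[1] <= 0.5)
  out0 <- toy_outcome(entry, tt$exit, rep(0L, 20000))
  expect_error(outcome_scan(out0, gg), "no events")
})
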