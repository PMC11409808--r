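# MR-Egger and MR-PRESSO summary-statistic diagnostics.

test_that("MR-Egger recovers an exact line and rejects underdetermined input", {
  expect_error(mr_egger(c(0.1, 0.2), c(0.01, 0.01), c(0.02, 0.04),
                        c(0.01, 0.01)), "at least 3")
  eg <- suppressWarnings(  # collinear fixture: perfect-fit warning expected
    mr_egger(c(0.1, 0.2, 0.3), rep(0.01, 3), c(0.02, 0.04, 0.06),
             rep(0.01, 3)))
  expect_equal(eg$slope, 0.2, tolerance = 1e-10)
  expect_equal(eg$intercept, 0, tolerance = 1e-10)
})

test_that("Egger orientation flips alleles so exposure effects are non-negative", {
  # flipping both effect signs of an instrument must not change the fit
  be <- c(0.1, -0.2, 0.3, 0.15); bo <- c(0.03, -0.05, 0.05, 0.04)
  e1 <- mr_egger(be, rep(0.01, 4), bo, rep(0.02, 4))
  e2 <- mr_egger(abs(be), rep(0.01, 4), bo * sign(be), rep(0.02, 4))
  expect_equal(e1$slope, e2$slope)
  expect_equal(e1$intercept, e2$intercept)
})

test_that("constrained Egger equals IVW equals the weighted mean of Wald ratios", {
  set.seed(37)
  s <- sim_summary(20)
  ivw <- mr_ivw(s$be, s$bo, s$se_out)
  w <- 1 / s$se_out^2
  fit0 <- lm(s$bo ~ 0 + s$be, weights = w)
  expect_equal(ivw$estimate, unname(coef(fit0)), tolerance = 1e-8)
  ratios <- s$bo / s$be
  wr <- w * s$be^2
  expect_equal(ivw$estimate, sum(wr * ratios) / sum(wr), tolerance = 1e-8)
})

test_that("the Egger intercept detects directional but not balanced pleiotropy", {
  set.seed(41)
  rej_bal <- mean(vapply(1:200, function(i) {
    s <- sim_summary(50, pleio_sd = 0.05)
    mr_egger(s$be, s$se_exp, s$bo, s$se_out)$intercept_p < 0.05
  }, TRUE))
  expect_true(rej_bal >= 0.01 && rej_bal <= 0.10)
  rej_dir <- mean(vapply(1:100, function(i) {
    s <- sim_summary(50, pleio_mean = 0.05, pleio_sd = 0.02)
    mr_egger(s$be, s$se_exp, s$bo, s$se_out)$intercept_p < 0.05
  }, TRUE))
  expect_gte(rej_dir, 0.8)
})

test_that("MR-PRESSO validates input and is bit-reproducible under a seed", {
  set.seed(43)
  s <- sim_summary(20)
  expect_error(mr_presso(s$be[1:3], s$se_exp[1:3], s$bo[1:3], s$se_out[1:3]),
               "at least 4")
  expect_error(mr_presso(s$be, s$se_exp, s$bo, s$se_out, n_sim = 50),
               "100")
  r1 <- mr_presso(s$be, s$se_exp, s$bo, s$se_out, n_sim = 200, seed = 9)
  r2 <- mr_presso(s$be, s$se_exp, s$bo, s$se_out, n_sim = 200, seed = 9)
  expect_identical(r1, r2)
})

test_that("a grossly inflated instrument is flagged and distortion handled", {
  set.seed(47)
  s <- sim_summary(30)
  s$bo[5] <- s$bo[5] + 10 * s$se_out[5]
  rep_ <- mr_presso(s$be, s$se_exp, s$bo, s$se_out, n_sim = 1000, seed = 11)
  expect_true(5 %in% rep_$outliers$index)
  expect_false(is.null(rep_$estimate_corrected))
  expect_true(is.finite(rep_$distortion_p))
  # homogeneous instruments: typically no outliers, distortion undefined
  s0 <- sim_summary(30)
  rep0 <- mr_presso(s0$be, s0$se_exp, s0$bo, s0$se_out, n_sim = 500, seed = 12)
  if (nrow(rep0$outliers) == 0) {
    expect_true(is.na(rep0$distortion_p))
    expect_null(rep0$estimate_corrected)
  }
})

test_that("multivariable MR separates a causal from a correlated null trait", {
  set.seed(53)
  n <- 10000
  s_a <- rnorm(n); s_b <- rnorm(n)
  trait_a <- 3 + 0.5 * s_a + rnorm(n)
  trait_b <- 3 + 0.5 * s_b + 0.3 * trait_a + rnorm(n)  # correlated, not causal
  entry <- runif(n, 45, 65)
  tt <- toy_surv_times(entry, log(0.75) * (trait_a - mean(trait_a)), rate = 0.012)
  out <- toy_outcome(entry, tt$exit, tt$event)
  res <- multivariable_mr(data.frame(a = trait_a, b = trait_b),
                          data.frame(a = s_a, b = s_b), out,
                          r_score = -1)  # force joint modelling
  est_a <- res$results$a; est_b <- res$results$b
  expect_true(est_a$ci_high < 1)
  expect_true(est_b$ci_low < 1 && est_b$ci_high > 1)
})

test_that("MVMR grouping honours the correlation thresholds and rejects collinearity", {
  set.seed(59)
  n <- 500
  s_a <- rnorm(n); s_b <- rnorm(n)
  entry <- runif(n, 45, 65)
  tt <- toy_surv_times(entry, rep(0, n), rate = 0.02)
  out <- toy_outcome(entry, tt$exit, tt$event)
  tr <- data.frame(a = rnorm(n), b = rnorm(n))
  # independent scores: all-singleton grouping, nothing modelled jointly
  res <- multivariable_mr(tr, data.frame(a = s_a, b = s_b), out)
  expect_length(res$results, 0)
  expect_true(all(lengths(res$groups) == 1))
  # duplicated trait entered twice is collinear
  expect_error(multivariable_mr(data.frame(a = tr$a, b = tr$a),
                                data.frame(a = s_a, b = s_a), out,
                                r_score = -1),
               "collinear")
  cors <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(mvmr_groups(cors), list(c("a", "b")))
})
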