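test_that("the Wald ratio and its degenerate cases behave", {
  expect_equal(wald_ratio(0.1, 0.5)$estimate, 0.2)
  expect_equal(wald_ratio(0, 0.4)$estimate, 0)
  expect_error(wald_ratio(0.1, 0), "non-zero")
  wr <- wald_ratio(0.1, 0.5, se_out = 0.02)
  expect_equal(wr$se, 0.02 / 0.5)
})

test_that("single-instrument 2SLS with a linear second stage equals the Wald ratio", {
  set.seed(17)
  n <- 200
  z <- rbinom(n, 2, 0.3)
  x <- 0.4 * z + rnorm(n)
  y <- 0.25 * x + rnorm(n)
  b_zx <- coef(lm(x ~ z))["z"]
  b_zy <- coef(lm(y ~ z))["z"]
  fitted <- fitted(lm(x ~ z))
  tsls <- coef(lm(y ~ fitted))["fitted"]
  expect_equal(unname(tsls), wald_ratio(unname(b_zy), unname(b_zx))$estimate,
               tolerance = 1e-8)
})

test_that("first stage returns fitted values and enforces the weak-instrument gate", {
  set.seed(19)
  n <- 2000
  score <- rnorm(n)
  trait <- 2 * score
  s1 <- suppressWarnings(first_stage(trait, score))  # noiseless: perfect fit
  expect_equal(s1$fitted, trait, tolerance = 1e-10)
  noisy <- rnorm(n)  # score unrelated to trait
  expect_error(first_stage(noisy, score), "weak instrument")
  s2 <- first_stage(noisy, score, allow_weak = TRUE)
  expect_lt(s2$diagnostics$F, 10)
  expect_error(first_stage(trait, rep(1, n)), "constant")
  # F matches the closed-form n R^2 / (1 - R^2) relation
  trait2 <- 0.15 * score + rnorm(n)
  s3 <- first_stage(trait2, score)
  r2 <- summary(s3$fit)$r.squared
  expect_equal(s3$diagnostics$F, (n - 2) * r2 / (1 - r2), tolerance = 1e-6)
})

test_that("effect estimates keep exp/log CI consistency", {
  e <- effect_estimate(log(0.8), 0.1, "2SLS-Cox", increment = 2)
  expect_equal(e$hr, exp(2 * log(0.8)))
  expect_equal(e$ci_low, exp(2 * log(0.8) - 1.96 * 0.2))
  expect_equal(e$ci_high, exp(2 * log(0.8) + 1.96 * 0.2))
  expect_true(e$ci_low < e$hr && e$hr < e$ci_high)
})

test_that("the second stage fits an age-scale Cox model with delayed entry", {
  set.seed(23)
  n <- 8000
  score <- rnorm(n)
  trait <- 3 + 0.5 * score + rnorm(n)
  entry <- runif(n, 45, 65)
  tt <- toy_surv_times(entry, log(0.8) * (trait - mean(trait)), rate = 0.01)
  out <- toy_outcome(entry, tt$exit, tt$event)
  s1 <- first_stage(trait, score)
  est <- second_stage_cox(s1$fitted, out, f = s1$diagnostics$F)
  expect_true(est$hr > 0.6 && est$hr < 1.0)
  expect_equal(est$events, sum(tt$event))
  out0 <- toy_outcome(entry, tt$exit, rep(0L, n))
  expect_error(second_stage_cox(s1$fitted, out0), "no events")
})

test_that("bootstrapped SEs propagate first-stage uncertainty", {
  set.seed(29)
  n <- 1500
  score <- rnorm(n)
  trait <- 3 + 0.4 * score + rnorm(n)
  entry <- runif(n, 45, 65)
  tt <- toy_surv_times(entry, rep(0, n), rate = 0.012)
  out <- toy_outcome(entry, tt$exit, tt$event)
  est <- mr_fit(trait, score, out, bootstrap = 30, seed = 5)
  mb <- attr(est, "model_based")
  expect_equal(est$loghr, mb$loghr)
  expect_gt(est$se, 0)
  expect_gte(est$se, 0.5 * mb$se)  # bootstrap SE in the model-based ballpark
})

test_that("subgroup runs subset by sex and censor the competing subsite", {
  set.seed(31)
  n <- 20000
  sex <- rbinom(n, 1, 0.5)
  score <- rnorm(n)
  trait <- 3 + 0.6 * score + rnorm(n)
  entry <- runif(n, 45, 65)
  # effect only in women (sex == 1)
  lp <- ifelse(sex == 1, log(0.7), 0) * (trait - mean(trait))
  tt <- toy_surv_times(entry, lp, rate = 0.012)
  out <- toy_outcome(entry, tt$exit, tt$event, sex = sex)
  res <- subgroup_run(out, by = "sex", estimator = function(o, rows) {
    mr_fit(trait[rows], score[rows], o)
  })
  women <- res[res$subgroup == "women", ]
  men <- res[res$subgroup == "men", ]
  expect_true(women$ci_high < 1)
  expect_true(men$ci_low < 1 && men$ci_high > 1)

  # colon-only effect: two independent competing processes, the colon hazard
  # depends on the trait (HR 0.7), the rectal hazard does not
  t_colon <- entry + rexp(n, 0.008 * exp(log(0.7) * (trait - mean(trait))))
  t_rect <- entry + rexp(n, 0.004)
  exit <- pmin(t_colon, t_rect, 75)
  event <- as.integer(pmin(t_colon, t_rect) <= 75)
  subsite <- ifelse(event == 0, "censored",
                    ifelse(t_colon < t_rect, "colon", "rectal"))
  out2 <- toy_outcome(entry, exit, event, sex = sex, subsite = subsite)
  res2 <- subgroup_run(out2, by = "subsite", estimator = function(o, rows) {
    mr_fit(trait[rows], score[rows], o)
  })
  expect_lt(res2$hr[res2$subgroup == "colon"], res2$hr[res2$subgroup == "rectal"])

  none <- toy_outcome(entry[1:10], entry[1:10] + 1, rep(0L, 10))
  expect_error(subgroup_run(none, by = "sex", estimator = function(o, rows) NULL),
               "no events|empty")
})
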