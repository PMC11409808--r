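test_that("genotype simulation is a deterministic function of the seed", {
  g1 <- simulate_genotypes(200, 30, seed = 7)
  g2 <- simulate_genotypes(200, 30, seed = 7)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$variants, g2$variants)
  g3 <- simulate_genotypes(200, 30, seed = 8)
  expect_false(identical(g1$dosages, g3$dosages))
})

test_that("genotype panels respect their declared structure", {
  g <- simulate_genotypes(1000, 50, maf_range = c(0.1, 0.5), seed = 1)
  expect_true(all(g$dosages %in% 0:2))
  expect_true(all(g$variants$maf > 0 & g$variants$maf <= 0.5))
  # positions strictly increasing within chromosome
  for (ch in unique(g$variants$chr)) {
    expect_true(all(diff(g$variants$pos[g$variants$chr == ch]) > 0))
  }
  # empirical allele frequency tracks the declared maf
  eaf <- colMeans(g$dosages) / 2
  expect_true(max(abs(eaf - g$variants$maf)) < 0.06)
  # tiny-panel sanity: binomial mean ~1 at p = 0.5
  gs <- simulate_genotypes(10, 1, maf_range = c(0.5, 0.5), seed = 3)
  expect_true(mean(gs$dosages) >= 0.4 && mean(gs$dosages) <= 1.6)
  expect_error(simulate_genotypes(1, 10), "non-positive")
  expect_error(simulate_genotypes(10, 10, maf_range = c(0.6, 0.7)), "maf_range")
})

test_that("HWE holds under the equilibrium generator and breaks with inbreeding", {
  g <- simulate_genotypes(1000, 50, maf_range = c(0.1, 0.5), hwe = TRUE, seed = 1)
  p <- hwe_test(colSums(g$dosages == 2), colSums(g$dosages == 1),
                colSums(g$dosages == 0))
  expect_gte(sum(p > 1e-6), 49)
  gi <- simulate_genotypes(2000, 50, maf_range = c(0.2, 0.5), hwe = FALSE, seed = 1)
  pi_ <- hwe_test(colSums(gi$dosages == 2), colSums(gi$dosages == 1),
                  colSums(gi$dosages == 0))
  expect_gte(sum(pi_ < 1e-6), 40)
})

test_that("trait simulation realizes the requested variance decomposition", {
  reps <- vapply(1:10, function(s) {
    g <- simulate_genotypes(20000, 200, seed = s)
    arch <- make_architecture(g, h2 = c(t = 0.3), n_causal = c(t = 30), seed = s)
    coh <- simulate_traits(g, arch, seed = s)
    coh$truth$decomposition$frac_genetic
  }, 0)
  expect_lt(abs(mean(reps) - 0.3), 0.02)
})

test_that("a zero-heritability trait is uncorrelated with its causal variants", {
  g <- simulate_genotypes(10000, 100, seed = 5)
  arch <- make_architecture(g, h2 = c(t = 0), n_causal = c(t = 20), seed = 5)
  coh <- simulate_traits(g, arch, seed = 5)
  g_raw <- drop(g$dosages[, arch$causal$t] %*% arch$effects$t)
  expect_lt(abs(cor(coh$traits$t, g_raw)), 0.05)
})

test_that("impossible variance budgets are rejected", {
  g <- simulate_genotypes(100, 20, seed = 1)
  expect_error(make_architecture(g, h2 = c(t = 1), n_causal = c(t = 5)),
               "\\[0, 1\\)")
  expect_error(make_architecture(g, h2 = c(t = 0.6), n_causal = c(t = 5),
                                 family_frac = c(t = 0.2),
                                 confounder_frac = c(t = 0.2)),
               "variance budget")
  expect_error(make_architecture(g, h2 = c(t = 0.1), causal = list(t = "nope")),
               "unknown causal")
})

test_that("family blocks partition the sample with valid coefficients", {
  kin <- make_kinship(10, block_size = 4)
  expect_equal(kin$family, c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3))
  expect_true(all(kin$pairs$coefficient >= 0 & kin$pairs$coefficient <= 0.5))
  expect_equal(nrow(kin$pairs), 6 + 6 + 1)
  expect_error(make_kinship(10, coefficient = 0.7))
})

test_that("outcome simulation respects hazards, censoring, and the subsite split", {
  g <- simulate_genotypes(20000, 100, seed = 2)
  arch <- make_architecture(g, h2 = c(t = 0.1), n_causal = c(t = 10),
                            log_hr = c(t = 0), seed = 2)
  coh <- simulate_traits(g, arch, seed = 2)
  out <- simulate_outcome(coh, arch, seed = 2)
  expect_true(all(out$exit_age > out$entry_age))
  ef <- attr(out, "event_fraction")
  expect_true(ef > 0.03 && ef < 0.3)
  tab <- table(out$subsite[out$event == 1])
  expect_lt(abs(tab[["colon"]] / tab[["rectal"]] - 2), 0.4)
  expect_error(simulate_outcome(coh, arch, censor_age = 30), "empty risk set")
  expect_error(simulate_outcome(coh, arch, baseline_rate = 0), "all-zero hazard")
  out2 <- simulate_outcome(coh, arch, seed = 2)
  expect_identical(out, out2)
})

test_that("a protective trait effect is recovered by the observational Cox model", {
  hrs <- vapply(1:5, function(s) {
    g <- simulate_genotypes(10000, 50, seed = s)
    arch <- make_architecture(g, h2 = c(fruit = 0.1), n_causal = c(fruit = 10),
                              log_hr = c(fruit = log(0.8)), seed = s)
    coh <- simulate_traits(g, arch, seed = s)
    out <- simulate_outcome(coh, arch, seed = s)
    cox_fit(coh$traits$fruit, out, mode = "univariate",
            spec = covariate_spec("fruit"))$hr
  }, 0)
  expect_true(mean(hrs) > 0.7 && mean(hrs) < 0.9)
})
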