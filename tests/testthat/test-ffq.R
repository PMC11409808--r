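test_that("frequency conversion returns the documented numeric values", {
  freq <- c("Never" = 0, "Less than once a week" = 0.5, "Once a week" = 1,
            "2-4 times a week" = 3, "5-6 times a week" = 5.5,
            "Once or more daily" = 7)
  for (cls in c("meat", "fish", "cheese")) {
    expect_equal(convert_frequency(cls, names(freq)), unname(freq))
  }
  alc <- c("Never" = 0, "Special occasions only" = 0.125,
           "One to three times a month" = 0.5, "One to two times a week" = 1.5,
           "Three to four times a week" = 3.5, "Five to six times a week" = 5.5,
           "Daily or almost daily" = 7)
  expect_equal(convert_frequency("alcohol", names(alc)), unname(alc))
})

test_that("conversion is monotone, label-robust, and errors on unknown labels", {
  v <- convert_frequency("meat", c("Never", "Less than once a week",
                                   "Once a week", "2-4 times a week",
                                   "5-6 times a week", "Once or more daily"))
  expect_true(all(diff(v) > 0))
  # case, surrounding whitespace and en-dash variants all match
  expect_equal(convert_frequency("meat", "  2–4 TIMES A WEEK "), 3)
  expect_true(is.na(convert_frequency("meat", "Do not know")))
  expect_true(is.na(convert_frequency("alcohol", "Prefer not to answer")))
  expect_error(convert_frequency("meat", "Twice a fortnight"),
               "meat.*Twice a fortnight")
  expect_error(convert_frequency("broccoli", "Never"), "broccoli")
})

test_that("milk volume estimate is the stated linear rule and zero for non-consumers", {
  expect_equal(estimate_milk("full cream", 1, 2, 1), 185)
  expect_equal(estimate_milk("semi-skimmed", 0, 0, 0), 0)
  for (b in 0:2) for (co in 0:2) for (te in 0:2) {
    expect_equal(estimate_milk("never/rarely", b, co, te), 0)
  }
  expect_error(estimate_milk("skimmed", -1, 0, 0), "non-negative")
  expect_error(estimate_milk("oat", 1, 1, 1), "unknown milk type")
})

test_that("food groups follow the composition formulas with missing propagation", {
  items <- data.frame(pork = c(1, 1, NA), beef = c(1, 1, 1), lamb = c(0.5, 0, 1),
                      oily_fish = c(1, NA, 2), nonoily_fish = c(2, 2, 0),
                      fresh_fruit = c(2, 1, 0), dried_fruit = c(2, 0, 4),
                      cooked_veg = c(3, 2, 1), raw_veg = c(1, 1, 1),
                      milk = c(185, 0, 60), cheese = c(3, 3, 3),
                      processed_meat = c(1, 1, 1), poultry = c(1, 1, 1),
                      coffee = c(2, 2, 2), tea = c(3, 3, 3),
                      alcohol = c(1.5, 0, 7))
  g <- compose_groups(items)
  expect_equal(g$red_meat, c(2.5, 2, NA))
  expect_equal(g$total_fish, c(3, NA, 2))
  expect_equal(g$total_fruits, c(3, 1, 2))
  expect_equal(g$total_veg, c(4, 3, 2))
  miss <- attr(g, "missing")
  expect_equal(miss$n_missing[miss$trait == "red_meat"], 1L)
  expect_equal(miss$n_missing[miss$trait == "total_fish"], 1L)
  expect_equal(miss$n_missing[miss$trait == "coffee"], 0L)
})

test_that("group composition is linear in its constituents", {
  set.seed(4)
  cols <- c("pork", "beef", "lamb", "oily_fish", "nonoily_fish",
            "fresh_fruit", "dried_fruit", "cooked_veg", "raw_veg")
  a <- as.data.frame(matrix(runif(5 * 9), 5, 9, dimnames = list(NULL, cols)))
  b <- as.data.frame(matrix(runif(5 * 9), 5, 9, dimnames = list(NULL, cols)))
  ga <- compose_groups(a); gb <- compose_groups(b); gab <- compose_groups(a + b)
  for (tr in c("red_meat", "total_fish", "total_fruits", "total_veg")) {
    expect_equal(gab[[tr]], ga[[tr]] + gb[[tr]])
  }
})

test_that("trait summaries switch between mean/sd and median/IQR on normality", {
  set.seed(11)
  tr <- data.frame(normalish = rnorm(500), skewed = rexp(500))
  s <- summarize_traits(tr)
  expect_equal(s$summary[s$trait == "normalish"], "mean +/- sd")
  expect_true(s$shapiro_p[s$trait == "normalish"] >= 0.05)
  expect_equal(s$summary[s$trait == "skewed"], "median (Q1-Q3)")
  expect_true(s$shapiro_p[s$trait == "skewed"] < 0.05)
  expect_equal(s$location[s$trait == "skewed"], median(tr$skewed))
  expect_error(summarize_traits(data.frame(flat = rep(2, 100))), "constant")
  expect_error(summarize_traits(data.frame(x = c(NA_real_, NA_real_, NA_real_))),
               "missing")
})

test_that("FFQ simulation and conversion round-trip on category values", {
  vals <- c(0, 0.5, 1, 3, 5.5, 7)
  labs <- simulate_ffq(vals, "meat")
  expect_equal(convert_frequency("meat", labs), vals)
  alc_vals <- c(0, 0.125, 0.5, 1.5, 3.5, 5.5, 7)
  expect_equal(convert_frequency("alcohol", simulate_ffq(alc_vals, "alcohol")),
               alc_vals)
  expect_equal(simulate_ffq(3.0, "meat"), "2-4 times a week")
  expect_equal(simulate_ffq(0, "meat"), "Never")
  # distance ties resolve to the lower category
  expect_equal(simulate_ffq(0.75, "meat"), "Less than once a week")
  expect_equal(simulate_ffq(2, "meat"), "Once a week")
  expect_error(simulate_ffq(-0.1, "meat"), "non-negative")
})
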