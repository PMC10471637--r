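test_that("classify_prediction distinguishes concordant/under/over", {
  expect_equal(classify_prediction(8, 8), "concordant")
  expect_equal(classify_prediction(7, 8), "under")
  expect_equal(classify_prediction(9, 7), "over")
  expect_equal(classify_prediction(c(8, 7, 9), c(8, 8, 7)),
               c("concordant", "under", "over"))
  expect_error(classify_prediction(0, 8), "positive")
})

test_that("Clopper-Pearson interval hits the textbook boundaries", {
  ci <- exact_binomial_ci(0, 10)
  expect_equal(unname(ci["lower"]), 0)
  ci <- exact_binomial_ci(10, 10)
  expect_equal(unname(ci["upper"]), 1)
  expect_error(exact_binomial_ci(11, 10), "successes")
  expect_error(exact_binomial_ci(5, 10, level = 1.2), "level")

  # nesting: 99% interval contains the 95% interval for the same (x, n)
  for (x in c(3, 40, 78)) {
    ci95 <- exact_binomial_ci(x, 92, 0.95)
    ci99 <- exact_binomial_ci(x, 92, 0.99)
    expect_lte(ci99["lower"], ci95["lower"])
    expect_gte(ci99["upper"], ci95["upper"])
  }

  # Wilson option stays inside [0, 1] and brackets the point estimate
  ci <- exact_binomial_ci(78, 92, method = "wilson")
  expect_true(ci["lower"] < 78 / 92 && 78 / 92 < ci["upper"])
})

test_that("weighted kappa matches limiting cases", {
  # perfect agreement across several categories
  k <- weighted_kappa_linear(c(6, 7, 8, 9, 10), c(6, 7, 8, 9, 10))
  expect_equal(k$kappa, 1)
  k <- weighted_kappa_linear(rep(c(7, 8), each = 10), rep(c(7, 8), each = 10))
  expect_equal(k$kappa, 1)

  # 2x2 independence: [[5,5],[5,5]] -> kappa 0
  pred <- rep(c(7, 7, 8, 8), each = 5)
  act <- rep(c(7, 8, 7, 8), each = 5)
  expect_equal(weighted_kappa_linear(pred, act)$kappa, 0)

  # all mass in one cell for both raters -> degenerate, not a number
  k <- weighted_kappa_linear(rep(8, 10), rep(8, 10))
  expect_true(k$degenerate)
  expect_true(is.na(k$kappa))

  expect_error(weighted_kappa_linear(8, 8), "at least 2")
  expect_error(weighted_kappa_linear(c(7, 8), c(7, 9), categories = 7:8), "grid")
})

test_that("weighted kappa equals the brute-force oracle on random tables", {
  set.seed(2024)
  for (rep in 1:1000) {
    k_cat <- sample(2:5, 1)
    categories <- seq(6, 6 + k_cat - 1)
    n <- sample(5:25, 1)
    pred <- sample(categories, n, replace = TRUE)
    act <- sample(categories, n, replace = TRUE)
    oracle <- brute_force_weighted_kappa(pred, act, categories)
    got <- weighted_kappa_linear(pred, act, categories = categories)
    if (is.na(oracle)) {
      expect_true(got$degenerate)
    } else {
      expect_equal(got$kappa, oracle, tolerance = 1e-12)
      expect_lte(got$kappa, 1)
    }
  }
})

test_that("kappa decreases when a concordant pair turns discordant", {
  set.seed(99)
  for (rep in 1:50) {
    categories <- 6:9
    n <- 30
    pred <- sample(categories, n, replace = TRUE)
    act <- pred
    flip <- sample(n, 4) # introduce some baseline disagreement
    act[flip] <- pmin(9, act[flip] + 1)
    k0 <- weighted_kappa_linear(pred, act, categories = categories)$kappa
    conc <- which(pred == act)
    i <- conc[1]
    act2 <- act
    act2[i] <- if (act[i] < 9) act[i] + 1 else act[i] - 1
    k1 <- weighted_kappa_linear(pred, act2, categories = categories)$kappa
    expect_lt(k1, k0)
  }
})

test_that("kappa bands follow the two-decimal rounding rule", {
  expect_equal(kappa_band(0.797), "Strong") # rounds to 0.80
  expect_equal(kappa_band(1.0), "Almost Perfect")
  expect_equal(kappa_band(0.50), "Weak")
  expect_equal(kappa_band(0.794), "Moderate") # rounds to 0.79
  expect_equal(kappa_band(0.905), "Almost Perfect") # rounds to 0.91
  expect_equal(kappa_band(0.10), "None")
  expect_equal(kappa_band(0.30), "Minimal")
  expect_error(kappa_band(1.2), "kappa")
})

test_that("agreement_summary reproduces the printed study proportions from its counts", {
  # pairs engineered to a 78 concordant / 8 under / 6 over split
  pred <- c(rep(8, 78), rep(7, 5), rep(8, 3), rep(8, 5), rep(9, 1))
  act <- c(rep(8, 78), rep(8, 5), rep(9, 3), rep(7, 5), rep(7, 1))
  res <- agreement_summary(pred, act)
  expect_equal(res$n, 92)
  expect_equal(res$n_concordant, 78)
  expect_equal(res$n_under, 8)
  expect_equal(res$n_over, 6)
  expect_equal(round_half_away(res$concordance_pct), 85)
  expect_equal(round_half_away(unname(res$concordance_ci)), c(76, 91))
  expect_equal(round_half_away(res$under_pct), 9)
  expect_equal(round_half_away(unname(res$under_ci)), c(4, 16))
  expect_equal(round_half_away(unname(res$over_ci)), c(2, 14))
  expect_equal(res$n_concordant + res$n_under + res$n_over, res$n)

  # single pair: 100% concordance, kappa flagged degenerate
  res <- agreement_summary(8, 8)
  expect_equal(res$concordance_pct, 100)
  expect_true(res$kappa_degenerate)
})

test_that("agreement_summary concordance tracks the sampling proportion", {
  set.seed(31)
  n <- 1000
  concord <- runif(n) < 0.85
  act <- sample(7:9, n, replace = TRUE)
  pred <- ifelse(concord, act, act + sample(c(-1, 1), n, replace = TRUE))
  res <- agreement_summary(pred, act)
  se <- sqrt(0.85 * 0.15 / n) * 100
  expect_lt(abs(res$concordance_pct - 85), 3 * se)
})
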