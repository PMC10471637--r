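test_that("simulation config validation rejects degenerate settings", {
  expect_error(simulation_config(p_under = 0.6, p_over = 0.6), "exceed 1")
  expect_error(simulation_config(st_sd_mm = 0), "positive")
  expect_error(simulation_config(eccentricity = 0.9), ">= 1")
  expect_error(simulation_config(st_mean_mm = 1, st_sd_mm = 0.45), "degenerate")
  expect_error(simulation_config(age_range = c(16, 50)), "age_range")
  expect_silent(validate_simulation_config(calibrated_default_config()))
})

test_that("simulated cohorts are structurally valid and seed-reproducible", {
  co <- simulate_cohort(simulation_config(seed = 1))
  expect_equal(n_patients(co), 92)
  expect_equal(nrow(co), 92 * 8)
  v <- validate_cohort(co)
  expect_equal(nrow(v[v$severity == "error", ]), 0)

  co2 <- simulate_cohort(simulation_config(seed = 1))
  expect_identical(tibble::as_tibble(co), tibble::as_tibble(co2))
  expect_identical(cohort_metadata(co)$truth, cohort_metadata(co2)$truth)

  co3 <- simulate_cohort(simulation_config(seed = 2))
  expect_false(identical(tibble::as_tibble(co), tibble::as_tibble(co3)))
})

test_that("zero reader noise gives exactly zero bias and CoR", {
  co <- simulate_cohort(simulation_config(seed = 9, noise_sd_mm = 0))
  rep <- reproducibility_report(co)
  for (nm in c("intra_st", "intra_gt", "inter_st", "inter_gt")) {
    expect_equal(rep[[nm]]$bias_mm, 0)
    expect_equal(rep[[nm]]$cor_mm, 0)
  }
})

test_that("generator recovers its discordance probabilities over replicates", {
  # actual graft sizes are generated from the true rounded prediction, so
  # comparing those labels recovers (p_equal, p_under, p_over) up to
  # binomial sampling error: 200 replicates of n = 92
  set.seed(314)
  reps <- 200
  n <- 92
  counts <- matrix(0, reps, 3, dimnames = list(NULL, c("eq", "under", "over")))
  for (i in seq_len(reps)) {
    co <- simulate_cohort(simulation_config(seed = sample.int(2^30, 1)))
    tr <- cohort_metadata(co)$truth
    cls <- classify_prediction(tr$true_pgd_rounded_mm, tr$actual_graft_mm)
    counts[i, ] <- c(mean(cls == "concordant"), mean(cls == "under"),
                     mean(cls == "over"))
  }
  p_true <- c(1 - 8 / 92 - 6 / 92, 8 / 92, 6 / 92)
  for (j in 1:3) {
    se <- sqrt(p_true[j] * (1 - p_true[j]) / (reps * n))
    expect_lt(abs(mean(counts[, j]) - p_true[j]), 3 * se)
  }
})

test_that("single-measurement repeatability recovers 1.96 * sqrt(2) * noise_sd", {
  # compare raw major-axis readings across sessions on a large cohort; at
  # noise well above the 0.1-mm grid the quantization inflation is small
  sd_noise <- 0.2
  co <- simulate_cohort(simulation_config(
    n_patients = 10000, seed = 77, noise_sd_mm = sd_noise
  ))
  data <- tibble::as_tibble(co)
  sl <- function(session) {
    s <- data[data$tendon == "ST" & data$reader == "R1" & data$session == session, ]
    s$major_mm[order(s$patient_id)]
  }
  res <- bland_altman(sl("t0"), sl("t1month"))
  target <- 1.96 * sqrt(2) * sd_noise
  expect_lt(abs(res$cor_mm - target) / target, 0.10)
})

test_that("expected CoR increases monotonically with reader noise", {
  cors <- vapply(c(0.02, 0.08, 0.25), function(s) {
    co <- simulate_cohort(simulation_config(n_patients = 2000, seed = 55,
                                            noise_sd_mm = s))
    reproducibility_report(co)$intra_st$cor_mm
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("calibrated defaults reproduce the study-scale summaries", {
  co <- simulate_cohort(calibrated_default_config(seed = 1))
  rep <- study_report(co)

  # median rounded prediction lands on the clinically typical 7-8 mm
  preds <- predict_cohort(co)
  expect_true(median(preds$pgd_rounded_mm) %in% c(7, 8))

  # CoRs at the study's order of magnitude
  for (nm in c("intra_st", "intra_gt", "inter_st", "inter_gt")) {
    expect_gte(rep$reproducibility[[nm]]$cor_mm, 0.03)
    expect_lte(rep$reproducibility[[nm]]$cor_mm, 0.15)
  }

  # concordance within 3 binomial SEs of 85% at n = 92
  se <- sqrt(0.85 * 0.15 / 92) * 100
  expect_lt(abs(rep$agreement$concordance_pct - 85), 3 * se)

  # median actual graft size 8 mm at n = 1000
  big <- simulate_cohort(simulation_config(n_patients = 1000, seed = 2))
  tr <- cohort_metadata(big)$truth
  expect_equal(median(tr$actual_graft_mm), 8)

  # forced concordance: no discordance probabilities -> kappa 1
  forced <- simulate_cohort(simulation_config(seed = 6, p_under = 0, p_over = 0,
                                              noise_sd_mm = 0))
  tr <- cohort_metadata(forced)$truth
  res <- agreement_summary(tr$true_pgd_rounded_mm, tr$actual_graft_mm)
  expect_equal(res$concordance_pct, 100)
  expect_equal(res$kappa, 1)
})
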