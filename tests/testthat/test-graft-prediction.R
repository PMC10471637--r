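test_that("mean tendon diameter is the exact two-decimal half-sum", {
  cases <- list(
    list(4.3, 3.2, 3.75),
    list(4.0, 4.0, 4.00),
    list(5.1, 3.0, 4.05)
  )
  for (cs in cases) {
    expect_equal(mean_tendon_diameter(cs[[1]], cs[[2]]), cs[[3]])
  }
  expect_error(mean_tendon_diameter(3.0, 4.5), "exceeds major")
  expect_error(mean_tendon_diameter(3.0, -1.0), "positive")
  expect_error(mean_tendon_diameter(3.05, 3.0), "0.1-mm grid")
})

test_that("round_up_mm is the ceiling with integer fixed points", {
  expect_equal(round_up_mm(7.01), 8L)
  expect_equal(round_up_mm(7.00), 7L)
  expect_equal(round_up_mm(7.50), 8L)
  # float representations of exact decimals are not bumped
  expect_equal(round_up_mm(4.05 + 3.95), 8L)
  expect_error(round_up_mm(0), "positive")
  expect_error(round_up_mm(-2), "positive")
})

test_that("predicted_graft_diameter composes means, sum and ceiling", {
  p <- predicted_graft_diameter(4.6, 4.0, 3.4, 3.0)
  expect_equal(p$mean_st_mm, 4.30)
  expect_equal(p$mean_gt_mm, 3.20)
  expect_equal(p$pgd_raw_mm, 7.50)
  expect_equal(p$pgd_rounded_mm, 8L)

  expect_equal(predicted_graft_diameter(4.0, 4.0, 3.0, 3.0)$pgd_rounded_mm, 7L)

  # hand arithmetic: (4.9+4.2)/2 + (3.7+3.2)/2 = 4.55 + 3.45 = 8.00
  p <- predicted_graft_diameter(4.9, 4.2, 3.7, 3.2)
  expect_equal(p$pgd_raw_mm, 8.00)
  expect_equal(p$pgd_rounded_mm, 8L)

  expect_error(predicted_graft_diameter(4.0, 4.5, 3.0, 3.0), "^ST")
  expect_error(predicted_graft_diameter(4.5, 4.0, 3.0, 3.4), "^GT")
})

test_that("PGD is monotone in every input and ceiling gap is in [0, 1)", {
  set.seed(42)
  for (rep in 1:200) {
    base <- c(st_major = 0, st_minor = 0, gt_major = 0, gt_minor = 0)
    mnr <- round(runif(2, 2.0, 4.0), 1)
    base[c("st_minor", "gt_minor")] <- mnr
    base[c("st_major", "gt_major")] <- mnr + round(runif(2, 0, 1.5), 1)
    p0 <- predicted_graft_diameter(base["st_major"], base["st_minor"],
                                   base["gt_major"], base["gt_minor"])
    gap <- p0$pgd_rounded_mm - p0$pgd_raw_mm
    expect_gte(gap, 0)
    expect_lt(gap, 1)

    # bump one input by 0.1 mm (major always safe; minor only if it stays <= major)
    which_input <- sample(4, 1)
    bumped <- base
    bumped[which_input] <- round(bumped[which_input] + 0.1, 1)
    if (bumped["st_minor"] <= bumped["st_major"] &&
        bumped["gt_minor"] <= bumped["gt_major"]) {
      p1 <- predicted_graft_diameter(bumped["st_major"], bumped["st_minor"],
                                     bumped["gt_major"], bumped["gt_minor"])
      expect_gte(p1$pgd_raw_mm, p0$pgd_raw_mm)
      expect_gte(p1$pgd_rounded_mm, p0$pgd_rounded_mm)
    }
  }
})

test_that("predict_cohort yields one prediction per complete record and reports exclusions", {
  sim <- simulate_cohort(simulation_config(seed = 3))
  preds <- predict_cohort(sim)
  expect_equal(nrow(preds), 92)
  expect_equal(nrow(prediction_exclusions(preds)), 0)

  # remove one patient's GT measurement at R1/t0 -> reported exclusion
  data <- tibble::as_tibble(sim)
  drop <- which(data$patient_id == "P001" & data$reader == "R1" &
                  data$session == "t0" & data$tendon == "GT")
  maimed <- graft_cohort(data[-drop, ])
  preds <- predict_cohort(maimed)
  expect_equal(nrow(preds), 91)
  excl <- prediction_exclusions(preds)
  expect_equal(excl$patient_id, "P001")

  expect_error(predict_cohort(sim, reader = "R9"), "unknown reader")
  expect_error(predict_cohort(sim, session = "t2"), "unknown session")
})

test_that("reader-averaged reconciliation agrees with single-reader on noise-free cohorts", {
  co <- make_cohort(default_specs(3))
  single <- predict_cohort(co, reader = "R1", session = "t0")
  averaged <- predict_cohort(co, reconcile = "mean")
  expect_equal(single$pgd_raw_mm, averaged$pgd_raw_mm)
  expect_equal(single$pgd_rounded_mm, averaged$pgd_rounded_mm)
})
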