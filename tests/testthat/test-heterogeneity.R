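test_that("Brier score closed forms", {
  expect_equal(brier_score(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(brier_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.25)
  expect_equal(brier_score(c(0.2, 0.8), c(0, 1)), 0.04)
  # constant event-rate predictor: Brier = rate * (1 - rate) exactly
  y <- rep(c(1, 0, 0, 0), 25)
  rate <- mean(y)
  expect_equal(brier_score(rep(rate, length(y)), y), rate * (1 - rate))
  expect_error(brier_score(numeric(0), numeric(0)), "empty")
  expect_error(brier_score(1.2, 1), "outside")
})

test_that("expected/observed ratio arithmetic and undefined case", {
  eo <- expected_observed_ratio(c(0.5, 0.5, 0.3), c(1, 0, 0), c("a", "a", "b"))
  expect_equal(eo$eo[eo$study == "a"], 1)
  expect_true(is.na(eo$eo[eo$study == "b"]))
  y <- rep(c(1, 0), 10)
  eo2 <- expected_observed_ratio(rep(mean(y), 20), y, rep("s", 20))
  expect_equal(eo2$eo, 1)
  # in-sample intercept-only model calibrates exactly
  d <- tibble::tibble(y = rep(c(1, 0, 0), 30))
  p <- fitted(glm(y ~ 1, binomial(), data = d))
  expect_lt(abs(expected_observed_ratio(p, d$y, rep("s", 90))$eo - 1), 1e-9)
})

make_calibration_table <- function(n, seed, shift = c(a = 0, b = 0, c = 0)) {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      study_id = sample(names(shift), n, TRUE),
      age = rnorm(n, 38, 12),
      female = runif(n) < 0.4,
      single = runif(n) < 0.5,
      low_education = runif(n) < 0.2,
      prior_trauma = factor(sample(c("none", "non-interpersonal",
                                     "interpersonal"), n, TRUE),
                            c("none", "non-interpersonal", "interpersonal")),
      index_trauma = factor(sample(c("MVA", "other_accident", "assault"),
                                   n, TRUE, prob = c(0.7, 0.2, 0.1)),
                            c("MVA", "other_accident", "assault"))
    )
    eta <- -1.2 + 0.6 * d$female - 0.01 * (d$age - 38) +
      0.4 * (d$index_trauma == "assault") + shift[d$study_id]
    d$ptsd_trajectory <- factor(
      ifelse(runif(n) < plogis(eta), "Persistent", "Never"),
      traumameta::trajectory_levels())
    d
  })
}

test_that("bootstrap calibration is deterministic under a fixed seed", {
  d <- make_calibration_table(400, 1)
  r1 <- bootstrap_calibration(d, "ptsd", model = "fixed", B = 2, seed = 5)
  r2 <- bootstrap_calibration(d, "ptsd", model = "fixed", B = 2, seed = 5)
  expect_identical(r1, r2)
  expect_s3_class(r1, "calibration_report")
})

test_that("a study intercept ignored by the model shows E/O below 1", {
  d <- make_calibration_table(1800, 2, shift = c(a = 0, b = 0, c = 1))
  # single-study-blind model: drop study information entirely
  d_blind <- d
  r <- withr::with_seed(1, {
    fit <- glm(I(ptsd_trajectory == "Persistent") ~ female + age,
               binomial(), data = d_blind)
    expected_observed_ratio(fitted(fit), d$ptsd_trajectory == "Persistent",
                            d$study_id)
  })
  expect_lt(r$eo[r$study == "c"], 1)
  expect_gt(r$eo[r$study == "a"], 1)
})

test_that("more bootstrap replicates reduce Monte-Carlo noise", {
  d <- make_calibration_table(600, 3)
  run_sd <- function(B) {
    reps <- vapply(1:4, function(s) {
      r <- bootstrap_calibration(d, "ptsd", model = "fixed", B = B, seed = s)
      r$eo[r$study == "a"]
    }, numeric(1))
    sd(reps)
  }
  expect_lt(run_sd(60), run_sd(5) + 1e-12)
})

test_that("leave-one-study-out drops exactly one study and keeps the schema", {
  coh <- generate_cohort(small_configs(220), generative_params(), seed = 43)
  cl <- classify_cohort(coh)
  full <- fit_risk_multinomial(cl, "ptsd")
  loso <- leave_one_study_out(cl, "study_h", "ptsd")
  expect_identical(names(loso), names(full))
  expect_identical(attr(loso, "excluded_study"), "study_h")
  # a dropped study contributing zero events leaves event counts unchanged
  cl0 <- dplyr::bind_rows(cl, dplyr::mutate(
    cl[1:5, ], study_id = "empty", participant_id = paste0("e", 1:5),
    ptsd_trajectory = factor("Never", traumameta::trajectory_levels())))
  ev_with <- sum(cl0$ptsd_trajectory == "Persistent")
  ev_without <- sum(dplyr::filter(cl0, study_id != "empty")$ptsd_trajectory
                    == "Persistent")
  expect_equal(ev_with, ev_without)
})

test_that("window sensitivity: identity window reproduces the primary labels", {
  coh <- generate_cohort(small_configs(80, followup = 0.8),
                         generative_params(), seed = 47)
  primary <- classify_cohort(coh)
  ws <- suppressWarnings(window_sensitivity(
    coh, window = c(122, 456), spec = imputation_spec(m = 2, cycles = 1,
                                                      engine = "fixed")))
  expect_equal(ws$classified, primary)
  expect_error(window_sensitivity(coh, c(100, 456)), "within")
  expect_error(window_sensitivity(coh, c(400, 300)), "increasing")
  # all wave-2 assessments outside the window: clean degenerate error
  coh_early <- coh
  coh_early$days_since_trauma[coh_early$wave == 2] <- 150
  expect_error(window_sensitivity(coh_early, c(400, 456)), "no wave-2")
})

test_that("random-intercept calibration model runs and stays calibrated", {
  d <- make_calibration_table(900, 7, shift = c(a = -0.4, b = 0, c = 0.4))
  rep <- suppressWarnings(
    bootstrap_calibration(d, "ptsd", model = "random", B = 3, seed = 2,
                          nAGQ = 1))
  expect_s3_class(rep, "calibration_report")
  expect_equal(unique(rep$model), "random")
  expect_true(all(is.finite(rep$eo)))
  expect_true(all(rep$brier > 0 & rep$brier < 0.3))
})
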