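test_that("generation is deterministic and validates parameters", {
  cfg <- list(study_config("s", 10, "BDI"))
  c1 <- generate_cohort(cfg, generative_params(), seed = 7)
  c2 <- generate_cohort(cfg, generative_params(), seed = 7)
  expect_identical(c1, c2)
  expect_error(generative_params(theta_wave_corr = 1), "inside")
  expect_error(generative_params(dep_ptsd_corr = -1.2), "inside")
  bad_bank <- default_item_bank()
  bad_bank$thresholds[[3]] <- c(1, 0.5)
  expect_error(generative_params(item_bank = bad_bank),
               "strictly increasing")
  expect_error(study_config("s", 0), ">= 1")
  expect_error(study_config("s", 5, followup_rate = 0), "followup_rate")
})

test_that("cohort invariants hold: waves, windows, ranges, constancy", {
  coh <- generate_cohort(small_configs(80, followup = 0.8),
                         generative_params(), seed = 3)
  expect_true(all(table(coh$participant_id) == 2))
  expect_true(all(coh$days_since_trauma[coh$wave == 1] >= 0 &
                    coh$days_since_trauma[coh$wave == 1] <= 60))
  expect_true(all(coh$days_since_trauma[coh$wave == 2] >= 122 &
                    coh$days_since_trauma[coh$wave == 2] <= 456))
  caps <- as.matrix(coh[, c(sprintf("caps_f%02d", 1:17),
                            sprintf("caps_i%02d", 1:17))])
  expect_true(all(is.na(caps) | (caps >= 0 & caps <= 4)))
  cov_by_id <- dplyr::distinct(coh, .data$participant_id, .data$age,
                               .data$female, .data$prior_trauma)
  expect_equal(nrow(cov_by_id), dplyr::n_distinct(coh$participant_id))
})

test_that("complete follow-up leaves no missing wave-2 assessments", {
  coh <- generate_cohort(small_configs(60, followup = 1),
                         generative_params(), seed = 5)
  expect_true(all(coh$obs_dep))
  expect_true(all(coh$obs_ptsd))
})

test_that("classifier-derived trajectories equal generator truth", {
  coh <- generate_cohort(small_configs(200, followup = 1),
                         generative_params(), seed = 9)
  cl <- classify_cohort(coh)
  tr <- attr(coh, "truth")
  cl <- dplyr::left_join(cl, tr, by = c("participant_id", "study_id"))
  expect_equal(as.character(cl$ptsd_trajectory), cl$true_class_ptsd)
  expect_equal(as.character(cl$mdd_trajectory), cl$true_class_mdd)
})

test_that("MCAR wave-2 missingness hits the configured rate", {
  # n and rate sized to the published cohort: 2571 participants, 31.2%
  n <- 2571
  coh <- generate_cohort(list(study_config("s", n, "BDI", followup_rate = 0.9)),
                         generative_params(missing_rate = 0.312), seed = 13)
  miss <- sum(!coh$obs_ptsd[coh$wave == 2])
  ci <- qbinom(c(0.005, 0.995), n, 0.312)  # 99% binomial interval around 802
  expect_gte(miss, ci[1])
  expect_lte(miss, ci[2])
  # and within 3 SE of the rate
  expect_lt(abs(miss / n - 0.312), 3 * sqrt(0.312 * 0.688 / n))
})

test_that("MAR missingness depends on wave-1 severity as constructed", {
  coh <- generate_cohort(
    list(study_config("s", 1500, "BDI", followup_rate = 0.65)),
    generative_params(missing_mechanism = "MAR"), seed = 17)
  scored <- score_cohort(coh)
  w1 <- scored[scored$wave == 1, ]
  w2 <- scored[scored$wave == 2, ]
  expect_gt(mean(w1$ptsd_severity[!w2$obs_ptsd]),
            mean(w1$ptsd_severity[w2$obs_ptsd]))
  # covariates and wave-1 assessments are never removed
  expect_true(all(!is.na(w1$ptsd_severity)))
  expect_true(all(!is.na(w2$age)))
})

test_that("class prevalences move monotonically with class intercepts", {
  prev <- vapply(c(-2.9, -1.9, -0.9), function(ic) {
    p <- generative_params()
    p$class_intercepts$ptsd["acute"] <- ic
    coh <- generate_cohort(list(study_config("s", 800, "BDI", followup_rate = 1)),
                           p, seed = 23)
    mean(attr(coh, "truth")$true_class_ptsd == "Acute")
  }, numeric(1))
  expect_true(all(diff(prev) > 0))
})

test_that("cohort round-trips to disk with its truth sidecar", {
  coh <- generate_cohort(list(study_config("s", 20, "HADS")),
                         generative_params(), seed = 29)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1])
  expect_equal(nrow(back), nrow(coh))
  sidecar <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(sidecar$params$theta_wave_corr, 0.7)
})

test_that("null covariate effects give OR confidence intervals covering 1", {
  null_effects <- list(ptsd = list(acute = c(), persistent = c()),
                       mdd = list(acute = c(), persistent = c()))
  cfgs <- list(study_config("b", 400, "BDI", followup_rate = 1),
               study_config("h", 400, "HADS", followup_rate = 1))
  cover <- vapply(1:200, function(r) {
    coh <- generate_cohort(cfgs,
                           generative_params(covariate_effects = null_effects),
                           seed = 40000 + r)
    or <- fit_risk_multinomial(classify_cohort(coh), "ptsd")
    row <- or[or$term == "femaleTRUE" & or$y.level == "Persistent", ]
    row$conf.low <= 1 && 1 <= row$conf.high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})
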