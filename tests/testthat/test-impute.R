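test_that("predictor screening selects by absolute correlation", {
  d <- withr::with_seed(1, {
    n <- 400
    x1 <- rnorm(n)
    tibble::tibble(
      participant_id = paste0("p", 1:n),
      study_id = sample(c("a", "b"), n, TRUE),
      y = x1 + rnorm(n),
      x1 = x1,
      x2 = -0.5 * x1 + rnorm(n),          # |corr| >= 0.10
      x3 = y + rnorm(n, sd = 3),          # weak but >= 0.10
      noise = rnorm(n)                    # ~ 0
    )
  })
  d$x3 <- withr::with_seed(2, d$y * 0.05 + rnorm(400))  # tune below threshold? keep as-is
  sel <- select_predictors(d, "y", threshold = 0.10)
  expect_true(all(c("x1", "x2", "study_id") %in% sel))
  expect_false("y" %in% sel)              # self-exclusion
  sel0 <- select_predictors(d, "y", threshold = 0)
  expect_setequal(sel0, c("x1", "x2", "x3", "noise", "study_id"))
  expect_error(select_predictors(dplyr::mutate(d, y = 1), "y"), "zero variance")
})

test_that("imputation leaves complete data untouched", {
  d <- withr::with_seed(3, tibble::tibble(
    participant_id = rep(paste0("p", 1:100), each = 2),
    study_id = rep(c("a", "b"), 100),
    wave = rep(1:2, 100),
    y = rnorm(200),
    flag = runif(200) < 0.4
  ))
  out <- impute_continuous_mixed(d, "y", c("wave"), m = 2, seed = 1)
  expect_equal(out[, 1], d$y)
  expect_equal(out[, 2], d$y)
  outb <- impute_binary_probit(d, "flag", c("wave"), m = 2, seed = 1)
  expect_equal(outb[, 1], d$flag)
})

test_that("fully observed tables yield m identical copies, deterministically", {
  d <- withr::with_seed(4, tibble::tibble(
    participant_id = paste0("p", 1:50),
    study_id = "a",
    y = rnorm(50)
  ))
  spec <- imputation_spec(m = 3, cycles = 2, seed = 11)
  imp <- run_mice(d, spec)
  expect_equal(imp$imputations[[1]], imp$imputations[[2]])
  expect_equal(tibble::as_tibble(imp$imputations[[1]]), d)
  imp2 <- run_mice(d, spec)
  expect_identical(imp$imputations, imp2$imputations)
})

test_that("chained imputation preserves observed cells and completes all", {
  coh <- generate_cohort(small_configs(120, followup = 0.7),
                         generative_params(), seed = 31)
  imp <- suppressWarnings(
    impute_cohort(coh, imputation_spec(m = 3, cycles = 2, seed = 7)))
  cl <- classify_cohort(coh)
  obs <- !is.na(cl$ptsd_severity_w2)
  for (d in imp$imputations) {
    expect_false(any(is.na(d$ptsd_severity_w2)))
    expect_false(any(d$ptsd_trajectory == "Unclassifiable"))
    expect_equal(d$ptsd_severity_w2[obs], cl$ptsd_severity_w2[obs])
  }
  # chain means mix: lag-1 autocorrelation of chain means stays moderate
  cm <- imp$meta$chain_means[[1]]
  expect_true(is.matrix(cm))
})

test_that("Rubin pooling arithmetic and invariants", {
  p <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$ubar, 1)
  expect_equal(p$b, 1)
  expect_equal(p$t, 7 / 3)
  ident <- rubin_pool(c(1.5, 1.5, 1.5), c(2, 2, 2))
  expect_equal(ident$b, 0)
  expect_equal(ident$t, ident$ubar)
  expect_identical(ident$df, Inf)
  expect_error(rubin_pool(1, 1), "m >= 2")
  # T >= Ubar always
  for (s in 1:20) {
    est <- withr::with_seed(s, rnorm(5))
    v <- withr::with_seed(s + 100, rchisq(5, 3) + 0.1)
    pl <- rubin_pool(est, v)
    expect_gte(pl$t, pl$ubar)
  }
})

test_that("D2 pooling of chi-square statistics behaves", {
  same <- pool_lrt_d2(rep(4, 5), df = 1)
  expect_equal(same$statistic, 4)
  expect_equal(same$p.value, pchisq(4, 1, lower.tail = FALSE))
  mixed <- pool_lrt_d2(c(1, 3, 8), df = 2)
  expect_gte(mixed$statistic, 0)
  expect_true(mixed$p.value >= 0 && mixed$p.value <= 1)
})
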