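test_that("linking a calibration to itself is the identity", {
  g <- grm_parameters(c("a1", "a2", "a3"), c(1.5, 1.2, 1.0),
                      list(c(-1, 0, 1), c(-0.5, 0.5, 1.5), c(0, 1, 2)),
                      anchor = TRUE)
  lk <- mean_sigma_link(g, g)
  expect_equal(lk$A, 1)
  expect_equal(lk$B, 0)
  g2 <- apply_linking(g, lk)
  expect_equal(g2$a, g$a)
  expect_equal(g2$thresholds, g$thresholds)
})

test_that("mean/sigma recovers an analytically forced transformation", {
  base <- grm_parameters(c("a1", "a2", "a3"), c(1.5, 1.2, 1.0),
                         list(c(-1, 0, 1), c(-0.5, 0.5, 1.5), c(0, 1, 2)),
                         anchor = TRUE)
  # target metric theta* = (theta - B) / A with A = 1.3, B = -0.4
  A <- 1.3
  B <- -0.4
  target <- grm_parameters(base$item, base$a * A,
                           lapply(base$thresholds, function(b) (b - B) / A),
                           anchor = TRUE)
  lk <- mean_sigma_link(base, target)
  expect_equal(lk$A, A, tolerance = 1e-12)
  expect_equal(lk$B, B, tolerance = 1e-12)
  back <- apply_linking(target, lk)
  expect_equal(back$a, base$a, tolerance = 1e-12)
  expect_equal(unlist(back$thresholds), unlist(base$thresholds),
               tolerance = 1e-12)
})

test_that("degenerate anchors raise an undefined-scale error", {
  g <- grm_parameters("a1", 1, list(0.5), anchor = TRUE)
  expect_error(mean_sigma_link(g, g), "fewer than 2 distinct")
})

test_that("true-score crosswalk pins endpoints and is monotone", {
  src <- grm_parameters(paste0("s", 1:4), rep(1.1, 4),
                        lapply(1:4, function(i) c(-1, 0, 1) + 0.1 * i))
  tgt <- grm_parameters(paste0("t", 1:8), rep(0.9, 8),
                        lapply(1:8, function(i) c(-1.2, 0.2, 0.9) + 0.05 * i))
  xw <- build_crosswalk(src, tgt)
  expect_equal(equate_score(xw, 0), 0L)
  expect_equal(equate_score(xw, 12), 24L)   # source max -> target max
  expect_true(all(diff(xw$equated_score) >= 0))
})

test_that("crosswalk round-trip changes a score by at most 2 points", {
  src <- grm_parameters(paste0("s", 1:5), rep(1.2, 5),
                        lapply(1:5, function(i) c(-1, 0, 1) + 0.1 * i))
  tgt <- grm_parameters(paste0("t", 1:5), rep(1.0, 5),
                        lapply(1:5, function(i) c(-0.8, 0.1, 1.1) + 0.08 * i))
  fwd <- build_crosswalk(src, tgt)
  bwd <- build_crosswalk(tgt, src)
  s <- fwd$source_score
  round_trip <- equate_score(bwd, equate_score(fwd, s))
  expect_true(all(abs(round_trip - s) <= 2))
})

test_that("cohort equating recovers a coherent probable-MDD threshold", {
  coh <- generate_cohort(small_configs(400), generative_params(), seed = 21)
  eq <- equate_cohort(coh)
  expect_gt(eq$link$A, 0.8)
  expect_lt(eq$link$A, 1.25)
  expect_lt(abs(eq$link$B), 0.3)
  thr <- min(eq$crosswalk$source_score[eq$crosswalk$equated_score >= 20])
  expect_true(thr %in% 11:15)
  # the implied rule agrees with the reference HADS >= 13 rule for nearly
  # everyone (disagreement only in the narrow band between thresholds)
  scored <- score_cohort(coh)
  hads <- scored$dep_raw[scored$instrument == "HADS" & scored$wave == 1]
  agree <- mean((hads >= thr) == (hads >= 13))
  expect_gte(agree, 0.9)
})
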