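test_that("CAPS scoring: zeros, rule boundary, and severity identity", {
  z <- score_caps(blank_caps())
  expect_equal(z$ptsd_severity, 0)
  expect_false(z$ptsd_dx)

  # exactly 1 B, 3 C, 2 D symptoms at freq 1 / intensity 2 -> diagnosis,
  # severity 6 symptoms x 3 points = 18
  rec <- blank_caps()
  on <- c(1, 6, 7, 8, 13, 14)
  for (s in on) {
    rec[[sprintf("caps_f%02d", s)]] <- 1
    rec[[sprintf("caps_i%02d", s)]] <- 2
  }
  sc <- score_caps(rec)
  expect_true(sc$ptsd_dx)
  expect_equal(sc$ptsd_severity, 18)
  expect_equal(sc$ptsd_severity, sc$ptsd_sev_b + sc$ptsd_sev_c + sc$ptsd_sev_d)

  # intensity 1 never counts as present even at high frequency
  rec2 <- rec
  rec2$caps_i01 <- 1
  rec2$caps_f01 <- 4
  expect_false(score_caps(rec2)$ptsd_dx)

  expect_error(score_caps(dplyr::mutate(blank_caps(), caps_f03 = 5)),
               "symptom 3")
})

test_that("CAPS scorer matches the per-symptom loop oracle", {
  recs <- random_caps(500, seed = 42)
  sc <- score_caps(recs)
  for (r in sample(nrow(recs), 60)) {
    o <- caps_oracle(recs[r, ])
    expect_equal(sc$ptsd_severity[r], o$severity)
    expect_equal(sc$ptsd_dx[r], o$dx)
  }
  expect_true(all(sc$ptsd_severity >= 0 & sc$ptsd_severity <= 136))
})

test_that("probable-MDD classification applies instrument thresholds", {
  expect_true(classify_mdd(20, "BDI")$probable_mdd)
  expect_false(classify_mdd(19, "BDI")$probable_mdd)
  h13 <- classify_mdd(13, "HADS")
  expect_true(h13$probable_mdd)
  expect_equal(h13$equated_severity, 20)
  h12 <- classify_mdd(12, "HADS")
  expect_false(h12$probable_mdd)
  expect_equal(h12$equated_severity, 18)
  # monotone flag in score for each instrument
  for (ins in c("BDI", "HADS")) {
    rng <- if (ins == "BDI") 0:63 else 0:21
    flags <- classify_mdd(rng, ins)$probable_mdd
    expect_true(all(diff(flags) >= 0))
  }
  expect_error(classify_mdd(64, "BDI"), "outside")
  expect_error(classify_mdd(22, "HADS"), "outside")
})

test_that("trajectory labels enumerate all diagnosis combinations", {
  got <- assign_trajectory(dx1 = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                           dx2 = c(TRUE, FALSE, FALSE, TRUE, NA))
  expect_equal(as.character(got),
               c("Persistent", "Acute", "Never", "Delayed", "Unclassifiable"))
  expect_setequal(levels(got), trajectory_levels())
  expect_error(assign_trajectory(TRUE, TRUE, day1 = 61), "outside")
  expect_error(assign_trajectory(TRUE, TRUE, day1 = 30, day2 = 500), "outside")
  expect_silent(assign_trajectory(TRUE, NA, day1 = 30, day2 = 500))
})

test_that("covariate harmonization maps codes and applies precedence", {
  raw <- tibble::tibble(
    age = c(30, 45, 60),
    sex = c("female", "male", "F"),
    marital = c("married", "single", "divorced"),
    education = c("university", "primary", "secondary"),
    index_trauma = c("mva", "assault", "fall"),
    prior_traumas = c("", "accident;combat", "accident")
  )
  h <- harmonize_covariates(raw)
  expect_equal(h$single, c(FALSE, TRUE, TRUE))
  expect_equal(h$low_education, c(FALSE, TRUE, FALSE))
  expect_equal(as.character(h$prior_trauma),
               c("none", "interpersonal", "non-interpersonal"))
  expect_equal(as.character(h$index_trauma), c("MVA", "assault", "other_accident"))
  expect_error(harmonize_covariates(dplyr::mutate(raw, marital = "widow")),
               "unmapped")
})
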