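test_that("packaged crosswalk maps the probable-MDD thresholds", {
  xw <- hads_bdi_crosswalk()
  expect_s3_class(xw, "crosswalk")
  expect_identical(equate_score(xw, 0), 0L)
  expect_identical(equate_score(xw, 13), 20L)
  expect_identical(equate_score(xw, 21), 63L)
  expect_identical(equate_score(xw, 12), 18L)
})

test_that("equate_score is monotone and validates its range", {
  xw <- hads_bdi_crosswalk()
  eq <- equate_score(xw, 0:21)
  expect_true(all(diff(eq) >= 0))
  expect_error(equate_score(xw, 22), "outside")
  expect_error(equate_score(xw, -1), "outside")
})

test_that("crosswalk construction enforces its invariants", {
  expect_error(new_crosswalk(c(0, 2), c(0, 5)), "no gaps")
  expect_error(new_crosswalk(0:2, c(0, 5, 4)), "non-decreasing")
  expect_silent(new_crosswalk(0:2, c(0, 2, 2)))
})

test_that("crosswalk CSV round-trips", {
  xw <- hads_bdi_crosswalk()
  path <- withr::local_tempfile(fileext = ".csv")
  write_crosswalk(xw, path)
  xw2 <- read_crosswalk(path)
  expect_equal(xw2$source_score, xw$source_score)
  expect_equal(xw2$equated_score, xw$equated_score)
})
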