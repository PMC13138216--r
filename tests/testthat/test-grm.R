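test_that("item response simulation follows the graded response model", {
  items <- grm_parameters("it", 1, list(0))
  x <- generate_item_responses(rep(0, 20000), items, seed = 1)
  expect_true(abs(mean(x) - 0.5) < 0.01)          # P(X=1)=0.5 at theta=b
  x_hi <- generate_item_responses(rep(50, 500),
                                  grm_parameters("it", 1.2, list(c(-1, 0, 1))),
                                  seed = 2)
  expect_true(all(x_hi == 3))                     # theta -> +inf: top category
  expect_error(generate_item_responses(c(0, Inf), items, 1), "non-finite")
})

test_that("empirical cumulative frequencies match the closed form", {
  items <- grm_parameters(c("a", "b"), c(1.4, 0.8),
                          list(c(-0.5, 0.4, 1.2), c(-1, 0, 1, 2)))
  theta <- rep(0.7, 50000)
  x <- generate_item_responses(theta, items, seed = 7)
  for (j in 1:2) {
    b <- items$thresholds[[j]]
    for (k in seq_along(b)) {
      emp <- mean(x[, j] >= k)
      expect_lt(abs(emp - plogis(items$a[j] * (0.7 - b[k]))), 0.01)
    }
  }
})

test_that("GRM estimation is permutation-equivariant and monotone in loglik", {
  items <- grm_parameters(c("i1", "i2", "i3"), c(1.2, 0.9, 1.5),
                          list(c(-1, 0, 1), c(-0.5, 0.5), c(0, 1)))
  theta <- withr::with_seed(5, rnorm(1500))
  x <- generate_item_responses(theta, items, seed = 6)
  f1 <- fit_grm(x)
  expect_true(!is.unsorted(attr(f1, "loglik_trace")))
  f2 <- fit_grm(x[, c(3, 1, 2)])
  expect_equal(f2$a[match(f1$item, f2$item)], f1$a, tolerance = 1e-6)
})

test_that("standard errors shrink roughly as 1/sqrt(n)", {
  items <- grm_parameters(c("i1", "i2", "i3"), c(1.2, 1.0, 0.8),
                          list(c(-1, 0.2), c(-0.4, 0.8), c(0, 1.1)))
  th <- withr::with_seed(11, rnorm(6000))
  x <- generate_item_responses(th, items, seed = 12)
  f_small <- fit_grm(x[1:3000, ], se = TRUE)
  f_big <- fit_grm(x, se = TRUE)
  ratio <- attr(f_big, "se")$se / attr(f_small, "se")$se
  expect_true(mean(ratio) > 0.6 && mean(ratio) < 0.8)  # ~ 1/sqrt(2)
})

test_that("degenerate items are rejected", {
  x <- cbind(i1 = rep(1L, 100), i2 = rep(0:1, 50))
  expect_error(fit_grm(x), "degenerate")
})
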