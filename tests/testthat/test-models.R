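make_multinomial_data <- function(n, seed, b_acute = c(0.8, 0.5),
                                  b_pers = c(0.8, 1.0),
                                  ia = -0.8, ip = -1.2) {
  withr::with_seed(seed, {
    d <- tibble::tibble(x1 = rnorm(n), x2 = as.numeric(runif(n) < 0.5),
                        study_id = sample(c("a", "b"), n, TRUE))
    ea <- ia + b_acute[1] * d$x1 + b_acute[2] * d$x2
    ep <- ip + b_pers[1] * d$x1 + b_pers[2] * d$x2
    pr <- cbind(1, exp(ea), exp(ep))
    pr <- pr / rowSums(pr)
    d$y <- apply(pr, 1, function(p)
      sample(c("Never", "Acute", "Persistent"), 1, prob = p))
    d
  })
}

test_that("intercept-only multinomial reproduces sample frequencies", {
  d <- make_multinomial_data(500, 1)
  fit <- fit_multinomial(d, "y", predictors = character(0),
                         ref = "Never", study_dummies = FALSE)
  freq <- table(d$y)[c("Never", "Acute", "Persistent")] / nrow(d)
  expect_equal(unname(fit$coefficients[, "(Intercept)"]),
               as.numeric(log(freq[-1] / freq[1])), tolerance = 1e-6)
})

test_that("multinomial likelihood matches a direct-optimizer oracle", {
  d <- make_multinomial_data(30, 2, b_acute = c(0.5, 0.3),
                             b_pers = c(0.4, 0.2), ia = -0.5, ip = -0.8)
  fit <- fit_multinomial(d, "y", c("x1", "x2"), ref = "Never",
                         study_dummies = FALSE)
  # independent oracle: optimize the multinomial log-likelihood written
  # from scratch with a general-purpose optimizer
  X <- cbind(1, d$x1, d$x2)
  yi <- match(d$y, c("Never", "Acute", "Persistent"))
  nll <- function(par) {
    b <- matrix(par, nrow = 2, byrow = TRUE)
    eta <- X %*% t(b)
    den <- 1 + rowSums(exp(eta))
    -sum(ifelse(yi > 1, eta[cbind(seq_along(yi), pmax(yi - 1, 1))], 0)) +
      sum(log(den))
  }
  o <- optim(rep(0, 6), nll, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(fit$logLik, -o$value, tolerance = 1e-6)
})

test_that("two-category multinomial reduces to binary logistic", {
  d <- make_multinomial_data(400, 3)
  d <- d[d$y != "Persistent", ]
  fit <- fit_multinomial(d, "y", c("x1", "x2"), ref = "Never")
  g <- glm(I(y == "Acute") ~ x1 + x2 + study_id, binomial(), data = d)
  expect_lt(max(abs(fit$coefficients - coef(g))), 1e-6)
})

test_that("constrained LRT statistic is non-negative and invariant to rescaling", {
  for (s in 1:25) {
    d <- make_multinomial_data(150, 100 + s)
    r <- constrained_lrt(d, "y", c("x1", "x2"), "x1", ref = "Never",
                         study_dummies = FALSE)
    expect_gte(r$statistic, 0)
  }
  d <- make_multinomial_data(600, 4)
  r1 <- constrained_lrt(d, "y", c("x1", "x2"), "x1", ref = "Never",
                        study_dummies = FALSE)
  d2 <- dplyr::mutate(d, x2 = 10 * x2 + 3)   # affine rescale of the OTHER covariate
  r2 <- constrained_lrt(d2, "y", c("x1", "x2"), "x1", ref = "Never",
                        study_dummies = FALSE)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-6)
})

test_that("constrained LRT has power against unequal effects", {
  d <- make_multinomial_data(4000, 5, b_acute = c(0, 0.4),
                             b_pers = c(log(2), 0.4))
  r <- constrained_lrt(d, "y", c("x1", "x2"), "x1", ref = "Never",
                       study_dummies = FALSE)
  expect_lt(r$p.value, 0.05)
})

test_that("persistence odds-ratio scaling arithmetic", {
  # per-5-point OR = exp(5 * beta): beta = 0.0314 -> 1.17
  expect_equal(round(exp(5 * 0.0314), 2), 1.17)
  # a zero coefficient gives OR 1 at any increment
  expect_equal(exp(15 * 0), 1)
})

test_that("persistence models return the documented schema and pool", {
  coh <- generate_cohort(small_configs(250),
                         generative_params(trajectory_model = "severity"),
                         seed = 41)
  cl <- classify_cohort(coh)
  ors <- fit_persistence_logistic(cl, "ptsd", models = 1:3)
  expect_s3_class(ors, "or_table")
  expect_setequal(unique(ors$model), 1:3)
  expect_true(all(c("term", "or", "conf.low", "conf.high", "increment",
                    "p.value") %in% names(ors)))
  expect_true(all(ors$conf.low <= ors$or & ors$or <= ors$conf.high))
  expect_equal(unique(ors$increment[ors$term == "ptsd_sev15"]), 15)
  expect_equal(unique(ors$increment[ors$term == "dep_sev5"]), 5)
  m1 <- ors[ors$model == 2, ]
  expect_true(all(c("dep_sev5", "ptsd_sev15") %in% m1$term))
})

test_that("null predictors are covered by pooled CIs at the nominal rate", {
  cover <- vapply(1:30, function(s) {
    d <- make_multinomial_data(500, 500 + s, b_acute = c(0.6, 0),
                               b_pers = c(0.6, 0))
    fit <- fit_multinomial(d, "y", c("x1", "x2"), ref = "Never",
                           study_dummies = FALSE)
    td <- tidy(fit)
    row <- td[td$term == "x2" & td$y.level == "Acute", ]
    row$conf.low <= 0 && 0 <= row$conf.high
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})

test_that("group descriptives report the documented denominators", {
  d <- descriptive_fixture("ptsd")
  tab <- describe_groups(d, "ptsd")
  pick <- function(v, l, g, col) {
    r <- tab[tab$variable == v & tab$group == g &
               (is.na(l) | tab$level %in% l), ]
    r[[col]][1]
  }
  expect_equal(pick("female", "yes", "Acute", "pct"), 100 * 136 / 267)
  expect_equal(pick("N", NA, "Missing", "pct"), 100 * 803 / 2571)
  expect_equal(pick("index_trauma", "assault", "Persistent", "pct"),
               100 * 20 / 137)
  # chi-square of a perfectly balanced 2x2 is zero
  bal <- tibble::tibble(
    ptsd_trajectory = factor(rep(c("Never", "Acute"), each = 20),
                             traumameta::trajectory_levels()),
    female = rep(c(TRUE, FALSE), 20),
    age = 40)
  tb <- describe_groups(bal, "ptsd", variables = "female")
  expect_equal(unique(na.omit(tb$statistic[tb$variable == "female"])), 0)
})
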