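#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang abort warn %||% .data :=
#' @importFrom stats plogis qlogis qnorm pnorm dnorm rnorm runif rbinom
#'   sd var cor coef vcov complete.cases model.matrix optim optimize uniroot
#'   quantile setNames aggregate pchisq pf pt qt binomial chisq.test glm
#'   oneway.test predict na.omit glm.fit rchisq as.formula
#' @importFrom utils head adist
NULL

# run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_input <- function(msg, ...) {
  abort(paste0(sprintf(msg, ...)), class = "traumameta_error")
}

check_range <- function(x, lo, hi, what) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad) > 0) {
    stop_input("%s outside [%s, %s] at position(s) %s", what, lo, hi,
               paste(head(bad, 5), collapse = ", "))
  }
  invisible(x)
}

# draws from N(mean, sd) truncated to [lo, hi], via inverse-CDF
rtruncnorm <- function(n, mean = 0, sd = 1, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  u <- runif(n, plo, phi)
  q <- qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
  pmin(pmax(q, lo), hi)
}

round_half_up <- function(x) floor(x + 0.5)

# deterministic per-stage seed derivation; stays below 2^31
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483629L)
}
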