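## Polychoric correlations (two-step ML under the discretized bivariate
## normal) and unweighted-least-squares ordinal confirmatory factor
## analysis with CFI / TLI / RMSEA fit indices.

#' Polychoric correlation between two ordinal variables
#'
#' Two-step maximum likelihood under the discretized bivariate-normal
#' model: thresholds from the marginal cumulative proportions, then the
#' latent correlation maximizing the contingency-table likelihood.
#'
#' @param x,y Integer/ordinal vectors of equal length; pairs with missing
#'   values are dropped. Each must retain at least two observed
#'   categories and 20 complete pairs.
#'
#' @return Correlation estimate in (-1, 1).
#' @export
polychoric_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- as.integer(factor(x[ok]))
  y <- as.integer(factor(y[ok]))
  if (length(x) < 20) stop_input("fewer than 20 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop_input("a variable is constant after listwise deletion; correlation undefined")
  }
  tab <- table(x, y)
  tx <- qnorm(cumsum(rowSums(tab)) / sum(tab))
  ty <- qnorm(cumsum(colSums(tab)) / sum(tab))
  cx <- c(-Inf, tx[-length(tx)], Inf)
  cy <- c(-Inf, ty[-length(ty)], Inf)

  loglik <- function(rho) {
    # bivariate normal CDF on the threshold grid, then cell probs by
    # second differences
    Phi2 <- matrix(0, length(cx), length(cy))
    for (i in seq_along(cx)) {
      for (j in seq_along(cy)) {
        Phi2[i, j] <- if (!is.finite(cx[i]) && cx[i] < 0 ||
                          !is.finite(cy[j]) && cy[j] < 0) {
          0
        } else if (!is.finite(cx[i]) && !is.finite(cy[j])) {
          1
        } else if (!is.finite(cx[i])) {
          pnorm(cy[j])
        } else if (!is.finite(cy[j])) {
          pnorm(cx[i])
        } else {
          mvtnorm::pmvnorm(upper = c(cx[i], cy[j]),
                           corr = matrix(c(1, rho, rho, 1), 2))[1]
        }
      }
    }
    p <- Phi2[-1, -1] - Phi2[-nrow(Phi2), -1] -
      Phi2[-1, -ncol(Phi2)] + Phi2[-nrow(Phi2), -ncol(Phi2)]
    sum(tab * log(pmax(p, 1e-12)))
  }
  optimize(loglik, c(-0.999, 0.999), maximum = TRUE, tol = 1e-5)$maximum
}

#' Polychoric correlation matrix of an ordinal data frame
#'
#' @param data Data frame / matrix of ordinal variables.
#' @return Symmetric correlation matrix.
#' @export
polychoric_matrix <- function(data) {
  data <- as.data.frame(data)
  p <- ncol(data)
  r <- diag(p)
  dimnames(r) <- list(names(data), names(data))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      r[i, j] <- r[j, i] <- polychoric_correlation(data[[i]], data[[j]])
    }
  }
  r
}

#' Fit a confirmatory factor model to a correlation matrix by ULS
#'
#' Unweighted least squares on the off-diagonal correlations: loadings
#' (and, for multi-factor patterns, factor correlations) minimize the sum
#' of squared residuals. The model chi-square is the minimized
#' discrepancy scaled by `n - 1`; the baseline model is independence
#' (all off-diagonal correlations zero). Fit indices follow the standard
#' definitions:
#' `CFI = 1 - max(X2_M - df_M, 0) / max(X2_0 - df_0, X2_M - df_M, 0)`,
#' `TLI = ((X2_0/df_0) - (X2_M/df_M)) / ((X2_0/df_0) - 1)`,
#' `RMSEA = sqrt(max(X2_M - df_M, 0) / (df_M * (n - 1)))`.
#'
#' @param corr Symmetric correlation matrix (ridge-repaired if not
#'   positive semi-definite).
#' @param n Sample size behind `corr`.
#' @param pattern Logical/0-1 matrix, items by factors, marking free
#'   loadings; every item must load on at least one factor. A single
#'   column gives the one-factor model.
#'
#' @return List of class `factor_fit`: `loadings`, `factor_cor`,
#'   `chisq`, `df`, `baseline_chisq`, `baseline_df`, `cfi`, `tli`,
#'   `rmsea`, `n`, `converged`.
#' @export
fit_factor_model <- function(corr, n, pattern) {
  corr <- as.matrix(corr)
  pattern <- as.matrix(pattern) > 0
  p <- nrow(corr)
  f <- ncol(pattern)
  if (any(rowSums(pattern) == 0)) stop_input("every item must load on >= 1 factor")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    ridge <- abs(min(ev)) + 1e-6
    corr <- (corr + ridge * diag(p)) / (1 + ridge)
  }
  free <- which(pattern)
  n_phi <- f * (f - 1) / 2
  n_free <- length(free) + n_phi
  pairs <- which(upper.tri(corr))
  df0 <- p * (p - 1) / 2
  dfm <- df0 - n_free
  if (dfm < 0) stop_input("model has negative degrees of freedom")

  discrepancy <- function(par) {
    L <- matrix(0, p, f)
    L[free] <- par[seq_along(free)]
    Phi <- diag(f)
    if (n_phi > 0) {
      Phi[upper.tri(Phi)] <- tanh(par[length(free) + seq_len(n_phi)])
      Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
    }
    S <- L %*% Phi %*% t(L)
    sum((corr[pairs] - S[pairs])^2)
  }
  par0 <- c(rep(0.5, length(free)), rep(0, n_phi))
  fit <- optim(par0, discrepancy, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-12))
  if (dfm == 0 && fit$value > 1e-8) {
    # saturated patterns should reproduce corr exactly; polish
    fit <- optim(fit$par, discrepancy, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-14))
  }
  L <- matrix(0, p, f, dimnames = list(rownames(corr), colnames(pattern)))
  L[free] <- fit$par[seq_along(free)]
  Phi <- diag(f)
  if (n_phi > 0) {
    Phi[upper.tri(Phi)] <- tanh(fit$par[length(free) + seq_len(n_phi)])
    Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
  }
  chisq_m <- (n - 1) * fit$value
  chisq_0 <- (n - 1) * sum(corr[pairs]^2)
  num <- max(chisq_m - dfm, 0)
  den <- max(chisq_0 - df0, chisq_m - dfm, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (dfm == 0) 1 else {
    ratio0 <- chisq_0 / df0
    ((ratio0 - chisq_m / dfm) / (ratio0 - 1))
  }
  rmsea <- if (dfm == 0) 0 else sqrt(max(chisq_m - dfm, 0) / (dfm * (n - 1)))
  structure(list(loadings = L, factor_cor = Phi, chisq = chisq_m, df = dfm,
                 baseline_chisq = chisq_0, baseline_df = df0,
                 cfi = min(max(cfi, 0), 1), tli = min(max(tli, 0), 1),
                 rmsea = max(rmsea, 0), n = n,
                 converged = fit$convergence == 0),
            class = "factor_fit")
}

#' @export
glance.factor_fit <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, df = x$df, cfi = x$cfi, tli = x$tli,
                 rmsea = x$rmsea, n = x$n, converged = x$converged)
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf(
    "ULS ordinal CFA: chisq(%d) = %.2f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f (n = %d)\n",
    x$df, x$chisq, x$cfi, x$tli, x$rmsea, x$n))
  invisible(x)
}
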