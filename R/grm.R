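## Graded response model (GRM): containers, category probabilities,
## simulation, marginal-maximum-likelihood EM estimation, and standard
## errors from the empirical Fisher information.

#' Construct a set of graded-response-model item parameters
#'
#' @param item Character vector of item labels.
#' @param a Positive discriminations, one per item.
#' @param thresholds List of strictly increasing numeric threshold vectors
#'   (`b_1 < ... < b_K`); an item with K thresholds has categories
#'   `0..K`.
#' @param anchor Logical anchor-item flags (items shared between
#'   calibrations, used for linking).
#'
#' @return Tibble of class `grm_parameters` with columns `item`, `a`,
#'   `thresholds` (list column), `anchor`.
#' @export
grm_parameters <- function(item, a, thresholds, anchor = FALSE) {
  anchor <- rep_len(anchor, length(item))
  if (any(a <= 0)) {
    stop_input("non-positive discrimination for item(s): %s",
               paste(item[a <= 0], collapse = ", "))
  }
  ok <- vapply(thresholds, function(b) length(b) >= 1 && !is.unsorted(b, strictly = TRUE),
               logical(1))
  if (any(!ok)) {
    stop_input("thresholds not strictly increasing for item(s): %s",
               paste(item[!ok], collapse = ", "))
  }
  out <- tibble::tibble(item = as.character(item), a = as.numeric(a),
                        thresholds = thresholds, anchor = anchor)
  class(out) <- c("grm_parameters", class(out))
  out
}

#' @export
tidy.grm_parameters <- function(x, ...) {
  tidyr::unnest_longer(
    dplyr::mutate(tibble::as_tibble(x),
                  threshold = purrr::map(.data$thresholds, ~ seq_along(.x))),
    c("thresholds", "threshold")
  ) |>
    dplyr::select("item", "a", "anchor", k = "threshold", b = "thresholds")
}

# category probability matrix for one item: length(theta) x (K+1)
grm_item_prob <- function(theta, a, b) {
  cum <- vapply(b, function(bk) plogis(a * (theta - bk)), numeric(length(theta)))
  cum <- cbind(1, matrix(cum, nrow = length(theta)), 0)
  p <- cum[, 1:(length(b) + 1), drop = FALSE] - cum[, 2:(length(b) + 2), drop = FALSE]
  pmax(p, 1e-300)
}

#' Simulate ordinal item responses from a graded response model
#'
#' Categories follow the cumulative-logistic model
#' `P(X >= k | theta) = plogis(a * (theta - b_k))`.
#'
#' @param theta Numeric vector of latent-trait values (finite).
#' @param items [grm_parameters()] object.
#' @param seed Integer seed.
#'
#' @return Integer matrix, `length(theta)` rows by `nrow(items)` columns,
#'   entries in `0..K_item`, column names = item labels.
#' @export
generate_item_responses <- function(theta, items, seed) {
  if (any(!is.finite(theta))) stop_input("non-finite latent trait values")
  stopifnot(inherits(items, "grm_parameters"))
  with_seed(seed, {
    out <- matrix(0L, length(theta), nrow(items),
                  dimnames = list(NULL, items$item))
    for (j in seq_len(nrow(items))) {
      b <- items$thresholds[[j]]
      u <- runif(length(theta))
      x <- integer(length(theta))
      for (bk in b) x <- x + (u < plogis(items$a[j] * (theta - bk)))
      out[, j] <- x
    }
    out
  })
}

# expected score (test characteristic curve) for a set of items
test_characteristic_curve <- function(items, theta) {
  out <- numeric(length(theta))
  for (j in seq_len(nrow(items))) {
    for (bk in items$thresholds[[j]]) {
      out <- out + plogis(items$a[j] * (theta - bk))
    }
  }
  out
}

#' Fit a graded response model by marginal maximum likelihood
#'
#' EM with a fixed Gauss-Legendre-type quadrature grid on the standard
#' normal prior; the latent metric is identified as N(0, 1). Categories
#' never observed for an item are collapsed (with the mapping recorded in
#' the `collapsed` attribute). The marginal log-likelihood is
#' non-decreasing over EM iterations.
#'
#' @param responses Integer matrix (or data frame) of ordinal responses,
#'   one column per item, values in `0..K_item`. Rows with all-missing
#'   responses are dropped; partially missing rows contribute their
#'   observed items.
#' @param anchor Logical vector flagging anchor items (stored in the
#'   result).
#' @param n_quad Number of quadrature points on `[-6, 6]` (default 61).
#' @param tol Convergence tolerance on the maximum absolute parameter
#'   change (default 1e-4).
#' @param max_iter EM iteration cap (default 500).
#' @param se Compute standard errors from the empirical Fisher
#'   information (default `FALSE`).
#'
#' @return A `grm_parameters` tibble with attributes `logLik`, `n`,
#'   `iterations`, `converged`, and (if requested) `se` (tibble of
#'   per-parameter standard errors).
#' @export
fit_grm <- function(responses, anchor = FALSE, n_quad = 61, tol = 1e-4,
                    max_iter = 500, se = FALSE) {
  x <- as.matrix(responses)
  storage.mode(x) <- "integer"
  if (is.null(colnames(x))) colnames(x) <- paste0("item_", seq_len(ncol(x)))
  keep <- rowSums(!is.na(x)) > 0
  x <- x[keep, , drop = FALSE]
  n <- nrow(x)
  J <- ncol(x)
  anchor <- rep_len(anchor, J)

  # collapse unobserved categories to a contiguous 0..K coding
  collapsed <- list()
  for (j in seq_len(J)) {
    obs <- sort(unique(x[!is.na(x[, j]), j]))
    if (length(obs) < 2) {
      stop_input("item %s is degenerate: all observed responses identical",
                 colnames(x)[j])
    }
    if (!identical(obs, seq.int(0L, max(obs)))) {
      map <- match(x[, j], obs) - 1L
      collapsed[[colnames(x)[j]]] <- setNames(seq_along(obs) - 1L, obs)
      x[, j] <- map
    }
  }
  K <- apply(x, 2, max, na.rm = TRUE)  # number of thresholds per item

  nodes <- seq(-6, 6, length.out = n_quad)
  wts <- dnorm(nodes)
  wts <- wts / sum(wts)

  # initial values: a = 1, thresholds from marginal category proportions
  a <- rep(1, J)
  b <- lapply(seq_len(J), function(j) {
    xo <- x[!is.na(x[, j]), j]
    p <- cumsum(tabulate(xo + 1L, K[j] + 1L) / length(xo))
    qlogis(pmin(pmax(1 - p[seq_len(K[j])], 0.005), 0.995))
  })
  b <- lapply(b, function(v) sort(v) + cumsum(c(0, diff(sort(v)) == 0)) * 1e-3)

  item_loglik_tables <- function(a, b) {
    lapply(seq_len(J), function(j) log(grm_item_prob(nodes, a[j], b[[j]])))
  }

  # Q x n matrix of log P(x_i | theta_q)
  person_loglik <- function(ltab) {
    ll <- matrix(0, n_quad, n)
    for (j in seq_len(J)) {
      oj <- which(!is.na(x[, j]))
      ll[, oj] <- ll[, oj] + ltab[[j]][, x[oj, j] + 1L, drop = FALSE]
    }
    ll
  }

  marginal <- function(ll) {
    mx <- apply(ll, 2, max)
    lik_q <- exp(sweep(ll, 2, mx))      # Q x n
    marg <- colSums(lik_q * wts)
    list(loglik = sum(log(marg) + mx),
         post = sweep(lik_q * wts, 2, marg, "/"))  # Q x n posterior weights
  }

  # expected category counts r[q, k] for item j given posterior weights
  expected_counts <- function(post, j) {
    r <- matrix(0, n_quad, K[j] + 1L)
    oj <- which(!is.na(x[, j]))
    xs <- x[oj, j] + 1L
    for (k in seq_len(K[j] + 1L)) {
      idx <- oj[xs == k]
      if (length(idx) > 0) r[, k] <- rowSums(post[, idx, drop = FALSE])
    }
    r
  }

  mstep_item <- function(r, a0, b0) {
    par0 <- c(log(a0), b0[1], log(diff(b0) + 1e-9)[seq_len(length(b0) - 1)])
    if (length(b0) == 1) par0 <- c(log(a0), b0[1])
    unpack <- function(p) {
      aa <- exp(p[1])
      bb <- if (length(p) == 2) p[2] else cumsum(c(p[2], exp(p[-(1:2)])))
      list(a = aa, b = bb)
    }
    nll <- function(p) {
      u <- unpack(p)
      -sum(r * log(grm_item_prob(nodes, u$a, u$b)))
    }
    fit <- optim(par0, nll, method = "BFGS",
                 control = list(maxit = 50, reltol = 1e-10))
    unpack(fit$par)
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  ltab <- item_loglik_tables(a, b)
  for (iter in seq_len(max_iter)) {
    est <- marginal(person_loglik(ltab))
    ll_trace <- c(ll_trace, est$loglik)
    max_delta <- 0
    for (j in seq_len(J)) {
      r <- expected_counts(est$post, j)
      upd <- mstep_item(r, a[j], b[[j]])
      max_delta <- max(max_delta, abs(upd$a - a[j]), abs(upd$b - b[[j]]))
      a[j] <- upd$a
      b[[j]] <- upd$b
    }
    ltab <- item_loglik_tables(a, b)
    if (max_delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("GRM EM reached %d iterations without convergence", max_iter))
  }
  final <- marginal(person_loglik(ltab))

  out <- grm_parameters(colnames(x), a, b, anchor = anchor)
  attr(out, "logLik") <- final$loglik
  attr(out, "n") <- n
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  attr(out, "loglik_trace") <- ll_trace
  if (length(collapsed) > 0) attr(out, "collapsed") <- collapsed
  if (se) attr(out, "se") <- grm_se(x, out, nodes, wts, final$post)
  out
}

#' @export
glance.grm_parameters <- function(x, ...) {
  tibble::tibble(logLik = attr(x, "logLik"), n = attr(x, "n"),
                 n_items = nrow(x), iterations = attr(x, "iterations"),
                 converged = attr(x, "converged"))
}

# empirical-Fisher standard errors: per-person marginal score vectors
# computed analytically through the quadrature posterior
grm_se <- function(x, pars, nodes, wts, post) {
  n <- nrow(x)
  J <- nrow(pars)
  labels <- unlist(lapply(seq_len(J), function(j) {
    c(sprintf("%s.a", pars$item[j]),
      sprintf("%s.b%d", pars$item[j], seq_along(pars$thresholds[[j]])))
  }))
  scores <- matrix(0, n, length(labels))
  col0 <- 0
  for (j in seq_len(J)) {
    a <- pars$a[j]
    b <- pars$thresholds[[j]]
    K <- length(b)
    p <- grm_item_prob(nodes, a, b)                    # Q x (K+1)
    cum <- cbind(1, vapply(b, function(bk) plogis(a * (nodes - bk)),
                           numeric(length(nodes))), 0) # Q x (K+2)
    dens <- cum * (1 - cum)                            # logistic density term
    # d P(X=k) / da and / d b_m
    dPda <- matrix(0, length(nodes), K + 1)
    dPdb <- array(0, c(length(nodes), K + 1, K))
    for (k in 0:K) {
      kk <- k + 1
      if (k >= 1) {
        dPda[, kk] <- dPda[, kk] + (nodes - b[k]) * dens[, k + 1]
        dPdb[, kk, k] <- dPdb[, kk, k] - a * dens[, k + 1]
      }
      if (k < K) {
        dPda[, kk] <- dPda[, kk] - (nodes - b[k + 1]) * dens[, k + 2]
        dPdb[, kk, k + 1] <- dPdb[, kk, k + 1] + a * dens[, k + 2]
      }
    }
    oj <- which(!is.na(x[, j]))
    xk <- x[oj, j] + 1L
    # score_i(param) = sum_q post_iq * dlogP(x_ij | theta_q)/dparam
    dlogda <- dPda / p
    sa <- dlogda[, xk, drop = FALSE]                 # Q x n_obs
    scores[oj, col0 + 1] <- colSums(post[, oj, drop = FALSE] * sa)
    for (m in seq_len(K)) {
      sb <- (dPdb[, , m] / p)[, xk, drop = FALSE]
      scores[oj, col0 + 1 + m] <- colSums(post[, oj, drop = FALSE] * sb)
    }
    col0 <- col0 + 1 + K
  }
  info <- crossprod(scores)
  v <- tryCatch(diag(solve(info)), error = function(e) rep(NA_real_, ncol(info)))
  tibble::tibble(parameter = labels, se = sqrt(pmax(v, 0)))
}
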