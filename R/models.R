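## Risk-factor models: multinomial logistic regression (Newton-Raphson,
## with optional equality constraints across outcome categories),
## constrained-vs-unconstrained likelihood-ratio tests (D2-pooled over
## imputations), persistence logistic models 1-3 with scaled odds
## ratios, and the descriptive group-comparison table.

RISK_FACTORS <- c("age", "female", "single", "low_education", "prior_trauma",
                  "index_trauma")

# design matrix (with intercept) from a data frame of predictors
build_design <- function(data, predictors, study_dummies = TRUE,
                         study_col = "study_id") {
  cols <- predictors
  if (study_dummies && length(unique(data[[study_col]])) > 1) {
    cols <- c(cols, study_col)
  }
  if (length(cols) == 0) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- data[, cols, drop = FALSE]
  df[] <- lapply(df, function(v) if (is.character(v)) factor(v) else v)
  X <- model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_input("design not full rank; drop: %s", paste(bad, collapse = ", "))
  }
  X
}

#' Fit a multinomial logistic regression by maximum likelihood
#'
#' Newton-Raphson on the full multinomial log-likelihood with the first
#' outcome level as reference. Coefficients for selected predictors can
#' be constrained equal across the non-reference outcome categories
#' (shared-parameter likelihood, used by the constrained likelihood-ratio
#' test). Separation (any standardized coefficient beyond 15) triggers a
#' warning and a ridge-stabilized refit flagged in the result.
#'
#' @param data Data frame.
#' @param outcome Name of the outcome column (factor/character); the
#'   reference category is `ref`.
#' @param predictors Character vector of predictor columns (factors are
#'   expanded to dummies).
#' @param ref Reference outcome level (default the first observed).
#' @param constrain Character vector of design-column names (or predictor
#'   names, matching all their dummies) whose coefficients are forced
#'   equal across outcome categories.
#' @param study_dummies Include fixed study dummies (default TRUE when a
#'   `study_id` column with >1 level is present).
#' @param study_col Study identifier column.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Newton iteration cap.
#'
#' @return Object of class `mnfit`: coefficient matrix (categories x
#'   design columns), `vcov` of the free parameters mapped to the full
#'   parameterization, `logLik`, `n`, `levels`, `converged`, `ridged`.
#' @export
fit_multinomial <- function(data, outcome, predictors, ref = NULL,
                            constrain = NULL, study_dummies = TRUE,
                            study_col = "study_id", tol = 1e-8,
                            max_iter = 100) {
  y <- factor(data[[outcome]])
  y <- droplevels(y)
  if (!is.null(ref)) y <- stats::relevel(y, ref = ref)
  C <- nlevels(y)
  if (C < 2) stop_input("outcome must have >= 2 observed categories")
  X <- build_design(data, predictors, study_dummies, study_col)
  n <- nrow(X)
  p <- ncol(X)
  yi <- as.integer(y)           # 1 = reference
  K <- C - 1                    # non-reference categories

  # parameter map: full vector (K*p) = M %*% free; equality constraints
  # tie a design column's K coefficients to one shared parameter
  con_cols <- integer(0)
  if (!is.null(constrain)) {
    for (cn in constrain) {
      hits <- which(colnames(X) == cn)
      if (length(hits) == 0) {
        # treat as a predictor name: match its expanded dummies
        hits <- grep(paste0("^", cn), colnames(X))
        hits <- setdiff(hits, 1L)
      }
      if (length(hits) == 0) stop_input("constraint column not found: %s", cn)
      con_cols <- union(con_cols, hits)
    }
  }
  full_index <- function(k, j) (k - 1) * p + j    # category k, column j
  n_full <- K * p
  M <- matrix(0, n_full, 0)
  for (j in seq_len(p)) {
    if (j %in% con_cols) {
      col <- numeric(n_full)
      for (k in seq_len(K)) col[full_index(k, j)] <- 1
      M <- cbind(M, col)
    } else {
      for (k in seq_len(K)) {
        col <- numeric(n_full)
        col[full_index(k, j)] <- 1
        M <- cbind(M, col)
      }
    }
  }

  loglik_grad_hess <- function(theta_free, ridge = 0) {
    beta <- matrix(M %*% theta_free, nrow = K, byrow = TRUE)  # K x p
    eta <- X %*% t(beta)                                       # n x K
    denom <- 1 + rowSums(exp(eta))
    P <- exp(eta) / denom                                      # n x K
    ll <- sum(ifelse(yi > 1, eta[cbind(seq_len(n), pmax(yi - 1, 1))], 0)) -
      sum(log(denom))
    Yk <- matrix(0, n, K)
    Yk[cbind(seq_len(n), yi - 1)[yi > 1, , drop = FALSE]] <- 1
    G_full <- numeric(n_full)
    for (k in seq_len(K)) {
      G_full[((k - 1) * p + 1):(k * p)] <- crossprod(X, Yk[, k] - P[, k])
    }
    H_full <- matrix(0, n_full, n_full)
    for (k in seq_len(K)) {
      for (l in k:K) {
        W <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
        blk <- -crossprod(X, X * W)
        H_full[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <- blk
        if (l != k) {
          H_full[((l - 1) * p + 1):(l * p), ((k - 1) * p + 1):(k * p)] <- t(blk)
        }
      }
    }
    g <- drop(crossprod(M, G_full))
    H <- crossprod(M, H_full %*% M)
    if (ridge > 0) {
      ll <- ll - ridge * sum(theta_free^2) / 2
      g <- g - ridge * theta_free
      H <- H - ridge * diag(ncol(M))
    }
    list(ll = ll, g = g, H = H)
  }

  newton <- function(ridge = 0) {
    theta <- numeric(ncol(M))
    state <- loglik_grad_hess(theta, ridge)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      step <- tryCatch(solve(state$H - 1e-10 * diag(ncol(M)), state$g),
                       error = function(e) NULL)
      if (is.null(step)) step <- state$g / (max(abs(diag(state$H))) + 1)
      alpha <- 1
      repeat {
        cand <- theta - alpha * step
        new_state <- loglik_grad_hess(cand, ridge)
        if (new_state$ll >= state$ll - 1e-12 || alpha < 1e-6) break
        alpha <- alpha / 2
      }
      theta <- cand
      state <- new_state
      if (max(abs(state$g)) < tol) {
        converged <- TRUE
        break
      }
    }
    list(theta = theta, state = state, converged = converged)
  }

  fit <- newton()
  sds <- apply(X, 2, sd)
  sds[sds == 0] <- 1
  beta_full <- matrix(M %*% fit$theta, nrow = K, byrow = TRUE)
  ridged <- FALSE
  if (any(abs(sweep(beta_full, 2, sds, "*")) > 15)) {
    warn("possible separation: refitting with a small ridge penalty")
    fit <- newton(ridge = 1e-3)
    beta_full <- matrix(M %*% fit$theta, nrow = K, byrow = TRUE)
    ridged <- TRUE
  }
  V_free <- tryCatch(solve(-fit$state$H), error = function(e) {
    matrix(NA_real_, ncol(M), ncol(M))
  })
  V_full <- M %*% V_free %*% t(M)
  dimnames(beta_full) <- list(levels(y)[-1], colnames(X))
  full_names <- as.vector(t(outer(levels(y)[-1], colnames(X), paste, sep = ":")))
  dimnames(V_full) <- list(full_names, full_names)
  structure(list(coefficients = beta_full, vcov = V_full,
                 logLik = fit$state$ll + if (ridged)
                   1e-3 * sum(fit$theta^2) / 2 else 0,
                 n = n, levels = levels(y), converged = fit$converged,
                 ridged = ridged, constrained = colnames(X)[con_cols],
                 design_cols = colnames(X)),
            class = "mnfit")
}

#' @export
tidy.mnfit <- function(x, exponentiate = FALSE, conf_level = 0.95, ...) {
  K <- nrow(x$coefficients)
  out <- purrr::map_dfr(seq_len(K), function(k) {
    est <- x$coefficients[k, ]
    se <- sqrt(pmax(diag(x$vcov)[((k - 1) * ncol(x$coefficients) + 1):
                                   (k * ncol(x$coefficients))], 0))
    tibble::tibble(y.level = rownames(x$coefficients)[k],
                   term = colnames(x$coefficients),
                   estimate = est, std.error = se,
                   statistic = est / se,
                   p.value = 2 * pnorm(-abs(est / se)))
  })
  q <- qnorm(1 - (1 - conf_level) / 2)
  out <- dplyr::mutate(out, conf.low = .data$estimate - q * .data$std.error,
                       conf.high = .data$estimate + q * .data$std.error)
  if (exponentiate) {
    out <- dplyr::mutate(out, dplyr::across(c("estimate", "conf.low",
                                              "conf.high"), exp))
  }
  out
}

#' @export
glance.mnfit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, n = x$n,
                 n_categories = length(x$levels),
                 converged = x$converged, ridged = x$ridged)
}

#' @export
print.mnfit <- function(x, ...) {
  cat(sprintf("multinomial fit: %s vs %s (ref); logLik = %.2f, n = %d\n",
              paste(x$levels[-1], collapse = "/"), x$levels[1], x$logLik, x$n))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Likelihood-ratio test of equal effects across outcome categories
#'
#' Refits the multinomial model constraining the named predictor's
#' coefficient(s) to be equal for the acute and persistent equations and
#' compares constrained vs unconstrained fits:
#' `statistic = 2 * (logLik_u - logLik_c)` with degrees of freedom equal
#' to the number of tied design columns.
#'
#' @inheritParams fit_multinomial
#' @param predictor Predictor (or design-column) whose effects are tested
#'   for equality across outcomes.
#'
#' @return Object of class `lrt_result` (a one-row tibble): `statistic`,
#'   `df`, `p.value`, `logLik_u`, `logLik_c`, `pooled`.
#' @export
constrained_lrt <- function(data, outcome, predictors, predictor, ref = NULL,
                            study_dummies = TRUE, study_col = "study_id") {
  fu <- fit_multinomial(data, outcome, predictors, ref = ref,
                        study_dummies = study_dummies, study_col = study_col)
  fc <- fit_multinomial(data, outcome, predictors, ref = ref,
                        constrain = predictor,
                        study_dummies = study_dummies, study_col = study_col)
  k <- length(fc$constrained) * (length(fu$levels) - 2)
  if (k == 0) stop_input("predictor %s yields no constraints", predictor)
  stat <- max(2 * (fu$logLik - fc$logLik), 0)
  out <- tibble::tibble(predictor = predictor, statistic = stat, df = k,
                        p.value = pchisq(stat, k, lower.tail = FALSE),
                        logLik_u = fu$logLik, logLik_c = fc$logLik,
                        pooled = FALSE)
  class(out) <- c("lrt_result", class(out))
  out
}

#' @export
tidy.lrt_result <- function(x, ...) tibble::as_tibble(x)

#' Constrained LRTs pooled across imputed datasets (D2 rule)
#'
#' @param imputed [impute_cohort()] / [run_mice()] result whose completed
#'   tables carry the outcome column.
#' @inheritParams constrained_lrt
#' @return `lrt_result` tibble with one row per tested predictor.
#' @export
mi_constrained_lrt <- function(imputed, outcome, predictors,
                               test_predictors = predictors, ref = "Never",
                               study_col = "study_id") {
  rows <- purrr::map_dfr(test_predictors, function(pr) {
    per <- purrr::map_dfr(imputed$imputations, function(d) {
      d <- droplevels(dplyr::filter(
        d, .data[[outcome]] %in% c("Never", "Acute", "Persistent")))
      constrained_lrt(d, outcome, predictors, pr, ref = ref,
                      study_col = study_col)
    })
    pooled <- pool_lrt_d2(per$statistic, per$df[1])
    tibble::tibble(predictor = pr, statistic = pooled$statistic,
                   df = per$df[1], p.value = pooled$p.value,
                   logLik_u = mean(per$logLik_u),
                   logLik_c = mean(per$logLik_c), pooled = TRUE)
  })
  class(rows) <- c("lrt_result", class(rows))
  rows
}

# pool tidy per-imputation coefficient tables into an OR table
pool_or_table <- function(tidies, increments, conf_level = 0.95) {
  grp_cols <- intersect(c("y.level", "term"), names(tidies[[1]]))
  all_terms <- dplyr::distinct(tidies[[1]][, grp_cols])
  purrr::pmap_dfr(all_terms, function(...) {
    key <- list(...)
    ests <- vapply(tidies, function(td) {
      r <- td
      for (g in names(key)) r <- r[r[[g]] == key[[g]], ]
      r$estimate[1]
    }, numeric(1))
    vars <- vapply(tidies, function(td) {
      r <- td
      for (g in names(key)) r <- r[r[[g]] == key[[g]], ]
      r$std.error[1]^2
    }, numeric(1))
    inc <- increments[key$term] %||% 1
    if (is.na(inc)) inc <- 1
    if (length(ests) >= 2) {
      pl <- rubin_pool(ests, vars, conf_level = conf_level)
      est <- pl$estimate; lo <- pl$lo; hi <- pl$hi
      se <- sqrt(pl$t); df <- pl$df
    } else {
      est <- ests[1]
      se <- sqrt(vars[1]); df <- Inf
      q <- qnorm(1 - (1 - conf_level) / 2)
      lo <- est - q * se; hi <- est + q * se
    }
    tibble::tibble(!!!key, increment = inc,
                   log_or = est * inc, std.error = se * inc,
                   or = exp(est * inc), conf.low = exp(lo * inc),
                   conf.high = exp(hi * inc),
                   p.value = if (is.finite(df))
                     2 * pt(-abs(est / se), df) else 2 * pnorm(-abs(est / se)),
                   m = length(ests))
  })
}

#' Multinomial risk-factor model, Rubin-pooled over imputations
#'
#' Fits the never/acute/persistent multinomial model with all seven
#' baseline risk factors (plus study dummies) on each completed dataset
#' and pools coefficients on the log-odds scale by Rubin's rules.
#'
#' @param imputed [impute_cohort()] result, or a single classified table.
#' @param disorder `"ptsd"` or `"mdd"`.
#' @param conf_level Confidence level for the Wald intervals.
#'
#' @return Tibble of class `or_table`: `y.level` (Acute/Persistent),
#'   `term`, `or`, `conf.low`, `conf.high`, `p.value`.
#' @export
fit_risk_multinomial <- function(imputed, disorder = c("ptsd", "mdd"),
                                 conf_level = 0.95) {
  disorder <- match.arg(disorder)
  outcome <- paste0(disorder, "_trajectory")
  tables <- if (inherits(imputed, "imputed_datasets")) imputed$imputations
  else list(imputed)
  tidies <- lapply(tables, function(d) {
    d <- droplevels(dplyr::filter(
      d, .data[[outcome]] %in% c("Never", "Acute", "Persistent")))
    d[[outcome]] <- factor(as.character(d[[outcome]]),
                           levels = c("Never", "Acute", "Persistent"))
    fit <- fit_multinomial(d, outcome, RISK_FACTORS, ref = "Never")
    tidy(fit)
  })
  out <- pool_or_table(tidies, increments = c(), conf_level = conf_level)
  out <- dplyr::filter(out, .data$term != "(Intercept)",
                       !grepl("^study_id", .data$term))
  attr(out, "disorder") <- disorder
  attr(out, "model") <- "multinomial"
  class(out) <- c("or_table", class(out))
  out
}

# model specifications for the persistence logistic models
persistence_terms <- function(disorder, model) {
  own5 <- "dep_sev5"; p15 <- "ptsd_sev15"
  clusters <- c("reexp5", "avoid5", "hyper5")
  if (disorder == "ptsd") {
    switch(model,
           `1` = c(RISK_FACTORS, own5),
           `2` = c(RISK_FACTORS, own5, p15),
           `3` = c(RISK_FACTORS, own5, clusters))
  } else {
    switch(model,
           `1` = c(RISK_FACTORS, p15),
           `2` = c(RISK_FACTORS, p15, own5),
           `3` = c(RISK_FACTORS, own5, clusters))
  }
}

#' Persistence logistic models (Models 1-3) with scaled odds ratios
#'
#' Among participants with an acute (reference) or persistent diagnosis
#' of the disorder, logistic regressions predict persistence from the
#' baseline risk factors and acute symptom severities: Model 1 adds the
#' other disorder's acute severity, Model 2 the acute severities of both
#' disorders, Model 3 the acute depression severity plus the
#' reexperiencing / avoidance / hyperarousal cluster severities. Odds
#' ratios are expressed per 5 points of depression or cluster severity
#' and per 15 points of total PTSD severity. Coefficients are estimated
#' per completed dataset and Rubin-pooled on the log-odds scale; a
#' completed dataset lacking either outcome class is excluded from
#' pooling with a logged count.
#'
#' @param imputed [impute_cohort()] result or single classified table.
#' @param disorder `"ptsd"` or `"mdd"`.
#' @param models Integer subset of 1:3.
#' @param conf_level Confidence level.
#'
#' @return `or_table` tibble with a `model` column; attribute
#'   `"excluded"` counts completed datasets skipped per model.
#' @export
fit_persistence_logistic <- function(imputed, disorder = c("ptsd", "mdd"),
                                     models = 1:3, conf_level = 0.95) {
  disorder <- match.arg(disorder)
  outcome <- paste0(disorder, "_trajectory")
  tables <- if (inherits(imputed, "imputed_datasets")) imputed$imputations
  else list(imputed)
  increments <- c(dep_sev5 = 5, ptsd_sev15 = 15, reexp5 = 5, avoid5 = 5,
                  hyper5 = 5)
  excluded <- integer(0)
  out <- purrr::map_dfr(models, function(mdl) {
    tds <- list()
    skip <- 0
    for (d in tables) {
      d <- dplyr::filter(d, .data[[outcome]] %in% c("Acute", "Persistent"))
      if (length(unique(d[[outcome]])) < 2) {
        skip <- skip + 1
        next
      }
      d <- dplyr::mutate(
        d,
        persist = as.numeric(.data[[outcome]] == "Persistent"),
        dep_sev5 = .data$dep_severity_w1 / 5,
        ptsd_sev15 = .data$ptsd_severity_w1 / 15,
        reexp5 = .data$ptsd_sev_b_w1 / 5,
        avoid5 = .data$ptsd_sev_c_w1 / 5,
        hyper5 = .data$ptsd_sev_d_w1 / 5)
      terms <- persistence_terms(disorder, as.character(mdl))
      X <- build_design(d, terms)
      fit <- suppressWarnings(glm.fit(X, d$persist, family = binomial()))
      se <- sqrt(diag(chol2inv(chol(crossprod(
        X * sqrt(pmax(fit$weights, 1e-12)))))))
      tds[[length(tds) + 1]] <- tibble::tibble(
        term = colnames(X), estimate = fit$coefficients, std.error = se)
    }
    if (length(tds) == 0) {
      stop_input("no completed dataset retained both outcome classes (model %d)",
                 mdl)
    }
    excluded[as.character(mdl)] <<- skip
    # severity columns are pre-scaled (/5, /15), so pooled coefficients are
    # already per-increment; the increment column is informational
    tb <- pool_or_table(tds, increments = c(), conf_level = conf_level)
    tb$increment <- unname(ifelse(is.na(increments[tb$term]), 1,
                                  increments[tb$term]))
    dplyr::mutate(tb, model = mdl)
  })
  out <- dplyr::filter(out, .data$term != "(Intercept)",
                       !grepl("^study_id", .data$term))
  attr(out, "disorder") <- disorder
  attr(out, "excluded") <- excluded
  attr(out, "model") <- "persistence"
  class(out) <- c("or_table", class(out))
  out
}

#' @export
tidy.or_table <- function(x, ...) tibble::as_tibble(x)

#' Forest plot of an odds-ratio table
#'
#' @param object An `or_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.or_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$panel <- if ("model" %in% names(df)) paste("Model", df$model)
  else df$y.level
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Descriptive comparison of trajectory groups
#'
#' Per-group counts, percentages and means (SD) of the baseline risk
#' factors and acute symptom severities across the Never / Acute /
#' Persistent / Missing (unclassifiable) groups, with Welch tests for
#' continuous variables and Pearson chi-square tests for categorical ones
#' computed across the three classified groups. Percentages are reported
#' against both the non-missing denominator (`pct`) and the full group
#' size (`pct_all`); the `N` row's `pct` is the group's share of the
#' total sample.
#'
#' @param classified Wide classified table ([classify_cohort()]).
#' @param disorder `"ptsd"` or `"mdd"`.
#' @param variables Optional subset of variables to describe.
#'
#' @return Tibble: `variable`, `level`, `group`, `n`, `denom`, `pct`,
#'   `pct_all`, `mean`, `sd`, `statistic`, `p.value`.
#' @export
describe_groups <- function(classified, disorder = c("ptsd", "mdd"),
                            variables = NULL) {
  disorder <- match.arg(disorder)
  lab <- classified[[paste0(disorder, "_trajectory")]]
  grp <- factor(dplyr::case_when(
    lab == "Unclassifiable" ~ "Missing",
    TRUE ~ as.character(lab)
  ), levels = c("Never", "Acute", "Persistent", "Delayed", "Missing"))
  keep <- grp %in% c("Never", "Acute", "Persistent", "Missing")
  d <- classified[keep, , drop = FALSE]
  grp <- droplevels(grp[keep])
  n_total <- nrow(d)

  cont_vars <- intersect(c("age", "ptsd_severity_w1", "dep_severity_w1"),
                         names(d))
  cat_vars <- intersect(c("female", "single", "low_education", "prior_trauma",
                          "index_trauma"), names(d))
  if (!is.null(variables)) {
    cont_vars <- intersect(cont_vars, variables)
    cat_vars <- intersect(cat_vars, variables)
  }
  groups <- levels(grp)
  test_groups <- grp %in% c("Never", "Acute", "Persistent")

  n_row <- purrr::map_dfr(groups, function(g) {
    ng <- sum(grp == g, na.rm = TRUE)
    if (ng == 0) stop_input("empty trajectory group: %s", g)
    tibble::tibble(variable = "N", level = NA_character_, group = g, n = ng,
                   denom = n_total, pct = 100 * ng / n_total,
                   pct_all = 100 * ng / n_total,
                   mean = NA_real_, sd = NA_real_,
                   statistic = NA_real_, p.value = NA_real_)
  })

  cont_rows <- purrr::map_dfr(cont_vars, function(v) {
    tst <- tryCatch(
      oneway.test(d[[v]][test_groups] ~ droplevels(grp[test_groups])),
      error = function(e) list(statistic = NA_real_, p.value = NA_real_))
    purrr::map_dfr(groups, function(g) {
      x <- d[[v]][grp == g]
      tibble::tibble(variable = v, level = NA_character_, group = g,
                     n = sum(!is.na(x)), denom = sum(!is.na(x)),
                     pct = NA_real_, pct_all = NA_real_,
                     mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE),
                     statistic = unname(tst$statistic),
                     p.value = tst$p.value)
    })
  })

  cat_rows <- purrr::map_dfr(cat_vars, function(v) {
    x <- d[[v]]
    if (is.logical(x)) x <- factor(ifelse(x, "yes", "no"), c("no", "yes"))
    x <- factor(x)
    tab <- table(droplevels(grp[test_groups]), x[test_groups])
    tst <- tryCatch(suppressWarnings(chisq.test(tab)),
                    error = function(e) list(statistic = NA_real_,
                                             p.value = NA_real_))
    lev <- if (is.factor(d[[v]])) levels(d[[v]]) else "yes"
    purrr::map_dfr(groups, function(g) {
      xg <- x[grp == g]
      denom <- sum(!is.na(xg))
      purrr::map_dfr(lev, function(l) {
        nl <- sum(xg == l, na.rm = TRUE)
        tibble::tibble(variable = v, level = l, group = g, n = nl,
                       denom = denom,
                       pct = if (denom > 0) 100 * nl / denom else NA_real_,
                       pct_all = 100 * nl / sum(grp == g),
                       mean = NA_real_, sd = NA_real_,
                       statistic = unname(tst$statistic),
                       p.value = tst$p.value)
      })
    })
  })
  dplyr::bind_rows(n_row, cont_rows, cat_rows)
}
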