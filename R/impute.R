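## Multiple imputation by chained equations honoring the two-level
## structure (assessment waves nested in participants), with study fixed
## effects, correlation-screened predictor sets, heteroskedastic
## random-intercept conditional models, and Rubin's-rules pooling.

#' Imputation settings
#'
#' @param m Number of imputed datasets (>= 2; default 20).
#' @param cycles Chained-equation cycles per chain (default 10).
#' @param threshold Predictor screening threshold: variables correlated at
#'   least this strongly (absolute value) with the index variable enter
#'   its imputation model (default 0.10).
#' @param engine `"mixed"` fits participant-random-intercept conditional
#'   models (heteroskedastic-by-study residuals for continuous targets,
#'   probit link for binary ones); `"fixed"` uses fixed-effects-only
#'   conditional models (faster, appropriate when participants contribute
#'   a single row).
#' @param seed Integer seed; chain k runs under a seed derived from
#'   `(seed, k)`.
#'
#' @return List of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 20, cycles = 10, threshold = 0.10,
                            engine = c("mixed", "fixed"), seed = 1) {
  engine <- match.arg(engine)
  if (m < 2) stop_input("imputation.m must be >= 2")
  if (threshold < 0 || threshold >= 1) stop_input("threshold must be in [0, 1)")
  structure(list(m = as.integer(m), cycles = as.integer(cycles),
                 threshold = threshold, engine = engine,
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

#' Select imputation-model predictors by correlation screening
#'
#' All variables whose absolute (pairwise-complete) correlation with the
#' target is at least `threshold` are selected; study dummies are always
#' included. Logical variables enter as 0/1 (point-biserial); factors are
#' screened through their level dummies.
#'
#' @param data Data frame.
#' @param target Target variable name.
#' @param threshold Absolute-correlation threshold (default 0.10).
#' @param study_col Study identifier column, always selected.
#' @param exclude Columns never eligible (identifiers etc.).
#'
#' @return Character vector of selected column names (including
#'   `study_col`), with the screening correlations in the
#'   `"correlations"` attribute.
#' @export
select_predictors <- function(data, target, threshold = 0.10,
                              study_col = "study_id",
                              exclude = c("participant_id")) {
  as_num <- function(v) {
    if (is.numeric(v)) v else if (is.logical(v)) as.numeric(v) else NULL
  }
  y <- as_num(data[[target]])
  if (is.null(y)) stop_input("target %s must be numeric or logical", target)
  if (stats::var(y, na.rm = TRUE) %in% c(0, NA)) {
    stop_input("target %s has zero variance", target)
  }
  candidates <- setdiff(names(data), c(target, study_col, exclude))
  cors <- vapply(candidates, function(nm) {
    v <- data[[nm]]
    if (is.factor(v) || is.character(v)) {
      lv <- unique(as.character(v[!is.na(v)]))
      if (length(lv) < 2) return(NA_real_)
      max(vapply(lv, function(l) {
        d <- as.numeric(v == l)
        if (stats::var(d, na.rm = TRUE) == 0) return(NA_real_)
        abs(suppressWarnings(cor(y, d, use = "pairwise.complete.obs")))
      }, numeric(1)), na.rm = TRUE)
    } else {
      x <- as_num(v)
      if (is.null(x) || isTRUE(stats::var(x, na.rm = TRUE) == 0)) return(NA_real_)
      abs(suppressWarnings(cor(y, x, use = "pairwise.complete.obs")))
    }
  }, numeric(1))
  selected <- candidates[!is.na(cors) & cors >= threshold]
  out <- unique(c(selected, intersect(study_col, names(data))))
  attr(out, "correlations") <- cors
  out
}

# design matrix for a conditional model; errors on rank deficiency
conditional_design <- function(data, predictors) {
  df <- data[, predictors, drop = FALSE]
  X <- model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_input("singular design; collinear column(s): %s",
               paste(drop_cols, collapse = ", "))
  }
  X
}

draw_mvnorm <- function(mu, Sigma) {
  drop(mvtnorm::rmvnorm(1, mean = mu, sigma = as.matrix(Sigma)))
}

#' Impute a continuous variable from a heteroskedastic mixed model
#'
#' Linear model with participant random intercept, the screened
#' predictors (study entering as fixed dummies) and study-specific
#' residual variances; missing entries are replaced by posterior
#' predictive draws under asymptotic-normal parameter draws. Observed
#' values are never modified.
#'
#' @param data Data frame containing the target, predictors, and the
#'   participant / study identifier columns.
#' @param target Name of the (partially missing) numeric column.
#' @param predictors Character vector of predictor columns.
#' @param id_col,study_col Identifier columns.
#' @param m Number of independent completed draws to return.
#' @param seed Integer seed.
#' @param engine `"mixed"` or `"fixed"` (see [imputation_spec()]).
#'
#' @return Numeric matrix with `nrow(data)` rows and `m` columns of
#'   completed values; attribute `"engine"` records the model actually
#'   used.
#' @export
impute_continuous_mixed <- function(data, target, predictors,
                                    id_col = "participant_id",
                                    study_col = "study_id",
                                    m = 1, seed = 1, engine = "mixed") {
  y <- data[[target]]
  obs <- !is.na(y)
  if (sum(obs) < 30) stop_input("fewer than 30 complete cases for %s", target)
  predictors <- setdiff(predictors, target)
  X <- conditional_design(data, predictors)
  multi_row <- any(duplicated(data[[id_col]][obs]))
  multi_study <- length(unique(data[[study_col]])) > 1

  used <- "fixed"
  fit <- NULL
  if (engine == "mixed" && multi_row) {
    rhs <- paste(sprintf("`%s`", setdiff(colnames(X), "(Intercept)")),
                 collapse = " + ")
    if (rhs == "") rhs <- "1"
    df2 <- data.frame(y = y[obs], .id = data[[id_col]][obs],
                      .study = data[[study_col]][obs],
                      X[obs, -1, drop = FALSE], check.names = FALSE)
    fit <- tryCatch(
      nlme::lme(stats::as.formula(paste("y ~", rhs)), data = df2,
                random = ~ 1 | .id,
                weights = if (multi_study) nlme::varIdent(form = ~ 1 | .study),
                method = "ML",
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) used <- "mixed"
  }

  out <- matrix(rep(y, m), ncol = m)
  mis <- which(!obs)
  if (length(mis) == 0) {
    attr(out, "engine") <- if (!is.null(fit)) used else "none"
    return(out)
  }

  if (used == "mixed") {
    beta <- nlme::fixef(fit)
    Vb <- vcov(fit)
    sigma <- fit$sigma
    vf <- fit$modelStruct$varStruct
    wts <- if (!is.null(vf)) {
      cf <- coef(vf, unconstrained = FALSE, allCoef = TRUE)
      setNames(as.numeric(cf), names(cf))
    } else NULL
    tau <- as.numeric(nlme::VarCorr(fit)[1, "StdDev"])
    re <- nlme::ranef(fit)
    re_map <- setNames(re[[1]], rownames(re))
    for (k in seq_len(m)) {
      bstar <- with_seed(derive_seed(seed, paste0("cont", k)), {
        b <- draw_mvnorm(beta, Vb)
        mu <- drop(X[mis, names(beta), drop = FALSE] %*% b)
        bid <- re_map[as.character(data[[id_col]][mis])]
        bid[is.na(bid)] <- rnorm(sum(is.na(bid)), 0, tau)
        sig_row <- if (!is.null(wts)) {
          sigma * unname(wts[as.character(data[[study_col]][mis])])
        } else rep(sigma, length(mis))
        sig_row[is.na(sig_row)] <- sigma
        mu + bid + rnorm(length(mis), 0, sig_row)
      })
      out[mis, k] <- bstar
    }
  } else {
    fitlm <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
    beta <- fitlm$coefficients
    res <- fitlm$residuals
    dfres <- sum(obs) - ncol(X)
    s2 <- sum(res^2) / dfres
    XtXinv <- chol2inv(chol(crossprod(X[obs, , drop = FALSE])))
    # study-specific residual SDs (heteroskedastic errors)
    st_obs <- data[[study_col]][obs]
    s_by <- tapply(res, st_obs, function(r) sqrt(mean(r^2)))
    for (k in seq_len(m)) {
      out[mis, k] <- with_seed(derive_seed(seed, paste0("cont", k)), {
        s2star <- s2 * dfres / stats::rchisq(1, dfres)
        b <- draw_mvnorm(beta, XtXinv * s2star)
        mu <- drop(X[mis, , drop = FALSE] %*% b)
        sig <- s_by[as.character(data[[study_col]][mis])]
        sig[is.na(sig)] <- sqrt(s2star)
        mu + rnorm(length(mis), 0, sig * sqrt(s2star / s2))
      })
    }
  }
  attr(out, "engine") <- used
  out
}

#' Impute a binary variable from a random-intercept probit model
#'
#' Probit regression with participant random intercept (fixed-effects
#' probit under `engine = "fixed"` or when participants contribute single
#' rows); missing entries are Bernoulli draws from predicted
#' probabilities under asymptotic-normal parameter draws.
#'
#' @inheritParams impute_continuous_mixed
#' @return Completed matrix (`nrow(data)` x `m`) of 0/1 values (logical
#'   input returns logical), with attribute `"engine"`.
#' @export
impute_binary_probit <- function(data, target, predictors,
                                 id_col = "participant_id",
                                 study_col = "study_id",
                                 m = 1, seed = 1, engine = "mixed") {
  y0 <- data[[target]]
  was_logical <- is.logical(y0)
  y <- as.numeric(y0)
  obs <- !is.na(y)
  if (length(unique(y[obs])) < 2) {
    stop_input("both classes must be present among complete cases of %s", target)
  }
  predictors <- setdiff(predictors, target)
  X <- conditional_design(data, predictors)
  multi_row <- any(duplicated(data[[id_col]][obs]))

  used <- "fixed"
  fit <- NULL
  if (engine == "mixed" && multi_row) {
    df2 <- data.frame(y = y[obs], .id = data[[id_col]][obs],
                      X[obs, -1, drop = FALSE], check.names = FALSE)
    rhs <- paste(c(sprintf("`%s`", setdiff(colnames(X), "(Intercept)")),
                   "(1 | .id)"), collapse = " + ")
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(stats::as.formula(paste("y ~", rhs)), data = df2,
                    family = binomial(link = "probit"), nAGQ = 1))),
      error = function(e) NULL)
    if (!is.null(fit)) used <- "mixed"
  }
  if (is.null(fit)) {
    fit <- suppressWarnings(
      glm.fit(X[obs, , drop = FALSE], y[obs],
              family = binomial(link = "probit")))
  }

  coefs <- if (used == "mixed") lme4::fixef(fit) else fit$coefficients
  if (any(abs(coefs) > 15)) {
    stop_input(
      "probable perfect separation imputing %s (|coef| > 15); reduce the predictor set",
      target)
  }
  Vb <- if (used == "mixed") as.matrix(vcov(fit)) else {
    w <- fit$weights
    chol2inv(chol(crossprod(X[obs, , drop = FALSE] * sqrt(w))))
  }
  tau <- if (used == "mixed") {
    as.numeric(lme4::VarCorr(fit)$.id[1])^0.5
  } else 0
  re_map <- if (used == "mixed") {
    r <- lme4::ranef(fit)$.id
    setNames(r[[1]], rownames(r))
  } else numeric(0)

  out <- matrix(rep(y, m), ncol = m)
  mis <- which(!obs)
  if (length(mis) > 0) {
    for (k in seq_len(m)) {
      out[mis, k] <- with_seed(derive_seed(seed, paste0("bin", k)), {
        b <- draw_mvnorm(coefs, Vb)
        eta <- drop(X[mis, names(coefs), drop = FALSE] %*% b)
        bid <- re_map[as.character(data[[id_col]][mis])]
        bid[is.na(bid)] <- if (tau > 0) rnorm(sum(is.na(bid)), 0, tau) else 0
        as.numeric(runif(length(mis)) < pnorm(eta + bid))
      })
    }
  }
  if (was_logical) out <- out > 0.5
  attr(out, "engine") <- used
  out
}

#' Run chained-equation multiple imputation
#'
#' Variables with missing values are visited in order of increasing
#' missingness fraction; each visit refits the variable's conditional
#' model (continuous: heteroskedastic random-intercept linear model;
#' binary: random-intercept probit; factors with more than two levels:
#' a dummy series, reassembled by most-probable category) on the current
#' completed data and redraws the missing entries. The `m` chains are
#' independent, seeded from `(spec$seed, chain)`. Observed cells are
#' identical across the completed datasets.
#'
#' @param data Data frame (long or wide analysis table).
#' @param spec [imputation_spec()].
#' @param id_col,study_col Identifier columns.
#' @param exclude Columns never imputed nor used as predictors
#'   (identifiers are always excluded).
#' @param drop_predictors Named list: for a target variable, predictors to
#'   remove from its imputation model even if they pass the correlation
#'   screen (e.g. a column that is a deterministic function of the
#'   target, which would separate the conditional model perfectly).
#'
#' @return Object of class `imputed_datasets`: list with elements
#'   `imputations` (list of m completed tibbles), `m`, `spec`, and `meta`
#'   (predictor sets, model types, engines used, chain means per cycle).
#' @export
run_mice <- function(data, spec = imputation_spec(),
                     id_col = "participant_id", study_col = "study_id",
                     exclude = character(0), drop_predictors = list()) {
  data <- tibble::as_tibble(data)
  exclude <- union(exclude, c(id_col))
  miss_frac <- vapply(data, function(v) mean(is.na(v)), numeric(1))
  targets <- setdiff(names(miss_frac)[miss_frac > 0], c(exclude, study_col))
  targets <- targets[order(miss_frac[targets])]

  model_type <- vapply(targets, function(v) {
    x <- data[[v]]
    if (is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1, NA)))) "binary"
    else if (is.numeric(x)) "continuous"
    else if (is.factor(x) || is.character(x)) "categorical"
    else stop_input("no imputation model for column %s (type %s)", v, class(x)[1])
  }, character(1))

  predictor_sets <- lapply(setNames(targets, targets), function(v) {
    if (model_type[v] == "categorical") {
      # screen through a temporary dummy of the most common level
      lv <- names(sort(table(data[[v]]), decreasing = TRUE))[1]
      tmp <- data
      tmp$.dummy <- as.numeric(as.character(tmp[[v]]) == lv)
      p <- select_predictors(tmp, ".dummy", spec$threshold, study_col,
                             exclude = c(exclude, v))
      attr(p, "correlations") <- NULL
      setdiff(p, ".dummy")
    } else {
      p <- select_predictors(data, v, spec$threshold, study_col, exclude)
      attr(p, "correlations") <- NULL
      p
    }
  })
  predictor_sets <- lapply(setNames(targets, targets), function(v) {
    setdiff(predictor_sets[[v]], drop_predictors[[v]])
  })

  impute_once <- function(df, v, chain_seed, cycle) {
    preds <- setdiff(predictor_sets[[v]], v)
    seed_v <- derive_seed(chain_seed, paste(v, cycle))
    mask <- is.na(data[[v]])
    if (model_type[v] == "continuous") {
      comp <- impute_continuous_mixed(
        dplyr::mutate(df, !!v := ifelse(mask, NA, .data[[v]])),
        v, preds, id_col, study_col, m = 1, seed = seed_v,
        engine = spec$engine)
      df[[v]] <- comp[, 1]
      attr(df, paste0(".engine_", v)) <- attr(comp, "engine")
    } else if (model_type[v] == "binary") {
      tmp <- df
      tmp[[v]][mask] <- NA
      comp <- impute_binary_probit(tmp, v, preds, id_col, study_col,
                                   m = 1, seed = seed_v, engine = spec$engine)
      df[[v]] <- comp[, 1]
    } else {
      lv <- levels(factor(data[[v]]))
      tmp <- df
      tmp[[v]][mask] <- NA
      # dummy series, one probit per level; reassemble by highest draw
      scores <- matrix(0, nrow(df), length(lv))
      for (li in seq_along(lv)) {
        tmp$.dummy <- as.numeric(as.character(df[[v]]) == lv[li])
        tmp$.dummy[mask] <- NA
        comp <- tryCatch(
          impute_binary_probit(tmp, ".dummy",
                               setdiff(preds, v), id_col, study_col,
                               m = 1,
                               seed = derive_seed(seed_v, lv[li]),
                               engine = spec$engine),
          error = function(e) matrix(mean(tmp$.dummy, na.rm = TRUE),
                                     nrow(df), 1))
        scores[, li] <- comp[, 1]
      }
      pick <- lv[max.col(scores, "first")]
      newv <- as.character(df[[v]])
      newv[mask] <- pick[mask]
      df[[v]] <- if (is.factor(data[[v]])) factor(newv, levels = levels(data[[v]])) else newv
    }
    df
  }

  chains <- vector("list", spec$m)
  chain_means <- list()
  for (k in seq_len(spec$m)) {
    chain_seed <- derive_seed(spec$seed, paste0("chain", k))
    df <- with_seed(chain_seed, {
      init <- data
      for (v in targets) {
        mask <- is.na(init[[v]])
        pool <- init[[v]][!mask]
        if (length(pool) == 0) stop_input("column %s has no observed values", v)
        init[[v]][mask] <- sample(pool, sum(mask), replace = TRUE)
      }
      init
    })
    means_k <- list()
    if (length(targets) > 0) {
      for (cyc in seq_len(spec$cycles)) {
        for (v in targets) {
          df <- tryCatch(impute_once(df, v, chain_seed, cyc),
                         error = function(e) {
                           stop_input("imputation of %s failed in chain %d: %s",
                                      v, k, conditionMessage(e))
                         })
        }
        means_k[[cyc]] <- vapply(targets, function(v) {
          x <- df[[v]][is.na(data[[v]])]
          if (is.numeric(x) || is.logical(x)) mean(as.numeric(x)) else NA_real_
        }, numeric(1))
      }
    }
    chain_means[[k]] <- do.call(rbind, means_k)
    chains[[k]] <- df
  }

  structure(list(imputations = chains, m = spec$m, spec = spec,
                 meta = list(predictor_sets = predictor_sets,
                             model_types = model_type,
                             chain_means = chain_means,
                             missing_fraction = miss_frac[targets])),
            class = "imputed_datasets")
}

#' @export
print.imputed_datasets <- function(x, ...) {
  cat(sprintf("%d imputed datasets (%d rows; %d imputed variable(s))\n",
              x$m, nrow(x$imputations[[1]]), length(x$meta$model_types)))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param estimates Numeric vector of per-imputation point estimates
#'   (length m >= 2).
#' @param variances Per-imputation squared standard errors.
#' @param dfcom Complete-data degrees of freedom (default `Inf`), used in
#'   the Barnard-Rubin small-sample adjustment.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return List of class `pooled_estimate`: `estimate` (Qbar), `ubar`,
#'   `b` (between-imputation variance), `t` (total variance),
#'   `df` (Barnard-Rubin), `lo`, `hi`, `m`.
#' @export
rubin_pool <- function(estimates, variances, dfcom = Inf, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop_input("rubin_pool requires m >= 2 estimates")
  if (length(variances) != m) stop_input("estimates/variances length mismatch")
  if (any(variances <= 0)) stop_input("variances must be positive")
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- stats::var(estimates)
  t <- ubar + (1 + 1 / m) * b
  lambda <- (1 + 1 / m) * b / t
  if (lambda < .Machine$double.eps) {
    df <- Inf
  } else {
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else df_old
  }
  alpha <- 1 - conf_level
  q <- if (is.finite(df)) qt(1 - alpha / 2, df) else qnorm(1 - alpha / 2)
  structure(list(estimate = qbar, ubar = ubar, b = b, t = t, df = df,
                 lo = qbar - q * sqrt(t), hi = qbar + q * sqrt(t), m = m,
                 conf_level = conf_level),
            class = "pooled_estimate")
}

#' @export
tidy.pooled_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, std.error = sqrt(x$t),
                 conf.low = x$lo, conf.high = x$hi, df = x$df,
                 ubar = x$ubar, b = x$b, m = x$m)
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4f (T = %.4f, df = %.1f, %d imputations)\n",
              x$estimate, x$t, x$df, x$m))
  invisible(x)
}

#' Pool likelihood-ratio chi-square statistics across imputations (D2)
#'
#' Combines per-imputation chi-square statistics by the D2 rule for
#' multiply imputed data, giving an F reference distribution.
#'
#' @param stats Per-imputation chi-square statistics.
#' @param df Test degrees of freedom (number of constraints).
#'
#' @return Tibble with `statistic` (D2), `df1`, `df2`, `p.value`, `m`.
#' @export
pool_lrt_d2 <- function(stats, df) {
  m <- length(stats)
  k <- df
  if (m == 1) {
    return(tibble::tibble(statistic = stats / k, df1 = k, df2 = Inf,
                          p.value = pchisq(stats, k, lower.tail = FALSE),
                          m = 1L))
  }
  dbar <- mean(stats)
  r2 <- (1 + 1 / m) * stats::var(sqrt(stats))
  if (r2 < .Machine$double.eps) {
    return(tibble::tibble(statistic = dbar / k, df1 = k, df2 = Inf,
                          p.value = pchisq(dbar, k, lower.tail = FALSE),
                          m = as.integer(m)))
  }
  D2 <- max((dbar / k - (m + 1) / (m - 1) * r2) / (1 + r2), 0)
  nu <- k^(-3 / m) * (m - 1) * (1 + 1 / r2)^2
  tibble::tibble(statistic = D2, df1 = k, df2 = nu,
                 p.value = pf(D2, k, nu, lower.tail = FALSE),
                 m = as.integer(m))
}

#' Write imputed datasets to indexed CSV files with a metadata sidecar
#'
#' @param imputed [run_mice()] result.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_imputations <- function(imputed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_len(imputed$m), function(k) {
    p <- file.path(dir, sprintf("imputation_%03d.csv", k))
    utils::write.csv(as.data.frame(imputed$imputations[[k]]), p,
                     row.names = FALSE)
    p
  }, character(1))
  meta_path <- file.path(dir, "imputation_meta.json")
  jsonlite::write_json(
    list(m = imputed$m,
         model_types = as.list(imputed$meta$model_types),
         predictor_sets = imputed$meta$predictor_sets,
         missing_fraction = as.list(imputed$meta$missing_fraction)),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta_path))
}
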