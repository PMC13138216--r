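## Between-study heterogeneity diagnostics: bootstrap out-of-bag
## calibration (per-study expected/observed ratios and Brier scores for
## fixed- vs random-study-effect models), leave-one-study-out refits, and
## the follow-up window sensitivity rerun.

#' Brier score of probabilistic predictions
#'
#' Mean squared difference between predicted probabilities and observed
#' binary outcomes.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param outcomes Observed 0/1 (or logical) outcomes.
#' @return The Brier score (scalar in `[0, 1]`).
#' @export
brier_score <- function(probs, outcomes) {
  if (length(probs) == 0) stop_input("empty input")
  if (length(probs) != length(outcomes)) stop_input("length mismatch")
  check_range(probs, 0, 1, "predicted probability")
  mean((probs - as.numeric(outcomes))^2)
}

#' Per-study expected/observed ratios
#'
#' `E/O = sum(predicted probabilities) / sum(observed events)` within each
#' study; above 1 the model over-predicts the outcome's prevalence, below
#' 1 it under-predicts. Studies without observed events get `NA` (ratio
#' undefined), not an error.
#'
#' @param probs Predicted probabilities.
#' @param outcomes Observed 0/1 outcomes.
#' @param study Study labels, same length.
#' @return Tibble: `study`, `expected`, `observed`, `eo`.
#' @export
expected_observed_ratio <- function(probs, outcomes, study) {
  if (length(probs) != length(outcomes) || length(probs) != length(study)) {
    stop_input("length mismatch")
  }
  tibble::tibble(study = as.character(study), p = probs,
                 y = as.numeric(outcomes)) |>
    dplyr::group_by(.data$study) |>
    dplyr::summarise(expected = sum(.data$p), observed = sum(.data$y),
                     .groups = "drop") |>
    dplyr::mutate(eo = ifelse(.data$observed > 0,
                              .data$expected / .data$observed, NA_real_))
}

# persistent-vs-rest outcome and risk-factor design for calibration models
calibration_frame <- function(d, disorder) {
  outcome <- paste0(disorder, "_trajectory")
  d <- dplyr::filter(d, .data[[outcome]] %in% c("Never", "Acute", "Persistent"))
  d$y <- as.numeric(d[[outcome]] == "Persistent")
  d
}

fit_calibration_model <- function(d, type, nAGQ = 15) {
  f <- y ~ female + age + single + low_education + prior_trauma + index_trauma
  if (type == "fixed") {
    if (length(unique(d$study_id)) > 1) {
      f <- stats::update(f, . ~ . + study_id)
    }
    glm(f, binomial(), data = d)
  } else {
    suppressMessages(suppressWarnings(
      lme4::glmer(stats::update(f, . ~ . + (1 | study_id)), data = d,
                  family = binomial(), nAGQ = nAGQ)))
  }
}

predict_calibration <- function(fit, newdata, type) {
  if (type == "fixed") {
    predict(fit, newdata = newdata, type = "response")
  } else {
    # empirical-Bayes study intercept when the study was in-bag, else the
    # population intercept
    pr <- predict(fit, newdata = newdata, type = "response",
                  allow.new.levels = TRUE)
    pr
  }
}

#' Bootstrap out-of-bag calibration of fixed vs random study-effect models
#'
#' For each replicate, participants are resampled with replacement; the
#' persistent-vs-rest logistic model (fixed study dummies, or a random
#' study intercept fit by adaptive quadrature) is fit on the in-bag
#' sample and evaluated on the out-of-bag participants (those never
#' drawn): per-study expected/observed ratios and Brier scores are
#' accumulated, averaged over replicates, then over imputed datasets.
#' Replicates whose in-bag sample lacks an outcome class are skipped and
#' counted.
#'
#' @param imputed [impute_cohort()] result or a single classified table.
#' @param disorder `"ptsd"` or `"mdd"`.
#' @param model `"fixed"`, `"random"`, or both.
#' @param B Bootstrap replicates per imputed dataset.
#' @param seed Integer seed (deterministic reports under a fixed seed).
#' @param nAGQ Adaptive Gauss-Hermite nodes for the random-intercept fit.
#'
#' @return Tibble of class `calibration_report`: `study`, `model`,
#'   `disorder`, `eo`, `brier`, `n_replicates`, `n_skipped`, `m`.
#' @export
bootstrap_calibration <- function(imputed, disorder = c("ptsd", "mdd"),
                                  model = c("fixed", "random"), B = 100,
                                  seed = 1, nAGQ = 15) {
  disorder <- match.arg(disorder)
  model <- match.arg(model, several.ok = TRUE)
  if (B < 1) stop_input("B must be >= 1")
  tables <- if (inherits(imputed, "imputed_datasets")) imputed$imputations
  else list(imputed)

  out <- purrr::map_dfr(model, function(ty) {
    per_imp <- purrr::imap_dfr(tables, function(d, mi) {
      d <- calibration_frame(d, disorder)
      if (length(unique(d$y)) < 2) stop_input("both outcomes must be present")
      n <- nrow(d)
      acc <- list()
      skipped <- 0
      for (b in seq_len(B)) {
        idx <- with_seed(derive_seed(seed, sprintf("%s-%d-%d", ty, mi, b)),
                         sample.int(n, n, replace = TRUE))
        oob <- setdiff(seq_len(n), unique(idx))
        inbag <- d[idx, , drop = FALSE]
        if (length(unique(inbag$y)) < 2 || length(oob) == 0) {
          skipped <- skipped + 1
          next
        }
        fit <- tryCatch(fit_calibration_model(inbag, ty, nAGQ),
                        error = function(e) NULL)
        if (is.null(fit)) {
          skipped <- skipped + 1
          next
        }
        dd <- d[oob, , drop = FALSE]
        pr <- tryCatch(predict_calibration(fit, dd, ty),
                       error = function(e) NULL)
        if (is.null(pr)) {
          skipped <- skipped + 1
          next
        }
        eo <- expected_observed_ratio(pr, dd$y, dd$study_id)
        br <- tibble::tibble(study = dd$study_id, p = pr, y = dd$y) |>
          dplyr::group_by(.data$study) |>
          dplyr::summarise(brier = mean((.data$p - .data$y)^2),
                           .groups = "drop")
        acc[[length(acc) + 1]] <- dplyr::left_join(eo, br, by = "study")
      }
      if (length(acc) == 0) {
        stop_input("all %d bootstrap replicates were skipped", B)
      }
      dplyr::bind_rows(acc) |>
        dplyr::group_by(.data$study) |>
        dplyr::summarise(eo = mean(.data$eo, na.rm = TRUE),
                         brier = mean(.data$brier, na.rm = TRUE),
                         .groups = "drop") |>
        dplyr::mutate(n_replicates = B - skipped, n_skipped = skipped)
    })
    per_imp |>
      dplyr::group_by(.data$study) |>
      dplyr::summarise(eo = mean(.data$eo), brier = mean(.data$brier),
                       n_replicates = sum(.data$n_replicates),
                       n_skipped = sum(.data$n_skipped), .groups = "drop") |>
      dplyr::mutate(model = ty, disorder = disorder, m = length(tables))
  })
  class(out) <- c("calibration_report", class(out))
  out
}

#' @export
tidy.calibration_report <- function(x, ...) tibble::as_tibble(x)

#' Calibration report plot (per-study E/O and Brier)
#'
#' @param object A `calibration_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("eo", "brier"),
                            names_to = "metric")
  ref <- tibble::tibble(metric = c("eo", "brier"), v = c(1, NA))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$study,
                                   colour = .data$model)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_vline(data = ref, ggplot2::aes(xintercept = .data$v),
                        linetype = 2, colour = "grey50", na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Leave-one-study-out refit of the risk-factor models
#'
#' @param imputed [impute_cohort()] result or classified table.
#' @param exclude_study Study to drop.
#' @param disorder `"ptsd"` or `"mdd"`.
#' @return `or_table` from [fit_risk_multinomial()] on the reduced pool,
#'   with attribute `"excluded_study"`.
#' @export
leave_one_study_out <- function(imputed, exclude_study,
                                disorder = c("ptsd", "mdd")) {
  disorder <- match.arg(disorder)
  drop_study <- function(d) {
    out <- dplyr::filter(d, .data$study_id != exclude_study)
    if (length(unique(out$study_id)) < 1) {
      stop_input("no studies remain after excluding %s", exclude_study)
    }
    out
  }
  reduced <- if (inherits(imputed, "imputed_datasets")) {
    imputed$imputations <- lapply(imputed$imputations, drop_study)
    imputed
  } else drop_study(imputed)
  out <- fit_risk_multinomial(reduced, disorder)
  attr(out, "excluded_study") <- exclude_study
  out
}

#' Follow-up window sensitivity rerun
#'
#' Marks wave-2 assessments outside the requested days-since-trauma
#' window as unobserved, re-derives trajectories, reruns imputation and
#' the pooled multinomial and persistence models. The identity window
#' `c(122, 456)` reproduces the primary analysis.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param window Length-2 numeric inside `[122, 456]`.
#' @param spec [imputation_spec()].
#' @param xwalk Crosswalk for HADS equating.
#' @param disorders Disorders to model.
#'
#' @return List: `window`, `classified`, `imputed`, `multinomial` (named
#'   by disorder), `persistence` (named by disorder).
#' @export
window_sensitivity <- function(cohort, window = c(270, 456),
                               spec = imputation_spec(),
                               xwalk = hads_bdi_crosswalk(),
                               disorders = c("ptsd", "mdd")) {
  if (length(window) != 2 || window[1] > window[2]) {
    stop_input("window must be an increasing day pair")
  }
  if (window[1] < 122 || window[2] > 456) {
    stop_input("window must lie within [122, 456]")
  }
  w2 <- cohort$wave == 2L
  outside <- w2 & (cohort$days_since_trauma < window[1] |
                     cohort$days_since_trauma > window[2])
  if (all(outside[w2])) {
    stop_input("no wave-2 assessments fall inside [%s, %s]",
               window[1], window[2])
  }
  cohort$obs_dep[outside] <- FALSE
  cohort$obs_ptsd[outside] <- FALSE
  mask_cols <- c(sprintf("bdi_%02d", 1:21), sprintf("hads_%d", 1:7),
                 caps_freq_cols(), caps_int_cols())
  cohort[outside, mask_cols] <- NA_integer_
  classified <- classify_cohort(cohort, xwalk = xwalk)
  imputed <- impute_cohort(cohort, spec = spec, xwalk = xwalk)
  list(window = window,
       classified = classified,
       imputed = imputed,
       multinomial = setNames(lapply(disorders, function(dz)
         fit_risk_multinomial(imputed, dz)), disorders),
       persistence = setNames(lapply(disorders, function(dz)
         fit_persistence_logistic(imputed, dz)), disorders))
}
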