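## Instrument harmonization on a cohort: pooled-by-instrument GRM
## calibrations with shared CAPS depression-overlap anchor items,
## mean/sigma linking of the HADS calibration onto the BDI metric, and
## the resulting total-score crosswalk, with ordinal-CFA
## unidimensionality checks.

ANCHOR_SYMPTOMS <- c(9, 13, 15)  # CAPS C4, D1, D3 (depression overlap)

#' Recode CAPS anchor symptoms to a 0-4 ordinal severity
#'
#' Frequency and intensity (each 0-4) are summed and binned
#' (0, 1-2, 3-4, 5-6, 7-8), i.e. `ceiling((freq + intensity) / 2)`.
#'
#' @param cohort Cohort rows containing CAPS columns.
#' @return Integer matrix with columns `anchor_c4`, `anchor_d1`,
#'   `anchor_d3`.
#' @export
anchor_ordinals <- function(cohort) {
  out <- vapply(ANCHOR_SYMPTOMS, function(s) {
    total <- cohort[[sprintf("caps_f%02d", s)]] + cohort[[sprintf("caps_i%02d", s)]]
    as.integer(ceiling(total / 2))
  }, integer(nrow(cohort)))
  colnames(out) <- c("anchor_c4", "anchor_d1", "anchor_d3")
  out
}

# pooled wave-1 item matrix for one instrument (instrument items + anchors)
pooled_instrument_data <- function(cohort, instrument) {
  rows <- cohort$wave == 1L & cohort$instrument == instrument & cohort$obs_dep
  d <- cohort[rows, , drop = FALSE]
  if (nrow(d) == 0) stop_input("no wave-1 %s assessments in the cohort", instrument)
  items <- if (instrument == "BDI") sprintf("bdi_%02d", 1:21) else
    sprintf("hads_%d", 1:7)
  cbind(as.matrix(d[, items]), anchor_ordinals(d))
}

#' Check unidimensionality of a pooled instrument dataset by ordinal CFA
#'
#' Fits the one-factor model (and optionally a two-factor model splitting
#' somatic from non-somatic depression items) to the polychoric
#' correlation matrix by ULS and reports CFI / TLI / RMSEA. The working
#' thresholds are CFI > 0.95, TLI > 0.95, RMSEA < 0.06 (RMSEA up to 0.10
#' tolerable).
#'
#' @param responses Ordinal item matrix (e.g. from the pooled instrument
#'   data of a cohort).
#' @param somatic Optional integer/logical index of somatic items for the
#'   two-factor comparison.
#'
#' @return List with `one_factor` and (if requested) `two_factor`
#'   [fit_factor_model()] results, plus `unidimensional` (logical, from
#'   the one-factor thresholds).
#' @export
check_unidimensionality <- function(responses, somatic = NULL) {
  corr <- polychoric_matrix(responses)
  n <- nrow(responses)
  p <- ncol(corr)
  one <- fit_factor_model(corr, n, matrix(TRUE, p, 1))
  out <- list(one_factor = one,
              unidimensional = one$cfi > 0.95 && one$tli > 0.95 &&
                one$rmsea < 0.10)
  if (!is.null(somatic)) {
    pat <- matrix(FALSE, p, 2)
    pat[somatic, 1] <- TRUE
    pat[setdiff(seq_len(p), somatic), 2] <- TRUE
    out$two_factor <- fit_factor_model(corr, n, pat)
  }
  out
}

#' Derive a HADS-to-BDI crosswalk from a cohort by IRT equating
#'
#' Builds the two pooled wave-1 datasets (instrument items plus the three
#' CAPS anchor ordinals), fits a graded response model to each, links the
#' HADS calibration onto the BDI metric by mean/sigma on the pooled
#' anchor thresholds, and converts the linked calibrations into a
#' total-score crosswalk by true-score equating.
#'
#' @param cohort A [generate_cohort()]-shaped tibble containing both BDI
#'   and HADS studies.
#' @param cfa Also run the ordinal-CFA unidimensionality checks
#'   (slower; default `FALSE`).
#' @param ... Passed to [fit_grm()].
#'
#' @return List of class `equating_result`: `crosswalk`, `grm_bdi`,
#'   `grm_hads`, `grm_hads_linked`, `link`, and optionally `cfa`.
#' @export
equate_cohort <- function(cohort, cfa = FALSE, ...) {
  bdi_data <- pooled_instrument_data(cohort, "BDI")
  hads_data <- pooled_instrument_data(cohort, "HADS")
  anchor_flag <- function(m) grepl("^anchor_", colnames(m))
  grm_bdi <- fit_grm(bdi_data, anchor = anchor_flag(bdi_data), ...)
  grm_hads <- fit_grm(hads_data, anchor = anchor_flag(hads_data), ...)
  link <- mean_sigma_link(grm_bdi, grm_hads)
  grm_hads_linked <- apply_linking(grm_hads, link)
  xwalk <- build_crosswalk(grm_hads_linked, grm_bdi,
                           source_instrument = "HADS",
                           target_instrument = "BDI")
  out <- list(crosswalk = xwalk, grm_bdi = grm_bdi, grm_hads = grm_hads,
              grm_hads_linked = grm_hads_linked, link = link)
  if (cfa) {
    out$cfa <- list(
      bdi = check_unidimensionality(bdi_data),
      hads = check_unidimensionality(hads_data)
    )
  }
  structure(out, class = "equating_result")
}

#' @export
print.equating_result <- function(x, ...) {
  cat("IRT equating result\n")
  print(x$link)
  thr <- x$crosswalk$source_score[x$crosswalk$equated_score >= 20]
  cat(sprintf("crosswalk over source scores %d-%d; probable-MDD source threshold: %s\n",
              min(x$crosswalk$source_score), max(x$crosswalk$source_score),
              if (length(thr) > 0) min(thr) else "none"))
  invisible(x)
}

#' Crosswalk step plot
#'
#' @param object A `crosswalk`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crosswalk <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$source_score,
                               y = .data$equated_score)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = attr(object, "source_instrument") %||% "source score",
                  y = attr(object, "target_instrument") %||% "equated score") +
    ggplot2::theme_minimal()
}
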