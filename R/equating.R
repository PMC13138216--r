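## Mean/sigma anchor linking and true-score (test characteristic curve)
## equating between two GRM calibrations.

#' Mean/sigma linking constants from anchor-item calibrations
#'
#' Places a target calibration on the metric of a base calibration using
#' anchor items estimated in both. The constants are computed from the
#' pooled anchor threshold parameters: `A = SD(b_base) / SD(b_target)`,
#' `B = mean(b_base) - A * mean(b_target)`. The transformed target metric
#' is `theta* = A * theta + B` (so `b* = A*b + B`, `a* = a / A`).
#'
#' @param anchors_base,anchors_target [grm_parameters()] containing the
#'   same anchor items (matched by label) with identical category counts.
#'
#' @return List of class `linking_constants` with elements `A` (positive
#'   scale) and `B` (shift).
#' @export
mean_sigma_link <- function(anchors_base, anchors_target) {
  ab <- dplyr::filter(tibble::as_tibble(anchors_base), .data$anchor)
  at <- dplyr::filter(tibble::as_tibble(anchors_target), .data$anchor)
  if (nrow(ab) == 0) ab <- tibble::as_tibble(anchors_base)
  if (nrow(at) == 0) at <- tibble::as_tibble(anchors_target)
  common <- intersect(ab$item, at$item)
  if (length(common) == 0) stop_input("no common anchor items between calibrations")
  ab <- ab[match(common, ab$item), ]
  at <- at[match(common, at$item), ]
  kb <- lengths(ab$thresholds)
  kt <- lengths(at$thresholds)
  if (!all(kb == kt)) {
    stop_input("anchor item category counts differ between calibrations: %s",
               paste(common[kb != kt], collapse = ", "))
  }
  b_base <- unlist(ab$thresholds)
  b_target <- unlist(at$thresholds)
  if (length(unique(b_target)) < 2 || length(unique(b_base)) < 2) {
    stop_input("fewer than 2 distinct anchor threshold values; scale undefined")
  }
  A <- sd(b_base) / sd(b_target)
  B <- mean(b_base) - A * mean(b_target)
  structure(list(A = A, B = B), class = "linking_constants")
}

#' @export
print.linking_constants <- function(x, ...) {
  cat(sprintf("mean/sigma linking constants: A = %.4f, B = %.4f\n", x$A, x$B))
  invisible(x)
}

#' Apply linking constants to a GRM calibration
#'
#' @param grm A [grm_parameters()] object.
#' @param link [mean_sigma_link()] constants.
#' @return The transformed `grm_parameters` (`b* = A*b + B`, `a* = a/A`).
#' @export
apply_linking <- function(grm, link) {
  stopifnot(inherits(link, "linking_constants"))
  grm_parameters(grm$item, grm$a / link$A,
                 lapply(grm$thresholds, function(b) link$A * b + link$B),
                 anchor = grm$anchor)
}

#' Build a total-score crosswalk by true-score equating
#'
#' For each integer total score `s` on the source instrument, the source
#' test characteristic curve (TCC; the monotone sum of item expected
#' scores) is inverted by bisection to find the latent value `theta_s`,
#' and the equated score is the target TCC at `theta_s`, rounded half-up.
#' Endpoints are pinned (`0 -> 0`, source max -> target max) and the
#' table is forced monotone non-decreasing. Scores below the source
#' TCC's floor are clamped to the boundary.
#'
#' @param grm_source GRM calibration of the source instrument, already
#'   transformed onto the base metric (see [apply_linking()]). Anchor
#'   items are excluded from the score range.
#' @param grm_target GRM calibration of the target instrument on its own
#'   (base) metric.
#' @param source_instrument,target_instrument Labels for the result.
#'
#' @return A [new_crosswalk()] tibble covering the full source range.
#' @export
build_crosswalk <- function(grm_source, grm_target,
                            source_instrument = "HADS",
                            target_instrument = "BDI") {
  src <- dplyr::filter(tibble::as_tibble(grm_source), !.data$anchor)
  tgt <- dplyr::filter(tibble::as_tibble(grm_target), !.data$anchor)
  s_max <- sum(lengths(src$thresholds))
  t_max <- sum(lengths(tgt$thresholds))
  tcc_s <- function(th) test_characteristic_curve(src, th)
  tcc_t <- function(th) test_characteristic_curve(tgt, th)
  lo <- -10
  hi <- 10
  equated <- integer(s_max + 1)
  equated[1] <- 0L
  equated[s_max + 1] <- as.integer(t_max)
  if (s_max >= 2) {
    for (s in 1:(s_max - 1)) {
      f <- function(th) tcc_s(th) - s
      if (f(lo) >= 0) {
        theta_s <- lo          # sub-floor score: clamp to boundary
      } else if (f(hi) <= 0) {
        theta_s <- hi
      } else {
        theta_s <- uniroot(f, c(lo, hi), tol = 1e-8)$root
      }
      equated[s + 1] <- as.integer(
        min(max(round_half_up(tcc_t(theta_s)), 0), t_max))
    }
  }
  equated <- as.integer(cummax(equated))
  new_crosswalk(0:s_max, equated, source_instrument, target_instrument)
}
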