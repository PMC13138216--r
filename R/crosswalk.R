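#' Construct a total-score crosswalk between two instruments
#'
#' A crosswalk maps every achievable total score on a source instrument to
#' an equated total score on a target instrument (e.g. HADS depression
#' 0-21 onto BDI-II 0-63). It is stored as a tibble with one row per
#' source score.
#'
#' @param source_score Integer vector covering the full source range with
#'   no gaps.
#' @param equated_score Integer vector of equated target scores,
#'   non-decreasing in `source_score`.
#' @param source_instrument,target_instrument Instrument labels.
#' @param method Equating method tag (e.g. `"mean-sigma/true-score"`).
#'
#' @return A tibble of class `crosswalk` with columns `source_score` and
#'   `equated_score`.
#' @export
new_crosswalk <- function(source_score, equated_score,
                          source_instrument = "HADS",
                          target_instrument = "BDI",
                          method = "mean-sigma/true-score") {
  source_score <- as.integer(source_score)
  equated_score <- as.integer(equated_score)
  if (length(source_score) != length(equated_score)) {
    stop_input("source and equated score vectors must have equal length")
  }
  o <- order(source_score)
  source_score <- source_score[o]
  equated_score <- equated_score[o]
  if (!identical(source_score, seq(min(source_score), max(source_score)))) {
    stop_input("crosswalk must cover the source score range with no gaps")
  }
  if (any(diff(equated_score) < 0)) {
    stop_input("equated scores must be non-decreasing in the source score")
  }
  out <- tibble::tibble(source_score = source_score,
                        equated_score = equated_score)
  class(out) <- c("crosswalk", class(out))
  attr(out, "source_instrument") <- source_instrument
  attr(out, "target_instrument") <- target_instrument
  attr(out, "method") <- method
  out
}

#' Look up equated scores in a crosswalk
#'
#' @param xwalk A [new_crosswalk()] object.
#' @param s Source score(s); must lie inside the crosswalk's source range.
#'
#' @return Integer vector of equated target scores.
#' @export
#'
#' @examples
#' xw <- hads_bdi_crosswalk()
#' equate_score(xw, 13)  # 20, the probable-MDD threshold
equate_score <- function(xwalk, s) {
  stopifnot(inherits(xwalk, "crosswalk"))
  s <- as.integer(s)
  lo <- min(xwalk$source_score)
  hi <- max(xwalk$source_score)
  check_range(s, lo, hi, "source score")
  xwalk$equated_score[match(s, xwalk$source_score)]
}

#' Reference HADS-to-BDI crosswalk
#'
#' The packaged reference table equating each HADS depression total score
#' (0-21) to a BDI-II total score (0-63), used for the harmonized
#' probable-MDD case rule (equated BDI >= 20, i.e. HADS >= 13).
#'
#' @return A `crosswalk` tibble with 22 rows.
#' @export
hads_bdi_crosswalk <- function() {
  path <- system.file("extdata", "hads_bdi_crosswalk.csv",
                      package = "traumameta", mustWork = TRUE)
  read_crosswalk(path, source_instrument = "HADS", target_instrument = "BDI")
}

#' Read / write crosswalk CSV files
#'
#' Crosswalks are serialized as a two-column CSV
#' (`source_score, equated_score`); comment lines starting with `#` are
#' ignored.
#'
#' @param path File path.
#' @param source_instrument,target_instrument Instrument labels attached
#'   to the object on read.
#' @return `read_crosswalk()` returns a `crosswalk`;
#'   `write_crosswalk()` returns `path` invisibly.
#' @export
read_crosswalk <- function(path, source_instrument = "HADS",
                           target_instrument = "BDI") {
  df <- utils::read.csv(path, comment.char = "#")
  new_crosswalk(df$source_score, df$equated_score,
                source_instrument = source_instrument,
                target_instrument = target_instrument)
}

#' @rdname read_crosswalk
#' @param xwalk A `crosswalk` object.
#' @export
write_crosswalk <- function(xwalk, path) {
  stopifnot(inherits(xwalk, "crosswalk"))
  utils::write.csv(as.data.frame(xwalk)[, c("source_score", "equated_score")],
                   path, row.names = FALSE)
  invisible(path)
}
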