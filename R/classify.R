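## DSM-IV CAPS scoring, probable-MDD classification, trajectory labels,
## and covariate harmonization.

CAPS_B_ITEMS <- 1:5    # reexperiencing
CAPS_C_ITEMS <- 6:12   # avoidance
CAPS_D_ITEMS <- 13:17  # hyperarousal

caps_freq_cols <- function() sprintf("caps_f%02d", 1:17)
caps_int_cols <- function() sprintf("caps_i%02d", 1:17)

#' Score CAPS records into DSM-IV PTSD severities and diagnoses
#'
#' Each of the 17 DSM-IV PTSD symptoms is rated for frequency (0-4) and
#' intensity (0-4). Severity is the sum of frequency and intensity over
#' all items (range 0-136), with cluster severities for criterion B
#' (reexperiencing, items 1-5), C (avoidance, items 6-12) and D
#' (hyperarousal, items 13-17). A symptom is present when frequency >= 1
#' and intensity >= 2; the diagnosis requires at least 1 B, 3 C and 2 D
#' symptoms. Criteria E/F (duration, impairment) are not evaluated.
#'
#' @param data Data frame with columns `caps_f01`..`caps_f17` and
#'   `caps_i01`..`caps_i17`, one row per assessment. Rows with any missing
#'   item get `NA` scores (missing items are handled upstream by
#'   imputation, not here).
#'
#' @return `data` with columns added: `ptsd_severity` (0-136),
#'   `ptsd_sev_b`, `ptsd_sev_c`, `ptsd_sev_d`, `ptsd_n_b`, `ptsd_n_c`,
#'   `ptsd_n_d` (present-symptom counts) and `ptsd_dx` (logical).
#' @export
#'
#' @examples
#' rec <- tibble::as_tibble(setNames(as.list(rep(0, 34)),
#'   c(sprintf("caps_f%02d", 1:17), sprintf("caps_i%02d", 1:17))))
#' score_caps(rec)$ptsd_dx  # FALSE
score_caps <- function(data) {
  fc <- caps_freq_cols()
  ic <- caps_int_cols()
  missing_cols <- setdiff(c(fc, ic), names(data))
  if (length(missing_cols) > 0) {
    stop_input("missing CAPS columns: %s", paste(missing_cols, collapse = ", "))
  }
  fmat <- as.matrix(data[, fc])
  imat <- as.matrix(data[, ic])
  for (j in 1:17) {
    check_range(fmat[, j], 0, 4, sprintf("CAPS frequency, symptom %d", j))
    check_range(imat[, j], 0, 4, sprintf("CAPS intensity, symptom %d", j))
  }
  sev <- fmat + imat
  present <- (fmat >= 1) & (imat >= 2)
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    ptsd_sev_b = rowSums(sev[, CAPS_B_ITEMS, drop = FALSE]),
    ptsd_sev_c = rowSums(sev[, CAPS_C_ITEMS, drop = FALSE]),
    ptsd_sev_d = rowSums(sev[, CAPS_D_ITEMS, drop = FALSE]),
    ptsd_severity = .data$ptsd_sev_b + .data$ptsd_sev_c + .data$ptsd_sev_d,
    ptsd_n_b = rowSums(present[, CAPS_B_ITEMS, drop = FALSE]),
    ptsd_n_c = rowSums(present[, CAPS_C_ITEMS, drop = FALSE]),
    ptsd_n_d = rowSums(present[, CAPS_D_ITEMS, drop = FALSE]),
    ptsd_dx = .data$ptsd_n_b >= 1 & .data$ptsd_n_c >= 3 & .data$ptsd_n_d >= 2
  )
  out
}

#' Classify probable MDD from a depression total score
#'
#' BDI-II totals are compared against the moderate-severity threshold of
#' 20. HADS depression totals are first equated onto the BDI metric
#' through a crosswalk and the same BDI >= 20 rule applied (equivalent to
#' HADS >= 13 under the packaged reference crosswalk).
#'
#' @param score Numeric vector of instrument total scores (BDI 0-63,
#'   HADS 0-21). `NA` propagates.
#' @param instrument `"BDI"` or `"HADS"` (scalar or vector).
#' @param xwalk Crosswalk used for HADS scores; defaults to the packaged
#'   reference crosswalk.
#' @param threshold Equated-BDI case threshold (default 20).
#'
#' @return A tibble with columns `equated_severity` (BDI metric) and
#'   `probable_mdd` (logical).
#' @export
classify_mdd <- function(score, instrument, xwalk = hads_bdi_crosswalk(),
                         threshold = 20) {
  instrument <- rep_len(as.character(instrument), length(score))
  bad <- setdiff(unique(instrument), c("BDI", "HADS"))
  if (length(bad) > 0) stop_input("unknown instrument: %s", bad[1])
  check_range(score[instrument == "BDI"], 0, 63, "BDI score")
  check_range(score[instrument == "HADS"], 0, 21, "HADS score")
  equated <- as.numeric(score)
  h <- which(instrument == "HADS" & !is.na(score))
  if (length(h) > 0) equated[h] <- equate_score(xwalk, score[h])
  tibble::tibble(equated_severity = equated,
                 probable_mdd = equated >= threshold)
}

#' Assign never/acute/persistent trajectory labels
#'
#' Diagnosis status at the acute wave (0-60 days post-trauma) and the
#' persistent wave (122-456 days) maps to: both waves -> `Persistent`,
#' acute only -> `Acute`, neither -> `Never`, follow-up only ->
#' `Delayed`, missing follow-up -> `Unclassifiable`. `Delayed` and
#' `Unclassifiable` are bookkeeping categories excluded from the primary
#' models.
#'
#' @param dx1 Logical, diagnosis at wave 1.
#' @param dx2 Logical, diagnosis at wave 2 (`NA` when unobserved).
#' @param day1,day2 Days since trauma of each wave; validated against the
#'   windows `[0, 60]` and `[122, 456]` when supplied.
#'
#' @return Factor with levels `Never`, `Acute`, `Persistent`, `Delayed`,
#'   `Unclassifiable`.
#' @export
assign_trajectory <- function(dx1, dx2, day1 = NULL, day2 = NULL) {
  if (any(is.na(dx1))) stop_input("wave-1 diagnosis must be observed")
  if (!is.null(day1)) check_range(day1, 0, 60, "wave-1 day since trauma")
  if (!is.null(day2)) check_range(day2[!is.na(dx2)], 122, 456,
                                  "wave-2 day since trauma")
  lab <- dplyr::case_when(
    is.na(dx2) ~ "Unclassifiable",
    dx1 & dx2 ~ "Persistent",
    dx1 & !dx2 ~ "Acute",
    !dx1 & dx2 ~ "Delayed",
    TRUE ~ "Never"
  )
  factor(lab, levels = trajectory_levels())
}

#' @rdname assign_trajectory
#' @export
trajectory_levels <- function() {
  c("Never", "Acute", "Persistent", "Delayed", "Unclassifiable")
}

#' Harmonize study-specific covariate codings into the shared risk-factor set
#'
#' Maps raw per-study codes onto the seven harmonized baseline risk
#' factors: age (years), female, single/not-cohabiting, below-secondary
#' education, prior-trauma category (`none`, `non-interpersonal`,
#' `interpersonal`) and index-trauma category (`MVA`, `other_accident`,
#' `assault`). A participant reporting several prior traumas is
#' `interpersonal` if any of them is interpersonal, else
#' `non-interpersonal`; no reported prior trauma is `none`.
#'
#' @param raw Data frame with columns `age`, `marital`, `education`,
#'   `index_trauma` plus a list- or delimiter-separated character column
#'   `prior_traumas` of reported prior trauma types.
#' @param dictionary Named list of named character vectors mapping raw
#'   codes to harmonized codes for `marital`, `education`, `index_trauma`
#'   and `prior_trauma_type`; defaults cover the common literals.
#'
#' @return Tibble with columns `age`, `female`, `single`, `low_education`,
#'   `prior_trauma`, `index_trauma`.
#' @export
harmonize_covariates <- function(raw, dictionary = default_dictionary()) {
  map_code <- function(x, field) {
    d <- dictionary[[field]]
    x <- as.character(x)
    unknown <- setdiff(unique(x[!is.na(x)]), names(d))
    if (length(unknown) > 0) {
      stop_input("unmapped %s code(s): %s", field,
                 paste(unknown, collapse = ", "))
    }
    unname(d[x])
  }
  prior <- raw$prior_traumas
  if (!is.list(prior)) prior <- strsplit(as.character(prior %||% ""), ";")
  prior_cat <- vapply(prior, function(p) {
    p <- p[!is.na(p) & nzchar(p)]
    if (length(p) == 0) return("none")
    types <- map_code(p, "prior_trauma_type")
    if (any(types == "interpersonal")) "interpersonal" else "non-interpersonal"
  }, character(1))
  tibble::tibble(
    age = as.numeric(raw$age),
    female = map_code(raw$sex, "sex") == "female",
    single = map_code(raw$marital, "marital") == "single",
    low_education = map_code(raw$education, "education") == "below_secondary",
    prior_trauma = factor(prior_cat,
                          levels = c("none", "non-interpersonal",
                                     "interpersonal")),
    index_trauma = factor(map_code(raw$index_trauma, "index_trauma"),
                          levels = c("MVA", "other_accident", "assault"))
  )
}

#' @rdname harmonize_covariates
#' @export
default_dictionary <- function() {
  list(
    sex = c(male = "male", female = "female", M = "male", F = "female"),
    marital = c(married = "married", cohabitating = "married",
                cohabiting = "married", partnered = "married",
                single = "single", divorced = "single", widowed = "single",
                separated = "single", never_married = "single"),
    education = c(secondary = "secondary", tertiary = "secondary",
                  university = "secondary", completed_secondary = "secondary",
                  primary = "below_secondary", none = "below_secondary",
                  below_secondary = "below_secondary"),
    index_trauma = c(MVA = "MVA", mva = "MVA", motor_vehicle = "MVA",
                     other_accident = "other_accident", fall = "other_accident",
                     work_accident = "other_accident", assault = "assault",
                     terror = "assault", violence = "assault"),
    prior_trauma_type = c(accident = "non-interpersonal",
                          disaster = "non-interpersonal",
                          illness = "non-interpersonal",
                          mva = "non-interpersonal",
                          combat = "interpersonal",
                          assault = "interpersonal",
                          abuse = "interpersonal",
                          ipv = "interpersonal")
  )
}

#' Score a cohort's item responses (long, per participant-wave)
#'
#' Computes CAPS severities and DSM-IV diagnoses and equated depression
#' severities / probable-MDD flags for every observed assessment,
#' returning the long analysis table (one row per participant-wave) used
#' by the imputation stage.
#'
#' @inheritParams classify_cohort
#' @return Tibble with identifiers, covariates, wave timing and columns
#'   `ptsd_severity`, `ptsd_sev_b/c/d`, `ptsd_dx`, `dep_raw`,
#'   `dep_severity` (equated-BDI metric), `mdd_dx`; unobserved
#'   assessments are `NA`.
#' @export
score_cohort <- function(cohort, xwalk = hads_bdi_crosswalk()) {
  scored <- score_caps(cohort)
  dep_raw <- dplyr::coalesce(rowSums(cohort[, sprintf("bdi_%02d", 1:21)]),
                             rowSums(cohort[, sprintf("hads_%d", 1:7)]))
  mdd <- classify_mdd(dep_raw, cohort$instrument, xwalk = xwalk)
  dplyr::mutate(
    scored,
    dep_raw = dep_raw,
    dep_severity = mdd$equated_severity,
    mdd_dx = mdd$probable_mdd,
    ptsd_severity = ifelse(.data$obs_ptsd, .data$ptsd_severity, NA_real_),
    ptsd_sev_b = ifelse(.data$obs_ptsd, .data$ptsd_sev_b, NA_real_),
    ptsd_sev_c = ifelse(.data$obs_ptsd, .data$ptsd_sev_c, NA_real_),
    ptsd_sev_d = ifelse(.data$obs_ptsd, .data$ptsd_sev_d, NA_real_),
    ptsd_dx = ifelse(.data$obs_ptsd, .data$ptsd_dx, NA),
    dep_severity = ifelse(.data$obs_dep, .data$dep_severity, NA_real_),
    mdd_dx = ifelse(.data$obs_dep, .data$mdd_dx, NA)
  ) |>
    dplyr::select(dplyr::all_of(c(
      "study_id", "participant_id", "wave", "days_since_trauma", "instrument",
      "age", "female", "single", "low_education", "prior_trauma",
      "index_trauma", "ptsd_severity", "ptsd_sev_b", "ptsd_sev_c",
      "ptsd_sev_d", "ptsd_dx", "dep_raw", "dep_severity", "mdd_dx",
      "obs_dep", "obs_ptsd")))
}

#' Classify a cohort into the wide per-participant analysis table
#'
#' Scores CAPS into DSM-IV PTSD severities/diagnoses and depression
#' totals into harmonized (equated-BDI) severities and probable-MDD flags
#' at both waves, then assigns never/acute/persistent trajectory labels
#' per disorder. Unobserved wave-2 assessments yield `NA` severities and
#' `Unclassifiable` labels (resolved downstream per imputed dataset).
#'
#' @param cohort A [generate_cohort()]-shaped tibble (one row per
#'   participant-wave).
#' @param xwalk Crosswalk for HADS equating; default the packaged
#'   reference crosswalk.
#'
#' @return Wide tibble, one row per participant: identifiers, covariates,
#'   `day1`/`day2`, per-wave PTSD severities (total and B/C/D clusters),
#'   equated depression severities, diagnosis flags and
#'   `ptsd_trajectory` / `mdd_trajectory` factors.
#' @export
classify_cohort <- function(cohort, xwalk = hads_bdi_crosswalk()) {
  pivot_classified(score_cohort(cohort, xwalk = xwalk))
}

# long scored table -> wide per-participant table with trajectory labels
pivot_classified <- function(scored) {
  keep <- c("ptsd_severity", "ptsd_sev_b", "ptsd_sev_c", "ptsd_sev_d",
            "dep_severity", "ptsd_dx", "mdd_dx", "days_since_trauma")
  wide <- scored |>
    dplyr::select(dplyr::all_of(c("study_id", "participant_id", "wave",
                                  "instrument", "age", "female", "single",
                                  "low_education", "prior_trauma",
                                  "index_trauma", keep))) |>
    tidyr::pivot_wider(names_from = "wave",
                       values_from = dplyr::all_of(keep),
                       names_sep = "_w")
  wide <- dplyr::rename(wide, day1 = "days_since_trauma_w1",
                        day2 = "days_since_trauma_w2")
  dplyr::mutate(
    wide,
    ptsd_trajectory = assign_trajectory(.data$ptsd_dx_w1, .data$ptsd_dx_w2,
                                        .data$day1, .data$day2),
    mdd_trajectory = assign_trajectory(.data$mdd_dx_w1, .data$mdd_dx_w2,
                                       .data$day1, .data$day2)
  )
}

#' Impute a scored cohort and re-derive trajectories per completed dataset
#'
#' Runs chained-equation imputation on the long (participant-wave)
#' analysis table -- severities as continuous targets, diagnosis flags as
#' binary probit targets, study fixed dummies and a participant random
#' intercept in every conditional model -- then reassembles each completed
#' dataset into the wide per-participant table with never/acute/persistent
#' labels re-derived from the completed diagnosis flags.
#'
#' @param x A [generate_cohort()] tibble or a [score_cohort()] long table.
#' @param spec [imputation_spec()].
#' @param xwalk Crosswalk for HADS equating (used only when `x` is a raw
#'   cohort).
#'
#' @return An `imputed_datasets` object whose `imputations` are wide
#'   classified tables (no `Unclassifiable` labels remain).
#' @export
impute_cohort <- function(x, spec = imputation_spec(), xwalk = hads_bdi_crosswalk()) {
  scored <- if ("caps_f01" %in% names(x)) score_cohort(x, xwalk = xwalk) else x
  long <- dplyr::select(scored, -dplyr::any_of(c("dep_raw", "obs_dep",
                                                 "obs_ptsd", "instrument")))
  imp <- run_mice(
    long, spec, id_col = "participant_id", study_col = "study_id",
    # cluster severities are exactly collinear with the total and only the
    # (complete) acute-wave values enter any model: keep them out of the
    # imputation system entirely
    exclude = c("ptsd_sev_b", "ptsd_sev_c", "ptsd_sev_d"),
    # a diagnosis flag is (nearly) deterministic in its own severity, which
    # would separate the probit; impute flags from the other disorder and
    # the covariates instead
    drop_predictors = list(mdd_dx = "dep_severity",
                           ptsd_dx = "ptsd_severity")
  )
  instr <- scored[, c("participant_id", "wave", "instrument")]
  imp$imputations <- lapply(imp$imputations, function(d) {
    d$instrument <- instr$instrument
    pivot_classified(d)
  })
  imp
}
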