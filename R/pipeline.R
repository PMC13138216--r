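## Declarative end-to-end pipeline: generate -> equate -> classify ->
## impute -> model -> calibrate, with deterministic per-stage seeding and
## CSV/JSON artifacts.

default_config_list <- function() {
  list(
    seed = 1L,
    studies = "icpp",            # "icpp" or a list of study_config fields
    generator = list(trajectory_model = "multinomial",
                     missing_mechanism = "MCAR"),
    stages = list(equate = TRUE, classify = TRUE, impute = TRUE,
                  model = TRUE, calibrate = TRUE),
    equating = list(use_packaged_crosswalk = TRUE, cfa = FALSE),
    imputation = list(m = 5L, cycles = 5L, threshold = 0.10,
                      engine = "mixed"),
    models = list(disorders = c("ptsd", "mdd"), persistence_models = 1:3,
                  lrt_predictors = c("female")),
    calibration = list(B = 100L, models = c("fixed", "random"), nAGQ = 5L),
    window = c(122, 456)
  )
}

#' Validate a pipeline configuration
#'
#' Parses YAML/JSON text or takes a list, fills defaults, and rejects
#' unknown keys (suggesting the nearest valid key).
#'
#' @param config `NULL` (all defaults), a named list, or a path to / text
#'   of a YAML or JSON configuration.
#'
#' @return Validated configuration list of class `run_config`.
#' @export
validate_config <- function(config = NULL) {
  defaults <- default_config_list()
  raw <- if (is.null(config)) {
    list()
  } else if (is.list(config)) {
    config
  } else if (is.character(config) && length(config) == 1) {
    txt <- if (file.exists(config)) paste(readLines(config), collapse = "\n")
    else config
    if (grepl("^\\s*\\{", txt)) jsonlite::fromJSON(txt, simplifyVector = TRUE)
    else yaml::yaml.load(txt) %||% list()
  } else {
    stop_input("config must be NULL, a list, or YAML/JSON text")
  }

  check_keys <- function(supplied, allowed, path = "") {
    unknown <- setdiff(names(supplied), allowed)
    if (length(unknown) > 0) {
      key <- unknown[1]
      dist <- adist(key, allowed)
      hint <- if (min(dist) <= 3) {
        sprintf(' (did you mean "%s"?)', allowed[which.min(dist)])
      } else ""
      stop_input('unknown configuration key "%s%s"%s', path, key, hint)
    }
  }
  check_keys(raw, names(defaults))
  merged <- utils::modifyList(defaults, raw)
  for (sec in c("generator", "stages", "equating", "imputation", "models",
                "calibration")) {
    if (!is.null(raw[[sec]])) {
      check_keys(raw[[sec]], names(defaults[[sec]]), paste0(sec, "."))
    }
  }
  if (merged$imputation$m < 2) stop_input("imputation.m must be >= 2")
  if (merged$imputation$cycles < 1) stop_input("imputation.cycles must be >= 1")
  if (merged$calibration$B < 1) stop_input("calibration.B must be >= 1")
  if (length(merged$window) != 2 || merged$window[1] > merged$window[2]) {
    stop_input("window must be an increasing day pair")
  }
  merged$seed <- as.integer(merged$seed)
  class(merged) <- c("run_config", class(merged))
  merged
}

config_checksum <- function(config) {
  x <- unclass(config)
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  # small deterministic polynomial digest so table headers can carry it
  h <- Reduce(function(acc, b) (acc * 31 + b) %% 2147483647,
              as.numeric(utf8ToInt(txt)), accumulate = FALSE, init = 7)
  sprintf("%08x", as.integer(h))
}

write_artifact <- function(df, path, checksum) {
  con <- file(path, "w")
  writeLines(sprintf("# config_checksum: %s", checksum), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  close(con)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates cohort generation, IRT equating, classification,
#' multilevel multiple imputation, pooled risk-factor models with
#' constrained LRTs, persistence models 1-3, and bootstrap calibration
#' diagnostics, writing CSV artifacts plus a JSON manifest (with per-file
#' checksums) to `out_dir`. All stage seeds derive deterministically from
#' the master seed, so identical configurations reproduce identical
#' manifests.
#'
#' @param config See [validate_config()].
#' @param out_dir Output directory.
#'
#' @return Invisibly, a list with the in-memory results per stage and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("traumameta_run_")) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checksum <- config_checksum(config)
  results <- list(config = config)
  artifacts <- character(0)
  stage <- function(name, enabled, fn) {
    if (!enabled) return(NULL)
    tryCatch(fn(), error = function(e) {
      writeLines(sprintf("stage %s FAILED: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop_input("pipeline stage %s failed: %s", name, conditionMessage(e))
    })
  }

  configs <- if (identical(config$studies, "icpp")) icpp_study_configs()
  else lapply(config$studies, function(s) do.call(study_config, s))
  params <- do.call(generative_params, config$generator)

  cohort <- stage("simulate", TRUE, function() {
    generate_cohort(configs, params, seed = derive_seed(config$seed, "simulate"))
  })
  if (!identical(as.numeric(config$window), c(122, 456))) {
    w2 <- cohort$wave == 2L
    outside <- w2 & (cohort$days_since_trauma < config$window[1] |
                       cohort$days_since_trauma > config$window[2])
    cohort$obs_dep[outside] <- FALSE
    cohort$obs_ptsd[outside] <- FALSE
  }
  results$cohort <- cohort

  equating <- stage("equate", isTRUE(config$stages$equate), function() {
    equate_cohort(cohort, cfa = isTRUE(config$equating$cfa))
  })
  results$equating <- equating
  xwalk <- if (isTRUE(config$equating$use_packaged_crosswalk) ||
                 is.null(equating)) {
    hads_bdi_crosswalk()
  } else equating$crosswalk
  if (!is.null(equating)) {
    artifacts <- c(artifacts, write_artifact(
      tibble::as_tibble(equating$crosswalk),
      file.path(out_dir, "crosswalk.csv"), checksum))
  }

  classified <- stage("classify", isTRUE(config$stages$classify), function() {
    classify_cohort(cohort, xwalk = xwalk)
  })
  results$classified <- classified
  if (!is.null(classified)) {
    artifacts <- c(artifacts, write_artifact(
      classified, file.path(out_dir, "classified.csv"), checksum))
    for (dz in config$models$disorders) {
      artifacts <- c(artifacts, write_artifact(
        describe_groups(classified, dz),
        file.path(out_dir, sprintf("descriptives_%s.csv", dz)), checksum))
    }
  }

  imputed <- stage("impute", isTRUE(config$stages$impute), function() {
    spec <- imputation_spec(m = config$imputation$m,
                            cycles = config$imputation$cycles,
                            threshold = config$imputation$threshold,
                            engine = config$imputation$engine,
                            seed = derive_seed(config$seed, "impute"))
    impute_cohort(cohort, spec = spec, xwalk = xwalk)
  })
  results$imputed <- imputed
  if (!is.null(imputed)) {
    write_imputations(imputed, file.path(out_dir, "imputations"))
  }

  if (isTRUE(config$stages$model) && !is.null(imputed)) {
    results$models <- stage("model", TRUE, function() {
      out <- list()
      for (dz in config$models$disorders) {
        out[[dz]] <- list(
          multinomial = fit_risk_multinomial(imputed, dz),
          lrt = mi_constrained_lrt(
            imputed, paste0(dz, "_trajectory"), RISK_FACTORS,
            test_predictors = config$models$lrt_predictors),
          persistence = fit_persistence_logistic(
            imputed, dz, models = config$models$persistence_models))
      }
      out
    })
    for (dz in names(results$models)) {
      artifacts <- c(artifacts,
        write_artifact(results$models[[dz]]$multinomial,
                       file.path(out_dir, sprintf("or_multinomial_%s.csv", dz)),
                       checksum),
        write_artifact(results$models[[dz]]$lrt,
                       file.path(out_dir, sprintf("lrt_%s.csv", dz)), checksum),
        write_artifact(results$models[[dz]]$persistence,
                       file.path(out_dir, sprintf("or_persistence_%s.csv", dz)),
                       checksum))
    }
  }

  if (isTRUE(config$stages$calibrate) && !is.null(imputed)) {
    results$calibration <- stage("calibrate", TRUE, function() {
      purrr::map_dfr(config$models$disorders, function(dz) {
        bootstrap_calibration(imputed, dz,
                              model = config$calibration$models,
                              B = config$calibration$B,
                              seed = derive_seed(config$seed, "calibrate"),
                              nAGQ = config$calibration$nAGQ)
      })
    })
    artifacts <- c(artifacts, write_artifact(
      results$calibration, file.path(out_dir, "calibration.csv"), checksum))
  }

  manifest <- list(
    config = unclass(config),
    config_checksum = checksum,
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, "simulate"),
                       impute = derive_seed(config$seed, "impute"),
                       calibrate = derive_seed(config$seed, "calibrate")),
    n_participants = if (!is.null(classified)) nrow(classified) else NA,
    artifacts = lapply(setNames(artifacts, basename(artifacts)),
                       function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  results$out_dir <- out_dir
  invisible(results)
}
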