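## Synthetic multi-study cohort generator. Emulates a pool of prospective
## emergency-room / critical-care studies with two assessment waves
## (acute: 0-60 days post-trauma; persistent: 122-456 days), instrument
## assignment (BDI vs HADS by study), item-level responses driven by
## correlated latent severities, covariate-dependent trajectory classes,
## and configurable wave-2 missingness.

#' Study-level configuration for the cohort generator
#'
#' @param study_id Study label.
#' @param n_participants Number of participants (>= 1).
#' @param instrument Depression instrument, `"BDI"` or `"HADS"`.
#' @param setting Recruitment setting label (e.g. `"ER"`, `"CCU"`).
#' @param acute_day_mean,acute_day_sd Days-since-trauma distribution of
#'   the acute assessment; draws truncated to `[0, 60]`.
#' @param persistent_day_mean,persistent_day_sd Same for the follow-up
#'   assessment; truncated to `[122, 456]`.
#' @param followup_rate Proportion of participants with an observed
#'   follow-up, in (0, 1].
#' @param mva_only All index traumas are motor vehicle accidents (used
#'   for critical-care motor-vehicle cohorts).
#'
#' @return List of class `study_config`.
#' @export
study_config <- function(study_id, n_participants, instrument = c("BDI", "HADS"),
                         setting = "ER",
                         acute_day_mean = 20, acute_day_sd = 10,
                         persistent_day_mean = 250, persistent_day_sd = 70,
                         followup_rate = 0.75, mva_only = FALSE) {
  instrument <- match.arg(instrument)
  if (n_participants < 1) stop_input("n_participants must be >= 1 (%s)", study_id)
  if (followup_rate <= 0 || followup_rate > 1) {
    stop_input("followup_rate must be in (0, 1] (%s)", study_id)
  }
  structure(list(study_id = study_id,
                 n_participants = as.integer(n_participants),
                 instrument = instrument, setting = setting,
                 acute_day_mean = acute_day_mean, acute_day_sd = acute_day_sd,
                 persistent_day_mean = persistent_day_mean,
                 persistent_day_sd = persistent_day_sd,
                 followup_rate = followup_rate, mva_only = mva_only),
            class = "study_config")
}

#' Default five-study configuration
#'
#' Study sizes, instruments, settings, assessment-timing distributions and
#' follow-up rates of the five-study emergency-room/critical-care pool the
#' generator emulates (total N = 2571).
#'
#' @return List of five [study_config()] objects.
#' @export
icpp_study_configs <- function() {
  list(
    study_config("multisite_asd", 1082, "HADS", "ER", 6.8, 7.1, 366.8, 46.7, 0.764),
    study_config("hadassah_startle", 118, "BDI", "ER", 37.6, 9.2, 153.3, 38.2, 0.873),
    study_config("jtops", 735, "BDI", "ER", 19.4, 5.2, 201.5, 77.0, 0.720),
    study_config("tcom", 155, "HADS", "CCU", 38.9, 6.1, 201.0, 28.5, 0.594,
                 mva_only = TRUE),
    study_config("amsterdam_cortisol", 481, "HADS", "ER", 42.1, 8.6, 327.0, 95.4,
                 0.726)
  )
}

#' Default graded-response item bank for the generator
#'
#' 21 BDI and 7 HADS items (categories 0-3) on the depression trait, and
#' 17 CAPS symptoms x (frequency, intensity) items (categories 0-4) on
#' the PTSD trait -- except the three depression-overlap anchor symptoms
#' (C4 = item 9, diminished interest; D1 = item 13, sleep; D3 = item 15,
#' concentration), which load on the depression trait and carry a higher
#' discrimination (1.5) to stabilize linking. Discriminations are
#' log-normal(0, 0.3); thresholds are sorted normal draws with a minimum
#' spacing of 0.15. The bank is deterministic (fixed internal seed).
#'
#' @return A [grm_parameters()] tibble with a `trait` column (`"dep"` or
#'   `"ptsd"`).
#' @export
default_item_bank <- function() {
  with_seed(104729, {
    draw_thresh <- function(k, mean, sd) {
      b <- sort(rnorm(k, mean, sd))
      b + cumsum(c(0, pmax(0.15 - diff(b), 0)))
    }
    mk <- function(labels, k, mean, sd, a = NULL) {
      n <- length(labels)
      grm_parameters(labels,
                     a %||% exp(rnorm(n, 0, 0.3)),
                     lapply(seq_len(n), function(i) draw_thresh(k, mean, sd)))
    }
    bdi <- mk(sprintf("bdi_%02d", 1:21), 3, 1.3, 0.9)
    hads <- mk(sprintf("hads_%d", 1:7), 3, 1.3, 0.9)
    # align the instruments' probable-MDD thresholds on the latent trait:
    # shift HADS thresholds so the theta at which the HADS expected total
    # reaches 13 equals the theta at which the BDI expected total reaches
    # 20 (real HADS totals saturate faster than BDI totals)
    t_bdi <- uniroot(function(th) test_characteristic_curve(bdi, th) - 20,
                     c(-6, 6))$root
    t_hads <- uniroot(function(th) test_characteristic_curve(hads, th) - 13,
                      c(-6, 6))$root
    hads$thresholds <- lapply(hads$thresholds, function(b) b + t_bdi - t_hads)
    anchors <- c(9, 13, 15)
    cf <- mk(caps_freq_cols(), 4, 1.5, 1.0)
    ci <- mk(caps_int_cols(), 4, 1.5, 1.0)
    cf$a[anchors] <- 1.5
    ci$a[anchors] <- 1.5
    bank <- dplyr::bind_rows(
      dplyr::mutate(bdi, trait = "dep"),
      dplyr::mutate(hads, trait = "dep"),
      dplyr::mutate(cf, trait = ifelse(seq_len(17) %in% anchors, "dep", "ptsd")),
      dplyr::mutate(ci, trait = ifelse(seq_len(17) %in% anchors, "dep", "ptsd"))
    )
    class(bank) <- c("grm_parameters", class(tibble::tibble()))
    bank
  })
}

#' Default covariate effects on trajectory class (log-odds)
#'
#' Log odds ratios linking the seven baseline risk factors to acute and
#' persistent class membership (vs never) per disorder. Defaults are the
#' published-effect-size regime the generator emulates: e.g. female ->
#' acute PTSD log(1.86), persistent PTSD log(2.14), acute MDD log(1.54),
#' persistent MDD log(1.48); accident index trauma protective
#' (OR 0.45-0.66), assault index trauma OR ~1.8 for PTSD; age ~0.99 per
#' year. Names: `female`, `age` (per year, centered at 38), `single`,
#' `low_education`, `prior_nonint`, `prior_int`, `index_other`,
#' `index_assault`.
#'
#' @return Nested list `list(ptsd = list(acute=, persistent=),
#'   mdd = list(acute=, persistent=))` of named numeric vectors.
#' @export
default_covariate_effects <- function() {
  list(
    ptsd = list(
      acute = c(female = log(1.86), age = log(0.99), index_other = log(0.55),
                index_assault = log(1.76), prior_nonint = log(0.68),
                prior_int = log(0.63)),
      persistent = c(female = log(2.14), age = log(0.99),
                     index_other = log(0.45), index_assault = log(1.78),
                     prior_nonint = log(0.80), prior_int = log(0.75))
    ),
    mdd = list(
      acute = c(female = log(1.54), age = log(0.99), index_other = log(0.60),
                index_assault = log(1.50), prior_nonint = log(0.85),
                prior_int = log(0.85)),
      persistent = c(female = log(1.48), age = log(0.99),
                     index_other = log(0.60), index_assault = log(1.50),
                     prior_nonint = log(0.85), prior_int = log(0.85))
    )
  )
}

#' Generative parameters for the synthetic cohort
#'
#' @param theta_study_shift Named numeric of per-study latent-trait
#'   offsets (default all 0).
#' @param theta_wave_corr Correlation between wave-1 and wave-2 latent
#'   traits, strictly inside (-1, 1). Default 0.7.
#' @param dep_ptsd_corr Correlation between the depression and PTSD
#'   latent severities, strictly inside (-1, 1). Default 0.6.
#' @param item_bank [grm_parameters()] with a `trait` column; default
#'   [default_item_bank()].
#' @param covariate_effects See [default_covariate_effects()].
#' @param class_intercepts Per-disorder log-odds intercepts for the
#'   acute / persistent / delayed classes versus never.
#' @param trajectory_model `"multinomial"` (classes drawn directly from a
#'   multinomial logit in the covariates; the stated odds ratios are the
#'   exact estimands of the downstream models) or `"severity"` (wave-1
#'   diagnosis from a logistic model in the covariates, persistence from
#'   a logistic model in the *realized* acute symptom severities; used
#'   for persistence-model recovery).
#' @param persistence Severity-mode persistence models: per disorder a
#'   list with `intercept`, `own` (log-odds per point of own acute
#'   severity on the harmonized scale), `other` (per point of the other
#'   disorder's severity), and optional named covariate log-odds.
#' @param missing_mechanism `"MCAR"` or `"MAR"` (missingness depending on
#'   covariates and wave-1 severity).
#' @param missing_rate Optional override of the wave-2 missingness rate
#'   (scalar, applied to both instruments in every study); by default the
#'   per-study rate is `1 - followup_rate` for the PTSD instrument with
#'   extra MDD-only missingness `mdd_extra_missing`.
#' @param mdd_extra_missing Extra MCAR missingness applied to the
#'   depression instrument on top of study follow-up loss (default 0.19,
#'   emulating the higher observed MDD attrition).
#'
#' @return List of class `generative_params`.
#' @export
generative_params <- function(theta_study_shift = NULL,
                              theta_wave_corr = 0.7,
                              dep_ptsd_corr = 0.6,
                              item_bank = default_item_bank(),
                              covariate_effects = default_covariate_effects(),
                              class_intercepts = list(
                                ptsd = c(acute = -1.9, persistent = -2.7,
                                         delayed = -5.0),
                                mdd = c(acute = -2.4, persistent = -3.2,
                                        delayed = -5.0)),
                              trajectory_model = c("multinomial", "severity"),
                              persistence = list(
                                ptsd = list(intercept = -1.5,
                                            own = log(1.15) / 15,
                                            other = log(1.17) / 5),
                                mdd = list(intercept = -1.2,
                                           own = log(1.13) / 5,
                                           other = log(1.15) / 15)),
                              missing_mechanism = c("MCAR", "MAR"),
                              missing_rate = NULL,
                              mdd_extra_missing = 0.19) {
  trajectory_model <- match.arg(trajectory_model)
  missing_mechanism <- match.arg(missing_mechanism)
  for (nm in c("theta_wave_corr", "dep_ptsd_corr")) {
    v <- get(nm)
    if (!is.finite(v) || abs(v) >= 1) {
      stop_input("%s must be strictly inside (-1, 1); got %s", nm, v)
    }
  }
  if (any(item_bank$a <= 0)) {
    stop_input("item bank discrimination must be positive (item %s)",
               item_bank$item[which(item_bank$a <= 0)[1]])
  }
  bad <- vapply(item_bank$thresholds, is.unsorted, logical(1), strictly = TRUE)
  if (any(bad)) {
    stop_input("item bank thresholds not strictly increasing (item %s)",
               item_bank$item[which(bad)[1]])
  }
  if (!is.null(missing_rate)) {
    check_range(missing_rate, 0, 1, "missing_rate")
  }
  structure(list(theta_study_shift = theta_study_shift,
                 theta_wave_corr = theta_wave_corr,
                 dep_ptsd_corr = dep_ptsd_corr, item_bank = item_bank,
                 covariate_effects = covariate_effects,
                 class_intercepts = class_intercepts,
                 trajectory_model = trajectory_model,
                 persistence = persistence,
                 missing_mechanism = missing_mechanism,
                 missing_rate = missing_rate,
                 mdd_extra_missing = mdd_extra_missing),
            class = "generative_params")
}

# design matrix of the harmonized risk factors used by the generator
risk_factor_design <- function(cov) {
  cbind(female = as.numeric(cov$female),
        age = cov$age - 38,
        single = as.numeric(cov$single),
        low_education = as.numeric(cov$low_education),
        prior_nonint = as.numeric(cov$prior_trauma == "non-interpersonal"),
        prior_int = as.numeric(cov$prior_trauma == "interpersonal"),
        index_other = as.numeric(cov$index_trauma == "other_accident"),
        index_assault = as.numeric(cov$index_trauma == "assault"))
}

lin_pred <- function(X, effects) {
  effects <- effects[names(effects) %in% colnames(X)]
  if (length(effects) == 0) return(rep(0, nrow(X)))
  drop(X[, names(effects), drop = FALSE] %*% effects)
}

# latent value at which the instrument's expected total crosses the
# probable-MDD threshold
dep_cutpoint <- function(bank, instrument) {
  items <- bank[bank$item %in%
                  (if (instrument == "BDI") sprintf("bdi_%02d", 1:21)
                   else sprintf("hads_%d", 1:7)), ]
  target <- if (instrument == "BDI") 20 else 13
  uniroot(function(th) test_characteristic_curve(items, th) - target,
          c(-6, 6), tol = 1e-6)$root
}

# latent value at which the expected CAPS present-symptom counts reach the
# diagnosis rule (1 B, 3 C, 2 D)
ptsd_cutpoint <- function(bank) {
  margin <- function(th) {
    pres <- vapply(1:17, function(s) {
      f <- bank[bank$item == sprintf("caps_f%02d", s), ]
      i <- bank[bank$item == sprintf("caps_i%02d", s), ]
      pf <- plogis(f$a[1] * (th - f$thresholds[[1]][1]))      # P(freq >= 1)
      pi <- plogis(i$a[1] * (th - i$thresholds[[1]][2]))      # P(int >= 2)
      pf * pi
    }, numeric(1))
    min(sum(pres[CAPS_B_ITEMS]) - 1, sum(pres[CAPS_C_ITEMS]) - 3,
        sum(pres[CAPS_D_ITEMS]) - 2)
  }
  uniroot(margin, c(-4, 5), tol = 1e-4)$root
}

# condition latent values on the diagnosis target: each person's latent
# quantile is mapped into the truncated-normal distribution on the
# required side of the cutpoint, preserving ranks (and hence the
# wave/disorder correlation structure)
condition_theta <- function(theta, cut, dx, mean = 0) {
  u <- pnorm(theta, mean, 1)
  p <- pnorm(cut, mean, 1)
  u2 <- ifelse(dx, p + u * (1 - p), u * p)
  qnorm(pmin(pmax(u2, 1e-10), 1 - 1e-10), mean, 1)
}

# responses for `items` at `theta` using the current RNG state
sim_grm <- function(theta, items) {
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
}

# depression item responses consistent with a target diagnosis flag
sim_dep_items <- function(theta, dx, bank, instrument) {
  labels <- if (instrument == "BDI") sprintf("bdi_%02d", 1:21) else sprintf("hads_%d", 1:7)
  thr <- if (instrument == "BDI") 20 else 13
  items <- bank[match(labels, bank$item), ]
  x <- sim_grm(theta, items)
  for (try in 1:40) {
    bad <- which((rowSums(x) >= thr) != dx)
    if (length(bad) == 0) break
    x[bad, ] <- sim_grm(theta[bad] + 0.15 * dx[bad] - 0.15 * (!dx[bad]), items)
  }
  bad <- which((rowSums(x) >= thr) != dx)
  for (i in bad) {   # deterministic fallback: nudge totals across the line
    if (dx[i]) {
      j <- 1
      while (sum(x[i, ]) < thr) {
        x[i, j] <- min(x[i, j] + 1L, 3L)
        j <- j %% ncol(x) + 1
      }
    } else {
      j <- 1
      while (sum(x[i, ]) >= thr) {
        x[i, j] <- max(x[i, j] - 1L, 0L)
        j <- j %% ncol(x) + 1
      }
    }
  }
  x
}

caps_dx_from_items <- function(f, i) {
  pres <- (f >= 1) & (i >= 2)
  rowSums(pres[, CAPS_B_ITEMS, drop = FALSE]) >= 1 &
    rowSums(pres[, CAPS_C_ITEMS, drop = FALSE]) >= 3 &
    rowSums(pres[, CAPS_D_ITEMS, drop = FALSE]) >= 2
}

# CAPS frequency/intensity responses consistent with a target diagnosis.
# Anchor symptoms load on the depression trait.
sim_caps_items <- function(theta_ptsd, theta_dep, dx, bank) {
  fitems <- bank[match(caps_freq_cols(), bank$item), ]
  iitems <- bank[match(caps_int_cols(), bank$item), ]
  th_for <- function(j) if (fitems$trait[j] == "dep") theta_dep else theta_ptsd
  draw <- function(rows) {
    f <- matrix(0L, length(rows), 17)
    i <- matrix(0L, length(rows), 17)
    for (j in 1:17) {
      th <- th_for(j)[rows]
      f[, j] <- sim_grm(th, fitems[j, ])
      i[, j] <- sim_grm(th, iitems[j, ])
    }
    list(f = f, i = i)
  }
  d <- draw(seq_along(dx))
  f <- d$f
  i <- d$i
  for (try in 1:40) {
    bad <- which(caps_dx_from_items(f, i) != dx)
    if (length(bad) == 0) break
    d <- draw(bad)
    f[bad, ] <- d$f
    i[bad, ] <- d$i
  }
  bad <- which(caps_dx_from_items(f, i) != dx)
  for (r in bad) {
    if (dx[r]) {
      force_present <- function(idx, need) {
        have <- which((f[r, idx] >= 1) & (i[r, idx] >= 2))
        add <- setdiff(seq_along(idx), have)[seq_len(max(0, need - length(have)))]
        for (k in add) {
          f[r, idx[k]] <<- max(f[r, idx[k]], 1L)
          i[r, idx[k]] <<- max(i[r, idx[k]], 2L)
        }
      }
      force_present(CAPS_B_ITEMS, 1)
      force_present(CAPS_C_ITEMS, 3)
      force_present(CAPS_D_ITEMS, 2)
    } else {
      i[r, CAPS_B_ITEMS] <- pmin(i[r, CAPS_B_ITEMS], 1L)  # break criterion B
    }
  }
  colnames(f) <- caps_freq_cols()
  colnames(i) <- caps_int_cols()
  cbind(f, i)
}

#' Generate a synthetic multi-study cohort
#'
#' Draws covariates, trajectory classes, latent severities, item-level
#' instrument responses (consistent with the class-implied diagnosis at
#' each wave) and assessment timing for every configured study, then
#' applies the configured wave-2 missingness. Identical
#' `(configs, params, seed)` reproduce byte-identical output.
#'
#' @param configs List of [study_config()]; see [icpp_study_configs()].
#' @param params [generative_params()].
#' @param seed Integer seed.
#'
#' @return Tibble with one row per participant-wave: identifiers, wave
#'   timing, covariates, item responses (`bdi_*`, `hads_*`, `caps_f*`,
#'   `caps_i*`), and `obs_dep` / `obs_ptsd` observation flags. The
#'   attribute `"truth"` holds a per-participant tibble of true classes
#'   and latent traits; `"configs"` the study configurations.
#' @export
generate_cohort <- function(configs, params = generative_params(), seed = 1) {
  if (inherits(configs, "study_config")) configs <- list(configs)
  if (length(configs) == 0) stop_input("configs must be non-empty")
  stopifnot(inherits(params, "generative_params"))
  bank <- params$item_bank
  cut_ptsd <- ptsd_cutpoint(bank)
  cut_bdi <- dep_cutpoint(bank, "BDI")
  cut_hads <- dep_cutpoint(bank, "HADS")

  cohort <- with_seed(seed, {
    studies <- lapply(configs, function(cfg) {
      n <- cfg$n_participants
      shift <- (params$theta_study_shift %||% numeric(0))[cfg$study_id] %||% 0
      if (is.na(shift)) shift <- 0
      cov <- tibble::tibble(
        age = round(rtruncnorm(n, 38, 14, 18, 90), 1),
        female = runif(n) < 0.36,
        single = runif(n) < 0.50,
        low_education = runif(n) < 0.20,
        prior_trauma = factor(
          sample(c("none", "non-interpersonal", "interpersonal"), n, TRUE,
                 prob = c(0.18, 0.34, 0.48)),
          levels = c("none", "non-interpersonal", "interpersonal")),
        index_trauma = factor(
          if (cfg$mva_only) rep("MVA", n) else
            sample(c("MVA", "other_accident", "assault"), n, TRUE,
                   prob = c(0.73, 0.20, 0.07)),
          levels = c("MVA", "other_accident", "assault"))
      )
      X <- risk_factor_design(cov)
      # correlated uniforms across disorders (Gaussian copula)
      z <- mvtnorm::rmvnorm(n, sigma = matrix(c(1, params$dep_ptsd_corr,
                                                params$dep_ptsd_corr, 1), 2))
      u <- pnorm(z)

      class_for <- function(disorder, uu) {
        if (params$trajectory_model == "multinomial") {
          ic <- params$class_intercepts[[disorder]]
          eff <- params$covariate_effects[[disorder]]
          eta <- cbind(0,
                       ic["acute"] + lin_pred(X, eff$acute) + shift,
                       ic["persistent"] + lin_pred(X, eff$persistent) + shift,
                       ic["delayed"] + shift)
          pr <- exp(eta - apply(eta, 1, max))
          pr <- pr / rowSums(pr)
          # inverse-CDF draw: first cumulative prob >= u
          cum <- t(apply(pr, 1, cumsum))
          idx <- rowSums(cum < uu) + 1L
          c("Never", "Acute", "Persistent", "Delayed")[pmin(idx, 4L)]
        } else {
          NULL  # severity mode derives the class from the diagnoses below
        }
      }

      if (params$trajectory_model == "multinomial") {
        cls_p <- class_for("ptsd", u[, 2])
        cls_d <- class_for("mdd", u[, 1])
        dx1_p <- cls_p %in% c("Acute", "Persistent")
        dx2_p <- cls_p %in% c("Persistent", "Delayed")
        dx1_d <- cls_d %in% c("Acute", "Persistent")
        dx2_d <- cls_d %in% c("Persistent", "Delayed")
      } else {
        eff <- params$covariate_effects
        p1p <- plogis(params$class_intercepts$ptsd["acute"] +
                        lin_pred(X, eff$ptsd$acute) + shift)
        p1d <- plogis(params$class_intercepts$mdd["acute"] +
                        lin_pred(X, eff$mdd$acute) + shift)
        dx1_p <- u[, 2] < p1p
        dx1_d <- u[, 1] < p1d
        dx2_p <- dx2_d <- rep(FALSE, n)   # filled in after wave-1 severities
      }

      # latent traits: MVN over (dep w1, dep w2, ptsd w1, ptsd w2)
      rw <- params$theta_wave_corr
      rd <- params$dep_ptsd_corr
      Sig <- rbind(c(1, rw, rd, rd * rw),
                   c(rw, 1, rd * rw, rd),
                   c(rd, rd * rw, 1, rw),
                   c(rd * rw, rd, rw, 1))
      th <- mvtnorm::rmvnorm(n, mean = rep(shift, 4), sigma = Sig)
      cut_dep <- if (cfg$instrument == "BDI") cut_bdi else cut_hads

      th_d1 <- condition_theta(th[, 1], cut_dep, dx1_d, mean = shift)
      th_p1 <- condition_theta(th[, 3], cut_ptsd, dx1_p, mean = shift)
      dep1 <- sim_dep_items(th_d1, dx1_d, bank, cfg$instrument)
      caps1 <- sim_caps_items(th_p1, th_d1, dx1_p, bank)

      if (params$trajectory_model == "severity") {
        sev_p1 <- rowSums(caps1)
        raw_d1 <- rowSums(dep1)
        eq_d1 <- if (cfg$instrument == "BDI") raw_d1 else
          equate_score(hads_bdi_crosswalk(), raw_d1)
        pp <- params$persistence$ptsd
        pd <- params$persistence$mdd
        eta_p <- pp$intercept + pp$own * sev_p1 + pp$other * eq_d1 +
          lin_pred(X, pp$covariates %||% numeric(0)) + shift
        eta_d <- pd$intercept + pd$own * eq_d1 + pd$other * sev_p1 +
          lin_pred(X, pd$covariates %||% numeric(0)) + shift
        dx2_p <- dx1_p & (runif(n) < plogis(eta_p))
        dx2_d <- dx1_d & (runif(n) < plogis(eta_d))
      }

      th_d2 <- condition_theta(th[, 2], cut_dep, dx2_d, mean = shift)
      th_p2 <- condition_theta(th[, 4], cut_ptsd, dx2_p, mean = shift)
      dep2 <- sim_dep_items(th_d2, dx2_d, bank, cfg$instrument)
      caps2 <- sim_caps_items(th_p2, th_d2, dx2_p, bank)

      day1 <- round(rtruncnorm(n, cfg$acute_day_mean, cfg$acute_day_sd, 0, 60))
      day2 <- round(rtruncnorm(n, cfg$persistent_day_mean,
                               cfg$persistent_day_sd, 122, 456))

      pid <- sprintf("%s_p%04d", cfg$study_id, seq_len(n))
      dep_names <- colnames(dep1)
      blank_dep <- function(mat) {
        full <- matrix(NA_integer_, n, 28,
                       dimnames = list(NULL, c(sprintf("bdi_%02d", 1:21),
                                               sprintf("hads_%d", 1:7))))
        full[, dep_names] <- mat
        full
      }
      wave_tbl <- function(w, day, dep, caps) {
        tibble::tibble(study_id = cfg$study_id, participant_id = pid,
                       wave = w, days_since_trauma = day,
                       instrument = cfg$instrument) |>
          dplyr::bind_cols(cov, tibble::as_tibble(blank_dep(dep)),
                           tibble::as_tibble(caps)) |>
          dplyr::mutate(obs_dep = TRUE, obs_ptsd = TRUE)
      }
      rows <- dplyr::bind_rows(wave_tbl(1L, day1, dep1, caps1),
                               wave_tbl(2L, day2, dep2, caps2))
      truth <- tibble::tibble(
        participant_id = pid, study_id = cfg$study_id,
        true_dx1_ptsd = dx1_p, true_dx2_ptsd = dx2_p,
        true_dx1_mdd = dx1_d, true_dx2_mdd = dx2_d,
        true_class_ptsd = as.character(assign_trajectory(dx1_p, dx2_p)),
        true_class_mdd = as.character(assign_trajectory(dx1_d, dx2_d)),
        theta_dep_w1 = th_d1, theta_ptsd_w1 = th_p1)
      list(rows = rows, truth = truth)
    })
    out <- dplyr::bind_rows(lapply(studies, `[[`, "rows")) |>
      dplyr::arrange(.data$study_id, .data$participant_id, .data$wave)
    attr(out, "truth") <- dplyr::bind_rows(lapply(studies, `[[`, "truth"))
    out
  })
  attr(cohort, "configs") <- configs
  attr(cohort, "params") <- params
  apply_missingness(cohort, params, seed = derive_seed(seed, "missingness"))
}

#' Apply wave-2 missingness to a cohort
#'
#' Clears the wave-2 observation flags (and masks the corresponding item
#' responses) per the configured mechanism. Under MCAR, flags are cleared
#' independently at the per-study rate; under MAR, the missingness
#' probability depends on wave-1 severity and covariates with the
#' intercept calibrated so the marginal rate matches the target. Wave-1
#' assessments and covariates are never removed.
#'
#' @param cohort A [generate_cohort()] tibble (complete, or already
#'   partially masked; only observed wave-2 rows are eligible).
#' @param params [generative_params()]; `missing_rate` (if set) overrides
#'   the per-study `1 - followup_rate` for both instruments.
#' @param seed Integer seed.
#'
#' @return The cohort with updated `obs_dep` / `obs_ptsd` flags.
#' @export
apply_missingness <- function(cohort, params, seed = 1) {
  configs <- attr(cohort, "configs")
  rate_for <- function(study, instrument) {
    if (!is.null(params$missing_rate)) return(params$missing_rate)
    cfg <- configs[[which(vapply(configs, `[[`, "", "study_id") == study)]]
    base <- 1 - cfg$followup_rate
    if (base == 0) return(0)  # complete follow-up: both instruments observed
    if (instrument == "dep") 1 - (1 - base) * (1 - params$mdd_extra_missing)
    else base
  }
  with_seed(seed, {
    w2 <- which(cohort$wave == 2L)
    w1 <- which(cohort$wave == 1L)
    stopifnot(length(w2) == length(w1))
    for (instr in c("ptsd", "dep")) {
      flag_col <- paste0("obs_", instr)
      sev1 <- if (instr == "ptsd") {
        rowSums(cohort[w1, c(caps_freq_cols(), caps_int_cols())])
      } else {
        dplyr::coalesce(rowSums(cohort[w1, sprintf("bdi_%02d", 1:21)]),
                        rowSums(cohort[w1, sprintf("hads_%d", 1:7)]))
      }
      rates <- vapply(cohort$study_id[w2], rate_for, numeric(1),
                      instrument = instr)
      check_range(rates, 0, 1, "missingness rate")
      eligible <- cohort[[flag_col]][w2]
      if (params$missing_mechanism == "MCAR") {
        drop <- runif(length(w2)) < rates
      } else {
        zsev <- as.numeric(scale(sev1))
        zsev[is.na(zsev)] <- 0
        lp <- 0.5 * zsev + 0.3 * as.numeric(cohort$female[w2])
        drop <- logical(length(w2))
        for (st in unique(cohort$study_id[w2])) {
          ix <- which(cohort$study_id[w2] == st)
          target <- rates[ix[1]]
          if (target <= 0) next
          alpha <- uniroot(function(a) mean(plogis(a + lp[ix])) - target,
                           c(-20, 20))$root
          drop[ix] <- runif(length(ix)) < plogis(alpha + lp[ix])
        }
      }
      drop <- drop & eligible
      cohort[[flag_col]][w2][drop] <- FALSE
      mask_cols <- if (instr == "ptsd") c(caps_freq_cols(), caps_int_cols())
      else c(sprintf("bdi_%02d", 1:21), sprintf("hads_%d", 1:7))
      cohort[w2[drop], mask_cols] <- NA_integer_
    }
    cohort
  })
}

#' Write a cohort to disk (tidy CSV plus parameter sidecar)
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, "cohort.csv")
  utils::write.csv(as.data.frame(cohort), data_path, row.names = FALSE)
  truth <- attr(cohort, "truth")
  truth_path <- file.path(dir, "cohort_truth.json")
  params <- attr(cohort, "params")
  jsonlite::write_json(
    list(truth = truth,
         params = list(theta_wave_corr = params$theta_wave_corr,
                       dep_ptsd_corr = params$dep_ptsd_corr,
                       trajectory_model = params$trajectory_model,
                       missing_mechanism = params$missing_mechanism)),
    truth_path, dataframe = "columns", digits = NA)
  invisible(c(data_path, truth_path))
}
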