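# shared fixtures built in code

# blank CAPS record(s): all frequencies/intensities zero
blank_caps <- function(n = 1) {
  cols <- c(sprintf("caps_f%02d", 1:17), sprintf("caps_i%02d", 1:17))
  tibble::as_tibble(setNames(as.list(rep(0, length(cols))), cols))[rep(1, n), ]
}

# random valid CAPS records
random_caps <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(sample(0:4, n * 34, replace = TRUE), n, 34)
    colnames(m) <- c(sprintf("caps_f%02d", 1:17), sprintf("caps_i%02d", 1:17))
    tibble::as_tibble(m)
  })
}

# per-record scoring oracle: plain loops over symptoms
caps_oracle <- function(rec) {
  f <- as.numeric(rec[paste0("caps_f", sprintf("%02d", 1:17))])
  i <- as.numeric(rec[paste0("caps_i", sprintf("%02d", 1:17))])
  sev <- sum(f) + sum(i)
  pres <- logical(17)
  for (s in 1:17) pres[s] <- (f[s] >= 1) && (i[s] >= 2)
  nb <- sum(pres[1:5]); nc <- sum(pres[6:12]); nd <- sum(pres[13:17])
  list(severity = sev, dx = (nb >= 1) && (nc >= 3) && (nd >= 2))
}

# individual-level reconstruction of the descriptive fixture: group sizes
# and per-variable counts chosen to match the published distribution of
# female and index-trauma frequencies by PTSD/MDD trajectory group
descriptive_fixture <- function(disorder = "ptsd") {
  if (disorder == "ptsd") {
    groups <- c(Never = 1363, Acute = 267, Persistent = 138,
                Unclassifiable = 803)
    female <- c(Never = 424, Acute = 136, Persistent = 77,
                Unclassifiable = 283)
    # index trauma (MVA / other accident / assault); NA-padded to group n
    index <- list(Never = c(951, 338, 66), Acute = c(214, 23, 29),
                  Persistent = c(110, 7, 20), Unclassifiable = c(586, 149, 67))
  } else {
    groups <- c(Never = 1217, Acute = 140, Persistent = 71,
                Unclassifiable = 1143)
    female <- c(Never = 439, Acute = 70, Persistent = 33,
                Unclassifiable = 378)
    index <- list(Never = c(884, 264, 63), Acute = c(110, 14, 16),
                  Persistent = c(57, 3, 10), Unclassifiable = c(810, 236, 93))
  }
  rows <- lapply(names(groups), function(g) {
    n <- groups[[g]]
    idx <- index[[g]]
    it <- c(rep("MVA", idx[1]), rep("other_accident", idx[2]),
            rep("assault", idx[3]))
    it <- c(it, rep(NA_character_, n - length(it)))
    tibble::tibble(
      group = g,
      female = c(rep(TRUE, female[[g]]), rep(FALSE, n - female[[g]])),
      index_trauma = factor(it, c("MVA", "other_accident", "assault"))
    )
  })
  d <- dplyr::bind_rows(rows)
  d[[paste0(disorder, "_trajectory")]] <-
    factor(d$group, levels = traumameta::trajectory_levels())
  d$age <- 38
  d
}

# two small balanced study configs, complete follow-up
small_configs <- function(n = 150, followup = 1) {
  list(study_config("study_b", n, "BDI", followup_rate = followup),
       study_config("study_h", n, "HADS", followup_rate = followup))
}
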