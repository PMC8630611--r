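# Shared fixtures, built in code. Expensive objects are memoised so the
# n = 2000 development-preset pipeline is run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# development-preset cohort at the generator defaults (n = 2000, seed 1),
# screened, aggregated, restricted to valid subjects
dev_cohort <- function() {
  memo("dev_cohort", {
    p <- cohort_params()
    g <- generate_cohort(p)
    scr <- apply_screening(g$readings, p$screening_threshold)
    coh <- aggregate_subjects(scr, "development", p$schedule)
    coh <- coh[coh$home_valid & coh$abp_valid, , drop = FALSE]
    list(params = p, latent = g$latent, cohort = coh,
         screened_ids = unique(scr$subject_id))
  })
}

# small noise-free generator configuration: all modalities share (nearly)
# one latent value, no reading noise, no dropout, no circadian offset
noise_free_params <- function(n = 40, seed = 5,
                              mu = rep(c(138, 87), 3)) {
  eq <- matrix(0.9999999, 6, 6); diag(eq) <- 1
  dimnames(eq) <- dimnames(default_latent_corr())
  cohort_params(n_subjects = n, latent_mean = mu,
                latent_corr = eq,
                reading_noise_sd = c(office = 0, home = 0, ambulatory = 0),
                noise_sd_corr = 0, missing_session_rate = 0,
                day_offset = 0, night_offset = 0, seed = seed)
}

# --- tiny reading-level builders -------------------------------------------

office_rows <- function(subject_id, visit, arm, sbp, dbp) {
  k <- length(sbp)
  data.frame(subject_id = subject_id, modality = "office", arm = arm,
             visit = as.integer(visit), day = NA_integer_,
             session = NA_character_, reading_index = seq_len(k),
             timestamp = NA_character_, sbp = sbp, dbp = dbp, valid = NA,
             stringsAsFactors = FALSE)
}

home_rows <- function(subject_id, day, session, sbp, dbp,
                      reading_index = seq_along(sbp)) {
  data.frame(subject_id = subject_id, modality = "home", arm = NA_character_,
             visit = NA_integer_, day = as.integer(day), session = session,
             reading_index = as.integer(reading_index),
             timestamp = NA_character_, sbp = sbp, dbp = dbp, valid = NA,
             stringsAsFactors = FALSE)
}

# a full valid 7-day home grid at constant BP, overridable per session
home_grid <- function(subject_id = 1L, sbp = 130, dbp = 80,
                      readings_per_session = 3) {
  rows <- list()
  for (d in 1:7) {
    for (s in c("morning", "evening")) {
      rows[[length(rows) + 1L]] <-
        home_rows(subject_id, d, s, rep(sbp, readings_per_session),
                  rep(dbp, readings_per_session))
    }
  }
  do.call(rbind, rows)
}

amb_rows <- function(subject_id, timestamp, sbp, dbp, valid = TRUE) {
  data.frame(subject_id = subject_id, modality = "ambulatory",
             arm = NA_character_, visit = NA_integer_, day = NA_integer_,
             session = NA_character_, reading_index = NA_integer_,
             timestamp = timestamp, sbp = sbp, dbp = dbp,
             valid = valid, stringsAsFactors = FALSE)
}

# --- independent brute-force ROC oracle ------------------------------------
# Exhaustive scan over every observed value as a candidate cut-off,
# computing sensitivity/specificity from first principles.

bf_cutoff <- function(values, truth, target, kind = c("sens", "spec")) {
  kind <- match.arg(kind)
  best <- NA_real_
  for (cc in sort(unique(values))) {
    tp <- sum(values >= cc & truth); fn <- sum(values < cc & truth)
    tn <- sum(values < cc & !truth); fp <- sum(values >= cc & !truth)
    if (kind == "sens") {
      if (tp / (tp + fn) >= target) best <- max(best, cc, na.rm = TRUE)
    } else {
      if (tn / (tn + fp) >= target && is.na(best)) best <- cc
    }
  }
  best
}

# random phenotype-by-zone table honouring the structural zeros of a
# threshold inside the zones (no WH/SH in the normotension zone, no NT/MH
# in the hypertension zone)
random_structured_table <- function() {
  ct <- matrix(0L, 4, 3, dimnames = list(PHENOTYPES, ZONES))
  ct["NT", 1:2] <- rpois(2, 15); ct["WH", 2:3] <- rpois(2, 6)
  ct["MH", 1:2] <- rpois(2, 10); ct["SH", 2:3] <- rpois(2, 40)
  if (sum(ct) == 0) ct["SH", 3] <- 1L
  if (sum(ct[c("MH", "SH"), ]) == 0) ct["SH", 2] <- 1L
  if (sum(ct[c("NT", "WH"), ]) == 0) ct["NT", 1] <- 1L
  zone_phenotype_table(ct, "office")
}
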