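#' Aggregate office readings to a single per-subject value
#'
#' Two index-arm schemes are supported, matching the two measurement
#' protocols:
#' \describe{
#'   \item{development}{Both arms are measured at visit 1; the index arm is
#'     the arm with the higher visit-1 mean SBP (ties: higher mean DBP,
#'     then right arm). The office BP is the mean of all index-arm readings
#'     across visits.}
#'   \item{validation}{Both arms are measured at every visit; per-arm means
#'     over all visits are computed first and the arm with the higher mean
#'     is the index arm; its mean is the office BP.}
#' }
#'
#' @param readings Data frame of one subject's office readings (columns
#'   `arm`, `visit`, `sbp`, `dbp`).
#' @param scheme `"development"` or `"validation"`.
#' @return List with `sbp`, `dbp` (mmHg) and `index_arm`.
#' @export
aggregate_office <- function(readings, scheme = c("development", "validation")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(readings), nrow(readings) > 0)
  sid <- readings$subject_id[1]
  if (scheme == "development") {
    v1 <- readings[readings$visit == 1L, , drop = FALSE]
    arms <- unique(v1$arm)
    if (!all(c("left", "right") %in% arms)) {
      stop(sprintf("subject %s: visit 1 lacks readings from both arms", sid))
    }
    m <- function(a, col) mean(v1[[col]][v1$arm == a])
    index_arm <- pick_arm(m("right", "sbp"), m("left", "sbp"),
                          m("right", "dbp"), m("left", "dbp"))
    sel <- readings[readings$arm == index_arm, , drop = FALSE]
  } else {
    for (v in sort(unique(readings$visit))) {
      av <- unique(readings$arm[readings$visit == v])
      if (!all(c("left", "right") %in% av)) {
        stop(sprintf("subject %s: visit %d lacks readings from both arms",
                     sid, v))
      }
    }
    m <- function(a, col) mean(readings[[col]][readings$arm == a])
    index_arm <- pick_arm(m("right", "sbp"), m("left", "sbp"),
                          m("right", "dbp"), m("left", "dbp"))
    sel <- readings[readings$arm == index_arm, , drop = FALSE]
  }
  list(sbp = mean(sel$sbp), dbp = mean(sel$dbp), index_arm = index_arm)
}

# higher SBP decides; tie -> higher DBP; tie -> right
pick_arm <- function(r_sbp, l_sbp, r_dbp, l_dbp) {
  if (l_sbp > r_sbp) return("left")
  if (r_sbp > l_sbp) return("right")
  if (l_dbp > r_dbp) "left" else "right"
}

# the discard rule: first-day evening and second-day morning sessions are
# never analyzed
discard_home_sessions <- function(readings) {
  drop <- (readings$day == 1L & readings$session == "evening") |
    (readings$day == 2L & readings$session == "morning")
  readings[!drop, , drop = FALSE]
}

#' Validate a subject's home BP series
#'
#' A home series is valid when, after discarding the first-day evening and
#' second-day morning sessions, at least 5 distinct days have a morning
#' session with >= 2 readings and at least 5 distinct days have an evening
#' session with >= 2 readings.
#'
#' @param readings Data frame of one subject's home readings (columns
#'   `day`, `session`, `sbp`).
#' @return Logical flag.
#' @export
validate_home <- function(readings) {
  if (!is.data.frame(readings) || nrow(readings) == 0) return(FALSE)
  kept <- discard_home_sessions(readings)
  if (nrow(kept) == 0) return(FALSE)
  n_by <- stats::aggregate(kept$sbp,
                           by = list(day = kept$day, session = kept$session),
                           FUN = length)
  ok_days <- function(s) length(unique(n_by$day[n_by$session == s & n_by$x >= 2]))
  ok_days("morning") >= 5 && ok_days("evening") >= 5
}

#' Aggregate home readings to a single per-subject value
#'
#' Discards the first-day evening and second-day morning sessions; within
#' each remaining session averages readings 1 and 2 (the third reading is
#' discarded; a single-reading session contributes that reading); the home
#' BP is the unweighted mean over session values, SBP and DBP separately.
#'
#' @inheritParams validate_home
#' @return List with `sbp` and `dbp` (mmHg).
#' @export
aggregate_home <- function(readings) {
  if (!validate_home(readings)) {
    stop("aggregate_home called on an invalid home series",
         if (is.data.frame(readings) && length(readings$subject_id))
           paste0(" (subject ", readings$subject_id[1], ")") else "")
  }
  kept <- discard_home_sessions(readings)
  key <- interaction(kept$day, kept$session, drop = TRUE)
  one <- function(col) {
    vapply(split(seq_len(nrow(kept)), key), function(ix) {
      sub <- kept[ix, , drop = FALSE]
      use <- sub$reading_index <= 2L
      if (nrow(sub) == 1L || !any(use)) mean(sub[[col]]) else mean(sub[[col]][use])
    }, numeric(1))
  }
  list(sbp = mean(one("sbp")), dbp = mean(one("dbp")))
}

#' Validate a subject's ambulatory BP series
#'
#' Valid when strictly more than 70% of measurement attempts produced a
#' valid reading, with at least 14 valid readings in the daytime window and
#' at least 7 in the nighttime window.
#'
#' @param readings Data frame of one subject's ambulatory readings
#'   (columns `timestamp`, `valid`).
#' @param schedule A [schedule_spec()] supplying the clock windows.
#' @return Logical flag.
#' @export
validate_ambulatory <- function(readings, schedule = schedule_spec()) {
  stopifnot(inherits(schedule, "schedule_spec"))
  if (!is.data.frame(readings) || nrow(readings) == 0) return(FALSE)
  valid <- as.logical(readings$valid)
  valid[is.na(valid)] <- FALSE
  if (!(mean(valid) > 0.70)) return(FALSE)
  clock <- vapply(readings$timestamp[valid], parse_hm, numeric(1))
  sum(in_clock_window(clock, schedule$daytime_window)) >= 14 &&
    sum(in_clock_window(clock, schedule$nighttime_window)) >= 7
}

#' Mean ambulatory BP over a clock window
#'
#' Unweighted mean of the valid readings whose clock timestamp falls in
#' the half-open window `[start, end)`. Use `c("00:00", "24:00")` for the
#' full-span (24-h) mean.
#'
#' @inheritParams validate_ambulatory
#' @param window Length-2 `"HH:MM"` clock interval.
#' @return List with `sbp` and `dbp` (mmHg).
#' @export
aggregate_window <- function(readings, window) {
  stopifnot(is.data.frame(readings), length(window) == 2L)
  valid <- as.logical(readings$valid)
  valid[is.na(valid)] <- FALSE
  sub <- readings[valid, , drop = FALSE]
  if (parse_hm(window[1]) == 0 && parse_hm(window[2]) %in% c(0, 1440)) {
    inw <- rep(TRUE, nrow(sub))
  } else {
    inw <- in_clock_window(vapply(sub$timestamp, parse_hm, numeric(1)), window)
  }
  if (!any(inw)) {
    stop(sprintf("no valid ambulatory readings inside window [%s, %s)",
                 window[1], window[2]))
  }
  list(sbp = mean(sub$sbp[inw]), dbp = mean(sub$dbp[inw]))
}

#' Aggregate a reading-level cohort to per-subject values
#'
#' Applies [aggregate_office()], [validate_home()]/[aggregate_home()] and
#' [validate_ambulatory()]/[aggregate_window()] per subject, producing the
#' per-subject table the triage analysis consumes. Home and ambulatory
#' values are `NA` when the corresponding validity rule fails; the office
#' value is always present.
#'
#' @param readings Reading-level data frame (schema of
#'   [read_readings_csv()]).
#' @param scheme Office index-arm scheme, see [aggregate_office()].
#' @param schedule A [schedule_spec()] (clock windows for ambulatory
#'   validity and the daytime mean).
#' @return Data frame with one row per subject: `subject_id`,
#'   `office_sbp/dbp`, `home_sbp/dbp`, `daytime_sbp/dbp`, `abp24_sbp/dbp`,
#'   `home_valid`, `abp_valid`, `index_arm`.
#' @export
aggregate_subjects <- function(readings, scheme = c("development", "validation"),
                               schedule = schedule_spec()) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(readings), inherits(schedule, "schedule_spec"))
  full <- c("00:00", "24:00")
  rows <- lapply(split(readings, factor(readings$subject_id,
                                        levels = unique(readings$subject_id))),
                 function(sub) {
    off <- sub[sub$modality == "office", , drop = FALSE]
    if (nrow(off) == 0) {
      stop("subject ", sub$subject_id[1], " has no office readings")
    }
    o <- aggregate_office(off, scheme)
    hm <- sub[sub$modality == "home", , drop = FALSE]
    ab <- sub[sub$modality == "ambulatory", , drop = FALSE]
    hv <- validate_home(hm)
    av <- validate_ambulatory(ab, schedule)
    h <- if (hv) aggregate_home(hm) else list(sbp = NA_real_, dbp = NA_real_)
    d <- if (av) aggregate_window(ab, schedule$daytime_window) else
      list(sbp = NA_real_, dbp = NA_real_)
    a24 <- if (av) aggregate_window(ab, full) else
      list(sbp = NA_real_, dbp = NA_real_)
    data.frame(subject_id = sub$subject_id[1],
               office_sbp = o$sbp, office_dbp = o$dbp,
               home_sbp = h$sbp, home_dbp = h$dbp,
               daytime_sbp = d$sbp, daytime_dbp = d$dbp,
               abp24_sbp = a24$sbp, abp24_dbp = a24$dbp,
               home_valid = hv, abp_valid = av,
               index_arm = o$index_arm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
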