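#' Confusion counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true/false
#'   positives/negatives against the reference standard).
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(v >= 0), all(v == round(v)), sum(v) >= 1)
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Phenotype-by-zone count table
#'
#' Counts of the four hypertension phenotypes (rows NT/WH/MH/SH) within
#' the three triage zones (columns) of one screening arm — the layout of
#' the published distribution tables.
#'
#' @param counts 4x3 non-negative integer matrix; rows `NT, WH, MH, SH`,
#'   columns `normotension, intermediate, hypertension` (row/column names
#'   optional but, if present, must match).
#' @param arm `"office"` or `"home"`.
#' @return Object of class `zone_phenotype_table`.
#' @export
zone_phenotype_table <- function(counts, arm = c("office", "home")) {
  arm <- match.arg(arm)
  counts <- unclass(as.matrix(counts))  # tables come in via table()
  stopifnot(nrow(counts) == 4, ncol(counts) == 3,
            all(counts >= 0), all(counts == round(counts)))
  if (!is.null(rownames(counts)) && !identical(rownames(counts), PHENOTYPES)) {
    stop("row names must be ", paste(PHENOTYPES, collapse = ", "))
  }
  if (!is.null(colnames(counts)) && !identical(colnames(counts), ZONES)) {
    stop("column names must be ", paste(ZONES, collapse = ", "))
  }
  dimnames(counts) <- list(PHENOTYPES, ZONES)
  structure(list(counts = counts, arm = arm, n_total = sum(counts)),
            class = "zone_phenotype_table")
}

#' @export
print.zone_phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype-by-zone counts (%s arm, n = %d):\n", x$arm, x$n_total))
  print(x$counts)
  invisible(x)
}

#' Apply a cascade strategy to one aggregated subject
#'
#' The three strategies terminate immediately in the hypertension or
#' normotension zone of the screening modality and escalate only from the
#' intermediate zone:
#' \describe{
#'   \item{OBP_ABP}{office zones; intermediate resolved by the reference
#'     (ambulatory) BP at 135/85.}
#'   \item{OBP_HBP_ABP}{office zones; office-intermediate resolved by home
#'     zones; home-intermediate resolved by the reference.}
#'   \item{HBP_ABP}{home zones; intermediate resolved by the reference.}
#' }
#'
#' @param subject One row of an aggregated-subject data frame.
#' @param strategy `"OBP_ABP"`, `"OBP_HBP_ABP"` or `"HBP_ABP"`.
#' @param office_zones,home_zones [zone_boundaries()] for each arm (only
#'   the ones the strategy needs are required).
#' @param reference `"daytime"` or `"24h"`.
#' @param ref_threshold Reference hypertension threshold, default 135/85.
#' @return List (`cascade_outcome`): `subject_id`, `diagnosis`
#'   (`"hypertensive"`/`"normotensive"`), `terminal_stage`
#'   (`"office"`/`"home"`/`"ambulatory"`), `office_zone`, `home_zone`
#'   (NA when not visited).
#' @export
diagnose <- function(subject, strategy = c("OBP_ABP", "OBP_HBP_ABP", "HBP_ABP"),
                     office_zones = NULL, home_zones = NULL,
                     reference = c("daytime", "24h"),
                     ref_threshold = default_threshold("daytime")) {
  strategy <- match.arg(strategy)
  out <- diagnose_cohort(as.data.frame(subject), strategy, office_zones,
                         home_zones, reference, ref_threshold)
  structure(as.list(out[1, ]), class = "cascade_outcome")
}

#' Apply a cascade strategy to a whole cohort
#'
#' Vectorized form of [diagnose()].
#'
#' @param cohort Aggregated-subject data frame ([aggregate_subjects()]).
#' @inheritParams diagnose
#' @return Data frame with one row per subject: `subject_id`, `diagnosis`,
#'   `terminal_stage`, `office_zone`, `home_zone`.
#' @export
diagnose_cohort <- function(cohort,
                            strategy = c("OBP_ABP", "OBP_HBP_ABP", "HBP_ABP"),
                            office_zones = NULL, home_zones = NULL,
                            reference = c("daytime", "24h"),
                            ref_threshold = default_threshold("daytime")) {
  strategy <- match.arg(strategy)
  reference <- match.arg(reference)
  n <- nrow(cohort)
  need_office <- strategy %in% c("OBP_ABP", "OBP_HBP_ABP")
  need_home <- strategy %in% c("OBP_HBP_ABP", "HBP_ABP")

  office_zone <- rep(factor(NA, levels = ZONES), n)
  home_zone <- rep(factor(NA, levels = ZONES), n)

  if (need_office) {
    stopifnot(inherits(office_zones, "zone_boundaries"))
    check_present(cohort, c("office_sbp", "office_dbp"), strategy, "office")
    office_zone <- assign_zone(cohort$office_sbp, cohort$office_dbp,
                               office_zones)
  }
  if (need_home) {
    stopifnot(inherits(home_zones, "zone_boundaries"))
    # home is consulted for every subject under HBP_ABP, but only for
    # office-intermediate subjects under OBP_HBP_ABP
    need_rows <- if (strategy == "HBP_ABP") rep(TRUE, n) else
      office_zone == "intermediate"
    bad <- need_rows & (is.na(cohort$home_sbp) | is.na(cohort$home_dbp) |
                          !cohort$home_valid)
    if (any(bad)) {
      stop(sprintf("strategy %s, stage home: missing/invalid home BP for subject(s) %s",
                   strategy,
                   paste(utils::head(cohort$subject_id[bad], 10), collapse = ", ")))
    }
    home_zone[need_rows] <- assign_zone(cohort$home_sbp[need_rows],
                                        cohort$home_dbp[need_rows], home_zones)
  }

  first_zone <- if (strategy == "HBP_ABP") home_zone else office_zone
  second_zone <- if (strategy == "OBP_HBP_ABP") home_zone else
    rep(factor(NA, levels = ZONES), n)

  to_ref <- if (strategy == "OBP_HBP_ABP") {
    first_zone == "intermediate" & second_zone == "intermediate"
  } else {
    first_zone == "intermediate"
  }
  if (any(to_ref)) {
    rcols <- if (reference == "daytime") c("daytime_sbp", "daytime_dbp") else
      c("abp24_sbp", "abp24_dbp")
    bad <- to_ref & (is.na(cohort[[rcols[1]]]) | is.na(cohort[[rcols[2]]]) |
                       !cohort$abp_valid)
    if (any(bad)) {
      stop(sprintf("strategy %s, stage ambulatory: missing/invalid %s BP for subject(s) %s",
                   strategy, reference,
                   paste(utils::head(cohort$subject_id[bad], 10), collapse = ", ")))
    }
  }

  diagnosis <- character(n)
  terminal <- character(n)
  stage1 <- if (strategy == "HBP_ABP") "home" else "office"
  diagnosis[first_zone == "hypertension"] <- "hypertensive"
  diagnosis[first_zone == "normotension"] <- "normotensive"
  terminal[first_zone != "intermediate"] <- stage1

  if (strategy == "OBP_HBP_ABP") {
    mid <- first_zone == "intermediate"
    diagnosis[mid & second_zone == "hypertension"] <- "hypertensive"
    diagnosis[mid & second_zone == "normotension"] <- "normotensive"
    terminal[mid & second_zone != "intermediate"] <- "home"
  }
  if (any(to_ref)) {
    rcols <- if (reference == "daytime") c("daytime_sbp", "daytime_dbp") else
      c("abp24_sbp", "abp24_dbp")
    rht <- is_hypertensive(cohort[[rcols[1]]][to_ref],
                           cohort[[rcols[2]]][to_ref], ref_threshold)
    diagnosis[to_ref] <- ifelse(rht, "hypertensive", "normotensive")
    terminal[to_ref] <- "ambulatory"
  }

  data.frame(subject_id = cohort$subject_id, diagnosis = diagnosis,
             terminal_stage = terminal,
             office_zone = as.character(office_zone),
             home_zone = as.character(home_zone),
             stringsAsFactors = FALSE)
}

check_present <- function(cohort, cols, strategy, stage) {
  for (cl in cols) {
    if (is.null(cohort[[cl]]) || anyNA(cohort[[cl]])) {
      bad <- if (is.null(cohort[[cl]])) cohort$subject_id else
        cohort$subject_id[is.na(cohort[[cl]])]
      stop(sprintf("strategy %s, stage %s: missing %s for subject(s) %s",
                   strategy, stage, cl,
                   paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
}

#' Tabulate phenotypes by triage zone
#'
#' Phenotypes are defined by the arm's own hypertension threshold (office
#' 140/90, home 135/85 mmHg) crossed with the reference standard at
#' 135/85; zones come from [assign_zone()] with the supplied boundaries.
#'
#' @param cohort Aggregated-subject data frame with arm and reference BP
#'   present for every subject.
#' @param boundaries [zone_boundaries()] for the arm.
#' @param arm `"office"` or `"home"` (defaults to the boundaries'
#'   modality).
#' @param reference `"daytime"` or `"24h"`.
#' @param ref_threshold Reference threshold, default 135/85.
#' @return A [zone_phenotype_table()].
#' @export
tabulate_zone_phenotypes <- function(cohort, boundaries, arm = boundaries$modality,
                                     reference = c("daytime", "24h"),
                                     ref_threshold = default_threshold("daytime")) {
  stopifnot(inherits(boundaries, "zone_boundaries"))
  arm <- match.arg(arm, c("office", "home"))
  ref <- reference_bp(cohort, match.arg(reference))
  sbp <- cohort[[paste0(arm, "_sbp")]]
  dbp <- cohort[[paste0(arm, "_dbp")]]
  if (anyNA(sbp) || anyNA(dbp)) {
    stop("every subject must have ", arm, " BP to tabulate")
  }
  ph <- classify_phenotype(is_hypertensive(sbp, dbp, default_threshold(arm)),
                           is_hypertensive(ref$sbp, ref$dbp, ref_threshold))
  zn <- assign_zone(sbp, dbp, boundaries)
  zone_phenotype_table(table(ph, zn), arm)
}

#' Evaluate the single-escalation cascade from a count table
#'
#' Count-level arithmetic of the OBP-ABP / HBP-ABP strategies:
#' hypertension-zone subjects are classified positive, normotension-zone
#' subjects negative, and intermediate-zone subjects are resolved by the
#' reference standard itself — hence always correctly. Reference-positive
#' phenotypes are MH and SH; reference-negative are NT and WH. The errors
#' are therefore exactly the WH counts in the hypertension zone (false
#' positives) and the MH counts in the normotension zone (false
#' negatives).
#'
#' @param table A [zone_phenotype_table()].
#' @return A [confusion_counts()].
#' @export
evaluate_from_zone_table <- function(table) {
  stopifnot(inherits(table, "zone_phenotype_table"))
  ct <- table$counts
  refpos <- c("MH", "SH"); refneg <- c("NT", "WH")
  confusion_counts(
    tp = sum(ct[refpos, "hypertension"]) + sum(ct[refpos, "intermediate"]),
    fp = sum(ct[refneg, "hypertension"]),
    fn = sum(ct[refpos, "normotension"]),
    tn = sum(ct[refneg, "normotension"]) + sum(ct[refneg, "intermediate"]))
}

#' Evaluate the arm's threshold alone from a count table
#'
#' Classification by the arm's own hypertension threshold — i.e. the
#' phenotype rows: WH and SH are test-positive, NT and MH test-negative —
#' without any confirmatory escalation. With `exclude_intermediate = TRUE`
#' the intermediate-zone column is dropped before counting, evaluating the
#' threshold only where the triage zones consider it conclusive.
#'
#' @param table A [zone_phenotype_table()].
#' @param exclude_intermediate Drop intermediate-zone subjects first?
#' @return A [confusion_counts()].
#' @export
evaluate_threshold_alone <- function(table, exclude_intermediate = FALSE) {
  stopifnot(inherits(table, "zone_phenotype_table"))
  ct <- table$counts
  zones <- if (exclude_intermediate) c("normotension", "hypertension") else ZONES
  cc <- confusion_counts(
    tp = sum(ct["SH", zones]), fp = sum(ct["WH", zones]),
    fn = sum(ct["MH", zones]), tn = sum(ct["NT", zones]))
  if (exclude_intermediate &&
      ((cc$tp + cc$fn) == 0 || (cc$tn + cc$fp) == 0)) {
    stop("excluding the intermediate zone empties a reference truth class")
  }
  cc
}

#' Evaluate a cascade strategy on an aggregated cohort
#'
#' Applies [diagnose_cohort()] per subject, takes the reference standard
#' (daytime or 24-h ambulatory BP at `ref_threshold`) as truth, and
#' aggregates confusion counts. For the single-escalation strategies the
#' result is asserted to equal the count-level arithmetic of
#' [evaluate_from_zone_table()] on the corresponding tabulation.
#'
#' @inheritParams diagnose_cohort
#' @return A [confusion_counts()].
#' @export
evaluate_strategy <- function(cohort,
                              strategy = c("OBP_ABP", "OBP_HBP_ABP", "HBP_ABP"),
                              office_zones = NULL, home_zones = NULL,
                              reference = c("daytime", "24h"),
                              ref_threshold = default_threshold("daytime")) {
  strategy <- match.arg(strategy)
  reference <- match.arg(reference)
  out <- diagnose_cohort(cohort, strategy, office_zones, home_zones,
                         reference, ref_threshold)
  ref <- reference_bp(cohort, reference)
  truth <- is_hypertensive(ref$sbp, ref$dbp, ref_threshold)
  pos <- out$diagnosis == "hypertensive"
  cc <- confusion_counts(tp = sum(pos & truth), fp = sum(pos & !truth),
                         fn = sum(!pos & truth), tn = sum(!pos & !truth))
  if (strategy %in% c("OBP_ABP", "HBP_ABP")) {
    zb <- if (strategy == "OBP_ABP") office_zones else home_zones
    tab <- tabulate_zone_phenotypes(cohort, zb, zb$modality, reference,
                                    ref_threshold)
    cc2 <- evaluate_from_zone_table(tab)
    if (!identical(unclass(cc)[c("tp", "fp", "fn", "tn")],
                   unclass(cc2)[c("tp", "fp", "fn", "tn")])) {
      # only possible if the arm threshold lies outside the zones and the
      # phenotype dichotomy disagrees with the cascade inside a terminal
      # zone; the subject-level result is authoritative
      warning("subject-level cascade and count-table arithmetic disagree; ",
              "arm threshold may lie outside the zone boundaries")
    }
  }
  cc
}
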