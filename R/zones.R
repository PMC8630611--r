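#' ROC cut-off at a target sensitivity
#'
#' Scans candidate cut-offs taken from the observed values (positivity:
#' value >= cut-off) and returns the largest cut-off whose sensitivity is
#' at or above `target`. This is the lower boundary of the intermediate
#' zone: below it, a negative screening result rules hypertension out with
#' at least `target` sensitivity.
#'
#' @param values Numeric vector of screening-test BP values (mmHg).
#' @param truth Logical vector: reference-standard hypertension.
#' @param target Target sensitivity (default 0.95).
#' @return The selected cut-off (mmHg), with attributes `sensitivity` and
#'   `specificity` giving its operating point.
#' @seealso [roc_cutoff_at_specificity()], [derive_zone_boundaries()]
#' @export
roc_cutoff_at_sensitivity <- function(values, truth, target = 0.95) {
  check_roc_input(values, truth, target)
  cand <- sort(unique(values))
  pos <- values[truth]
  sens <- vapply(cand, function(cc) mean(pos >= cc), numeric(1))
  ok <- which(sens >= target)
  if (!length(ok)) {
    stop(sprintf("no candidate cut-off reaches sensitivity %.3f", target))
  }
  i <- max(ok)
  cutoff_result(cand[i], sens[i], mean(values[!truth] < cand[i]))
}

#' ROC cut-off at a target specificity
#'
#' Returns the smallest candidate cut-off (positivity: value >= cut-off)
#' whose specificity — the fraction of reference-negative subjects strictly
#' below the cut-off — is at or above `target`. This is the upper boundary
#' of the intermediate zone: at or above it, a positive screening result
#' rules hypertension in with at least `target` specificity.
#'
#' @inheritParams roc_cutoff_at_sensitivity
#' @param target Target specificity (default 0.95).
#' @return The selected cut-off (mmHg) with operating-point attributes.
#' @export
roc_cutoff_at_specificity <- function(values, truth, target = 0.95) {
  check_roc_input(values, truth, target)
  cand <- sort(unique(values))
  neg <- values[!truth]
  spec <- vapply(cand, function(cc) mean(neg < cc), numeric(1))
  ok <- which(spec >= target)
  if (!length(ok)) {
    stop(sprintf(
      "no candidate cut-off reaches specificity %.3f (max attainable %.3f)",
      target, max(spec)))
  }
  i <- min(ok)
  cutoff_result(cand[i], mean(values[truth] >= cand[i]), spec[i])
}

check_roc_input <- function(values, truth, target) {
  stopifnot(is.numeric(values), is.logical(truth),
            length(values) == length(truth), !anyNA(values), !anyNA(truth),
            target > 0, target <= 1)
  if (!any(truth) || all(truth)) {
    stop("both truth classes must be present to derive a cut-off")
  }
}

cutoff_result <- function(cutoff, sens, spec) {
  structure(cutoff, sensitivity = sens, specificity = spec)
}

#' Zone boundaries for one screening modality
#'
#' Lower and upper SBP/DBP cut-offs delimiting the intermediate zone.
#' All four values must be multiples of 5 mmHg with lower strictly below
#' upper, component-wise.
#'
#' @param lower,upper [bp_threshold()] pairs (lower / upper cut-offs).
#' @param modality `"office"` or `"home"`.
#' @return Object of class `zone_boundaries`.
#' @examples
#' zone_boundaries(bp_threshold(130, 80), bp_threshold(145, 95), "office")
#' @export
zone_boundaries <- function(lower, upper, modality = c("office", "home")) {
  modality <- match.arg(modality)
  stopifnot(inherits(lower, "bp_threshold"), inherits(upper, "bp_threshold"))
  vals <- c(lower$sbp, lower$dbp, upper$sbp, upper$dbp)
  if (any(vals %% 5 != 0)) {
    stop("zone boundaries must be multiples of 5 mmHg")
  }
  if (!(lower$sbp < upper$sbp && lower$dbp < upper$dbp)) {
    stop("lower boundary must lie strictly below upper boundary")
  }
  structure(list(lower = lower, upper = upper, modality = modality),
            class = "zone_boundaries")
}

#' @export
print.zone_boundaries <- function(x, ...) {
  cat(sprintf(
    "%s BP zones: normotension < %g/%g | intermediate | hypertension >= %g/%g mmHg\n",
    x$modality, x$lower$sbp, x$lower$dbp, x$upper$sbp, x$upper$dbp))
  raw <- attr(x, "raw_cutoffs")
  if (!is.null(raw)) {
    cat(sprintf("  raw ROC cut-offs: lower %.1f/%.1f, upper %.1f/%.1f mmHg\n",
                raw["lower_sbp"], raw["lower_dbp"],
                raw["upper_sbp"], raw["upper_dbp"]))
  }
  invisible(x)
}

#' Derive intermediate-zone boundaries from a cohort by ROC analysis
#'
#' Against the binary reference truth (daytime or 24-h ambulatory BP at
#' 135/85 mmHg by default), the lower SBP and DBP cut-offs are chosen at
#' 95% sensitivity and the upper cut-offs at 95% specificity, each
#' independently, then snapped to the nearest multiple of 5 mmHg.
#'
#' @param cohort Aggregated-subject data frame (see [aggregate_subjects()]);
#'   needs `<modality>_sbp`, `<modality>_dbp` and the reference columns.
#' @param modality `"office"` or `"home"` — the screening test.
#' @param reference `"daytime"` or `"24h"` — the reference standard.
#' @param target_sens,target_spec ROC targets (default 0.95 each).
#' @param ref_threshold Reference hypertension threshold, default 135/85.
#' @return A [zone_boundaries()] with attribute `raw_cutoffs` holding the
#'   pre-rounding ROC cut-offs.
#' @export
derive_zone_boundaries <- function(cohort, modality = c("office", "home"),
                                   reference = c("daytime", "24h"),
                                   target_sens = 0.95, target_spec = 0.95,
                                   ref_threshold = default_threshold("daytime")) {
  modality <- match.arg(modality)
  reference <- match.arg(reference)
  ref <- reference_bp(cohort, reference)
  truth <- is_hypertensive(ref$sbp, ref$dbp, ref_threshold)
  sbp <- cohort[[paste0(modality, "_sbp")]]
  dbp <- cohort[[paste0(modality, "_dbp")]]
  if (is.null(sbp) || is.null(dbp) || anyNA(sbp) || anyNA(dbp)) {
    stop("cohort is missing ", modality, " BP values")
  }
  lo_s <- roc_cutoff_at_sensitivity(sbp, truth, target_sens)
  lo_d <- roc_cutoff_at_sensitivity(dbp, truth, target_sens)
  up_s <- roc_cutoff_at_specificity(sbp, truth, target_spec)
  up_d <- roc_cutoff_at_specificity(dbp, truth, target_spec)
  raw <- c(lower_sbp = as.numeric(lo_s), lower_dbp = as.numeric(lo_d),
           upper_sbp = as.numeric(up_s), upper_dbp = as.numeric(up_d))
  rl <- round_to_multiple_of_5(raw)
  if (!(rl["lower_sbp"] < rl["upper_sbp"] && rl["lower_dbp"] < rl["upper_dbp"])) {
    stop(sprintf(
      paste0("degenerate zones after rounding (raw cut-offs: ",
             "lower %.2f/%.2f, upper %.2f/%.2f mmHg)"),
      raw["lower_sbp"], raw["lower_dbp"], raw["upper_sbp"], raw["upper_dbp"]))
  }
  zb <- zone_boundaries(bp_threshold(rl[["lower_sbp"]], rl[["lower_dbp"]]),
                        bp_threshold(rl[["upper_sbp"]], rl[["upper_dbp"]]),
                        modality)
  attr(zb, "raw_cutoffs") <- raw
  zb
}

reference_bp <- function(cohort, reference = c("daytime", "24h")) {
  reference <- match.arg(reference)
  cols <- if (reference == "daytime") {
    c("daytime_sbp", "daytime_dbp")
  } else {
    c("abp24_sbp", "abp24_dbp")
  }
  if (!all(cols %in% names(cohort))) {
    stop("cohort lacks reference columns: ", paste(cols, collapse = ", "))
  }
  if (anyNA(cohort[[cols[1]]]) || anyNA(cohort[[cols[2]]])) {
    stop("cohort has missing ", reference, " reference BP values")
  }
  list(sbp = cohort[[cols[1]]], dbp = cohort[[cols[2]]])
}

#' Assign triage zones to BP values
#'
#' Worst-component logic: hypertension zone when SBP or DBP reaches the
#' upper boundary; normotension zone when both lie strictly below the lower
#' boundary; intermediate otherwise.
#'
#' @param sbp,dbp Numeric vectors (mmHg).
#' @param boundaries A [zone_boundaries()].
#' @return Factor with levels `normotension`, `intermediate`,
#'   `hypertension`.
#' @examples
#' zb <- zone_boundaries(bp_threshold(130, 80), bp_threshold(145, 95), "office")
#' assign_zone(c(138, 125, 129), c(88, 96, 79), zb)
#' @export
assign_zone <- function(sbp, dbp, boundaries) {
  stopifnot(inherits(boundaries, "zone_boundaries"), length(sbp) == length(dbp))
  up <- sbp >= boundaries$upper$sbp | dbp >= boundaries$upper$dbp
  lo <- sbp < boundaries$lower$sbp & dbp < boundaries$lower$dbp
  z <- ifelse(up, "hypertension", ifelse(lo, "normotension", "intermediate"))
  factor(z, levels = ZONES)
}
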