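#' Blood pressure threshold pair
#'
#' A systolic/diastolic threshold pair in mmHg, used with the "and/or" rule:
#' a BP value is hypertensive when SBP meets the systolic threshold OR DBP
#' meets the diastolic threshold.
#'
#' @param sbp Systolic threshold (mmHg).
#' @param dbp Diastolic threshold (mmHg).
#' @return An object of class `bp_threshold`.
#' @examples
#' bp_threshold(140, 90)  # office hypertension threshold
#' bp_threshold(135, 85)  # home / daytime ambulatory threshold
#' @export
bp_threshold <- function(sbp, dbp) {
  stopifnot(is.numeric(sbp), is.numeric(dbp), length(sbp) == 1L, length(dbp) == 1L)
  if (!(sbp > 0 && dbp > 0)) stop("threshold components must be positive")
  if (!(sbp > dbp)) stop("systolic threshold must exceed diastolic threshold")
  structure(list(sbp = as.numeric(sbp), dbp = as.numeric(dbp)),
            class = "bp_threshold")
}

#' @export
print.bp_threshold <- function(x, ...) {
  cat(sprintf("BP threshold: >= %g/%g mmHg (and/or rule)\n", x$sbp, x$dbp))
  invisible(x)
}

#' Conventional diagnostic thresholds
#'
#' Office hypertension is defined as >= 140/90 mmHg; home and daytime
#' ambulatory hypertension as >= 135/85 mmHg.
#'
#' @param modality One of `"office"`, `"home"`, `"daytime"`.
#' @return A [bp_threshold()].
#' @export
default_threshold <- function(modality = c("office", "home", "daytime")) {
  modality <- match.arg(modality)
  if (modality == "office") bp_threshold(140, 90) else bp_threshold(135, 85)
}

#' Test a BP value against a threshold (and/or rule)
#'
#' Returns `TRUE` when the systolic value is at or above the systolic
#' threshold, or the diastolic value is at or above the diastolic threshold.
#' Both comparisons are inclusive.
#'
#' @param sbp,dbp Numeric vectors of systolic/diastolic values (mmHg).
#' @param threshold A [bp_threshold()].
#' @return Logical vector.
#' @examples
#' is_hypertensive(134, 86, bp_threshold(135, 85))  # TRUE via DBP
#' is_hypertensive(134.9, 84.9, bp_threshold(135, 85))
#' @export
is_hypertensive <- function(sbp, dbp, threshold) {
  stopifnot(inherits(threshold, "bp_threshold"), length(sbp) == length(dbp))
  sbp >= threshold$sbp | dbp >= threshold$dbp
}

#' Hypertension phenotype labels
#'
#' The four phenotypes arising from crossing a screening test (office or
#' home BP) with the reference standard (daytime ambulatory BP):
#' concordant negative (NT, normotension), discordant screening-positive
#' (WH, white-coat hypertension), discordant screening-negative (MH, masked
#' hypertension), and concordant positive (SH, sustained hypertension).
#'
#' @format Character vector of length 4.
#' @export
PHENOTYPES <- c("NT", "WH", "MH", "SH")

#' Zone labels for the three-category triage partition
#' @format Character vector of length 3.
#' @export
ZONES <- c("normotension", "intermediate", "hypertension")

#' Classify hypertension phenotype
#'
#' @param screen_ht Logical: hypertensive by the screening modality's
#'   threshold?
#' @param reference_ht Logical: hypertensive by the reference standard?
#' @return Factor with levels `NT`, `WH`, `MH`, `SH` (vectorized).
#' @examples
#' classify_phenotype(TRUE, FALSE)   # white-coat hypertension
#' classify_phenotype(FALSE, TRUE)   # masked hypertension
#' @export
classify_phenotype <- function(screen_ht, reference_ht) {
  stopifnot(is.logical(screen_ht), is.logical(reference_ht),
            length(screen_ht) == length(reference_ht),
            !anyNA(screen_ht), !anyNA(reference_ht))
  lab <- ifelse(screen_ht,
                ifelse(reference_ht, "SH", "WH"),
                ifelse(reference_ht, "MH", "NT"))
  factor(lab, levels = PHENOTYPES)
}

#' Round a pressure to the nearest multiple of 5 mmHg
#'
#' Cut-offs are snapped to multiples of 5 mmHg for clinical practicality.
#' Exact midpoints (2.5 mod 5) round up.
#'
#' @param x Positive numeric vector (mmHg).
#' @return Numeric vector of multiples of 5.
#' @examples
#' round_to_multiple_of_5(c(130.2, 146.1, 94.0, 127.5))
#' @export
round_to_multiple_of_5 <- function(x) {
  stopifnot(is.numeric(x), all(x > 0))
  # floor(x/5 + 0.5) rounds half-up, unlike round()'s banker's rounding
  5 * floor(x / 5 + 0.5)
}
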