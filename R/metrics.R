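#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Central exact interval for a binomial proportion via beta quantiles.
#' The lower limit is 0 when `successes = 0` and the upper limit is 1 when
#' `successes = trials`.
#'
#' @param successes,trials Non-negative integer counts,
#'   `0 <= successes <= trials`, `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @return Object of class `proportion_ci`: `estimate`, `lower`, `upper`,
#'   `level`, `successes`, `trials`.
#' @examples
#' clopper_pearson(186, 188)   # rounds to (0.962, 0.999)
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  stopifnot(length(successes) == 1L, length(trials) == 1L,
            trials >= 1, successes >= 0, successes <= trials,
            successes == round(successes), trials == round(trials),
            level > 0, level < 1)
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else stats::qbeta(a, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else stats::qbeta(1 - a, successes + 1, trials - successes)
  structure(list(estimate = successes / trials, lower = lower, upper = upper,
                 level = level, successes = successes, trials = trials),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, digits = 1, ...) {
  cat(sprintf("%.*f%% (%.*f-%.*f%%), %d/%d, %g%% CI\n",
              digits, 100 * x$estimate, digits, 100 * x$lower,
              digits, 100 * x$upper, x$successes, x$trials, 100 * x$level))
  invisible(x)
}

#' Do two confidence intervals overlap?
#'
#' Closed-interval convention: touching endpoints count as overlap.
#' Non-overlap of 95% intervals is the package's (conservative) criterion
#' for a statistically significant difference between two proportions.
#'
#' @param a,b `proportion_ci` objects (same level).
#' @return Logical flag.
#' @export
ci_overlap <- function(a, b) {
  stopifnot(inherits(a, "proportion_ci"), inherits(b, "proportion_ci"))
  if (!isTRUE(all.equal(a$level, b$level))) {
    stop("intervals have different confidence levels")
  }
  a$lower <= b$upper && b$lower <= a$upper
}

#' Diagnostic metric panel from confusion counts
#'
#' Sensitivity, specificity, PPV, NPV and accuracy, each with an exact
#' Clopper-Pearson interval, plus the single-operating-point AUC
#' `(sensitivity + specificity) / 2` — the trapezoidal area under the
#' one-point ROC curve of a binary test. The AUC interval uses the
#' Hanley-McNeil standard error (labelled as such; a large-sample
#' approximation, unlike the exact proportion intervals).
#'
#' A metric whose denominator is zero is returned as `NA` and flagged in
#' `undefined`; the others are still computed.
#'
#' @param counts A [confusion_counts()].
#' @param level Confidence level (default 0.95).
#' @return Object of class `diagnostic_metrics`: named list of
#'   `proportion_ci` (`sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`), `auc` (estimate/lower/upper/method), `counts`,
#'   `undefined`.
#' @examples
#' m <- compute_metrics(confusion_counts(tp = 186, fp = 7, fn = 2, tn = 61))
#' m$sensitivity$estimate  # 0.989
#' m$auc$estimate          # 0.943
#' @export
compute_metrics <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n <- tp + fp + fn + tn
  safe <- function(k, d) if (d >= 1) clopper_pearson(k, d, level) else NULL
  m <- list(sensitivity = safe(tp, tp + fn),
            specificity = safe(tn, tn + fp),
            ppv = safe(tp, tp + fp),
            npv = safe(tn, tn + fn),
            accuracy = safe(tp + tn, n))
  undefined <- names(m)[vapply(m, is.null, logical(1))]
  auc <- NULL
  if (!is.null(m$sensitivity) && !is.null(m$specificity)) {
    a <- (m$sensitivity$estimate + m$specificity$estimate) / 2
    npos <- tp + fn; nneg <- tn + fp
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (npos - 1) * (q1 - a^2) +
                  (nneg - 1) * (q2 - a^2)) / (npos * nneg))
    zq <- stats::qnorm(1 - (1 - level) / 2)
    auc <- list(estimate = a, lower = max(0, a - zq * se),
                upper = min(1, a + zq * se), se = se,
                method = "Hanley-McNeil")
  } else {
    undefined <- c(undefined, "auc")
  }
  structure(c(m[!vapply(m, is.null, logical(1))],
              list(auc = auc, counts = counts, level = level,
                   undefined = undefined)),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  fmt <- function(ci) sprintf("%5.1f (%.1f-%.1f)", 100 * ci$estimate,
                              100 * ci$lower, 100 * ci$upper)
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("%-12s %s %%\n", nm, fmt(x[[nm]])))
    } else {
      cat(sprintf("%-12s undefined (zero denominator)\n", nm))
    }
  }
  if (!is.null(x$auc)) {
    cat(sprintf("%-12s %.3f (%.3f-%.3f) [%s]\n", "auc", x$auc$estimate,
                x$auc$lower, x$auc$upper, x$auc$method))
  }
  invisible(x)
}

#' Flatten a metric panel to a one-row data frame
#'
#' Percentages to one decimal, AUC to three, matching conventional print
#' precision for diagnostic accuracy tables.
#'
#' @param x A `diagnostic_metrics` object.
#' @param label Optional row label (e.g. the strategy name).
#' @return Data frame with estimate and CI columns per metric.
#' @export
metrics_row <- function(x, label = NA_character_) {
  stopifnot(inherits(x, "diagnostic_metrics"))
  out <- data.frame(label = label, stringsAsFactors = FALSE)
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    ci <- x[[nm]]
    out[[nm]] <- if (is.null(ci)) NA_real_ else round(100 * ci$estimate, 1)
    out[[paste0(nm, "_lo")]] <- if (is.null(ci)) NA_real_ else round(100 * ci$lower, 1)
    out[[paste0(nm, "_hi")]] <- if (is.null(ci)) NA_real_ else round(100 * ci$upper, 1)
  }
  out$auc <- if (is.null(x$auc)) NA_real_ else round(x$auc$estimate, 3)
  out$auc_lo <- if (is.null(x$auc)) NA_real_ else round(x$auc$lower, 3)
  out$auc_hi <- if (is.null(x$auc)) NA_real_ else round(x$auc$upper, 3)
  out
}
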