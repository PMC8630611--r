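READINGS_HEADER <- c("subject_id", "modality", "arm", "visit", "day",
                     "session", "reading_index", "timestamp", "sbp", "dbp",
                     "valid")

#' Read a reading-level BP CSV
#'
#' The file must carry exactly the header
#' `subject_id, modality, arm, visit, day, session, reading_index,
#' timestamp, sbp, dbp, valid`; fields not applicable to a modality are
#' empty. Office rows need `arm`, `visit`, `reading_index`; home rows need
#' `day`, `session`, `reading_index`; ambulatory rows need `timestamp`
#' (24-h `HH:MM`) and `valid`. Row-level violations (unknown modality,
#' `sbp <= dbp`, out-of-range pressures, missing context) are collected
#' and reported together.
#'
#' @param path CSV file path.
#' @return Reading-level data frame (typed columns, `NA` for
#'   non-applicable fields).
#' @export
read_readings_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                         check.names = FALSE)
  if (!identical(names(raw), READINGS_HEADER)) {
    stop("unexpected header: ", paste(names(raw), collapse = ","),
         "\nexpected: ", paste(READINGS_HEADER, collapse = ","))
  }
  to_num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  to_int <- function(x) suppressWarnings(as.integer(ifelse(x == "", NA, x)))
  to_chr <- function(x) ifelse(x == "", NA_character_, x)
  df <- data.frame(
    subject_id = to_int(raw$subject_id),
    modality = to_chr(raw$modality), arm = to_chr(raw$arm),
    visit = to_int(raw$visit), day = to_int(raw$day),
    session = to_chr(raw$session), reading_index = to_int(raw$reading_index),
    timestamp = to_chr(raw$timestamp),
    sbp = to_num(raw$sbp), dbp = to_num(raw$dbp),
    valid = as.logical(ifelse(raw$valid == "", NA, raw$valid)),
    stringsAsFactors = FALSE)

  errs <- character(0)
  bad <- function(rows, what) {
    if (any(rows)) {
      errs <<- c(errs, sprintf("row %d: %s", which(rows), what))
    }
  }
  bad(is.na(df$modality) | !df$modality %in% c("office", "home", "ambulatory"),
      "unknown modality")
  bad(is.na(df$sbp) | is.na(df$dbp), "missing sbp/dbp")
  ok_bp <- !is.na(df$sbp) & !is.na(df$dbp)
  bad(ok_bp & df$sbp <= df$dbp, "sbp <= dbp")
  bad(ok_bp & (df$sbp < 40 | df$sbp > 300), "sbp outside [40, 300]")
  bad(ok_bp & (df$dbp < 20 | df$dbp > 200), "dbp outside [20, 200]")
  off <- !is.na(df$modality) & df$modality == "office"
  bad(off & (is.na(df$arm) | is.na(df$visit) | is.na(df$reading_index)),
      "office row missing arm/visit/reading_index")
  hom <- !is.na(df$modality) & df$modality == "home"
  bad(hom & (is.na(df$day) | is.na(df$session) | is.na(df$reading_index)),
      "home row missing day/session/reading_index")
  amb <- !is.na(df$modality) & df$modality == "ambulatory"
  bad(amb & (is.na(df$timestamp) | is.na(df$valid)),
      "ambulatory row missing timestamp/valid")
  ts_ok <- vapply(df$timestamp[amb & !is.na(df$timestamp)],
                  function(x) !inherits(try(parse_hm(x), silent = TRUE), "try-error"),
                  logical(1))
  if (length(ts_ok) && !all(ts_ok)) {
    errs <- c(errs, sprintf("row %d: malformed timestamp",
                            which(amb & !is.na(df$timestamp))[!ts_ok]))
  }
  if (length(errs)) {
    stop("invalid readings file ", path, ":\n  ",
         paste(utils::head(errs, 25), collapse = "\n  "),
         if (length(errs) > 25) sprintf("\n  ... and %d more", length(errs) - 25))
  }
  df
}

#' Write a reading-level BP CSV
#'
#' Inverse of [read_readings_csv()]; numeric pressures are written at full
#' precision so write-then-read is an identity.
#'
#' @param readings Reading-level data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_readings_csv <- function(readings, path) {
  stopifnot(is.data.frame(readings),
            identical(names(readings), READINGS_HEADER))
  out <- readings
  out$sbp <- sprintf("%.17g", out$sbp)
  out$dbp <- sprintf("%.17g", out$dbp)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a phenotype-by-zone count table from CSV
#'
#' Layout: first column `phenotype` with rows NT/WH/MH/SH, then the three
#' zone columns. The arm is taken from a header comment line
#' (`# ... arm=office ...`) when present, or given explicitly.
#'
#' @param path CSV file path.
#' @param arm Override the arm recorded in the file.
#' @return A [zone_phenotype_table()].
#' @export
read_zone_table_csv <- function(path, arm = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(arm)) {
    m <- regmatches(first, regexec("arm=(office|home)", first))[[1]]
    if (length(m) == 2L) arm <- m[2] else
      stop("arm not recorded in ", path, "; pass arm explicitly")
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  stopifnot(identical(names(df), c("phenotype", ZONES)),
            identical(df$phenotype, PHENOTYPES))
  counts <- as.matrix(df[, ZONES])
  rownames(counts) <- df$phenotype
  zone_phenotype_table(counts, arm)
}

#' Write a phenotype-by-zone count table to CSV
#'
#' @param table A [zone_phenotype_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_zone_table_csv <- function(table, path) {
  stopifnot(inherits(table, "zone_phenotype_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bptriage zone-phenotype counts v1, arm=%s, n=%d",
                     table$arm, table$n_total), con)
  df <- data.frame(phenotype = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published reference count tables
#'
#' The phenotype-by-zone distributions of the original development
#' (n = 256) and validation (n = 399) cohorts, as published, for the
#' office and home screening arms under the fixed zones office
#' 130-144/80-94 and home 120-144/80-94 mmHg. These count tables make the
#' published diagnostic-accuracy panels exactly recomputable at the count
#' level.
#'
#' @param population `"development"` or `"validation"`.
#' @param arm `"office"` or `"home"`.
#' @return A [zone_phenotype_table()].
#' @examples
#' compute_metrics(evaluate_from_zone_table(reference_counts()))
#' @export
reference_counts <- function(population = c("development", "validation"),
                             arm = c("office", "home")) {
  population <- match.arg(population)
  arm <- match.arg(arm)
  path <- system.file("extdata",
                      sprintf("counts_%s_%s.csv", population, arm),
                      package = "bptriage", mustWork = TRUE)
  read_zone_table_csv(path)
}

#' The fixed published zone boundaries
#'
#' Office: normotension < 130/80, hypertension >= 145/95; home:
#' normotension < 120/80, hypertension >= 145/95 (all mmHg).
#'
#' @param modality `"office"` or `"home"`.
#' @return A [zone_boundaries()].
#' @export
reference_zones <- function(modality = c("office", "home")) {
  modality <- match.arg(modality)
  if (modality == "office") {
    zone_boundaries(bp_threshold(130, 80), bp_threshold(145, 95), "office")
  } else {
    zone_boundaries(bp_threshold(120, 80), bp_threshold(145, 95), "home")
  }
}

#' Serialize zone boundaries to / from JSON
#'
#' @param boundaries A [zone_boundaries()] (or a list of them).
#' @param path JSON file path.
#' @return `path` invisibly for the writer; a [zone_boundaries()] or list
#'   of them for the reader.
#' @export
write_zones_json <- function(boundaries, path) {
  as_one <- function(zb) {
    x <- list(modality = zb$modality,
              lower = list(sbp = zb$lower$sbp, dbp = zb$lower$dbp),
              upper = list(sbp = zb$upper$sbp, dbp = zb$upper$dbp))
    raw <- attr(zb, "raw_cutoffs")
    if (!is.null(raw)) x$raw_cutoffs <- as.list(raw)
    x
  }
  obj <- if (inherits(boundaries, "zone_boundaries")) as_one(boundaries) else
    lapply(boundaries, as_one)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_zones_json
#' @export
read_zones_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  from_one <- function(x) {
    zb <- zone_boundaries(bp_threshold(x$lower$sbp, x$lower$dbp),
                          bp_threshold(x$upper$sbp, x$upper$dbp), x$modality)
    if (!is.null(x$raw_cutoffs)) {
      attr(zb, "raw_cutoffs") <- unlist(x$raw_cutoffs)
    }
    zb
  }
  if (!is.null(obj$modality)) from_one(obj) else lapply(obj, from_one)
}
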