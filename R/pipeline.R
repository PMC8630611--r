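#' Pipeline run configuration
#'
#' Declarative description of one end-to-end run: where the data come from
#' (simulation, a reading-level CSV, or phenotype-by-zone count tables),
#' how zones are obtained (derived by ROC or fixed), which cascade
#' strategies to evaluate, and where to write the report bundle.
#'
#' @param mode `"simulate"`, `"from-readings"` or `"from-table"`.
#' @param out_dir Output directory for the report bundle.
#' @param params [cohort_params()] (simulate mode; built from `seed` and
#'   `preset` when omitted).
#' @param readings_path Reading-level CSV (from-readings mode).
#' @param table_paths Named list/vector with elements `office` and/or
#'   `home` pointing at count-table CSVs (from-table mode).
#' @param zone_mode `"derive"` or `"fixed"`.
#' @param office_zones,home_zones Fixed [zone_boundaries()] (required when
#'   `zone_mode = "fixed"`).
#' @param strategies Subset of `OBP_ABP`, `OBP_HBP_ABP`, `HBP_ABP`.
#' @param reference `"daytime"` or `"24h"`.
#' @param scheme Office aggregation scheme; defaults to the preset.
#' @param level Confidence level for all intervals.
#' @param seed Root seed (simulate mode).
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "from-readings", "from-table"),
                       out_dir = tempfile("bptriage-run-"),
                       params = NULL, readings_path = NULL, table_paths = NULL,
                       zone_mode = c("derive", "fixed"),
                       office_zones = NULL, home_zones = NULL,
                       strategies = c("OBP_ABP", "OBP_HBP_ABP", "HBP_ABP"),
                       reference = c("daytime", "24h"),
                       scheme = NULL, level = 0.95, seed = 1L) {
  mode <- match.arg(mode)
  zone_mode <- match.arg(zone_mode)
  reference <- match.arg(reference)
  strategies <- match.arg(strategies, several.ok = TRUE)
  sources <- c(simulate = mode == "simulate",
               readings = !is.null(readings_path),
               tables = !is.null(table_paths))
  if (sum(sources) != 1L) {
    stop("exactly one input source must be configured (got: ",
         paste(names(sources)[sources], collapse = ", "), ")")
  }
  if (mode == "simulate" && is.null(params)) {
    params <- cohort_params(seed = seed)
  }
  if (mode == "from-table") {
    if (zone_mode == "derive") {
      stop("zones cannot be derived from count tables; use zone_mode = 'fixed'")
    }
    stopifnot(!is.null(names(table_paths)),
              all(names(table_paths) %in% c("office", "home")))
  }
  if (zone_mode == "fixed") {
    for (zb in list(office_zones, home_zones)) {
      if (!is.null(zb)) stopifnot(inherits(zb, "zone_boundaries"))
    }
    if (is.null(office_zones) && is.null(home_zones)) {
      stop("zone_mode = 'fixed' requires office_zones and/or home_zones")
    }
  }
  if (is.null(scheme)) {
    scheme <- if (!is.null(params)) params$preset else "development"
  }
  scheme <- match.arg(scheme, c("development", "validation"))
  structure(list(mode = mode, out_dir = out_dir, params = params,
                 readings_path = readings_path, table_paths = table_paths,
                 zone_mode = zone_mode, office_zones = office_zones,
                 home_zones = home_zones, strategies = strategies,
                 reference = reference, scheme = scheme, level = level,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full triage pipeline
#'
#' Executes generate/ingest, screening, aggregation, zone derivation (or
#' fixed zones), phenotype-by-zone tabulation, strategy evaluation and the
#' metric panels, writing every artifact into `config$out_dir`:
#' `readings.csv` and `latent.csv` (simulate mode), `subjects.csv`,
#' `zones.json`, `counts_office.csv` / `counts_home.csv`,
#' `threshold_alone.csv`, `cascade.csv`, `flow.csv` and `run_log.txt`.
#' Deterministic given the configuration (including its seed).
#'
#' In from-table mode only the count-level results are computable: the
#' threshold-alone panels and the single-escalation cascades (OBP-ABP from
#' the office table, HBP-ABP from the home table).
#'
#' @param config A [run_config()].
#' @return Object of class `report_bundle`: the in-memory tables, metric
#'   panels, zones, attrition log and file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- character(0)
  say <- function(...) logf <<- c(logf, sprintf(...))
  paths <- list()
  wpath <- function(nm) file.path(config$out_dir, nm)

  tables <- list()
  cohort <- NULL
  zones <- list(office = config$office_zones, home = config$home_zones)

  if (config$mode == "from-table") {
    for (arm in names(config$table_paths)) {
      tables[[arm]] <- read_zone_table_csv(config$table_paths[[arm]], arm = arm)
      say("loaded %s count table (n = %d)", arm, tables[[arm]]$n_total)
    }
  } else {
    if (config$mode == "simulate") {
      gen <- generate_cohort(config$params)
      readings <- gen$readings
      paths$readings <- write_readings_csv(readings, wpath("readings.csv"))
      utils::write.csv(gen$latent, wpath("latent.csv"), row.names = FALSE)
      paths$latent <- wpath("latent.csv")
      say("simulated %d subjects (%d readings)",
          config$params$n_subjects, nrow(readings))
      schedule <- config$params$schedule
      screen_thr <- config$params$screening_threshold
    } else {
      readings <- read_readings_csv(config$readings_path)
      say("read %d readings from %s", nrow(readings), config$readings_path)
      schedule <- schedule_spec()
      screen_thr <- bp_threshold(140, 90)
    }
    n0 <- length(unique(readings$subject_id))
    readings <- apply_screening(readings, screen_thr)
    scr <- attr(readings, "screening")
    for (i in which(!scr$retained)) {
      say("excluded subject %s at screening: %s (visit-1 mean %.1f/%.1f)",
          scr$subject_id[i], scr$reason[i], scr$visit1_sbp[i], scr$visit1_dbp[i])
    }
    n1 <- length(unique(readings$subject_id))
    say("screening (>= %g/%g mmHg at visit 1): %d -> %d subjects",
        screen_thr$sbp, screen_thr$dbp, n0, n1)
    cohort <- aggregate_subjects(readings, config$scheme, schedule)
    drop <- !(cohort$home_valid & cohort$abp_valid)
    for (i in which(drop)) {
      say("excluded subject %s: %s", cohort$subject_id[i],
          paste(c("invalid home series"[!cohort$home_valid[i]],
                  "invalid ambulatory series"[!cohort$abp_valid[i]]),
                collapse = " + "))
    }
    cohort <- cohort[!drop, , drop = FALSE]
    say("validity filters: %d -> %d subjects with complete data", n1, nrow(cohort))
    if (nrow(cohort) == 0) {
      stop("no subjects remain after screening and validity filters; ",
           sum(drop), " dropped by validity, see run log")
    }
    utils::write.csv(cohort, wpath("subjects.csv"), row.names = FALSE)
    paths$subjects <- wpath("subjects.csv")

    if (config$zone_mode == "derive") {
      zones$office <- derive_zone_boundaries(cohort, "office", config$reference)
      zones$home <- derive_zone_boundaries(cohort, "home", config$reference)
      say("derived office zones: %g-%g / %g-%g mmHg",
          zones$office$lower$sbp, zones$office$upper$sbp,
          zones$office$lower$dbp, zones$office$upper$dbp)
      say("derived home zones: %g-%g / %g-%g mmHg",
          zones$home$lower$sbp, zones$home$upper$sbp,
          zones$home$lower$dbp, zones$home$upper$dbp)
    }
    for (arm in c("office", "home")) {
      if (!is.null(zones[[arm]])) {
        tables[[arm]] <- tabulate_zone_phenotypes(cohort, zones[[arm]], arm,
                                                  config$reference)
      }
    }
  }

  if (length(Filter(Negate(is.null), zones))) {
    paths$zones <- write_zones_json(Filter(Negate(is.null), zones),
                                    wpath("zones.json"))
  }
  for (arm in names(tables)) {
    paths[[paste0("counts_", arm)]] <-
      write_zone_table_csv(tables[[arm]], wpath(sprintf("counts_%s.csv", arm)))
    stopifnot(sum(tables[[arm]]$counts) == tables[[arm]]$n_total)  # cross-foot
  }

  # threshold-alone panels (all subjects / excluding the intermediate zone)
  thr_rows <- list()
  for (arm in names(tables)) {
    for (excl in c(FALSE, TRUE)) {
      cc <- tryCatch(
        evaluate_threshold_alone(tables[[arm]], exclude_intermediate = excl),
        error = function(e) {
          say("threshold-alone (%s, excluding intermediate) not evaluable: %s",
              arm, conditionMessage(e))
          NULL
        })
      if (is.null(cc)) next
      m <- compute_metrics(cc, config$level)
      thr_rows[[length(thr_rows) + 1L]] <-
        cbind(arm = arm,
              subset = if (excl) "excluding_intermediate" else "all",
              n = cc$tp + cc$fp + cc$fn + cc$tn,
              metrics_row(m, label = sprintf("%s_BP_alone", arm)))
    }
  }
  threshold_alone <- do.call(rbind, thr_rows)
  utils::write.csv(threshold_alone, wpath("threshold_alone.csv"),
                   row.names = FALSE)
  paths$threshold_alone <- wpath("threshold_alone.csv")

  # cascade panels
  casc_rows <- list(); flow_rows <- list(); cascade_metrics <- list()
  for (st in config$strategies) {
    cc <- NULL
    if (!is.null(cohort)) {
      need_home <- st %in% c("OBP_HBP_ABP", "HBP_ABP")
      if ((st != "HBP_ABP" && is.null(zones$office)) ||
          (need_home && is.null(zones$home))) {
        say("strategy %s skipped: required zones not configured", st)
        next
      }
      outc <- diagnose_cohort(cohort, st, zones$office, zones$home,
                              config$reference)
      cc <- evaluate_strategy(cohort, st, zones$office, zones$home,
                              config$reference)
      fl <- as.data.frame(table(stage = outc$terminal_stage,
                                diagnosis = outc$diagnosis))
      fl <- fl[fl$Freq > 0, , drop = FALSE]
      flow_rows[[st]] <- cbind(strategy = st, fl)
      stopifnot(sum(fl$Freq) == nrow(cohort))  # cross-foot at cascade depth
    } else {
      # count-level route: single-escalation strategies only
      arm <- switch(st, OBP_ABP = "office", HBP_ABP = "home", NA_character_)
      if (is.na(arm) || is.null(tables[[arm]])) {
        say("strategy %s not computable from count tables", st)
        next
      }
      cc <- evaluate_from_zone_table(tables[[arm]])
      ct <- tables[[arm]]$counts
      flow_rows[[st]] <- data.frame(
        strategy = st,
        stage = c(arm, arm, "ambulatory", "ambulatory"),
        diagnosis = c("hypertensive", "normotensive", "hypertensive",
                      "normotensive"),
        Freq = c(sum(ct[, "hypertension"]), sum(ct[, "normotension"]),
                 sum(ct[c("MH", "SH"), "intermediate"]),
                 sum(ct[c("NT", "WH"), "intermediate"])))
    }
    m <- compute_metrics(cc, config$level)
    cascade_metrics[[st]] <- m
    casc_rows[[st]] <- cbind(strategy = st, n = cc$tp + cc$fp + cc$fn + cc$tn,
                             metrics_row(m, label = st))
  }
  cascade <- if (length(casc_rows)) do.call(rbind, casc_rows) else NULL
  if (!is.null(cascade)) {
    utils::write.csv(cascade, wpath("cascade.csv"), row.names = FALSE)
    paths$cascade <- wpath("cascade.csv")
  }
  flow <- if (length(flow_rows)) do.call(rbind, flow_rows) else NULL
  if (!is.null(flow)) {
    utils::write.csv(flow, wpath("flow.csv"), row.names = FALSE)
    paths$flow <- wpath("flow.csv")
  }

  writeLines(logf, wpath("run_log.txt"))
  paths$log <- wpath("run_log.txt")
  structure(list(config = config, cohort = cohort, zones = zones,
                 tables = tables, threshold_alone = threshold_alone,
                 cascade = cascade, cascade_metrics = cascade_metrics,
                 flow = flow, log = logf, paths = paths),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("bptriage report bundle:", x$config$mode, "mode\n")
  if (!is.null(x$cohort)) cat("  subjects analyzed:", nrow(x$cohort), "\n")
  for (arm in names(x$tables)) {
    cat(sprintf("  %s counts (n = %d)\n", arm, x$tables[[arm]]$n_total))
  }
  if (!is.null(x$cascade)) {
    cat("  cascade accuracy (%):\n")
    print(x$cascade[, c("strategy", "n", "accuracy", "accuracy_lo",
                        "accuracy_hi", "auc")], row.names = FALSE)
  }
  cat("  artifacts in:", x$config$out_dir, "\n")
  invisible(x)
}
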