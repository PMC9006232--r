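#' Build a duty calendar from a config entry
#'
#' Accepts either an explicit `dates` vector or a `from`/`to` range with
#' `days_per_week` (7 = every day), plus an optional `window`.
#'
#' @param method observation method.
#' @param spec named list from the config tree.
#' @return a [duty_calendar()].
#' @keywords internal
calendar_from_spec <- function(method, spec) {
  window <- spec$window %||% c("06:00:00", "18:00:00")
  if (!is.null(spec$dates)) {
    return(duty_calendar(method, as.Date(unlist(spec$dates)), window))
  }
  if (is.null(spec$from) || is.null(spec$to)) {
    abort(sprintf("calendar for '%s' needs either dates or from/to", method))
  }
  dpw <- spec$days_per_week %||% 7
  if (dpw >= 7) {
    daily_calendar(method, spec$from, spec$to, window)
  } else {
    weekday_calendar(method, spec$from, spec$to, dpw, window)
  }
}

clip_calendar <- function(cal, start_date, end_date) {
  dates <- cal$dates[cal$dates >= as.Date(start_date) & cal$dates <= as.Date(end_date)]
  duty_calendar(cal$method, dates,
                c(format_tod(cal$window_start), format_tod(cal$window_end)))
}

#' Render the agreement table as aligned text
#' @param tab output of [agreement_table()].
#' @return character vector of lines.
#' @export
render_agreement_text <- function(tab) {
  fmt_p <- function(p) ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3f", p)))
  body <- sprintf("%-40s %-42s %-8s %6.2f %11.3g %11.3g %8s%s",
                  tab$predictor, tab$response, tab$species, tab$adj_r2,
                  tab$residual_se, tab$f_stat, fmt_p(tab$p_value),
                  ifelse(tab$significant, " *", ""))
  header <- sprintf("%-40s %-42s %-8s %6s %11s %11s %8s", "Predictor", "Response",
                    "Species", "AdjR2", "ResidSE", "F", "p")
  c(header, strrep("-", nchar(header)), body, "", "* p < .05 (8 simultaneous tests, uncorrected)")
}

#' Run the full method-comparison pipeline
#'
#' End-to-end composition of the package's stages: obtain the three raw data
#' streams (synthetic simulation or CSV inputs), delineate independent events
#' per method, aggregate daily measures to matched-day ten-day-period means,
#' fit the eight agreement regressions, and run the camera-subset design
#' simulation. All stage outputs are written as CSV plus a plain-text summary
#' and a JSON run manifest recording seed, configuration hash, package
#' version, per-stage row counts and input checksums.
#'
#' The configuration is a nested key/value tree (YAML file or R list):
#' \describe{
#'   \item{mode}{`"synthetic"` or `"real"`.}
#'   \item{seed}{integer master seed (synthetic mode).}
#'   \item{generator}{[generator_config()] fields (synthetic mode).}
#'   \item{inputs}{real mode: paths `camera_photos`, `guard_log`,
#'     `researcher_log`, `stations`, and a `calendars` block per method.}
#'   \item{clustering}{`camera_window_min`, `obs_gap_min`.}
#'   \item{analysis}{`start_date`, `end_date`, `period_len_days`,
#'     `diurnal_only` (default `TRUE`: only events starting 06:00-18:00 enter
#'     the comparison).}
#'   \item{subsets}{`sizes` (default 1..n stations), `restrict_to_analysis`
#'     (default `FALSE`: the design simulation uses the full deployment
#'     stream).}
#' }
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param out_dir output directory.
#' @param strict promote rejected input rows to errors.
#' @return invisibly, a list with all in-memory stage results (`events`,
#'   `measures`, `agreement`, `subset_results`, `subset_summary`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, strict = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  mode <- config$mode %||% "synthetic"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  checksums <- list()

  if (mode == "synthetic") {
    gen <- config$generator %||% list()
    if (!is.null(config$seed)) gen$seed <- config$seed
    gcfg <- as_generator_config(gen)
    sim <- simulate_dataset(gcfg)
    write_dataset(sim, file.path(out_dir, "data"))
    detections <- sim$detections
    guard_log <- sim$guard_log
    researcher_log <- sim$researcher_log
    stations <- sim$stations
    calendars <- sim$calendars
    default_range <- c(gcfg$start_date, gcfg$end_date)
    counts$truth_events <- nrow(sim$truth)
  } else {
    inp <- config$inputs
    for (key in c("camera_photos", "guard_log", "researcher_log", "stations")) {
      if (is.null(inp[[key]])) abort(sprintf("real-mode config missing input: %s", key))
    }
    stations <- read_stations_csv(inp$stations)
    detections <- read_camera_csv(inp$camera_photos, stations, strict = strict)
    guard_log <- read_guard_csv(inp$guard_log, strict = strict)
    researcher_log <- read_researcher_csv(inp$researcher_log, strict = strict)
    cal_spec <- inp$calendars %||% abort("real-mode config missing inputs$calendars")
    calendars <- lapply(setNames(nm = METHOD_LEVELS), function(m) {
      if (is.null(cal_spec[[m]])) abort(sprintf("missing calendar for method: %s", m))
      calendar_from_spec(m, cal_spec[[m]])
    })
    default_range <- range(unlist(lapply(calendars, function(x) x$dates)))
    default_range <- as.Date(default_range, origin = "1970-01-01")
    for (key in c("camera_photos", "guard_log", "researcher_log", "stations")) {
      checksums[[key]] <- rlang::hash(readLines(inp[[key]], warn = FALSE))
    }
    counts$rejected_rows <- sum(attr(detections, "n_rejected") %||% 0,
                                attr(guard_log, "n_rejected") %||% 0,
                                attr(researcher_log, "n_rejected") %||% 0)
  }
  counts$detections <- nrow(detections)
  counts$guard_records <- nrow(guard_log)
  counts$researcher_records <- nrow(researcher_log)

  # --- event delineation ------------------------------------------------
  ccfg <- do.call(clustering_config, config$clustering %||% list())
  cam_events <- cluster_detections(detections, ccfg)
  guard_events <- guard_records_to_events(guard_log, ccfg)
  res_events <- researcher_records_to_events(researcher_log, ccfg)
  events <- dplyr::bind_rows(cam_events, guard_events, res_events)
  write_events_csv(events, file.path(out_dir, "events.csv"))
  counts$camera_events <- nrow(cam_events)
  counts$guard_events <- nrow(guard_events)
  counts$researcher_events <- nrow(res_events)

  # --- matched-day period aggregation ----------------------------------
  an <- config$analysis %||% list()
  start_date <- as.Date(an$start_date %||% default_range[1])
  end_date <- as.Date(an$end_date %||% default_range[2])
  period_len <- an$period_len_days %||% 10
  diurnal_only <- an$diurnal_only %||% TRUE
  window <- an$diurnal_window %||% c("06:00:00", "18:00:00")

  periods <- build_periods(start_date, end_date, period_len)
  cal_clip <- lapply(calendars, clip_calendar, start_date, end_date)
  matched <- matched_days(cal_clip)

  in_range <- function(ev) ev[as.Date(ev$start) >= start_date & as.Date(ev$start) <= end_date, ]
  cam_cmp <- in_range(if (diurnal_only) filter_diurnal(cam_events, window) else cam_events)
  daily <- bind_daily_measures(
    list(daily_event_counts(cam_cmp, cal_clip$camera),
         daily_event_counts(in_range(guard_events), cal_clip$guard),
         daily_event_counts(in_range(res_events), cal_clip$researcher)),
    crop_loss_daily(in_range(res_events), cal_clip$researcher)
  )
  measures <- aggregate_to_periods(daily, matched, periods)
  readr::write_csv(measures, file.path(out_dir, "period_measures.csv"))
  counts$matched_days <- length(matched)
  counts$period_measures <- nrow(measures)

  # --- agreement regressions -------------------------------------------
  agreement <- agreement_table(measures)
  readr::write_csv(agreement, file.path(out_dir, "agreement.csv"))
  counts$agreement_fits <- nrow(agreement)

  # --- camera-subset design simulation ---------------------------------
  sub_cfg <- config$subsets %||% list()
  sizes <- unlist(sub_cfg$sizes) %||% seq_len(nrow(stations))
  sub_detections <- if (isTRUE(sub_cfg$restrict_to_analysis)) {
    detections[as.Date(detections$timestamp) >= start_date &
                 as.Date(detections$timestamp) <= end_date, ]
  } else {
    detections
  }
  subset_results <- subset_event_counts(sub_detections, stations, sizes, ccfg)
  readr::write_csv(subset_results, file.path(out_dir, "subsets.csv"))
  ssum <- subset_summary(subset_results)
  readr::write_csv(ssum$by_size, file.path(out_dir, "subsets_by_size.csv"))
  readr::write_csv(ssum$fold_ratio, file.path(out_dir, "single_camera_fold_ratio.csv"))
  counts$subsets <- length(unique(subset_results$subset_id))

  writeLines(render_agreement_text(agreement), file.path(out_dir, "summary.txt"))

  manifest <- list(
    package = "cropwatch",
    version = as.character(packageVersion("cropwatch")),
    mode = mode,
    seed = config$seed %||% (config$generator$seed %||% NA),
    config_hash = rlang::hash(config),
    input_checksums = checksums,
    row_counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(events = events, measures = measures, agreement = agreement,
                 subset_results = subset_results, subset_summary = ssum,
                 manifest = manifest))
}
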