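#' Event-delineation configuration
#'
#' Two rules delineate independent crop-foraging events. Camera photographs
#' of one species are clustered with a temporal-independence window: a
#' photograph starts a new event iff at least `camera_window_min` minutes have
#' passed since the previous photograph of the same species on any retained
#' camera (the field's visits rarely exceed 30 minutes, so 30 is the default).
#' Observer records (guard, researcher) follow the empty-field rule: at least
#' `obs_gap_min` minutes with no animals in the field separate events;
#' records closer together are merged. Setting `obs_gap_min = 0` takes
#' observer records verbatim without deduplication.
#'
#' @param camera_window_min camera independence window in minutes (> 0).
#' @param obs_gap_min observer empty-field gap in minutes (>= 0; 0 disables
#'   merging).
#' @return list of class `clustering_config`.
#' @export
clustering_config <- function(camera_window_min = 30, obs_gap_min = 1) {
  stopifnot(camera_window_min > 0, obs_gap_min >= 0)
  structure(list(camera_window_min = camera_window_min, obs_gap_min = obs_gap_min),
            class = "clustering_config")
}

empty_events_tbl <- function() {
  tibble::tibble(method = character(0), species = character(0),
                 start = as.POSIXct(character(0), tz = "UTC"),
                 end = as.POSIXct(character(0), tz = "UTC"),
                 items_removed = integer(0), n_detections = integer(0))
}

#' Cluster camera photographs into independent crop-foraging events
#'
#' Greedy chronological scan over the pooled photo stream of the retained
#' stations, per species: a photograph opens a new event iff the gap to the
#' immediately preceding photograph of the same species (on any retained
#' station) is at least the independence window; the boundary is inclusive
#' ("at least 30 min had passed" starts a new event). Photographs of
#' different species never share an event. Event start and end are the first
#' and last photograph times; `n_detections` counts photographs merged. The
#' scan runs over the full stream, crossing midnight freely.
#'
#' Pooling more stations can merge events rather than only adding them: a
#' bridging photograph on an extra camera can connect two otherwise
#' independent clusters. This non-monotonicity is intrinsic to the pooled
#' window rule.
#'
#' @param detections tibble `(station_id, timestamp, species, ...)`; sorted
#'   internally if needed.
#' @param config a [clustering_config()].
#' @param stations_subset optional character vector of station ids; if given,
#'   detections are first restricted to those stations.
#' @return event-record tibble (`method = "camera"`), one row per independent
#'   event, ordered by species then start.
#' @examples
#' det <- tibble::tibble(
#'   station_id = "C1",
#'   timestamp = as.POSIXct("2013-05-01 09:00:00", tz = "UTC") +
#'     c(0, 600, 2700, 7200),
#'   species = "baboon")
#' cluster_detections(det, clustering_config())
#' @export
cluster_detections <- function(detections, config = clustering_config(),
                               stations_subset = NULL) {
  stopifnot(inherits(config, "clustering_config"))
  if (!is.null(stations_subset)) {
    detections <- detections[detections$station_id %in% stations_subset, ]
  }
  if (nrow(detections) == 0) return(empty_events_tbl())
  assert_species(detections$species)
  detections <- dplyr::arrange(detections, .data$timestamp, .data$station_id)
  window_sec <- config$camera_window_min * 60

  out <- lapply(split(detections, detections$species), function(d) {
    t <- as.numeric(d$timestamp)
    gap <- c(Inf, diff(t))
    event_id <- cumsum(gap >= window_sec)
    grp <- dplyr::group_by(tibble::tibble(t = t, event_id = event_id), .data$event_id)
    ev <- dplyr::summarise(grp, start = min(.data$t), end = max(.data$t),
                           n_detections = dplyr::n(), .groups = "drop")
    tibble::tibble(
      method = "camera", species = d$species[1],
      start = as.POSIXct(ev$start, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(ev$end, origin = "1970-01-01", tz = "UTC"),
      items_removed = NA_integer_,
      n_detections = as.integer(ev$n_detections)
    )
  })
  out <- dplyr::bind_rows(out)
  dplyr::arrange(out, .data$species, .data$start)
}

#' Convert guard log records into events
#'
#' Guards write down event starts; duplicate notes of one incursion fall
#' within the empty-field gap and collapse into one event (the first written
#' time is kept). Records at least `obs_gap_min` minutes apart are separate
#' events.
#'
#' @param records guard-record tibble `(date, time, species, ...)` as from
#'   [read_guard_csv()] or [simulate_guard()].
#' @param config a [clustering_config()].
#' @return event-record tibble (`method = "guard"`; `end`, `items_removed`
#'   and `n_detections` are `NA`).
#' @export
guard_records_to_events <- function(records, config = clustering_config()) {
  stopifnot(inherits(config, "clustering_config"))
  if (nrow(records) == 0) return(empty_events_tbl())
  assert_species(records$species)
  dt <- make_datetime_local(records$date, records$time)
  d <- tibble::tibble(t = as.numeric(dt), species = records$species)
  d <- dplyr::arrange(d, .data$species, .data$t)
  gap_sec <- config$obs_gap_min * 60
  out <- lapply(split(d, d$species), function(x) {
    gap <- c(Inf, diff(x$t))
    new_event <- if (gap_sec == 0) rep(TRUE, nrow(x)) else gap >= gap_sec
    starts <- x$t[new_event]
    tibble::tibble(
      method = "guard", species = x$species[1],
      start = as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(NA), items_removed = NA_integer_,
      n_detections = NA_integer_
    )
  })
  out <- dplyr::bind_rows(out)
  out$end <- as.POSIXct(out$end, tz = "UTC")
  dplyr::arrange(out, .data$species, .data$start)
}

#' Convert researcher records into events
#'
#' Researcher records already delimit events (first individual in, last
#' individual out). Same-species records whose empty-field gap (previous exit
#' to next entry) is shorter than `obs_gap_min` are merged: the merged event
#' spans both, and item counts add with missing-propagation (`NA + x = NA`,
#' since the total removed is then unknown). Overlapping same-species records
#' violate the field definition of an event and raise an error.
#'
#' @param records researcher-record tibble `(date, entry_time, exit_time,
#'   species, items_removed, ...)`.
#' @param config a [clustering_config()].
#' @return event-record tibble (`method = "researcher"`).
#' @export
researcher_records_to_events <- function(records, config = clustering_config()) {
  stopifnot(inherits(config, "clustering_config"))
  if (nrow(records) == 0) return(empty_events_tbl())
  assert_species(records$species)
  d <- tibble::tibble(
    start = as.numeric(make_datetime_local(records$date, records$entry_time)),
    end = as.numeric(make_datetime_local(records$date, records$exit_time)),
    species = records$species,
    items = records$items_removed
  )
  d <- dplyr::arrange(d, .data$species, .data$start)
  gap_sec <- config$obs_gap_min * 60
  out <- lapply(split(d, d$species), function(x) {
    if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)])) {
      abort(sprintf("overlapping researcher events for species '%s'", x$species[1]))
    }
    gap <- c(Inf, x$start[-1] - x$end[-nrow(x)])
    new_event <- if (gap_sec == 0) rep(TRUE, nrow(x)) else gap >= gap_sec
    id <- cumsum(new_event)
    grp <- dplyr::group_by(tibble::tibble(x, id = id), .data$id)
    ev <- dplyr::summarise(
      grp, start = min(.data$start), end = max(.data$end),
      items = if (anyNA(.data$items)) NA_integer_ else as.integer(sum(.data$items)),
      .groups = "drop")
    tibble::tibble(
      method = "researcher", species = x$species[1],
      start = as.POSIXct(ev$start, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(ev$end, origin = "1970-01-01", tz = "UTC"),
      items_removed = ev$items, n_detections = NA_integer_
    )
  })
  out <- dplyr::bind_rows(out)
  dplyr::arrange(out, .data$species, .data$start)
}

#' Restrict events to a diurnal comparison window
#'
#' Cameras record around the clock, but guard and researcher cannot observe
#' outside their duty window, so only events starting within the window enter
#' the method comparison. Attribution is by event start time.
#'
#' @param events event-record tibble.
#' @param window length-2 character times of day.
#' @return filtered event tibble.
#' @export
filter_diurnal <- function(events, window = c("06:00:00", "18:00:00")) {
  if (nrow(events) == 0) return(events)
  win <- parse_tod(window)
  tod <- as.numeric(events$start) - as.numeric(make_datetime_local(as.Date(events$start), 0L))
  events[tod >= win[1] & tod < win[2], ]
}

#' Daily event counts on duty dates
#'
#' One row per duty date and species with the number of events starting that
#' day. Duty days with no events are explicit zeros (zero is data); non-duty
#' days are absent (missing, not zero). An event dated outside the calendar
#' indicates an upstream invariant breach and raises an error.
#'
#' @param events event-record tibble for one method.
#' @param calendar that method's [duty_calendar()].
#' @return tibble `(date, species, method, n_events)`.
#' @export
daily_event_counts <- function(events, calendar) {
  stopifnot(inherits(calendar, "duty_calendar"))
  method <- calendar$method
  if (nrow(events) > 0) {
    if (!all(events$method == method)) {
      abort(sprintf("events table mixes methods; expected only '%s'", method))
    }
    ev_date <- as.Date(events$start)
    off <- setdiff(as.character(ev_date), as.character(calendar$dates))
    if (length(off) > 0) {
      abort(sprintf("%s event(s) on non-duty date(s): %s", method,
                    paste(off, collapse = ", ")))
    }
    counts <- dplyr::count(
      tibble::tibble(date = ev_date, species = events$species),
      .data$date, .data$species, name = "n_events")
  } else {
    counts <- tibble::tibble(date = as.Date(character(0)), species = character(0),
                             n_events = integer(0))
  }
  grid <- tidyr::expand_grid(date = calendar$dates, species = SPECIES_LEVELS)
  out <- dplyr::left_join(grid, counts, by = c("date", "species"))
  out$n_events <- as.integer(tidyr::replace_na(out$n_events, 0L))
  out$method <- method
  dplyr::select(out, "date", "species", "method", "n_events")
}
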