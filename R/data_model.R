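#' Camera station table
#'
#' Builds and validates the table of camera stations along the field edge.
#' Positions are metres from the southerly corner of the field; each camera
#' covers a closed interval of the edge (its field of view projected onto the
#' fence line).
#'
#' @param station_id character vector of unique short identifiers.
#' @param position_m numeric, metres along the field edge (>= 0).
#' @param view_start_m,view_end_m numeric bounds of the interval of edge
#'   covered by each camera; `view_end_m` must exceed `view_start_m`.
#' @return a tibble with class `cw_stations`.
#' @examples
#' camera_stations(c("C1", "C2"), c(10, 30), c(0, 20), c(20, 40))
#' @export
camera_stations <- function(station_id, position_m, view_start_m, view_end_m) {
  station_id <- as.character(station_id)
  if (anyDuplicated(station_id)) abort("station_id values must be unique")
  if (any(position_m < 0)) abort("position_m must be >= 0")
  if (any(view_end_m <= view_start_m)) abort("view_interval must have positive length")
  out <- tibble::tibble(
    station_id = station_id,
    position_m = as.numeric(position_m),
    view_start_m = as.numeric(view_start_m),
    view_end_m = as.numeric(view_end_m)
  )
  class(out) <- c("cw_stations", class(out))
  out
}

#' Default five-camera deployment
#'
#' Five stations at 20-m intervals along a 100-m field edge, each covering the
#' 20-m stretch of fence centred on its position, mirroring a typical
#' field-edge deployment.
#'
#' @return a `cw_stations` tibble with five rows.
#' @export
default_stations <- function() {
  pos <- c(10, 30, 50, 70, 90)
  camera_stations(paste0("C", 1:5), pos, pos - 10, pos + 10)
}

#' Read a camera-station CSV
#'
#' Schema: `station_id, position_m, view_start_m, view_end_m`.
#'
#' @param path file path.
#' @return a `cw_stations` tibble.
#' @export
read_stations_csv <- function(path) {
  df <- read_csv_checked(path, c("station_id", "position_m", "view_start_m", "view_end_m"))
  camera_stations(df$station_id, as.numeric(df$position_m),
                  as.numeric(df$view_start_m), as.numeric(df$view_end_m))
}

#' Write a camera-station CSV
#' @param stations a `cw_stations` tibble.
#' @param path file path.
#' @export
write_stations_csv <- function(stations, path) {
  readr::write_csv(tibble::as_tibble(unclass_tb(stations)), path)
  invisible(path)
}

#' Duty calendar for an observation method
#'
#' Records the set of calendar dates on which a method was actively recording
#' and its daily duty window. Absence from the calendar means missing data for
#' that day, never zero events.
#'
#' @param method one of `"camera"`, `"guard"`, `"researcher"`.
#' @param dates a `Date` vector (duplicates removed, sorted).
#' @param window length-2 character `c(start, end)` times of day, e.g.
#'   `c("06:00:00", "18:00:00")`. Cameras run around the clock by default.
#' @return an object of class `duty_calendar`.
#' @examples
#' duty_calendar("guard", seq(as.Date("2013-05-01"), as.Date("2013-05-10"), 1))
#' @export
duty_calendar <- function(method, dates, window = c("06:00:00", "18:00:00")) {
  method <- match.arg(method, METHOD_LEVELS)
  dates <- sort(unique(as.Date(dates)))
  if (length(dates) == 0) abort("duty calendar needs at least one date")
  win <- parse_tod(window)
  if (anyNA(win) || length(win) != 2L || win[2] <= win[1]) {
    abort("window must be two HH:MM:SS times with end after start")
  }
  structure(
    list(method = method, dates = dates,
         window_start = win[1], window_end = win[2]),
    class = "duty_calendar"
  )
}

#' @export
print.duty_calendar <- function(x, ...) {
  cat(sprintf("<duty_calendar> %s: %d dates (%s to %s), window %s-%s\n",
              x$method, length(x$dates), min(x$dates), max(x$dates),
              format_tod(x$window_start), format_tod(x$window_end)))
  invisible(x)
}

#' Weekday duty calendar
#'
#' Convenience constructor for an observer working about five days a week:
#' all Mondays-Fridays in `[from, to]`.
#'
#' @param method observation method.
#' @param from,to first and last date.
#' @param days_per_week number of duty days per week counted from Monday
#'   (default 5, i.e. Monday-Friday).
#' @param window daily duty window.
#' @return a `duty_calendar`.
#' @export
weekday_calendar <- function(method, from, to, days_per_week = 5,
                             window = c("06:00:00", "18:00:00")) {
  stopifnot(days_per_week >= 1, days_per_week <= 7)
  all_days <- seq(as.Date(from), as.Date(to), by = "day")
  dow <- as.integer(format(all_days, "%u")) # 1 = Monday
  duty_calendar(method, all_days[dow <= days_per_week], window)
}

#' Every-day duty calendar
#' @inheritParams weekday_calendar
#' @export
daily_calendar <- function(method, from, to, window = c("06:00:00", "18:00:00")) {
  duty_calendar(method, seq(as.Date(from), as.Date(to), by = "day"), window)
}

# ---- internal reader plumbing -----------------------------------------------

unclass_tb <- function(x) {
  class(x) <- setdiff(class(x), c("cw_stations"))
  x
}

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("missing required column(s) in %s: %s", basename(path),
                  paste(missing, collapse = ", ")))
  }
  df
}

# Attach rejection bookkeeping and emit one summarising warning (or abort
# under strict mode). Row counts always reconcile: accepted + rejected = input.
finish_read <- function(accepted, rejected, path, strict) {
  attr(accepted, "rejected") <- rejected
  attr(accepted, "n_rejected") <- nrow(rejected)
  if (nrow(rejected) > 0) {
    msg <- sprintf("%s: rejected %d row(s) [%s]", basename(path), nrow(rejected),
                   paste(sprintf("line %d: %s", rejected$line, rejected$reason),
                         collapse = "; "))
    if (strict) abort(msg) else warn(msg)
  }
  accepted
}

#' Read a camera photograph CSV
#'
#' Schema: `station_id, datetime, species` with ISO 8601 date-times
#' (`YYYY-MM-DD HH:MM:SS`, naive local time). Rows with an unknown station,
#' an unknown or unidentifiable species, or an unparseable date-time are
#' rejected, counted and reported (line numbers refer to the file, header =
#' line 1); they never abort the run unless `strict = TRUE`.
#'
#' @param path file path.
#' @param stations a `cw_stations` table; rows referencing other stations are
#'   rejected.
#' @param strict if `TRUE`, any rejected row becomes an error.
#' @return a tibble `(station_id, timestamp, species)` sorted by timestamp
#'   then station id, with attributes `rejected` (tibble of `line`, `reason`)
#'   and `n_rejected`.
#' @export
read_camera_csv <- function(path, stations, strict = FALSE) {
  df <- read_csv_checked(path, c("station_id", "datetime", "species"))
  line <- seq_len(nrow(df)) + 1L
  ts <- suppressWarnings(lubridate::ymd_hms(df$datetime, tz = "UTC", quiet = TRUE))
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(ts)] <- "unparseable datetime"
  unknown_station <- is.na(reason) & !(df$station_id %in% stations$station_id)
  reason[unknown_station] <- paste0("unknown station_id '", df$station_id[unknown_station], "'")
  bad_species <- is.na(reason) & !(df$species %in% SPECIES_LEVELS)
  reason[bad_species] <- paste0("unknown species '", df$species[bad_species], "'")

  keep <- is.na(reason)
  accepted <- tibble::tibble(
    station_id = df$station_id[keep],
    timestamp = ts[keep],
    species = df$species[keep]
  )
  accepted <- dplyr::arrange(accepted, .data$timestamp, .data$station_id)
  rejected <- tibble::tibble(line = line[!keep], reason = reason[!keep])
  finish_read(accepted, rejected, path, strict)
}

#' Read a guard log CSV
#'
#' Schema: `date, time, species`. Records outside the guard's duty window are
#' kept but flagged `out_of_window` rather than silently dropped.
#'
#' @param path file path.
#' @param duty_window length-2 character duty window (default 06:00-18:00).
#' @param strict promote rejected rows to errors.
#' @return tibble `(date, time, species, out_of_window)` sorted by date+time;
#'   `time` is integer seconds since midnight. Rejection attributes as in
#'   [read_camera_csv()].
#' @export
read_guard_csv <- function(path, duty_window = c("06:00:00", "18:00:00"),
                           strict = FALSE) {
  df <- read_csv_checked(path, c("date", "time", "species"))
  line <- seq_len(nrow(df)) + 1L
  d <- suppressWarnings(lubridate::ymd(df$date, quiet = TRUE))
  tod <- parse_tod(df$time)
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(d)] <- "unparseable date"
  reason[is.na(reason) & is.na(tod)] <- "unparseable time"
  reason[is.na(reason) & !(df$species %in% SPECIES_LEVELS)] <-
    paste0("unknown species '", df$species[is.na(reason) & !(df$species %in% SPECIES_LEVELS)], "'")

  keep <- is.na(reason)
  win <- parse_tod(duty_window)
  accepted <- tibble::tibble(
    date = d[keep], time = tod[keep], species = df$species[keep],
    out_of_window = tod[keep] < win[1] | tod[keep] > win[2]
  )
  accepted <- dplyr::arrange(accepted, .data$date, .data$time, .data$species)
  rejected <- tibble::tibble(line = line[!keep], reason = reason[!keep])
  finish_read(accepted, rejected, path, strict)
}

#' Read a researcher event CSV
#'
#' Schema: `date, entry_time, exit_time, species, items_removed`. An empty
#' `items_removed` cell is a legal state meaning "not recorded" and is kept as
#' `NA`, distinct from an explicit 0: events with unknown item counts still
#' count as crop-foraging events but are excluded from crop-loss totals
#' downstream. Rows with exit before entry are rejected with a row-level
#' error message.
#'
#' @inheritParams read_guard_csv
#' @return tibble `(date, entry_time, exit_time, species, items_removed)`
#'   sorted by date + entry time; times are seconds since midnight.
#' @export
read_researcher_csv <- function(path, strict = FALSE) {
  df <- read_csv_checked(path, c("date", "entry_time", "exit_time", "species", "items_removed"))
  line <- seq_len(nrow(df)) + 1L
  d <- suppressWarnings(lubridate::ymd(df$date, quiet = TRUE))
  entry <- parse_tod(df$entry_time)
  exit <- parse_tod(df$exit_time)
  items_chr <- df$items_removed
  items <- suppressWarnings(as.integer(items_chr))
  items_bad <- !is.na(items_chr) & items_chr != "" & is.na(items)

  reason <- rep(NA_character_, nrow(df))
  reason[is.na(d)] <- "unparseable date"
  reason[is.na(reason) & is.na(entry)] <- "unparseable entry_time"
  reason[is.na(reason) & is.na(exit)] <- "unparseable exit_time"
  reason[is.na(reason) & !(df$species %in% SPECIES_LEVELS)] <- "unknown species"
  reason[is.na(reason) & items_bad] <- "non-integer items_removed"
  reason[is.na(reason) & !is.na(items) & items < 0] <- "negative items_removed"
  reason[is.na(reason) & exit < entry] <- "exit_time before entry_time"

  keep <- is.na(reason)
  accepted <- tibble::tibble(
    date = d[keep], entry_time = entry[keep], exit_time = exit[keep],
    species = df$species[keep], items_removed = items[keep]
  )
  accepted <- dplyr::arrange(accepted, .data$date, .data$entry_time, .data$species)
  rejected <- tibble::tibble(line = line[!keep], reason = reason[!keep])
  finish_read(accepted, rejected, path, strict)
}

#' Validate an event-record table
#'
#' Checks the event-record contract: known methods and species; camera events
#' carry `n_detections >= 1`; and events of the same method and species are
#' strictly ordered and non-overlapping in time.
#'
#' @param events tibble with columns `method, species, start, end,
#'   items_removed, n_detections`.
#' @return `events`, invisibly, if valid; otherwise an error.
#' @export
validate_events <- function(events) {
  req <- c("method", "species", "start", "end", "items_removed", "n_detections")
  missing <- setdiff(req, names(events))
  if (length(missing) > 0) abort(paste("events table missing column(s):", paste(missing, collapse = ", ")))
  bad_m <- setdiff(unique(events$method), METHOD_LEVELS)
  if (length(bad_m) > 0) abort(paste("unknown method:", paste(bad_m, collapse = ", ")))
  assert_species(events$species)
  cam <- events[events$method == "camera", ]
  if (nrow(cam) > 0 && (anyNA(cam$n_detections) || any(cam$n_detections < 1))) {
    abort("camera events must have n_detections >= 1")
  }
  chk <- dplyr::group_by(events, .data$method, .data$species)
  chk <- dplyr::summarise(
    chk,
    ordered = !is.unsorted(as.numeric(.data$start), strictly = TRUE),
    disjoint = {
      e <- ifelse(is.na(as.numeric(.data$end)), as.numeric(.data$start), as.numeric(.data$end))
      n <- length(e)
      n < 2 || all(as.numeric(.data$start)[-1] >= e[-n])
    },
    .groups = "drop"
  )
  if (any(!chk$ordered)) abort("events of one method+species are not strictly time-ordered")
  if (any(!chk$disjoint)) abort("events of one method+species overlap in time")
  invisible(events)
}

#' Write an event-record CSV
#'
#' Serialises an event table so that [read_events_csv()] round-trips it
#' losslessly. Missing `end`, `items_removed` or `n_detections` become empty
#' cells.
#'
#' @param events event-record tibble (see [validate_events()]).
#' @param path output path.
#' @export
write_events_csv <- function(events, path) {
  validate_events(events)
  out <- tibble::tibble(
    method = events$method,
    species = events$species,
    start = format(events$start, "%Y-%m-%d %H:%M:%S"),
    end = ifelse(is.na(events$end), "", format(events$end, "%Y-%m-%d %H:%M:%S")),
    items_removed = ifelse(is.na(events$items_removed), "", as.character(events$items_removed)),
    n_detections = ifelse(is.na(events$n_detections), "", as.character(events$n_detections))
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read an event-record CSV written by [write_events_csv()]
#' @param path file path.
#' @return event-record tibble.
#' @export
read_events_csv <- function(path) {
  df <- read_csv_checked(path, c("method", "species", "start", "end",
                                 "items_removed", "n_detections"))
  blank <- function(x) is.na(x) | x == ""
  out <- tibble::tibble(
    method = df$method,
    species = df$species,
    start = lubridate::ymd_hms(df$start, tz = "UTC"),
    end = lubridate::ymd_hms(ifelse(blank(df$end), NA_character_, df$end), tz = "UTC", quiet = TRUE),
    items_removed = as.integer(ifelse(blank(df$items_removed), NA_character_, df$items_removed)),
    n_detections = as.integer(ifelse(blank(df$n_detections), NA_character_, df$n_detections))
  )
  validate_events(out)
  out
}

#' Write guard / researcher / detection CSVs
#'
#' Writers matching the reader schemas, used by the simulator to materialise
#' a synthetic dataset on disk.
#'
#' @param x table to write.
#' @param path output path.
#' @name raw_writers
NULL

#' @rdname raw_writers
#' @export
write_camera_csv <- function(x, path) {
  out <- tibble::tibble(
    station_id = x$station_id,
    datetime = format(x$timestamp, "%Y-%m-%d %H:%M:%S"),
    species = x$species
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname raw_writers
#' @export
write_guard_csv <- function(x, path) {
  out <- tibble::tibble(
    date = format(x$date, "%Y-%m-%d"),
    time = format_tod(x$time),
    species = x$species
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname raw_writers
#' @export
write_researcher_csv <- function(x, path) {
  out <- tibble::tibble(
    date = format(x$date, "%Y-%m-%d"),
    entry_time = format_tod(x$entry_time),
    exit_time = format_tod(x$exit_time),
    species = x$species,
    items_removed = ifelse(is.na(x$items_removed), "", as.character(x$items_removed))
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
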