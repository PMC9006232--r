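#' Ten-day period index
#'
#' Divides the analysis range into consecutive blocks of `period_len_days`
#' anchored at `start_date`. A trailing partial block is dropped with a
#' warning (periods must be comparable units); a range shorter than one
#' period is an error.
#'
#' @param start_date,end_date analysis range (inclusive).
#' @param period_len_days block length in days, default 10.
#' @return tibble `(period_index, start, end)`, 1-based indices.
#' @examples
#' build_periods("2013-05-01", "2013-08-08") # 100 days -> 10 periods
#' @export
build_periods <- function(start_date, end_date, period_len_days = 10) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  stopifnot(period_len_days >= 1)
  if (end_date < start_date) abort("end_date precedes start_date")
  n_days <- as.integer(end_date - start_date) + 1L
  n_periods <- n_days %/% period_len_days
  if (n_periods < 1) {
    abort(sprintf("range of %d day(s) is shorter than one %d-day period",
                  n_days, period_len_days))
  }
  dropped <- n_days %% period_len_days
  if (dropped > 0) {
    warn(sprintf("dropping %d trailing day(s) not filling a %d-day period",
                 dropped, period_len_days))
  }
  tibble::tibble(
    period_index = seq_len(n_periods),
    start = start_date + (seq_len(n_periods) - 1L) * period_len_days,
    end = start_date + seq_len(n_periods) * period_len_days - 1L
  )
}

#' Dates on which all methods were recording
#'
#' The matched-day contract: every period mean is taken over days where all
#' compared methods collected data, so removing a day removes it from every
#' method's denominator identically. Returns the intersection of the duty
#' calendars' date sets.
#'
#' @param calendars list of [duty_calendar()]s (at least one).
#' @return sorted `Date` vector.
#' @export
matched_days <- function(calendars) {
  stopifnot(length(calendars) >= 1)
  sets <- lapply(calendars, function(cal) {
    stopifnot(inherits(cal, "duty_calendar"))
    cal$dates
  })
  out <- Reduce(intersect, sets)
  out <- sort(as.Date(out, origin = "1970-01-01"))
  if (length(out) == 0) {
    sizes <- vapply(sets, length, integer(1))
    limiting <- vapply(calendars, function(cal) cal$method, character(1))[which.min(sizes)]
    abort(sprintf("no matched days: the duty calendars have empty intersection (limiting method: %s)",
                  limiting))
  }
  out
}

#' Daily crop-loss totals from researcher events
#'
#' Sums `items_removed` per duty date and species over events with a known
#' item count. Events whose count was not recorded still count as
#' crop-foraging events elsewhere but contribute nothing here; the number of
#' such excluded events is reported per day.
#'
#' @param events researcher event-record tibble (from
#'   [researcher_records_to_events()]).
#' @param calendar researcher [duty_calendar()]; duty days with no events are
#'   explicit zeros.
#' @return tibble `(date, species, method, items_removed, n_excluded_events)`.
#' @export
crop_loss_daily <- function(events, calendar) {
  stopifnot(inherits(calendar, "duty_calendar"))
  if (nrow(events) > 0) {
    if (!all(events$method == "researcher")) {
      abort("crop loss is defined from researcher events only")
    }
    known <- !is.na(events$items_removed)
    if (any(events$items_removed[known] < 0)) abort("negative items_removed")
    df <- tibble::tibble(
      date = as.Date(events$start), species = events$species,
      items = ifelse(known, events$items_removed, 0L),
      excluded = as.integer(!known)
    )
    grp <- dplyr::group_by(df, .data$date, .data$species)
    sums <- dplyr::summarise(grp, items_removed = sum(.data$items),
                             n_excluded_events = sum(.data$excluded),
                             .groups = "drop")
  } else {
    sums <- tibble::tibble(date = as.Date(character(0)), species = character(0),
                           items_removed = integer(0), n_excluded_events = integer(0))
  }
  grid <- tidyr::expand_grid(date = calendar$dates, species = SPECIES_LEVELS)
  out <- dplyr::left_join(grid, sums, by = c("date", "species"))
  out$items_removed <- as.integer(tidyr::replace_na(out$items_removed, 0L))
  out$n_excluded_events <- as.integer(tidyr::replace_na(out$n_excluded_events, 0L))
  out$method <- "researcher"
  dplyr::select(out, "date", "species", "method", "items_removed", "n_excluded_events")
}

#' Assemble the long daily-measure table
#'
#' Binds per-method daily event counts and researcher crop-loss totals into
#' one long table `(date, species, method, measure, value)` ready for
#' [aggregate_to_periods()].
#'
#' @param daily_counts list of [daily_event_counts()] outputs (one per method).
#' @param crop_loss optional [crop_loss_daily()] output.
#' @return long daily tibble.
#' @export
bind_daily_measures <- function(daily_counts, crop_loss = NULL) {
  ev <- dplyr::bind_rows(daily_counts)
  ev <- tibble::tibble(date = ev$date, species = ev$species, method = ev$method,
                       measure = "events_per_day", value = as.numeric(ev$n_events))
  if (!is.null(crop_loss)) {
    cl <- tibble::tibble(date = crop_loss$date, species = crop_loss$species,
                         method = crop_loss$method, measure = "items_per_day",
                         value = as.numeric(crop_loss$items_removed))
    ev <- dplyr::bind_rows(ev, cl)
  }
  ev
}

#' Aggregate daily measures to matched-day period means
#'
#' For every period x species x method x measure, the arithmetic mean of the
#' daily values over the period's matched days. If some days of a ten-day
#' period are not matched, the mean is over the remaining matched days (the
#' denominator is `n_matched_days`, not the period length). Periods with zero
#' matched days are dropped with a warning.
#'
#' @param daily long daily tibble from [bind_daily_measures()]; must be
#'   zero-filled on duty dates.
#' @param matched `Date` vector from [matched_days()].
#' @param periods period table from [build_periods()].
#' @return tibble `(period_index, species, method, measure, value,
#'   n_matched_days)`.
#' @export
aggregate_to_periods <- function(daily, matched, periods) {
  period_of <- function(d) {
    idx <- findInterval(as.integer(d), as.integer(periods$start))
    ok <- idx >= 1 & idx <= nrow(periods) & d <= periods$end[pmax(idx, 1)]
    out <- rep(NA_integer_, length(d))
    out[ok] <- periods$period_index[idx[ok]]
    out
  }
  md <- tibble::tibble(date = matched, period_index = period_of(matched))
  md <- md[!is.na(md$period_index), ]
  empty_periods <- setdiff(periods$period_index, unique(md$period_index))
  if (length(empty_periods) > 0) {
    warn(sprintf("dropping period(s) with zero matched days: %s",
                 paste(empty_periods, collapse = ", ")))
  }
  df <- dplyr::inner_join(daily, md, by = "date")
  grp <- dplyr::group_by(df, .data$period_index, .data$species, .data$method,
                         .data$measure)
  out <- dplyr::summarise(grp, value = mean(.data$value),
                          n_matched_days = dplyr::n_distinct(.data$date),
                          .groups = "drop")
  dplyr::arrange(out, .data$period_index, .data$species, .data$method, .data$measure)
}
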