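#' Per-species simulation parameters
#'
#' Free parameters of the foraging-event generator for one species. Daily
#' event rates, group sizes and per-capita item removal are qualitative
#' stand-ins for the two study taxa: baboons forage in larger parties, remove
#' more crop items per individual and trip motion cameras more reliably than
#' the smaller-bodied vervets.
#'
#' @param daily_rate mean crop-foraging events per day (Poisson), before
#'   seasonal modulation and the minimum-gap thinning.
#' @param group_size_mean mean foraging party size; sizes are drawn as
#'   `1 + Poisson(group_size_mean - 1)` so every event has at least one animal.
#' @param duration_meanlog,duration_sdlog log-normal parameters of event
#'   duration in minutes. Defaults put the bulk of durations well under 30
#'   minutes, the empirical upper range for these species; durations are
#'   capped at `duration_cap_min`.
#' @param duration_cap_min hard cap on duration (minutes) so events stay
#'   within the day.
#' @param items_per_individual_mean mean crop items carried out per individual
#'   (Poisson).
#' @param camera_trigger_prob probability that one passage of one individual
#'   through a camera's field of view triggers that camera.
#' @return a list of class `species_params`.
#' @export
species_params <- function(daily_rate,
                           group_size_mean,
                           duration_meanlog = log(10),
                           duration_sdlog = 0.6,
                           duration_cap_min = 120,
                           items_per_individual_mean = 1,
                           camera_trigger_prob = 0.5) {
  stopifnot(daily_rate >= 0, group_size_mean >= 1,
            duration_sdlog > 0, duration_cap_min > 0,
            items_per_individual_mean >= 0,
            camera_trigger_prob >= 0, camera_trigger_prob <= 1)
  structure(list(
    daily_rate = daily_rate,
    group_size_mean = group_size_mean,
    duration_meanlog = duration_meanlog,
    duration_sdlog = duration_sdlog,
    duration_cap_min = duration_cap_min,
    items_per_individual_mean = items_per_individual_mean,
    camera_trigger_prob = camera_trigger_prob
  ), class = "species_params")
}

#' Configuration of the synthetic crop-foraging dataset generator
#'
#' Bundles every parameter of the ground-truth event process and of the three
#' imperfect observation processes layered on top of it. Defaults encode the
#' study conditions the package models: a 100-day overlap window, diurnal
#' (06:00-18:00) incursions, a guard who responds to 85% of baboon but only
#' 15% of vervet incursions, a researcher present about five days a week who
#' detects essentially every event, and five field-edge cameras firing
#' three-shot bursts with a five-second refractory period.
#'
#' @param start_date,end_date first and last calendar date of the simulated
#'   season (inclusive).
#' @param species named list of [species_params()], one per modelled species.
#' @param seasonal_amplitude relative amplitude of the sinusoidal modulation
#'   of daily rates across ten-day blocks; both species share the seasonal
#'   shape, giving the between-period signal that the agreement regressions
#'   estimate. Set 0 for a flat season.
#' @param seasonal_block_days length of the blocks over which rates are
#'   piecewise constant (default 10 days).
#' @param field_edge_m length of the monitored field edge in metres.
#' @param guard_position_m guard station position along the edge.
#' @param guard_avoidance nonnegative exponent of the entry-position bias:
#'   entry density is proportional to `(5 + d)^guard_avoidance` where `d` is
#'   distance (m) from the guard. 0 gives uniform entries; larger values push
#'   entries away from the guard.
#' @param guard_detect_prob named numeric, probability the guard logs an
#'   incursion, per species.
#' @param guard_delay_min maximum delay (minutes) between a true event start
#'   and the guard's written time; actual delays are uniform on that range.
#' @param researcher_detect_prob probability the researcher records an event
#'   occurring on a researcher duty day.
#' @param researcher_duty_days_per_week duty days per week (from Monday).
#' @param items_missing_frac fraction of researcher-recorded events whose
#'   crop-item count goes unrecorded (`NA`), as happens when counting every
#'   item carried out is infeasible.
#' @param burst_size photographs per camera trigger.
#' @param rest_seconds camera refractory period after a trigger, during which
#'   the camera cannot be triggered again.
#' @param inter_photo_seconds spacing of photographs within a burst.
#' @param min_event_gap_min minimum empty-field gap (minutes) separating
#'   successive true events of one species.
#' @param diurnal_window daily window within which events start.
#' @param seed master integer seed; one sub-stream per simulated method is
#'   derived from it.
#' @return a list of class `generator_config`.
#' @examples
#' cfg <- generator_config(seed = 7)
#' truth <- generate_truth(cfg)
#' @export
generator_config <- function(start_date = "2013-05-01",
                             end_date = "2013-08-08",
                             species = list(
                               baboon = species_params(
                                 daily_rate = 3, group_size_mean = 8,
                                 duration_meanlog = log(10),
                                 items_per_individual_mean = 2,
                                 camera_trigger_prob = 0.7),
                               vervet = species_params(
                                 daily_rate = 4, group_size_mean = 3,
                                 duration_meanlog = log(6),
                                 items_per_individual_mean = 1,
                                 camera_trigger_prob = 0.2)
                             ),
                             seasonal_amplitude = 0.6,
                             seasonal_block_days = 10,
                             field_edge_m = 100,
                             guard_position_m = 0,
                             guard_avoidance = 1.5,
                             guard_detect_prob = c(baboon = 0.85, vervet = 0.15),
                             guard_delay_min = 2,
                             researcher_detect_prob = 1.0,
                             researcher_duty_days_per_week = 5,
                             items_missing_frac = 0.1,
                             burst_size = 3,
                             rest_seconds = 5,
                             inter_photo_seconds = 1,
                             min_event_gap_min = 1,
                             diurnal_window = c("06:00:00", "18:00:00"),
                             seed = 1L) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || end_date < start_date) {
    abort("empty or invalid date_range: end_date must not precede start_date")
  }
  if (!is.list(species) || length(species) == 0 || is.null(names(species))) {
    abort("species must be a named list of species_params()")
  }
  assert_species(names(species))
  for (sp in names(species)) {
    if (!inherits(species[[sp]], "species_params")) {
      species[[sp]] <- do.call(species_params, species[[sp]])
    }
  }
  probs <- c(guard_detect_prob, researcher_detect_prob, items_missing_frac)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (is.null(names(guard_detect_prob)) || !all(names(species) %in% names(guard_detect_prob))) {
    abort("guard_detect_prob must be named with an entry per species")
  }
  stopifnot(burst_size >= 1, rest_seconds >= 0, inter_photo_seconds >= 0,
            min_event_gap_min > 0, guard_avoidance >= 0, seasonal_amplitude >= 0,
            seasonal_block_days >= 1, field_edge_m > 0,
            guard_position_m >= 0, guard_position_m <= field_edge_m)
  win <- parse_tod(diurnal_window)
  if (anyNA(win) || win[2] <= win[1]) abort("diurnal_window must be an increasing pair of times")
  structure(list(
    start_date = start_date, end_date = end_date, species = species,
    seasonal_amplitude = seasonal_amplitude,
    seasonal_block_days = as.integer(seasonal_block_days),
    field_edge_m = field_edge_m,
    guard_position_m = guard_position_m, guard_avoidance = guard_avoidance,
    guard_detect_prob = guard_detect_prob, guard_delay_min = guard_delay_min,
    researcher_detect_prob = researcher_detect_prob,
    researcher_duty_days_per_week = as.integer(researcher_duty_days_per_week),
    items_missing_frac = items_missing_frac,
    burst_size = as.integer(burst_size), rest_seconds = rest_seconds,
    inter_photo_seconds = inter_photo_seconds,
    min_event_gap_min = min_event_gap_min,
    diurnal_window_sec = win,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Seasonal multiplier for each date: sinusoid over ten-day blocks, shared by
# both species so that period means co-vary and agreement slopes are estimable.
seasonal_multiplier <- function(dates, config) {
  day_idx <- as.integer(dates - config$start_date)
  block <- day_idx %/% config$seasonal_block_days
  n_blocks <- max(1L, as.integer(config$end_date - config$start_date) %/%
                    config$seasonal_block_days + 1L)
  1 + config$seasonal_amplitude * sin(2 * pi * block / n_blocks)
}

# Entry positions along the field edge, biased away from the guard station.
# Inverse-CDF sampling on a fine grid with density (5 + d)^avoidance.
sample_entry_positions <- function(n, config) {
  if (n == 0) return(numeric(0))
  step <- 0.1
  grid <- seq(step / 2, config$field_edge_m - step / 2, by = step)
  w <- (5 + abs(grid - config$guard_position_m))^config$guard_avoidance
  idx <- sample.int(length(grid), n, replace = TRUE, prob = w)
  pmin(pmax(grid[idx] + runif(n, -step / 2, step / 2), 0), config$field_edge_m)
}

#' Generate ground-truth crop-foraging events
#'
#' Draws one season of true incursions. Per day and species the event count is
#' Poisson with that day's seasonally modulated rate; event starts are uniform
#' in the diurnal window; durations, group sizes, entry positions and item
#' removals come from the per-species distributions. Successive same-species
#' events closer than the minimum empty-field gap are thinned (the later event
#' is dropped), mirroring the field definition that one minute must pass with
#' no animals in the field before a new event can begin.
#'
#' @param config a [generator_config()].
#' @return tibble with one row per true event: `event_id, species, date,
#'   start, end, duration_min, group_size, entry_position_m, items_removed`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  seeds <- split_seed(config$seed, 4L)
  set.seed(seeds[1])
  dates <- seq(config$start_date, config$end_date, by = "day")
  mult <- seasonal_multiplier(dates, config)
  win <- config$diurnal_window_sec

  per_species <- lapply(names(config$species), function(sp) {
    pars <- config$species[[sp]]
    n_day <- rpois(length(dates), pars$daily_rate * mult)
    n <- sum(n_day)
    if (n == 0) return(NULL)
    date <- rep(dates, n_day)
    start_tod <- floor(runif(n, win[1], win[2]))
    duration <- pmin(rlnorm(n, pars$duration_meanlog, pars$duration_sdlog),
                     pars$duration_cap_min)
    group <- 1L + rpois(n, pars$group_size_mean - 1)
    items <- vapply(group, function(g) sum(rpois(g, pars$items_per_individual_mean)),
                    numeric(1))
    pos <- sample_entry_positions(n, config)
    tibble::tibble(
      species = sp, date = date,
      start = make_datetime_local(date, start_tod),
      duration_min = duration,
      group_size = as.integer(group),
      entry_position_m = pos,
      items_removed = as.integer(items)
    )
  })
  truth <- dplyr::bind_rows(per_species)
  if (nrow(truth) == 0) {
    return(tibble::tibble(event_id = integer(0), species = character(0),
                          date = as.Date(character(0)),
                          start = as.POSIXct(character(0), tz = "UTC"),
                          end = as.POSIXct(character(0), tz = "UTC"),
                          duration_min = numeric(0), group_size = integer(0),
                          entry_position_m = numeric(0), items_removed = integer(0)))
  }
  truth$end <- truth$start + truth$duration_min * 60
  truth <- dplyr::arrange(truth, .data$species, .data$start)

  # empty-field gap thinning: drop an event starting before the previous
  # same-species event has been over for min_event_gap_min
  gap_sec <- config$min_event_gap_min * 60
  keep_chr <- unlist(lapply(split(seq_len(nrow(truth)), truth$species), function(ix) {
    keep <- logical(length(ix))
    last_end <- -Inf
    for (k in seq_along(ix)) {
      i <- ix[k]
      s <- as.numeric(truth$start[i])
      if (s >= last_end + gap_sec) {
        keep[k] <- TRUE
        last_end <- as.numeric(truth$end[i])
      }
    }
    ix[keep]
  }), use.names = FALSE)
  truth <- truth[sort(keep_chr), ]
  truth <- dplyr::arrange(truth, .data$start, .data$species)
  truth$event_id <- seq_len(nrow(truth))
  dplyr::select(truth, "event_id", "species", "date", "start", "end",
                "duration_min", "group_size", "entry_position_m", "items_removed")
}

#' Simulate researcher observation of true events
#'
#' The researcher sits in a hide overlooking the whole (small) field, so on a
#' duty day every event is seen with probability `researcher_detect_prob`
#' (default 1). Recorded events carry exact entry and exit times; a fraction
#' of item counts goes unrecorded (`NA`), and those events still count as
#' events but are excluded from crop-loss sums downstream.
#'
#' @param truth output of [generate_truth()].
#' @param calendar researcher [duty_calendar()].
#' @param config the [generator_config()].
#' @return researcher-record tibble `(date, entry_time, exit_time, species,
#'   items_removed, truth_event_id)`; times are seconds since midnight.
#' @export
simulate_researcher <- function(truth, calendar, config) {
  stopifnot(inherits(config, "generator_config"),
            inherits(calendar, "duty_calendar"))
  seeds <- split_seed(config$seed, 4L)
  set.seed(seeds[2])
  on_duty <- truth[truth$date %in% calendar$dates, ]
  if (nrow(on_duty) == 0) return(empty_researcher_tbl())
  seen <- runif(nrow(on_duty)) < config$researcher_detect_prob
  obs <- on_duty[seen, ]
  if (nrow(obs) == 0) return(empty_researcher_tbl())
  items <- obs$items_removed
  miss <- runif(nrow(obs)) < config$items_missing_frac
  items[miss] <- NA_integer_
  day_start <- as.numeric(make_datetime_local(obs$date, 0L))
  tibble::tibble(
    date = obs$date,
    entry_time = as.integer(as.numeric(obs$start) - day_start),
    exit_time = as.integer(pmin(as.numeric(obs$end) - day_start, 86399)),
    species = obs$species,
    items_removed = as.integer(items),
    truth_event_id = obs$event_id
  )
}

empty_researcher_tbl <- function() {
  tibble::tibble(date = as.Date(character(0)), entry_time = integer(0),
                 exit_time = integer(0), species = character(0),
                 items_removed = integer(0), truth_event_id = integer(0))
}

#' Simulate the guard's written log
#'
#' Each true event is logged independently with the species-specific response
#' probability (defaults: 0.85 for baboons, 0.15 for vervets — guards rarely
#' react to the smaller, less conspicuous species). The written time is the
#' event start plus a small uniform delay, clamped to the duty window; the
#' guard is on duty every day by default.
#'
#' @param truth output of [generate_truth()].
#' @param config the [generator_config()].
#' @param calendar optional guard [duty_calendar()]; default: every day of the
#'   simulated range, 06:00-18:00.
#' @return guard-record tibble `(date, time, species, truth_event_id)`;
#'   `time` in seconds since midnight.
#' @export
simulate_guard <- function(truth, config, calendar = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seeds <- split_seed(config$seed, 4L)
  set.seed(seeds[3])
  if (is.null(calendar)) {
    calendar <- daily_calendar("guard", config$start_date, config$end_date,
                               window = format_tod(config$diurnal_window_sec))
  }
  on_duty <- truth[truth$date %in% calendar$dates, ]
  if (nrow(on_duty) == 0) return(empty_guard_tbl())
  p <- config$guard_detect_prob[on_duty$species]
  seen <- runif(nrow(on_duty)) < p
  obs <- on_duty[seen, ]
  if (nrow(obs) == 0) return(empty_guard_tbl())
  delay <- floor(runif(nrow(obs), 0, config$guard_delay_min * 60))
  day_start <- as.numeric(make_datetime_local(obs$date, 0L))
  tod <- as.integer(as.numeric(obs$start) - day_start + delay)
  tod <- pmin(pmax(tod, calendar$window_start), calendar$window_end - 1L)
  out <- tibble::tibble(
    date = obs$date, time = tod, species = obs$species,
    truth_event_id = obs$event_id
  )
  dplyr::arrange(out, .data$date, .data$time, .data$species)
}

empty_guard_tbl <- function() {
  tibble::tibble(date = as.Date(character(0)), time = integer(0),
                 species = character(0), truth_event_id = integer(0))
}

#' Simulate camera-trap photographs of true events
#'
#' Animals cross the field edge at the event's entry position, so an event is
#' visible only to stations whose view interval contains that position. Each
#' individual's passage is one trigger opportunity: the first individual
#' crosses exactly at the event start and the remaining `group_size - 1`
#' passages are spread uniformly over the event duration (animals trickle in
#' and out across the edge; cameras never see mid-field foraging). Each
#' opportunity trips each covering camera independently with the species'
#' per-passage trigger probability. A tripped camera emits a burst of
#' `burst_size` photographs `inter_photo_seconds` apart and then cannot be
#' triggered again until `rest_seconds` have elapsed since the trigger
#' (opportunities falling inside the refractory period are suppressed).
#'
#' @param truth output of [generate_truth()].
#' @param stations a `cw_stations` table.
#' @param config the [generator_config()].
#' @return detection tibble `(station_id, timestamp, species,
#'   truth_event_id)` sorted by timestamp, one row per photograph.
#' @export
simulate_cameras <- function(truth, stations, config) {
  stopifnot(inherits(config, "generator_config"), nrow(stations) > 0)
  seeds <- split_seed(config$seed, 4L)
  set.seed(seeds[4])
  empty <- tibble::tibble(station_id = character(0),
                          timestamp = as.POSIXct(character(0), tz = "UTC"),
                          species = character(0), truth_event_id = integer(0))
  if (nrow(truth) == 0) return(empty)

  # per-individual passage opportunities (seconds offset from event start)
  n_ind <- truth$group_size
  ev_idx <- rep(seq_len(nrow(truth)), n_ind)
  first <- !duplicated(ev_idx)
  offs <- floor(runif(length(ev_idx), 0, truth$duration_min[ev_idx] * 60))
  offs[first] <- 0
  opp <- tibble::tibble(
    event = ev_idx,
    time = as.numeric(truth$start[ev_idx]) + offs,
    species = truth$species[ev_idx],
    position = truth$entry_position_m[ev_idx]
  )

  p_by_species <- vapply(config$species, function(s) s$camera_trigger_prob, numeric(1))
  per_station <- lapply(seq_len(nrow(stations)), function(si) {
    st <- stations[si, ]
    o <- opp[opp$position >= st$view_start_m & opp$position <= st$view_end_m, ]
    if (nrow(o) == 0) return(NULL)
    o <- o[runif(nrow(o)) < p_by_species[o$species], ]
    if (nrow(o) == 0) return(NULL)
    o <- o[order(o$time, o$event), ]
    # refractory scan: a camera cannot be re-triggered within rest_seconds
    keep <- logical(nrow(o))
    last_trigger <- -Inf
    for (i in seq_len(nrow(o))) {
      if (o$time[i] >= last_trigger + config$rest_seconds) {
        keep[i] <- TRUE
        last_trigger <- o$time[i]
      }
    }
    o <- o[keep, ]
    burst_off <- (seq_len(config$burst_size) - 1L) * config$inter_photo_seconds
    tibble::tibble(
      station_id = st$station_id,
      timestamp = as.POSIXct(rep(o$time, each = config$burst_size) +
                               rep(burst_off, nrow(o)),
                             origin = "1970-01-01", tz = "UTC"),
      species = rep(o$species, each = config$burst_size),
      truth_event_id = truth$event_id[rep(o$event, each = config$burst_size)]
    )
  })
  out <- dplyr::bind_rows(per_station)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$timestamp, .data$station_id)
}

#' Simulate a full three-method dataset
#'
#' Runs [generate_truth()] and the three observation simulators with their
#' independent seed streams, together with the duty calendars the study design
#' implies: cameras every day around the clock, the guard every day within
#' the diurnal window, the researcher on `researcher_duty_days_per_week` days
#' per week within the diurnal window.
#'
#' @param config a [generator_config()].
#' @param stations camera deployment, default [default_stations()].
#' @return a list of class `cw_simulation`: `truth`, `detections`,
#'   `guard_log`, `researcher_log`, `stations`, `calendars` (named list of
#'   [duty_calendar()]s) and the resolved `config`.
#' @export
simulate_dataset <- function(config, stations = default_stations()) {
  stopifnot(inherits(config, "generator_config"))
  win <- format_tod(config$diurnal_window_sec)
  calendars <- list(
    camera = daily_calendar("camera", config$start_date, config$end_date,
                            window = c("00:00:00", "23:59:59")),
    guard = daily_calendar("guard", config$start_date, config$end_date, window = win),
    researcher = weekday_calendar("researcher", config$start_date, config$end_date,
                                  days_per_week = config$researcher_duty_days_per_week,
                                  window = win)
  )
  truth <- generate_truth(config)
  structure(list(
    truth = truth,
    detections = simulate_cameras(truth, stations, config),
    guard_log = simulate_guard(truth, config, calendars$guard),
    researcher_log = simulate_researcher(truth, calendars$researcher, config),
    stations = stations,
    calendars = calendars,
    config = config
  ), class = "cw_simulation")
}

#' Write a simulated dataset to a directory
#'
#' Materialises `truth.csv`, `camera_photos.csv`, `guard_log.csv`,
#' `researcher_log.csv`, `stations.csv` and the resolved configuration
#' (`config.yaml`, including the seed) for provenance.
#'
#' @param sim a `cw_simulation` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "cw_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth_out <- sim$truth
  truth_out$start <- format(truth_out$start, "%Y-%m-%d %H:%M:%S")
  truth_out$end <- format(truth_out$end, "%Y-%m-%d %H:%M:%S")
  readr::write_csv(truth_out, file.path(dir, "truth.csv"))
  write_camera_csv(sim$detections, file.path(dir, "camera_photos.csv"))
  write_guard_csv(sim$guard_log, file.path(dir, "guard_log.csv"))
  write_researcher_csv(sim$researcher_log, file.path(dir, "researcher_log.csv"))
  write_stations_csv(sim$stations, file.path(dir, "stations.csv"))
  yaml::write_yaml(config_to_list(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$start_date <- format(out$start_date)
  out$end_date <- format(out$end_date)
  out$species <- lapply(out$species, unclass)
  out$guard_detect_prob <- as.list(out$guard_detect_prob)
  out$diurnal_window <- format_tod(out$diurnal_window_sec)
  out$diurnal_window_sec <- NULL
  out
}

#' Build a generator configuration from a plain list
#'
#' Inverse of the YAML serialisation written by [write_dataset()]; used by
#' [run_pipeline()] to consume config files.
#'
#' @param x a named list (e.g. parsed YAML).
#' @return a [generator_config()].
#' @export
as_generator_config <- function(x) {
  if (inherits(x, "generator_config")) return(x)
  x$diurnal_window_sec <- NULL
  if (!is.null(x$guard_detect_prob)) x$guard_detect_prob <- unlist(x$guard_detect_prob)
  do.call(generator_config, x)
}
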