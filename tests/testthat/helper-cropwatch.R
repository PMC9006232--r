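# shared fixtures and independent oracles, built in code

ts <- function(x) as.POSIXct(x, tz = "UTC")

# seconds since midnight from "HH:MM[:SS]" (independent of package internals)
tod_sec <- function(x) {
  vapply(strsplit(x, ":", fixed = TRUE), function(p) {
    sum(as.integer(p) * c(3600L, 60L, 1L)[seq_along(p)])
  }, integer(1))
}

make_detections <- function(times, station = "C1", species = "baboon") {
  tibble::tibble(station_id = station, timestamp = ts(times), species = species)
}

# independent O(n^2) reference for the pooled independence-window rule:
# a photo starts a new event iff its gap to EVERY earlier photo of the same
# species is at least the window (checked against all predecessors, not just
# the nearest one)
oracle_cluster <- function(detections, window_min) {
  d <- detections[order(detections$timestamp, detections$station_id), ]
  out <- lapply(split(d, d$species), function(x) {
    t <- as.numeric(x$timestamp)
    eid <- integer(length(t))
    eid[1] <- 1L
    if (length(t) > 1) {
      for (i in 2:length(t)) {
        prev <- t[1:(i - 1)]
        eid[i] <- if (all(t[i] - prev >= window_min * 60)) eid[i - 1] + 1L else eid[i - 1]
      }
    }
    do.call(rbind, lapply(split(seq_along(t), eid), function(ix) {
      data.frame(species = x$species[1],
                 start = min(t[ix]), end = max(t[ix]),
                 n_detections = length(ix))
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$species, out$start), ]
  rownames(out) <- NULL
  out
}

# random photo streams for property tests: clumped arrivals so that both
# within-window and across-window gaps occur
random_detections <- function(n, n_stations = 3, span_hours = 24,
                              species = c("baboon", "vervet")) {
  base <- ts("2013-06-01 00:00:00")
  clump <- cumsum(rexp(n, rate = 1 / 600)) # mean 10 min between photos
  tibble::tibble(
    station_id = paste0("C", sample.int(n_stations, n, replace = TRUE)),
    timestamp = base + round(clump %% (span_hours * 3600)),
    species = sample(species, n, replace = TRUE)
  )
}

# random valid event tables for the read/write round-trip property
random_events <- function(n, method = "researcher") {
  starts <- ts("2013-05-01 06:00:00") + sort(sample.int(86400 * 30, n)) * 10
  ends <- starts + sample(60:1200, n, replace = TRUE)
  if (method == "guard") {
    ends <- as.POSIXct(rep(NA_real_, n), tz = "UTC", origin = "1970-01-01")
  }
  items <- if (method == "researcher") {
    suppressWarnings(as.integer(ifelse(runif(n) < 0.2, NA, sample(0:20, n, TRUE))))
  } else rep(NA_integer_, n)
  n_det <- if (method == "camera") sample(1:9, n, TRUE) else rep(NA_integer_, n)
  tibble::tibble(
    method = method,
    species = rep(sample(c("baboon", "vervet"), 1), n),
    start = starts, end = ends, items_removed = items, n_detections = n_det
  )
}

# tiny generator configuration for fast tests
small_config <- function(..., seed = 99) {
  generator_config(
    start_date = "2013-05-01", end_date = "2013-05-30",
    species = list(
      baboon = species_params(daily_rate = 2, group_size_mean = 4,
                              items_per_individual_mean = 2, camera_trigger_prob = 0.8),
      vervet = species_params(daily_rate = 2, group_size_mean = 2,
                              items_per_individual_mean = 1, camera_trigger_prob = 0.4)
    ),
    seed = seed, ...
  )
}

published_stats <- function() {
  utils::read.csv(system.file("extdata", "agreement_stats_published.csv",
                              package = "cropwatch"), stringsAsFactors = FALSE)
}
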