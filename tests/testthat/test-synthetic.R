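test_that("zero rates give an empty truth table; invalid ranges error", {
  cfg <- generator_config(
    start_date = "2013-05-01", end_date = "2013-05-20",
    species = list(baboon = species_params(daily_rate = 0, group_size_mean = 8),
                   vervet = species_params(daily_rate = 0, group_size_mean = 3)),
    seed = 1)
  expect_equal(nrow(generate_truth(cfg)), 0)
  expect_error(generator_config(start_date = "2013-06-01", end_date = "2013-05-01"),
               "date_range")
})

test_that("total event count is consistent with the daily Poisson rate", {
  # rate 3/day over 100 days, flat season: total ~ Poisson(300) before the
  # empty-field thinning, which at this rate removes only a small fraction
  cfg <- generator_config(
    start_date = "2013-05-01", end_date = "2013-08-08",
    species = list(baboon = species_params(daily_rate = 3, group_size_mean = 8),
                   vervet = species_params(daily_rate = 0, group_size_mean = 3)),
    seasonal_amplitude = 0, seed = 2024)
  truth <- generate_truth(cfg)
  expect_true(all(truth$species == "baboon"))
  bounds <- qpois(c(0.005, 0.995), 300)
  expect_gte(nrow(truth), bounds[1] - 15) # small allowance for thinning losses
  expect_lte(nrow(truth), bounds[2])
})

test_that("truth events honour the empty-field gap and the diurnal window", {
  cfg <- small_config(seed = 5)
  for (seed in 1:5) {
    cfg$seed <- seed
    truth <- generate_truth(cfg)
    tod <- as.numeric(truth$start) %% 86400
    expect_true(all(tod >= 6 * 3600 & tod < 18 * 3600))
    for (sp in unique(truth$species)) {
      x <- truth[truth$species == sp, ]
      if (nrow(x) > 1) {
        gaps <- as.numeric(x$start[-1]) - as.numeric(x$end[-nrow(x)])
        expect_true(all(gaps >= cfg$min_event_gap_min * 60))
      }
    }
  }
})

test_that("a perfect researcher reproduces truth on duty dates; a blind one sees nothing", {
  cfg <- small_config(researcher_detect_prob = 1, items_missing_frac = 0)
  cal <- weekday_calendar("researcher", cfg$start_date, cfg$end_date)
  truth <- generate_truth(cfg)
  obs <- simulate_researcher(truth, cal, cfg)
  on_duty <- truth[truth$date %in% cal$dates, ]
  expect_equal(obs$truth_event_id, on_duty$event_id)
  expect_equal(obs$items_removed, on_duty$items_removed)
  expect_equal(as.numeric(obs$entry_time), as.numeric(on_duty$start) %% 86400)

  cfg0 <- small_config(researcher_detect_prob = 0)
  expect_equal(nrow(simulate_researcher(generate_truth(cfg0), cal, cfg0)), 0)
})

test_that("researcher missing-item fraction is binomially consistent", {
  cfg <- generator_config(
    start_date = "2013-05-01", end_date = "2013-08-08",
    species = list(baboon = species_params(daily_rate = 12, group_size_mean = 4)),
    guard_detect_prob = c(baboon = 0.85),
    items_missing_frac = 0.2, seed = 77)
  cal <- daily_calendar("researcher", cfg$start_date, cfg$end_date)
  truth <- generate_truth(cfg)
  obs <- simulate_researcher(truth, cal, cfg)
  expect_gt(nrow(obs), 500)
  n_missing <- sum(is.na(obs$items_removed))
  bounds <- qbinom(c(0.005, 0.995), nrow(obs), 0.2)
  expect_gte(n_missing, bounds[1])
  expect_lte(n_missing, bounds[2])
})

test_that("degenerate guard probabilities keep exactly one species", {
  cfg <- small_config(guard_detect_prob = c(baboon = 1, vervet = 0),
                      guard_delay_min = 0)
  truth <- generate_truth(cfg)
  log <- simulate_guard(truth, cfg)
  expect_setequal(log$truth_event_id, truth$event_id[truth$species == "baboon"])
  expect_true(all(log$species == "baboon"))
  expect_equal(nrow(simulate_guard(truth[0, ], cfg)), 0)
})

test_that("one small event seen by one camera yields a single clean burst", {
  cfg <- generator_config(
    start_date = "2013-05-01", end_date = "2013-05-01",
    species = list(baboon = species_params(daily_rate = 1, group_size_mean = 1,
                                           camera_trigger_prob = 1)),
    guard_detect_prob = c(baboon = 1), seed = 3)
  truth <- tibble::tibble(
    event_id = 1L, species = "baboon", date = as.Date("2013-05-01"),
    start = ts("2013-05-01 09:00:00"), end = ts("2013-05-01 09:10:00"),
    duration_min = 10, group_size = 1L, entry_position_m = 30,
    items_removed = 2L)
  stations <- camera_stations(c("A", "B"), c(30, 70), c(20, 60), c(40, 80))
  det <- simulate_cameras(truth, stations, cfg)
  expect_equal(nrow(det), 3) # one three-shot burst
  expect_true(all(det$station_id == "A"))
  expect_equal(as.numeric(diff(det$timestamp)), c(1, 1))
  expect_equal(det$timestamp[1], truth$start)
})

test_that("the camera refractory period suppresses rapid re-triggers", {
  cfg <- generator_config(
    start_date = "2013-05-01", end_date = "2013-05-01",
    species = list(baboon = species_params(daily_rate = 1, group_size_mean = 6,
                                           camera_trigger_prob = 1)),
    guard_detect_prob = c(baboon = 1), seed = 8)
  # 6 passages crammed into a 4-second event: only the first can trigger
  truth <- tibble::tibble(
    event_id = 1L, species = "baboon", date = as.Date("2013-05-01"),
    start = ts("2013-05-01 09:00:00"), end = ts("2013-05-01 09:00:04"),
    duration_min = 4 / 60, group_size = 6L, entry_position_m = 50,
    items_removed = 0L)
  st <- camera_stations("A", 50, 40, 60)
  det <- simulate_cameras(truth, st, cfg)
  expect_equal(nrow(det), 3)

  # property: on any random stream, burst starts on one station are >= rest apart
  cfg2 <- small_config(seed = 31)
  sim <- simulate_dataset(cfg2)
  d <- sim$detections
  for (stn in unique(d$station_id)) {
    tt <- sort(as.numeric(d$timestamp[d$station_id == stn]))
    gaps <- diff(tt)
    burst_starts <- tt[c(TRUE, gaps > cfg2$inter_photo_seconds * (cfg2$burst_size - 1))]
    if (length(burst_starts) > 1) {
      expect_true(all(diff(burst_starts) >= cfg2$rest_seconds))
    }
  }
})

test_that("every simulated observation maps to exactly one truth event", {
  sim <- simulate_dataset(small_config(seed = 12))
  ids <- sim$truth$event_id
  expect_true(all(sim$detections$truth_event_id %in% ids))
  expect_true(all(sim$guard_log$truth_event_id %in% ids))
  expect_true(all(sim$researcher_log$truth_event_id %in% ids))
  # no phantom species flips either
  sp <- setNames(sim$truth$species, sim$truth$event_id)
  expect_equal(sim$detections$species, unname(sp[as.character(sim$detections$truth_event_id)]))
})

test_that("simulation is seed-deterministic and method streams are independent", {
  a <- simulate_dataset(small_config(seed = 17))
  b <- simulate_dataset(small_config(seed = 17))
  expect_identical(a$truth, b$truth)
  expect_identical(a$detections, b$detections)
  expect_identical(a$guard_log, b$guard_log)
  expect_identical(a$researcher_log, b$researcher_log)
  # changing a researcher-only parameter leaves the other streams untouched
  c2 <- simulate_dataset(small_config(seed = 17, items_missing_frac = 0.5))
  expect_identical(a$detections, c2$detections)
  expect_identical(a$guard_log, c2$guard_log)
  expect_false(identical(a$researcher_log$items_removed, c2$researcher_log$items_removed))
})

test_that("entry positions are biased away from the guard station", {
  cfg <- generator_config(
    start_date = "2013-05-01", end_date = "2013-08-08",
    species = list(vervet = species_params(daily_rate = 15, group_size_mean = 3)),
    guard_detect_prob = c(vervet = 0.15),
    guard_position_m = 0, guard_avoidance = 1.5, seed = 21)
  truth <- generate_truth(cfg)
  expect_gt(nrow(truth), 500)
  # under uniform entries the mean distance from a corner guard is 50 m
  expect_gt(mean(abs(truth$entry_position_m - cfg$guard_position_m)), 52)
  expect_true(all(truth$entry_position_m >= 0 & truth$entry_position_m <= 100))
})
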