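test_that("period construction follows the floor rule", {
  p <- build_periods("2013-05-01", "2013-08-08")
  expect_equal(nrow(p), 10) # 100 days divide evenly
  expect_equal(p$start[1], as.Date("2013-05-01"))
  expect_equal(p$end[10], as.Date("2013-08-08"))

  expect_equal(nrow(build_periods("2013-05-01", "2013-05-10")), 1)
  expect_warning(p15 <- build_periods("2013-05-01", "2013-05-15"), "5 trailing day")
  expect_equal(nrow(p15), 1)
  expect_error(build_periods("2013-05-01", "2013-05-05"), "shorter than one")
})

test_that("matched days are the intersection of the duty calendars", {
  full <- seq(as.Date("2013-05-01"), as.Date("2013-05-10"), 1)
  cam <- duty_calendar("camera", full, c("00:00:00", "23:59:59"))
  gd <- duty_calendar("guard", full)
  res <- duty_calendar("researcher", full[-c(3, 7)]) # absent 2 of 10 days
  expect_equal(matched_days(list(cam, gd, res)), full[-c(3, 7)])
  expect_length(matched_days(list(cam, gd, res)), 8)
  expect_equal(matched_days(list(cam)), full)

  other <- duty_calendar("researcher", full + 30)
  expect_error(matched_days(list(cam, other)), "limiting method")
})

test_that("daily crop loss sums known items and reports exclusions", {
  cal <- duty_calendar("researcher", seq(as.Date("2013-05-01"), as.Date("2013-05-03"), 1))
  r <- tibble::tibble(
    date = as.Date(c("2013-05-01", "2013-05-01", "2013-05-02", "2013-05-02")),
    entry_time = tod_sec(c("08:00:00", "11:00:00", "09:00:00", "14:00:00")),
    exit_time = tod_sec(c("08:30:00", "11:20:00", "09:10:00", "14:30:00")),
    species = "baboon",
    items_removed = c(3L, 2L, 3L, NA))
  ev <- researcher_records_to_events(r, clustering_config())
  cl <- crop_loss_daily(ev, cal)
  b <- cl[cl$species == "baboon", ]
  expect_equal(b$items_removed, c(5L, 3L, 0L))
  expect_equal(b$n_excluded_events, c(0L, 1L, 0L))
  # duty day with no events is an explicit zero, not missing
  expect_equal(nrow(cl), 3 * 2)
})

test_that("period means are matched-day means with exact conservation", {
  periods <- build_periods("2013-05-01", "2013-05-10")
  dates <- seq(as.Date("2013-05-01"), as.Date("2013-05-10"), 1)
  matched <- dates[-c(4, 9)] # 8 matched days
  daily <- tibble::tibble(
    date = dates, species = "baboon", method = "guard",
    measure = "events_per_day", value = c(1, 2, 3, 99, 4, 0, 0, 5, 99, 1))
  m <- aggregate_to_periods(daily, matched, periods)
  expect_equal(m$n_matched_days, 8)
  expect_equal(m$value, mean(daily$value[daily$date %in% matched]))
  # conservation: mean x n_matched_days = sum of matched-day values, exactly
  expect_identical(m$value * m$n_matched_days,
                   sum(daily$value[daily$date %in% matched]))
  # day-symmetry: permuting day order changes nothing
  perm <- daily[sample.int(nrow(daily)), ]
  expect_equal(aggregate_to_periods(perm, matched, periods), m)
  # all-zero days yield a genuine 0.0, not a missing value
  daily0 <- daily
  daily0$value <- 0
  expect_equal(aggregate_to_periods(daily0, matched, periods)$value, 0)
})

test_that("periods without matched days are dropped with a warning", {
  periods <- build_periods("2013-05-01", "2013-05-20")
  dates <- seq(as.Date("2013-05-01"), as.Date("2013-05-20"), 1)
  daily <- tibble::tibble(date = dates, species = "vervet", method = "camera",
                          measure = "events_per_day", value = 1)
  matched <- dates[1:10]
  expect_warning(m <- aggregate_to_periods(daily, matched, periods), "period")
  expect_equal(m$period_index, 1L)
})

test_that("three-method simulated aggregation keeps denominators matched", {
  sim <- simulate_dataset(small_config(seed = 404))
  ccfg <- clustering_config()
  cal <- lapply(sim$calendars, function(x) x)
  cam_ev <- filter_diurnal(cluster_detections(sim$detections, ccfg))
  daily <- bind_daily_measures(
    list(daily_event_counts(cam_ev, cal$camera),
         daily_event_counts(guard_records_to_events(sim$guard_log, ccfg), cal$guard),
         daily_event_counts(researcher_records_to_events(sim$researcher_log, ccfg),
                            cal$researcher)),
    crop_loss_daily(researcher_records_to_events(sim$researcher_log, ccfg),
                    cal$researcher))
  matched <- matched_days(cal)
  periods <- build_periods(sim$config$start_date, sim$config$end_date)
  m <- aggregate_to_periods(daily, matched, periods)
  # every method shares the same matched-day denominator within a period
  denom <- unique(m[, c("period_index", "n_matched_days")])
  expect_equal(nrow(denom), length(unique(m$period_index)))
})
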