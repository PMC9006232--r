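cfg <- clustering_config()

test_that("the greedy window scan reproduces hand-computed clusterings", {
  expect_equal(nrow(cluster_detections(make_detections(character(0))[0, ], cfg)), 0)

  det <- make_detections(c("2013-05-01 09:00:00", "2013-05-01 09:10:00",
                           "2013-05-01 09:45:00", "2013-05-01 11:00:00"))
  ev <- cluster_detections(det, cfg)
  expect_equal(nrow(ev), 3) # gaps 10 < 30; 35 >= 30; 75 >= 30
  expect_equal(ev$n_detections, c(2L, 1L, 1L))
  expect_equal(ev$start[1], ts("2013-05-01 09:00:00"))
  expect_equal(ev$end[1], ts("2013-05-01 09:10:00"))

  # window boundary is inclusive: exactly 30 min starts a new event
  det2 <- make_detections(c("2013-05-01 09:00:00", "2013-05-01 09:30:00"))
  expect_equal(nrow(cluster_detections(det2, cfg)), 2)
  det3 <- make_detections(c("2013-05-01 09:00:00", "2013-05-01 09:29:59"))
  expect_equal(nrow(cluster_detections(det3, cfg)), 1)
})

test_that("different species never share an event", {
  det <- dplyr::bind_rows(
    make_detections("2013-05-01 09:00:00", species = "baboon"),
    make_detections("2013-05-01 09:05:00", species = "vervet"))
  ev <- cluster_detections(det, cfg)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$species, c("baboon", "vervet"))
})

test_that("pooling an extra station can merge events (non-monotonicity)", {
  a <- dplyr::bind_rows(
    make_detections(c("2013-05-01 09:00:00", "2013-05-01 09:40:00"), station = "A"),
    make_detections("2013-05-01 09:20:00", station = "B"))
  expect_equal(nrow(cluster_detections(a, cfg, stations_subset = "A")), 2)
  expect_equal(nrow(cluster_detections(a, cfg, stations_subset = c("A", "B"))), 1)
})

test_that("clustering matches the O(n^2) oracle on random pooled streams", {
  withr::with_seed(123, {
    for (rep in 1:50) {
      det <- random_detections(sample(2:120, 1))
      got <- cluster_detections(det, cfg)
      want <- oracle_cluster(det, 30)
      expect_equal(nrow(got), nrow(want))
      expect_equal(as.numeric(got$start), want$start)
      expect_equal(as.numeric(got$end), want$end)
      expect_equal(got$n_detections, want$n_detections)
    }
  })
})

test_that("clustering partitions detections and respects the gap law", {
  withr::with_seed(7, {
    det <- random_detections(400)
    ev <- cluster_detections(det, cfg)
    expect_equal(sum(ev$n_detections), nrow(det))
    for (sp in unique(ev$species)) {
      e <- ev[ev$species == sp, ]
      if (nrow(e) > 1) {
        gaps <- as.numeric(e$start[-1]) - as.numeric(e$end[-nrow(e)])
        expect_true(all(gaps >= 30 * 60))
      }
    }
    validate_events(ev)
  })
})

test_that("guard records merge within the empty-field gap", {
  g <- tibble::tibble(date = as.Date("2013-05-01"),
                      time = tod_sec(c("08:00:00", "08:00:30")),
                      species = "baboon")
  expect_equal(nrow(guard_records_to_events(g, cfg)), 1)
  g2 <- g
  g2$time <- tod_sec(c("08:00:00", "08:10:00"))
  expect_equal(nrow(guard_records_to_events(g2, cfg)), 2)
  expect_equal(nrow(guard_records_to_events(g[0, ], cfg)), 0)
  # obs_gap_min = 0 takes the written log verbatim
  expect_equal(nrow(guard_records_to_events(g, clustering_config(obs_gap_min = 0))), 2)
})

test_that("researcher records merge with missing-propagation on item counts", {
  r <- tibble::tibble(
    date = as.Date("2013-05-01"),
    entry_time = tod_sec(c("09:00:00", "09:30:20")),
    exit_time = tod_sec(c("09:30:00", "09:45:00")),
    species = "baboon", items_removed = c(3L, NA_integer_))
  ev <- researcher_records_to_events(r, cfg)
  expect_equal(nrow(ev), 1) # 20-second empty-field gap merges
  expect_true(is.na(ev$items_removed))
  expect_equal(ev$start, ts("2013-05-01 09:00:00"))
  expect_equal(ev$end, ts("2013-05-01 09:45:00"))

  r2 <- r
  r2$items_removed <- c(3L, 2L)
  expect_equal(researcher_records_to_events(r2, cfg)$items_removed, 5L)

  # disjoint events pass through unchanged
  r3 <- r2
  r3$entry_time <- tod_sec(c("09:00:00", "11:30:00"))
  r3$exit_time <- tod_sec(c("09:30:00", "11:45:00"))
  ev3 <- researcher_records_to_events(r3, cfg)
  expect_equal(nrow(ev3), 2)
  expect_equal(ev3$items_removed, c(3L, 2L))

  # overlapping same-species events violate the field definition
  r4 <- r2
  r4$entry_time <- tod_sec(c("09:00:00", "09:15:00"))
  expect_error(researcher_records_to_events(r4, cfg), "overlap")
})

test_that("daily counts zero-fill duty dates and reject off-calendar events", {
  cal <- duty_calendar("guard", seq(as.Date("2013-05-01"), as.Date("2013-05-20"), 1))
  g <- tibble::tibble(date = as.Date("2013-05-03"),
                      time = tod_sec(c("08:00:00", "10:00:00", "12:00:00")),
                      species = "baboon")
  counts <- daily_event_counts(guard_records_to_events(g, cfg), cal)
  expect_equal(nrow(counts), 20 * 2) # 20 duty dates x 2 species
  expect_equal(counts$n_events[counts$date == as.Date("2013-05-03") &
                                 counts$species == "baboon"], 3L)
  expect_true(all(counts$n_events[counts$date != as.Date("2013-05-03")] == 0L))

  off <- guard_records_to_events(
    tibble::tibble(date = as.Date("2013-06-15"), time = tod_sec("08:00:00"),
                   species = "baboon"), cfg)
  expect_error(daily_event_counts(off, cal), "non-duty")
})

test_that("diurnal filtering keeps events by start time", {
  ev <- cluster_detections(make_detections(
    c("2013-05-01 05:59:59", "2013-05-01 09:00:00", "2013-05-01 18:00:00")), cfg)
  kept <- filter_diurnal(ev)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, ts("2013-05-01 09:00:00"))
})
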