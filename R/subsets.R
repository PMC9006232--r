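#' Enumerate camera-station subsets
#'
#' All distinct combinations of the requested sizes, in deterministic
#' lexicographic order of sorted station ids (sizes ascending).
#'
#' @param stations a `cw_stations` table or character vector of station ids.
#' @param sizes integer vector of subset sizes.
#' @return list of character vectors of station ids.
#' @examples
#' length(enumerate_subsets(default_stations(), 1:4)) # 30
#' @export
enumerate_subsets <- function(stations, sizes) {
  ids <- if (is.character(stations)) stations else stations$station_id
  ids <- sort(unique(ids))
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1) || any(sizes > length(ids))) {
    abort(sprintf("subset sizes must lie in 1..%d", length(ids)))
  }
  unlist(lapply(sizes, function(k) {
    combn(ids, k, simplify = FALSE)
  }), recursive = FALSE)
}

#' Independent event counts for every camera subset
#'
#' The survey-design simulation: for each subset of stations, restrict the
#' photo stream to those stations, re-run the pooled independence-window
#' clustering from scratch, and count independent events per species. Because
#' the window is applied to the pooled stream, event counts need not grow
#' with subset size (pooling can merge events), although photo counts do.
#'
#' @param detections full detection table.
#' @param stations `cw_stations` table.
#' @param sizes subset sizes to enumerate (default 1 up to all stations).
#' @param config a [clustering_config()].
#' @param species species to report (default both).
#' @return tibble `(subset_id, station_ids, subset_size, species, n_events)`;
#'   `station_ids` is a `+`-collapsed string.
#' @export
subset_event_counts <- function(detections, stations, sizes = NULL,
                                config = clustering_config(),
                                species = SPECIES_LEVELS) {
  if (is.null(sizes)) sizes <- seq_len(nrow(stations))
  subsets <- enumerate_subsets(stations, sizes)
  rows <- purrr::imap(subsets, function(ids, i) {
    ev <- cluster_detections(detections, config, stations_subset = ids)
    counts <- table(factor(ev$species, levels = species))
    tibble::tibble(
      subset_id = i,
      station_ids = paste(ids, collapse = "+"),
      subset_size = length(ids),
      species = species,
      n_events = as.integer(counts[species])
    )
  })
  dplyr::bind_rows(rows)
}

#' Summarise the subset simulation
#'
#' Per-size minimum / median / maximum event counts, the single-camera table
#' (each station alone), and the per-species fold ratio between the
#' single cameras recording the most and the fewest events (a measure of how
#' much camera placement matters; undefined and flagged when the minimum is
#' zero).
#'
#' @param results output of [subset_event_counts()].
#' @return list with tibbles `by_size`, `single_camera` and `fold_ratio`.
#' @export
subset_summary <- function(results) {
  grp <- dplyr::group_by(results, .data$subset_size, .data$species)
  by_size <- dplyr::summarise(
    grp, n_subsets = dplyr::n(),
    min = min(.data$n_events), median = median(.data$n_events),
    max = max(.data$n_events), .groups = "drop")
  single <- results[results$subset_size == 1,
                    c("station_ids", "species", "n_events")]
  names(single)[1] <- "station_id"
  if (nrow(single) > 0) {
    fr_grp <- dplyr::group_by(single, .data$species)
    fold <- dplyr::summarise(
      fr_grp, max_count = max(.data$n_events), min_count = min(.data$n_events),
      fold_ratio = ifelse(min(.data$n_events) > 0,
                          max(.data$n_events) / min(.data$n_events), NA_real_),
      defined = min(.data$n_events) > 0, .groups = "drop")
  } else {
    fold <- tibble::tibble(species = character(0), max_count = integer(0),
                           min_count = integer(0), fold_ratio = numeric(0),
                           defined = logical(0))
  }
  list(by_size = by_size, single_camera = single, fold_ratio = fold)
}

#' Plot event counts against number of cameras
#'
#' One point per subset (jittered) with per-size medians, faceted by species
#' — the design curve showing how many cameras a deployment needs.
#'
#' @param results output of [subset_event_counts()].
#' @return a ggplot object.
#' @export
plot_subset_counts <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$subset_size, y = .data$n_events)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = median, geom = "line", colour = "steelblue") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "Number of cameras", y = "Independent crop-foraging events") +
    ggplot2::theme_minimal()
}

#' Plot single-camera event counts along the field edge
#'
#' Event counts for each camera alone against its position, with the guard
#' station marked — visualising placement effects such as guard avoidance.
#'
#' @param single single-camera tibble from [subset_summary()].
#' @param stations `cw_stations` table (for positions).
#' @param guard_position_m optional guard position to mark.
#' @return a ggplot object.
#' @export
plot_station_counts <- function(single, stations, guard_position_m = NULL) {
  df <- dplyr::inner_join(single, stations, by = "station_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position_m, y = .data$n_events)) +
    ggplot2::geom_col(width = 6, fill = "grey40") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "Position along field edge (m)",
                  y = "Independent crop-foraging events") +
    ggplot2::theme_minimal()
  if (!is.null(guard_position_m)) {
    p <- p + ggplot2::geom_vline(xintercept = guard_position_m,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}
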