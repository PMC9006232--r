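#' Simple linear regression with the agreement-table summary columns
#'
#' Ordinary least squares `y = a + b x` via [stats::lm()], summarised with
#' the columns used to report method agreement: adjusted R-squared, residual
#' standard error, F statistic and its upper-tail p-value on (1, n-2)
#' degrees of freedom (equivalent to the slope t-test in simple regression).
#'
#' @param x predictor values (one per period).
#' @param y response values.
#' @param predictor_label,response_label,species labels carried into the
#'   output row.
#' @return one-row tibble `(predictor, response, species, n, slope,
#'   intercept, r2, adj_r2, residual_se, f_stat, p_value)`.
#' @examples
#' fit_ols(1:5, 2 * (1:5) + 1)
#' @export
fit_ols <- function(x, y, predictor_label = "x", response_label = "y",
                    species = NA_character_) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) abort("x and y must be complete")
  n <- length(x)
  if (n < 3) abort(sprintf("need at least 3 points to fit, got %d", n))
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0) {
    abort("predictor has no variance")
  }
  fit <- stats::lm(y ~ x)
  # an exact linear relation is a legal input (e.g. self-regression checks);
  # silence summary.lm's perfect-fit advisory only
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  r2 <- sm$r.squared
  if (r2 < 1) {
    f_stat <- (n - 2) * r2 / (1 - r2)
    p_value <- pf(f_stat, 1, n - 2, lower.tail = FALSE)
  } else {
    f_stat <- Inf
    p_value <- .Machine$double.xmin # perfect fit: p underflows, reported as > 0
  }
  tibble::tibble(
    predictor = predictor_label, response = response_label, species = species,
    n = n,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
    residual_se = sm$sigma,
    f_stat = f_stat,
    p_value = p_value
  )
}

#' Method-agreement regression table
#'
#' Fits the eight simple regressions assessing how well the low-cost methods
#' predict researcher data: predictor in {guard events/day, camera
#' events/day}, response in {researcher crop items/day, researcher
#' events/day}, for each species. Row order groups by species (baboons first)
#' with, within species, crop-loss responses before event-count responses and
#' guard before camera within each response.
#'
#' @param measures period-measure tibble from [aggregate_to_periods()]; must
#'   contain, per species, guard and camera `events_per_day`, researcher
#'   `events_per_day` and researcher `items_per_day`.
#' @param alpha significance level for the `significant` flag (default .05).
#'   No multiple-testing correction is applied across the eight simultaneous
#'   tests; `attr(, "n_tests")` records their number.
#' @return 8-row tibble of [fit_ols()] rows plus a `significant` logical.
#' @export
agreement_table <- function(measures, alpha = 0.05) {
  get_series <- function(species, method, measure) {
    s <- measures[measures$species == species & measures$method == method &
                    measures$measure == measure, ]
    if (nrow(s) == 0) {
      abort(sprintf("missing measure series: %s %s %s", species, method, measure))
    }
    s[order(s$period_index), c("period_index", "value")]
  }
  design <- tidyr::expand_grid(
    species = SPECIES_LEVELS,
    response_measure = c("items_per_day", "events_per_day"),
    predictor_method = c("guard", "camera")
  )
  rows <- purrr::pmap(design, function(species, response_measure, predictor_method) {
    pred <- get_series(species, predictor_method, "events_per_day")
    resp <- get_series(species, "researcher", response_measure)
    joined <- dplyr::inner_join(pred, resp, by = "period_index",
                                suffix = c("_x", "_y"))
    fit_ols(
      joined$value_x, joined$value_y,
      predictor_label = paste(predictor_method, "recorded crop-foraging events"),
      response_label = if (response_measure == "items_per_day") {
        "researcher recorded crop loss"
      } else {
        "researcher recorded crop-foraging events"
      },
      species = species
    )
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p_value < alpha
  attr(out, "n_tests") <- nrow(out)
  out
}
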