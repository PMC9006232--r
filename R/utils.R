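#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats rpois rbinom runif rlnorm median pf setNames
#' @importFrom utils combn packageVersion head
NULL

# All date-times in the package are naive local clock time stored as POSIXct
# with tz = "UTC" (the study region has no daylight-saving transitions, so
# clock time is linear). Times of day are integer seconds since midnight.

SPECIES_LEVELS <- c("baboon", "vervet")
METHOD_LEVELS <- c("camera", "guard", "researcher")

#' Parse a time of day to seconds since midnight
#'
#' Accepts `"HH:MM:SS"` or `"HH:MM"` strings. Vectorised; invalid entries
#' return `NA` rather than erroring so that file readers can report bad rows.
#'
#' @param x character vector of times of day.
#' @return integer vector of seconds since midnight (`NA` where unparseable).
#' @keywords internal
parse_tod <- function(x) {
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & grepl("^\\s*\\d{1,2}:\\d{2}(:\\d{2})?\\s*$", x)
  if (any(ok)) {
    parts <- strsplit(trimws(x[ok]), ":", fixed = TRUE)
    sec <- vapply(parts, function(p) {
      p <- as.integer(p)
      if (length(p) == 2L) p <- c(p, 0L)
      p[1L] * 3600L + p[2L] * 60L + p[3L]
    }, integer(1))
    sec[sec >= 86400L] <- NA_integer_
    out[ok] <- sec
  }
  out
}

#' Format seconds since midnight as HH:MM:SS
#' @param sec integer seconds since midnight.
#' @keywords internal
format_tod <- function(sec) {
  ifelse(is.na(sec), NA_character_,
         sprintf("%02d:%02d:%02d", sec %/% 3600L, (sec %% 3600L) %/% 60L, sec %% 60L))
}

#' Combine a calendar date and a time of day into a naive datetime
#' @param date `Date` vector.
#' @param tod_sec integer seconds since midnight.
#' @keywords internal
make_datetime_local <- function(date, tod_sec) {
  as.POSIXct(as.numeric(as.POSIXct(date, tz = "UTC")) + as.numeric(tod_sec),
             origin = "1970-01-01", tz = "UTC")
}

#' Derive independent sub-seeds from a master seed
#'
#' One seeded stream is used per simulated observation method, split
#' deterministically from the master seed, so adding or re-running one method
#' never perturbs the draws of another.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of `n` sub-seeds in `[1, 2^31 - 2]`.
#' @keywords internal
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

assert_species <- function(x, what = "species") {
  bad <- setdiff(unique(x), SPECIES_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf("%s must be one of %s; found: %s", what,
                  paste(SPECIES_LEVELS, collapse = ", "),
                  paste(bad, collapse = ", ")))
  }
  invisible(x)
}
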