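#' Censor GPS fixes to high-quality, high-frequency pairs
#'
#' Drops fixes with HDOP above `hdop_max`, then flags, per individual,
#' the fixes that end a consecutive pair whose time lag lies in the
#' high-frequency window (`[interval_min, interval_max]` minutes,
#' "about 30 min" by default). Censoring is idempotent.
#'
#' @param fixes data frame `individual_id`, `species`, `timestamp`
#'   (`POSIXct`), `lon`, `lat`, `hdop`, sorted by timestamp within
#'   individual (unsorted input is an error, never silently sorted).
#' @param hdop_max maximum HDOP retained (fixes with `hdop > hdop_max`
#'   are removed; the boundary value is kept).
#' @param interval_min,interval_max accepted pair lag, minutes.
#' @return the retained fixes with a logical column `pair_end` marking
#'   fixes that close a valid high-frequency pair.
#' @export
censor_fixes <- function(fixes, hdop_max = 10, interval_min = 25,
                         interval_max = 35) {
  stopifnot(is.data.frame(fixes))
  .check_sorted(fixes)
  keep <- fixes$hdop <= hdop_max
  out <- fixes[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    out$pair_end <- logical(0)
    return(out)
  }
  lag_min <- rep(NA_real_, nrow(out))
  same <- c(FALSE, out$individual_id[-1] ==
    out$individual_id[-nrow(out)])
  lag_min[same] <- diff(as.numeric(out$timestamp))[same[-1]] / 60
  out$pair_end <- !is.na(lag_min) & lag_min >= interval_min &
    lag_min <= interval_max
  # retain only fixes participating in at least one valid pair
  pair_start <- c(out$pair_end[-1], FALSE)
  out[out$pair_end | pair_start, , drop = FALSE]
}

.check_sorted <- function(fixes) {
  if (nrow(fixes) < 2) return(invisible(TRUE))
  same <- fixes$individual_id[-1] == fixes$individual_id[-nrow(fixes)]
  dt <- diff(as.numeric(fixes$timestamp))
  if (any(same & dt <= 0)) {
    stop("fixes must be strictly increasing in time within individual; ",
      "refusing to sort silently", call. = FALSE)
  }
  invisible(TRUE)
}

#' Step velocity between two GPS fixes
#'
#' Straight-line (great-circle, haversine on a sphere of radius
#' 6,371,000 m) distance between the fixes divided by the time lag in
#' hours, stamped at the interval end.
#'
#' @param fix_a,fix_b single-row data frames (or lists) with `lon`,
#'   `lat`, `timestamp`, `individual_id`, `species`; `fix_b` must be the
#'   later fix of the same individual.
#' @return one-row data frame: `individual_id`, `species`,
#'   `interval_end`, `velocity` (m/hr), `type = "True"`.
#' @export
step_velocity <- function(fix_a, fix_b) {
  lag_hr <- as.numeric(fix_b$timestamp - fix_a$timestamp,
    units = "hours")
  if (!isTRUE(lag_hr > 0)) {
    stop("`fix_b` must be strictly later than `fix_a`", call. = FALSE)
  }
  if (!identical(fix_a$individual_id, fix_b$individual_id)) {
    stop("fixes belong to different individuals", call. = FALSE)
  }
  d <- geosphere::distHaversine(c(fix_a$lon, fix_a$lat),
    c(fix_b$lon, fix_b$lat), r = 6371000)
  data.frame(individual_id = fix_b$individual_id,
    species = fix_b$species, interval_end = fix_b$timestamp,
    velocity = d / lag_hr, type = "True")
}

#' True Velocity series from censored fixes
#'
#' Computes the step velocity for every flagged high-frequency pair in a
#' censored fix table (see [censor_fixes()]).
#'
#' @param fixes output of [censor_fixes()].
#' @return data frame of `type = "True"` velocity records.
#' @export
track_velocities <- function(fixes) {
  stopifnot("pair_end" %in% names(fixes))
  idx <- which(fixes$pair_end)
  if (length(idx) == 0) {
    return(data.frame(individual_id = character(0),
      species = character(0),
      interval_end = as.POSIXct(character(0), tz = "UTC"),
      velocity = numeric(0), type = character(0)))
  }
  lag_hr <- as.numeric(fixes$timestamp[idx] -
    fixes$timestamp[idx - 1], units = "hours")
  d <- geosphere::distHaversine(
    cbind(fixes$lon[idx - 1], fixes$lat[idx - 1]),
    cbind(fixes$lon[idx], fixes$lat[idx]), r = 6371000)
  data.frame(individual_id = fixes$individual_id[idx],
    species = fixes$species[idx], interval_end = fixes$timestamp[idx],
    velocity = d / lag_hr, type = "True")
}
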