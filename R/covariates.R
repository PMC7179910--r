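#' Diel period from sun altitude
#'
#' Day when the sun is more than `threshold` degrees above the horizon,
#' Night when more than `threshold` degrees below, Crepuscular otherwise.
#' The default 13.5 degrees brackets civil twilight and the first/last
#' hour of low sun. Boundary values are Crepuscular.
#'
#' @param sun_alt sun altitude in degrees, in `[-90, 90]`.
#' @param threshold half-width of the crepuscular band, degrees.
#' @return factor with levels Day, Night, Crepuscular.
#' @export
classify_diel <- function(sun_alt, threshold = 13.5) {
  stopifnot(all(is.finite(sun_alt)), all(abs(sun_alt) <= 90))
  out <- rep("Crepuscular", length(sun_alt))
  out[sun_alt > threshold] <- "Day"
  out[sun_alt < -threshold] <- "Night"
  factor(out, levels = c("Day", "Night", "Crepuscular"))
}

#' Moon phase category from illumination and altitude
#'
#' Full when the illuminated fraction is at least `full_min` and the moon
#' is above the horizon; Dark when the fraction is below `dark_max` *or*
#' the moon is at or below the horizon (no lunar light reaches the ground
#' either way); Mid otherwise. A moon altitude of exactly zero counts as
#' not above the horizon, keeping Full strictly above-horizon.
#'
#' @param moon_frac illuminated fraction in `[0, 1]`.
#' @param moon_alt moon altitude in degrees.
#' @param dark_max,full_min fraction thresholds (defaults 0.1 and 0.9).
#' @return factor with levels Dark, Mid, Full.
#' @export
classify_moon <- function(moon_frac, moon_alt, dark_max = 0.1,
                          full_min = 0.9) {
  stopifnot(all(moon_frac >= 0 & moon_frac <= 1))
  out <- rep("Mid", length(moon_frac))
  out[moon_frac >= full_min & moon_alt > 0] <- "Full"
  out[moon_frac < dark_max | moon_alt <= 0] <- "Dark"
  factor(out, levels = c("Dark", "Mid", "Full"))
}

.lunar_diel_levels <- c("Day",
  "Dark Moon Night", "Mid Moon Night", "Full Moon Night",
  "Dark Moon Crepuscular", "Mid Moon Crepuscular", "Full Moon Crepuscular")

#' Merged lunar-diel time period
#'
#' Crosses moon phase with diel period for Night and Crepuscular records
#' only; all Day records collapse to the single level "Day", since lunar
#' illumination cannot matter in daylight. The codomain has exactly 7
#' levels.
#'
#' @param diel factor from [classify_diel()].
#' @param moon_phase factor from [classify_moon()].
#' @return factor with the 7 lunar-diel levels.
#' @export
lunar_diel <- function(diel, moon_phase) {
  diel <- as.character(diel)
  moon_phase <- as.character(moon_phase)
  out <- ifelse(diel == "Day", "Day",
    paste(moon_phase, "Moon", diel))
  factor(out, levels = .lunar_diel_levels)
}

#' Thermal season from daily maximum temperature
#'
#' Hot when TMAX is at or above `hot_tmax` (33 C by default, the upper
#' bound of the ocelot thermoneutral zone), Cool otherwise.
#'
#' @param tmax daily maximum temperature, degrees C.
#' @param hot_tmax threshold, degrees C.
#' @return factor with levels Cool, Hot.
#' @export
classify_season <- function(tmax, hot_tmax = 33) {
  stopifnot(all(is.finite(tmax)))
  factor(ifelse(tmax >= hot_tmax, "Hot", "Cool"),
    levels = c("Cool", "Hot"))
}

#' Join daily TMAX onto timestamped records
#'
#' Each record is joined to the TMAX of its *local civil date* (fixed
#' UTC offset, default -6 h). TMIN is retained for diagnostics only.
#'
#' @param records data frame with a `POSIXct` `timestamp` column.
#' @param weather data frame `date`, `tmax`, `tmin`.
#' @param tz_offset civil-time offset from UTC in hours.
#' @return `records` with columns `TMAX` and `local_date` appended.
#' @export
attach_tmax <- function(records, weather, tz_offset = -6) {
  stopifnot(is.data.frame(records), "timestamp" %in% names(records))
  local_date <- as.Date(records$timestamp + tz_offset * 3600)
  idx <- match(as.character(local_date), as.character(weather$date))
  if (anyNA(idx) && nrow(records) > 0) {
    miss <- sort(unique(local_date[is.na(idx)]))
    stop("weather table has no entry for date(s): ",
      paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  }
  records$local_date <- local_date
  records$TMAX <- weather$tmax[idx]
  records
}

#' Per-species standardized log velocity
#'
#' Applies `log(1 + v)` and then centres and scales to unit standard
#' deviation within each species, so species with different baseline
#' movement rates become comparable. (Centring raw velocity first would
#' make the log undefined for sub-mean values, so the log is taken first;
#' see the methods vignette.)
#'
#' @param records data frame with `velocity` (>= 0) and `species`.
#' @return `records` with a `log_velocity` column appended.
#' @export
standardize_velocity <- function(records) {
  stopifnot(all(records$velocity >= 0))
  records$log_velocity <- rep(NA_real_, nrow(records))
  for (sp in unique(records$species)) {
    i <- records$species == sp
    if (sum(i) < 2) {
      stop("species `", sp, "` has fewer than 2 records", call. = FALSE)
    }
    lv <- log1p(records$velocity[i])
    s <- stats::sd(lv)
    if (s == 0) {
      stop("species `", sp, "` has zero velocity variance", call. = FALSE)
    }
    records$log_velocity[i] <- (lv - mean(lv)) / s
  }
  records
}

#' Build the categorized analysis table
#'
#' Takes a combined velocity series (see [combine_velocity()]), attaches
#' ephemeris covariates and daily TMAX, classifies each record into diel,
#' moon-phase, lunar-diel and season levels, and standardizes velocity per
#' species. One output row per input record.
#'
#' @param velocity data frame `individual_id`, `species`, `timestamp`,
#'   `velocity`, `type`.
#' @param weather daily weather table (`date`, `tmax`, `tmin`).
#' @param lon,lat study site, degrees.
#' @param tz_offset civil-time offset from UTC, hours.
#' @param diel_threshold,dark_max,full_min,hot_tmax category thresholds.
#' @return data frame of categorized records ready for model fitting.
#' @export
build_analysis_table <- function(velocity, weather, lon, lat,
                                 tz_offset = -6, diel_threshold = 13.5,
                                 dark_max = 0.1, full_min = 0.9,
                                 hot_tmax = 33) {
  out <- velocity
  if (!"timestamp" %in% names(out) && "interval_end" %in% names(out)) {
    names(out)[names(out) == "interval_end"] <- "timestamp"
  }
  out <- attribute_ephemeris(out, lon, lat)
  out <- attach_tmax(out, weather, tz_offset)
  out$Diel <- classify_diel(out$SunAlt, diel_threshold)
  out$MoonPhase <- classify_moon(out$MoonIlluminatedFrac, out$MoonAlt,
    dark_max, full_min)
  out$LunarDiel <- lunar_diel(out$Diel, out$MoonPhase)
  out$Season <- classify_season(out$TMAX, hot_tmax)
  out$Species <- factor(out$species)
  out <- standardize_velocity(out)
  out
}
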