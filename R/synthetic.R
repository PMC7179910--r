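#' Species activity profile for the synthetic generator
#'
#' Encodes the activity drivers the analysis is designed to detect: a
#' baseline movement rate, multiplicative diel effects, a lunar-illumination
#' effect on nocturnal movement, and a hot-day suppression of diurnal
#' movement. A nocturnal archetype has `night > crepuscular > day`
#' multipliers; a crepuscular archetype has `crepuscular > night > day`.
#'
#' @param name species label.
#' @param baseline_velocity baseline movement rate, metres/hour (> 0).
#' @param night_multiplier,crepuscular_multiplier,day_multiplier positive
#'   multipliers applied to the baseline by diel period.
#' @param lunar_effect signed coefficient on `MoonIlluminatedFrac` x
#'   (moon above horizon), applied to log nocturnal velocity. Negative
#'   values mean moonlight suppresses movement.
#' @param heat_day_suppression multiplier in `[0, 1]` applied to diurnal
#'   velocity on days with `TMAX >=` the hot threshold (33 C).
#' @return a `species_profile` object.
#' @export
species_profile <- function(name, baseline_velocity = 200,
                            night_multiplier = 1.8,
                            crepuscular_multiplier = 1.25,
                            day_multiplier = 0.55,
                            lunar_effect = 0,
                            heat_day_suppression = 1) {
  stopifnot(baseline_velocity > 0, night_multiplier > 0,
    crepuscular_multiplier > 0, day_multiplier > 0,
    heat_day_suppression >= 0, heat_day_suppression <= 1)
  structure(list(name = name, baseline_velocity = baseline_velocity,
    night_multiplier = night_multiplier,
    crepuscular_multiplier = crepuscular_multiplier,
    day_multiplier = day_multiplier, lunar_effect = lunar_effect,
    heat_day_suppression = heat_day_suppression),
    class = "species_profile")
}

#' Built-in archetype profiles
#'
#' `ocelot_profile()` is a nocturnal archetype: strongest movement at
#' night, suppressed by lunar illumination (a dark-moon nocturnal boost)
#' and by hot days. `bobcat_profile()` is a crepuscular archetype with a
#' positive lunar effect and only mild heat suppression.
#'
#' @return a [species_profile()].
#' @export
ocelot_profile <- function() {
  species_profile("ocelot", baseline_velocity = 200,
    night_multiplier = 1.9, crepuscular_multiplier = 1.3,
    day_multiplier = 0.5, lunar_effect = -0.5,
    heat_day_suppression = 0.55)
}

#' @rdname ocelot_profile
#' @export
bobcat_profile <- function() {
  species_profile("bobcat", baseline_velocity = 230,
    night_multiplier = 1.35, crepuscular_multiplier = 1.85,
    day_multiplier = 0.75, lunar_effect = 0.35,
    heat_day_suppression = 0.9)
}

#' Collar GPS schedule
#'
#' Continuous collars record a fix every `fix_interval` minutes for the
#' whole deployment. Lunar-window collars record daily anchor fixes at
#' local noon and midnight plus a high-frequency burst (every
#' `fix_interval` minutes) in a 24- or 72-hour window centred on each
#' full-moon and new-moon instant.
#'
#' @param mode `"continuous"` or `"lunar_window"`.
#' @param fix_interval minutes between high-frequency fixes (default 30).
#' @param window_hours 24 or 72; width of the lunar high-frequency window.
#' @param daily_anchors include the noon/midnight anchor fixes
#'   (lunar-window mode only).
#' @return a `collar_schedule` object.
#' @export
collar_schedule <- function(mode = c("continuous", "lunar_window"),
                            fix_interval = 30, window_hours = 24,
                            daily_anchors = TRUE) {
  mode <- match.arg(mode)
  if (fix_interval <= 0) stop("`fix_interval` must be > 0", call. = FALSE)
  if (!window_hours %in% c(24, 72)) {
    stop("`window_hours` must be 24 or 72", call. = FALSE)
  }
  structure(list(mode = mode, fix_interval = fix_interval,
    window_hours = window_hours, daily_anchors = daily_anchors),
    class = "collar_schedule")
}

#' Simulate a daily weather series
#'
#' Daily TMAX/TMIN with a shared sinusoidal seasonal cycle plus correlated
#' Gaussian anomalies. The anomaly correlation is solved so that the
#' overall Pearson correlation between TMAX and TMIN targets `target_cor`
#' (0.85 by default, the magnitude typical of co-located station extremes).
#'
#' @param start_date first date (`Date` or string).
#' @param n_days number of days (>= 1).
#' @param tmax_mean,tmin_mean annual mean TMAX / TMIN, degrees C.
#' @param amplitude seasonal half-amplitude, degrees C (shared by both).
#' @param sd_noise daily anomaly standard deviation, degrees C.
#' @param target_cor target overall corr(TMAX, TMIN).
#' @param peak_doy day-of-year of the seasonal maximum.
#' @param seed optional RNG seed.
#' @return data frame `date`, `tmax`, `tmin` with `tmax >= tmin`.
#' @export
simulate_weather <- function(start_date, n_days, tmax_mean = 30,
                             tmin_mean = 20, amplitude = 7,
                             sd_noise = 2.5, target_cor = 0.85,
                             peak_doy = 200, seed = NULL) {
  if (!is.numeric(n_days) || n_days < 1) {
    stop("`n_days` must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  dates <- as.Date(start_date) + seq_len(n_days) - 1
  doy <- as.integer(strftime(dates, "%j"))
  seasonal <- amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
  if (sd_noise > 0) {
    # overall cov = amp^2/2 + rho * sd^2 ; solve rho for the target
    v <- amplitude^2 / 2 + sd_noise^2
    rho <- (target_cor * v - amplitude^2 / 2) / sd_noise^2
    if (rho > 1 || rho < -1) {
      warning("target correlation unattainable at these parameters; ",
        "anomaly correlation clamped", call. = FALSE)
      rho <- pmin(1, pmax(-1, rho))
    }
    z1 <- stats::rnorm(n_days, 0, sd_noise)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_days, 0, sd_noise)
  } else {
    z1 <- z2 <- numeric(n_days)
  }
  tmax <- tmax_mean + seasonal + z1
  tmin <- tmin_mean + seasonal + z2
  tmax <- pmax(tmax, tmin)
  data.frame(date = dates, tmax = tmax, tmin = tmin)
}

# five-minute latent grid for one individual's deployment
.five_min_grid <- function(start, n_days) {
  t0 <- as.POSIXct(paste(as.Date(start), "00:00:00"), tz = "UTC")
  seq(from = t0, by = 300, length.out = n_days * 288)
}

# stationary AR1 Gaussian series, marginal sd `sd`
.ar1_series <- function(n, phi, sd) {
  if (sd == 0 || n == 0) return(numeric(n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive",
    init = stats::rnorm(1, 0, sd)))
}

#' Simulate one collared individual
#'
#' Generates the latent 5-minute velocity series (the ground truth), the
#' GPS fix stream under the collar schedule, and the bi-axial
#' accelerometer stream. The latent velocity is
#' `baseline x diel multiplier x lunar modulation x heat suppression`
#' times a log-normal AR1 innovation; positions evolve as a correlated
#' random walk with 5-minute step lengths matching the latent velocity;
#' accelerometer counts are a saturating monotone map of latent velocity
#' plus AR1 noise, rounded and clipped to `[0, 255]`.
#'
#' @param id individual label.
#' @param profile a [species_profile()].
#' @param schedule a [collar_schedule()].
#' @param lon,lat deployment site, degrees.
#' @param start first day of the deployment (`Date` or string).
#' @param n_days deployment length in days (>= 2).
#' @param weather data frame from [simulate_weather()]; must cover the
#'   deployment dates (local civil dates at `tz_offset`).
#' @param ar1_phi AR1 coefficient of the log-velocity innovation at
#'   5-minute steps.
#' @param sd_log marginal SD of the log-velocity innovation.
#' @param jitter_sd GPS positional jitter SD, metres.
#' @param hdop_shape shape of the shifted-gamma HDOP distribution; the
#'   scale is solved so about 5 percent of draws exceed 10, exercising the
#'   censoring path.
#' @param accel_halfsat latent velocity (m/hr) at which the activity-count
#'   map reaches half of the 255 ceiling.
#' @param accel_noise_sd SD of the additive AR1 count noise per axis.
#' @param axis_cor correlation of the between-axis noise components.
#' @param turn_sd SD (radians) of the per-step heading increment of the
#'   correlated random walk.
#' @param tz_offset civil-time offset (hours from UTC) used for the
#'   heat-suppression date join and schedule anchors.
#' @param hot_tmax TMAX threshold (degrees C) activating diurnal heat
#'   suppression.
#' @param malfunction simulate a faulty accelerometer whose counts are
#'   decoupled from movement (for censoring tests).
#' @param seed optional RNG seed.
#' @return list with data frames `truth` (timestamp, velocity, diel,
#'   multiplier components), `gps` (id, species, timestamp, lon, lat,
#'   hdop) and `accel` (id, timestamp, activity_x, activity_y).
#' @export
simulate_individual <- function(id, profile, schedule, lon, lat, start,
                                n_days, weather, ar1_phi = 0.6,
                                sd_log = 0.45, jitter_sd = 15,
                                hdop_shape = 1.5, accel_halfsat = 400,
                                accel_noise_sd = 12, axis_cor = 0.5,
                                turn_sd = 0.4, tz_offset = -6,
                                hot_tmax = 33, malfunction = FALSE,
                                seed = NULL) {
  stopifnot(inherits(profile, "species_profile"),
    inherits(schedule, "collar_schedule"))
  if (n_days < 2) stop("`n_days` must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  tt <- .five_min_grid(start, n_days)
  local_date <- as.Date(tt + tz_offset * 3600)
  miss <- setdiff(as.character(unique(local_date)),
    as.character(weather$date))
  if (length(miss) > 0) {
    stop("weather series does not cover deployment dates: ",
      paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  tmax <- weather$tmax[match(as.character(local_date),
    as.character(weather$date))]

  sun <- sun_altitude(tt, lon, lat)
  malt <- moon_altitude(tt, lon, lat)
  frac <- moon_illuminated_fraction(tt)
  diel <- classify_diel(sun)

  mult <- rep(profile$day_multiplier, length(tt))
  mult[diel == "Night"] <- profile$night_multiplier
  mult[diel == "Crepuscular"] <- profile$crepuscular_multiplier
  lunar <- ifelse(diel == "Night" & malt > 0,
    exp(profile$lunar_effect * frac), 1)
  heat <- ifelse(diel == "Day" & tmax >= hot_tmax,
    profile$heat_day_suppression, 1)
  noise <- .ar1_series(length(tt), ar1_phi, sd_log)
  velocity <- profile$baseline_velocity * mult * lunar * heat * exp(noise)

  # correlated random walk: per-5-min step length from latent velocity
  step_m <- velocity * 300 / 3600
  heading <- cumsum(stats::rnorm(length(tt), 0, turn_sd))
  dlat <- step_m * cos(heading) / 111320
  dlon <- step_m * sin(heading) / (111320 * .cosd(lat))
  lat_path <- lat + c(0, cumsum(dlat[-length(dlat)]))
  lon_path <- lon + c(0, cumsum(dlon[-length(dlon)]))

  fix_times <- .schedule_times(schedule, tt[1], tt[length(tt)], lon, lat,
    tz_offset)
  fi <- match(as.numeric(fix_times), as.numeric(tt))
  fi <- fi[!is.na(fi)]
  hdop_scale <- 9.2 / stats::qgamma(0.95, hdop_shape)
  gps <- data.frame(
    individual_id = id, species = profile$name,
    timestamp = tt[fi],
    lon = lon_path[fi] + stats::rnorm(length(fi), 0,
      jitter_sd / (111320 * .cosd(lat))),
    lat = lat_path[fi] + stats::rnorm(length(fi), 0, jitter_sd / 111320),
    hdop = 0.8 + stats::rgamma(length(fi), hdop_shape, scale = hdop_scale))

  accel_v <- if (malfunction) {
    # faulty sensor: counts follow an unrelated low-level AR1 process
    rep(0.15 * profile$baseline_velocity, length(tt)) *
      exp(.ar1_series(length(tt), ar1_phi, sd_log))
  } else {
    velocity
  }
  base_count <- 255 * (2 / pi) * atan(accel_v / accel_halfsat)
  shared <- .ar1_series(length(tt), ar1_phi, accel_noise_sd)
  nx <- sqrt(axis_cor) * shared +
    sqrt(1 - axis_cor) * .ar1_series(length(tt), ar1_phi, accel_noise_sd)
  ny <- sqrt(axis_cor) * shared +
    sqrt(1 - axis_cor) * .ar1_series(length(tt), ar1_phi, accel_noise_sd)
  accel <- data.frame(
    individual_id = id, timestamp = tt,
    activity_x = pmin(255, pmax(0, round(base_count + nx))),
    activity_y = pmin(255, pmax(0, round(0.92 * base_count + ny))))

  truth <- data.frame(individual_id = id, species = profile$name,
    timestamp = tt, velocity = velocity, diel = diel, sun_alt = sun,
    moon_alt = malt, moon_frac = frac, tmax = tmax)
  list(truth = truth, gps = gps, accel = accel)
}

# fix instants for a schedule within [t0, t1]
.schedule_times <- function(schedule, t0, t1, lon, lat, tz_offset) {
  by_s <- schedule$fix_interval * 60
  if (schedule$mode == "continuous") {
    return(seq(from = t0, to = t1, by = by_s))
  }
  phases <- sort(c(
    moon_phase_instants(t0 - 2 * 86400, t1 + 2 * 86400, "full"),
    moon_phase_instants(t0 - 2 * 86400, t1 + 2 * 86400, "new")))
  half <- schedule$window_hours / 2 * 3600
  hf <- lapply(phases, function(p) {
    # snap window edges onto the global fix grid so fixes land on the
    # 5-minute latent grid
    lo <- t0 + ceiling(as.numeric(p - half - t0, units = "secs") / by_s) *
      by_s
    if (lo > t1 || (p + half) < t0) return(NULL)
    seq(from = max(lo, t0), to = min(p + half, t1), by = by_s)
  })
  anchors <- NULL
  if (isTRUE(schedule$daily_anchors)) {
    days <- seq(from = as.Date(t0), to = as.Date(t1), by = "day")
    noon_utc <- as.POSIXct(paste(days, "12:00:00"), tz = "UTC") -
      tz_offset * 3600
    midnight_utc <- as.POSIXct(paste(days, "00:00:00"), tz = "UTC") -
      tz_offset * 3600
    anchors <- c(noon_utc, midnight_utc)
    anchors <- anchors[anchors >= t0 & anchors <= t1]
  }
  out <- sort(unique(do.call(c, c(hf, list(anchors)))))
  out[!is.na(out)]
}

#' Default synthetic cohort configuration
#'
#' Mirrors the field deployment the analysis was designed around: 8
#' nocturnal-archetype ("ocelot-like") and 6 crepuscular-archetype
#' ("bobcat-like") individuals on a mix of continuous and lunar-window
#' collar schedules at a single subtropical site.
#'
#' @param n_ocelot,n_bobcat cohort sizes per archetype.
#' @param n_days deployment length per individual, days.
#' @param start first deployment day.
#' @param lon,lat study site, degrees.
#' @param malfunction_ids ids whose accelerometer is simulated as faulty.
#' @param ... forwarded to [simulate_individual()] (noise levels etc.).
#' @return a config list for [simulate_cohort()].
#' @export
cohort_config <- function(n_ocelot = 8, n_bobcat = 6, n_days = 60,
                          start = "2016-03-01", lon = -97.44, lat = 26.54,
                          malfunction_ids = character(0), ...) {
  ids <- c(sprintf("O%02d", seq_len(n_ocelot)),
    sprintf("B%02d", seq_len(n_bobcat)))
  species <- c(rep("ocelot", n_ocelot), rep("bobcat", n_bobcat))
  # roughly one third of each archetype on continuous collars, the rest on
  # 24-h lunar windows, echoing the mixed field schedules
  sched <- rep("lunar_window", length(ids))
  sched[seq_along(ids) %% 3 == 0] <- "continuous"
  list(ids = ids, species = species, schedule = sched,
    n_days = n_days, start = start, lon = lon, lat = lat,
    malfunction_ids = malfunction_ids, sim_args = list(...))
}

#' Simulate a full cohort with ground truth
#'
#' @param config list from [cohort_config()].
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list of class `synthetic_dataset` with elements `gps`, `accel`,
#'   `weather`, `truth` (all data frames), `profiles`, and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  if (anyDuplicated(config$ids)) {
    stop("duplicate individual ids in config", call. = FALSE)
  }
  set.seed(seed)
  weather <- simulate_weather(as.Date(config$start) - 2,
    config$n_days + 4, seed = NULL)
  profiles <- list(ocelot = ocelot_profile(), bobcat = bobcat_profile())
  seeds <- sample.int(.Machine$integer.max, length(config$ids))
  parts <- lapply(seq_along(config$ids), function(i) {
    sched <- collar_schedule(config$schedule[i])
    args <- c(list(id = config$ids[i],
      profile = profiles[[config$species[i]]], schedule = sched,
      lon = config$lon, lat = config$lat, start = config$start,
      n_days = config$n_days, weather = weather,
      malfunction = config$ids[i] %in% config$malfunction_ids,
      seed = seeds[i]), config$sim_args)
    do.call(simulate_individual, args)
  })
  structure(list(
    gps = do.call(rbind, lapply(parts, `[[`, "gps")),
    accel = do.call(rbind, lapply(parts, `[[`, "accel")),
    weather = weather,
    truth = do.call(rbind, lapply(parts, `[[`, "truth")),
    profiles = profiles, config = config, seed = seed),
    class = "synthetic_dataset")
}

#' Write a synthetic dataset as CSV streams
#'
#' Emits `gps.csv` (id, timestamp, lon, lat, hdop), `accel.csv`
#' (id, timestamp, activity_x, activity_y), `weather.csv`
#' (date, tmax, tmin) and `truth.csv`, timestamps ISO-8601 UTC.
#'
#' @param dataset a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(x) strftime(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  gps <- dataset$gps
  gps$timestamp <- iso(gps$timestamp)
  accel <- dataset$accel
  accel$timestamp <- iso(accel$timestamp)
  truth <- dataset$truth
  truth$timestamp <- iso(truth$timestamp)
  paths <- file.path(dir, c("gps.csv", "accel.csv", "weather.csv",
    "truth.csv"))
  utils::write.csv(gps, paths[1], row.names = FALSE)
  utils::write.csv(accel, paths[2], row.names = FALSE)
  utils::write.csv(dataset$weather, paths[3], row.names = FALSE)
  utils::write.csv(truth, paths[4], row.names = FALSE)
  invisible(paths)
}
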