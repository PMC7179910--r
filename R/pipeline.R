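#' Pipeline configuration
#'
#' Collects every tunable the pipeline uses: the synthetic cohort (or a
#' directory of CSV streams), the study site, censoring and
#' categorization thresholds, and model options.
#'
#' @param cohort a [cohort_config()] list (synthetic mode), or `NULL`
#'   when `input_dir` is given.
#' @param input_dir directory holding `gps.csv`, `accel.csv`,
#'   `weather.csv` as written by [write_dataset()].
#' @param seed integer seed controlling the synthetic cohort and the
#'   forest fit.
#' @param hdop_max,interval_min,interval_max GPS censoring thresholds.
#' @param diel_threshold,dark_max,full_min,hot_tmax categorization
#'   thresholds (degrees, fractions, degrees C).
#' @param tz_offset civil-time offset from UTC, hours.
#' @param n_trees forest size for the velocity model.
#' @param fit_candidates fit and rank the 9-model exploratory set
#'   (per species) in addition to the final model.
#' @param velocity_model optional pre-fitted [fit_velocity_model()]
#'   object, used when the run itself yields no trainable data.
#' @param output_dir directory for CSV/JSON products (`NULL` = none).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), input_dir = NULL,
                            seed = 1, hdop_max = 10, interval_min = 25,
                            interval_max = 35, diel_threshold = 13.5,
                            dark_max = 0.1, full_min = 0.9,
                            hot_tmax = 33, tz_offset = -6,
                            n_trees = 1000, fit_candidates = TRUE,
                            velocity_model = NULL, output_dir = NULL) {
  thresholds <- c(hdop_max, interval_min, interval_max, diel_threshold,
    dark_max, full_min, hot_tmax)
  if (any(!is.finite(thresholds))) {
    stop("all thresholds must be finite", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full activity-analysis pipeline
#'
#' Executes simulate/ingest, ephemeris attribution, trajectory
#' censoring, accelerometer fusion, covariate categorization, and AR1
#' mixed-model inference with marginal-means contrasts, recording the
#' record count at every censoring step in a JSON-serializable manifest.
#' A failed stage is recorded with its cause; completed products are
#' kept. Identical seed and config give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` plus the intermediate and final products
#'   (`dataset`, `velocity`, `analysis_table`, `model_comparison`,
#'   `final_fit`, `emmeans`, `contrasts`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed, stages = list())
  out <- list()
  note <- function(stage, status, counts = NULL, message = NULL) {
    manifest$stages[[stage]] <<- list(status = status,
      counts = counts, message = message)
  }
  fail <- function(stage, e) {
    note(stage, "failed", message = conditionMessage(e))
    out$manifest <<- manifest
    if (!is.null(config$output_dir)) {
      .write_products(out, config$output_dir)
    }
    out
  }

  # --- data ---------------------------------------------------------
  r <- tryCatch({
    ds <- if (!is.null(config$input_dir)) {
      read_dataset(config$input_dir)
    } else {
      simulate_cohort(config$cohort, seed = config$seed)
    }
    note("data", "ok", counts = list(gps = nrow(ds$gps),
      accel = if (is.null(ds$accel)) 0 else nrow(ds$accel)))
    ds
  }, error = function(e) e)
  if (inherits(r, "error")) return(fail("data", r))
  out$dataset <- ds <- r
  site <- c(lon = ds$config$lon %||% config$cohort$lon,
    lat = ds$config$lat %||% config$cohort$lat)

  # --- trajectory ---------------------------------------------------
  r <- tryCatch({
    cf <- censor_fixes(ds$gps, hdop_max = config$hdop_max,
      interval_min = config$interval_min,
      interval_max = config$interval_max)
    tv <- track_velocities(cf)
    note("trajectory", "ok", counts = list(fixes_in = nrow(ds$gps),
      fixes_retained = nrow(cf), true_velocity = nrow(tv)))
    tv
  }, error = function(e) e)
  if (inherits(r, "error")) return(fail("trajectory", r))
  out$true_velocity <- tv <- r

  # --- fusion -------------------------------------------------------
  r <- tryCatch({
    species_map <- NULL
    pred <- tv[0, ]
    model <- config$velocity_model
    flags <- NULL
    if (!is.null(ds$accel) && nrow(ds$accel) > 0) {
      species_map <- stats::setNames(
        as.character(ds$gps$species[!duplicated(ds$gps$individual_id)]),
        ds$gps$individual_id[!duplicated(ds$gps$individual_id)])
      if (nrow(tv) == 0) {
        warning("no True Velocity records after censoring; ",
          if (is.null(model)) "fusion skipped" else
            "using supplied velocity model (Predicted-only)",
          call. = FALSE)
      } else {
        tab <- build_training_table(tv, ds$accel)
        flags <- detect_accel_malfunction(tab)
        bad <- flags$individual_id[isTRUE_v(flags$flagged)]
        tab_ok <- tab[!tab$individual_id %in% bad, , drop = FALSE]
        if (nrow(tab_ok) >= 50) {
          model <- fit_velocity_model(tab_ok, n_trees = config$n_trees,
            seed = config$seed)
        }
        accel_ok <- ds$accel[!ds$accel$individual_id %in% bad, ,
          drop = FALSE]
      }
      if (!is.null(model)) {
        accel_use <- if (exists("accel_ok", inherits = FALSE)) {
          accel_ok
        } else {
          ds$accel
        }
        pred <- predict_velocity(model, accel_use, species = species_map)
      }
    }
    vc <- combine_velocity(tv, pred)
    note("fusion", "ok", counts = list(predicted = nrow(pred),
      combined = nrow(vc), true_in_combined = sum(vc$type == "True"),
      flagged_individuals = if (is.null(flags)) 0 else
        sum(flags$flagged, na.rm = TRUE)))
    list(vc = vc, model = model, flags = flags)
  }, error = function(e) e)
  if (inherits(r, "error")) return(fail("fusion", r))
  out$velocity_model <- r$model
  out$malfunction <- r$flags
  out$velocity <- vc <- r$vc

  # --- covariates ---------------------------------------------------
  r <- tryCatch({
    at <- build_analysis_table(vc, ds$weather, site["lon"], site["lat"],
      tz_offset = config$tz_offset,
      diel_threshold = config$diel_threshold,
      dark_max = config$dark_max, full_min = config$full_min,
      hot_tmax = config$hot_tmax)
    note("covariates", "ok", counts = list(records = nrow(at)))
    at
  }, error = function(e) e)
  if (inherits(r, "error")) return(fail("covariates", r))
  out$analysis_table <- at <- r

  # --- inference ----------------------------------------------------
  r <- tryCatch({
    comparison <- NULL
    if (isTRUE(config$fit_candidates)) {
      comparison <- do.call(rbind, lapply(split(at, at$species),
        function(d) {
          tab <- rank_aic(fit_candidates(d))
          tab$species <- d$species[1]
          tab
        }))
      rownames(comparison) <- NULL
    }
    final <- fit_final_model(at)
    # a factor constant in the data (e.g. an all-Cool deployment) is
    # dropped by fit_final_model; the grid follows suit
    specs <- intersect(c("LunarDiel", "Season", "Species"),
      names(final$xlev))
    emm <- estimate_marginal_means(final, specs)
    contr <- list(
      time_periods = pairwise_contrasts(emm,
        by = intersect("Species", specs)),
      species = pairwise_contrasts(emm,
        by = intersect(c("LunarDiel", "Season"), specs)))
    note("inference", "ok", counts = list(n_modelled = final$n,
      n_candidates = if (is.null(comparison)) 0 else nrow(comparison)))
    list(comparison = comparison, final = final, emm = emm,
      contr = contr)
  }, error = function(e) e)
  if (inherits(r, "error")) return(fail("inference", r))
  out$model_comparison <- r$comparison
  out$final_fit <- r$final
  out$emmeans <- r$emm
  out$contrasts <- r$contr

  out$manifest <- manifest
  if (!is.null(config$output_dir)) {
    .write_products(out, config$output_dir)
  }
  out
}

isTRUE_v <- function(x) !is.na(x) & x

#' Timestamp formatting for CSV interchange
#'
#' Formats `POSIXct` values as explicit ISO-8601 UTC
#' (`2016-04-20T00:30:00Z`) and parses them back. Plain
#' `as.POSIXct()` on mixed columns silently drops the time of day when
#' any element is an exact midnight, so all CSV products round-trip
#' through these.
#'
#' @param x `POSIXct` vector (`iso8601_utc`) or character vector
#'   (`parse_iso8601_utc`).
#' @return character or `POSIXct` vector respectively.
#' @export
iso8601_utc <- function(x) {
  strftime(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' @rdname iso8601_utc
#' @export
parse_iso8601_utc <- function(x) {
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
}

#' Read a CSV dataset written by [write_dataset()]
#'
#' @param dir directory with `gps.csv`, `accel.csv` (optional) and
#'   `weather.csv`.
#' @return a `synthetic_dataset`-shaped list (without truth unless
#'   `truth.csv` is present).
#' @export
read_dataset <- function(dir) {
  parse_time <- function(x) as.POSIXct(x, tz = "UTC",
    format = "%Y-%m-%dT%H:%M:%SZ")
  gps <- utils::read.csv(file.path(dir, "gps.csv"))
  gps$timestamp <- parse_time(gps$timestamp)
  weather <- utils::read.csv(file.path(dir, "weather.csv"))
  weather$date <- as.Date(weather$date)
  accel <- NULL
  if (file.exists(file.path(dir, "accel.csv"))) {
    accel <- utils::read.csv(file.path(dir, "accel.csv"))
    accel$timestamp <- parse_time(accel$timestamp)
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv"))) {
    truth <- utils::read.csv(file.path(dir, "truth.csv"))
    truth$timestamp <- parse_time(truth$timestamp)
  }
  structure(list(gps = gps, accel = accel, weather = weather,
    truth = truth, config = list(lon = NULL, lat = NULL)),
    class = "synthetic_dataset")
}

.write_products <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) if (!is.null(d)) {
    for (v in names(d)) {
      if (inherits(d[[v]], "POSIXct")) d[[v]] <- iso8601_utc(d[[v]])
    }
    utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  }
  wr(out$velocity, "velocity_combined.csv")
  wr(out$analysis_table, "analysis_table.csv")
  wr(out$model_comparison, "model_comparison.csv")
  if (!is.null(out$final_fit)) {
    wr(out$final_fit$coefficients, "coefficients.csv")
  }
  if (!is.null(out$emmeans)) {
    wr(as.data.frame(out$emmeans), "emmeans.csv")
  }
  if (!is.null(out$contrasts)) {
    wr(out$contrasts$time_periods, "contrasts_time_periods.csv")
    wr(out$contrasts$species, "contrasts_species.csv")
  }
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Mean velocity profile over sun-angle bins
#'
#' Mean velocity and standard error of the mean within half-open 10
#' degree sun-altitude bins, split by species and velocity provenance
#' Type — the standard visual summary of diel activity structure.
#'
#' @param records data frame with `SunAlt`, `velocity`, `species`,
#'   `type`.
#' @param bin_width bin width in degrees (default 10).
#' @return data frame `species`, `type`, `bin_lo`, `bin_hi`, `n`,
#'   `mean_velocity`, `sem`; empty bins appear with `n = 0`.
#' @export
sun_angle_profile <- function(records, bin_width = 10) {
  stopifnot(all(c("SunAlt", "velocity", "species", "type") %in%
    names(records)))
  breaks <- seq(-90, 90, by = bin_width)
  bin <- cut(records$SunAlt, breaks, right = FALSE,
    include.lowest = FALSE)
  combos <- expand.grid(species = unique(records$species),
    type = unique(records$type), bin = levels(bin),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- records$species == combos$species[i] &
      records$type == combos$type[i] &
      !is.na(bin) & bin == combos$bin[i]
    v <- records$velocity[sel]
    k <- match(combos$bin[i], levels(bin))
    data.frame(species = combos$species[i], type = combos$type[i],
      bin_lo = breaks[k], bin_hi = breaks[k + 1], n = length(v),
      mean_velocity = if (length(v) > 0) mean(v) else NA_real_,
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else
        if (length(v) == 1) 0 else NA_real_)
  })
  out <- do.call(rbind, rows)
  out[order(out$species, out$type, out$bin_lo), , drop = FALSE]
}
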