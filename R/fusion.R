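.feature_names <- c("min_x", "max_x", "mean_x", "var_x",
  "min_y", "max_y", "mean_y", "var_y")

#' Accelerometer feature window for one interval end
#'
#' Summarizes the 6 accelerometer readings in the trailing half-open
#' 30-minute window `(interval_end - 30 min, interval_end]` as the
#' minimum, maximum, mean and sample variance (n - 1 denominator) of each
#' axis. Returns `NULL` (missingness, not failure) when fewer than 6
#' readings fall in the window.
#'
#' @param accel_stream one individual's accelerometer data frame
#'   (`timestamp`, `activity_x`, `activity_y`), sorted.
#' @param interval_end `POSIXct` window end.
#' @return one-row data frame of the 8 features, or `NULL`.
#' @export
window_features <- function(accel_stream, interval_end) {
  sel <- accel_stream$timestamp > interval_end - 1800 &
    accel_stream$timestamp <= interval_end
  if (sum(sel) < 6) return(NULL)
  x <- accel_stream$activity_x[sel]
  y <- accel_stream$activity_y[sel]
  out <- data.frame(interval_end = interval_end,
    min_x = min(x), max_x = max(x), mean_x = mean(x),
    var_x = stats::var(x),
    min_y = min(y), max_y = max(y), mean_y = mean(y),
    var_y = stats::var(y))
  out
}

# vectorized feature windows at every grid timestamp with a complete
# trailing window; assumes (and checks) the 5-min report grid
.all_window_features <- function(accel) {
  parts <- lapply(split(accel, accel$individual_id), function(a) {
    a <- a[order(a$timestamp), , drop = FALSE]
    n <- nrow(a)
    if (n < 6) return(NULL)
    idx <- 6:n
    # window complete iff the 6 readings span exactly 25 minutes
    ok <- as.numeric(a$timestamp[idx]) -
      as.numeric(a$timestamp[idx - 5]) == 1500
    if (!any(ok)) return(NULL)
    roll <- function(v, fun) {
      m <- stats::embed(v, 6)  # row i = v[i+5], v[i+4], ..., v[i]
      apply(m, 1, fun)
    }
    out <- data.frame(
      individual_id = a$individual_id[idx][ok],
      interval_end = a$timestamp[idx][ok],
      min_x = roll(a$activity_x, min)[ok],
      max_x = roll(a$activity_x, max)[ok],
      mean_x = roll(a$activity_x, mean)[ok],
      var_x = roll(a$activity_x, stats::var)[ok],
      min_y = roll(a$activity_y, min)[ok],
      max_y = roll(a$activity_y, max)[ok],
      mean_y = roll(a$activity_y, mean)[ok],
      var_y = roll(a$activity_y, stats::var)[ok])
    out
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Training table of feature windows and True Velocity
#'
#' Joins each True Velocity record to the accelerometer feature window
#' ending at the same instant for the same individual. Velocity records
#' are deduplicated on (individual, interval end); records without a
#' complete window are dropped and counted.
#'
#' @param true_velocities data frame from [track_velocities()].
#' @param accel accelerometer data frame for the cohort.
#' @return data frame with the 8 features plus `velocity`; the number of
#'   velocity records dropped for missing windows is attached as
#'   attribute `n_dropped`.
#' @export
build_training_table <- function(true_velocities, accel) {
  tv <- true_velocities[!duplicated(true_velocities[,
    c("individual_id", "interval_end")]), , drop = FALSE]
  if (nrow(tv) == 0) {
    stop("no True Velocity records supplied", call. = FALSE)
  }
  fw <- .all_window_features(accel)
  if (is.null(fw) || nrow(fw) == 0) {
    stop("no complete accelerometer feature windows; streams may not ",
      "overlap the GPS track period", call. = FALSE)
  }
  key_tv <- paste(tv$individual_id, as.numeric(tv$interval_end))
  key_fw <- paste(fw$individual_id, as.numeric(fw$interval_end))
  idx <- match(key_tv, key_fw)
  keep <- !is.na(idx)
  if (!any(keep)) {
    stop("True Velocity and accelerometer streams share no timestamps: ",
      "empty training join", call. = FALSE)
  }
  out <- cbind(tv[keep, c("individual_id", "species", "interval_end",
    "velocity")], fw[idx[keep], .feature_names])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Fit the accelerometer-to-velocity regression ensemble
#'
#' Random-forest regression of True Velocity on the 8 window features,
#' with 1,000 trees and `floor(p/3)` variables tried per split (the
#' regression default). Being a mean-of-trees ensemble, predictions are
#' bounded by the training-target range.
#'
#' @param table training table from [build_training_table()].
#' @param n_trees trees in the forest.
#' @param vars_per_split variables tried at each split.
#' @param seed integer seed; one seed fully determines the fit.
#' @return a `velocity_model` object wrapping the fitted forest with
#'   out-of-bag and resubstitution accuracy summaries.
#' @export
fit_velocity_model <- function(table, n_trees = 1000,
                               vars_per_split = max(1, floor(
                                 length(.feature_names) / 3)),
                               seed = 1) {
  if (nrow(table) < 50) {
    stop("need at least 50 training rows", call. = FALSE)
  }
  x <- table[, .feature_names]
  y <- table$velocity
  degenerate <- stats::var(y) == 0
  if (degenerate) {
    warning("constant velocity target: degenerate fit returned",
      call. = FALSE)
  }
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
    mtry = vars_per_split)
  resub <- stats::predict(rf, x)
  oob_rsq <- if (degenerate) NA_real_ else utils::tail(rf$rsq, 1)
  structure(list(forest = rf, n_trees = n_trees,
    vars_per_split = vars_per_split, seed = seed,
    target_range = range(y),
    oob = list(variance_explained = oob_rsq,
      rmse = sqrt(utils::tail(rf$mse, 1))),
    resubstitution = list(
      r_squared = if (degenerate) NA_real_ else
        stats::cor(resub, y)^2,
      rmse = sqrt(mean((resub - y)^2)))),
    class = "velocity_model")
}

#' @export
print.velocity_model <- function(x, ...) {
  cat("<velocity_model>", x$n_trees, "trees,",
    x$vars_per_split, "vars/split\n")
  cat(sprintf("  OOB variance explained: %.1f%%  OOB RMSE: %.2f\n",
    100 * x$oob$variance_explained, x$oob$rmse))
  cat(sprintf("  resubstitution R2: %.4f  RMSE: %.2f\n",
    x$resubstitution$r_squared, x$resubstitution$rmse))
  invisible(x)
}

#' Predicted Velocity series from accelerometer data
#'
#' Applies the fitted ensemble to every accelerometer timestamp with a
#' complete trailing 30-minute window, one prediction per 5-minute
#' report.
#'
#' @param model a [fit_velocity_model()] result.
#' @param accel accelerometer data frame (may span several individuals).
#' @param species optional named vector mapping individual id to species
#'   label (carried through to the output).
#' @return data frame `individual_id`, `species`, `interval_end`,
#'   `velocity`, `type = "Predicted"`.
#' @export
predict_velocity <- function(model, accel, species = NULL) {
  stopifnot(inherits(model, "velocity_model"))
  fw <- .all_window_features(accel)
  if (is.null(fw) || nrow(fw) == 0) {
    return(data.frame(individual_id = character(0),
      species = character(0),
      interval_end = as.POSIXct(character(0), tz = "UTC"),
      velocity = numeric(0), type = character(0)))
  }
  pred <- stats::predict(model$forest, fw[, .feature_names])
  data.frame(individual_id = fw$individual_id,
    species = if (is.null(species)) NA_character_ else
      unname(species[fw$individual_id]),
    interval_end = fw$interval_end,
    velocity = as.numeric(pred), type = "Predicted")
}

#' Validate predicted against true velocity
#'
#' Ordinary least-squares regression of Predicted on True Velocity over
#' paired records, plus the studentized Breusch-Pagan test of
#' homoscedasticity of the regression residuals.
#'
#' @param true,predicted velocity data frames sharing
#'   (`individual_id`, `interval_end`) keys.
#' @return list with `n`, `slope`, `intercept`, `r_squared`,
#'   `bp_statistic`, `bp_df`, `bp_p_value`.
#' @export
validate_prediction <- function(true, predicted) {
  key_t <- paste(true$individual_id, as.numeric(true$interval_end))
  key_p <- paste(predicted$individual_id,
    as.numeric(predicted$interval_end))
  idx <- match(key_t, key_p)
  ok <- !is.na(idx)
  if (sum(ok) < 3) {
    stop("fewer than 3 paired records", call. = FALSE)
  }
  tv <- true$velocity[ok]
  pv <- predicted$velocity[idx[ok]]
  fit <- stats::lm(pv ~ tv)
  bp <- lmtest::bptest(fit, studentize = TRUE)
  list(n = sum(ok), slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    bp_statistic = unname(bp$statistic), bp_df = unname(bp$parameter),
    bp_p_value = unname(bp$p.value))
}

#' Added variance from an interaction with a covariate
#'
#' Compares the base regression of Predicted on True Velocity with a
#' model adding the covariate main effect and its interaction with True
#' Velocity; reports the R-squared gain as a percentage. Near-zero values
#' show that the activity-to-velocity relationship does not depend on the
#' covariate.
#'
#' @param true,predicted paired velocity vectors (equal length).
#' @param covariate vector (numeric or factor) aligned with the pairs.
#' @return added variance explained, in percent.
#' @export
interaction_check <- function(true, predicted, covariate) {
  stopifnot(length(true) == length(predicted),
    length(covariate) == length(true))
  if (length(unique(covariate)) < 2) {
    warning("constant covariate: added variance is 0", call. = FALSE)
    return(0)
  }
  base <- stats::lm(predicted ~ true)
  full <- stats::lm(predicted ~ true * covariate)
  100 * (summary(full)$r.squared - summary(base)$r.squared)
}

#' Flag individuals with malfunctioning accelerometers
#'
#' An accelerometer is considered faulty when the individual repeatedly
#' shows high-velocity GPS movements while its activity counts sit in the
#' cohort's low tail: at least `min_events` paired intervals with
#' velocity above the cohort `vel_hi_quantile` and mean window activity
#' below the cohort `act_lo_quantile`. Flagged individuals are excluded
#' from model training (their GPS-only records remain usable).
#'
#' @param training_table cohort training table from
#'   [build_training_table()].
#' @param ids optional ids to assess (defaults to those present);
#'   ids with no paired data are reported as unassessable (`NA` flag).
#' @param vel_hi_quantile,act_lo_quantile cohort quantile thresholds.
#' @param min_events events needed to flag an individual.
#' @return data frame `individual_id`, `n_events`, `flagged`.
#' @export
detect_accel_malfunction <- function(training_table, ids = NULL,
                                     vel_hi_quantile = 0.9,
                                     act_lo_quantile = 0.1,
                                     min_events = 3) {
  act <- (training_table$mean_x + training_table$mean_y) / 2
  vel_hi <- stats::quantile(training_table$velocity, vel_hi_quantile)
  act_lo <- stats::quantile(act, act_lo_quantile)
  event <- training_table$velocity > vel_hi & act < act_lo
  tab <- tapply(event, training_table$individual_id, sum)
  if (is.null(ids)) ids <- names(tab)
  n_events <- as.integer(tab[ids])
  flagged <- ifelse(is.na(n_events), NA, n_events >= min_events)
  if (anyNA(flagged)) {
    message("individuals with no paired data (unassessable): ",
      paste(ids[is.na(flagged)], collapse = ", "))
  }
  data.frame(individual_id = ids, n_events = n_events,
    flagged = flagged, row.names = NULL)
}

#' Fuse True and Predicted Velocity into Velocity Combined
#'
#' At timestamps holding a True (GPS-derived) record the True record is
#' used; every other Predicted timestamp contributes its Predicted
#' record. The `type` column preserves provenance. Individuals with no
#' Predicted records pass through as their True series.
#'
#' @param true_series,predicted_series velocity data frames.
#' @return the fused, time-sorted velocity data frame.
#' @export
combine_velocity <- function(true_series, predicted_series) {
  dup <- function(d) anyDuplicated(paste(d$individual_id,
    as.numeric(d$interval_end)))
  if (dup(true_series)) {
    stop("duplicate (individual, timestamp) keys in True series",
      call. = FALSE)
  }
  if (nrow(predicted_series) > 0 && dup(predicted_series)) {
    stop("duplicate (individual, timestamp) keys in Predicted series",
      call. = FALSE)
  }
  if (nrow(predicted_series) == 0) {
    out <- true_series
  } else {
    key_t <- paste(true_series$individual_id,
      as.numeric(true_series$interval_end))
    key_p <- paste(predicted_series$individual_id,
      as.numeric(predicted_series$interval_end))
    out <- rbind(true_series,
      predicted_series[!key_p %in% key_t, , drop = FALSE])
  }
  out <- out[order(out$individual_id, out$interval_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
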