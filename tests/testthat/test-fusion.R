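# small fused cohort reused across fusion tests
fusion_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- simulate_weather("2016-02-27", 30, seed = 2)
      parts <- lapply(1:3, function(i) simulate_individual(
        paste0("id", i), ocelot_profile(), collar_schedule("continuous"),
        -97.44, 26.54, "2016-03-01", 18, w, seed = 100 + i))
      cache <<- list(
        gps = do.call(rbind, lapply(parts, `[[`, "gps")),
        accel = do.call(rbind, lapply(parts, `[[`, "accel")),
        truth = do.call(rbind, lapply(parts, `[[`, "truth")))
    }
    cache
  }
})

mk_accel <- function(x, y = x, start = "2016-03-01 00:05",
                     id = "a") {
  data.frame(individual_id = id,
    timestamp = as.POSIXct(start, tz = "UTC") +
      300 * (seq_along(x) - 1),
    activity_x = x, activity_y = y)
}

test_that("feature windows summarize exactly six trailing readings", {
  a <- mk_accel(c(10, 20, 30, 40, 50, 60))
  end <- a$timestamp[6]
  fw <- window_features(a, end)
  expect_equal(fw$min_x, 10)
  expect_equal(fw$max_x, 60)
  expect_equal(fw$mean_x, 35)
  expect_equal(fw$var_x, 350)  # sample variance, n - 1

  const <- window_features(mk_accel(rep(100, 6)),
    as.POSIXct("2016-03-01 00:30", tz = "UTC"))
  expect_equal(unlist(const[c("min_x", "max_x", "mean_x", "var_x")]),
    c(min_x = 100, max_x = 100, mean_x = 100, var_x = 0))

  # five readings only: missing, not an error
  expect_null(window_features(mk_accel(1:5),
    as.POSIXct("2016-03-01 00:25", tz = "UTC")))
})

test_that("30-min GPS intervals align with six accelerometer reports", {
  fx <- fusion_fixture()
  tv <- track_velocities(censor_fixes(fx$gps))
  i30 <- which(as.numeric(diff(tv$interval_end)) == 30)[1]
  end <- tv$interval_end[i30 + 1]
  a <- fx$accel[fx$accel$individual_id == tv$individual_id[i30 + 1], ]
  n_in_window <- sum(a$timestamp > end - 1800 & a$timestamp <= end)
  expect_equal(n_in_window, 6)
  expect_false(is.null(window_features(a, end)))
})

test_that("training table joins, deduplicates, and errors when empty", {
  fx <- fusion_fixture()
  tv <- track_velocities(censor_fixes(fx$gps))
  tab <- build_training_table(tv, fx$accel)
  expect_true(all(c(lunardiel:::.feature_names, "velocity") %in%
    names(tab)))
  # per individual, the first fix of the track cannot close a pair, and
  # the earliest window ends are edge-lossy; counts must reconcile
  expect_equal(nrow(tab) + attr(tab, "n_dropped"), nrow(tv))

  dup <- rbind(tv, tv[1, ])
  tab2 <- build_training_table(dup, fx$accel)
  expect_equal(nrow(tab2), nrow(tab))

  shifted <- fx$accel
  shifted$timestamp <- shifted$timestamp + 365 * 86400
  expect_error(build_training_table(tv, shifted), "no timestamps|overlap")
})

test_that("forest respects its hyperparameter and range contracts", {
  fx <- fusion_fixture()
  tv <- track_velocities(censor_fixes(fx$gps))
  tab <- build_training_table(tv, fx$accel)
  m <- fit_velocity_model(tab, n_trees = 150, seed = 5)
  expect_equal(m$vars_per_split, 2)  # floor(8 / 3)
  pred <- predict_velocity(m, fx$accel)
  expect_true(all(pred$velocity >= m$target_range[1]))
  expect_true(all(pred$velocity <= m$target_range[2]))
  expect_equal(unique(pred$type), "Predicted")

  # deterministic under a fixed seed
  m2 <- fit_velocity_model(tab, n_trees = 150, seed = 5)
  expect_identical(predict_velocity(m2, fx$accel)$velocity,
    pred$velocity)

  # constant target: degenerate but usable
  tab0 <- tab
  tab0$velocity <- 7
  expect_warning(m0 <- fit_velocity_model(tab0, n_trees = 50, seed = 1),
    "constant")
  expect_true(all(stats::predict(m0$forest,
    tab[, lunardiel:::.feature_names]) == 7))

  expect_error(fit_velocity_model(tab[1:20, ]), "50")
})

test_that("short or empty accelerometer streams predict nothing", {
  fx <- fusion_fixture()
  tv <- track_velocities(censor_fixes(fx$gps))
  m <- fit_velocity_model(build_training_table(tv, fx$accel),
    n_trees = 50, seed = 2)
  short <- fx$accel[1:4, ]
  expect_equal(nrow(predict_velocity(m, short)), 0)
})

test_that("predictions track the latent truth at default noise", {
  fx <- fusion_fixture()
  tv <- track_velocities(censor_fixes(fx$gps))
  m <- fit_velocity_model(build_training_table(tv, fx$accel),
    n_trees = 400, seed = 3)
  pred <- predict_velocity(m, fx$accel)
  key_p <- paste(pred$individual_id, as.numeric(pred$interval_end))
  key_t <- paste(fx$truth$individual_id, as.numeric(fx$truth$timestamp))
  i <- match(key_p, key_t)
  expect_gt(stats::cor(pred$velocity, fx$truth$velocity[i],
    method = "spearman"), 0.8)
})

test_that("validation regression recognises a perfect prediction", {
  fx <- fusion_fixture()
  tv <- track_velocities(censor_fixes(fx$gps))
  ident <- tv
  ident$type <- "Predicted"
  rep <- validate_prediction(tv, ident)
  expect_equal(rep$slope, 1, tolerance = 1e-12)
  expect_equal(rep$intercept, 0, tolerance = 1e-9)
  expect_equal(rep$r_squared, 1, tolerance = 1e-12)
  expect_error(validate_prediction(tv[1:2, ], ident[1:2, ]), "3")
})

test_that("Breusch-Pagan flags variance growing with the fitted value", {
  set.seed(77)
  n <- 500
  tvv <- stats::runif(n, 0, 10)
  fitted <- 1 + 2 * tvv
  het <- fitted + stats::rnorm(n, 0, sqrt(0.5 * fitted))
  hom <- fitted + stats::rnorm(n, 0, 2)
  base <- as.POSIXct("2016-03-01", tz = "UTC") + 1800 * seq_len(n)
  mk <- function(v, type) data.frame(individual_id = "a",
    species = "ocelot", interval_end = base, velocity = v, type = type)
  r_het <- validate_prediction(mk(tvv, "True"), mk(het, "Predicted"))
  r_hom <- validate_prediction(mk(tvv, "True"), mk(hom, "Predicted"))
  expect_lt(r_het$bp_p_value, 0.05)
  expect_gt(r_hom$bp_p_value, 0.01)
})

test_that("interaction terms add nothing under a shared relationship", {
  set.seed(11)
  n <- 2000
  true <- stats::runif(n, 0, 10)
  pred <- 2 * true + stats::rnorm(n)
  indep <- factor(sample(c("a", "b"), n, replace = TRUE))
  expect_lt(interaction_check(true, pred, indep), 0.5)

  # a covariate that flips the slope between groups explains a lot
  flip <- ifelse(indep == "a", 2 * true, -2 * true) + stats::rnorm(n)
  expect_gt(interaction_check(true, flip, indep), 20)

  expect_warning(d0 <- interaction_check(true, pred,
    rep("a", n)), "constant")
  expect_equal(d0, 0)
})

test_that("malfunction screening flags the injected fault only", {
  w <- simulate_weather("2016-02-27", 22, seed = 2)
  mk <- function(id, bad, seed) simulate_individual(id,
    ocelot_profile(), collar_schedule("continuous"), -97.44, 26.54,
    "2016-03-01", 15, w, malfunction = bad, seed = seed)
  parts <- list(mk("ok1", FALSE, 1), mk("ok2", FALSE, 2),
    mk("ok3", FALSE, 3), mk("bad", TRUE, 4))
  gps <- do.call(rbind, lapply(parts, `[[`, "gps"))
  accel <- do.call(rbind, lapply(parts, `[[`, "accel"))
  tab <- build_training_table(track_velocities(censor_fixes(gps)),
    accel)
  flags <- detect_accel_malfunction(tab)
  expect_true(flags$flagged[flags$individual_id == "bad"])
  expect_false(any(flags$flagged[flags$individual_id != "bad"]))

  expect_message(
    flags2 <- detect_accel_malfunction(tab, ids = c("ok1", "ghost")),
    "unassessable")
  expect_true(is.na(flags2$flagged[flags2$individual_id == "ghost"]))
})

test_that("velocity fusion prefers True and unions the rest", {
  base <- as.POSIXct("2016-03-01", tz = "UTC")
  mk <- function(n, offset, type, v) data.frame(individual_id = "a",
    species = "ocelot", interval_end = base + offset + 1800 * seq_len(n),
    velocity = v, type = type)
  tv <- mk(10, 0, "True", 100)
  pv <- mk(100, 10 * 1800, "Predicted", 50)
  out <- combine_velocity(tv, pv)
  expect_equal(nrow(out), 110)
  expect_equal(sum(out$type == "True"), 10)

  # coincident timestamp: True wins
  pv2 <- mk(10, 0, "Predicted", 50)
  out2 <- combine_velocity(tv, pv2)
  expect_equal(nrow(out2), 10)
  expect_true(all(out2$type == "True"))
  expect_true(all(out2$velocity == 100))

  # GPS-only collar
  empty <- pv[0, ]
  expect_identical(combine_velocity(tv, empty)$velocity, tv$velocity)

  expect_error(combine_velocity(rbind(tv, tv[1, ]), pv), "duplicate")
  # no timestamp appears twice
  expect_equal(anyDuplicated(paste(out$individual_id,
    out$interval_end)), 0)
})

test_that("validation R2 improves as sensor noise shrinks", {
  w <- simulate_weather("2016-02-27", 20, seed = 2)
  r2_at <- function(noise_sd) {
    parts <- lapply(1:2, function(i) simulate_individual(
      paste0("n", i), ocelot_profile(), collar_schedule("continuous"),
      -97.44, 26.54, "2016-03-01", 12, w, accel_noise_sd = noise_sd,
      seed = 300 + i))
    gps <- do.call(rbind, lapply(parts, `[[`, "gps"))
    accel <- do.call(rbind, lapply(parts, `[[`, "accel"))
    tv <- track_velocities(censor_fixes(gps))
    m <- fit_velocity_model(build_training_table(tv, accel),
      n_trees = 200, seed = 4)
    validate_prediction(tv, predict_velocity(m, accel))$r_squared
  }
  r2 <- vapply(c(40, 12, 2), r2_at, numeric(1))
  expect_true(all(diff(r2) > 0))
})
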