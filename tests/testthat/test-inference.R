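test_that("candidate set reproduces the nine exploratory structures", {
  specs <- build_candidate_models()
  expect_length(specs, 9)
  rhs <- vapply(specs, `[[`, "", "rhs")
  expect_identical(rhs, c("SunAlt", "MoonIlluminatedFrac", "TMAX",
    "SunAlt + MoonIlluminatedFrac", "SunAlt + TMAX",
    "SunAlt + MoonIlluminatedFrac + TMAX",
    "SunAlt * MoonIlluminatedFrac", "SunAlt * TMAX",
    "SunAlt * MoonIlluminatedFrac * TMAX"))
  for (s in specs) {
    expect_identical(s$random, c("individual_id", "type"))
    expect_identical(s$correlation, "ar1")
  }
  # the global interactive model expands to 8 coefficients
  dummy <- data.frame(SunAlt = rnorm(10), MoonIlluminatedFrac = runif(10),
    TMAX = rnorm(10), log_velocity = rnorm(10))
  mm <- model.matrix(specs[[9]]$formula, dummy)
  expect_equal(ncol(mm), 8)
  expect_true("SunAlt:MoonIlluminatedFrac:TMAX" %in% colnames(mm))
})

test_that("structured likelihood equals the dense-covariance oracle", {
  for (s in 1:3) {
    d <- simulate_lmm_data(n_id = 4, n_per = 12, phi = 0.5, seed = s)
    fit <- fit_lme(y ~ x, d)
    do <- d[order(d$individual_id, d$interval_end), ]
    X <- model.matrix(~x, do)
    ll <- dense_lmm_loglik(do$y, X, fit$beta, do$individual_id, do$type,
      fit$phi, fit$sigma2, max(fit$sigma2_id, 0),
      max(fit$sigma2_type, 0))
    expect_lt(abs(fit$logLik - ll), 1e-8)
  }
})

test_that("single-grouping fits match nlme::lme", {
  skip_if_not_installed("nlme")
  d <- simulate_lmm_data(n_id = 6, n_per = 30, sd_type = 0, seed = 3)
  mine <- fit_lme(y ~ x, d, type = NULL)
  ref <- nlme::lme(y ~ x, random = ~ 1 | individual_id,
    correlation = nlme::corAR1(form = ~ 1 | individual_id),
    data = d, method = "ML")
  expect_equal(mine$logLik, as.numeric(stats::logLik(ref)),
    tolerance = 1e-6)
  expect_equal(unname(mine$beta), unname(nlme::fixef(ref)),
    tolerance = 1e-5)
  expect_equal(mine$phi,
    as.numeric(stats::coef(ref$modelStruct$corStruct,
      unconstrained = FALSE)), tolerance = 1e-3)
})

test_that("white-noise data reduce the fit to ordinary least squares", {
  set.seed(4)
  n <- 300
  d <- data.frame(individual_id = "a", x = stats::rnorm(n),
    interval_end = seq_len(n))
  d$y <- 1 + 0.5 * d$x + stats::rnorm(n)
  fit <- fit_lme(y ~ x, d, type = NULL)
  expect_lt(abs(fit$phi), 0.1)
  # with phi pinned at zero the GLS solution is exactly OLS
  fit0 <- fit_lme(y ~ x, d, type = NULL, ar1 = FALSE)
  expect_equal(unname(fit0$beta), unname(stats::coef(stats::lm(y ~ x, d))),
    tolerance = 1e-6)
})

test_that("ML likelihood is monotone in nested fixed effects", {
  d <- simulate_lmm_data(n_id = 5, n_per = 40, seed = 9)
  d$z <- stats::rnorm(nrow(d))
  small <- fit_lme(y ~ x, d)
  big <- fit_lme(y ~ x + z, d)
  expect_gte(big$logLik, small$logLik - 1e-4)
})

test_that("fits and AIC ranking are invariant to row permutation", {
  d <- simulate_lmm_data(n_id = 4, n_per = 30, seed = 6)
  f1 <- fit_lme(y ~ x, d)
  set.seed(1)
  f2 <- fit_lme(y ~ x, d[sample(nrow(d)), ])
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
  expect_equal(f1$AIC, f2$AIC, tolerance = 1e-8)
})

test_that("AIC ranking validates comparability and sorts", {
  d <- simulate_lmm_data(n_id = 4, n_per = 30, seed = 8)
  d$z <- stats::rnorm(nrow(d))
  f1 <- fit_lme(y ~ x, d)
  f2 <- fit_lme(y ~ x + z, d)
  tab <- rank_aic(list(a = f1, b = f2))
  expect_equal(tab$delta_AIC[1], 0)
  expect_true(!is.unsorted(tab$AIC))
  # a duplicated single fit ties at delta 0 for both entries
  tab2 <- rank_aic(list(a = f1, dup = f1))
  expect_equal(tab2$delta_AIC, c(0, 0))

  f3 <- fit_lme(y ~ x, d[1:60, ])
  expect_error(rank_aic(list(f1, f3)), "differing row counts")
  expect_error(rank_aic(list(only = f1)), "at least 2")
})

test_that("an interaction-generated series is recovered by AIC", {
  mk_data <- function(seed) {
    set.seed(seed)
    n_id <- 5; n_per <- 360
    id <- rep(sprintf("i%d", 1:n_id), each = n_per)
    hour <- rep(seq_len(n_per) %% 48 / 2, n_id)
    SunAlt <- 60 * sin(2 * pi * (hour - 6) / 24)
    TMAX <- rep(stats::runif(n_id * 8, 26, 40), each = 45)
    MoonIlluminatedFrac <- stats::runif(n_id * n_per)
    ar1 <- function(n) as.numeric(stats::filter(
      stats::rnorm(n, 0, 0.4), 0.5, method = "recursive"))
    y <- 0.01 * SunAlt + 0.0025 * SunAlt * (TMAX - 32) +
      rep(stats::rnorm(n_id, 0, 0.3), each = n_per) +
      unlist(lapply(1:n_id, function(i) ar1(n_per)))
    data.frame(individual_id = id, type = "True",
      interval_end = rep(seq_len(n_per), n_id), SunAlt = SunAlt,
      TMAX = TMAX, MoonIlluminatedFrac = MoonIlluminatedFrac,
      log_velocity = y)
  }
  for (seed in c(21, 22)) {
    fits <- fit_candidates(mk_data(seed), type = NULL)
    tab <- rank_aic(fits)
    expect_true(tab$model[1] %in% c("8", "9"))
  }
})

test_that("Wald intervals cover the generating slope", {
  hits <- 0
  for (s in 1:20) {
    d <- simulate_lmm_data(n_id = 4, n_per = 25, beta = c(1, 0.5),
      seed = 100 + s)
    fit <- fit_lme(y ~ x, d)
    est <- fit$coefficients[fit$coefficients$term == "x", ]
    half <- stats::qt(0.975, est$df) * est$std_error
    hits <- hits + (abs(est$estimate - 0.5) <= half)
  }
  expect_gte(hits, 16)  # 95% nominal, 20 draws
})

test_that("final model handles the full and collapsed factorials", {
  set.seed(33)
  grid <- expand.grid(
    LunarDiel = factor(lunardiel:::.lunar_diel_levels,
      levels = lunardiel:::.lunar_diel_levels),
    Season = factor(c("Cool", "Hot")),
    Species = factor(c("bobcat", "ocelot")))
  d <- grid[rep(seq_len(nrow(grid)), each = 12), ]
  d$individual_id <- rep_len(sprintf("i%d", 1:6), nrow(d))
  d$type <- rep_len(c("True", "Predicted"), nrow(d))
  d$interval_end <- seq_len(nrow(d))
  d$log_velocity <- stats::rnorm(nrow(d)) +
    as.numeric(d$LunarDiel) * 0.2
  fit <- fit_final_model(d)
  emm <- estimate_marginal_means(fit, c("LunarDiel", "Season",
    "Species"))
  expect_equal(nrow(emm), 28)
  expect_true(all(emm$estimable))

  # collapsing Season reduces to the two-factor fit
  d1 <- d[d$Season == "Cool", ]
  fit1 <- fit_final_model(d1)
  fit_direct <- fit_lme(log_velocity ~ LunarDiel * Species, d1)
  expect_equal(fit1$beta, fit_direct$beta, tolerance = 1e-8)
})

test_that("marginal means equal cell means in balanced designs", {
  set.seed(14)
  d <- data.frame(individual_id = rep(c("a", "b"), each = 30),
    g = factor(rep(rep(c("L", "M", "H"), each = 10), 2)),
    interval_end = rep(1:30, 2))
  d$y <- c(L = 1, M = 2, H = 3)[as.character(d$g)] +
    stats::rnorm(60, 0, 0.3)
  fit <- suppressWarnings(fit_lme(y ~ g, d, type = NULL, ar1 = FALSE))
  emm <- estimate_marginal_means(fit, "g")
  cell <- tapply(d$y, d$g, mean)
  expect_equal(emm$emmean, as.numeric(cell[as.character(emm$g)]),
    tolerance = 1e-9)
})

test_that("marginal means agree with the emmeans package", {
  skip_if_not_installed("emmeans")
  set.seed(15)
  d <- data.frame(individual_id = "a",
    g = factor(rep(c("x", "y", "z"), each = 20)),
    b = factor(rep_len(c("u", "v"), 60)), interval_end = 1:60)
  d$y <- as.numeric(d$g) + 0.5 * (d$b == "v") + stats::rnorm(60, 0, 0.4)
  fit <- suppressWarnings(fit_lme(y ~ g * b, d, type = NULL,
    ar1 = FALSE))
  emm <- estimate_marginal_means(fit, "g")
  ref <- summary(emmeans::emmeans(stats::lm(y ~ g * b, d), "g"))
  expect_equal(emm$emmean, ref$emmean, tolerance = 1e-8)
  expect_equal(emm$SE, ref$SE, tolerance = 1e-8)

  mine <- pairwise_contrasts(emm)
  refp <- summary(emmeans::contrast(emmeans::emmeans(
    stats::lm(y ~ g * b, d), "g"), "pairwise"))
  expect_equal(mine$p.value, refp$p.value, tolerance = 1e-6)
})

test_that("an orthogonal centred covariate leaves means unchanged", {
  set.seed(16)
  xpat <- scale(stats::rnorm(20), scale = FALSE)  # sum-zero pattern
  d <- data.frame(individual_id = "a",
    g = factor(rep(c("p", "q", "r"), each = 20)),
    x = rep(as.numeric(xpat), 3), interval_end = 1:60)
  d$y <- as.numeric(d$g) + 0.8 * d$x + stats::rnorm(60, 0, 0.3)
  f1 <- suppressWarnings(fit_lme(y ~ g, d, type = NULL, ar1 = FALSE))
  f2 <- suppressWarnings(fit_lme(y ~ g + x, d, type = NULL,
    ar1 = FALSE))
  e1 <- estimate_marginal_means(f1, "g")
  e2 <- estimate_marginal_means(f2, "g")
  expect_equal(e1$emmean, e2$emmean, tolerance = 1e-9)
})

test_that("equal-weight means diverge from raw means under imbalance", {
  # cells: (a1,b1) mean 0 n 50, (a1,b2) mean 10 n 10,
  #        (a2,b1) mean 0 n 10, (a2,b2) mean 10 n 50
  set.seed(17)
  d <- data.frame(
    A = factor(c(rep("a1", 60), rep("a2", 60))),
    B = factor(c(rep("b1", 50), rep("b2", 10),
      rep("b1", 10), rep("b2", 50))))
  d$y <- ifelse(d$B == "b2", 10, 0) + stats::rnorm(120, 0, 0.1)
  d$individual_id <- "a"
  d$interval_end <- seq_len(nrow(d))
  fit <- suppressWarnings(fit_lme(y ~ A * B, d, type = NULL,
    ar1 = FALSE))
  emm <- estimate_marginal_means(fit, "A")
  raw <- tapply(d$y, d$A, mean)
  # a1 oversamples its low cell: raw mean below the equal-weight mean
  expect_lt(raw["a1"], emm$emmean[emm$A == "a1"])
  expect_gt(raw["a2"], emm$emmean[emm$A == "a2"])
  expect_equal(emm$emmean[emm$A == "a1"], emm$emmean[emm$A == "a2"],
    tolerance = 0.1)
})

test_that("contrast tables are antisymmetric with Tukey floors", {
  set.seed(18)
  d <- data.frame(individual_id = "a",
    g = factor(rep(c("x", "y", "z"), each = 25)), interval_end = 1:75)
  d$y <- as.numeric(d$g) + stats::rnorm(75, 0, 0.5)
  fit <- suppressWarnings(fit_lme(y ~ g, d, type = NULL, ar1 = FALSE))
  emm <- estimate_marginal_means(fit, "g")
  ct <- pairwise_contrasts(emm)
  ct_none <- pairwise_contrasts(emm, adjust = "none")
  expect_true(all(ct$p.value >= ct_none$p.value - 1e-12))
  expect_true(all(ct$p.value >= 0 & ct$p.value <= 1))
  # reversing the grid flips every estimate's sign
  emm_rev <- emm[3:1, ]
  attr(emm_rev, "L") <- attr(emm, "L")[3:1, ]
  for (a in c("vcov_beta", "beta", "specs", "df")) {
    attr(emm_rev, a) <- attr(emm, a)
  }
  class(emm_rev) <- class(emm)
  ct_rev <- pairwise_contrasts(emm_rev)
  expect_equal(sort(abs(ct$estimate)), sort(abs(ct_rev$estimate)))
  m <- outer(ct$estimate, ct_rev$estimate, "+")
  expect_true(all(apply(abs(m) < 1e-12, 1, any)))
})

test_that("identical cells contrast to zero with adjusted p of one", {
  d <- data.frame(individual_id = "a",
    g = factor(rep(c("x", "y"), each = 20)),
    y = rep(stats::rnorm(20, 0, 1), 2), interval_end = 1:40)
  fit <- suppressWarnings(fit_lme(y ~ g, d, type = NULL, ar1 = FALSE))
  emm <- estimate_marginal_means(fit, "g")
  ct <- pairwise_contrasts(emm)
  expect_equal(ct$estimate, 0)
  expect_equal(ct$p.value, 1)

  # single-cell family yields an empty table
  empty <- pairwise_contrasts(emm, by = "g")
  expect_equal(nrow(empty), 0)
})

test_that("Tukey p matches a numeric studentized-range integration", {
  ptukey_oracle <- function(q, k, df) {
    inner <- function(s) {
      g <- function(z) stats::dnorm(z) *
        (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
      k * stats::integrate(g, -Inf, Inf, rel.tol = 1e-10)$value
    }
    fs <- function(s) exp(log(2) + (df / 2) * log(df / 2) -
      lgamma(df / 2) + (df - 1) * log(s) - df * s^2 / 2)
    cdf <- stats::integrate(function(ss) vapply(ss,
      function(s) fs(s) * inner(s), numeric(1)),
      0, Inf, rel.tol = 1e-9)$value
    1 - cdf
  }
  for (q in c(2.2, 3.4)) {
    expect_equal(stats::ptukey(q, 3, 57, lower.tail = FALSE),
      ptukey_oracle(q, 3, 57), tolerance = 1e-4)
  }
})
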