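#' The nine candidate fixed-effect structures
#'
#' The exploratory model set over the three continuous drivers: each
#' single-covariate model, the three additive combinations containing sun
#' altitude, and the three interactive expansions (three "single", three
#' "additive", three "interactive"). Every candidate carries random
#' intercepts for individual and provenance Type and the AR1 residual
#' correlation.
#'
#' @param response name of the response column.
#' @return list of `model_spec` objects (label, formula, random-effect
#'   and correlation declarations).
#' @export
build_candidate_models <- function(response = "log_velocity") {
  rhs <- c(
    "SunAlt",
    "MoonIlluminatedFrac",
    "TMAX",
    "SunAlt + MoonIlluminatedFrac",
    "SunAlt + TMAX",
    "SunAlt + MoonIlluminatedFrac + TMAX",
    "SunAlt * MoonIlluminatedFrac",
    "SunAlt * TMAX",
    "SunAlt * MoonIlluminatedFrac * TMAX")
  lapply(seq_along(rhs), function(i) {
    structure(list(label = as.character(i), rhs = rhs[i],
      formula = stats::as.formula(paste(response, "~", rhs[i])),
      random = c("individual_id", "type"), correlation = "ar1"),
      class = "model_spec")
  })
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec", x$label, "> ", deparse(x$formula),
    " + (1|", x$random[1], ") + (1|", x$random[2], ") + AR1\n", sep = "")
  invisible(x)
}

#' Fit every candidate model on one data set
#'
#' @param data categorized analysis table (one species, or pooled).
#' @param specs list from [build_candidate_models()].
#' @param ... forwarded to [fit_lme()].
#' @return named list of `ar1_lmm` fits (failures stored as `try-error`).
#' @export
fit_candidates <- function(data, specs = build_candidate_models(), ...) {
  out <- lapply(specs, function(s) {
    try(fit_lme(s$formula, data, ...), silent = TRUE)
  })
  names(out) <- vapply(specs, `[[`, "", "label")
  out
}

#' Rank fitted models by AIC
#'
#' @param fits named list of `ar1_lmm` fits on identical data.
#' @return data frame sorted by ascending AIC with `delta_AIC`, `BIC`
#'   and `logLik`.
#' @export
rank_aic <- function(fits) {
  fits <- Filter(function(f) inherits(f, "ar1_lmm"), fits)
  if (length(fits) < 2) {
    stop("need at least 2 successful fits", call. = FALSE)
  }
  n <- vapply(fits, `[[`, 0, "n")
  if (length(unique(n)) != 1) {
    stop("fits used differing row counts; AIC not comparable",
      call. = FALSE)
  }
  tab <- data.frame(model = names(fits),
    formula = vapply(fits, function(f) deparse(f$formula), ""),
    df = vapply(fits, `[[`, 0, "df"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    BIC = vapply(fits, `[[`, 0, "BIC"),
    logLik = vapply(fits, `[[`, 0, "logLik"), row.names = NULL)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  rownames(tab) <- NULL
  tab
}

#' Fit the final interactive time-period model
#'
#' Full-factorial fixed structure LunarDiel x Season x Species with
#' random intercepts for individual and Type and AR1 residuals. Empty
#' factor cells are reported; the fit proceeds with non-estimable
#' contrasts flagged downstream.
#'
#' @param data categorized analysis table (both species).
#' @param ... forwarded to [fit_lme()].
#' @return an `ar1_lmm` fit.
#' @export
fit_final_model <- function(data, ...) {
  cells <- table(data$LunarDiel, data$Season, data$Species)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    msg <- apply(empty, 1, function(i) paste(
      dimnames(cells)[[1]][i[1]], dimnames(cells)[[2]][i[2]],
      dimnames(cells)[[3]][i[3]], sep = " / "))
    message("empty factor cells (non-estimable contrasts will be ",
      "flagged): ", paste(msg, collapse = "; "))
  }
  # factors that are constant in the data drop out of the factorial
  keep <- Filter(function(v) length(unique(data[[v]])) >= 2,
    c("LunarDiel", "Season", "Species"))
  if (length(keep) == 0) {
    stop("no factor varies; nothing to compare", call. = FALSE)
  }
  fml <- stats::as.formula(paste("log_velocity ~",
    paste(keep, collapse = " * ")))
  fit_lme(fml, data, ...)
}
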