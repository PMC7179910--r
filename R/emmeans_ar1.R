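#' Estimated marginal means over a factor grid
#'
#' Model-implied mean for every combination of the requested factor
#' levels, averaging with equal weight over the levels of model factors
#' not in the grid and holding numeric covariates at their sample means.
#' Standard errors come from the fixed-effect covariance; intervals are
#' t-based with residual degrees of freedom (n minus fixed-effect rank).
#' Cells whose averaging weights touch an aliased (rank-deficient)
#' coefficient are flagged non-estimable rather than dropped.
#'
#' @param fit an [fit_lme()] result.
#' @param specs character vector of factor names to keep in the grid.
#' @param level confidence level (default 0.95).
#' @return an `emm_ar1` data frame: the factor grid plus `emmean`, `SE`,
#'   `df`, `lower.CL`, `upper.CL`, `estimable`.
#' @export
estimate_marginal_means <- function(fit, specs, level = 0.95) {
  stopifnot(inherits(fit, "ar1_lmm"))
  factors <- names(fit$xlev)
  if (!all(specs %in% factors)) {
    stop("`specs` must name factors in the model: ",
      paste(setdiff(specs, factors), collapse = ", "), call. = FALSE)
  }
  tt <- stats::delete.response(fit$terms)
  vars <- all.vars(tt)
  num_vars <- setdiff(vars, factors)

  grid_all <- expand.grid(fit$xlev, KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = TRUE)
  if (nrow(grid_all) == 0) grid_all <- data.frame(row.names = 1)
  for (v in num_vars) {
    grid_all[[v]] <- mean(fit$model_frame[[v]])
  }
  mm <- stats::model.matrix(tt, grid_all, contrasts.arg = fit$contrasts)
  # restrict to the non-aliased columns the fit retained
  keep <- match(names(fit$beta), colnames(mm))
  aliased_cols <- setdiff(colnames(mm), names(fit$beta))

  cells <- unique(grid_all[, specs, drop = FALSE])
  rownames(cells) <- NULL
  L <- matrix(0, nrow(cells), length(fit$beta),
    dimnames = list(NULL, names(fit$beta)))
  estimable <- rep(TRUE, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(grid_all))
    for (v in specs) sel <- sel & grid_all[[v]] == cells[i, v]
    rows <- mm[sel, , drop = FALSE]
    avg <- colMeans(rows)
    if (length(aliased_cols) > 0 &&
      any(abs(avg[aliased_cols]) > 1e-12)) {
      estimable[i] <- FALSE
    }
    L[i, ] <- avg[keep]
  }
  est <- as.numeric(L %*% fit$beta)
  se <- sqrt(pmax(0, rowSums((L %*% fit$vcov_beta) * L)))
  df <- fit$df_resid
  tq <- stats::qt(1 - (1 - level) / 2, df)
  out <- cbind(cells, data.frame(emmean = est, SE = se, df = df,
    lower.CL = est - tq * se, upper.CL = est + tq * se,
    estimable = estimable))
  out$emmean[!estimable] <- NA_real_
  structure(out, class = c("emm_ar1", "data.frame"),
    L = L, vcov_beta = fit$vcov_beta, beta = fit$beta,
    specs = specs, df = df)
}

#' Tukey-adjusted pairwise contrasts of marginal means
#'
#' All pairwise differences of marginal means, optionally within groups
#' defined by `by` columns (e.g. within species, or within time period).
#' P-values are adjusted with the studentized-range (Tukey) method over
#' the number of means in each family; a family of one cell yields an
#' empty table.
#'
#' @param emm an [estimate_marginal_means()] result.
#' @param by optional character vector of grid columns defining contrast
#'   families; pairs are formed within each family.
#' @param adjust `"tukey"` (default) or `"none"`.
#' @param alpha significance level recorded alongside (default 0.05).
#' @return data frame with `contrast`, the `by` columns, `estimate`,
#'   `SE`, `df`, `t.ratio`, `p.value`, `significant`.
#' @export
pairwise_contrasts <- function(emm, by = NULL, adjust = c("tukey", "none"),
                               alpha = 0.05) {
  stopifnot(inherits(emm, "emm_ar1"))
  adjust <- match.arg(adjust)
  if (!is.null(by) && length(by) == 0) by <- NULL
  specs <- attr(emm, "specs")
  L <- attr(emm, "L")
  vb <- attr(emm, "vcov_beta")
  beta <- attr(emm, "beta")
  df <- attr(emm, "df")
  if (!is.null(by) && !all(by %in% specs)) {
    stop("`by` must be a subset of the grid factors", call. = FALSE)
  }
  vary <- setdiff(specs, by)
  lab <- apply(emm[, vary, drop = FALSE], 1, paste, collapse = " ")
  groups <- if (is.null(by)) rep("", nrow(emm)) else
    apply(emm[, by, drop = FALSE], 1, paste, collapse = " ")

  rows <- list()
  for (gr in unique(groups)) {
    idx <- which(groups == gr & emm$estimable)
    k <- length(idx)
    if (k < 2) next
    pairs <- utils::combn(idx, 2)
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      l <- L[i1, ] - L[i2, ]
      est <- sum(l * beta)
      se <- sqrt(max(0, sum((l %*% vb) * l)))
      tval <- if (se > 0) est / se else 0
      p <- if (adjust == "tukey") {
        stats::ptukey(sqrt(2) * abs(tval), k, df, lower.tail = FALSE)
      } else {
        2 * stats::pt(abs(tval), df, lower.tail = FALSE)
      }
      row <- data.frame(contrast = paste(lab[i1], "-", lab[i2]),
        estimate = est, SE = se, df = df, t.ratio = tval, p.value = p,
        significant = p < alpha)
      if (!is.null(by)) {
        row <- cbind(emm[i1, by, drop = FALSE], row)
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(contrast = character(0), estimate = numeric(0),
      SE = numeric(0), df = numeric(0), t.ratio = numeric(0),
      p.value = numeric(0), significant = logical(0))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
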