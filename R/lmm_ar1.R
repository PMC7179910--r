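# AR1 linear mixed model with crossed random intercepts, fit by maximum
# likelihood.
#
# Model: y = X beta + Z_id b_id + Z_type b_type + e, with
#   b_id ~ N(0, sigma2_id I), b_type ~ N(0, sigma2_type I), and
#   e ~ N(0, sigma2 R(phi)) where R is block-diagonal AR1 by observation
#   order within individual.
#
# The marginal covariance is sigma2 * (R + Z G Z') with G the
# variance-ratio matrix; beta and sigma2 are profiled out analytically,
# leaving a 1-3 dimensional optimization over (phi, ratios) on
# transformed scales (Fisher-z for phi, log for ratios). All solves use
# the Woodbury identity with the sparse tridiagonal AR1 inverse, so cost
# is linear in n.

# sparse inverse of the block AR1 correlation matrix, plus log|R|
.ar1_rinv <- function(phi, block_sizes) {
  n <- sum(block_sizes)
  one <- 1 - phi^2
  d <- numeric(n)
  e <- numeric(n - 1)  # superdiagonal
  pos <- 0
  for (nb in block_sizes) {
    i <- pos + seq_len(nb)
    if (nb == 1) {
      d[i] <- 1
    } else {
      d[i] <- c(1, rep(1 + phi^2, nb - 2), 1) / one
      e[pos + seq_len(nb - 1)] <- -phi / one
    }
    pos <- pos + nb
  }
  list(
    Rinv = Matrix::bandSparse(n, n, k = c(0, 1), symmetric = TRUE,
      diagonals = list(d, e)),
    logdet = sum(block_sizes - 1) * log(one))
}

# indicator matrix for a factor, sparse
.indicator <- function(f) {
  f <- droplevels(factor(f))
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f),
    x = 1, dims = c(length(f), nlevels(f)),
    dimnames = list(NULL, levels(f)))
}

#' Fit an AR1 linear mixed-effects model by maximum likelihood
#'
#' Gaussian linear mixed model with independent random intercepts for
#' individual and for velocity provenance ("Type": True vs Predicted),
#' crossed, and a first-order autoregressive residual correlation indexed
#' by observation order within individual. Variance parameters are
#' profiled on transformed scales (Fisher-z for the AR1 coefficient, log
#' for variance ratios) and optimized quasi-Newton from three fixed
#' starting points; the fixed effects and residual variance are profiled
#' analytically, so the fit is deterministic given the data.
#'
#' @param fixed fixed-effects formula, e.g.
#'   `log_velocity ~ LunarDiel * Season * Species`.
#' @param data data frame holding the model variables.
#' @param id name of the individual-id column (random intercept and AR1
#'   blocking factor).
#' @param type name of the provenance column used as the second random
#'   intercept; set `NULL` to omit. A single-level column is dropped with
#'   a message.
#' @param order_by optional column used to order observations within
#'   individual before indexing the AR1 process; defaults to
#'   `interval_end` or `timestamp` when present, so fits are invariant to
#'   row permutations of `data`.
#' @param ar1 include the AR1 residual correlation (default `TRUE`).
#' @param control list: `reltol` for the optimizer (default 1e-8).
#' @return an object of class `ar1_lmm`: coefficient table, variance
#'   components (`sigma2`, `sigma2_id`, `sigma2_type`), AR1 coefficient
#'   `phi`, `logLik`, `AIC`, `BIC`, and the ingredients needed for
#'   marginal-means computation.
#' @export
fit_lme <- function(fixed, data, id = "individual_id", type = "type",
                    order_by = NULL, ar1 = TRUE, control = list()) {
  stopifnot(inherits(fixed, "formula"), is.data.frame(data))
  if (!id %in% names(data)) {
    stop("id column `", id, "` not found", call. = FALSE)
  }
  if (is.null(order_by)) {
    order_by <- intersect(c("interval_end", "timestamp"), names(data))[1]
  }
  ord <- if (!is.na(order_by) && !is.null(order_by)) {
    order(data[[id]], data[[order_by]])
  } else {
    order(data[[id]])
  }
  data <- data[ord, , drop = FALSE]

  mf <- stats::model.frame(fixed, data = data, na.action = stats::na.omit)
  if (nrow(mf) < nrow(data)) {
    data <- data[-attr(mf, "na.action"), , drop = FALSE]
  }
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  contrasts_used <- attr(X, "contrasts")
  n <- length(y)
  qr_x <- qr(X)
  aliased <- character(0)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    aliased <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)

  id_f <- droplevels(factor(data[[id]]))
  block_sizes <- as.integer(table(id_f)[unique(as.character(id_f))])
  use_id <- nlevels(id_f) >= 2
  use_type <- FALSE
  if (!is.null(type) && type %in% names(data)) {
    type_f <- droplevels(factor(data[[type]]))
    use_type <- nlevels(type_f) >= 2
    if (!use_type) {
      message("`", type, "` has a single level; dropping its random ",
        "intercept")
    }
  } else {
    type_f <- NULL
  }

  z_list <- list()
  if (use_id) z_list$id <- .indicator(id_f)
  if (use_type) z_list$type <- .indicator(type_f)
  n_re <- length(z_list)
  z_all <- if (n_re > 0) do.call(cbind, z_list) else NULL
  re_index <- rep(seq_len(n_re), vapply(z_list, ncol, 0L))

  n_par <- ar1 + n_re
  reltol <- control$reltol %||% 1e-8

  nll <- function(theta) {
    phi <- if (ar1) tanh(theta[1]) else 0
    g <- exp(theta[ar1 + seq_len(n_re)])
    ri <- .ar1_rinv(phi, block_sizes)
    if (n_re > 0) {
      g_vec <- g[re_index]
      riz <- ri$Rinv %*% z_all
      m <- as.matrix(Matrix::crossprod(z_all, riz)) +
        diag(1 / g_vec, length(g_vec))
      ch <- tryCatch(chol(m), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      logdet_v <- ri$logdet + sum(log(g_vec)) + 2 * sum(log(diag(ch)))
      vinv <- function(b) {
        rib <- as.matrix(ri$Rinv %*% b)
        rib - as.matrix(riz %*% backsolve(ch, forwardsolve(t(ch),
          as.matrix(Matrix::crossprod(z_all, rib)))))
      }
    } else {
      logdet_v <- ri$logdet
      vinv <- function(b) as.matrix(ri$Rinv %*% b)
    }
    w <- vinv(cbind(X, y))
    xtvx <- crossprod(X, w[, seq_len(p), drop = FALSE])
    xtvy <- crossprod(X, w[, p + 1])
    ytvy <- sum(y * w[, p + 1])
    beta <- tryCatch(solve(xtvx, xtvy), error = function(e) NULL)
    if (is.null(beta)) return(1e10)
    qform <- ytvy - sum(xtvy * beta)
    if (qform <= 0) return(1e10)
    sigma2 <- qform / n
    0.5 * (n * log(2 * pi * sigma2) + logdet_v + n)
  }

  if (n_par > 0) {
    starts <- list(
      c(atanh(0.3), rep(log(0.2), n_re))[seq_len(n_par)],
      c(0, rep(-5, n_re))[seq_len(n_par)],
      c(atanh(0.8), rep(log(1), n_re))[seq_len(n_par)])
    if (!ar1) starts <- lapply(starts, function(s) s[seq_len(n_re)])
    best <- NULL
    for (s in starts) {
      opt <- tryCatch(stats::optim(s, nll, method = "L-BFGS-B",
        lower = c(if (ar1) -6, rep(-20, n_re)),
        upper = c(if (ar1) 6, rep(8, n_re)),
        control = list(factr = reltol / .Machine$double.eps,
          maxit = 500)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
        best <- opt
      }
    }
    if (is.null(best)) {
      stop("AR1 mixed-model optimization failed from all starts",
        call. = FALSE)
    }
    theta <- best$par
    value <- best$value
    convergence <- best$convergence
  } else {
    theta <- numeric(0)
    value <- nll(theta)
    convergence <- 0L
  }

  # recompute profiled quantities at the optimum
  phi <- if (ar1) tanh(theta[1]) else 0
  g <- exp(theta[ar1 + seq_len(n_re)])
  ri <- .ar1_rinv(phi, block_sizes)
  if (n_re > 0) {
    g_vec <- g[re_index]
    riz <- ri$Rinv %*% z_all
    m <- as.matrix(Matrix::crossprod(z_all, riz)) +
      diag(1 / g_vec, length(g_vec))
    ch <- chol(m)
    vinv <- function(b) {
      rib <- as.matrix(ri$Rinv %*% b)
      rib - as.matrix(riz %*% backsolve(ch, forwardsolve(t(ch),
        as.matrix(Matrix::crossprod(z_all, rib)))))
    }
  } else {
    vinv <- function(b) as.matrix(ri$Rinv %*% b)
  }
  w <- vinv(cbind(X, y))
  xtvx <- crossprod(X, w[, seq_len(p), drop = FALSE])
  xtvy <- crossprod(X, w[, p + 1])
  beta <- solve(xtvx, xtvy)
  sigma2 <- (sum(y * w[, p + 1]) - sum(xtvy * beta)) / n
  # likelihood and AIC use the ML residual variance; standard errors use
  # the df-adjusted scale, the convention of the field's mixed-model
  # software even under ML estimation
  vcov_beta <- sigma2 * n / (n - p) * solve(xtvx)
  se <- sqrt(diag(vcov_beta))
  df_resid <- n - p
  tval <- beta / se
  coef_table <- data.frame(term = colnames(X), estimate = as.numeric(beta),
    std_error = se, df = df_resid, t_value = as.numeric(tval),
    p_value = 2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE),
    row.names = NULL)

  df_model <- p + 1 + n_par
  loglik <- -value
  g_named <- stats::setNames(rep(NA_real_, 2), c("id", "type"))
  if (n_re > 0) g_named[names(z_list)] <- g

  fit <- structure(list(
    formula = fixed, coefficients = coef_table,
    beta = stats::setNames(as.numeric(beta), colnames(X)),
    vcov_beta = vcov_beta, aliased = aliased,
    phi = phi, sigma2 = sigma2,
    sigma2_id = unname(g_named["id"] * sigma2),
    sigma2_type = unname(g_named["type"] * sigma2),
    logLik = loglik, df = df_model, AIC = -2 * loglik + 2 * df_model,
    BIC = -2 * loglik + log(n) * df_model,
    n = n, n_individuals = nlevels(id_f), df_resid = df_resid,
    terms = attr(mf, "terms"), xlev = stats::.getXlevels(
      attr(mf, "terms"), mf),
    contrasts = contrasts_used, model_frame = mf,
    convergence = convergence, ar1 = ar1,
    boundary = n_re > 0 && any(theta[ar1 + seq_len(n_re)] <= -19)),
    class = "ar1_lmm")
  if (fit$boundary) {
    warning("a random-effect variance is at the zero boundary",
      call. = FALSE)
  }
  fit
}

#' @export
print.ar1_lmm <- function(x, digits = 4, ...) {
  cat("AR1 linear mixed model (ML)\n")
  cat("  ", deparse(x$formula), "\n")
  cat(sprintf("  n = %d over %d individuals; logLik = %.2f, AIC = %.2f\n",
    x$n, x$n_individuals, x$logLik, x$AIC))
  cat(sprintf("  phi = %.3f; sigma2 = %.4f; sigma2_id = %s; sigma2_type = %s\n",
    x$phi, x$sigma2,
    ifelse(is.na(x$sigma2_id), "-", sprintf("%.4f", x$sigma2_id)),
    ifelse(is.na(x$sigma2_type), "-", sprintf("%.4f", x$sigma2_type))))
  cat("Fixed effects:\n")
  print(x$coefficients, digits = digits)
  invisible(x)
}

#' @export
logLik.ar1_lmm <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n,
    class = "logLik")
}

#' @export
coef.ar1_lmm <- function(object, ...) object$beta

#' @export
vcov.ar1_lmm <- function(object, ...) object$vcov_beta

#' @export
nobs.ar1_lmm <- function(object, ...) object$n
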