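# Brute-force dense multivariate-normal log-likelihood for the AR1 +
# crossed-random-intercepts model, used to validate the structured
# (Woodbury) likelihood on small instances. Built directly from the
# marginal covariance: Sigma = sigma2 R(phi) + sigma2_id Zid Zid' +
# sigma2_type Zt Zt', with R assembled densely as phi^|i-j| per block.
dense_lmm_loglik <- function(y, X, beta, id, type = NULL, phi, sigma2,
                             sigma2_id = 0, sigma2_type = 0) {
  n <- length(y)
  id <- factor(id, levels = unique(as.character(id)))
  R <- matrix(0, n, n)
  pos <- 0
  for (nb in as.integer(table(id)[levels(id)])) {
    i <- pos + seq_len(nb)
    R[i, i] <- phi^abs(outer(seq_len(nb), seq_len(nb), "-"))
    pos <- pos + nb
  }
  Sigma <- sigma2 * R
  if (sigma2_id > 0) {
    Zi <- outer(id, levels(id), "==") * 1
    Sigma <- Sigma + sigma2_id * tcrossprod(Zi)
  }
  if (!is.null(type) && sigma2_type > 0) {
    type <- factor(type)
    Zt <- outer(type, levels(type), "==") * 1
    Sigma <- Sigma + sigma2_type * tcrossprod(Zt)
  }
  r <- y - X %*% beta
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (n * log(2 * pi) + ld + t(r) %*% solve(Sigma, r)))
}

# small simulated dataset from the model's own generative structure
simulate_lmm_data <- function(n_id = 4, n_per = 12, phi = 0.5,
                              sigma = 1, sd_id = 0.5, sd_type = 0.3,
                              beta = c(1, 0.5), seed = 1) {
  set.seed(seed)
  id <- rep(sprintf("i%02d", seq_len(n_id)), each = n_per)
  type <- rep_len(c("True", "Predicted"), n_id * n_per)
  x <- stats::rnorm(n_id * n_per)
  ar1 <- function(n) {
    e <- stats::rnorm(n, 0, sigma * sqrt(1 - phi^2))
    as.numeric(stats::filter(e, phi, method = "recursive",
      init = stats::rnorm(1, 0, sigma)))
  }
  eps <- unlist(lapply(seq_len(n_id), function(i) ar1(n_per)))
  b_id <- stats::rnorm(n_id, 0, sd_id)[as.integer(factor(id))]
  b_ty <- stats::rnorm(2, 0, sd_type)[as.integer(factor(type))]
  y <- beta[1] + beta[2] * x + b_id + b_ty + eps
  data.frame(individual_id = id, type = type, x = x, y = y,
    interval_end = rep(seq_len(n_per), n_id))
}
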