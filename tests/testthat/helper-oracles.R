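# Brute-force oracles, independent of the package's log-space code paths.

# PCM probabilities by direct summation of unnormalized terms
oracle_pcm_probs <- function(theta, tau) {
  K <- length(tau) + 1L
  un <- numeric(K)
  for (k in seq_len(K)) {
    ex <- 0
    if (k > 1) for (j in seq_len(k - 1)) ex <- ex + (theta - tau[j])
    un[k] <- exp(ex)
  }
  un / sum(un)
}

# extended PCM probabilities by direct evaluation
oracle_ext_probs <- function(theta, eta, tau, s) {
  K <- length(s)
  un <- numeric(K)
  for (k in seq_len(K)) {
    tsum <- if (k > 1) sum(tau[seq_len(k - 1)]) else 0
    un[k] <- exp((k - 1) * theta + s[k] * eta - tsum)
  }
  un / sum(un)
}

# Dense-grid marginal posterior for an intercept-only latent regression
# with known thresholds and no country residual: persons integrated out
# over a fine theta grid, intercept scanned over b0_grid.
oracle_grid_posterior_b0 <- function(Y, tau, b0_grid, beta_sd = 5,
                                     theta_grid = seq(-8, 8, by = 0.02)) {
  n_items <- ncol(Y)
  F <- matrix(1, nrow(Y), length(theta_grid)) # person x theta likelihood
  for (i in seq_len(n_items)) {
    P <- t(sapply(theta_grid, function(t) pcm_category_probs(t, tau[i, ])))
    obs <- !is.na(Y[, i])
    F[obs, ] <- F[obs, , drop = FALSE] * t(P[, Y[obs, i], drop = FALSE])
  }
  dt <- theta_grid[2] - theta_grid[1]
  W <- sapply(b0_grid, function(b0) dnorm(theta_grid, b0, 1) * dt)
  L <- F %*% W # person x b0 marginal likelihoods
  lp <- colSums(log(L)) + dnorm(b0_grid, 0, beta_sd, log = TRUE)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(mean = sum(b0_grid * w), weights = w)
}

# small long-format dataset builder
toy_dataset <- function(responses_by_person, countries_of_person,
                        K = 9, x = NULL) {
  n_p <- length(responses_by_person)
  I <- length(responses_by_person[[1]])
  long <- do.call(rbind, lapply(seq_len(n_p), function(p) {
    data.frame(
      person_id = sprintf("p%02d", p),
      country_id = countries_of_person[p],
      item_id = sprintf("i%02d", seq_len(I)),
      response = responses_by_person[[p]],
      stringsAsFactors = FALSE
    )
  }))
  cts <- sort(unique(countries_of_person))
  if (is.null(x)) x <- seq_along(cts)
  covs <- data.frame(country_id = cts, hdi = x)
  response_dataset(long, covs, K)
}
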