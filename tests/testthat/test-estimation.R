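make_params <- function(ds, variant = "pcm", I, K, seed = 1) {
  set.seed(seed)
  G <- nrow(ds$countries)
  N <- nrow(ds$persons)
  tau <- matrix(rnorm(I * (K - 1)), I)
  tau <- tau - mean(tau)
  p <- list(
    beta = c(0.2, -0.1, 0.05), sigma_u = 0.4,
    mu_theta = rnorm(G), theta = rnorm(N), tau = tau
  )
  if (variant == "ext_pcm") {
    mu_eta <- rnorm(G)
    p$mu_eta <- mu_eta - mean(mu_eta)
    p$eta <- rnorm(N)
    p$sigma_eta <- 0.5
    p$sigma_mu_eta <- 0.4
  }
  p
}

test_that("log-posterior enforces the identification constraints by name", {
  ds <- toy_dataset(list(c(2L, 5L), c(7L, 1L), c(4L, 4L)),
    c("A", "B", "C"),
    K = 9
  )
  p <- make_params(ds, "pcm", I = 2, K = 9)
  p$tau <- p$tau + 1 # break the grand-sum constraint
  expect_error(log_posterior(p, ds), "grand sum of thresholds")

  pe <- make_params(ds, "ext_pcm", I = 2, K = 9)
  pe$mu_eta <- pe$mu_eta + 0.5
  expect_error(
    log_posterior(pe, ds, variant = "ext_pcm"), "ERS means must\\s+sum to 0"
  )

  # pcm variant refuses eta machinery
  p2 <- make_params(ds, "pcm", I = 2, K = 9)
  p2$eta <- rnorm(3)
  expect_error(log_posterior(p2, ds), "does not accept eta")
})

test_that("empty data leaves prior plus hierarchy; one cell adds its log-prob", {
  ds_na <- toy_dataset(list(c(NA, NA), c(NA, NA)), c("A", "B"), K = 9,
    x = c(0.3, 0.9))
  ds_one <- ds_na
  ds_one$responses$response[1] <- 4L
  p <- make_params(ds_na, "pcm", I = 2, K = 9)
  lp0 <- log_posterior(p, ds_na)
  lp1 <- log_posterior(p, ds_one)
  cell <- log(pcm_category_probs(p$theta[1], p$tau[1, ])[4])
  expect_equal(lp1 - lp0, cell, tolerance = 1e-10)

  # lp0 equals the directly assembled prior + hierarchy terms
  x <- ds_na$countries$x
  m <- p$beta[1] + p$beta[2] * x + p$beta[3] * x^2
  manual <- sum(dnorm(p$theta, p$mu_theta[ds_na$persons$country_index], 1,
    log = TRUE
  )) +
    sum(dnorm(p$mu_theta, m, p$sigma_u, log = TRUE)) +
    sum(dnorm(p$tau, 0, 3, log = TRUE)) +
    sum(dnorm(p$beta, 0, 5, log = TRUE)) +
    log(2) + dnorm(p$sigma_u, 0, 2.5, log = TRUE)
  expect_equal(lp0, manual, tolerance = 1e-10)
})

test_that("fits are deterministic given data, seed and config", {
  d <- simulation_design(G = 4, n_g = 15, I = 2, K = 5, seed = 19)
  sim <- simulate_dataset(d)
  f1 <- suppressWarnings(
    fit_model(sim$data, "pcm", chains = 2, warmup = 50, sampling = 50,
      seed = 42)
  )
  f2 <- suppressWarnings(
    fit_model(sim$data, "pcm", chains = 2, warmup = 50, sampling = 50,
      seed = 42)
  )
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(
    fit_model(sim$data, "pcm", chains = 2, warmup = 50, sampling = 50,
      seed = 43)
  )
  expect_false(identical(f1$draws, f3$draws))
})

test_that("every stored draw satisfies the identification constraints", {
  d <- simulation_design(G = 4, n_g = 15, I = 2, K = 5, seed = 23)
  sim <- simulate_dataset(d)
  fit <- suppressWarnings(
    fit_model(sim$data, "ext_pcm", chains = 2, warmup = 100, sampling = 100,
      seed = 3)
  )
  pn <- dimnames(fit$draws)[[3]]
  tau_cols <- grep("^tau\\[", pn, value = TRUE)
  mu_eta_cols <- grep("^mu_eta\\[", pn, value = TRUE)
  tau_sums <- apply(fit$draws[, , tau_cols], c(1, 2), sum)
  mu_eta_sums <- apply(fit$draws[, , mu_eta_cols], c(1, 2), sum)
  expect_lt(max(abs(tau_sums)), 1e-8)
  expect_lt(max(abs(mu_eta_sums)), 1e-8)
})

test_that("the extended variant refuses a two-category scale", {
  long <- expand.grid(
    person_id = sprintf("p%02d", 1:8), item_id = c("i1", "i2"),
    stringsAsFactors = FALSE
  )
  long$country_id <- rep(c("A", "B"), each = 4)
  set.seed(4)
  long$response <- sample(1:2, nrow(long), replace = TRUE)
  covs <- data.frame(country_id = c("A", "B"), hdi = c(0.5, 0.8))
  ds <- response_dataset(long, covs, K = 2)
  expect_error(
    fit_model(ds, "ext_pcm", chains = 2, warmup = 10, sampling = 10,
      degree = 0),
    "unidentified"
  )
})

test_that("standardized coefficients match the per-draw ratio by hand", {
  d <- simulation_design(G = 5, n_g = 10, I = 2, K = 5, seed = 29)
  sim <- simulate_dataset(d)
  fit <- suppressWarnings(
    fit_model(sim$data, "pcm", chains = 2, warmup = 50, sampling = 25,
      seed = 8)
  )
  std <- standardized_coefficients(fit)
  x <- fit$countries$x
  pn <- dimnames(fit$draws)[[3]]
  mu_cols <- grep("^mu_theta\\[", pn, value = TRUE)
  # check the first pooled draw by direct formula
  mu1 <- sapply(mu_cols, function(cn) fit$draws[1, 1, cn])
  b1 <- fit$draws[1, 1, "beta1"]
  b2 <- fit$draws[1, 1, "beta2"]
  expect_equal(std$draws$beta1_std[1], b1 * sd(x) / sd(mu1),
    tolerance = 1e-12
  )
  expect_equal(std$draws$beta2_std[1], b2 * sd(x^2) / sd(mu1),
    tolerance = 1e-12
  )
  # beta1 = 0 in every draw implies beta1* = 0
  fit0 <- fit
  fit0$draws[, , "beta1"] <- 0
  expect_true(all(standardized_coefficients(fit0)$draws$beta1_std == 0))
  # doubling all country means halves the standardized coefficients
  fit2 <- fit
  for (cn in mu_cols) fit2$draws[, , cn] <- 2 * fit$draws[, , cn]
  expect_equal(standardized_coefficients(fit2)$draws$beta2_std,
    std$draws$beta2_std / 2,
    tolerance = 1e-12
  )
})
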