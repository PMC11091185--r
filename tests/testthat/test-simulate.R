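test_that("covariate generation standardizes exactly and is reproducible", {
  x <- generate_covariate(40, seed = 9)
  expect_lt(abs(mean(x)), 1e-12)
  expect_lt(abs(sd(x) - 1), 1e-12)
  expect_identical(x, generate_covariate(40, seed = 9))
  # two standardized points are +/- the same magnitude 1/sqrt(2)
  # (sample SD with denominator G - 1 equal to 1)
  x2 <- generate_covariate(2, seed = 1)
  expect_equal(sum(x2), 0)
  expect_equal(abs(x2), rep(1 / sqrt(2), 2))
  expect_error(generate_covariate(1), "at least 2")
})

test_that("simulation is seed-deterministic and emits full ground truth", {
  d <- simulation_design(G = 4, n_g = 10, I = 3, K = 9, seed = 77)
  s1 <- simulate_dataset(d)
  s2 <- simulate_dataset(d)
  expect_identical(s1$data$responses, s2$data$responses)
  expect_identical(s1$truth$theta, s2$truth$theta)
  tr <- s1$truth
  expect_length(tr$theta, 40)
  expect_length(tr$eta, 40)
  expect_length(tr$mu_theta, 4)
  expect_equal(dim(tr$tau), c(3, 8))
  expect_lt(abs(sum(tr$tau)), 1e-12) # grand-sum centered
})

test_that("ground truth reproduces every response probability (closure)", {
  d <- simulation_design(G = 3, n_g = 5, I = 2, K = 5, seed = 5)
  sim <- simulate_dataset(d)
  tr <- sim$truth
  s <- d$scale$s
  df <- sim$data$responses
  for (r in sample(nrow(df), 10)) {
    p <- sim$data$person_index[r]
    i <- sim$data$item_index[r]
    pr <- ext_pcm_category_probs(tr$theta[p], tr$eta[p], tr$tau[i, ], s)
    expect_true(pr[df$response[r]] > 0 && pr[df$response[r]] <= 1)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }
})

test_that("null configuration yields uniform category frequencies", {
  d <- simulation_design(G = 5, n_g = 50, I = 5, K = 9, seed = 123)
  truth <- true_parameters(d,
    sigma_u = 0, sigma_theta = 0, sigma_eta = 0,
    tau = matrix(0, 5, 8)
  )
  sim <- simulate_dataset(d, truth)
  n <- nrow(sim$data$responses) # 1250 draws
  freq <- tabulate(sim$data$responses$response, 9)
  # binomial sampling band: +/- 3 SE around n/9
  se <- sqrt(n * (1 / 9) * (8 / 9))
  expect_true(all(abs(freq - n / 9) <= 3 * se))
})

test_that("large positive trait pushes every country to the top category", {
  d <- simulation_design(G = 3, n_g = 20, I = 2, K = 9, seed = 31)
  truth <- true_parameters(d,
    beta0 = 10, sigma_u = 0, sigma_theta = 0, sigma_eta = 0,
    tau = matrix(0, 2, 8)
  )
  sim <- simulate_dataset(d, truth)
  tab <- table(sim$data$responses$country_id,
    factor(sim$data$responses$response, levels = 1:9))
  modal <- apply(tab, 1, which.max)
  expect_true(all(modal == 9))
})

test_that("empirical frequencies converge to model probabilities", {
  # one parameter point, ~1e5 cells
  d <- simulation_design(G = 2, n_g = 6250, I = 8, K = 9, seed = 99)
  tau <- matrix(rep(c(-1.5, -1, -0.5, -0.2, 0.2, 0.5, 1, 1.5), 8),
    nrow = 8, byrow = TRUE
  )
  tau <- tau - mean(tau)
  truth <- true_parameters(d,
    beta0 = 0.5, sigma_u = 0, sigma_theta = 0, sigma_eta = 0, tau = tau
  )
  sim <- simulate_dataset(d, truth)
  expected <- ext_pcm_category_probs(0.5, 0, tau[1, ], d$scale$s)
  freq <- tabulate(sim$data$responses$response, 9) /
    nrow(sim$data$responses)
  expect_lt(max(abs(freq - expected)), 0.01)
})

test_that("confound scenario carries the covariate signal in ERS means only", {
  d <- simulation_design(G = 30, n_g = 200, I = 8, K = 9, seed = 13)
  sim <- confound_scenario(d, gamma2 = 0.75)
  tr <- sim$truth
  expect_identical(tr$beta1, 0)
  expect_identical(tr$beta2, 0)
  expect_lt(abs(sum(tr$mu_eta)), 1e-10)
  expect_equal(tr$mu_eta, 0.75 * (tr$x^2 - mean(tr$x^2)), tolerance = 1e-12)

  # with gamma2 > 0, observed extreme-response share rises with x^2
  df <- sim$data$responses
  extreme <- df$response %in% c(1, 2, 8, 9)
  share <- tapply(extreme, df$country_id, mean)
  share <- share[sim$data$countries$country_id]
  r_obs <- cor(rank(share), rank(sim$data$countries$x^2))
  expect_gt(r_obs, 0)
  # bootstrap lower confidence bound above zero
  set.seed(1)
  boot <- replicate(500, {
    idx <- sample(length(share), replace = TRUE)
    suppressWarnings(cor(rank(share[idx]), rank(sim$data$countries$x[idx]^2)))
  })
  expect_gt(quantile(boot, 0.025, na.rm = TRUE), 0)
})

test_that("gamma2 = 0 reduces the confound scenario to a null dataset", {
  d <- simulation_design(G = 6, n_g = 10, I = 2, K = 9, seed = 3)
  sim <- confound_scenario(d, gamma2 = 0)
  expect_true(all(sim$truth$mu_eta == 0))
  expect_identical(sim$truth$beta2, 0)
})

test_that("scale-usage presets move category mass as illustrated", {
  expect_identical(fig1_presets("A")$mu_eta, 0)
  expect_identical(fig1_presets("B")$mu_eta, -1)
  expect_identical(fig1_presets("C")$mu_eta, 1)
  expect_error(fig1_presets("D"))

  s <- ers_scoring_weights(9)
  tau <- seq(-2, 2, length.out = 8)
  p_a <- ext_pcm_category_probs(0.5, fig1_presets("A")$mu_eta, tau, s)
  p_b <- ext_pcm_category_probs(0.5, fig1_presets("B")$mu_eta, tau, s)
  p_c <- ext_pcm_category_probs(0.5, fig1_presets("C")$mu_eta, tau, s)
  mid <- 4:6
  out <- c(1, 2, 8, 9)
  expect_gt(sum(p_b[mid]), sum(p_a[mid]))
  expect_gt(sum(p_c[out]), sum(p_a[out]))
})

test_that("simulated datasets round-trip through the sidecar files", {
  d <- simulation_design(G = 3, n_g = 4, I = 2, K = 9, seed = 8)
  sim <- simulate_dataset(d)
  dir <- tempfile("simout")
  paths <- write_simulated(sim, dir, prefix = "toy")
  expect_true(all(file.exists(paths)))
  ds <- read_and_validate(paths["responses"], paths["covariates"],
    K = 9, quiet = TRUE
  )
  expect_equal(nrow(ds$responses), nrow(sim$data$responses))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$beta2, sim$truth$beta2)
  expect_equal(
    matrix(truth$tau, truth$tau_dim[1], truth$tau_dim[2]),
    sim$truth$tau,
    tolerance = 1e-12
  )
})
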