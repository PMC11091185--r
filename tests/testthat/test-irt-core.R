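test_that("PCM probabilities match direct summation on worked examples", {
  expect_equal(pcm_category_probs(0, rep(0, 8)), rep(1 / 9, 9))
  expect_equal(pcm_category_probs(0, 0), c(0.5, 0.5))
  p <- pcm_category_probs(0, c(-1, 1))
  expect_equal(round(p, 4), c(0.2119, 0.5761, 0.2119))
  expect_equal(p, oracle_pcm_probs(0, c(-1, 1)), tolerance = 1e-12)
})

test_that("PCM probabilities match the brute-force oracle at random draws", {
  set.seed(401)
  for (r in 1:50) {
    K <- sample(3:9, 1)
    theta <- rnorm(1, sd = 2)
    tau <- rnorm(K - 1, sd = 2)
    expect_equal(pcm_category_probs(theta, tau),
      oracle_pcm_probs(theta, tau),
      tolerance = 1e-10
    )
  }
})

test_that("extended PCM matches its oracle and reduces to PCM at eta 0", {
  expect_equal(
    ext_pcm_category_probs(0, log(2), c(0, 0), c(1, 0, 1)),
    c(0.4, 0.2, 0.4)
  )
  set.seed(402)
  for (r in 1:50) {
    K <- sample(3:9, 1)
    s <- ers_scoring_weights(K)
    theta <- rnorm(1, sd = 2)
    eta <- rnorm(1)
    tau <- rnorm(K - 1, sd = 2)
    expect_equal(ext_pcm_category_probs(theta, eta, tau, s),
      oracle_ext_probs(theta, eta, tau, s),
      tolerance = 1e-10
    )
    expect_equal(ext_pcm_category_probs(theta, 0, tau, s),
      pcm_category_probs(theta, tau),
      tolerance = 1e-14
    )
  }
})

test_that("symmetric thresholds give palindromic probabilities at theta 0", {
  s <- ers_scoring_weights(9)
  tau <- c(-1.2, -0.8, -0.5, -0.1, 0.1, 0.5, 0.8, 1.2)
  for (eta in c(-1, 0, 0.7)) {
    p <- ext_pcm_category_probs(0, eta, tau, s)
    expect_equal(p, rev(p), tolerance = 1e-12)
  }
})

test_that("threshold-shift form is the scoring-weight form exactly", {
  s <- ers_scoring_weights(9)
  expect_equal(shifted_thresholds(rep(0, 8), 1, s),
    c(1, 1, 1, 1, -1, -1, -1, -1))
  expect_equal(shifted_thresholds(1:8 / 10, 0, s), 1:8 / 10)
  set.seed(403)
  worst <- 0
  for (r in 1:1000) {
    K <- sample(c(3, 4, 5, 7, 9), 1)
    s_r <- ers_scoring_weights(K)
    theta <- rnorm(1, sd = 3)
    eta <- rnorm(1, sd = 2)
    tau <- rnorm(K - 1, sd = 3)
    a <- ext_pcm_category_probs(theta, eta, tau, s_r)
    b <- pcm_category_probs(theta, shifted_thresholds(tau, eta, s_r))
    worst <- max(worst, max(abs(a - b)))
  }
  expect_lt(worst, 1e-12)
})

test_that("probability vectors are normalized, positive, and stable to |30|", {
  set.seed(404)
  s <- ers_scoring_weights(9)
  for (r in 1:200) {
    theta <- runif(1, -30, 30)
    eta <- runif(1, -30, 30)
    tau <- runif(8, -30, 30)
    p <- ext_pcm_category_probs(theta, eta, tau, s)
    expect_true(all(is.finite(p)))
    expect_true(all(p > 0))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("expected category is strictly increasing in theta", {
  s <- ers_scoring_weights(9)
  tau <- c(-2, -1.5, -0.5, 0, 0.2, 0.7, 1.4, 2.1)
  thetas <- seq(-4, 4, by = 0.5)
  for (eta in c(-0.5, 0, 1)) {
    ev <- sapply(thetas, function(th) {
      sum(seq_len(9) * ext_pcm_category_probs(th, eta, tau, s))
    })
    expect_true(all(diff(ev) > 0))
  }
})

test_that("extreme-category mass is strictly increasing in eta at the center", {
  s <- ers_scoring_weights(9)
  tau <- c(-1.2, -0.8, -0.5, -0.1, 0.1, 0.5, 0.8, 1.2)
  etas <- seq(-2, 2, by = 0.25)
  pex <- sapply(etas, function(e) {
    p <- ext_pcm_category_probs(0, e, tau, s)
    p[1] + p[9]
  })
  expect_true(all(diff(pex) > 0))
})

test_that("joint log-likelihood sums cell log-probabilities and skips NA", {
  # single person, single item, flat thresholds: every category has p 1/9
  ds <- toy_dataset(list(c(5L), c(NA)), c("A", "B"), K = 9)
  ll <- response_loglik(ds, theta = c(0, 0), tau = matrix(0, 1, 8))
  expect_equal(ll, log(1 / 9))

  # all-missing dataset contributes zero
  ds_na <- toy_dataset(list(c(NA, NA), c(NA, NA)), c("A", "B"), K = 3)
  expect_identical(
    response_loglik(ds_na, theta = c(1, -1), tau = matrix(0.3, 2, 2)), 0
  )

  # 2 persons x 2 items against cell-by-cell oracle, both variants
  ds2 <- toy_dataset(list(c(1L, 3L), c(2L, 3L)), c("A", "B"), K = 3)
  tau <- matrix(c(-0.4, 0.2, 0.5, -0.1), 2, 2, byrow = TRUE)
  theta <- c(0.3, -0.6)
  eta <- c(0.2, -0.4)
  s <- ers_scoring_weights(3)
  y <- matrix(c(1, 3, 2, 3), 2, 2, byrow = TRUE)
  expected_pcm <- 0
  expected_ext <- 0
  for (p in 1:2) {
    for (i in 1:2) {
      expected_pcm <- expected_pcm +
        log(oracle_pcm_probs(theta[p], tau[i, ])[y[p, i]])
      expected_ext <- expected_ext +
        log(oracle_ext_probs(theta[p], eta[p], tau[i, ], s)[y[p, i]])
    }
  }
  expect_equal(response_loglik(ds2, theta, tau), expected_pcm,
    tolerance = 1e-10
  )
  expect_equal(
    response_loglik(ds2, theta, tau, variant = "ext_pcm", eta = eta),
    expected_ext,
    tolerance = 1e-10
  )
})

test_that("out-of-range responses are rejected with the offending cell named", {
  ds <- toy_dataset(list(c(2L, 3L), c(NA, NA)), c("A", "B"), K = 3)
  ds$responses$response[2] <- 9L # corrupt after validation
  expect_error(
    response_loglik(ds, theta = c(0, 0), tau = matrix(0, 2, 2)),
    "outside 1..3.*p01.*i02"
  )
})

test_that("non-finite inputs are rejected", {
  expect_error(pcm_category_probs(Inf, c(0, 0)), "finite")
  expect_error(pcm_category_probs(0, c(NA, 0)), "finite")
  expect_error(ext_pcm_category_probs(0, NaN, c(0, 0), c(1, 0, 1)), "finite")
  expect_error(
    ext_pcm_category_probs(0, 0, c(0, 0), c(1, 0, 1, 1)), "length K"
  )
})
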