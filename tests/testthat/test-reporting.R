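small_fit <- function(variant = "pcm", seed = 17) {
  d <- simulation_design(G = 4, n_g = 15, I = 2, K = 5, seed = 37)
  sim <- simulate_dataset(d)
  suppressWarnings(
    fit_model(sim$data, variant, chains = 2, warmup = 100, sampling = 100,
      seed = seed)
  )
}

test_that("summary rows reproduce the credibility-interval op exactly", {
  fit <- small_fit()
  tab <- summarize_fit(fit, c("beta0", "beta2", "sigma_u"))
  for (r in seq_len(nrow(tab))) {
    d <- extract_draws(fit, tab$parameter[r])
    ci <- credibility_interval(d)
    expect_identical(tab$lo[r], ci[["lo"]])
    expect_identical(tab$hi[r], ci[["hi"]])
    expect_identical(tab$mean[r], mean(d))
  }
  expect_error(summarize_fit(fit, "nonexistent"), "unknown parameter")
})

test_that("constant draws summarize to a point interval", {
  fit <- small_fit()
  fit$draws[, , "beta1"] <- 0.25
  tab <- summarize_fit(fit, "beta1")
  expect_equal(tab$mean, 0.25)
  expect_equal(tab$lo, 0.25)
  expect_equal(tab$hi, 0.25)
})

test_that("verdict logic is a pure function of the interval flags", {
  expect_identical(
    sensitivity_verdict(c(-0.10, -0.02), c(-0.10, 0.01)),
    "adjustment-sensitive"
  )
  expect_identical(
    sensitivity_verdict(c(-0.10, -0.02), c(-0.09, -0.01)),
    "not adjustment-sensitive"
  )
  expect_identical(
    sensitivity_verdict(c(-0.05, 0.05), c(-0.04, 0.06)),
    "not adjustment-sensitive"
  )
  expect_identical(
    sensitivity_verdict(c(-0.05, 0.05), c(0.01, 0.06)),
    "adjustment-sensitive"
  )
})

test_that("identical fits compare as not adjustment-sensitive", {
  fit <- small_fit()
  fit$converged <- TRUE
  rep <- compare_variants(fit, fit)
  expect_identical(rep$verdict, "not adjustment-sensitive")
  expect_equal(nrow(rep$table), 4)
})

test_that("comparison refuses non-converged fits with a diagnostic listing", {
  fit <- small_fit()
  bad <- fit
  bad$converged <- FALSE
  bad$diagnostics$rhat[1] <- 1.2
  fit$converged <- TRUE
  expect_error(compare_variants(bad, fit), "non-converged.*rhat")
})

test_that("plot data export matches the polynomial and the draws", {
  fit <- small_fit()
  fit$converged <- TRUE
  pd <- export_plot_data(fit, n_curves = 10, seed = 5)
  expect_equal(nrow(pd$country_means), 4)
  expect_equal(max(pd$curves$draw), 10)
  # curve values at x = 0 equal the sampled beta0 draws
  b0 <- as.vector(fit$draws[, , "beta0"])[pd$draw_indices]
  at0 <- pd$curves$value[abs(pd$curves$x) < 1e-12]
  if (length(at0)) expect_equal(at0, b0, tolerance = 1e-12)
  # hand-evaluate the quadratic for the first sampled draw
  i1 <- pd$draw_indices[1]
  b <- sapply(paste0("beta", 0:2), function(p) as.vector(fit$draws[, , p])[i1])
  g <- pd$grid
  expect_equal(
    pd$curves$value[pd$curves$draw == 1],
    b[1] + b[2] * g + b[3] * g^2,
    tolerance = 1e-12
  )
  # degenerate and error paths
  pd0 <- export_plot_data(fit, n_curves = 0)
  expect_null(pd0$curves)
  expect_error(export_plot_data(fit, n_curves = 1e6), "exceeds")
})

test_that("default curve count is 50 posterior draws", {
  fit <- small_fit()
  fit$converged <- TRUE
  pd <- export_plot_data(fit, seed = 2)
  expect_equal(pd$n_curves, 50)
  expect_equal(length(unique(pd$curves$draw)), 50)
})

test_that("reports and draws round-trip through serialization", {
  fit <- small_fit()
  fit$converged <- TRUE
  dp <- tempfile(fileext = ".csv")
  sp <- tempfile(fileext = ".json")
  write_fit(fit, dp, sp)
  dr <- utils::read.csv(dp, check.names = FALSE)
  # report numbers are reproducible from the draws file alone
  expect_equal(mean(dr[["beta2"]]), mean(extract_draws(fit, "beta2")),
    tolerance = 1e-12
  )
  ci_file <- credibility_interval(dr[["beta2"]])
  ci_fit <- credibility_interval(extract_draws(fit, "beta2"))
  expect_equal(ci_file, ci_fit, tolerance = 1e-12)
  js <- jsonlite::read_json(sp, simplifyVector = TRUE)
  expect_identical(js$variant, "pcm_multigroup")

  md <- render_report_md(compare_variants(fit, fit))
  expect_match(md, "not adjustment-sensitive")
})
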