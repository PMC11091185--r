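#' Simulation design for hierarchical rating-scale data
#'
#' Describes the sampling frame the generator emulates: persons nested
#' in countries, each answering the same set of ordinal items. Defaults
#' mirror a multi-country survey on a nine-point scale with 45
#' countries.
#'
#' @param G number of countries (>= 2).
#' @param n_g persons per country (>= 1).
#' @param I number of items (>= 1).
#' @param K category count of the rating scale.
#' @param scale optional [rating_scale()]; defaults to graded weights.
#' @param seed integer RNG seed driving every random quantity of the
#'   simulation.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(G = 45, n_g = 100, I = 8, K = 9,
                              scale = NULL, seed = 1) {
  stopifnot(G >= 2, n_g >= 1, I >= 1)
  if (is.null(scale)) scale <- rating_scale(K)
  stopifnot(inherits(scale, "rating_scale"), scale$K == K)
  structure(
    list(
      G = as.integer(G), n_g = as.integer(n_g), I = as.integer(I),
      K = as.integer(K), scale = scale, seed = as.integer(seed)
    ),
    class = "simulation_design"
  )
}

#' Standardized country-level covariate
#'
#' Draws `G` values from a standard normal and standardizes them to
#' sample mean 0 and sample SD 1 exactly (SD with denominator `G - 1`),
#' emulating a standardized country covariate such as the HDI.
#'
#' @param G number of countries (>= 2).
#' @param seed integer RNG seed.
#' @return numeric vector of length `G` with mean 0 and SD 1.
#' @export
generate_covariate <- function(G, seed = 1) {
  if (G < 2) stop("G must be at least 2 (SD undefined otherwise).",
    call. = FALSE
  )
  set.seed(seed)
  x <- stats::rnorm(G)
  as.numeric((x - mean(x)) / stats::sd(x))
}

#' Ground-truth parameters for the generative model
#'
#' Country trait means follow a quadratic latent regression on the
#' standardized covariate, `mu_theta_g = beta0 + beta1 x_g + beta2 x_g^2
#' + u_g` with `u_g ~ N(0, sigma_u^2)`. Persons draw their target trait
#' `theta` and ERS trait `eta` from country-specific normals; the
#' within-country trait SD is fixed at 1 for identification. Item
#' thresholds are standard-normal draws centered so their grand sum is
#' zero, matching the estimation module's identification constraint.
#'
#' Within-country SDs are homogeneous across countries by default; pass
#' vectors of length `G` to `sigma_theta`/`sigma_eta` for heterogeneous
#' variants.
#'
#' @param design a [simulation_design()].
#' @param beta0,beta1,beta2 latent-regression coefficients.
#' @param sigma_u country residual SD.
#' @param sigma_theta,sigma_eta within-country SDs (scalar or length G).
#' @param mu_eta country ERS means, scalar (recycled) or length `G`.
#' @param x standardized covariate of length `G`; drawn via
#'   [generate_covariate()] when `NULL`.
#' @param tau `I x (K-1)` threshold matrix; drawn when `NULL`.
#' @return an object of class `true_parameters`.
#' @export
true_parameters <- function(design, beta0 = 0, beta1 = 0, beta2 = 0,
                            sigma_u = 0.3, sigma_theta = 1,
                            sigma_eta = 0.5, mu_eta = 0, x = NULL,
                            tau = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  G <- design$G
  if (any(c(sigma_u, sigma_theta, sigma_eta) < 0)) {
    stop("SDs must be non-negative.", call. = FALSE)
  }
  if (length(mu_eta) == 1L) mu_eta <- rep(mu_eta, G)
  if (length(mu_eta) != G) {
    stop("`mu_eta` must be scalar or length G.", call. = FALSE)
  }
  if (!is.null(x)) {
    if (length(x) != G) stop("`x` must have length G.", call. = FALSE)
    if (abs(mean(x)) > 1e-8 || abs(stats::sd(x) - 1) > 1e-8) {
      stop("`x` must be standardized (mean 0, SD 1).", call. = FALSE)
    }
  }
  if (!is.null(tau)) {
    tau <- as.matrix(tau)
    if (nrow(tau) != design$I || ncol(tau) != design$K - 1L) {
      stop("`tau` must be I x (K-1).", call. = FALSE)
    }
  }
  structure(
    list(
      beta0 = beta0, beta1 = beta1, beta2 = beta2, sigma_u = sigma_u,
      sigma_theta = rep(sigma_theta, length.out = G),
      sigma_eta = rep(sigma_eta, length.out = G),
      mu_eta = as.numeric(mu_eta), x = x, tau = tau
    ),
    class = "true_parameters"
  )
}

#' Simulate a response dataset with full ground truth
#'
#' Forward-simulates the hierarchical generative model: covariate,
#' country means, person traits, and categorical responses drawn from
#' the ERS-extended PCM ([ext_pcm_category_probs()]). Every generated
#' latent quantity is returned so that each response probability used in
#' generation can be recomputed from the output alone.
#'
#' @param design a [simulation_design()].
#' @param truth a [true_parameters()]; defaults to the null configuration.
#' @return a list of class `simulated_dataset` with components `data`
#'   (a [response_dataset()]) and `truth` (the input parameters extended
#'   by the realized `x`, `tau`, `u`, `mu_theta`, `theta`, `eta`).
#' @export
simulate_dataset <- function(design, truth = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (is.null(truth)) truth <- true_parameters(design)
  stopifnot(inherits(truth, "true_parameters"))
  G <- design$G
  n_g <- design$n_g
  I <- design$I
  K <- design$K
  s <- design$scale$s
  if (length(truth$mu_eta) != G) {
    stop("`truth$mu_eta` must have length G.", call. = FALSE)
  }
  set.seed(design$seed)
  x <- truth$x
  if (is.null(x)) {
    x <- stats::rnorm(G)
    x <- (x - mean(x)) / stats::sd(x)
  }
  tau <- truth$tau
  if (is.null(tau)) {
    tau <- matrix(stats::rnorm(I * (K - 1L)), nrow = I)
    tau <- tau - mean(tau) # grand sum zero, matching estimation
  }
  u <- stats::rnorm(G, 0, truth$sigma_u)
  mu_theta <- truth$beta0 + truth$beta1 * x + truth$beta2 * x^2 + u
  N <- G * n_g
  country_of <- rep(seq_len(G), each = n_g)
  theta <- stats::rnorm(N, mu_theta[country_of],
    truth$sigma_theta[country_of])
  eta <- stats::rnorm(N, truth$mu_eta[country_of],
    truth$sigma_eta[country_of])

  wid <- max(5L, nchar(as.character(N)))
  person_id <- sprintf("p%0*d", wid, seq_len(N))
  country_id <- sprintf("c%03d", seq_len(G))
  item_id <- sprintf("i%02d", seq_len(I))

  responses <- matrix(NA_integer_, nrow = N, ncol = I)
  cats <- seq_len(K)
  for (p in seq_len(N)) {
    for (i in seq_len(I)) {
      pr <- ext_pcm_category_probs(theta[p], eta[p], tau[i, ], s)
      responses[p, i] <- sample(cats, 1L, prob = pr)
    }
  }
  long <- data.frame(
    person_id = rep(person_id, times = I),
    country_id = rep(country_id[country_of], times = I),
    item_id = rep(item_id, each = N),
    response = as.integer(responses),
    stringsAsFactors = FALSE
  )
  covariates <- data.frame(country_id = country_id, x = x)
  data <- response_dataset(long, covariates, K)

  truth$x <- x
  truth$tau <- tau
  truth$u <- u
  truth$mu_theta <- mu_theta
  truth$theta <- theta
  truth$eta <- eta
  truth$country_of <- country_of
  structure(list(data = data, truth = truth, design = design),
    class = "simulated_dataset"
  )
}

#' Spurious-quadratic confound scenario
#'
#' Builds the confounding mechanism in which response-style differences
#' masquerade as a substantive country-level effect: the true
#' trait-covariate relationship is null (`beta1 = beta2 = 0`), but
#' country ERS means carry the quadratic covariate signal,
#' `mu_eta_g = gamma2 * (x_g^2 - mean(x^2))`. Because the trait
#' distribution sits off-center on the scale (`beta0` defaults to 1),
#' country differences in extreme responding shift observed country
#' means, so an unadjusted PCM attributes the quadratic pattern to the
#' trait itself while the ERS-adjusted model does not.
#'
#' @param design a [simulation_design()].
#' @param gamma2 strength of the quadratic covariate signal in the
#'   country ERS means. Negative values give mid-covariate countries the
#'   stronger extreme response style, producing an apparent inverted-U.
#' @param beta0 trait grand mean; off-center by default so that ERS
#'   differences move observed means.
#' @param sigma_u country residual SD around the (null) regression.
#' @return a `simulated_dataset`; its ground truth records
#'   `beta2 = 0` and the injected `mu_eta`.
#' @export
confound_scenario <- function(design, gamma2 = -0.75, beta0 = 1,
                              sigma_u = 0.2) {
  stopifnot(inherits(design, "simulation_design"))
  check_finite_scalar(gamma2, "gamma2")
  x <- generate_covariate(design$G, seed = design$seed)
  mu_eta <- gamma2 * (x^2 - mean(x^2))
  truth <- true_parameters(design,
    beta0 = beta0, beta1 = 0, beta2 = 0,
    sigma_u = sigma_u, mu_eta = mu_eta, x = x
  )
  out <- simulate_dataset(design, truth)
  out$truth$gamma2 <- gamma2
  out
}

#' Scale-usage scenario presets
#'
#' Three stylized country scenarios on a nine-point scale: a baseline
#' country with average scale usage (`A`), a country preferring the
#' medium categories (`B`, negative ERS mean widening the middle
#' intervals), and a country preferring the extreme categories (`C`,
#' positive ERS mean widening the outermost intervals).
#'
#' @param case `"A"`, `"B"`, or `"C"`.
#' @return a template list with the scenario's country ERS mean
#'   (`mu_eta`) and a description; feed `mu_eta` to
#'   [true_parameters()].
#' @export
fig1_presets <- function(case = c("A", "B", "C")) {
  case <- match.arg(case)
  mu_eta <- switch(case, A = 0, B = -1, C = 1)
  desc <- switch(case,
    A = "baseline scale usage",
    B = "middle-category preference (wide medium intervals)",
    C = "extreme-category preference (wide outer intervals)"
  )
  list(case = case, mu_eta = mu_eta, description = desc)
}

#' Write a simulated dataset with its ground-truth sidecar
#'
#' Writes the long-format response CSV, the covariate CSV, and a
#' ground-truth sidecar (JSON) sufficient to recompute every response
#' probability used during generation.
#'
#' @param sim a `simulated_dataset` from [simulate_dataset()] or
#'   [confound_scenario()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the written paths.
#' @export
write_simulated <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "simulated_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rp <- file.path(dir, paste0(prefix, "_responses.csv"))
  cp <- file.path(dir, paste0(prefix, "_covariates.csv"))
  tp <- file.path(dir, paste0(prefix, "_truth.json"))
  write_dataset(sim$data, rp, cp)
  truth <- unclass(sim$truth)
  truth$tau <- as.vector(truth$tau)
  truth$tau_dim <- c(sim$design$I, sim$design$K - 1L)
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(responses = rp, covariates = cp, truth = tp))
}
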