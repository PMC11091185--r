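#' Split-chain potential scale reduction (R-hat)
#'
#' Classic between/within variance diagnostic computed on split chains:
#' each chain is halved, doubling the number of chains, so that
#' within-chain trends register as between-chain disagreement. Values
#' near 1 indicate the chains have mixed; fits are flagged when any
#' monitored parameter exceeds 1.01.
#'
#' Chains that are all constant and identical have zero variance both
#' between and within; the statistic is defined as 1 in that case.
#'
#' @param draws iterations-by-chains numeric matrix for one parameter.
#' @return the split R-hat value.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) {
    stop("split R-hat requires at least 2 chains.", call. = FALSE)
  }
  if (nrow(draws) < 4L) {
    stop("split R-hat requires at least 4 iterations per chain.",
      call. = FALSE
    )
  }
  sp <- split_chains(draws)
  n <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) {
    if (B == 0) return(1)
    return(Inf)
  }
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

split_chains <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  # drop the middle iteration when n is odd
  lower <- draws[seq_len(half), , drop = FALSE]
  upper <- draws[seq.int(n - half + 1L, n), , drop = FALSE]
  cbind(lower, upper)
}

#' Bulk effective sample size
#'
#' Effective sample size of the rank-normalized split chains, using the
#' multi-chain autocorrelation estimate with Geyer's initial monotone
#' positive sequence truncation. Measures how many independent draws
#' the correlated chains are worth for bulk summaries such as posterior
#' means and central intervals.
#'
#' @param draws iterations-by-chains numeric matrix for one parameter.
#' @return the effective sample size (capped at the total draw count).
#' @export
ess_bulk <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 4L) {
    stop("ESS requires at least 4 iterations per chain.", call. = FALSE)
  }
  sp <- split_chains(draws)
  z <- rank_normalize(sp)
  ess_mean(z)
}

rank_normalize <- function(draws) {
  r <- rank(as.vector(draws), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(draws))
}

ess_mean <- function(draws) {
  n <- nrow(draws)
  m <- ncol(draws)
  vars <- apply(draws, 2L, stats::var)
  W <- mean(vars)
  means <- colMeans(draws)
  B_over_n <- if (m > 1L) stats::var(means) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  if (var_plus == 0) return(n * m)
  # chain-averaged autocovariances
  acov <- sapply(seq_len(m), function(j) {
    x <- draws[, j] - means[j]
    sapply(0:(n - 2L), function(t) {
      sum(x[seq_len(n - t)] * x[seq.int(t + 1L, n)]) / n
    })
  })
  acov <- as.matrix(acov)
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1L] <- 1
  # Geyer initial positive monotone sequence on paired sums
  # P_k = rho_{2k} + rho_{2k+1}, k = 0, 1, ... (1-based indexing below)
  max_pairs <- floor(length(rho) / 2)
  pair_sums <- numeric(0)
  for (k in seq_len(max_pairs)) {
    ps <- rho[2 * k - 1L] + rho[2 * k]
    if (ps <= 0) break
    pair_sums <- c(pair_sums, ps)
  }
  if (length(pair_sums)) pair_sums <- cummin(pair_sums)
  tau_hat <- -1 + 2 * sum(pair_sums)
  tau_hat <- max(tau_hat, 1 / (n * m)) # guard against antithetic chains
  min(n * m / tau_hat, n * m * log10(n * m))
}

#' Equal-tailed credibility interval
#'
#' Percentile interval at the requested level, pooled across chains,
#' using linear-interpolation percentiles (R's default `type = 7`
#' quantile convention).
#'
#' @param draws numeric vector or iterations-by-chains matrix.
#' @param level interval mass in (0, 1); default 0.95.
#' @return named numeric vector `c(lo, hi)`.
#' @examples
#' credibility_interval(1:100, 0.5) # c(25.75, 75.25)
#' @export
credibility_interval <- function(draws, level = 0.95) {
  if (length(level) != 1L || !is.finite(level) || level <= 0 ||
    level >= 1) {
    stop("`level` must be a single number in (0, 1).", call. = FALSE)
  }
  x <- as.vector(as.matrix(draws))
  if (length(x) < 2L) {
    stop("credibility interval requires at least 2 draws.", call. = FALSE)
  }
  a <- (1 - level) / 2
  q <- stats::quantile(x, probs = c(a, 1 - a), names = FALSE, type = 7)
  c(lo = q[1L], hi = q[2L])
}
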