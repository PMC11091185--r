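#' Partial Credit Model category probabilities
#'
#' Computes `P(Y = k)` for `k = 1..K` under the Partial Credit Model.
#' The cumulative exponent of category `k` is
#' `sum_{j<k} (theta - tau_j)`, with the empty sum for `k = 1` equal to
#' zero; probabilities are the softmax of these exponents, evaluated with
#' max-subtraction so that extreme values of `theta` or `tau` stay
#' finite and normalized.
#'
#' Thresholds need not be ordered: disordered thresholds are standard
#' PCM behavior and are passed through untouched.
#'
#' @param theta latent trait value (logit scale), a single finite number.
#' @param tau threshold vector of length `K - 1`, finite, logit scale.
#' @return probability vector of length `K` summing to 1.
#' @examples
#' pcm_category_probs(0, rep(0, 8)) # uniform over nine categories
#' pcm_category_probs(0, c(-1, 1))
#' @export
pcm_category_probs <- function(theta, tau) {
  check_finite_scalar(theta, "theta")
  check_finite_vector(tau, "tau")
  z <- c(0, cumsum(theta - tau))
  softmax(z)
}

#' Extended PCM category probabilities with an ERS dimension
#'
#' Category probabilities under the two-dimensional extension of the PCM
#' in which a person-level extreme-response-style value `eta` loads on
#' each category through scoring weights `s`:
#' `P(Y = k)` is proportional to
#' `exp((k - 1) * theta + s_k * eta - sum_{j<k} tau_j)`.
#' At `eta = 0` (or constant `s`) this reduces exactly to
#' [pcm_category_probs()].
#'
#' @param theta latent target-trait value.
#' @param eta latent ERS value; positive values favor the outer
#'   categories, negative values the middle ones.
#' @param tau threshold vector of length `K - 1`.
#' @param s ERS scoring weights of length `K` (see
#'   [ers_scoring_weights()]).
#' @return probability vector of length `K` summing to 1.
#' @examples
#' s <- ers_scoring_weights(9)
#' ext_pcm_category_probs(0, 1, rep(0, 8), s)
#' @export
ext_pcm_category_probs <- function(theta, eta, tau, s) {
  check_finite_scalar(theta, "theta")
  check_finite_scalar(eta, "eta")
  check_finite_vector(tau, "tau")
  check_finite_vector(s, "s")
  if (length(s) != length(tau) + 1L) {
    stop("`s` must have length K = length(tau) + 1.", call. = FALSE)
  }
  K <- length(s)
  z <- (seq_len(K) - 1) * theta + s * eta - c(0, cumsum(tau))
  softmax(z)
}

#' Threshold-shift form of the ERS extension
#'
#' Maps an ERS value onto item thresholds: `tau'_j = tau_j + d_j * eta`
#' with `d_j = s_j - s_{j+1}`. For the default graded weights on a
#' nine-point scale, `d = (1, 1, 1, 1, -1, -1, -1, -1)`: positive `eta`
#' raises the lower thresholds and lowers the upper ones, widening the
#' outermost category intervals symmetrically, while negative `eta`
#' widens the middle. Plain PCM probabilities at the shifted thresholds
#' reproduce [ext_pcm_category_probs()] exactly — the two
#' parameterizations are algebraically identical.
#'
#' @inheritParams ext_pcm_category_probs
#' @return shifted threshold vector of length `K - 1`.
#' @examples
#' shifted_thresholds(rep(0, 8), 1, ers_scoring_weights(9))
#' @export
shifted_thresholds <- function(tau, eta, s) {
  check_finite_scalar(eta, "eta")
  check_finite_vector(tau, "tau")
  check_finite_vector(s, "s")
  if (length(s) != length(tau) + 1L) {
    stop("`s` must have length K = length(tau) + 1.", call. = FALSE)
  }
  d <- s[-length(s)] - s[-1]
  tau + d * eta
}

#' Joint log-likelihood of a response dataset
#'
#' Sums the log category probabilities of every observed response under
#' either model variant. Missing responses (`NA`) are ignorably missing
#' and contribute zero.
#'
#' @param data a [response_dataset()].
#' @param theta person trait values, one per person (in the order of
#'   `data$persons`).
#' @param tau item threshold matrix, `I` rows by `K - 1` columns (rows in
#'   the order of `data$items`).
#' @param scale a [rating_scale()]; defaults to graded weights at the
#'   dataset's `K`.
#' @param variant `"pcm"` or `"ext_pcm"`.
#' @param eta person ERS values, required for `"ext_pcm"`.
#' @return a single number, the joint log-likelihood.
#' @export
response_loglik <- function(data, theta, tau, scale = NULL,
                            variant = c("pcm", "ext_pcm"), eta = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(data, "response_dataset"))
  K <- data$K
  if (is.null(scale)) {
    scale <- if (variant == "ext_pcm") {
      rating_scale(K) # errors for K = 2: ERS unidentified
    } else {
      list(K = K, s = rep(0, K))
    }
  }
  if (scale$K != K) stop("scale K does not match dataset K.", call. = FALSE)
  tau <- as.matrix(tau)
  n_persons <- nrow(data$persons)
  n_items <- nrow(data$items)
  if (length(theta) != n_persons) {
    stop("`theta` must have one value per person.", call. = FALSE)
  }
  if (nrow(tau) != n_items || ncol(tau) != K - 1L) {
    stop("`tau` must be I x (K-1).", call. = FALSE)
  }
  if (variant == "ext_pcm") {
    if (is.null(eta) || length(eta) != n_persons) {
      stop("`eta` must have one value per person for the ext_pcm variant.",
        call. = FALSE
      )
    }
  } else {
    eta <- rep(0, n_persons)
  }
  df <- data$responses
  obs <- !is.na(df$response)
  if (!any(obs)) return(0)
  bad <- obs & (df$response < 1L | df$response > K)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "response outside 1..%d at person '%s', item '%s' (value %s)",
      K, df$person_id[i], df$item_id[i], df$response[i]
    ), call. = FALSE)
  }
  p_idx <- data$person_index[obs]
  i_idx <- data$item_index[obs]
  y <- df$response[obs]
  ll <- 0
  s <- if (variant == "ext_pcm") scale$s else rep(0, K)
  for (r in seq_along(y)) {
    pr <- ext_pcm_category_probs(
      theta[p_idx[r]], eta[p_idx[r]], tau[i_idx[r], ], s
    )
    ll <- ll + log(pr[y[r]])
  }
  ll
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

check_finite_scalar <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number.", name),
      call. = FALSE
    )
  }
  invisible(x)
}

check_finite_vector <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be a finite numeric vector.", name),
      call. = FALSE
    )
  }
  invisible(x)
}
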