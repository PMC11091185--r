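#' Extreme-response-style scoring weights
#'
#' Builds the per-category ERS scoring weights for a K-point rating scale.
#' The default `"graded"` weights score each category by its distance from
#' the scale midpoint, `s_k = |k - (K + 1) / 2|`, so that a positive ERS
#' value widens the latent intervals of the outermost categories
#' symmetrically on both ends of the scale, and a negative value widens
#' the middle. `"binary"` weights score the two outermost categories on
#' each side as 1 and everything else as 0.
#'
#' @param K integer category count (categories are labeled `1..K`).
#' @param type `"graded"` (distance from midpoint, the default) or
#'   `"binary"` (extreme-vs-rest).
#' @return numeric weight vector of length `K`.
#' @examples
#' ers_scoring_weights(9)
#' ers_scoring_weights(4)
#' @export
ers_scoring_weights <- function(K, type = c("graded", "binary")) {
  type <- match.arg(type)
  K <- check_category_count(K)
  k <- seq_len(K)
  s <- switch(type,
    graded = abs(k - (K + 1) / 2),
    binary = as.numeric(k == 1 | k == K)
  )
  s
}

check_category_count <- function(K) {
  if (length(K) != 1L || !is.finite(K) || K != as.integer(K)) {
    stop("`K` must be a single integer.", call. = FALSE)
  }
  K <- as.integer(K)
  if (K < 3L) {
    stop(
      "ERS is unidentified for K < 3: with only two categories every ",
      "symmetric weight vector is constant across categories.",
      call. = FALSE
    )
  }
  K
}

#' Rating-scale specification
#'
#' Bundles the category count `K` with an ERS scoring-weight vector `s`.
#' Weights must be non-negative, symmetric (`s_k = s_{K+1-k}`), and
#' unimodally decreasing toward the scale midpoint, where the minimum is
#' attained: this is the geometry under which the ERS dimension acts as
#' symmetric threshold shifts.
#'
#' @param K integer category count, at least 3.
#' @param s optional weight vector of length `K`; defaults to
#'   [ers_scoring_weights()] graded weights.
#' @return an object of class `rating_scale` with fields `K` and `s`.
#' @examples
#' rating_scale(9)
#' @export
rating_scale <- function(K, s = NULL) {
  K <- check_category_count(K)
  if (is.null(s)) s <- ers_scoring_weights(K)
  if (!is.numeric(s) || length(s) != K || anyNA(s) || any(!is.finite(s))) {
    stop("`s` must be a finite numeric vector of length K.", call. = FALSE)
  }
  if (any(s < 0)) stop("ERS weights must be non-negative.", call. = FALSE)
  if (max(abs(s - rev(s))) > 1e-12) {
    stop("ERS weights must be symmetric: s_k = s_{K+1-k}.", call. = FALSE)
  }
  mid <- (K + 1) / 2
  lower <- s[seq_len(ceiling(mid))]
  if (any(diff(lower) > 1e-12)) {
    stop(
      "ERS weights must be non-increasing up to the scale midpoint.",
      call. = FALSE
    )
  }
  mid_val <- if (K %% 2 == 1L) s[(K + 1L) / 2L] else min(s[K / 2 + 0:1])
  if (abs(mid_val - min(s)) > 1e-12) {
    stop("ERS weights must attain their minimum at the scale midpoint.",
      call. = FALSE
    )
  }
  structure(list(K = K, s = as.numeric(s)), class = "rating_scale")
}

#' @export
print.rating_scale <- function(x, ...) {
  cat("<rating_scale> K =", x$K, "\n  ERS weights:", format(x$s), "\n")
  invisible(x)
}
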