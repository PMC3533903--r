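#' Partial Credit Model category probabilities
#'
#' Computes the category response probabilities of the Partial Credit Model
#' (PCM) for a polytomous item with step thresholds `delta`. For a person
#' with latent trait `theta` and an item with categories `0..m`,
#' \deqn{P(Y = y \mid \theta) \propto \exp\{y\theta - \sum_{l \le y} \delta_l\},}
#' with the empty sum for category 0 equal to zero. Computation is carried
#' out on the log scale with max-subtraction, so results are stable for
#' `|theta|` up to at least 40.
#'
#' @param theta numeric vector of latent trait values (logit scale).
#' @param delta numeric vector of the item's step thresholds
#'   `delta_1..delta_m` (logit scale); `m = length(delta)` is the maximum
#'   category code.
#' @return A `length(theta) x (m+1)` matrix of probabilities; each row sums
#'   to 1. Column `y+1` holds `P(Y = y)`.
#' @examples
#' pcm_prob(0, 0)            # dichotomous item: (0.5, 0.5)
#' pcm_prob(c(-1, 0, 1), c(-1, 1))
#' @export
pcm_prob <- function(theta, delta) {
  stopifnot(is.numeric(theta), is.numeric(delta), length(delta) >= 1L,
            all(is.finite(delta)))
  m <- length(delta)
  cd <- c(0, cumsum(delta))           # cumulative thresholds, category 0 first
  z <- outer(theta, 0:m) - rep(cd, each = length(theta))
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' PCM expected score and score variance
#'
#' Model-implied mean and variance of the item score under the PCM at given
#' trait values. The expected score is strictly increasing in `theta`.
#'
#' @inheritParams pcm_prob
#' @return `pcm_expected` returns a numeric vector of expected scores;
#'   `pcm_score_var` the corresponding score variances.
#' @export
pcm_expected <- function(theta, delta) {
  p <- pcm_prob(theta, delta)
  drop(p %*% (0:length(delta)))
}

#' @rdname pcm_expected
#' @export
pcm_score_var <- function(theta, delta) {
  cats <- 0:length(delta)
  p <- pcm_prob(theta, delta)
  e1 <- drop(p %*% cats)
  e2 <- drop(p %*% cats^2)
  pmax(e2 - e1^2, 0)
}

#' Draw PCM responses
#'
#' Samples one response per trait value from the PCM category distribution.
#'
#' @inheritParams pcm_prob
#' @return integer vector of category codes in `0..length(delta)`.
#' @export
pcm_draw <- function(theta, delta) {
  p <- pcm_prob(theta, delta)
  cp <- t(apply(p, 1L, cumsum))
  u <- stats::runif(length(theta))
  rowSums(u > cp)  # number of cumulative bins strictly below u = category
}

# Gauss-Hermite nodes/weights for integrals against a N(mu, sigma^2) density:
# int f(t) phi(t; mu, s2) dt = sum_q w[q] f(mu + sqrt(2 s2) x[q]).
gh_rule <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x, w = gh$w / sqrt(pi))
}

# log(sum(exp(x))) by columns of a matrix, stable
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}
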