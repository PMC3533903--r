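#' Expected a posteriori (EAP) trait estimates
#'
#' Posterior mean (and SD) of the latent trait under a Normal prior,
#' computed by fixed-order Gauss-Hermite quadrature. Persons with no
#' observed responses get `NA`.
#'
#' @param responses persons x items matrix, `NA` = missing; columns must
#'   match the bank's item ids.
#' @param bank an [item_bank()] of thresholds.
#' @param prior_mean,prior_var Normal prior parameters.
#' @param nodes quadrature order (default 61).
#' @return data.frame with columns `eap` and `sd`.
#' @export
eap_estimate <- function(responses, bank, prior_mean = 0, prior_var = 1,
                         nodes = 61L) {
  responses <- as.matrix(responses)
  ids <- names(bank$delta)
  stopifnot(all(ids %in% colnames(responses)), prior_var > 0)
  gh <- gh_rule(nodes)
  tq <- prior_mean + sqrt(2 * prior_var) * gh$x
  N <- nrow(responses)
  ll <- matrix(0, N, nodes)
  for (id in ids) {
    lp <- log(pcm_prob(tq, bank$delta[[id]]))   # nodes x (m+1)
    y <- responses[, id]
    obs <- !is.na(y)
    if (any(obs)) ll[obs, ] <- ll[obs, ] + t(lp)[y[obs] + 1L, , drop = FALSE]
  }
  # posterior weights per person
  mx <- apply(ll, 1L, max)
  wpost <- exp(ll - mx) * rep(gh$w, each = N)
  norm <- rowSums(wpost)
  eap <- drop(wpost %*% tq) / norm
  e2 <- drop(wpost %*% tq^2) / norm
  sd <- sqrt(pmax(e2 - eap^2, 0))
  none <- rowSums(!is.na(responses[, ids, drop = FALSE])) == 0L
  eap[none] <- NA_real_; sd[none] <- NA_real_
  data.frame(eap = eap, sd = sd)
}
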