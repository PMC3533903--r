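#' Log pairwise conditional likelihood of a PCM
#'
#' For every unordered item pair (j, k) and every person with both items
#' observed, the probability of the observed pair (y_j, y_k) conditional on
#' the pair sum y_j + y_k is free of the latent trait:
#' \deqn{P(y_j, y_k \mid y_j + y_k = s) =
#'   \frac{\exp(-\sum_{l\le y_j}\delta_{jl} - \sum_{l\le y_k}\delta_{kl})}
#'        {\sum_{a+b=s}\exp(-\sum_{l\le a}\delta_{jl} - \sum_{l\le b}\delta_{kl})}.}
#' The pairwise conditional log-likelihood is the sum of these log
#' probabilities over all pairs (equal pair weighting).
#'
#' @param delta named list of threshold vectors (or an [item_bank()]).
#' @param responses persons x items matrix with `NA` for missing; columns
#'   named as in `delta`.
#' @return scalar log pairwise conditional likelihood.
#' @export
pce_loglik <- function(delta, responses) {
  if (inherits(delta, "item_bank")) delta <- delta$delta
  pd <- pce_pair_data(responses, vapply(delta, length, integer(1L)))
  -pce_objective(unlist(delta, use.names = FALSE), pd)$nll
}

# Precompute per-pair count matrices and anti-diagonal index groups.
# m: named integer vector of max codes per item (in column order).
pce_pair_data <- function(responses, m) {
  ids <- names(m)
  idx_end <- cumsum(m)
  idx_start <- idx_end - m + 1L
  pairs <- list()
  for (j in seq_along(ids)[-length(ids)]) for (k in (j + 1L):length(ids)) {
    yj <- responses[, ids[j]]; yk <- responses[, ids[k]]
    keep <- !is.na(yj) & !is.na(yk)
    if (!any(keep)) next
    C <- matrix(0, m[j] + 1L, m[k] + 1L)
    tb <- table(factor(yj[keep], levels = 0:m[j]),
                factor(yk[keep], levels = 0:m[k]))
    C[] <- tb
    sgrid <- outer(0:m[j], 0:m[k], `+`)
    cells_by_s <- split(seq_along(sgrid), as.vector(sgrid))
    Ns <- vapply(cells_by_s, function(ix) sum(C[ix]), numeric(1L))
    pairs[[length(pairs) + 1L]] <-
      list(j = j, k = k, C = C, sgrid = sgrid + 1L,
           cells_by_s = cells_by_s, Ns = Ns)
  }
  list(pairs = pairs, m = m, idx_start = idx_start, idx_end = idx_end,
       K = sum(m))
}

# Negative log pairwise likelihood and its gradient w.r.t. the full
# threshold vector.
pce_objective <- function(delta_vec, pd) {
  nll <- 0
  grad <- numeric(pd$K)
  for (p in pd$pairs) {
    dj <- delta_vec[pd$idx_start[p$j]:pd$idx_end[p$j]]
    dk <- delta_vec[pd$idx_start[p$k]:pd$idx_end[p$k]]
    U <- outer(-c(0, cumsum(dj)), -c(0, cumsum(dk)), `+`)
    lse <- vapply(p$cells_by_s, function(ix) {
      u <- U[ix]; mx <- max(u); mx + log(sum(exp(u - mx)))
    }, numeric(1L))
    nll <- nll - sum(p$C * U) + sum(p$Ns * lse)
    W <- p$Ns[p$sgrid] * exp(U - lse[p$sgrid])
    dj_resid <- rowSums(p$C) - rowSums(W)   # by category a = 0..mj
    dk_resid <- colSums(p$C) - colSums(W)
    # d nll / d delta_jl = sum_{a >= l} (C - W) row margins
    gj <- rev(cumsum(rev(dj_resid)))[-1L]
    gk <- rev(cumsum(rev(dk_resid)))[-1L]
    grad[pd$idx_start[p$j]:pd$idx_end[p$j]] <-
      grad[pd$idx_start[p$j]:pd$idx_end[p$j]] + gj
    grad[pd$idx_start[p$k]:pd$idx_end[p$k]] <-
      grad[pd$idx_start[p$k]:pd$idx_end[p$k]] + gk
  }
  list(nll = nll, grad = grad)
}

# Collapse categories observed by nobody, recording the mapping.
collapse_unobserved <- function(responses, m) {
  maps <- list()
  for (id in names(m)) {
    y <- responses[, id]
    obs <- sort(unique(y[!is.na(y)]))
    full <- 0:m[id]
    if (length(obs) < 2L)
      stop("item ", id, " has fewer than 2 observed categories")
    if (!identical(as.integer(obs), full)) {
      remap <- match(y, obs) - 1L
      responses[, id] <- remap
      m[id] <- length(obs) - 1L
      maps[[id]] <- stats::setNames(seq_along(obs) - 1L, obs)
      warning("item ", id, ": unobserved categories collapsed (",
              length(full) - length(obs), " removed)", call. = FALSE)
    }
  }
  list(responses = responses, m = m, maps = maps)
}

#' Pairwise conditional estimation of PCM thresholds
#'
#' Estimates the step thresholds of all items by minimising the negative
#' log pairwise conditional likelihood (see [pce_loglik()]), a consistent
#' estimator that conditions the latent trait out entirely and therefore
#' does not depend on the trait distribution. Identifiability is fixed by
#' the constraint that the sum of ALL thresholds is zero, so stratum-wise
#' locations are comparable as relative quantities. Categories observed by
#' nobody are collapsed downward with a warning and the mapping recorded.
#'
#' @param responses persons x items matrix of codes, `NA` = missing.
#' @param m optional named integer vector of maximum codes per item
#'   (default: observed maxima).
#' @param control passed to [stats::optim()] (`method = "BFGS"`).
#' @return object of class `c("pce_fit", "item_bank")` with elements
#'   `delta` (named list of thresholds), `logPL`, `convergence`,
#'   `grad_norm`, `n_pairs`, `collapse_maps`.
#' @examples
#' set.seed(1)
#' bank <- item_bank(list(a = c(-1, 0.5), b = c(-0.2, 0.8), c = c(0, 1)))
#' th <- rnorm(500)
#' y <- sapply(bank$delta, function(d) pcm_draw(th, d))
#' fit <- pce_fit(y)
#' item_locations(fit)
#' @export
pce_fit <- function(responses, m = NULL, control = list(maxit = 500)) {
  responses <- as.matrix(responses)
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("item", seq_len(ncol(responses)))
  if (ncol(responses) < 2L) stop("PCE needs at least 2 items")
  if (is.null(m)) {
    m <- apply(responses, 2L, max, na.rm = TRUE)
    m <- stats::setNames(as.integer(m), colnames(responses))
  } else m <- stats::setNames(as.integer(m[colnames(responses)]),
                              colnames(responses))
  cc <- collapse_unobserved(responses, m)
  pd <- pce_pair_data(cc$responses, cc$m)
  if (length(pd$pairs) < 1L) stop("no item pair has overlapping observations")
  n_items_in_pairs <- unique(unlist(lapply(pd$pairs, function(p) c(p$j, p$k))))
  if (length(n_items_in_pairs) < length(cc$m))
    warning("item(s) without any pair overlap dropped from linkage",
            call. = FALSE)
  K <- pd$K
  # free parameters: all thresholds but the last; last = -sum(rest)
  expand <- function(free) c(free, -sum(free))
  fn <- function(free) pce_objective(expand(free), pd)$nll
  gr <- function(free) {
    g <- pce_objective(expand(free), pd)$grad
    g[-K] - g[K]
  }
  opt <- stats::optim(numeric(K - 1L), fn, gr, method = "BFGS",
                      control = control)
  dv <- expand(opt$par)
  gn <- sqrt(sum(gr(opt$par)^2))
  if (opt$convergence != 0L)
    warning(sprintf("PCE did not converge (code %d, |grad| = %.3g)",
                    opt$convergence, gn), call. = FALSE)
  delta <- lapply(stats::setNames(seq_along(cc$m), names(cc$m)),
                  function(j) dv[pd$idx_start[j]:pd$idx_end[j]])
  structure(list(delta = delta, logPL = -opt$value,
                 convergence = opt$convergence, grad_norm = gn,
                 n_pairs = length(pd$pairs), collapse_maps = cc$maps),
            class = c("pce_fit", "item_bank"))
}

#' @export
print.pce_fit <- function(x, ...) {
  cat("Pairwise conditional estimation:", length(x$delta), "items,",
      x$n_pairs, "pairs; log PL =", format(x$logPL), "\n")
  NextMethod()
}
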