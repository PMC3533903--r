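#' Item-trait interaction chi-square fit test
#'
#' Global fit test of a calibrated PCM: persons are partitioned into
#' `n_class` groups of near-equal size by their EAP trait estimate; per
#' item and class interval the summed observed score is compared with the
#' summed model-expected score, standardised by the summed model score
#' variance, `z_g = (O_g - E_g) / sqrt(V_g)`; the item chi-square is
#' `sum(z_g^2)` with `n_class - 1` degrees of freedom and the total sums
#' over items (`df = items x (intervals - 1)`). Intervals without
#' observations for an item drop out (their degrees of freedom with them).
#'
#' So the tested item does not predict itself through the trait estimate,
#' each person's expected score and score variance for item j are taken
#' under the posterior trait distribution given the person's OTHER items
#' (leave-one-out posterior; variance by the law of total variance), and
#' item j's class intervals are cut on the leave-one-out EAP. With plug-in
#' expected scores at the full-data EAP the statistic is severely
#' deflated (the item's own residual shrinks the trait estimate toward
#' itself); with full-data grouping it is inflated (the item selects its
#' own interval). The leave-one-out construction makes the interval sums
#' genuinely pivotal under the model.
#'
#' @param responses persons x items matrix.
#' @param bank an [item_bank()] of calibrated thresholds.
#' @param prior_mean,prior_var Normal prior for the trait
#'   (typically 0 and the calibrated variance).
#' @param n_class number of class intervals (default 10).
#' @param nodes quadrature order.
#' @return list of class `item_fit`: `items` (data.frame with chisq, df, p
#'   per item), `total`, `df`, `p`, `n`, `n_class`.
#' @export
item_trait_chisq <- function(responses, bank, prior_mean = 0,
                             prior_var = 1, n_class = 10L, nodes = 61L) {
  responses <- as.matrix(responses)
  ids <- names(bank$delta)
  Y <- responses[, ids, drop = FALSE]
  keep <- rowSums(!is.na(Y)) > 0L
  Y <- Y[keep, , drop = FALSE]
  N <- nrow(Y)
  if (n_class < 2L) stop("fit test undefined with fewer than 2 intervals")
  gh <- gh_rule(nodes)
  tq <- prior_mean + sqrt(2 * prior_var) * gh$x
  # per-item log-likelihood contributions on the node grid
  lp <- Es <- Vs <- vector("list", length(ids))
  ll <- matrix(0, N, nodes)
  for (j in seq_along(ids)) {
    d <- bank$delta[[j]]
    p <- pcm_prob(tq, d)
    cats <- 0:length(d)
    Es[[j]] <- drop(p %*% cats)
    Vs[[j]] <- pmax(drop(p %*% cats^2) - Es[[j]]^2, 0)
    lpj <- matrix(0, N, nodes)
    y <- Y[, j]; obs <- !is.na(y)
    if (any(obs))
      lpj[obs, ] <- t(log(pmax(p, 1e-300)))[y[obs] + 1L, , drop = FALSE]
    lp[[j]] <- lpj
    ll <- ll + lpj
  }
  lw <- rep(log(gh$w), each = N)
  rows <- list()
  for (j in seq_along(ids)) {
    y <- Y[, j]; obs <- !is.na(y)
    A <- (ll - lp[[j]]) + lw                  # leave item j out
    w <- exp(A - logsumexp_rows(A))
    E <- drop(w %*% Es[[j]])
    V <- drop(w %*% Vs[[j]]) + pmax(drop(w %*% Es[[j]]^2) - E^2, 0)
    # class intervals by the leave-one-out trait estimate, so interval
    # membership is a function of the conditioning items only; rounded
    # because the subtraction ll - lp[j] leaves a ~1e-16 residue of item
    # j's own response that would otherwise order persons within tied
    # rest patterns by y_j and bias the interval sums
    th <- signif(drop(w %*% tq), 9)
    grp <- as.integer(cut(rank(th, ties.method = "first"),
                          breaks = round(seq(0, N,
                                             length.out = n_class + 1L)),
                          labels = FALSE))
    O_g <- tapply(y[obs], grp[obs], sum)
    E_g <- tapply(E[obs], grp[obs], sum)
    V_g <- tapply(V[obs], grp[obs], sum)
    ok <- V_g > 0
    z <- (O_g[ok] - E_g[ok]) / sqrt(V_g[ok])
    # project out the item's overall location residual: the test targets
    # the item-trait INTERACTION (misfit of the score-curve shape across
    # trait intervals), and the location component is what threshold
    # estimation absorbs; the projection makes sum(z^2) chi-square with
    # exactly (intervals - 1) df under the model
    a <- sqrt(V_g[ok] / sum(V_g[ok]))
    z <- z - sum(z * a) * a
    chisq <- sum(z^2)
    df <- sum(ok) - 1L
    rows[[j]] <- data.frame(item = ids[j], chisq = chisq, df = df,
                            p = stats::pchisq(chisq, df, lower.tail = FALSE))
  }
  items <- do.call(rbind, rows)
  total <- sum(items$chisq); df <- sum(items$df)
  structure(list(items = items, total = total, df = df,
                 p = stats::pchisq(total, df, lower.tail = FALSE),
                 n = N, n_class = n_class),
            class = "item_fit")
}

#' @export
print.item_fit <- function(x, ...) {
  cat(sprintf("Item-trait chi-square: total = %.2f, df = %d, p = %.4g (n = %d%s)\n",
              x$total, x$df, x$p, x$n,
              if (!is.null(x$rescaled_to) && !is.na(x$rescaled_to))
                sprintf(", rescaled to %d", x$rescaled_to) else ""))
  invisible(x)
}

#' Rescale a chi-square statistic to a moderate effective sample size
#'
#' With very large samples, chi-square fit tests flag tiny, irrelevant
#' misfits. The statistic is therefore rescaled to an effective sample of
#' `N0` persons by multiplying it by `N0 / N` (degrees of freedom
#' unchanged, p-value recomputed). When `N < N0` the statistic is returned
#' unchanged with a note.
#'
#' @param chisq observed statistic (scalar or `item_fit`).
#' @param N sample size behind the statistic.
#' @param N0 target effective sample size (default 500).
#' @param df degrees of freedom (required for scalar input).
#' @return for scalar input, list with `chisq`, `df`, `p`, `scaled`;
#'   for `item_fit` input, a rescaled `item_fit`.
#' @export
rescale_statistic <- function(chisq, N, N0 = 500L, df = NULL) {
  if (inherits(chisq, "item_fit")) {
    fit <- chisq
    r <- rescale_statistic(fit$total, N = fit$n, N0 = N0, df = fit$df)
    fit$items$chisq <- fit$items$chisq * (r$chisq / fit$total)
    fit$items$p <- stats::pchisq(fit$items$chisq, fit$items$df,
                                 lower.tail = FALSE)
    fit$total <- r$chisq; fit$p <- r$p
    fit$rescaled_to <- if (r$scaled) N0 else NA_integer_
    return(fit)
  }
  stopifnot(is.numeric(chisq), !is.null(df))
  if (N < N0) {
    message("N below the target effective size; statistic unchanged")
    return(list(chisq = chisq, df = df,
                p = stats::pchisq(chisq, df, lower.tail = FALSE),
                scaled = FALSE))
  }
  sc <- chisq * N0 / N
  list(chisq = sc, df = df, p = stats::pchisq(sc, df, lower.tail = FALSE),
       scaled = TRUE)
}
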