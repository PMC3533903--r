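# Marginal-likelihood machinery shared by calibrate_pcm() and lrpcm().
#
# The marginal likelihood integrates the PCM response probabilities over the
# person's Normal trait distribution. The integral is evaluated by
# Gauss-Hermite quadrature centred on each person's prior, i.e. with the
# exact reparameterisation theta = mu_n + sigma_n * sqrt(2) * x_q, which
# adapts the node placement to heteroscedastic trait distributions.
#
# Persons sharing the same (mu_n, sigma2_n) are grouped so item
# probabilities are evaluated once per distinct trait grid point; with
# factor covariates this reduces the grid from N*Q to (#profiles)*Q.
mml_eval <- function(Y, delta, grp, mu_g, sig_g, gh, grad_delta = FALSE) {
  G <- length(mu_g); Q <- length(gh$x); N <- nrow(Y)
  tvec <- rep(mu_g, Q) + sqrt(2) * rep(sig_g, Q) * rep(gh$x, each = G)
  GQ <- G * Q
  IDX <- outer(grp, (seq_len(Q) - 1L) * G, `+`)
  ll <- matrix(0, N, Q)
  s <- matrix(0, N, Q)
  items <- names(delta)
  Pge_list <- if (grad_delta) vector("list", length(items))
  for (jj in seq_along(items)) {
    dj <- delta[[jj]]
    m <- length(dj)
    p <- pcm_prob(tvec, dj)
    lp <- log(pmax(p, 1e-300))
    E <- drop(p %*% (0:m))
    y <- Y[, items[jj]]
    obs <- !is.na(y)
    if (any(obs)) {
      lin <- IDX[obs, , drop = FALSE]
      ll[obs, ] <- ll[obs, ] + lp[lin + y[obs] * GQ]
      s[obs, ] <- s[obs, ] + (y[obs] - E[lin])
    }
    if (grad_delta) {
      cum <- p
      for (cc in 2:(m + 1L)) cum[, cc] <- cum[, cc - 1L] + p[, cc]
      Pge_list[[jj]] <- 1 - cum[, 1:m, drop = FALSE]  # P(Y >= l), l = 1..m
    }
  }
  A <- ll + rep(log(gh$w), each = N)
  logLn <- logsumexp_rows(A)
  rho <- exp(A - logLn)
  S1 <- rowSums(rho * s)
  xq <- sqrt(2) * gh$x
  S2 <- rowSums(rho * s * rep(xq, each = N))
  gd <- NULL
  if (grad_delta) {
    gd <- lapply(seq_along(items), function(jj) {
      m <- length(delta[[jj]])
      y <- Y[, items[jj]]
      obs <- !is.na(y)
      lin <- IDX[obs, , drop = FALSE]
      vapply(1:m, function(l) {
        sum(rho[obs, , drop = FALSE] *
              Pge_list[[jj]][lin + (l - 1L) * GQ]) - sum(y[obs] >= l)
      }, numeric(1L))
    })
    names(gd) <- items
  }
  list(logL = sum(logLn), logLn = logLn, S1 = S1, S2 = S2, grad_delta = gd)
}

#' Calibrate PCM thresholds by marginal maximum likelihood
#'
#' Fits the PCM with a Normal latent trait of mean fixed at 0 (the
#' identifiability constraint) and free variance, estimating all item
#' thresholds and the trait variance jointly by Gauss-Hermite marginal ML.
#' The resulting thresholds are meant to be frozen and passed to [lrpcm()]
#' for all subsequent latent-regression fits.
#'
#' @param responses persons x items matrix, `NA` = missing.
#' @param m optional named maximum codes (default: observed maxima).
#' @param nodes quadrature order.
#' @param start optional list with `delta` (named list) and `sigma2`.
#' @param control passed to [stats::optim()].
#' @return object of class `pcm_calibration`: `bank` (an [item_bank()]),
#'   `sigma2`, `logL`, `k` (free parameters), `AIC`, `convergence`, `n`.
#' @export
calibrate_pcm <- function(responses, m = NULL, nodes = 21L, start = NULL,
                          control = list(maxit = 500)) {
  responses <- as.matrix(responses)
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("item", seq_len(ncol(responses)))
  if (is.null(m)) {
    m <- apply(responses, 2L, max, na.rm = TRUE)
    m <- stats::setNames(as.integer(m), colnames(responses))
  }
  if (ncol(responses) == 1L && m[1L] == 1L)
    stop("a single dichotomous item is unidentifiable under marginal ML")
  cc <- collapse_unobserved(responses, m)
  Y <- cc$responses; m <- cc$m
  keep <- rowSums(!is.na(Y)) > 0L
  Y <- Y[keep, , drop = FALSE]
  N <- nrow(Y)
  K <- sum(m)
  idx_end <- cumsum(m); idx_start <- idx_end - m + 1L
  gh <- gh_rule(nodes)
  grp <- rep(1L, N)
  split_delta <- function(dv)
    lapply(stats::setNames(seq_along(m), names(m)),
           function(j) dv[idx_start[j]:idx_end[j]])
  par0 <- c(if (!is.null(start)) unlist(start$delta) else numeric(K),
            log(sqrt(if (!is.null(start)) start$sigma2 else 1)))
  cache <- new.env(parent = emptyenv())
  evalp <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$res)
    sig <- exp(par[K + 1L])
    res <- mml_eval(Y, split_delta(par[1:K]), grp, 0, sig, gh,
                    grad_delta = TRUE)
    res$sig <- sig
    cache$par <- par; cache$res <- res
    res
  }
  fn <- function(par) -evalp(par)$logL
  gr <- function(par) {
    r <- evalp(par)
    c(-unlist(r$grad_delta, use.names = FALSE),
      -r$sig * sum(r$S2))
  }
  opt <- stats::optim(par0, fn, gr, method = "BFGS", control = control)
  if (opt$convergence != 0L)
    warning("calibration did not converge (code ", opt$convergence, ")",
            call. = FALSE)
  bank <- item_bank(split_delta(opt$par[1:K]))
  structure(list(bank = bank, sigma2 = exp(2 * opt$par[K + 1L]),
                 logL = -opt$value, k = K + 1L,
                 AIC = 2 * (K + 1L) + 2 * opt$value,
                 convergence = opt$convergence, n = N, nodes = nodes,
                 collapse_maps = cc$maps),
            class = "pcm_calibration")
}

#' @export
print.pcm_calibration <- function(x, ...) {
  cat("PCM calibration (marginal ML, latent mean fixed at 0)\n")
  cat(sprintf("  n = %d, items = %d, sigma2 = %.4f, logL = %.2f, AIC = %.2f\n",
              x$n, length(x$bank$delta), x$sigma2, x$logL, x$AIC))
  invisible(x)
}

#' Latent regression mixed Partial Credit Model
#'
#' Fits the measurement-cum-structural model in which responses follow a
#' PCM with FIXED item thresholds and the latent trait of person `n` is
#' `Theta_n ~ N(mu_n, sigma2_n)` with
#' `mu_n = mu* + X_n beta` and `sigma2_n = sigma2* + Z_n gamma`
#' (identity link on the variance, so covariates shift the variance
#' additively; the reference group is absorbed into the intercepts
#' `mu*`/`sigma2*`). Estimation maximises the marginal likelihood by
#' prior-centred Gauss-Hermite quadrature; Wald standard errors come from
#' the observed information (finite differences of the analytic gradient).
#'
#' @param responses persons x items (or pseudo-items) matrix, `NA` missing.
#' @param data data.frame of person covariates (one row per person).
#' @param mean one-sided formula for the latent-mean design `X`.
#' @param var one-sided formula for the latent-variance design `Z`
#'   (default intercept-only = homoscedastic).
#' @param bank an [item_bank()] of frozen thresholds (typically from
#'   [calibrate_pcm()] or [pce_fit()]).
#' @param nodes quadrature order (default 21).
#' @param start optional numeric start vector (mean coefs then var coefs).
#' @param var_floor smallest admissible person variance; configurations
#'   crossing it are pushed back by a quadratic penalty and the fit is
#'   flagged invalid if the optimum sits on the boundary.
#' @param control passed to [stats::optim()].
#' @param hessian compute the observed information (set `FALSE` to skip).
#' @return an object of class `lrpcm`; see [summary.lrpcm()]. Components
#'   include `beta`, `gamma`, `se`, `vcov`, `logL`, `AIC` (with `k` the
#'   number of free mean/variance parameters; thresholds are fixed),
#'   `boundary` (TRUE if any fitted person variance is at the floor).
#' @examples
#' set.seed(1)
#' bank <- item_bank(list(a = c(-1, 0, 1), b = c(-0.5, 0.5, 1.2)))
#' d <- data.frame(g = factor(rep(c("m", "w"), each = 150)))
#' th <- rnorm(300, ifelse(d$g == "w", -0.5, 0), 1)
#' y <- sapply(bank$delta, function(dd) pcm_draw(th, dd))
#' fit <- lrpcm(y, d, mean = ~ g, bank = bank)
#' coef(fit)
#' @export
lrpcm <- function(responses, data, mean = ~ 1, var = ~ 1, bank,
                  nodes = 21L, start = NULL, var_floor = 1e-3,
                  control = list(maxit = 500, reltol = 1e-10),
                  hessian = TRUE) {
  stopifnot(inherits(bank, "item_bank"))
  responses <- as.matrix(responses)
  ids <- names(bank$delta)
  if (!all(ids %in% colnames(responses)))
    stop("responses lack bank item(s): ",
         paste(setdiff(ids, colnames(responses)), collapse = ", "))
  Y <- responses[, ids, drop = FALSE]
  keep <- rowSums(!is.na(Y)) > 0L
  if (!all(keep)) {
    Y <- Y[keep, , drop = FALSE]
    data <- data[keep, , drop = FALSE]
  }
  N <- nrow(Y)
  mf_x <- stats::model.frame(mean, data = data, na.action = stats::na.fail)
  mf_z <- stats::model.frame(var, data = data, na.action = stats::na.fail)
  X <- stats::model.matrix(mean, mf_x)
  Z <- stats::model.matrix(var, mf_z)
  if (qr(X)$rank < ncol(X)) stop("mean design is rank deficient")
  if (qr(Z)$rank < ncol(Z)) stop("variance design is rank deficient")
  px <- ncol(X); pz <- ncol(Z)
  gh <- gh_rule(nodes)
  delta <- bank$delta

  if (is.null(start)) {
    pe <- eap_estimate(Y, bank, prior_mean = 0, prior_var = 2)
    b0 <- stats::lm.fit(X, pe$eap)$coefficients
    b0[is.na(b0)] <- 0
    g0 <- numeric(pz)
    g0[1L] <- max(stats::var(pe$eap), 0.2)
    start <- c(b0, g0)
  }
  stopifnot(length(start) == px + pz)

  cache <- new.env(parent = emptyenv())
  evalp <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$res)
    beta <- par[1:px]; gamma <- par[px + (1:pz)]
    mu <- drop(X %*% beta); sig2 <- drop(Z %*% gamma)
    res <- list(mu = mu, sig2 = sig2)
    if (any(sig2 < var_floor)) {
      v <- pmax(var_floor - sig2, 0)
      res$pen <- TRUE
      res$nll <- 1e8 + 1e8 * sum(v^2)
      res$grad <- c(numeric(px), drop(crossprod(Z, -2e8 * v)))
    } else {
      key <- paste(mu, sig2)
      ug <- !duplicated(key)
      grp <- match(key, key[ug])
      ev <- mml_eval(Y, delta, grp, mu[ug], sqrt(sig2[ug]), gh)
      res$pen <- FALSE
      res$nll <- -ev$logL
      dmu <- ev$S1
      dsig2 <- ev$S2 / (2 * sqrt(sig2))
      res$grad <- -c(drop(crossprod(X, dmu)), drop(crossprod(Z, dsig2)))
    }
    cache$par <- par; cache$res <- res
    res
  }
  fn <- function(par) evalp(par)$nll
  gr <- function(par) evalp(par)$grad
  opt <- stats::optim(start, fn, gr, method = "BFGS", control = control)
  if (opt$convergence != 0L)
    warning("lrpcm did not converge (code ", opt$convergence, ")",
            call. = FALSE)
  par <- opt$par
  beta <- stats::setNames(par[1:px], colnames(X))
  gamma <- stats::setNames(par[px + (1:pz)], colnames(Z))
  sig2_hat <- drop(Z %*% gamma)
  boundary <- any(sig2_hat <= var_floor * 1.01)
  if (boundary)
    warning("fitted latent variance at the positivity floor for ",
            sum(sig2_hat <= var_floor * 1.01), " person(s); fit flagged",
            call. = FALSE)
  k <- px + pz
  V <- NULL; se <- rep(NA_real_, k)
  if (hessian) {
    H <- fd_hessian(gr, par)
    V <- try(solve(H), silent = TRUE)
    if (inherits(V, "try-error")) {
      warning("observed information not invertible", call. = FALSE)
      V <- NULL
    } else se <- sqrt(pmax(diag(V), 0))
  }
  names(se) <- c(colnames(X), colnames(Z))
  structure(list(beta = beta, gamma = gamma, se = se, vcov = V,
                 logL = -opt$value, k = k, AIC = 2 * k + 2 * opt$value,
                 n = N, nodes = nodes, boundary = boundary,
                 convergence = opt$convergence,
                 mean_formula = mean, var_formula = var, bank = bank,
                 X_assign = attr(X, "assign"), Z_assign = attr(Z, "assign"),
                 xlevels = stats::.getXlevels(stats::terms(mf_x), mf_x),
                 zlevels = stats::.getXlevels(stats::terms(mf_z), mf_z),
                 data = data, responses = Y,
                 call = match.call()),
            class = "lrpcm")
}

# central finite differences of an analytic gradient
fd_hessian <- function(gr, par, h_rel = 1e-5) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    h <- h_rel * (1 + abs(par[i]))
    e <- numeric(p); e[i] <- h
    H[i, ] <- (gr(par + e) - gr(par - e)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' @export
print.lrpcm <- function(x, ...) {
  cat("Latent regression mixed PCM\n")
  cat(sprintf("  n = %d persons, %d items/pseudo-items, %d quadrature nodes\n",
              x$n, length(x$bank$delta), x$nodes))
  cat(sprintf("  logL = %.2f, AIC = %.2f (k = %d)\n", x$logL, x$AIC, x$k))
  cat("Mean model:\n"); print(round(x$beta, 4))
  cat("Variance model:\n"); print(round(x$gamma, 4))
  if (x$boundary) cat("NOTE: variance at positivity floor - fit invalid\n")
  invisible(x)
}

#' Summarise a latent regression mixed PCM fit
#'
#' Coefficient tables with Wald standard errors and p-values for the mean
#' and variance models.
#'
#' @param object,x an [lrpcm()] fit.
#' @param ... unused.
#' @export
summary.lrpcm <- function(object, ...) {
  est <- c(object$beta, object$gamma)
  z <- est / object$se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(section = rep(c("mean", "variance"),
                                  c(length(object$beta),
                                    length(object$gamma))),
                    term = names(est), estimate = est, se = object$se,
                    z = z, p = p, row.names = NULL)
  structure(list(coefficients = tab, logL = object$logL, AIC = object$AIC,
                 k = object$k, n = object$n, boundary = object$boundary),
            class = "summary.lrpcm")
}

#' @rdname summary.lrpcm
#' @export
print.summary.lrpcm <- function(x, ...) {
  cat(sprintf("Latent regression mixed PCM: n = %d, logL = %.2f, AIC = %.2f\n",
              x$n, x$logL, x$AIC))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, 4)
  tab$se <- round(tab$se, 4)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 3)
  print(tab)
  invisible(x)
}

#' @export
coef.lrpcm <- function(object, ...) c(object$beta, object$gamma)

#' @export
logLik.lrpcm <- function(object, ...) {
  structure(object$logL, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
vcov.lrpcm <- function(object, ...) object$vcov

#' Predicted latent mean / variance for the fitted persons or new profiles
#'
#' @param object an [lrpcm()] fit.
#' @param newdata optional data.frame of covariate profiles.
#' @param type `"mean"` for `mu_n`, `"variance"` for `sigma2_n`.
#' @param ... unused.
#' @export
predict.lrpcm <- function(object, newdata = NULL,
                          type = c("mean", "variance"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  if (type == "mean") {
    X <- stats::model.matrix(object$mean_formula, data = newdata,
                             xlev = object$xlevels)
    drop(X[, names(object$beta), drop = FALSE] %*% object$beta)
  } else {
    Z <- stats::model.matrix(object$var_formula, data = newdata,
                             xlev = object$zlevels)
    drop(Z[, names(object$gamma), drop = FALSE] %*% object$gamma)
  }
}

#' Simulate response matrices from a fitted latent regression PCM
#'
#' Draws latent traits from the fitted `N(mu_n, sigma2_n)` and responses
#' from the PCM at the frozen thresholds.
#'
#' @param object an [lrpcm()] fit.
#' @param nsim number of replicate matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` response matrices.
#' @export
simulate.lrpcm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, type = "mean")
  s2 <- predict(object, type = "variance")
  lapply(seq_len(nsim), function(i) {
    th <- stats::rnorm(length(mu), mu, sqrt(s2))
    vapply(object$bank$delta, function(d) pcm_draw(th, d),
           numeric(length(th)))
  })
}

#' Person-level residuals of a latent regression PCM
#'
#' EAP trait estimates under the fitted person-specific prior minus the
#' modelled latent mean; useful as a coarse diagnostic of the mean model.
#'
#' @param object an [lrpcm()] fit.
#' @param ... unused.
#' @export
residuals.lrpcm <- function(object, ...) {
  mu <- predict(object, type = "mean")
  s2 <- predict(object, type = "variance")
  # person-wise EAP under N(mu_n, sigma2_n): reuse eap_estimate per profile
  key <- paste(mu, s2)
  out <- numeric(length(mu))
  for (k in unique(key)) {
    sel <- key == k
    pe <- eap_estimate(object$responses[sel, , drop = FALSE], object$bank,
                       prior_mean = mu[sel][1L], prior_var = s2[sel][1L],
                       nodes = object$nodes)
    out[sel] <- pe$eap - mu[sel][1L]
  }
  out
}

#' Plot expected-score curves of the fitted item bank
#'
#' @param x an [lrpcm()] fit or [item_bank()].
#' @param theta_range range of trait values.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lrpcm <- function(x, theta_range = c(-4, 4), ...) {
  plot_bank(x$bank, theta_range, ...)
}

#' @export
plot.item_bank <- function(x, theta_range = c(-4, 4), ...) {
  plot_bank(x, theta_range, ...)
}

plot_bank <- function(bank, theta_range, ...) {
  th <- seq(theta_range[1L], theta_range[2L], length.out = 101L)
  E <- vapply(bank$delta, function(d) pcm_expected(th, d), numeric(101L))
  graphics::matplot(th, E, type = "l", lty = 1, xlab = "latent trait",
                    ylab = "expected item score", ...)
  graphics::legend("topleft", legend = names(bank$delta), lty = 1,
                   col = seq_along(bank$delta), cex = 0.7, bty = "n")
  invisible(NULL)
}
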