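#' Explained-variance rate of a latent regression
#'
#' Compares the latent-trait variance estimated without covariates
#' (`sigma2_0`, from a model with `k0` parameters) with the variance
#' estimated with the mean covariates (`sigma2`, `k` parameters), adjusted
#' for the parameter counts:
#' \deqn{\tau = 1 - \frac{(n - 1 - k)\,\hat\sigma^2}
#'                       {(n - 1 - k_0)\,\hat\sigma_0^2}.}
#' Parameter counts follow the reporting convention of the fitted models:
#' `k0` counts the thresholds plus the trait variance, `k` adds the
#' mean-model parameters.
#'
#' @param sigma2_0 latent variance without covariates.
#' @param k0 parameter count of that model.
#' @param sigma2 latent variance with covariates.
#' @param k parameter count of the covariate model.
#' @param n number of persons.
#' @return the rate `tau` (a proportion).
#' @examples
#' tau_explained(1.4272, 37, 1.2406, 50, 26388)  # ~0.131
#' @export
tau_explained <- function(sigma2_0, k0, sigma2, k, n) {
  stopifnot(n > max(k, k0) + 1)
  if (sigma2_0 <= 0 || sigma2 <= 0) stop("variances must be positive")
  1 - ((n - 1 - k) * sigma2) / ((n - 1 - k0) * sigma2_0)
}

#' Quantitative recoding of an ordinal age variable
#'
#' Converts the fitted dummy coefficients of an ordinal variable (reference
#' level coefficient 0) into small integer scores proportional to the
#' coefficients, so the variable can enter the model as a single
#' quantitative term. The common slope is chosen as the smallest-magnitude
#' nonzero coefficient divided by a small integer multiplier (1..`max_mult`)
#' picked as the smallest multiplier whose integer-rounded scores
#' reproduce the coefficient ratios within `tol`.
#'
#' @param coefs named numeric vector of dummy coefficients in level order,
#'   reference first with value 0.
#' @param max_mult largest multiplier tried.
#' @param tol largest acceptable absolute rounding error on a score.
#' @param monotone_fix if the coefficient pattern is not monotone, project
#'   it onto a monotone sequence (isotonic regression) before scoring
#'   (default warns and proceeds without projection).
#' @return list of class `age_recoding`: `scores` (named integer vector,
#'   reference 0), `slope` (latent change per score unit), `max_error`.
#' @examples
#' recode_age_quantitative(c(0, -0.6, -1.2, -2.4, -3.6, -4.8, -6.0))
#' @export
recode_age_quantitative <- function(coefs, max_mult = 4L, tol = 0.25,
                                    monotone_fix = FALSE) {
  stopifnot(is.numeric(coefs), length(coefs) >= 2L)
  if (abs(coefs[1L]) > 1e-12)
    stop("first (reference) coefficient must be 0")
  if (all(abs(coefs) < 1e-12)) stop("all coefficients zero; recoding refused")
  dir <- sign(coefs[which.max(abs(coefs))])
  u <- coefs * dir                       # orient so scores are nonnegative
  if (any(u < -1e-8)) {
    if (monotone_fix) {
      u <- stats::isoreg(u)$yf
    } else warning("dummy coefficients are not monotone", call. = FALSE)
  }
  base <- min(abs(u[abs(u) > 1e-12]))
  best <- NULL
  for (q in seq_len(max_mult)) {
    raw <- q * u / base
    sc <- round(raw)
    err <- max(abs(raw - sc))
    if (is.null(best) || err < best$err - 1e-12)
      best <- list(q = q, scores = sc, err = err)
    if (err <= tol) { best <- list(q = q, scores = sc, err = err); break }
  }
  scores <- as.integer(best$scores)
  names(scores) <- names(coefs)
  if (is.unsorted(scores) && is.unsorted(rev(scores)))
    warning("recoded scores are not monotone in age", call. = FALSE)
  structure(list(scores = scores, slope = dir * base / best$q,
                 max_error = best$err), class = "age_recoding")
}

#' @export
print.age_recoding <- function(x, ...) {
  cat("Quantitative age recoding (slope", format(round(x$slope, 4)), "):\n")
  print(x$scores)
  invisible(x)
}

#' Modelled latent-mean deviation between two covariate profiles
#'
#' Difference of the modelled latent means `mu_n` between a covariate
#' profile and a reference profile; the variance model is untouched. The
#' default method works directly on a named coefficient vector whose names
#' are term labels (interaction terms joined by `:`), each profile being a
#' named list of numeric variable values (dummies as 0/1, quantitative
#' scores as numbers; absent variables count as 0, i.e. the reference
#' level). The `lrpcm` method uses the fit's design.
#'
#' @param object coefficient vector or an [lrpcm()] fit.
#' @param profile,reference named lists (default method) or one-row
#'   data.frames (`lrpcm` method).
#' @param ... unused.
#' @return scalar deviation (logits).
#' @examples
#' profile_deviation(c(Ager = -0.596, `Women:Ager` = 0.0667),
#'                   profile = list(Ager = 10, Women = 1),
#'                   reference = list(Ager = 0, Women = 1))
#' @export
profile_deviation <- function(object, profile, reference, ...) {
  UseMethod("profile_deviation")
}

#' @rdname profile_deviation
#' @export
profile_deviation.default <- function(object, profile, reference = list(),
                                      ...) {
  stopifnot(is.numeric(object), !is.null(names(object)))
  term_value <- function(term, prof) {
    vars <- strsplit(term, ":", fixed = TRUE)[[1L]]
    prod(vapply(vars, function(v)
      if (is.null(prof[[v]])) 0 else as.numeric(prof[[v]]), numeric(1L)))
  }
  sum(vapply(names(object), function(tm)
    object[[tm]] * (term_value(tm, profile) - term_value(tm, reference)),
    numeric(1L)))
}

#' @rdname profile_deviation
#' @export
profile_deviation.lrpcm <- function(object, profile, reference, ...) {
  p <- predict(object, newdata = as.data.frame(profile), type = "mean")
  r <- predict(object, newdata = as.data.frame(reference), type = "mean")
  unname(p - r)
}
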