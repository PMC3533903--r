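#' Published latent regression estimates for the French SF-36 surveys
#'
#' Coefficient tables, variance/parameter summaries and age-trend series
#' as reported by a latent regression mixed PCM analysis of two large
#' French general-population SF-36 surveys (1995 and 2003; 26388 persons)
#' for the General Health (GH), Physical Functioning (PF) and Mental
#' Health (MH) dimensions. The raw survey data are not distributed; these
#' printed estimates serve as worked-example inputs, e.g. for
#' [tau_explained()] and [profile_deviation()]. Pooled regional terms are
#' encoded as single indicator names joined by underscores (e.g.
#' `West_SouthWest`); interactions use `:`.
#'
#' @param dimension optionally restrict to one of `"GH"`, `"PF"`, `"MH"`.
#' @return `published_sf36_estimates()`: list with `coefficients`
#'   (data.frame: dimension, section, term, estimate, se, p), `footers`
#'   (data.frame: dimension, sigma2_0, k0, sigma2, k, n) and `age_trends`
#'   (data.frame: dimension, band, deviation - the modelled latent-mean
#'   deviation of each age band from the youngest, reference-group men).
#' @examples
#' pub <- published_sf36_estimates("GH")
#' f <- pub$footers
#' tau_explained(f$sigma2_0, f$k0, f$sigma2, f$k, f$n)
#' @export
published_sf36_estimates <- function(dimension = NULL) {
  path <- function(f) system.file("extdata", f, package = "pcmreg",
                                  mustWork = TRUE)
  co <- utils::read.csv(path("published_fit_tables.csv"),
                        stringsAsFactors = FALSE)
  fo <- utils::read.csv(path("published_fit_footers.csv"),
                        stringsAsFactors = FALSE)
  ag <- utils::read.csv(path("published_age_trends.csv"),
                        stringsAsFactors = FALSE)
  if (!is.null(dimension)) {
    stopifnot(dimension %in% fo$dimension)
    co <- co[co$dimension == dimension, , drop = FALSE]
    fo <- fo[fo$dimension == dimension, , drop = FALSE]
    ag <- ag[ag$dimension == dimension, , drop = FALSE]
  }
  list(coefficients = co, footers = fo, age_trends = ag)
}

#' @rdname published_sf36_estimates
#' @param section `"mean"` or `"variance"`.
#' @return `published_coef_vector()`: named numeric vector of the
#'   dimension's non-intercept coefficients for the given model part,
#'   ready for [profile_deviation()].
#' @export
published_coef_vector <- function(dimension, section = "mean") {
  co <- published_sf36_estimates(dimension)$coefficients
  co <- co[co$section == section & co$term != "(Intercept)", , drop = FALSE]
  stats::setNames(co$estimate, co$term)
}
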