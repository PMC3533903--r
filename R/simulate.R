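#' Simulation configuration for survey-like questionnaire data
#'
#' Describes a synthetic population with the statistical structure the
#' analysis assumes: person covariates drawn from stated frequencies, a
#' latent trait `theta_n ~ N(mu_n, sigma2_n)` whose mean and variance are
#' linear in covariates,
#' `mu_n = mu* + X_n beta` and `sigma2_n = sigma2* + Z_n gamma`,
#' PCM response generation from true item thresholds, optional uniform
#' threshold shifts for selected covariate levels (DIF), and optional
#' missingness that may depend on the latent trait.
#'
#' The default configuration emulates a large French general-population
#' SF-36 survey pair: N = 26388; gender 46.5/53.5; seven age bands; nine
#' regions with the published regional frequencies; two survey years with
#' 13.9/86.1 weights; a five-item, five-category General-Health-like scale;
#' and mean/variance coefficients of the size reported for the General
#' Health latent trait (women -0.21, 2003 -0.14, quantitative age -0.035
#' per recoded-age unit, regional effects up to 0.2 in magnitude;
#' reference variance 1.41 with small negative age and survey effects).
#'
#' @param N number of persons.
#' @param bank an [item_bank()] of true thresholds.
#' @param covariate_levels named list; element = named numeric vector of
#'   level frequencies (must sum to 1).
#' @param transform function(data.frame) -> data.frame adding derived
#'   numeric covariates (e.g. a recoded quantitative age) before the design
#'   matrices are built.
#' @param mean_formula,var_formula one-sided formulas for the mean and
#'   variance design matrices.
#' @param beta,gamma named coefficient vectors; names must match columns of
#'   the corresponding `model.matrix` (the reference group is absorbed into
#'   `mu_star`/`sigma2_star`).
#' @param mu_star,sigma2_star reference-group mean and variance.
#' @param dif_offsets list of `list(item=, factor=, levels=, offset=)`:
#'   persons with those factor levels get `offset` added to every threshold
#'   of `item`.
#' @param missingness `list(type = "none")`, `list(type = "mcar", rate=)`,
#'   or `list(type = "informative", rate=, slope=)`; the informative
#'   mechanism makes a cell missing with probability
#'   `plogis(a - slope * theta_n)`, `a` calibrated to the target overall
#'   rate, so low-trait persons are more often missing.
#' @param seed integer seed used by [simulate_qol()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(N = 26388,
                       bank = default_gh_bank(),
                       covariate_levels = default_covariate_levels(),
                       transform = default_age_transform(),
                       mean_formula = ~ gender + year + ager + region,
                       var_formula = ~ year + ager + region,
                       beta = default_gh_beta(),
                       gamma = default_gh_gamma(),
                       mu_star = 0.82, sigma2_star = 1.41,
                       dif_offsets = list(),
                       missingness = list(type = "none"),
                       seed = 1L) {
  stopifnot(N >= 0, inherits(bank, "item_bank"))
  for (f in names(covariate_levels)) {
    fr <- covariate_levels[[f]]
    if (abs(sum(fr) - 1) > 1e-8)
      stop("frequencies of factor ", f, " must sum to 1")
    if (any(fr < 0)) stop("negative frequency in factor ", f)
  }
  structure(list(N = as.integer(N), bank = bank,
                 covariate_levels = covariate_levels, transform = transform,
                 mean_formula = mean_formula, var_formula = var_formula,
                 beta = beta, gamma = gamma, mu_star = mu_star,
                 sigma2_star = sigma2_star, dif_offsets = dif_offsets,
                 missingness = missingness, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_covariate_levels <- function() {
  list(
    gender = c(Men = 0.465, Women = 0.535),
    age_band = c("18-24" = 0.14, "25-34" = 0.18, "35-44" = 0.17,
                 "45-54" = 0.16, "55-64" = 0.14, "65-74" = 0.11,
                 "75-84" = 0.10),
    region = c("ParisBasin" = 0.21, "North" = 0.10, "East" = 0.08,
               "EasternParisBasin" = 0.15, "WesternParisBasin" = 0.07,
               "West" = 0.11, "SouthWest" = 0.08, "SouthEast" = 0.09,
               "MediterraneanBasin" = 0.11),
    year = c("1995" = 0.139, "2003" = 0.861))
}

# GH-like quantitative age scores per band (reference band scored 0)
gh_age_scores <- c("18-24" = 0, "25-34" = 2, "35-44" = 12, "45-54" = 17,
                   "55-64" = 24, "65-74" = 32, "75-84" = 40)

#' @rdname sim_config
#' @export
default_age_transform <- function(scores = gh_age_scores) {
  force(scores)
  function(d) {
    if ("age_band" %in% names(d))
      d$ager <- unname(scores[as.character(d$age_band)])
    d
  }
}

#' @rdname sim_config
#' @export
default_gh_bank <- function() {
  locs <- c(-0.8, -0.3, 0, 0.4, 0.9)
  steps <- c(-1.5, -0.5, 0.5, 1.5)
  item_bank(stats::setNames(lapply(locs, function(l) l + steps),
                            c("GH1", "GH11a", "GH11b", "GH11c", "GH11d")))
}

#' @rdname sim_config
#' @export
default_gh_beta <- function() {
  c(genderWomen = -0.21, year2003 = -0.14, ager = -0.0349,
    regionEast = -0.20, regionWest = 0.13, regionSouthWest = -0.07,
    regionNorth = 0, regionEasternParisBasin = 0,
    regionWesternParisBasin = 0, regionSouthEast = 0,
    regionMediterraneanBasin = 0)
}

#' @rdname sim_config
#' @export
default_gh_gamma <- function() {
  c(year2003 = -0.15, ager = -0.0068, regionEast = -0.23,
    regionSouthWest = -0.13, regionNorth = 0, regionEasternParisBasin = 0,
    regionWesternParisBasin = 0, regionWest = 0, regionSouthEast = 0,
    regionMediterraneanBasin = 0)
}

#' Draw person covariates
#'
#' Factor levels are drawn independently per person from the configured
#' frequencies; derived numeric covariates are added by the config's
#' `transform`.
#'
#' @param config a [sim_config()].
#' @return data.frame with `person_id` and one column per factor.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cl <- config$covariate_levels
  d <- data.frame(person_id = seq_len(config$N))
  for (f in names(cl)) {
    lev <- names(cl[[f]])
    d[[f]] <- factor(if (config$N) sample(lev, config$N, TRUE, prob = cl[[f]])
                     else character(), levels = lev)
  }
  if (is.function(config$transform)) d <- config$transform(d)
  d
}

design_part <- function(formula, data, coefs, label) {
  X <- stats::model.matrix(formula, data = data)
  miss <- setdiff(names(coefs), colnames(X))
  if (length(miss))
    stop(label, " coefficient(s) not in design: ", paste(miss, collapse = ", "))
  drop(X[, names(coefs), drop = FALSE] %*% coefs)
}

#' Draw latent traits
#'
#' `theta_n ~ N(mu* + X_n beta, sigma2* + Z_n gamma)` independently.
#' Configurations implying a non-positive variance for any person are
#' rejected.
#'
#' @param config a [sim_config()].
#' @param covariates output of [simulate_covariates()].
#' @return list with numeric vectors `theta`, `mu`, `sigma2`.
#' @export
simulate_latent <- function(config, covariates) {
  stopifnot(inherits(config, "sim_config"))
  mu <- config$mu_star
  s2 <- config$sigma2_star
  if (length(config$beta))
    mu <- mu + design_part(config$mean_formula, covariates, config$beta,
                           "mean")
  if (length(config$gamma))
    s2 <- s2 + design_part(config$var_formula, covariates, config$gamma,
                           "variance")
  mu <- rep_len(mu, config$N); s2 <- rep_len(s2, config$N)
  if (config$N && any(s2 <= 0))
    stop("configuration implies non-positive latent variance for ",
         sum(s2 <= 0), " person(s)")
  list(theta = stats::rnorm(config$N, mu, sqrt(s2)), mu = mu, sigma2 = s2)
}

person_offsets <- function(config, covariates, item_id) {
  off <- numeric(config$N)
  for (e in config$dif_offsets) {
    if (e$item != item_id) next
    off <- off + e$offset * (as.character(covariates[[e$factor]]) %in% e$levels)
  }
  off
}

#' Draw PCM responses
#'
#' Each response is drawn from the PCM category distribution at the
#' person's trait value, with the item's base thresholds shifted by any DIF
#' offsets that apply to the person.
#'
#' @param config a [sim_config()].
#' @param theta numeric vector of trait values.
#' @param covariates covariate table (used only for DIF offsets).
#' @return integer matrix, persons x items.
#' @export
simulate_responses <- function(config, theta, covariates) {
  stopifnot(length(theta) == config$N)
  ids <- names(config$bank$delta)
  out <- matrix(NA_integer_, config$N, length(ids),
                dimnames = list(NULL, ids))
  for (id in ids) {
    delta <- config$bank$delta[[id]]
    off <- person_offsets(config, covariates, id)
    for (o in unique(off)) {
      sel <- off == o
      out[sel, id] <- pcm_draw(theta[sel], delta + o)
    }
  }
  out
}

#' Apply a missingness mechanism
#'
#' `mcar`: each cell independently missing at the given rate.
#' `informative`: cell missing with probability `plogis(a - slope*theta_n)`,
#' with `a` calibrated so the overall expected rate matches `rate`; a
#' positive slope makes low-trait persons more often missing.
#'
#' @param responses response matrix.
#' @param theta latent trait vector.
#' @param mechanism see [sim_config()].
#' @return the matrix with entries set to `NA`.
#' @export
apply_missingness <- function(responses, theta, mechanism) {
  type <- mechanism$type %||% "none"
  if (type == "none") return(responses)
  N <- nrow(responses); J <- ncol(responses)
  if (type == "mcar") {
    r <- mechanism$rate
    if (!is.numeric(r) || r < 0 || r >= 1) stop("mcar rate must be in [0,1)")
    responses[matrix(stats::runif(N * J) < r, N, J)] <- NA
    return(responses)
  }
  if (type == "informative") {
    r <- mechanism$rate; s <- mechanism$slope
    if (!is.numeric(r) || r < 0 || r >= 1) stop("rate must be in [0,1)")
    a <- stats::uniroot(function(a) mean(stats::plogis(a - s * theta)) - r,
                        c(-50, 50))$root
    p <- stats::plogis(a - s * theta)
    responses[matrix(stats::runif(N * J), N, J) < p] <- NA
    return(responses)
  }
  stop("unknown missingness type: ", type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a complete synthetic dataset
#'
#' Runs the full generator (covariates, latent traits, PCM responses,
#' missingness) deterministically under the config's seed.
#'
#' @param config a [sim_config()].
#' @return list with `responses`, `covariates`, `theta`, `mu`, `sigma2`,
#'   `config`.
#' @export
simulate_qol <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  covariates <- simulate_covariates(config)
  lat <- simulate_latent(config, covariates)
  responses <- simulate_responses(config, lat$theta, covariates)
  responses <- apply_missingness(responses, lat$theta, config$missingness)
  list(responses = responses, covariates = covariates, theta = lat$theta,
       mu = lat$mu, sigma2 = lat$sigma2, config = config)
}

#' Read a simulation configuration from a YAML file
#'
#' Flat key-value representation of [sim_config()]: scalar fields
#' (`N`, `mu_star`, `sigma2_star`, `seed`) as keys; `items` as a map of
#' item id to threshold vector; `covariate_levels` as a map of factor to
#' level-frequency map; `beta`/`gamma` as coefficient maps;
#' `mean_formula`/`var_formula` as formula strings; `dif_offsets` as a
#' list of `{item, factor, levels, offset}` maps; `missingness` as a
#' `{type, rate, slope}` map. Omitted fields keep their defaults.
#'
#' @param path YAML file path.
#' @return a [sim_config()].
#' @export
sim_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `N` key as boolean FALSE; accept either spelling
  if (!is.null(y[["FALSE"]]) && is.null(y$N)) y$N <- y[["FALSE"]]
  args <- list()
  for (f in c("N", "mu_star", "sigma2_star", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$items))
    args$bank <- item_bank(lapply(y$items, as.numeric))
  if (!is.null(y$covariate_levels))
    args$covariate_levels <- lapply(y$covariate_levels, unlist)
  for (f in c("beta", "gamma"))
    if (!is.null(y[[f]])) args[[f]] <- unlist(y[[f]])
  for (f in c("mean_formula", "var_formula"))
    if (!is.null(y[[f]])) args[[f]] <- stats::as.formula(y[[f]])
  if (!is.null(y$dif_offsets)) args$dif_offsets <- y$dif_offsets
  if (!is.null(y$missingness)) args$missingness <- y$missingness
  do.call(sim_config, args)
}

#' Item specifications matching a simulated bank
#'
#' Simulated responses are generated on the analysis scale (higher code =
#' more of the trait), so their [item_spec()]s carry no reversal.
#'
#' @param bank an [item_bank()].
#' @return list of [item_spec()].
#' @export
item_specs_from_bank <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  lapply(stats::setNames(names(bank$delta), names(bank$delta)),
         function(id) item_spec(id, length(bank$delta[[id]]) + 1L))
}

#' Write a simulated dataset as the package's CSV schemas
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of file paths written.
#' @export
simulate_dataset <- function(config, out_dir) {
  dat <- simulate_qol(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- paste0("seed=", config$seed, " N=", config$N)
  rp <- file.path(out_dir, "responses.csv")
  cp <- file.path(out_dir, "covariates.csv")
  write_table_csv(dat$responses, rp, comment = meta)
  write_table_csv(dat$covariates, cp, comment = meta)
  invisible(list(responses = rp, covariates = cp))
}
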