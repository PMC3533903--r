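#' Pipeline configuration
#'
#' All analysis thresholds in one place, defaulting to the conventional
#' values: 5% significance and 0.1 location difference for the DIF flag
#' rule, H cutoffs 0.3 (scale and item) and 0 (pairs), Crit cutoff 40,
#' effective fit-test sample 500, 21 quadrature nodes.
#'
#' @param alpha DIF / selection significance level.
#' @param max_diff DIF location-difference threshold.
#' @param h_cut,hjk_cut,crit_cut Mokken thresholds.
#' @param N0 effective sample size of the rescaled fit test.
#' @param nodes quadrature order for calibration and latent regression.
#' @param min_stratum smallest stratum used in the DIF scan.
#' @param stage1_factors,stage1_test,stage2_factors DIF scan factor sets.
#' @param age_factor name of the ordinal age variable.
#' @param mean_terms,var_terms candidate model terms (default: the four
#'   survey factors for both parts).
#' @param super_groups optional named list of locally dependent item
#'   groups for [build_super_items()].
#' @param aic_margin largest AIC increase tolerated when replacing age
#'   dummies by the quantitative recoding.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, max_diff = 0.1, h_cut = 0.3,
                            hjk_cut = 0, crit_cut = 40, N0 = 500L,
                            nodes = 21L, min_stratum = 30L,
                            stage1_factors = c("gender", "age_band", "year"),
                            stage1_test = c("gender", "age_band"),
                            stage2_factors = c("region", "year"),
                            age_factor = "age_band",
                            mean_terms = c("gender", "age_band", "region",
                                           "year"),
                            var_terms = c("gender", "age_band", "region",
                                          "year"),
                            super_groups = NULL, aic_margin = 0) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full questionnaire analysis pipeline
#'
#' Orchestrates the three analysis stages on one questionnaire dimension:
#' (1) DIF detection - reverse coding, super-item construction, a
#' stratum-wise PCM scan for gender/age DIF, then a region/year scan
#' adjusted for the first stage; (2) nonparametric IRT assumption checks
#' (Loevinger H, monotonicity Crit); (3) latent-trait analysis -
#' pseudo-item expansion over all detected DIF, marginal-ML calibration
#' with the trait mean fixed at 0, item-trait fit tests at full and
#' moderate effective sample size, backward-selected latent regression of
#' the trait mean and variance, quantitative age recoding, and the
#' explained-variance rate tau.
#'
#' The pipeline is a pure function of its inputs, configuration and seed;
#' reports are written as CSV with a one-line `#` metadata header when
#' `out_dir` is given, and the stage-1 location table is cached there and
#' reused when `resume = TRUE`.
#'
#' @param responses persons x items matrix (raw codes).
#' @param covariates person covariate data.frame (factors named as in the
#'   config's factor sets).
#' @param items list of [item_spec()] describing the raw items.
#' @param config a [pipeline_config()].
#' @param out_dir optional report directory.
#' @param resume reuse cached stage-1 locations from `out_dir`.
#' @param seed recorded in the manifest and set before the run.
#' @return list of class `pipeline_result` with elements `dif_stage1`,
#'   `dif_stage2`, `dif_spec`, `mokken`, `calibration`, `fit_full`,
#'   `fit_rescaled`, `selection`, `age_recoding`, `tau`, `counts`,
#'   `manifest`.
#' @export
run_pipeline <- function(responses, covariates, items,
                         config = pipeline_config(), out_dir = NULL,
                         resume = FALSE, seed = 1L) {
  set.seed(seed)
  stopifnot(inherits(config, "pipeline_config"))
  responses <- validate_responses(responses, items)
  counts <- list(persons = nrow(responses), items_raw = ncol(responses))
  message("persons: ", nrow(responses), ", raw items: ", ncol(responses))

  ## stage 0: recode
  responses <- reverse_code(responses, items)
  if (!is.null(config$super_groups)) {
    si <- build_super_items(responses, config$super_groups, items)
    responses <- si$responses; items <- si$items
    message("after super-items: ", ncol(responses), " items")
  }
  counts$items_scored <- ncol(responses)

  ## stage 1 DIF: gender/age (year in the design)
  cache <- if (!is.null(out_dir))
    file.path(out_dir, "stage1_locations.csv") else NULL
  tab1 <- NULL
  if (resume && !is.null(cache) && file.exists(cache))
    tab1 <- read_location_table(cache)
  if (is.null(tab1))
    tab1 <- fit_strata_locations(responses, covariates,
                                 config$stage1_factors, config$min_stratum)
  rep1 <- weighted_anova_dif(tab1, factors = config$stage1_factors,
                             alpha = config$alpha,
                             max_diff = config$max_diff,
                             ordered_factors = config$age_factor)
  rep1 <- rep1[rep1$factor %in% config$stage1_test, , drop = FALSE]
  stage1 <- structure(list(report = rep1, table = tab1), class = "dif_scan")
  counts$strata_stage1 <- nrow(tab1$locations)
  message("stage-1 strata: ", nrow(tab1$locations), ", flags: ",
          sum(rep1$flag))

  ## stage 2 DIF: region/year adjusted for stage 1
  stage2 <- second_stage_region_year(
    responses, covariates, stage1, items,
    factors = config$stage2_factors, alpha = config$alpha,
    max_diff = config$max_diff, min_stratum = config$min_stratum)
  counts$strata_stage2 <- nrow(stage2$table$locations)
  message("stage-2 strata: ", nrow(stage2$table$locations), ", flags: ",
          sum(stage2$report$flag))

  ## stage 2b: Mokken checks on the scored (pre-pseudo-item) matrix
  mok <- mokken_report(responses)

  ## stage 3: pseudo-item expansion over all detected DIF
  all_flags <- rbind(stage1$report, stage2$report)
  spec <- dif_report_to_spec(all_flags)
  ex <- expand_pseudo_items(responses, covariates, spec, items)
  counts$pseudo_items <- ncol(ex$responses)
  message("items/pseudo-items analysed: ", ncol(ex$responses))

  ## calibration (trait mean fixed at 0) and fit tests
  cal <- calibrate_pcm(ex$responses, nodes = config$nodes)
  fit_full <- item_trait_chisq(ex$responses, cal$bank, prior_mean = 0,
                               prior_var = cal$sigma2)
  fit_resc <- rescale_statistic(fit_full, N0 = config$N0)

  ## latent regression with backward selection (mean first, then variance)
  sel <- backward_select(ex$responses, covariates, cal$bank,
                         mean_terms = config$mean_terms,
                         var_terms = config$var_terms,
                         alpha = config$alpha, nodes = config$nodes)

  ## quantitative age recoding, if the age factor survived
  recoding <- NULL
  if (config$age_factor %in% sel$mean_terms) {
    ab <- grep(paste0("^", config$age_factor), names(sel$fit$beta))
    co <- c(0, sel$fit$beta[ab])
    rc <- tryCatch(recode_age_quantitative(co), error = function(e) NULL)
    if (!is.null(rc)) {
      lv <- levels(factor(covariates[[config$age_factor]]))
      names(rc$scores) <- lv
      cov2 <- covariates
      cov2$ager <- rc$scores[as.character(cov2[[config$age_factor]])]
      sub <- function(terms) unique(gsub(config$age_factor, "ager",
                                         terms, fixed = TRUE))
      fit_q <- lrpcm(ex$responses, cov2,
                     mean = stats::reformulate(sub(sel$mean_terms)),
                     var = if (length(sel$var_terms))
                       stats::reformulate(sub(sel$var_terms)) else ~ 1,
                     bank = cal$bank, nodes = config$nodes)
      if (fit_q$AIC <= sel$fit$AIC + config$aic_margin) {
        sel$fit <- fit_q
        mean_fit_q <- lrpcm(ex$responses, cov2,
                            mean = stats::reformulate(sub(sel$mean_terms)),
                            var = ~ 1, bank = cal$bank,
                            nodes = config$nodes)
        sel$mean_fit <- mean_fit_q
        sel$mean_terms <- sub(sel$mean_terms)
        sel$var_terms <- sub(sel$var_terms)
        recoding <- rc
      }
    }
  }

  ## explained-variance rate: homoscedastic mean-model fit vs calibration
  k0 <- cal$k
  k <- k0 + length(sel$mean_fit$beta)
  tau <- tau_explained(cal$sigma2, k0, sel$mean_fit$gamma[[1L]], k, cal$n)

  manifest <- data.frame(
    key = c("seed", "persons", "items_analysed", "alpha", "max_diff",
            "h_cut", "crit_cut", "N0", "nodes", "tau"),
    value = c(seed, counts$persons, counts$pseudo_items, config$alpha,
              config$max_diff, config$h_cut, config$crit_cut, config$N0,
              config$nodes, round(tau, 6)))

  res <- structure(list(dif_stage1 = stage1, dif_stage2 = stage2,
                        dif_spec = spec, mokken = mok, calibration = cal,
                        fit_full = fit_full, fit_rescaled = fit_resc,
                        selection = sel, age_recoding = recoding,
                        tau = tau, counts = counts, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir, seed)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== Questionnaire analysis pipeline ==\n")
  cat("persons:", x$counts$persons, "; items/pseudo-items:",
      x$counts$pseudo_items, "\n")
  cat("DIF flags stage 1:", sum(x$dif_stage1$report$flag),
      "; stage 2:", sum(x$dif_stage2$report$flag), "\n")
  print(x$mokken)
  print(x$calibration)
  print(x$fit_rescaled)
  cat(sprintf("Explained-variance rate tau = %.1f%%\n", 100 * x$tau))
  invisible(x)
}

write_pipeline_reports <- function(res, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- paste0("seed=", seed)
  dif <- rbind(cbind(stage = 1L, res$dif_stage1$report),
               cbind(stage = 2L, res$dif_stage2$report))
  dif$diff <- round(dif$diff, 4); dif$p <- signif(dif$p, 4)
  write_table_csv(dif, file.path(out_dir, "dif_report.csv"), meta)
  write_table_csv(round(res$mokken$summary, 4),
                  file.path(out_dir, "mokken.csv"), meta)
  ff <- res$fit_full; fr <- res$fit_rescaled
  fit <- data.frame(scope = c("full", "rescaled"),
                    chisq = round(c(ff$total, fr$total), 2),
                    df = c(ff$df, fr$df), p = signif(c(ff$p, fr$p), 4),
                    n = c(ff$n, fr$rescaled_to %||% ff$n))
  write_table_csv(fit, file.path(out_dir, "fit_tests.csv"), meta)
  s <- summary(res$selection$fit)$coefficients
  s$estimate <- round(s$estimate, 4); s$se <- round(s$se, 4)
  s$z <- round(s$z, 2); s$p <- signif(s$p, 4)
  write_table_csv(s, file.path(out_dir, "coefficients.csv"), meta)
  write_table_csv(res$manifest, file.path(out_dir, "manifest.csv"), meta)
  write_location_table(res$dif_stage1$table,
                       file.path(out_dir, "stage1_locations.csv"), meta)
  invisible(out_dir)
}

write_location_table <- function(tab, path, comment = NULL) {
  df <- cbind(tab$strata, .n = tab$sizes, tab$locations)
  write_table_csv(df, path, comment)
}

read_location_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  nidx <- match(".n", names(df))
  strata <- df[, seq_len(nidx - 1L), drop = FALSE]
  for (f in names(strata)) strata[[f]] <- factor(strata[[f]])
  structure(list(locations = as.matrix(df[, -seq_len(nidx), drop = FALSE]),
                 sizes = df$.n, strata = strata),
            class = "location_table")
}
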