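#' Stratum-wise item locations
#'
#' Fits one PCM per stratum (every observed combination of the stratifying
#' factors) by pairwise conditional estimation and collects the item
#' locations under the sum-zero threshold constraint, together with the
#' stratum sizes. Strata smaller than `min_stratum` are dropped with a
#' warning; a failed stratum fit leaves its row missing.
#'
#' @param responses persons x items matrix.
#' @param covariates data.frame of person factors.
#' @param factors character vector of stratifying factor names.
#' @param min_stratum smallest stratum retained (default 30).
#' @return list of class `location_table`: `locations` (strata x items
#'   matrix), `sizes`, `strata` (data.frame of factor levels per row).
#' @export
fit_strata_locations <- function(responses, covariates, factors,
                                 min_stratum = 30L) {
  stopifnot(nrow(covariates) == nrow(responses),
            all(factors %in% names(covariates)))
  m <- stats::setNames(as.integer(apply(responses, 2L, max, na.rm = TRUE)),
                       colnames(responses))
  key <- interaction(covariates[factors], drop = TRUE, sep = "\r")
  levs <- levels(key)
  loc <- matrix(NA_real_, length(levs), ncol(responses),
                dimnames = list(NULL, colnames(responses)))
  sizes <- integer(length(levs))
  for (i in seq_along(levs)) {
    sel <- key == levs[i]
    sizes[i] <- sum(sel)
    if (sizes[i] < min_stratum) {
      warning("stratum ", gsub("\r", ":", levs[i]), " below size floor (",
              sizes[i], "), dropped", call. = FALSE)
      next
    }
    fit <- tryCatch(
      suppressWarnings(pce_fit(responses[sel, , drop = FALSE], m = m)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("PCE failed in stratum ", gsub("\r", ":", levs[i]),
              call. = FALSE)
      next
    }
    # items whose categories collapsed are not comparable across strata
    ok <- setdiff(names(fit$delta), names(fit$collapse_maps))
    loc[i, ok] <- item_locations(fit)[ok]
  }
  strata <- as.data.frame(do.call(rbind, strsplit(levs, "\r", fixed = TRUE)),
                          stringsAsFactors = FALSE)
  names(strata) <- factors
  for (f in factors)   # keep the covariates' level order (age bands etc.)
    strata[[f]] <- factor(strata[[f]], levels = levels(factor(covariates[[f]])))
  keep <- sizes >= min_stratum
  structure(list(locations = loc[keep, , drop = FALSE],
                 sizes = sizes[keep],
                 strata = strata[keep, , drop = FALSE]),
            class = "location_table")
}

#' @export
print.location_table <- function(x, ...) {
  cat("Stratum-wise item locations:", nrow(x$locations), "strata x",
      ncol(x$locations), "items\n")
  df <- cbind(x$strata, n = x$sizes, round(x$locations, 3))
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("...\n")
  invisible(x)
}

#' DIF scan by weighted ANOVA on item locations
#'
#' For each item, a main-effects least-squares ANOVA of the stratum-wise
#' item locations on the stratifying factors, weighted by the stratum
#' sizes. Per item and factor the scan reports the F-test p-value, the
#' maximum pairwise difference of the weighted factor-level mean locations,
#' and a flag: DIF is called large when `p < alpha` AND the maximum
#' difference exceeds `max_diff` (defaults 0.05 and 0.1). Flagged
#' item-factor combinations get a level grouping from [collapse_levels()];
#' a grouping that collapses to a single group rescinds the flag.
#'
#' @param table a [fit_strata_locations()] table.
#' @param factors factors to test (default: all stratifying factors).
#' @param alpha significance level of the flag rule.
#' @param max_diff location-difference threshold of the flag rule.
#' @param ordered_factors names of factors whose levels are ordered (e.g.
#'   age); others are sorted by mean location before level collapsing.
#' @return data.frame of class `dif_report`: item, factor, `diff` (max
#'   location difference), `p`, `flag`, `grouping` (string, `""` when not
#'   flagged).
#' @export
weighted_anova_dif <- function(table, factors = names(table$strata),
                               alpha = 0.05, max_diff = 0.1,
                               ordered_factors = "age_band") {
  stopifnot(inherits(table, "location_table"))
  out <- list()
  for (item in colnames(table$locations)) {
    y <- table$locations[, item]
    ok <- !is.na(y)
    df <- cbind(loc = y, table$strata, w = table$sizes)[ok, , drop = FALSE]
    constant <- diff(range(df$loc)) < 1e-10
    fml <- stats::reformulate(factors, response = "loc")
    fit <- stats::lm(fml, data = df, weights = w)
    dr <- if (constant) NULL else
      tryCatch(stats::drop1(fit, test = "F"), error = function(e) NULL)
    for (f in factors) {
      pval <- if (constant) 1 else if (!is.null(dr) && f %in% rownames(dr))
        dr[f, "Pr(>F)"] else NA_real_
      means <- weighted_level_means(df$loc, df[[f]], df$w)
      dmax <- if (length(means) >= 2L) max(dist(means)) else 0
      flag <- isTRUE(pval < alpha) && dmax > max_diff
      grouping <- ""
      if (flag) {
        grp <- collapse_levels(means, ordered = f %in% ordered_factors,
                               max_spread = max_diff)
        if (length(grp) < 2L) flag <- FALSE       # no split survives
        else grouping <- paste(vapply(grp, group_label, character(1L)),
                               collapse = " / ")
      }
      out[[length(out) + 1L]] <- data.frame(
        item = item, factor = f, diff = dmax, p = pval, flag = flag,
        grouping = grouping)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("dif_report", "data.frame")
  res
}

weighted_level_means <- function(y, f, w) {
  lv <- if (is.factor(f)) intersect(levels(f), unique(as.character(f)))
        else unique(as.character(f))
  stats::setNames(vapply(lv, function(l) {
    sel <- as.character(f) == l
    sum(y[sel] * w[sel]) / sum(w[sel])
  }, numeric(1L)), lv)
}

#' Collapse factor levels by location proximity
#'
#' Greedy merging of (ordered) adjacent levels while the merged group's
#' location spread stays within `max_spread`. Unordered factors are first
#' sorted by mean location. Returns the partition as a list of level
#' vectors.
#'
#' @param level_means named numeric vector of level mean locations (in
#'   level order for ordered factors).
#' @param ordered logical; keep the given level order (e.g. age bands)?
#' @param max_spread largest within-group location spread allowed.
#' @return list of character vectors partitioning the levels.
#' @export
collapse_levels <- function(level_means, ordered = TRUE, max_spread = 0.1) {
  if (!ordered) level_means <- sort(level_means)
  groups <- list()
  cur <- names(level_means)[1L]
  cur_vals <- level_means[1L]
  for (i in seq_along(level_means)[-1L]) {
    cand <- c(cur_vals, level_means[i])
    if (max(cand) - min(cand) <= max_spread) {
      cur <- c(cur, names(level_means)[i]); cur_vals <- cand
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- names(level_means)[i]; cur_vals <- level_means[i]
    }
  }
  groups[[length(groups) + 1L]] <- cur
  groups
}

#' Stage-1 DIF scan (gender/age style factors)
#'
#' Convenience wrapper: stratifies on the given factors, fits per-stratum
#' PCMs and runs the weighted ANOVA scan.
#'
#' @inheritParams fit_strata_locations
#' @inheritParams weighted_anova_dif
#' @param test_factors factors whose DIF is flagged (default: all
#'   stratifying factors).
#' @return list of class `dif_scan`: `report` (a `dif_report`), `table`
#'   (the location table).
#' @export
dif_scan <- function(responses, covariates, factors,
                     test_factors = factors, alpha = 0.05, max_diff = 0.1,
                     min_stratum = 30L, ordered_factors = "age_band") {
  tab <- fit_strata_locations(responses, covariates, factors, min_stratum)
  rep <- weighted_anova_dif(tab, factors = factors, alpha = alpha,
                            max_diff = max_diff,
                            ordered_factors = ordered_factors)
  rep <- rep[rep$factor %in% test_factors, , drop = FALSE]
  structure(list(report = rep, table = tab), class = "dif_scan")
}

#' @export
print.dif_scan <- function(x, ...) {
  cat("DIF scan over", nrow(x$table$locations), "strata\n")
  r <- x$report
  r$diff <- round(r$diff, 3); r$p <- signif(r$p, 3)
  print(r, row.names = FALSE)
  invisible(x)
}

#' Turn flagged DIF rows into a pseudo-item specification
#'
#' @param report a `dif_report` (or `dif_scan`).
#' @return a [dif_spec()] with one split per flagged item-factor row.
#' @export
dif_report_to_spec <- function(report) {
  if (inherits(report, "dif_scan")) report <- report$report
  rows <- report[report$flag, , drop = FALSE]
  entries <- lapply(seq_len(nrow(rows)), function(i) {
    groups <- strsplit(strsplit(rows$grouping[i], " / ", fixed = TRUE)[[1L]],
                       "+", fixed = TRUE)
    dif_split(rows$item[i], rows$factor[i], groups)
  })
  do.call(dif_spec, entries)
}

#' Stage-2 DIF scan for region and year, adjusted for stage-1 DIF
#'
#' Expands the responses into pseudo-items according to the stage-1 DIF
#' report, estimates item locations per region x year stratum, averages a
#' split item's pseudo-item locations with observation-count weights back
#' to one location per original item, and applies the same weighted-ANOVA
#' flag rule with region and year as factors.
#'
#' @param responses persons x items matrix (before pseudo-item expansion).
#' @param covariates person covariates including region and year factors.
#' @param stage1 a `dif_report`/`dif_scan` from the first stage.
#' @param items list of [item_spec()] for the responses.
#' @param factors the stage-2 stratifying factors,
#'   default `c("region", "year")`.
#' @inheritParams weighted_anova_dif
#' @inheritParams fit_strata_locations
#' @return list of class `dif_scan` (report rows for the stage-2 factors).
#' @export
second_stage_region_year <- function(responses, covariates, stage1, items,
                                     factors = c("region", "year"),
                                     alpha = 0.05, max_diff = 0.1,
                                     min_stratum = 30L) {
  spec <- dif_report_to_spec(stage1)
  ex <- expand_pseudo_items(responses, covariates, spec, items)
  tab <- fit_strata_locations(ex$responses, covariates, factors, min_stratum)
  # pool pseudo-item locations back to their source item
  src <- vapply(ex$items, function(s)
    if (length(s$parent_ids)) s$parent_ids[1L] else s$item_id, character(1L))
  pooled <- matrix(NA_real_, nrow(tab$locations), length(unique(src)),
                   dimnames = list(NULL, unique(src)))
  for (it in unique(src)) {
    cols <- names(src)[src == it]
    sub <- tab$locations[, cols, drop = FALSE]
    wts <- vapply(cols, function(cl) sum(!is.na(ex$responses[, cl])),
                  numeric(1L))
    pooled[, it] <- apply(sub, 1L, function(r) {
      ok <- !is.na(r)
      if (!any(ok)) NA_real_ else sum(r[ok] * wts[ok]) / sum(wts[ok])
    })
  }
  tab$locations <- pooled
  rep <- weighted_anova_dif(tab, factors = factors, alpha = alpha,
                            max_diff = max_diff, ordered_factors = character())
  structure(list(report = rep, table = tab), class = "dif_scan")
}
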