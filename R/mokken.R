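#' Loevinger scalability coefficients
#'
#' Computes the three kinds of Loevinger H coefficients used to assess the
#' fit of a Monotonely Homogeneous Mokken model to polytomous items:
#' per-pair `H_jk = Cov(Y_j, Y_k) / Cov_max(Y_j, Y_k)`, where `Cov_max` is
#' the covariance attained by the maximally concordant (comonotone) joint
#' distribution with the same margins; per-item `H_j` and global `H`
#' aggregate the covariance numerators and denominators over the pairs
#' involving item j / over all pairs. Pairwise-complete cases are used per
#' pair.
#'
#' @param responses persons x items matrix of codes, `NA` = missing.
#' @return list of class `scalability_report`: `H`, `H_j` (named vector),
#'   `H_jk` (matrix, `NA` diagonal), `cov` and `cov_max` matrices, and
#'   `undefined_pairs` (zero-variance pairs, reported as `NA`).
#' @export
loevinger_h <- function(responses) {
  responses <- as.matrix(responses)
  J <- ncol(responses)
  if (J < 2L) stop("need at least 2 items")
  ids <- colnames(responses)
  if (is.null(ids)) ids <- paste0("item", seq_len(J))
  CV <- CM <- matrix(NA_real_, J, J, dimnames = list(ids, ids))
  for (j in seq_len(J - 1L)) for (k in (j + 1L):J) {
    yj <- responses[, j]; yk <- responses[, k]
    keep <- !is.na(yj) & !is.na(yk)
    if (sum(keep) < 2L) next
    yj <- yj[keep]; yk <- yk[keep]
    cv <- stats::cov(yj, yk) * (length(yj) - 1) / length(yj)  # ML covariance
    cm <- covmax_comonotone(yj, yk)
    CV[j, k] <- CV[k, j] <- cv
    CM[j, k] <- CM[k, j] <- cm
  }
  Hjk <- CV / CM
  Hjk[CM == 0] <- NA
  Hj <- rowSums(CV, na.rm = TRUE) / rowSums(CM, na.rm = TRUE)
  H <- sum(CV[upper.tri(CV)], na.rm = TRUE) /
    sum(CM[upper.tri(CM)], na.rm = TRUE)
  structure(list(H = H, H_j = Hj, H_jk = Hjk, cov = CV, cov_max = CM,
                 undefined_pairs = which(CM == 0, arr.ind = TRUE)),
            class = "scalability_report")
}

# Maximum covariance over joint distributions with the observed margins:
# attained by the comonotone coupling (pair the sorted quantiles).
covmax_comonotone <- function(yj, yk) {
  n <- length(yj)
  mean(sort(yj) * sort(yk)) - mean(yj) * mean(yk)
}

#' @export
print.scalability_report <- function(x, ...) {
  cat(sprintf("Loevinger scalability: H = %.3f, min(H_j) = %.3f, min(H_jk) = %.3f\n",
              x$H, min(x$H_j, na.rm = TRUE),
              min(x$H_jk, na.rm = TRUE)))
  invisible(x)
}

#' Monotone homogeneity fit rule
#'
#' The scale is taken to fit a Monotonely Homogeneous Mokken model when
#' `H > 0.3`, every `H_j > 0.3` and every `H_jk > 0` (strict inequalities).
#'
#' @param report a [loevinger_h()] report.
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   violated conditions, empty when passing).
#' @export
check_mhm_fit <- function(report) {
  stopifnot(inherits(report, "scalability_report"))
  reasons <- character()
  if (!(report$H > 0.3)) reasons <- c(reasons, "H <= 0.3")
  bad_j <- names(report$H_j)[!(report$H_j > 0.3)]
  if (length(bad_j))
    reasons <- c(reasons, paste0("H_j <= 0.3: ", paste(bad_j, collapse = ", ")))
  hjk <- report$H_jk[upper.tri(report$H_jk)]
  if (any(!is.na(hjk) & hjk <= 0)) reasons <- c(reasons, "some H_jk <= 0")
  if (any(is.na(hjk))) reasons <- c(reasons, "some H_jk undefined")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Monotonicity check with Crit composite
#'
#' For one item, persons are grouped by their rest score (total over the
#' OTHER items, complete cases for the item set), adjacent rest-score
#' values being merged until each group holds at least `min_group_size`
#' persons. For every item step `l` the estimated step-response function
#' `P(Y >= l | rest-score group)` is compared across all ordered group
#' pairs; a decrease larger than `minvi` is a violation, with a pooled
#' two-proportion z statistic. The `Crit` composite is the MSP-style
#' weighted sum
#' \deqn{Crit = 50(0.3 - H_j) + \sqrt{\#vi} + 100\,\#vi/\#ac + 100\,maxvi +
#'   10\sqrt{\sum vi} + 1000 \sum vi/\#ac + 5\,maxz + 10\sqrt{\sum z} +
#'   100 \sum z/\#ac,}
#' where `#ac` is the number of active comparisons; it is reported raw (not
#' floored at 0), so items with `H_j > 0.3` and no violations get negative
#' values. Values below 40 are conventionally taken as acceptable.
#'
#' @param responses persons x items matrix.
#' @param item column name (or index) of the item checked.
#' @param min_group_size minimum rest-score group size; default
#'   `min(N/10, 500)`.
#' @param minvi smallest decrease counted as a violation.
#' @return list with `n_violations`, `max_violation`, `z` (vector of z
#'   statistics of the violations), `max_z`, `Crit`, `n_groups`,
#'   `n_active`, `H_j`.
#' @export
monotonicity_check <- function(responses, item, min_group_size = NULL,
                               minvi = 0.03) {
  responses <- as.matrix(responses)
  if (is.numeric(item)) item <- colnames(responses)[item]
  keep <- rowSums(is.na(responses)) == 0L    # listwise for rest scores
  Y <- responses[keep, , drop = FALSE]
  N <- nrow(Y)
  if (is.null(min_group_size)) min_group_size <- min(ceiling(N / 10), 500)
  y <- Y[, item]
  rest <- rowSums(Y[, setdiff(colnames(Y), item), drop = FALSE])
  groups <- merge_rest_groups(rest, min_group_size)
  G <- length(unique(groups))
  hj <- loevinger_h(Y)$H_j[[item]]
  if (G < 2L) {
    return(list(n_violations = 0L, max_violation = 0, z = numeric(),
                max_z = 0, Crit = 50 * (0.3 - hj), n_groups = G,
                n_active = 0L, H_j = hj))
  }
  m <- max(y)
  ng <- tabulate(groups, G)
  vi <- numeric(); zs <- numeric(); n_active <- 0L
  for (l in 1:m) {
    p <- vapply(1:G, function(g) mean(y[groups == g] >= l), numeric(1L))
    for (a in 1:(G - 1L)) for (b in (a + 1L):G) {
      n_active <- n_active + 1L
      d <- p[a] - p[b]
      if (d > minvi) {
        vi <- c(vi, d)
        pool <- (p[a] * ng[a] + p[b] * ng[b]) / (ng[a] + ng[b])
        sep <- sqrt(pool * (1 - pool) * (1 / ng[a] + 1 / ng[b]))
        zs <- c(zs, if (sep > 0) d / sep else 0)
      }
    }
  }
  crit <- 50 * (0.3 - hj)
  if (length(vi)) {
    crit <- crit + sqrt(length(vi)) + 100 * length(vi) / n_active +
      100 * max(vi) + 10 * sqrt(sum(vi)) + 1000 * sum(vi) / n_active +
      5 * max(zs) + 10 * sqrt(sum(zs)) + 100 * sum(zs) / n_active
  }
  list(n_violations = length(vi), max_violation = if (length(vi)) max(vi) else 0,
       z = zs, max_z = if (length(zs)) max(zs) else 0, Crit = crit,
       n_groups = G, n_active = n_active, H_j = hj)
}

# merge adjacent rest-score values until every group >= min_size
merge_rest_groups <- function(rest, min_size) {
  vals <- sort(unique(rest))
  counts <- vapply(vals, function(v) sum(rest == v), numeric(1L))
  grp_of_val <- integer(length(vals))
  g <- 1L; acc <- 0
  for (i in seq_along(vals)) {
    grp_of_val[i] <- g
    acc <- acc + counts[i]
    if (acc >= min_size && i < length(vals)) { g <- g + 1L; acc <- 0 }
  }
  # fold a trailing undersized group into its neighbour
  if (acc < min_size && g > 1L) grp_of_val[grp_of_val == g] <- g - 1L
  grp_of_val <- match(grp_of_val, unique(grp_of_val))
  grp_of_val[match(rest, vals)]
}

#' Nonparametric IRT assumption report for a scale
#'
#' Runs [loevinger_h()], [check_mhm_fit()] and [monotonicity_check()] for
#' every item, mirroring the usual summary columns H, min(H_j), min(H_jk),
#' max(Crit).
#'
#' @inheritParams monotonicity_check
#' @return list of class `mokken_report` with the scalability report, the
#'   fit rule outcome, per-item monotonicity results and a one-row summary
#'   data.frame.
#' @export
mokken_report <- function(responses, min_group_size = NULL, minvi = 0.03) {
  rep_h <- loevinger_h(responses)
  fit <- check_mhm_fit(rep_h)
  mono <- lapply(colnames(responses), function(it)
    monotonicity_check(responses, it, min_group_size, minvi))
  names(mono) <- colnames(responses)
  summary <- data.frame(
    H = rep_h$H, min_Hj = min(rep_h$H_j, na.rm = TRUE),
    min_Hjk = min(rep_h$H_jk, na.rm = TRUE),
    max_Crit = max(vapply(mono, `[[`, numeric(1L), "Crit")),
    mhm_pass = fit$pass)
  structure(list(scalability = rep_h, fit = fit, monotonicity = mono,
                 summary = summary), class = "mokken_report")
}

#' @export
print.mokken_report <- function(x, ...) {
  cat("Nonparametric IRT (Mokken) checks\n")
  print(x$summary, row.names = FALSE)
  if (!x$fit$pass)
    cat("violations:", paste(x$fit$reasons, collapse = "; "), "\n")
  invisible(x)
}
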