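#' Backward elimination for the latent regression mixed PCM
#'
#' Two-phase backward selection reproducing the usual reporting order:
#' the mean model is pruned first (variance held at the intercept-only
#' start), then the variance model is pruned with the selected mean model
#' fixed. In each round the removable term with the largest Wald p-value
#' `>= alpha` whose removal does not increase the AIC is dropped and the
#' model refitted; the hierarchy is respected (an interaction is removable
#' before its main effects, a main effect only when no retained
#' interaction contains it). Multi-column terms (factors) get a multi-df
#' Wald chi-square p-value.
#'
#' @inheritParams lrpcm
#' @param mean_terms character vector of candidate mean-model term labels
#'   (may include `a:b` interactions).
#' @param var_terms candidate variance-model term labels.
#' @param alpha removal significance threshold.
#' @param verbose print the removal log as it happens.
#' @param ... passed to [lrpcm()].
#' @return list of class `lrpcm_selection`: `fit` (final [lrpcm()]),
#'   `mean_fit` (the homoscedastic fit after the mean phase, the one the
#'   explained-variance rate compares against the no-covariate model),
#'   `removed` (data.frame log with phase, term, p, AIC before/after),
#'   `mean_terms`, `var_terms` (retained labels).
#' @export
backward_select <- function(responses, data, bank, mean_terms,
                            var_terms = character(), alpha = 0.05,
                            verbose = FALSE, ...) {
  log_rows <- list()
  fit_with <- function(mt, vt) {
    lrpcm(responses, data,
          mean = if (length(mt)) stats::reformulate(mt) else ~ 1,
          var = if (length(vt)) stats::reformulate(vt) else ~ 1,
          bank = bank, ...)
  }
  prune <- function(fit, terms, other_terms, phase) {
    repeat {
      if (!length(terms)) return(list(fit = fit, terms = terms))
      pvals <- vapply(terms, function(tm)
        term_wald_p(fit, tm, phase), numeric(1L))
      removable <- terms[hierarchy_removable(terms) & pvals >= alpha &
                           !is.na(pvals)]
      if (!length(removable)) return(list(fit = fit, terms = terms))
      ord <- removable[order(-pvals[match(removable, terms)])]
      dropped <- FALSE
      for (tm in ord) {
        cand_terms <- setdiff(terms, tm)
        cand <- if (phase == "mean")
          fit_with(cand_terms, other_terms)
        else fit_with(other_terms, cand_terms)
        if (cand$AIC <= fit$AIC + 1e-8) {
          log_rows[[length(log_rows) + 1L]] <<- data.frame(
            phase = phase, term = tm, p = pvals[[tm]],
            AIC_before = fit$AIC, AIC_after = cand$AIC)
          if (verbose)
            message(sprintf("drop %s term %s (p = %.3f, AIC %.2f -> %.2f)",
                            phase, tm, pvals[[tm]], fit$AIC, cand$AIC))
          fit <- cand; terms <- cand_terms; dropped <- TRUE
          break
        }
      }
      if (!dropped) return(list(fit = fit, terms = terms))
    }
  }
  fit <- fit_with(mean_terms, character())
  ph1 <- prune(fit, mean_terms, character(), "mean")
  mean_kept <- ph1$terms
  if (length(var_terms)) {
    fit <- fit_with(mean_kept, var_terms)
    ph2 <- prune(fit, var_terms, mean_kept, "variance")
    var_kept <- ph2$terms
    final <- ph2$fit
  } else {
    var_kept <- character()
    final <- ph1$fit
  }
  removed <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(phase = character(), term = character(), p = numeric(),
               AIC_before = numeric(), AIC_after = numeric())
  structure(list(fit = final, mean_fit = ph1$fit, removed = removed,
                 mean_terms = mean_kept, var_terms = var_kept),
            class = "lrpcm_selection")
}

#' @export
print.lrpcm_selection <- function(x, ...) {
  cat("Backward selection:", nrow(x$removed), "term(s) removed\n")
  if (nrow(x$removed)) print(x$removed, row.names = FALSE)
  cat("Retained mean terms:",
      if (length(x$mean_terms)) paste(x$mean_terms, collapse = ", ")
      else "(intercept only)", "\n")
  cat("Retained variance terms:",
      if (length(x$var_terms)) paste(x$var_terms, collapse = ", ")
      else "(intercept only)", "\n")
  print(x$fit)
  invisible(x)
}

# Wald chi-square p-value of a whole term (possibly several columns)
term_wald_p <- function(fit, term, phase = c("mean", "variance")) {
  phase <- match.arg(phase)
  if (phase == "mean") {
    fml <- fit$mean_formula; assign <- fit$X_assign; est <- fit$beta
    off <- 0L
  } else {
    fml <- fit$var_formula; assign <- fit$Z_assign; est <- fit$gamma
    off <- length(fit$beta)
  }
  labels <- attr(stats::terms(fml), "term.labels")
  ti <- match_term(term, labels)
  if (is.na(ti)) return(NA_real_)
  cols <- which(assign == ti)
  if (!length(cols)) return(NA_real_)
  idx <- off + cols
  V <- fit$vcov[idx, idx, drop = FALSE]
  b <- est[cols]
  w <- try(drop(t(b) %*% solve(V, b)), silent = TRUE)
  if (inherits(w, "try-error")) return(NA_real_)
  stats::pchisq(w, df = length(cols), lower.tail = FALSE)
}

# interaction labels may be written in either variable order
match_term <- function(term, labels) {
  norm <- function(x) vapply(strsplit(x, ":", fixed = TRUE), function(v)
    paste(sort(v), collapse = ":"), character(1L))
  match(norm(term), norm(labels))
}

# a main effect is removable only when no other candidate term contains it
hierarchy_removable <- function(terms) {
  comp <- strsplit(terms, ":", fixed = TRUE)
  vapply(seq_along(terms), function(i) {
    if (length(comp[[i]]) > 1L) return(TRUE)   # interactions always removable
    !any(vapply(seq_along(terms), function(j)
      j != i && length(comp[[j]]) > 1L && terms[i] %in% comp[[j]],
      logical(1L)))
  }, logical(1L))
}
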