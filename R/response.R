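#' Item specification
#'
#' Describes one questionnaire item: its number of response categories
#' (`m_j = n_categories - 1` is the maximum code), whether its raw coding
#' must be reversed so that higher codes mean more of the trait, and, for a
#' super-item built from locally dependent items, the ids of its parents.
#'
#' @param item_id character id.
#' @param n_categories integer >= 2.
#' @param reversed logical.
#' @param parent_ids character vector of source item ids (empty for ordinary
#'   items). A super-item scored as the sum of its parents has
#'   `n_categories = 1 + sum(parent n_categories - 1)`.
#' @return A list of class `item_spec`.
#' @export
item_spec <- function(item_id, n_categories, reversed = FALSE,
                      parent_ids = character()) {
  stopifnot(is.character(item_id), length(item_id) == 1L,
            n_categories >= 2L, is.logical(reversed))
  structure(list(item_id = item_id, n_categories = as.integer(n_categories),
                 reversed = reversed, parent_ids = as.character(parent_ids)),
            class = "item_spec")
}

max_code <- function(spec) spec$n_categories - 1L

#' SF-36 dimension item specifications
#'
#' Item sets for the three most used SF-36 dimensions. General Health (GH):
#' 5 items with 5 categories, three of which (GH1, GH11b, GH11d) are worded
#' positively and must be reverse-coded; responses are coded 0-4 without
#' item-1 weights. Physical Functioning (PF): 10 items with 3 categories
#' coded 0-2, none reversed; three sets of locally dependent items
#' ({PF1,PF2}, {PF4,PF5}, {PF7,PF8,PF9}) are combined into sum-scored
#' super-items by [build_super_items()]. Mental Health (MH): 5 items with 6
#' categories coded 0-5, none reversed.
#'
#' @param dimension one of `"GH"`, `"PF"`, `"MH"`.
#' @return list of [item_spec()].
#' @export
sf36_items <- function(dimension = c("GH", "PF", "MH")) {
  dimension <- match.arg(dimension)
  switch(dimension,
    GH = {
      ids <- c("GH1", "GH11a", "GH11b", "GH11c", "GH11d")
      rev <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
      mapply(item_spec, ids, 5L, rev, SIMPLIFY = FALSE, USE.NAMES = TRUE)
    },
    PF = {
      ids <- paste0("PF", 1:10)
      mapply(item_spec, ids, 3L, FALSE, SIMPLIFY = FALSE, USE.NAMES = TRUE)
    },
    MH = {
      ids <- paste0("MH", 1:5)
      mapply(item_spec, ids, 6L, FALSE, SIMPLIFY = FALSE, USE.NAMES = TRUE)
    })
}

#' Locally dependent PF item groups
#'
#' The three groups of Physical Functioning items combined into super-items
#' (PF12, PF45, PF789), leaving 6 PF items in total.
#' @return list of character vectors.
#' @export
sf36_pf_groups <- function() {
  list(PF12 = c("PF1", "PF2"), PF45 = c("PF4", "PF5"),
       PF789 = c("PF7", "PF8", "PF9"))
}

specs_by_id <- function(items) {
  stats::setNames(items, vapply(items, `[[`, character(1L), "item_id"))
}

#' Validate a response matrix against item specifications
#'
#' Checks that every non-missing code lies in `0..m_j` and that every person
#' has at least one observed response.
#'
#' @param responses numeric matrix, persons x items, `NA` = missing; column
#'   names are item ids.
#' @param items list of [item_spec()] covering every column.
#' @return `responses`, invisibly, after validation.
#' @export
validate_responses <- function(responses, items) {
  responses <- as.matrix(responses)
  if (is.null(colnames(responses))) stop("responses need item column names")
  sp <- specs_by_id(items)
  missing_spec <- setdiff(colnames(responses), names(sp))
  if (length(missing_spec))
    stop("no item_spec for: ", paste(missing_spec, collapse = ", "))
  for (id in colnames(responses)) {
    y <- responses[, id]
    bad <- which(!is.na(y) & (y < 0 | y > max_code(sp[[id]]) | y != round(y)))
    if (length(bad))
      stop(sprintf("item %s: code out of range 0..%d for person(s) %s",
                   id, max_code(sp[[id]]),
                   paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (nrow(responses) > 0L && any(rowSums(!is.na(responses)) == 0L))
    warning("persons with no observed responses present")
  invisible(responses)
}

#' Reverse-code items
#'
#' Replaces the codes `y` of every item flagged `reversed` by `m_j - y`;
#' other items and missing entries are unchanged. Applying the operation
#' twice returns the original matrix.
#'
#' @inheritParams validate_responses
#' @return the recoded matrix.
#' @export
reverse_code <- function(responses, items) {
  responses <- validate_responses(responses, items)
  sp <- specs_by_id(items)
  for (id in colnames(responses)) {
    if (isTRUE(sp[[id]]$reversed))
      responses[, id] <- max_code(sp[[id]]) - responses[, id]
  }
  responses
}

#' Combine locally dependent items into sum-scored super-items
#'
#' Each group of item ids is replaced by a single super-item scored as the
#' sum of the component codes (range `0..sum(m_j)`). A super-item is missing
#' whenever ANY component is missing, keeping the score range exact.
#'
#' @inheritParams validate_responses
#' @param groups named list of character vectors of component item ids;
#'   names become the super-item ids. Groups must not overlap.
#' @return list with `responses` (matrix with grouped columns replaced,
#'   order: super-items at the position of their first component) and
#'   `items` (updated list of [item_spec()]).
#' @export
build_super_items <- function(responses, groups, items) {
  responses <- validate_responses(responses, items)
  sp <- specs_by_id(items)
  comp <- unlist(groups)
  if (anyDuplicated(comp)) stop("overlapping super-item groups")
  if (!all(comp %in% colnames(responses)))
    stop("group component not in responses: ",
         paste(setdiff(comp, colnames(responses)), collapse = ", "))
  out_cols <- list(); out_specs <- list()
  consumed <- character()
  for (id in colnames(responses)) {
    if (id %in% consumed) next
    g <- which(vapply(groups, function(gg) id %in% gg, logical(1L)))
    if (length(g)) {
      gname <- names(groups)[g]
      members <- groups[[g]]
      block <- responses[, members, drop = FALSE]
      y <- rowSums(block)                       # NA if any component NA
      m_sum <- sum(vapply(sp[members], max_code, integer(1L)))
      out_cols[[gname]] <- y
      out_specs[[gname]] <- item_spec(gname, m_sum + 1L, FALSE, members)
      consumed <- c(consumed, members)
    } else {
      out_cols[[id]] <- responses[, id]
      out_specs[[id]] <- sp[[id]]
    }
  }
  list(responses = do.call(cbind, out_cols), items = out_specs)
}

#' DIF specification
#'
#' Declares, per item, the factor(s) on which the item functions
#' differentially and the grouping of factor levels that share thresholds.
#' Level groups must partition the factor's levels.
#'
#' @param ... entries created by [dif_split()].
#' @return list of class `dif_spec`.
#' @export
dif_spec <- function(...) {
  entries <- list(...)
  for (e in entries) stopifnot(inherits(e, "dif_split"))
  structure(entries, class = "dif_spec")
}

#' @rdname dif_spec
#' @param item item id to split.
#' @param factor covariate name.
#' @param groups list of character vectors of factor levels; together they
#'   must cover every level exactly once.
#' @export
dif_split <- function(item, factor, groups) {
  stopifnot(is.character(item), is.character(factor), is.list(groups))
  structure(list(item = item, factor = factor,
                 groups = lapply(groups, as.character)),
            class = "dif_split")
}

group_label <- function(levels) paste(levels, collapse = "+")

#' Expand DIF items into pseudo-items
#'
#' Replaces each item that shows DIF on a factor by one pseudo-item per
#' level group: the pseudo-item equals the original response for persons in
#' its group and is missing for everyone else, so group-specific thresholds
#' can be estimated within one model. An item split on two factors yields
#' one independent pseudo-item set per factor by default
#' (`cross_product = FALSE`), or one pseudo-item per combination of level
#' groups when `cross_product = TRUE`.
#'
#' Pseudo-item columns are named `<item>@<factor>:<group>`.
#'
#' @inheritParams validate_responses
#' @param covariates data.frame with one row per person and the factor
#'   columns named in `dif`.
#' @param dif a [dif_spec()]; empty means no expansion.
#' @param cross_product logical, see above.
#' @return list with `responses` and `items` as in [build_super_items()].
#' @export
expand_pseudo_items <- function(responses, covariates, dif, items,
                                cross_product = FALSE) {
  responses <- validate_responses(responses, items)
  sp <- specs_by_id(items)
  if (length(dif) == 0L)
    return(list(responses = responses, items = sp))
  stopifnot(nrow(covariates) == nrow(responses))
  split_items <- unique(vapply(dif, `[[`, character(1L), "item"))
  out_cols <- list(); out_specs <- list()
  for (id in colnames(responses)) {
    if (!(id %in% split_items)) {
      out_cols[[id]] <- responses[, id]
      out_specs[[id]] <- sp[[id]]
      next
    }
    entries <- dif[vapply(dif, function(e) e$item == id, logical(1L))]
    if (cross_product && length(entries) > 1L) {
      grids <- lapply(entries, function(e) seq_along(e$groups))
      combos <- expand.grid(grids)
      for (r in seq_len(nrow(combos))) {
        sel <- rep(TRUE, nrow(responses)); labs <- character()
        for (k in seq_along(entries)) {
          e <- entries[[k]]; g <- e$groups[[combos[r, k]]]
          check_levels(covariates[[e$factor]], e)
          sel <- sel & covariates[[e$factor]] %in% g
          labs <- c(labs, paste0(e$factor, ":", group_label(g)))
        }
        nm <- paste0(id, "@", paste(labs, collapse = "@"))
        y <- responses[, id]; y[!sel] <- NA
        out_cols[[nm]] <- y
        out_specs[[nm]] <- item_spec(nm, sp[[id]]$n_categories,
                                     parent_ids = id)
      }
    } else {
      for (e in entries) {
        check_levels(covariates[[e$factor]], e)
        for (g in e$groups) {
          nm <- paste0(id, "@", e$factor, ":", group_label(g))
          y <- responses[, id]
          y[!(covariates[[e$factor]] %in% g)] <- NA
          out_cols[[nm]] <- y
          out_specs[[nm]] <- item_spec(nm, sp[[id]]$n_categories,
                                       parent_ids = id)
        }
      }
    }
  }
  list(responses = do.call(cbind, out_cols), items = out_specs)
}

check_levels <- function(values, entry) {
  lv <- unique(as.character(values[!is.na(values)]))
  covered <- unlist(entry$groups)
  if (anyDuplicated(covered))
    stop("level groups overlap for item ", entry$item)
  outside <- setdiff(lv, covered)
  if (length(outside))
    stop(sprintf("factor %s has level(s) outside the DIF grouping: %s",
                 entry$factor, paste(outside, collapse = ", ")))
  invisible(TRUE)
}

#' Read and write the package's CSV schemas
#'
#' Responses: one row per person, columns are item codes, empty cell =
#' missing. Covariates: `person_id` plus factor columns. A leading `#`
#' comment line (e.g. recording the simulation seed) is ignored on read and
#' may be supplied on write.
#'
#' @param path file path.
#' @param x matrix or data.frame to write.
#' @param comment optional metadata line written as `# ...`.
#' @return read functions return a matrix (responses) or data.frame.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_responses
#' @export
read_covariates <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = TRUE,
                  check.names = FALSE)
}

#' @rdname read_responses
#' @export
write_table_csv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}
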