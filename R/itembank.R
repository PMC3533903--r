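#' Item bank of PCM step thresholds
#'
#' An `item_bank` stores, for each item `j`, the step thresholds
#' `delta_j1..delta_jm_j` on the logit scale. The item *location* is the mean
#' of an item's thresholds and is the one-number difficulty summary used by
#' the DIF scan.
#'
#' @param delta named list; element `j` is the numeric threshold vector of
#'   item `j`. Names are item ids.
#' @return An object of class `item_bank`.
#' @seealso [pce_fit()], [calibrate_pcm()]
#' @export
item_bank <- function(delta) {
  stopifnot(is.list(delta), length(delta) >= 1L)
  if (is.null(names(delta)) || anyNA(names(delta)) || any(names(delta) == ""))
    stop("every item needs an id (list names)")
  ok <- vapply(delta, function(d) is.numeric(d) && length(d) >= 1L &&
                 all(is.finite(d)), logical(1L))
  if (!all(ok)) stop("thresholds must be finite numeric vectors (m_j >= 1)")
  structure(list(delta = delta), class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat("Item bank:", length(x$delta), "items\n")
  loc <- item_locations(x)
  m <- vapply(x$delta, length, integer(1L))
  print(data.frame(item = names(x$delta), m = m, location = round(loc, 4),
                   row.names = NULL))
  invisible(x)
}

#' @export
coef.item_bank <- function(object, ...) object$delta

#' Item locations
#'
#' The location of item `j` is `mean(delta_j)`, i.e. the average of its step
#' thresholds.
#'
#' @param bank an [item_bank()].
#' @return named numeric vector of locations.
#' @export
item_locations <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  vapply(bank$delta, mean, numeric(1L))
}

#' Read/write an item bank as CSV
#'
#' Long format with columns `item_id`, `l`, `delta`; values round-trip at 12
#' significant digits.
#'
#' @param bank an [item_bank()].
#' @param path file path.
#' @return `write_item_bank` returns `path` invisibly; `read_item_bank`
#'   returns an [item_bank()].
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  rows <- do.call(rbind, lapply(names(bank$delta), function(id) {
    d <- bank$delta[[id]]
    data.frame(item_id = id, l = seq_along(d),
               delta = formatC(d, digits = 12, format = "g"))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("item_id", "l", "delta") %in% names(df)))
  sp <- split(df, factor(df$item_id, levels = unique(df$item_id)))
  item_bank(lapply(sp, function(s) as.numeric(s$delta[order(s$l)])))
}
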