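#' Item parameter sets for the graded response model
#'
#' An `item_parameters` object holds, for each item, a discrimination
#' (logistic slope, in units of 1/theta) and a strictly increasing vector of
#' thresholds (theta units). Items may differ in category count.
#'
#' @param alpha numeric vector of discriminations, all > 0.
#' @param betas list of numeric threshold vectors (length K_i - 1 for a
#'   K_i-category item), each strictly increasing; a single numeric vector is
#'   accepted for a one-item set.
#' @param item_names optional character vector of item labels.
#' @return an object of class `item_parameters`: a list with elements
#'   `alpha`, `betas`, `item_names`.
#' @export
#' @examples
#' item_parameters(c(1.5, 2), list(c(-1, 0, 1), c(-0.5, 0.5)))
item_parameters <- function(alpha, betas, item_names = NULL) {
  if (is.numeric(betas)) betas <- list(betas)
  stopifnot(is.numeric(alpha), is.list(betas), length(alpha) == length(betas))
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("all discriminations must be finite and > 0")
  }
  for (b in betas) {
    if (length(b) < 1L || any(!is.finite(b))) {
      stop("each item needs at least one finite threshold")
    }
    if (length(b) > 1L && any(diff(b) <= 0)) {
      stop("thresholds must be strictly increasing within item")
    }
  }
  if (is.null(item_names)) item_names <- paste0("item", seq_along(alpha))
  structure(
    list(alpha = as.numeric(alpha), betas = lapply(betas, as.numeric),
         item_names = as.character(item_names)),
    class = "item_parameters"
  )
}

#' @export
print.item_parameters <- function(x, ...) {
  cat("<item_parameters> ", n_items(x), " items\n", sep = "")
  for (i in seq_len(n_items(x))) {
    cat(sprintf("  %-12s alpha=%.3f  betas=[%s]\n", x$item_names[i],
                x$alpha[i], paste(sprintf("%.3f", x$betas[[i]]), collapse = ", ")))
  }
  invisible(x)
}

#' Number of items in a parameter set
#' @param params an `item_parameters` object.
#' @return integer item count.
#' @export
n_items <- function(params) length(params$alpha)

#' Number of response categories per item
#' @param params an `item_parameters` object.
#' @return integer vector, `K_i` for each item.
#' @export
n_categories <- function(params) vapply(params$betas, length, 1L) + 1L

#' Subset an item-parameter set
#' @param params an `item_parameters` object.
#' @param items integer indices of items to keep.
#' @return an `item_parameters` object for the subset.
#' @export
subset_items <- function(params, items) {
  stopifnot(all(items >= 1L), all(items <= n_items(params)))
  item_parameters(params$alpha[items], params$betas[items],
                  params$item_names[items])
}

#' Read / write item parameters as JSON
#'
#' The on-disk format is `{"items": [{"name": ..., "alpha": ...,
#' "betas": [...]}, ...]}` and round-trips at full double precision.
#'
#' @param params an `item_parameters` object.
#' @param path file path.
#' @return `write_item_parameters` returns `path` invisibly;
#'   `read_item_parameters` returns an `item_parameters` object.
#' @export
write_item_parameters <- function(params, path) {
  items <- lapply(seq_len(n_items(params)), function(i) {
    list(name = params$item_names[i], alpha = params$alpha[i],
         betas = params$betas[[i]])
  })
  jsonlite::write_json(list(items = items), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_item_parameters
#' @export
read_item_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$items)) stop("no 'items' field in ", path)
  item_parameters(
    alpha = vapply(obj$items, function(it) as.numeric(it$alpha), 0),
    betas = lapply(obj$items, function(it) as.numeric(unlist(it$betas))),
    item_names = vapply(obj$items, function(it) as.character(it$name), "")
  )
}
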