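# Nonparametric scalability: Mokken-type H coefficients, monotonicity
# checks against rest-score groups, and invariant item ordering (HT).

# maximum covariance between two integer item vectors given their margins
# (comonotonic coupling: pair the sorted marginals)
.covmax <- function(x, y) {
  stats::cov(sort(x), sort(y))
}

#' Scalability coefficients H, Hi and Hij
#'
#' `H_ij = cov(X_i, X_j) / covmax(X_i, X_j)` with the maximum covariance
#' attainable under the observed marginals (sorted pairing); `H_i` and `H`
#' are the corresponding ratio-of-sums aggregates. Verdicts use H_i >= 0.30
#' and H >= 0.50. A perfect Guttman pattern yields H = 1; independent items
#' yield H near 0. Zero-variance items are excluded with a warning.
#'
#' @param responses persons x items integer matrix.
#' @return list with `H`, `Hi` (named per item), `Hij` (matrix),
#'   `excluded_items`, `verdicts`, `h_note` (scale-threshold provenance
#'   note).
#' @export
mokken_coefficients <- function(responses) {
  responses <- as.matrix(responses)
  if (ncol(responses) < 2L) stop("need at least 2 items")
  v <- apply(responses, 2L, var)
  excluded <- which(v == 0)
  if (length(excluded)) {
    warning("excluding zero-variance item(s): ",
            paste(excluded, collapse = ", "))
    responses <- responses[, -excluded, drop = FALSE]
  }
  J <- ncol(responses)
  C <- stats::cov(responses)
  S <- apply(responses, 2L, sort)   # comonotonic coupling per pair
  Cmax <- stats::cov(S)
  diag(C) <- diag(Cmax) <- 0
  Hij <- ifelse(Cmax > 0, C / Cmax, NA_real_)
  diag(Hij) <- NA_real_
  Hi <- rowSums(C) / rowSums(Cmax)
  H <- sum(C[upper.tri(C)]) / sum(Cmax[upper.tri(Cmax)])
  names(Hi) <- colnames(responses)
  list(H = H, Hi = Hi, Hij = Hij, excluded_items = excluded,
       verdicts = list(H_acceptable = H >= 0.50, Hi_acceptable = Hi >= 0.30),
       h_note = "scale-level threshold 0.50 (a 0.60 convention also circulates)")
}

#' Monotonicity check against rest-score groups
#'
#' For every item and category step k, estimates `P(X_i >= k | rest-score
#' group)` over groups of adjacent rest scores (each of at least
#' `min_group_size` persons) and counts significant decreases between
#' adjacent groups (one-sided two-proportion z-test at `alpha`). Data
#' generated by any graded model are monotone, so violations indicate
#' model-inconsistent items.
#'
#' @param responses persons x items integer matrix (0..K-1).
#' @param min_group_size minimum rest-score group size (default 50).
#' @param alpha significance level for a decrease (default 0.05).
#' @param minvi minimum violation magnitude considered at all
#'   (default 0.03), so trivially small sample wiggles are not tested.
#' @return list with per-item `violations` (significant decreases),
#'   `active_comparisons`, `checkable` (FALSE when only one group forms).
#' @export
monotonicity_check <- function(responses, min_group_size = 50L,
                               alpha = 0.05, minvi = 0.03) {
  responses <- as.matrix(responses)
  n <- nrow(responses); J <- ncol(responses)
  zcrit <- qnorm(1 - alpha)
  viol <- integer(J); ncomp <- integer(J); checkable <- logical(J)
  total <- rowSums(responses)
  for (j in seq_len(J)) {
    rest <- total - responses[, j]
    # group adjacent rest scores until each group reaches the minimum size
    tab <- table(rest)
    vals <- as.numeric(names(tab))
    groups <- integer(length(vals)); g <- 1L; size <- 0L
    for (i in seq_along(vals)) {
      groups[i] <- g
      size <- size + tab[i]
      if (size >= min_group_size && i < length(vals)) { g <- g + 1L; size <- 0L }
    }
    # merge a trailing undersized group into its neighbour
    if (size < min_group_size && g > 1L) groups[groups == g] <- g - 1L
    gid <- groups[match(rest, vals)]
    G <- max(gid)
    checkable[j] <- G >= 2L
    if (!checkable[j]) next
    ng <- tabulate(gid, G)
    K <- max(responses[, j]) + 1L
    for (k in seq_len(K - 1L)) {
      pg <- vapply(seq_len(G), function(g) mean(responses[gid == g, j] >= k), 0)
      for (g in seq_len(G - 1L)) {
        ncomp[j] <- ncomp[j] + 1L
        d <- pg[g] - pg[g + 1L]
        if (d <= minvi) next
        pp <- (pg[g] * ng[g] + pg[g + 1L] * ng[g + 1L]) / (ng[g] + ng[g + 1L])
        se <- sqrt(pp * (1 - pp) * (1 / ng[g] + 1 / ng[g + 1L]))
        if (se > 0 && d / se > zcrit) viol[j] <- viol[j] + 1L
      }
    }
  }
  nm <- colnames(responses)
  if (!is.null(nm)) names(viol) <- names(ncomp) <- names(checkable) <- nm
  list(violations = viol, active_comparisons = ncomp, checkable = checkable)
}

#' Invariant item ordering: the HT coefficient
#'
#' H computed on the transposed matrix (persons as items), restricted to
#' person pairs with distinct total scores; high HT means respondents
#' order the items similarly. Reported descriptively with accuracy bands:
#' < 0.30 inaccurate ordering, 0.30-0.39 low, 0.40-0.49 medium,
#' >= 0.50 high accuracy.
#'
#' @param responses persons x items integer matrix.
#' @return list with `HT`, `band`, `n_pairs_used`.
#' @export
iio_ht <- function(responses) {
  responses <- as.matrix(responses)
  if (ncol(responses) < 3L) stop("need at least 3 items")
  totals <- rowSums(responses)
  if (length(unique(totals)) < 2L) {
    return(list(HT = NA_real_, band = "undefined (all totals tied)",
                n_pairs_used = 0L))
  }
  X <- t(responses)                       # items x persons
  C <- stats::cov(X)                      # person-pair covariances over items
  S <- apply(X, 2L, sort)
  Cmax <- stats::cov(S)
  use <- outer(totals, totals, "!=") & upper.tri(C) & Cmax > 0
  ht <- sum(C[use]) / sum(Cmax[use])
  band <- if (ht >= 0.50) "high accuracy" else if (ht >= 0.40) "medium accuracy"
  else if (ht >= 0.30) "low accuracy" else "inaccurate ordering"
  list(HT = ht, band = band, n_pairs_used = sum(use))
}
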