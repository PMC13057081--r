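# Generalized Orlando-Thissen S-X2 item fit for polytomous items:
# observed vs model-implied category frequencies conditional on the rest
# score (summed score excluding the studied item).

# model-implied rest-score distribution at each quadrature node for every
# item: recursion (sequential convolution) over the other items' category
# probability vectors. Returns a list over items of Q x (S_max+1) matrices.
.rest_score_tables <- function(params, nodes) {
  J <- n_items(params)
  K <- n_categories(params)
  probs <- lapply(seq_len(J), function(j) {
    category_probabilities(params$alpha[j], params$betas[[j]], nodes)
  })
  lapply(seq_len(J), function(j) {
    others <- setdiff(seq_len(J), j)
    smax <- sum(K[others] - 1L)
    r <- matrix(0, length(nodes), smax + 1L)
    r[, 1] <- 1
    width <- 0L
    for (o in others) {
      newr <- matrix(0, length(nodes), smax + 1L)
      for (k in seq_len(K[o])) {
        cols <- seq_len(width + 1L) + (k - 1L)
        newr[, cols] <- newr[, cols] +
          r[, seq_len(width + 1L), drop = FALSE] * probs[[o]][, k]
      }
      r <- newr
      width <- width + K[o] - 1L
    }
    r
  })
}

# collapse a (scores x categories) table of observed counts O and expected
# counts E until every expected cell is >= min_expected. Categories are
# collapsed within each score group first (from the outer categories
# inward), then whole score groups are merged from the distribution tails
# inward if a group's expected total still falls short. Returns lists of
# per-group observed/expected cell vectors.
.collapse_cells <- function(O, E, min_expected = 1) {
  collapse_row <- function(o, e) {
    while (length(e) > 1L && any(e < min_expected)) {
      bad <- which(e < min_expected)
      # violating cell nearest an end of the category range, merged inward
      j <- if (bad[1] - 1L <= length(e) - bad[length(bad)]) bad[1]
           else bad[length(bad)]
      tgt <- if (j == 1L) 2L else j - 1L
      o[tgt] <- o[tgt] + o[j]; e[tgt] <- e[tgt] + e[j]
      o <- o[-j]; e <- e[-j]
    }
    list(o = o, e = e)
  }
  rowsO <- lapply(seq_len(nrow(O)), function(i) O[i, ])
  rowsE <- lapply(seq_len(nrow(E)), function(i) E[i, ])
  repeat {
    for (i in seq_along(rowsO)) {
      cr <- collapse_row(rowsO[[i]], rowsE[[i]])
      rowsO[[i]] <- cr$o; rowsE[[i]] <- cr$e
    }
    short <- which(vapply(rowsE, sum, 0) < min_expected)
    if (!length(short) || length(rowsO) == 1L) break
    i <- if (short[1] - 1L <= length(rowsO) - short[length(short)]) short[1]
         else short[length(short)]
    tgt <- if (i == 1L) 2L else i - 1L
    # merge score groups on the original category layout: re-expand is not
    # possible after per-row collapsing, so merge the collapsed cell sums
    # into a fresh single-row layout of matched length
    lo <- max(length(rowsO[[i]]), length(rowsO[[tgt]]))
    pad <- function(x, l) c(x, rep(0, l - length(x)))
    rowsO[[tgt]] <- pad(rowsO[[tgt]], lo) + pad(rowsO[[i]], lo)
    rowsE[[tgt]] <- pad(rowsE[[tgt]], lo) + pad(rowsE[[i]], lo)
    rowsO[[i]] <- NULL; rowsE[[i]] <- NULL
  }
  list(O = rowsO, E = rowsE)
}

#' Generalized S-X2 item fit
#'
#' For each item, the model-implied distribution of the rest score is
#' obtained by convolving the other items' category probability vectors at
#' each quadrature node and marginalizing over the latent prior. Observed
#' and expected counts per (rest score, category) cell are compared with a
#' Pearson chi-square; adjacent cells are collapsed (categories first,
#' then score groups, from the tails inward) until every expected count is
#' at least `min_expected`. Degrees of freedom follow the Orlando-Thissen
#' convention: the collapsed cell count minus one per remaining score
#' group, minus the item's free parameter count (floored at 1). Items are
#' flagged at p < 0.001.
#'
#' @param params fitted [item_parameters()] for the whole bank.
#' @param responses persons x items matrix of categories 0..K-1.
#' @param grid a [quadrature_grid()].
#' @param min_expected collapsing floor for expected counts (default 1).
#' @param flag_p misfit flag level (default 0.001).
#' @return data frame with columns `item`, `sx2`, `df`, `p_value`,
#'   `n_cells`, `collapsed_cells`, `testable`, `misfit`.
#' @export
sx2_item_fit <- function(params, responses, grid = quadrature_grid(),
                         min_expected = 1, flag_p = 0.001) {
  responses <- as.matrix(responses)
  n <- nrow(responses); J <- n_items(params)
  K <- n_categories(params)
  for (j in seq_len(J)) {
    if (max(responses[, j]) > K[j] - 1L || min(responses[, j]) < 0L) {
      stop("item ", j, " has categories outside the fitted 0..", K[j] - 1L,
           " range; recode with apply_category_maps() first")
    }
  }
  rest_tabs <- .rest_score_tables(params, grid$nodes)
  probs <- lapply(seq_len(J), function(j) {
    category_probabilities(params$alpha[j], params$betas[[j]], grid$nodes)
  })
  total <- rowSums(responses)
  out <- data.frame(item = params$item_names, sx2 = NA_real_, df = NA_real_,
                    p_value = NA_real_, n_cells = NA_integer_,
                    collapsed_cells = NA_integer_, testable = TRUE,
                    misfit = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(J)) {
    obs_cats <- length(unique(responses[, j]))
    if (obs_cats < 2L) {
      out$testable[j] <- FALSE
      next
    }
    rest <- total - responses[, j]
    smax <- ncol(rest_tabs[[j]]) - 1L
    # expected joint mass over (rest score s, category k):
    # E_sk = n * sum_q w_q r_q(s) P_k(theta_q)
    wq <- grid$weights
    Ej <- t(rest_tabs[[j]] * wq) %*% probs[[j]] * n   # (smax+1) x K
    O <- matrix(0, smax + 1L, K[j])
    idx <- cbind(rest + 1L, responses[, j] + 1L)
    for (r in seq_len(nrow(idx))) O[idx[r, 1], idx[r, 2]] <- O[idx[r, 1], idx[r, 2]] + 1
    # condition expected on the observed rest-score counts so row totals match
    ns <- rowSums(O)
    rowE <- rowSums(Ej)
    keep <- ns > 0
    Econd <- Ej[keep, , drop = FALSE] / rowE[keep] * ns[keep]
    Ocond <- O[keep, , drop = FALSE]
    cl <- .collapse_cells(Ocond, Econd, min_expected)
    n_groups <- length(cl$O)
    n_cells <- sum(lengths(cl$O))
    sx2 <- sum(vapply(seq_len(n_groups), function(g) {
      sum((cl$O[[g]] - cl$E[[g]])^2 / pmax(cl$E[[g]], 1e-12))
    }, 0))
    n_par <- K[j]                                  # alpha + (K-1) thresholds
    df <- n_cells - n_groups - n_par
    if (df < 1) {
      out$testable[j] <- FALSE
      out$sx2[j] <- sx2; out$n_cells[j] <- n_cells
      next
    }
    out$sx2[j] <- sx2
    out$df[j] <- df
    out$p_value[j] <- pchisq(sx2, df, lower.tail = FALSE)
    out$n_cells[j] <- n_cells
    out$collapsed_cells[j] <- (sum(keep) * K[j]) - n_cells
    out$misfit[j] <- out$p_value[j] < flag_p
  }
  out
}

#' Observed vs expected category proportions across trait groups
#'
#' Diagnostic data behind item-fit plots: persons are binned into
#' `n_groups` by the EAP trait estimate computed from the *other* items
#' (the rest-score estimate, in the Orlando-Thissen spirit), so the
#' studied item cannot sort itself into favourable bins. Per bin, the
#' observed category proportions are compared with the model-expected
#' proportions: each person's rest-posterior-weighted category
#' probabilities, averaged over the bin. Under the fitted model observed
#' and expected then agree up to sampling error in every bin; binning on
#' an estimate that includes the item, or evaluating the curves at the
#' shrunken bin-mean theta, would both show spurious tail gaps. The
#' curves evaluated at the bin mean theta are also returned
#' (`expected_at_mean`). The item information curve is attached, and a
#' "negligible misfit" heuristic flags whether the maximum
#' observed-expected gap stays below `bound`.
#'
#' @param params fitted [item_parameters()].
#' @param responses persons x items matrix.
#' @param item item index to inspect.
#' @param n_groups number of trait bins (default 10; empty bins merge).
#' @param grid a [quadrature_grid()].
#' @param bound negligible-misfit bound on max |obs - exp| (default 0.05).
#' @return list with `groups` (data frame: bin, theta_mean, n, category,
#'   observed, expected, expected_at_mean), `information` (theta grid +
#'   curve), `max_abs_gap`, `negligible`.
#' @export
fit_plot_data <- function(params, responses, item, n_groups = 10L,
                          grid = quadrature_grid(), bound = 0.05) {
  responses <- as.matrix(responses)
  rest <- eap_score(responses[, -item, drop = FALSE],
                    subset_items(params, setdiff(seq_len(n_items(params)), item)),
                    grid)
  th <- rest$theta_hat
  br <- quantile(th, probs = seq(0, 1, length.out = n_groups + 1L))
  br <- unique(br)                      # duplicate quantiles merge bins
  bin <- cut(th, breaks = br, include.lowest = TRUE, labels = FALSE)
  K <- n_categories(params)[item]
  # rest-posterior predictive category probabilities per person
  post <- .posterior_matrix(
    responses[, -item, drop = FALSE],
    subset_items(params, setdiff(seq_len(n_items(params)), item)), grid)
  pitem <- category_probabilities(params$alpha[item], params$betas[[item]],
                                  grid$nodes)
  pp <- post %*% pitem                  # n x K
  rows <- list()
  for (g in sort(unique(bin))) {
    sel <- bin == g
    tm <- mean(th[sel])
    at_mean <- category_probabilities(params$alpha[item],
                                      params$betas[[item]], tm)
    for (k in seq_len(K)) {
      rows[[length(rows) + 1L]] <- data.frame(
        bin = g, theta_mean = tm, n = sum(sel), category = k - 1L,
        observed = mean(responses[sel, item] == k - 1L),
        expected = mean(pp[sel, k]),
        expected_at_mean = at_mean[1, k])
    }
  }
  groups <- do.call(rbind, rows)
  info_grid <- seq(-4, 4, length.out = 81)
  info <- item_information(params$alpha[item], params$betas[[item]], info_grid)
  gap <- max(abs(groups$observed - groups$expected))
  list(groups = groups,
       information = data.frame(theta = info_grid, information = info),
       max_abs_gap = gap, negligible = gap < bound,
       n_groups_used = length(unique(bin)))
}
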