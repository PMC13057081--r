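# Differential item functioning by ordinal logistic regression: three
# nested proportional-odds models per item (trait; trait + group; trait +
# group + trait x group), with McFadden pseudo-R2 differences as effect
# sizes, and the downstream impact procedure (re-calibration without the
# flagged items and comparison of T-scores and reliability).

#' Proportional-odds (cumulative logit) model
#'
#' Fits `P(Y <= k | x) = logistic(zeta_k - x' beta)` by quasi-Newton
#' maximization with analytic gradients on a parameterization that keeps
#' the cutpoints ordered. The intercept-only fit (zero-column `X`)
#' supplies the null log-likelihood for McFadden's pseudo-R2.
#'
#' @param y integer response categories 0..K-1.
#' @param X numeric model matrix without intercept column (may have zero
#'   columns for the intercept-only model).
#' @return list with `zeta` (ordered cutpoints), `beta`, `log_lik`,
#'   `converged`.
#' @export
prop_odds_fit <- function(y, X = NULL) {
  y <- as.integer(y)
  K <- max(y) + 1L
  if (K < 2L) stop("response needs at least 2 categories")
  n <- length(y)
  if (is.null(X)) X <- matrix(0, n, 0L)
  X <- as.matrix(X)
  p <- ncol(X)
  pack <- function(zeta, beta) {
    if (K == 2L) c(zeta, beta) else c(zeta[1], log(diff(zeta)), beta)
  }
  unpack <- function(th) {
    if (K == 2L) list(zeta = th[1], beta = th[-1])
    else list(zeta = cumsum(c(th[1], exp(th[2:(K - 1L)]))),
              beta = th[-seq_len(K - 1L)])
  }
  iup <- y + 1L          # index of upper cutpoint (1..K-1, K -> +Inf)
  ilo <- y               # index of lower cutpoint (0 -> -Inf)
  negll_grad <- function(th, want_grad = FALSE) {
    par <- unpack(th)
    eta <- if (p) as.numeric(X %*% par$beta) else numeric(n)
    zup <- ifelse(iup <= K - 1L, par$zeta[pmin(iup, K - 1L)] - eta, Inf)
    zlo <- ifelse(ilo >= 1L, par$zeta[pmax(ilo, 1L)] - eta, -Inf)
    A <- plogis(zup); B <- plogis(zlo)
    pr <- pmax(A - B, 1e-300)
    val <- -sum(log(pr))
    if (!want_grad) return(val)
    a <- A * (1 - A); b <- B * (1 - B)   # logistic densities (0 at +-Inf)
    g_zeta <- numeric(K - 1L)
    for (k in seq_len(K - 1L)) {
      g_zeta[k] <- sum((a / pr)[iup == k]) - sum((b / pr)[ilo == k])
    }
    g_beta <- if (p) as.numeric(crossprod(X, (b - a) / pr)) else numeric(0)
    g <- numeric(length(th))
    if (K == 2L) {
      g[1] <- g_zeta
    } else {
      g[1] <- sum(g_zeta)
      for (m2 in 2:(K - 1L)) {
        g[m2] <- sum(g_zeta[m2:(K - 1L)]) * exp(th[m2])
      }
    }
    if (p) g[(length(th) - p + 1L):length(th)] <- g_beta
    list(value = val, grad = -g)
  }
  cum <- cumsum(tabulate(y + 1L, K))[seq_len(K - 1L)] / n
  cum <- pmin(pmax(cum, 1 / (n + 1)), 1 - 1 / (n + 1))
  th0 <- pack(qlogis(cum), rep(0, p))
  opt <- optim(th0, function(t) negll_grad(t, FALSE),
               function(t) negll_grad(t, TRUE)$grad,
               method = "BFGS", control = list(maxit = 300L, reltol = 1e-12))
  par <- unpack(opt$par)
  list(zeta = par$zeta, beta = par$beta, log_lik = -opt$value,
       converged = opt$convergence == 0)
}

# McFadden pseudo-R2 of a fitted model against the intercept-only model
.mcfadden <- function(ll_model, ll_null) 1 - ll_model / ll_null

#' DIF scan over a bank by nested ordinal models
#'
#' For each item and each pair of covariate levels, three nested
#' proportional-odds models are fitted on the observed categories:
#' M1 (trait only), M2 (trait + group), M3 (trait + group + trait x
#' group). Differences in McFadden's pseudo-R2 between nested models give
#' the uniform (M2 - M1), non-uniform (M3 - M2), and total (M3 - M1)
#' effect sizes; values above `threshold` (default 0.02) flag DIF. For
#' covariates with more than two levels, all pairwise comparisons are
#' computed and their mean reported alongside.
#'
#' @param responses persons x items matrix of categories 0..K-1.
#' @param theta_hat matching criterion: EAP trait estimates from all
#'   items (single pass, no purification).
#' @param group factor (>= 2 levels) of group membership.
#' @param threshold McFadden R2 flag threshold (default 0.02).
#' @param min_per_level minimum persons per level (default 25).
#' @return object of class `dif_result`: list with `pairwise` (data frame
#'   item x comparison with r2_uniform, r2_nonuniform, r2_total and
#'   flags), `by_item` (mean R2 over comparisons per item, with flags),
#'   `threshold`.
#' @export
dif_scan <- function(responses, theta_hat, group, threshold = 0.02,
                     min_per_level = 25L) {
  responses <- as.matrix(responses)
  group <- droplevels(as.factor(group))
  lv <- levels(group)
  if (length(lv) < 2L) stop("group needs at least 2 levels")
  cnt <- table(group)
  if (any(cnt < min_per_level)) {
    stop("each group level needs at least ", min_per_level, " persons (",
         paste(names(cnt)[cnt < min_per_level], collapse = ", "), " too small)")
  }
  item_names <- colnames(responses)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(ncol(responses)))
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  rows <- list()
  for (pp in pairs) {
    sel <- group %in% pp
    g01 <- as.numeric(group[sel] == pp[2])
    th <- theta_hat[sel]
    for (j in seq_len(ncol(responses))) {
      yraw <- responses[sel, j]
      # re-map to consecutive categories observed within this comparison
      obs <- sort(unique(yraw))
      y <- match(yraw, obs) - 1L
      if (length(obs) < 2L) next
      ll_null <- prop_odds_fit(y, NULL)$log_lik
      m1 <- prop_odds_fit(y, cbind(theta = th))
      m2 <- prop_odds_fit(y, cbind(theta = th, group = g01))
      m3 <- prop_odds_fit(y, cbind(theta = th, group = g01,
                                   inter = th * g01))
      r1 <- .mcfadden(m1$log_lik, ll_null)
      r2 <- .mcfadden(m2$log_lik, ll_null)
      r3 <- .mcfadden(m3$log_lik, ll_null)
      rows[[length(rows) + 1L]] <- data.frame(
        item = item_names[j], comparison = paste(pp, collapse = " vs "),
        r2_uniform = r2 - r1, r2_nonuniform = r3 - r2, r2_total = r3 - r1,
        converged = m1$converged && m2$converged && m3$converged,
        stringsAsFactors = FALSE)
    }
  }
  pw <- do.call(rbind, rows)
  pw$flag_uniform <- pw$r2_uniform > threshold
  pw$flag_nonuniform <- pw$r2_nonuniform > threshold
  pw$flag_total <- pw$r2_total > threshold
  agg <- aggregate(pw[c("r2_uniform", "r2_nonuniform", "r2_total")],
                   by = list(item = pw$item), FUN = mean)
  agg <- agg[match(item_names, agg$item), ]
  rownames(agg) <- NULL
  agg$flag_any_pairwise <- vapply(agg$item, function(it) {
    any(pw$flag_uniform[pw$item == it] | pw$flag_nonuniform[pw$item == it])
  }, TRUE)
  agg$flag_mean <- agg$r2_uniform > threshold | agg$r2_nonuniform > threshold
  structure(list(pairwise = pw, by_item = agg, threshold = threshold),
            class = "dif_result")
}

#' Impact of removing DIF-flagged items
#'
#' Re-fits the graded model without the flagged items, re-scores every
#' person, and summarizes the consequences: mean absolute and maximum
#' T-score differences, the percentage of persons whose T-score moves by
#' at least one point, mean SE(theta) and the percentage with SE <= 0.32
#' before and after, and both test characteristic curves. With an empty
#' `dif_items` the deltas are exactly zero.
#'
#' @param responses persons x items matrix for the full bank.
#' @param dif_items integer indices of flagged items (possibly empty).
#' @param grid a [quadrature_grid()].
#' @param se_threshold reliable-measurement SE bound (default 0.32).
#' @param refit if `TRUE` (default) both calibrations are estimated from
#'   the data; supply `params` to score the full bank from known
#'   parameters instead.
#' @param params optional [item_parameters()] for the full bank.
#' @return object of class `dif_impact`: list with `mean_abs_tdiff`,
#'   `max_tdiff`, `pct_ge1`, `se_before`, `se_after`,
#'   `pct_reliable_before`, `pct_reliable_after`, `tcc` (data frame
#'   theta, expected_score_before, expected_score_after), `items_removed`.
#' @export
dif_impact <- function(responses, dif_items, grid = quadrature_grid(),
                       se_threshold = 0.32, refit = TRUE, params = NULL) {
  responses <- as.matrix(responses)
  J <- ncol(responses)
  dif_items <- as.integer(dif_items)
  if (length(dif_items) && (any(dif_items < 1L) || any(dif_items > J))) {
    stop("dif_items out of range")
  }
  keep <- setdiff(seq_len(J), dif_items)
  if (length(keep) < 3L) stop("removal would leave fewer than 3 items")
  params_full <- if (refit || is.null(params)) {
    fit_grm(responses, grid)$params
  } else params
  scores_full <- eap_score(responses, params_full, grid)
  if (length(dif_items) == 0L) {
    params_red <- params_full
    scores_red <- scores_full
  } else {
    params_red <- if (refit || is.null(params)) {
      fit_grm(responses[, keep, drop = FALSE], grid)$params
    } else subset_items(params, keep)
    scores_red <- eap_score(responses[, keep, drop = FALSE], params_red, grid)
  }
  dt <- scores_red$t_score - scores_full$t_score
  tgrid <- seq(-4, 4, length.out = 81)
  tcc_b <- information_profile(params_full, tgrid)$tcc
  tcc_a <- information_profile(params_red, tgrid)$tcc
  structure(list(
    mean_abs_tdiff = mean(abs(dt)), max_tdiff = max(abs(dt)),
    pct_ge1 = 100 * mean(abs(dt) >= 1),
    se_before = mean(scores_full$se_theta),
    se_after = mean(scores_red$se_theta),
    pct_reliable_before = 100 * mean(scores_full$se_theta <= se_threshold),
    pct_reliable_after = 100 * mean(scores_red$se_theta <= se_threshold),
    tcc = data.frame(theta = tgrid, expected_score_before = tcc_b,
                     expected_score_after = tcc_a),
    items_removed = dif_items), class = "dif_impact")
}

#' CAT exposure summary for flagged items
#'
#' For post-hoc CAT traces, reports whether each flagged item was ever
#' administered and its information rank at each person's final trait
#' estimate (rank 1 = most informative item of the bank at that theta).
#'
#' @param traces list of CAT traces from [batch_cat()].
#' @param params full-bank [item_parameters()].
#' @param dif_items integer indices of flagged items.
#' @return data frame per flagged item: `item`, `ever_administered`,
#'   `pct_administered`, `pct_rank1`, `pct_top3`.
#' @export
dif_cat_exposure <- function(traces, params, dif_items) {
  thetas <- vapply(traces, function(tr) tr$final_theta, 0)
  J <- n_items(params)
  info <- vapply(seq_len(J), function(j) {
    item_information(params$alpha[j], params$betas[[j]], thetas)
  }, numeric(length(thetas)))
  info <- matrix(info, nrow = length(thetas))
  rk <- t(apply(-info, 1L, rank, ties.method = "first"))
  do.call(rbind, lapply(dif_items, function(j) {
    adm <- vapply(traces, function(tr) j %in% tr$administered, TRUE)
    data.frame(item = params$item_names[j],
               ever_administered = any(adm),
               pct_administered = 100 * mean(adm),
               pct_rank1 = 100 * mean(rk[, j] == 1L),
               pct_top3 = 100 * mean(rk[, j] <= 3L))
  }))
}
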