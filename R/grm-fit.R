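# Marginal maximum likelihood calibration of the graded response model.
#
# E-step: posterior weights for every person over the quadrature grid under
# the N(0,1) prior (which also fixes the latent scale). M-step: per item,
# maximize the expected complete-data log-likelihood sum_{q,k} n_qk log
# P_k(theta_q) over (alpha, betas) by quasi-Newton with analytic gradients
# on a reparameterized scale (log alpha, first threshold, log spacings)
# that keeps alpha positive and thresholds strictly ordered.

# pack/unpack the order-safe parameterization
.grm_pack <- function(alpha, betas) {
  if (length(betas) == 1L) c(log(alpha), betas)
  else c(log(alpha), betas[1], log(diff(betas)))
}

.grm_unpack <- function(par) {
  # clamps keep wild line-search steps inside the admissible region
  par[1] <- min(max(par[1], -9), 4.7)            # alpha in [1.2e-4, 110]
  par[2] <- min(max(par[2], -30), 30)
  if (length(par) > 2L) {
    par[-(1:2)] <- pmin(pmax(par[-(1:2)], -14), 3)
  }
  alpha <- exp(par[1])
  if (length(par) == 2L) betas <- par[2]
  else betas <- cumsum(c(par[2], exp(par[-(1:2)])))
  list(alpha = alpha, betas = betas)
}

# expected-count negative log-likelihood and gradient for one item.
# counts: Q x K matrix of expected responses per node/category.
.grm_item_negll <- function(par, counts, nodes) {
  th <- .grm_unpack(par)
  p <- category_probabilities(th$alpha, th$betas, nodes)
  -sum(counts * log(p))
}

.grm_item_neggrad <- function(par, counts, nodes) {
  th <- .grm_unpack(par)
  alpha <- th$alpha; betas <- th$betas
  K <- length(betas) + 1L
  star <- cbind(1, plogis(outer(nodes, betas, function(t, b) alpha * (t - b))), 0)
  w <- star * (1 - star)                       # Q x (K+1), W_0 = W_K = 0
  p <- star[, 1:K, drop = FALSE] - star[, 2:(K + 1), drop = FALSE]
  p[p < 1e-300] <- 1e-300
  r <- counts / p                              # Q x K
  # d ll / d alpha: sum_qk n_qk (dPstar_k - dPstar_{k+1}) / P_k with
  # dPstar_k/dalpha = W_k (theta - beta_k)
  dstar_a <- cbind(0, w[, 2:K, drop = FALSE] *
                     outer(nodes, betas, "-"), 0)
  g_alpha <- sum(r * (dstar_a[, 1:K, drop = FALSE] -
                        dstar_a[, 2:(K + 1), drop = FALSE]))
  # d ll / d beta_j: beta_j enters Pstar_j only; P_{j-1} gains +dPstar_j?
  # P_{j-1} = Pstar_{j-1} - Pstar_j  -> -dPstar_j
  # P_j     = Pstar_j - Pstar_{j+1}  -> +dPstar_j, dPstar_j/dbeta_j = -alpha W_j
  g_beta <- vapply(seq_len(K - 1L), function(j) {
    d <- -alpha * w[, j + 1L]
    sum(d * (r[, j + 1L] - r[, j]))
  }, 0)
  # chain rule to the packed scale
  g <- numeric(length(par))
  g[1] <- g_alpha * alpha
  if (K == 2L) {
    g[2] <- g_beta
  } else {
    g[2] <- sum(g_beta)
    for (m in seq_len(K - 2L)) {
      g[2 + m] <- sum(g_beta[(m + 1L):(K - 1L)]) * exp(par[2 + m])
    }
  }
  -g
}

#' Fit a graded response model by marginal maximum likelihood
#'
#' EM estimation of per-item discriminations and ordered thresholds under a
#' standard-normal latent trait (the prior fixes the latent scale). The
#' marginal log-likelihood is non-decreasing over EM cycles; convergence is
#' declared when the largest absolute parameter change falls below `tol`.
#' Categories never observed for an item are collapsed away before fitting
#' and the mapping is recorded.
#'
#' @param responses persons x items matrix/data frame of integer categories
#'   coded 0..K-1 (`NA` allowed and skipped in the likelihood).
#' @param grid a [quadrature_grid()].
#' @param tol convergence tolerance on the max absolute parameter change
#'   (default 1e-4).
#' @param max_iter maximum EM cycles (default 500).
#' @param verbose print per-cycle log-likelihoods.
#' @return list with `params` ([item_parameters()]), `log_lik`,
#'   `log_lik_trace`, `converged`, `n_iter`, `category_maps` (per item, the
#'   observed-category recoding applied; `NULL` when none).
#' @export
fit_grm <- function(responses, grid = quadrature_grid(), tol = 1e-4,
                    max_iter = 500L, verbose = FALSE) {
  responses <- as.matrix(responses)
  n <- nrow(responses); J <- ncol(responses)
  if (n < J) stop("need at least as many persons as items")
  item_names <- colnames(responses)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(J))

  # collapse unobserved categories, record mapping old -> new
  category_maps <- vector("list", J)
  for (j in seq_len(J)) {
    obs <- sort(unique(responses[, j]))
    obs <- obs[!is.na(obs)]
    if (length(obs) < 2L) {
      stop("item ", j, " (", item_names[j],
           ") has a single observed category; cannot be calibrated")
    }
    if (!identical(as.numeric(obs), as.numeric(seq_along(obs) - 1L))) {
      map <- match(responses[, j], obs) - 1L
      category_maps[[j]] <- data.frame(old = obs, new = seq_along(obs) - 1L)
      responses[, j] <- map
    }
  }
  K <- vapply(seq_len(J), function(j) max(responses[, j], na.rm = TRUE) + 1L, 0)

  # starting values: alpha 1, thresholds at inverse-normal marginal splits
  alpha <- rep(1, J)
  betas <- lapply(seq_len(J), function(j) {
    x <- responses[, j]; x <- x[!is.na(x)]
    cum <- cumsum(tabulate(x + 1L, nbins = K[j]))[seq_len(K[j] - 1L)] / length(x)
    b <- qnorm(pmin(pmax(cum, 0.02), 0.98)) * 1.7
    b + cumsum(c(0, pmax(0, 1e-3 - diff(b))))   # enforce strict order
  })

  nodes <- grid$nodes
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    params <- item_parameters(alpha, betas, item_names)
    # E-step (also yields the marginal log-likelihood at current params)
    logp <- .log_prob_tables(params, nodes)
    ll <- matrix(rep(log(grid$weights), each = n), n, length(nodes))
    for (j in seq_len(J)) {
      x <- responses[, j]; ok <- !is.na(x)
      ll[ok, ] <- ll[ok, ] + t(logp[[j]])[x[ok] + 1L, , drop = FALSE]
    }
    m <- apply(ll, 1L, max)
    marg <- m + log(rowSums(exp(ll - m)))
    ll_trace <- c(ll_trace, sum(marg))
    post <- exp(ll - marg)                     # n x Q, rows sum to 1
    if (verbose) message("EM cycle ", iter, "  logLik ", round(sum(marg), 4))

    # M-step per item
    max_change <- 0
    for (j in seq_len(J)) {
      x <- responses[, j]; ok <- !is.na(x)
      ind <- matrix(0, sum(ok), K[j])
      ind[cbind(seq_len(sum(ok)), x[ok] + 1L)] <- 1
      counts <- crossprod(post[ok, , drop = FALSE], ind)  # Q x K
      par0 <- .grm_pack(alpha[j], betas[[j]])
      opt <- optim(par0, .grm_item_negll, .grm_item_neggrad,
                   counts = counts, nodes = nodes, method = "BFGS",
                   control = list(maxit = 50L, reltol = 1e-10))
      new <- .grm_unpack(opt$par)
      max_change <- max(max_change, abs(new$alpha - alpha[j]),
                        abs(new$betas - betas[[j]]))
      alpha[j] <- new$alpha
      betas[[j]] <- new$betas
    }
    if (max_change < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning("GRM EM did not converge in ", max_iter,
            " cycles (max parameter change ",
            format(signif(max_change, 3)), ")")
  }
  list(params = item_parameters(alpha, betas, item_names),
       log_lik = ll_trace[length(ll_trace)], log_lik_trace = ll_trace,
       converged = converged, n_iter = iter, category_maps = category_maps)
}

#' Apply the category recoding recorded by a calibration
#'
#' [fit_grm()] collapses categories that were never observed and records
#' the old-to-new mapping per item; this helper recodes a response matrix
#' accordingly so it can be scored or tested against the fitted
#' parameters.
#'
#' @param responses persons x items matrix in the original coding.
#' @param category_maps the `category_maps` element of a [fit_grm()]
#'   result.
#' @return the recoded response matrix.
#' @export
apply_category_maps <- function(responses, category_maps) {
  responses <- as.matrix(responses)
  for (j in seq_along(category_maps)) {
    m <- category_maps[[j]]
    if (is.null(m)) next
    responses[, j] <- m$new[match(responses[, j], m$old)]
  }
  responses
}
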