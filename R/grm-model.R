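#' GRM category response probabilities
#'
#' Samejima's graded response model. The cumulative ("star") probabilities
#' are `P*_k(theta) = 1 / (1 + exp(-alpha (theta - beta_k)))` with
#' `P*_0 = 1` and `P*_K = 0`; category probabilities are the successive
#' differences `P_k = P*_k - P*_{k+1}` for `k = 0, ..., K-1`.
#'
#' @param alpha discrimination (> 0).
#' @param betas strictly increasing threshold vector, length K - 1.
#' @param theta numeric vector of latent-trait values.
#' @return a `length(theta) x K` matrix of category probabilities; rows sum
#'   to one.
#' @export
#' @examples
#' category_probabilities(2, c(-1, 1), 0)  # c(0.1192, 0.7616, 0.1192)
category_probabilities <- function(alpha, betas, theta) {
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  if (length(betas) > 1L && any(diff(betas) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  if (alpha <= 0) stop("discrimination must be > 0")
  K <- length(betas) + 1L
  star <- cbind(1, plogis(outer(theta, betas, function(t, b) alpha * (t - b))), 0)
  p <- star[, seq_len(K), drop = FALSE] - star[, seq_len(K) + 1L, drop = FALSE]
  # numerical floor keeps log-likelihoods finite at extreme theta
  p[p < 1e-300] <- 1e-300
  unname(p)
}

#' GRM item information function
#'
#' Fisher information of a graded item about theta, from the category
#' response derivatives: `I(theta) = sum_k (P_k')^2 / P_k` where
#' `P_k' = alpha (W_k - W_{k+1})` and `W_k = P*_k (1 - P*_k)`.
#'
#' @inheritParams category_probabilities
#' @return numeric vector of information values at `theta` (>= 0).
#' @export
item_information <- function(alpha, betas, theta) {
  K <- length(betas) + 1L
  star <- cbind(1, plogis(outer(theta, betas, function(t, b) alpha * (t - b))), 0)
  w <- star * (1 - star)
  dp <- alpha * (w[, seq_len(K), drop = FALSE] - w[, seq_len(K) + 1L, drop = FALSE])
  p <- star[, seq_len(K), drop = FALSE] - star[, seq_len(K) + 1L, drop = FALSE]
  p[p < 1e-300] <- 1e-300
  rowSums(dp^2 / p)
}

#' Test information, item information and test characteristic curve
#'
#' Evaluates, on a theta grid, each item's information curve, the test
#' information function (TIF, the sum over items), and the test
#' characteristic curve (TCC): the model-expected summed score
#' `sum_items sum_k k P_k(theta)` with categories coded 0..K-1.
#'
#' @param params an [item_parameters()] object.
#' @param theta_grid numeric vector of theta values (default 121 points on
#'   \[-4.5, 4.5\]).
#' @return an object of class `information_profile`: list with
#'   `theta_grid`, `item_information` (grid x items matrix),
#'   `test_information`, and `tcc`.
#' @export
information_profile <- function(params, theta_grid = seq(-4.5, 4.5, length.out = 121)) {
  J <- n_items(params)
  ii <- matrix(0, length(theta_grid), max(J, 1L))
  tcc <- numeric(length(theta_grid))
  if (J == 0L) {
    ii <- matrix(0, length(theta_grid), 0L)
  } else {
    for (j in seq_len(J)) {
      ii[, j] <- item_information(params$alpha[j], params$betas[[j]], theta_grid)
      p <- category_probabilities(params$alpha[j], params$betas[[j]], theta_grid)
      tcc <- tcc + p %*% (seq_len(ncol(p)) - 1)
    }
    colnames(ii) <- params$item_names
  }
  structure(
    list(theta_grid = theta_grid, item_information = ii,
         test_information = rowSums(ii), tcc = as.numeric(tcc)),
    class = "information_profile"
  )
}

#' T-score transform and its inverse
#'
#' `T = 50 + 10 theta`, anchoring scores to a calibration population with
#' mean 50 and SD 10.
#'
#' @param theta_hat numeric vector of trait estimates.
#' @param t_score numeric vector of T-scores.
#' @return the transformed vector.
#' @export
#' @examples
#' t_transform(0)     # 50
#' t_inverse(30)      # -2
t_transform <- function(theta_hat) {
  stopifnot(all(is.finite(theta_hat)))
  50 + 10 * theta_hat
}

#' @rdname t_transform
#' @export
t_inverse <- function(t_score) (t_score - 50) / 10

#' Quadrature grid under a normal prior
#'
#' Equally spaced nodes weighted by the N(mean, sd) prior density and
#' renormalized to sum to one — the grid used for EAP scoring, marginal
#' maximum likelihood and posterior-weighted item selection.
#'
#' @param n_nodes number of nodes (default 61).
#' @param range theta range covered (default c(-4.5, 4.5)).
#' @param mean,sd prior mean and SD (default standard normal).
#' @return list with `nodes` and `weights` (weights sum to 1).
#' @export
quadrature_grid <- function(n_nodes = 61L, range = c(-4.5, 4.5),
                            mean = 0, sd = 1) {
  stopifnot(n_nodes >= 3L, range[2] > range[1], sd > 0)
  nodes <- seq(range[1], range[2], length.out = n_nodes)
  w <- dnorm(nodes, mean, sd)
  # trapezoid end-point weights: integrals then agree with arbitrarily
  # dense grids on the same support instead of carrying an O(h) boundary
  # term when posterior mass reaches the edge of the grid
  w[c(1L, n_nodes)] <- w[c(1L, n_nodes)] / 2
  list(nodes = nodes, weights = w / sum(w))
}

# log category-probability arrays for a bank, evaluated on a node vector:
# list over items of (n_nodes x K_i) matrices. Shared by the EM, EAP and CAT.
.log_prob_tables <- function(params, nodes) {
  lapply(seq_len(n_items(params)), function(j) {
    log(category_probabilities(params$alpha[j], params$betas[[j]], nodes))
  })
}

# posterior weights over grid nodes for each person (rows of `responses`,
# integer categories 0..K-1, NA allowed = skipped). Returns n x Q matrix.
.posterior_matrix <- function(responses, params, grid) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  Q <- length(grid$nodes)
  logp <- .log_prob_tables(params, grid$nodes)
  ll <- matrix(rep(log(grid$weights), each = n), n, Q)
  for (j in seq_len(n_items(params))) {
    x <- responses[, j]
    ok <- !is.na(x)
    if (!any(ok)) next
    ll[ok, ] <- ll[ok, ] + t(logp[[j]])[x[ok] + 1L, , drop = FALSE]
  }
  m <- apply(ll, 1L, max)
  w <- exp(ll - m)
  w / rowSums(w)
}
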