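#' EAP scoring of response patterns
#'
#' Expected a posteriori trait estimates under a normal prior: for each
#' person, the posterior over the quadrature grid is proportional to
#' `prior(theta) * prod_j P(x_j | theta)`; `theta_hat` is the posterior
#' mean and `se` the posterior SD. Missing responses are skipped in the
#' likelihood; an all-missing row returns the prior mean and SD and is
#' flagged.
#'
#' @param responses integer matrix or data frame of categories coded
#'   0..K-1 (persons x items); `NA` allowed.
#' @param params an [item_parameters()] object matching the columns.
#' @param grid a [quadrature_grid()]; its weights encode the prior.
#' @return a `score_table` data frame with columns `person_id`,
#'   `theta_hat`, `se_theta`, `t_score` (= 50 + 10 theta_hat), `raw_sum`,
#'   `n_answered`, `prior_only` (logical flag for all-missing rows).
#' @export
eap_score <- function(responses, params, grid = quadrature_grid()) {
  responses <- as.matrix(responses)
  if (ncol(responses) != n_items(params)) {
    stop("response columns (", ncol(responses), ") must match item count (",
         n_items(params), ")")
  }
  K <- n_categories(params)
  for (j in seq_len(ncol(responses))) {
    x <- responses[, j]
    bad <- which(!is.na(x) & (x < 0 | x > K[j] - 1L | x != floor(x)))
    if (length(bad)) {
      stop("out-of-range category at row ", bad[1], ", item ", j,
           " (value ", x[bad[1]], ", allowed 0..", K[j] - 1L, ")")
    }
  }
  post <- .posterior_matrix(responses, params, grid)
  theta_hat <- as.numeric(post %*% grid$nodes)
  m2 <- as.numeric(post %*% grid$nodes^2)
  se <- sqrt(pmax(m2 - theta_hat^2, 0))
  n_answered <- rowSums(!is.na(responses))
  prior_only <- n_answered == 0L
  if (any(prior_only)) {
    warning(sum(prior_only), " all-missing row(s) scored at the prior")
  }
  ids <- rownames(responses)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(responses)))
  structure(
    data.frame(person_id = ids, theta_hat = theta_hat, se_theta = se,
               t_score = 50 + 10 * theta_hat,
               raw_sum = rowSums(responses, na.rm = TRUE),
               n_answered = n_answered, prior_only = prior_only,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("score_table", "data.frame")
  )
}

#' Write / read a score table as CSV
#' @param scores a `score_table` from [eap_score()].
#' @param path file path.
#' @return the path (write) or the score table (read).
#' @export
write_scores <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("score_table", "data.frame")
  df
}

#' Marginal reliability of EAP scores
#'
#' Two coefficients summarizing measurement precision over a population:
#' the theoretical coefficient `rho_T = 1 - integral v(theta) phi(theta)
#' d theta`, where `v(theta)` is the expected posterior variance of a
#' respondent at true theta (computed by quadrature under the standard
#' normal prior); and the empirical coefficient
#' `rho_E = var(theta_hat) / (var(theta_hat) + mean(se^2))`, which uses the
#' observed score distribution. Under a ceiling-skewed sample the empirical
#' coefficient falls below the theoretical one.
#'
#' @param params an [item_parameters()] object.
#' @param scores a `score_table` from [eap_score()] (for `rho_E`).
#' @param grid quadrature grid for the population integral.
#' @return list with `rho_theoretical`, `rho_empirical`, and `band`
#'   labels ("acceptable" 0.70-0.80, "good" 0.81-0.90, "excellent" >0.90).
#' @export
marginal_reliabilities <- function(params, scores, grid = quadrature_grid()) {
  if (nrow(scores) == 0L) stop("empty score table")
  # posterior variance at true theta from the TIF: v(theta) =
  # 1 / (I(theta) + 1); the +1 is the N(0,1) prior's information.
  I <- information_profile(params, grid$nodes)$test_information
  v <- 1 / (I + 1)
  rho_t <- 1 - sum(v * grid$weights)
  rho_e <- var(scores$theta_hat) /
    (var(scores$theta_hat) + mean(scores$se_theta^2))
  band <- function(r) {
    if (r > 0.90) "excellent" else if (r > 0.80) "good"
    else if (r >= 0.70) "acceptable" else "insufficient"
  }
  list(rho_theoretical = rho_t, rho_empirical = rho_e,
       band = c(theoretical = band(rho_t), empirical = band(rho_e)))
}
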