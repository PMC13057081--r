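# shared fixtures: small banks and populations built in code

fix_bank <- function(J = 8L, seed = 100L, K = 5L, ...) {
  generate_item_bank(bank_spec(J, K, ...), seed)
}

# a hand-specified 3-item bank with easy-to-reason-about parameters
fix_tiny_bank <- function() {
  item_parameters(c(1.5, 2.0, 1.0),
                  list(c(-1, 0, 1), c(-0.5, 0.5), c(0)),
                  c("a", "b", "c"))
}

fix_responses <- function(bank, n = 500L, seed = 100L, theta = NULL, ...) {
  if (is.null(theta)) {
    theta <- simulate_thetas(population_spec(n, ...), seed)$theta
  }
  simulate_responses(bank, theta, seed = seed)
}

# numerical EAP oracle: dense-grid posterior integration over the
# scoring model's latent support
oracle_eap <- function(row, params, n_grid = 1e5, lim = 4.5) {
  thg <- seq(-lim, lim, length.out = n_grid)
  lp <- dnorm(thg, log = TRUE)
  for (j in seq_len(n_items(params))) {
    if (is.na(row[j])) next
    p <- category_probabilities(params$alpha[j], params$betas[[j]], thg)
    lp <- lp + log(p[cbind(seq_len(n_grid), row[j] + 1L)])
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  th <- sum(w * thg)
  list(theta = th, se = sqrt(sum(w * thg^2) - th^2))
}
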