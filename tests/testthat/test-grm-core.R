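test_that("category probabilities match the graded-model algebra", {
  # logistic at its location splits a 2-category item evenly
  expect_equal(as.numeric(category_probabilities(1, 0, 0)), c(0.5, 0.5))
  # hand-evaluated: P*(+-1) with alpha = 2 gives 1/(1+e^-2) = 0.88079...
  p <- as.numeric(category_probabilities(2, c(-1, 1), 0))
  expect_equal(p, c(0.1192, 0.7616, 0.1192), tolerance = 1e-4)
  # extreme theta concentrates all mass in the top category
  p_hi <- category_probabilities(1.7, c(-1, 0, 1, 2), 40)
  expect_equal(p_hi[1, 5], 1, tolerance = 1e-10)
  expect_error(category_probabilities(2, c(1, -1), 0), "increasing")
})

test_that("category probabilities sum to one across random parameter draws", {
  set.seed(42)
  for (r in 1:25) {
    K <- sample(2:6, 1)
    alpha <- runif(1, 0.3, 3.5)
    betas <- sort(runif(K - 1, -3, 3))
    if (K > 2) betas <- betas + cumsum(c(0, pmax(0, 1e-3 - diff(betas))))
    th <- runif(7, -6, 6)
    p <- category_probabilities(alpha, betas, th)
    expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("T transform is the 50 + 10 theta anchor with an inverse", {
  expect_equal(t_transform(c(0, -2, 0.41)), c(50, 30, 54.1))
  expect_equal(t_inverse(t_transform(1.234)), 1.234)
})

test_that("item information has the closed logistic form and adds over items", {
  # 2-category item at its threshold: I = alpha^2 / 4
  for (a in c(0.5, 1, 2.3)) {
    expect_equal(item_information(a, 0, 0), a^2 * 0.25, tolerance = 1e-10)
  }
  bank <- fix_bank(5, seed = 7)
  doubled <- item_parameters(rep(bank$alpha, 2), c(bank$betas, bank$betas))
  g <- seq(-3, 3, length.out = 21)
  expect_equal(information_profile(doubled, g)$test_information,
               2 * information_profile(bank, g)$test_information,
               tolerance = 1e-10)
  empty <- information_profile(subset_items(bank, integer(0)), g)
  expect_equal(empty$test_information, rep(0, 21))
  expect_equal(empty$tcc, rep(0, 21))
})

test_that("test characteristic curve is non-decreasing in theta", {
  bank <- fix_bank(9, seed = 3)
  prof <- information_profile(bank)
  expect_true(all(diff(prof$tcc) >= -1e-10))
  expect_true(all(prof$test_information >= 0))
})

test_that("EAP scoring reduces to the prior for empty rows and orders extremes", {
  bank <- fix_tiny_bank()
  expect_warning(sc0 <- eap_score(matrix(NA_integer_, 1, 3), bank),
                 "all-missing")
  expect_equal(sc0$theta_hat, 0, tolerance = 1e-8)
  expect_equal(sc0$se_theta, 1, tolerance = 1e-2)   # grid-truncated prior SD
  top <- eap_score(matrix(c(3L, 2L, 1L), 1), bank)
  bot <- eap_score(matrix(c(0L, 0L, 0L), 1), bank)
  expect_gt(top$theta_hat, bot$theta_hat)
  expect_equal(top$t_score, 50 + 10 * top$theta_hat)
})

test_that("EAP matches dense-grid posterior integration", {
  bank <- fix_bank(6, seed = 9)
  X <- fix_responses(bank, n = 20, seed = 9)
  sc <- eap_score(X, bank)
  for (i in seq_len(nrow(X))) {
    o <- oracle_eap(X[i, ], bank, n_grid = 2e4)
    expect_lt(abs(sc$theta_hat[i] - o$theta), 1e-4)
    expect_lt(abs(sc$se_theta[i] - o$se), 1e-4)
  }
})

test_that("EAP rejects out-of-range categories with the cell named", {
  bank <- fix_tiny_bank()
  X <- matrix(c(1L, 5L, 0L), 1)
  expect_error(eap_score(X, bank), "row 1, item 2")
})

test_that("GRM calibration recovers generating parameters at moderate n", {
  bank <- fix_bank(8, seed = 15, alpha_range = c(1.2, 2.6),
                   threshold_span = c(-2, 2.2))
  X <- fix_responses(bank, n = 1500, seed = 15)
  fit <- fit_grm(X)
  expect_true(fit$converged)
  expect_gt(cor(fit$params$alpha, bank$alpha), 0.9)
  expect_lt(sqrt(mean((unlist(fit$params$betas) - unlist(bank$betas))^2)), 0.2)
  # EM marginal log-likelihood never decreases
  expect_true(all(diff(fit$log_lik_trace) > -1e-6))
})

test_that("identical response columns give identical estimates", {
  bank <- fix_bank(4, seed = 16)
  X <- fix_responses(bank, n = 400, seed = 16)
  X2 <- cbind(X, X[, 2])
  colnames(X2) <- paste0("it", 1:5)
  fit <- fit_grm(X2)
  expect_equal(fit$params$alpha[2], fit$params$alpha[5], tolerance = 1e-6)
  expect_equal(fit$params$betas[[2]], fit$params$betas[[5]], tolerance = 1e-6)
})

test_that("single-observed-category items are rejected with a message", {
  bank <- fix_bank(3, seed = 17)
  X <- fix_responses(bank, n = 100, seed = 17)
  X[, 2] <- 1L
  expect_error(fit_grm(X), "single observed category")
})

test_that("unobserved categories are collapsed with the mapping recorded", {
  bank <- fix_bank(3, seed = 18)
  X <- fix_responses(bank, n = 300, seed = 18)
  X[X[, 1] == 2L, 1] <- 3L           # category 2 never observed
  obs <- sort(unique(X[, 1]))
  fit <- suppressWarnings(fit_grm(X))
  map <- fit$category_maps[[1]]
  expect_false(is.null(map))
  expect_equal(map$old, obs)
  expect_equal(map$new, seq_along(obs) - 1)
  expect_length(fit$params$betas[[1]], length(obs) - 1L)
  # recoded responses score cleanly against the fitted parameters
  Xr <- apply_category_maps(X, fit$category_maps)
  expect_lte(max(Xr[, 1]), length(obs) - 1L)
  expect_silent(eap_score(Xr, fit$params))
})

test_that("marginal reliabilities align for a matched normal population", {
  bank <- fix_bank(10, seed = 19, alpha_range = c(1.5, 2.5))
  X <- fix_responses(bank, n = 3000, seed = 19)
  sc <- eap_score(X, bank)
  mr <- marginal_reliabilities(bank, sc)
  expect_true(mr$rho_theoretical > 0 && mr$rho_theoretical < 1)
  expect_lt(abs(mr$rho_theoretical - mr$rho_empirical), 0.03)
})

test_that("item parameter JSON round-trips at full precision", {
  bank <- fix_bank(5, seed = 20)
  path <- withr::local_tempfile(fileext = ".json")
  write_item_parameters(bank, path)
  back <- read_item_parameters(path)
  expect_equal(back$alpha, bank$alpha, tolerance = 1e-12)
  expect_equal(back$betas, bank$betas, tolerance = 1e-12)
  expect_equal(back$item_names, bank$item_names)
})
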