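test_that("polychoric correlation recovers known latent correlations", {
  set.seed(77)
  n <- 10000
  for (rho in c(0, 0.6)) {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    x <- findInterval(z1, c(-1, -0.2, 0.5, 1.2))
    y <- findInterval(z2, c(-0.8, 0, 0.7, 1.5))
    pc <- polychoric_matrix(cbind(x, y))
    expect_lt(abs(pc$rho[1, 2] - rho), 0.05)
    expect_equal(diag(pc$rho), c(x = 1, y = 1))
    expect_equal(pc$rho[1, 2], pc$rho[2, 1])
  }
  # dichotomized case with rho = 0.6 stays in the stated window
  z1 <- rnorm(n); z2 <- 0.6 * z1 + 0.8 * rnorm(n)
  pc2 <- polychoric_matrix(cbind(as.integer(z1 > 0), as.integer(z2 > 0.3)))
  expect_true(pc2$rho[1, 2] > 0.55 && pc2$rho[1, 2] < 0.65)
})

test_that("independent items give near-zero polychoric correlations", {
  set.seed(78)
  X <- replicate(4, findInterval(rnorm(5000), c(-1, 0, 1)))
  pc <- polychoric_matrix(X)
  off <- pc$rho[upper.tri(pc$rho)]
  expect_true(all(abs(off) < 0.05))
})

test_that("single-factor fit indices separate clean and violated structures", {
  bank <- fix_bank(8, seed = 81, alpha_range = c(1.4, 2.4))
  X <- fix_responses(bank, n = 2000, seed = 81)
  pc <- polychoric_matrix(X)
  sf <- single_factor_fit(pc$rho, nrow(X))
  expect_gte(sf$cfi, 0.95)
  expect_lte(sf$srmr, 0.08)
  expect_true(all(sf$loadings > 0.3 & sf$loadings < 1))
  # an exactly rank-one-plus-diagonal matrix fits perfectly
  lam <- seq(0.5, 0.9, length.out = 6)
  R1 <- tcrossprod(lam); diag(R1) <- 1
  sf1 <- single_factor_fit(R1, 500)
  expect_lt(sf1$srmr, 1e-4)
  expect_gte(sf1$cfi, 0.999)
  # two orthogonal clusters must fail at least one index
  b1 <- fix_bank(4, seed = 82); b2 <- fix_bank(4, seed = 83)
  set.seed(84)
  Xo <- cbind(simulate_responses(b1, rnorm(2000), seed = 84),
              simulate_responses(b2, rnorm(2000), seed = 85))
  sfo <- single_factor_fit(polychoric_matrix(Xo)$rho, 2000)
  expect_true(any(!sfo$verdicts))
  expect_error(single_factor_fit(diag(2), 100), "3 items")
})

test_that("residual correlations flag injected local dependence only", {
  lam <- rep(0.7, 8)
  R <- tcrossprod(lam); diag(R) <- 1
  sf <- single_factor_fit(R, 1000)
  rc <- residual_correlations(R, sf$loadings)
  expect_equal(rc$n_flagged, 0L)
  # inject one locally dependent pair
  R2 <- R; R2[2, 5] <- R2[5, 2] <- R[2, 5] + 0.3
  sf2 <- single_factor_fit(.5 * (R2 + t(R2)), 1000)
  rc2 <- residual_correlations(R2, sf2$loadings)
  flagged <- rc2$pairs[rc2$pairs$flagged, ]
  expect_equal(nrow(flagged), 1L)
  expect_equal(c(flagged$item_i, flagged$item_j), c(2, 5))
  expect_equal(rc2$label, sprintf("1 (%.1f)", 100 / 28))
})

test_that("bifactor indices are exact on constructed loading matrices", {
  # equal general and group loadings split common variance evenly
  idx <- bifactor_indices_from_loadings(rep(0.5, 6), matrix(rep(0.5, 6), 6))
  expect_equal(idx$ecv, 0.5)
  # hand-computed mixed structure
  lg <- c(0.8, 0.7, 0.6, 0.5)
  ls <- matrix(c(0.3, 0.3, 0, 0, 0, 0, 0.4, 0.4), 4, 2)
  idx2 <- bifactor_indices_from_loadings(lg, ls)
  expect_equal(idx2$ecv, sum(lg^2) / (sum(lg^2) + sum(ls^2)))
  uniq <- 1 - lg^2 - rowSums(ls^2)
  vt <- sum(lg)^2 + sum(colSums(ls)^2) + sum(uniq)
  expect_equal(idx2$omega_h, sum(lg)^2 / vt)
  # zero group loadings: all common variance is general
  idx3 <- bifactor_indices_from_loadings(rep(0.7, 6), matrix(0, 6, 2))
  expect_equal(idx3$ecv, 1)
})

test_that("essentially unidimensional data earn supportive bifactor verdicts", {
  bank <- fix_bank(10, seed = 86, alpha_range = c(1.5, 2.5))
  X <- fix_responses(bank, n = 2000, seed = 86)
  bf <- bifactor_indices(polychoric_matrix(X)$rho)
  expect_gte(bf$ecv, 0.70)
  expect_gte(bf$omega_h, 0.80)
  expect_true(all(bf$verdicts))
  expect_lte(bf$omega_h, 1)
  expect_error(bifactor_indices(diag(4)), "6 items")
})

test_that("Mokken H is 1 on Guttman data and near 0 on independent items", {
  # perfect Guttman pattern: person i endorses the first i items
  n <- 60; J <- 6
  X <- matrix(0L, n, J)
  for (i in seq_len(n)) X[i, seq_len(min(J, i %/% 10))] <- 1L
  mk <- mokken_coefficients(X)
  expect_equal(mk$H, 1, tolerance = 1e-12)
  set.seed(87)
  Xi <- replicate(6, sample(0:4, 5000, replace = TRUE))
  mki <- mokken_coefficients(Xi)
  expect_lt(abs(mki$H), 0.05)
  # highly discriminating graded items scale acceptably
  bankh <- fix_bank(6, seed = 88, alpha_range = c(2.5, 2.5))
  Xh <- fix_responses(bankh, n = 2000, seed = 88)
  mkh <- mokken_coefficients(Xh)
  expect_gte(mkh$H, 0.5)
  expect_true(mkh$verdicts$H_acceptable)
})

test_that("Mokken H is invariant to person reordering and drops constant items", {
  bank <- fix_bank(5, seed = 89)
  X <- fix_responses(bank, n = 400, seed = 89)
  mk1 <- mokken_coefficients(X)
  mk2 <- mokken_coefficients(X[sample(nrow(X)), ])
  expect_equal(mk1$H, mk2$H, tolerance = 1e-12)
  Xz <- cbind(X, zero = 2L)
  expect_warning(mkz <- mokken_coefficients(Xz), "zero-variance")
  expect_equal(mkz$H, mk1$H, tolerance = 1e-12)
})

test_that("monotonicity holds for graded data and catches an inverted item", {
  bank <- fix_bank(6, seed = 90, alpha_range = c(1.5, 2.5))
  X <- fix_responses(bank, n = 529, seed = 90)
  mono <- monotonicity_check(X)
  expect_lte(sum(mono$violations), 1)
  # reversing one item's coding creates detectable violations
  Xr <- X; Xr[, 3] <- 4L - Xr[, 3]
  monor <- monotonicity_check(Xr)
  expect_gt(monor$violations[3], 2)
  # one rest-score group only: nothing checkable
  mono1 <- monotonicity_check(X[1:30, ], min_group_size = 100)
  expect_true(all(!mono1$checkable))
})

test_that("HT reflects item-ordering accuracy with the banded labels", {
  # widely separated, steep items order invariantly
  bank <- item_parameters(rep(2.5, 5),
                          list(c(-2.4, -2, -1.6, -1.2), c(-1.4, -1, -0.6, -0.2),
                               c(-0.4, 0, 0.4, 0.8), c(0.6, 1, 1.4, 1.8),
                               c(1.6, 2, 2.4, 2.8)))
  X <- fix_responses(bank, n = 800, seed = 91)
  ht <- iio_ht(X)
  expect_gte(ht$HT, 0.50)
  expect_equal(ht$band, "high accuracy")
  # identical totals for everyone: undefined
  ht0 <- iio_ht(matrix(1L, 10, 3))
  expect_true(is.na(ht0$HT))
})
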