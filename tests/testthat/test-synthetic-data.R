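test_that("degenerate bank spec forces the parameter values", {
  spec <- bank_spec(1, 2, alpha_range = c(1, 1), threshold_span = c(0, 0))
  bank <- generate_item_bank(spec, 1)
  expect_equal(bank$alpha, 1)
  expect_equal(bank$betas[[1]], 0)
})

test_that("bank generation is reproducible and yields ordered thresholds", {
  spec <- bank_spec(13, 5)
  b1 <- generate_item_bank(spec, 42)
  b2 <- generate_item_bank(spec, 42)
  expect_identical(b1$alpha, b2$alpha)
  expect_identical(b1$betas, b2$betas)
  expect_equal(n_items(b1), 13L)
  for (b in b1$betas) {
    expect_length(b, 4L)
    expect_true(all(diff(b) > 0))
  }
  b3 <- generate_item_bank(spec, 43)
  expect_false(identical(b1$alpha, b3$alpha))
  expect_error(bank_spec(5, 5, alpha_range = c(-1, 2)))
})

test_that("latent traits follow the requested distribution", {
  pop <- population_spec(1e4)
  th <- simulate_thetas(pop, 5)$theta
  expect_lt(abs(mean(th)), 0.05)
  expect_true(sd(th) > 0.97 && sd(th) < 1.03)
  # full ceiling mass: everyone at the best-functioning extreme
  pop1 <- population_spec(200, ceiling_mass = 1, best_direction = "low")
  th1 <- simulate_thetas(pop1, 5)$theta
  expect_lt(max(th1), -1.2)
  expect_lt(abs(mean(th1) + 2.5), 0.1)
  # seed sensitivity
  expect_false(identical(simulate_thetas(pop, 1)$theta,
                         simulate_thetas(pop, 2)$theta))
  expect_error(population_spec(10, covariate_margins = list(g = c(a = .6, b = .6))),
               "sum to 1")
})

test_that("skewed trait option standardizes to mean 0 / SD 1", {
  pop <- population_spec(2e4, theta_distribution = list(kind = "skewed", shape = 4))
  th <- simulate_thetas(pop, 6)$theta
  expect_lt(abs(mean(th)), 0.05)
  expect_lt(abs(sd(th) - 1), 0.03)
  skew <- mean(((th - mean(th)) / sd(th))^3)
  expect_gt(skew, 0.3)
})

test_that("response simulation matches quadrature-integrated marginals", {
  params <- item_parameters(1.7, list(c(-1, 0, 1, 2)))
  th <- simulate_thetas(population_spec(5000), 31)$theta
  X <- simulate_responses(params, th, seed = 31)
  emp <- tabulate(X[, 1] + 1L, 5) / 5000
  g <- quadrature_grid(201, c(-6, 6))
  expected <- colSums(category_probabilities(1.7, c(-1, 0, 1, 2), g$nodes) *
                        g$weights)
  expect_true(all(abs(emp - expected) < 0.02))
  # deterministic limit: huge alpha, theta above the only threshold
  big <- item_parameters(80, list(0))
  Xb <- simulate_responses(big, rep(2, 200), seed = 1)
  expect_true(all(Xb == 1L))
  expect_error(simulate_responses(params, c(0, Inf), seed = 1), "finite")
})

test_that("injected uniform DIF shifts only the targeted item for the focal group", {
  bank <- fix_bank(6, seed = 33)
  pop <- population_spec(5000, covariate_margins = list(g = c(ref = .5, foc = .5)))
  pers <- simulate_thetas(pop, 33)
  X0 <- simulate_responses(bank, pers, seed = 33)
  X1 <- simulate_responses(bank, pers,
                           dif = dif_spec(2, "g", "foc", uniform_shift = 0.5),
                           seed = 33)
  foc <- pers$g == "foc"
  # same seed, zero-shift spec reproduces the no-DIF data exactly
  X2 <- simulate_responses(bank, pers, dif = dif_spec(2, "g", "foc", 0), seed = 33)
  expect_identical(X0, X2)
  # reference group and off-target items untouched
  expect_identical(X0[!foc, ], X1[!foc, ])
  expect_identical(X0[, -2], X1[, -2])
  # positive threshold shift makes the item harder for the focal group
  expect_lt(mean(X1[foc, 2]), mean(X0[foc, 2]) - 0.05)
})

test_that("legacy scale hits the target correlation and the 0-100 coding", {
  th <- simulate_thetas(population_spec(5000), 44)$theta
  leg <- simulate_legacy_scale(th, 0.7, seed = 44)
  r <- cor(th, leg$latent)
  expect_true(r > 0.67 && r < 0.73)
  # category 0 ("never a problem") maps to item score 100
  expect_true(all(leg$item_scores[leg$items == 0L] == 100))
  expect_true(all(leg$item_scores >= 0 & leg$item_scores <= 100))
  # perfect correlation: legacy latent == standardized theta
  leg1 <- simulate_legacy_scale(th, 1, seed = 44)
  expect_equal(leg1$latent, (th - mean(th)) / sd(th), tolerance = 1e-10)
})

test_that("reference sampling meets margins when feasible and flags when not", {
  pop <- population_spec(800, covariate_margins = list(
    sex = c(m = .5, f = .5), edu = c(lo = .2, mid = .4, hi = .4)))
  pers <- simulate_thetas(pop, 55)
  margins <- list(sex = c(m = .5, f = .5),
                  edu = c(lo = .135, mid = .36, hi = .505))
  dr <- draw_reference_sample(pers, margins, n_target = 370)
  expect_equal(nrow(dr$sample), 370L)
  expect_true(all(!dr$deviations$flagged))
  expect_true(all(dr$deviations$deviation <= 0.025))
  # a pool with no low-education members cannot meet that stratum
  pers2 <- pers[pers$edu != "lo", ]
  dr2 <- draw_reference_sample(pers2, margins["edu"], n_target = 300)
  expect_true(dr2$deviations$flagged[dr2$deviations$level == "lo"])
  # pool already matching margins: no flags
  dr3 <- draw_reference_sample(pers, list(sex = c(
    m = mean(pers$sex == "m"), f = mean(pers$sex == "f"))))
  expect_true(all(!dr3$deviations$flagged))
  expect_error(draw_reference_sample(pers[0, ], margins), "empty")
})

test_that("child seeds are deterministic, stage-distinct and 32-bit safe", {
  expect_identical(child_seed(7, "bank"), child_seed(7, "bank"))
  expect_false(child_seed(7, "bank") == child_seed(7, "thetas"))
  expect_false(child_seed(7, "bank") == child_seed(8, "bank"))
  big <- vapply(c("a", "boot", "responses"), function(s)
    child_seed(2147483646, s), 0L)
  expect_true(all(abs(big) < 2^31))
})

test_that("response CSV round-trips through write/read including 1-based files", {
  bank <- fix_bank(4, seed = 66)
  pop <- population_spec(30, covariate_margins = list(sex = c(m = .5, f = .5)))
  pers <- simulate_thetas(pop, 66)
  X <- simulate_responses(bank, pers, seed = 66)
  p0 <- withr::local_tempfile(fileext = ".csv")
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_responses(X, p0, covariates = pers["sex"])
  write_responses(X, p1, covariates = pers["sex"], category_base = 1L)
  r0 <- read_responses(p0, covariate_columns = "sex")
  r1 <- read_responses(p1, covariate_columns = "sex", category_base = 1L)
  expect_identical(r0$responses, r1$responses)
  expect_equal(unname(r0$responses), unname(X))
  expect_equal(as.character(r0$covariates$sex), as.character(pers$sex))
  # invalid category errors name the offending cell
  bad <- X; bad[3, 2] <- 9L
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(bad, p2)
  expect_error(read_responses(p2, n_categories = 5), "row 3")
})
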