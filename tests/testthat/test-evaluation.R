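test_that("reliability summaries count reliable persons and handle the ceiling", {
  sc <- data.frame(se_theta = rep(0.2, 10), raw_sum = 1:10)
  expect_equal(reliability_summary(sc, 5)$pct_reliable, 100)
  sc$se_theta <- rep(0.5, 10)
  expect_equal(reliability_summary(sc, 5)$pct_reliable, 0)
  # ceiling exclusion improves reliability on skewed data
  bank <- fix_bank(10, seed = 131, threshold_span = c(-3, 0.5),
                   direction = "function")
  pop <- population_spec(800, ceiling_mass = 0.35, best_direction = "high")
  pers <- simulate_thetas(pop, 131)
  X <- simulate_responses(bank, pers, seed = 131)
  sc2 <- eap_score(X, bank)
  max_raw <- sum(n_categories(bank) - 1L)
  tot <- reliability_summary(sc2, 10, FALSE, "function", max_raw)
  noc <- reliability_summary(sc2, 10, TRUE, "function", max_raw)
  expect_gt(noc$pct_reliable, tot$pct_reliable)
  expect_lt(noc$n, tot$n)
})

test_that("efficiency follows the information-per-item formula", {
  expect_equal(efficiency(0.32, 8), (1 - 0.32^2) / 8)
  expect_equal(round(efficiency(0.32, 8), 4), 0.1122)
  expect_equal(efficiency(1, 5), 0)
  # halving the item count doubles efficiency at fixed SE
  expect_equal(efficiency(0.32, 4), 2 * efficiency(0.32, 8))
  expect_warning(e <- efficiency(1.2, 3), "floored")
  expect_equal(e, 0)
})

test_that("relative efficiency of an application with itself is exactly 1", {
  se <- runif(200, 0.2, 0.6)
  re <- relative_efficiency(se, se, 8, 8, n_boot = 500, seed = 5)
  expect_equal(re$ratio, 1)
  expect_lte(re$ci_low, 1)
  expect_gte(re$ci_high, 1)
  expect_error(relative_efficiency(se, se[-1], 8, 8), "same persons")
})

test_that("bootstrap intervals bracket a known efficiency ratio", {
  set.seed(132)
  se_a <- runif(400, 0.30, 0.50)
  se_b <- runif(400, 0.30, 0.50)
  true_ratio <- mean((1 - se_b^2) / 4) / mean((1 - se_a^2) / 8)
  re <- relative_efficiency(se_a, se_b, 8, 4, n_boot = 1000, seed = 6)
  expect_equal(re$ratio, true_ratio, tolerance = 1e-12)
  expect_true(re$ci_low < true_ratio && true_ratio < re$ci_high)
  expect_gt(re$ci_low, 1)   # halving items at similar SE is clearly better
})

test_that("construct validity marks unmet expectations", {
  set.seed(133)
  th <- rnorm(400)
  strong <- 0.8 * th + 0.6 * rnorm(400)
  weak <- 0.3 * th + rnorm(400)
  hyp <- data.frame(measure = c("m_strong", "m_weak"),
                    expected_threshold = c(0.5, 0.7))
  out <- construct_validity(hyp, list(
    m_strong = list(x = th, y = strong),
    m_weak = list(x = th, y = weak)))
  expect_true(out$met[1])
  expect_equal(out$marked[1], "")
  expect_false(out$met[2])
  expect_equal(out$marked[2], "*")
  # exact linear transform: |r| = 1, met for any threshold < 1
  out2 <- construct_validity(
    data.frame(measure = "lin", expected_threshold = 0.99),
    list(lin = list(x = th, y = 100 - 3 * th)))
  expect_equal(out2$observed_r, 1)
  expect_true(out2$met)
  expect_warning(construct_validity(
    data.frame(measure = "z", expected_threshold = 0.3),
    list(z = list(x = th, y = rep(1, 400)))), "zero-variance")
})

test_that("reference tables recombine subgroups into the total exactly", {
  set.seed(134)
  t_scores <- rnorm(300, 50, 10)
  cov <- data.frame(sex = factor(sample(c("m", "f"), 300, TRUE)))
  tab <- reference_values(t_scores, cov, grouping = "sex")
  tot <- tab[tab$group == "total", ]
  sub <- tab[tab$group == "sex", ]
  expect_equal(sum(sub$n), tot$n)
  expect_equal(weighted.mean(sub$mean_t, sub$n), tot$mean_t, tolerance = 1e-12)
  # constant sample: SD 0, mean preserved
  tabc <- reference_values(rep(50, 20))
  expect_equal(tabc$mean_t, 50)
  expect_equal(tabc$sd_t, 0)
})

test_that("scoring the same responses under two versions shows the version effect", {
  bank <- fix_bank(8, seed = 135)
  X <- fix_responses(bank, n = 300, seed = 135)
  a <- list(params = bank, items = 1:8)
  cw_same <- version_crosswalk(X, a, a)
  expect_equal(cw_same$scores_a$t_score, cw_same$scores_b$t_score)
  expect_false(any(cw_same$provisional))
  # dropping items cannot reduce the mean SE under the same calibration
  b <- list(params = bank, items = 1:5)
  cw_sub <- version_crosswalk(X, a, b)
  expect_gte(cw_sub$summary$mean_se_theta[2], cw_sub$summary$mean_se_theta[1])
  expect_true(cw_sub$provisional["b"])
  # a shifted anchor calibration moves the T-score distribution
  shifted <- item_parameters(bank$alpha,
                             lapply(bank$betas, function(b) b - 0.5),
                             bank$item_names)
  cw_ver <- version_crosswalk(X, a, list(params = shifted, items = 1:8))
  expect_gt(abs(cw_ver$summary$mean_t[2] - cw_ver$summary$mean_t[1]), 1)
  expect_error(version_crosswalk(X, a, list(params = bank, items = integer(0))),
               "empty")
})
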