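test_that("imputation draws land inside their intervals", {
  # degenerate intervals return their value exactly, consuming no RNG
  iv <- data.frame(tt_lo_c = c(100, 250), tt_hi_c = c(100, 250))
  set.seed(0)
  before <- .Random.seed
  expect_identical(impute_times(iv), c(100, 250))
  expect_identical(.Random.seed, before)

  set.seed(1)
  x <- impute_times(data.frame(tt_lo_c = rep(100, 1e5), tt_hi_c = rep(200, 1e5)))
  expect_gt(min(x), 100)
  expect_lte(max(x), 200)
  expect_equal(mean(x), 150, tolerance = 1)

  set.seed(9)
  a <- impute_times(data.frame(tt_lo_c = 1:5 * 10, tt_hi_c = 1:5 * 10 + 30))
  set.seed(9)
  b <- impute_times(data.frame(tt_lo_c = 1:5 * 10, tt_hi_c = 1:5 * 10 + 30))
  expect_identical(a, b)
})

test_that("permutation test returns p = 1 for identical degenerate groups", {
  a <- data.frame(tt_lo_c = rep(500, 4), tt_hi_c = rep(500, 4))
  set.seed(2)
  res <- mc_permutation_test(a, a, n_iter = 200)
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)
})

test_that("permutation p matches the exhaustive-enumeration oracle on point data", {
  set.seed(3)
  # clearly separated groups: exhaustive p = 2/70 one-sided-extreme share
  g1 <- c(1, 2, 3, 4)
  g2 <- c(101, 102, 103, 104)
  expect_equal(exhaustive_perm_p(g1, g2), 2 / 70)
  res <- mc_permutation_test(g1, g2, n_iter = 2000)
  expect_lte(res$p_value, 0.05)
  se <- sqrt(2 / 70 * (1 - 2 / 70) / 2000)
  expect_lt(abs(res$p_value - 2 / 70), 3 * se + 1 / 2001)

  # assorted overlapping 3+3 and 4+4 datasets against the oracle
  set.seed(4)
  for (k in 1:10) {
    n1 <- if (k %% 2 == 0) 3 else 4
    a <- round(rnorm(n1, 1000, 80))
    b <- round(rnorm(n1, 1000 + 40 * (k %% 3), 80))
    p_ex <- exhaustive_perm_p(a, b)
    res <- mc_permutation_test(a, b, n_iter = 1000)
    se <- sqrt(p_ex * (1 - p_ex) / 1000)
    expect_lt(abs(res$p_value - p_ex), 3 * se + 2 / 1001)
  }
})

test_that("permutation p is invariant to swapping the group labels", {
  # the absolute-difference statistic is symmetric, so the p-value is
  # exchangeable in the group order up to Monte-Carlo error
  a <- data.frame(tt_lo_c = c(900, 950, 1000), tt_hi_c = c(990, 1040, 1090))
  b <- data.frame(tt_lo_c = c(1000, 1050, 1100), tt_hi_c = c(1090, 1140, 1190))
  n_iter <- 2000
  set.seed(5)
  p_ab <- mc_permutation_test(a, b, n_iter = n_iter)$p_value
  set.seed(5)
  p_ba <- mc_permutation_test(b, a, n_iter = n_iter)$p_value
  se <- sqrt(p_ab * (1 - p_ab) / n_iter)
  expect_lt(abs(p_ab - p_ba), 3 * se + 2 / (n_iter + 1))
})

test_that("null rejection rate stays at or below the nominal level", {
  set.seed(6)
  n_sim <- 300
  reject <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    lo <- rnorm(12, 1000, 70)
    iv <- data.frame(tt_lo_c = lo, tt_hi_c = lo + 90)
    lab <- sample(12) <= 6
    reject[i] <- mc_permutation_test(iv[lab, ], iv[!lab, ],
                                     n_iter = 300)$p_value <= 0.05
  }
  expect_lte(mean(reject), 0.08)  # nominal 5% plus binomial slack
})

test_that("group size preconditions are enforced", {
  a <- data.frame(tt_lo_c = 1, tt_hi_c = 2)
  expect_error(mc_permutation_test(a[0, ], a), class = "phenokit_domain")
  expect_error(mc_permutation_test(a, a), class = "phenokit_domain")  # n = 2
})

test_that("bootstrap CI collapses to zero width on constant degenerate data", {
  iv <- data.frame(tt_lo_c = rep(800, 6), tt_hi_c = rep(800, 6))
  set.seed(7)
  ci <- bootstrap_mean_ci(iv, n_boot = 500)
  expect_equal(ci$lo, 800)
  expect_equal(ci$hi, 800)
  expect_equal(ci$estimate, 800)
})

test_that("bootstrap on point data equals the textbook percentile oracle", {
  x <- c(950, 1010, 1080, 1130, 990, 1040, 1200, 905)
  B <- 400
  set.seed(8)
  ci <- bootstrap_mean_ci(x, n_boot = B)

  set.seed(8)
  means <- numeric(B)
  for (b in seq_len(B)) means[b] <- mean(x[sample.int(length(x), length(x), replace = TRUE)])
  qs <- unname(quantile(means, c(0.025, 0.975)))
  expect_identical(ci$lo, qs[1])
  expect_identical(ci$hi, qs[2])
  expect_identical(ci$estimate, mean(means))
  expect_true(ci$lo <= ci$estimate && ci$estimate <= ci$hi)
})

test_that("bootstrap CI achieves near-nominal coverage for interval data", {
  set.seed(10)
  n_sim <- 300
  covered <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    latent <- rnorm(15, 1000, 80)
    lo <- floor(latent / 90) * 90
    iv <- data.frame(tt_lo_c = lo, tt_hi_c = lo + 90)
    ci <- bootstrap_mean_ci(iv, n_boot = 1000)
    covered[i] <- ci$lo <= 1000 && 1000 <= ci$hi
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("single observation warns about the degenerate CI", {
  expect_warning(bootstrap_mean_ci(data.frame(tt_lo_c = 100, tt_hi_c = 190),
                                   n_boot = 50),
                 class = "phenokit_degenerate_ci")
})

test_that("pairwise stage comparison emits means and p-values per stage", {
  cfg <- tiny_scenario(99)
  st <- gen_stage_intervals(cfg)
  set.seed(11)
  cmp <- compare_stages(st[st$bbch_stage == 93, ], n_iter = 200, n_boot = 300)
  expect_equal(nrow(cmp$means), 4L)       # one row per species
  expect_equal(nrow(cmp$pairwise), 6L)    # all species pairs
  expect_true(all(cmp$pairwise$p_value > 0 & cmp$pairwise$p_value <= 1))
  cmp_h <- compare_stages(st[st$bbch_stage == 93, ], n_iter = 100, n_boot = 100,
                          adjust = "holm")
  expect_true(all(cmp_h$pairwise$p_adjusted >= cmp_h$pairwise$p_value))
})
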