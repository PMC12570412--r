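test_that("AUC equals exhaustive pair counting on random small instances", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5)) # guarantee both classes
    s <- sample(round(rnorm(n), 1)) # coarse values force ties
    ac <- auc_with_covariance(s, s, y)
    expect_equal(ac$auc_a, auc_pairs_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("degenerate score comparisons behave as identities", {
  y <- rep(c(0, 1), each = 10)
  expect_equal(auc_with_covariance(y, y, y)$auc_a, 1)
  s <- rnorm(20)
  ac <- auc_with_covariance(s, s, y)
  expect_equal(ac$cov_ab, ac$var_a)
  dl <- suppressWarnings(delong_test(s, s, y))
  expect_equal(dl$delta_auc, 0)
  expect_equal(dl$p, 1)
  expect_warning(delong_test(s, s, y), "zero variance")
  expect_error(auc_with_covariance(s, s, rep(1, 20)), "single class")
})

test_that("the DeLong test matches the reference implementation and is sign-symmetric", {
  skip_if_not_installed("pROC")
  set.seed(55)
  for (i in 1:5) {
    y <- c(0, 1, rbinom(58, 1, 0.4))
    a <- rnorm(60) + 0.8 * y
    b <- rnorm(60) + 0.3 * y
    mine <- delong_test(a, b, y)
    ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                          pROC::roc(y, b, quiet = TRUE, direction = "<"),
                          method = "delong", paired = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    swapped <- delong_test(b, a, y)
    expect_equal(swapped$z, -mine$z, tolerance = 1e-12)
    expect_equal(swapped$p, mine$p, tolerance = 1e-12)
  }
})

test_that("an informative score beats pure noise at n=500 in most seeds", {
  wins <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    y <- rbinom(500, 1, 0.3)
    good <- rnorm(500) + 1.2 * y
    noise <- rnorm(500)
    if (delong_test(good, noise, y)$p < 0.05) wins <- wins + 1L
  }
  expect_gt(wins, 10L)
})

test_that("weighted AUC reduces to the unweighted estimator at equal weights", {
  set.seed(77)
  y <- c(0, 1, rbinom(48, 1, 0.4))
  a <- rnorm(50); b <- rnorm(50) + 0.5 * y
  eq <- auc_with_covariance(a, b, y, weights = rep(2.5, 50))
  un <- auc_with_covariance(a, b, y)
  expect_equal(eq, un, tolerance = 1e-12)
  # informative weights move the point estimate
  wt <- auc_with_covariance(a, b, y, weights = runif(50, 0.5, 3))
  expect_false(isTRUE(all.equal(wt$auc_b, un$auc_b)))
})

test_that("gain ranking is deterministic, complete, and zeroes constant factors", {
  cat3 <- tiny_catalog()
  d <- tiny_cohort(n = 300, seed = 31)
  d$outcome <- rbinom(300, 1, ifelse(d$greens == "often", 0.15, 0.45))
  d$insured <- factor(rep("no", 300), c("no", "yes")) # constant column
  rk <- rank_factors(d, cat3, seed = 7)
  expect_setequal(rk$factor, catalog_names(cat3))
  expect_identical(rk$rank, 1:3)
  expect_true(all(diff(rk$gain) <= 0))
  expect_equal(rk$gain[rk$factor == "insured"], 0)
  expect_identical(rank_factors(d, cat3, seed = 7), rk)
  d1 <- d; d1$outcome <- 1L
  expect_error(rank_factors(d1, cat3, seed = 7), "single class")
})

test_that("the stopping gate honours its boundary significance levels", {
  cat3 <- default_catalog()
  ps <- null_and_alternative_presets(seed = 41, n_participants = 400,
                                     missingness = list(mechanism = "MCAR",
                                                        rate = 0))
  coh <- simulate_cohort(ps$null)
  factors6 <- catalog_names(cat3)[1:6]
  rk <- rank_factors(coh, cat3, factors = factors6, seed = 2,
                     hyperparams = list(nrounds = 25L))
  # alpha = 0: no test can be significant, scanning stops after two comparisons
  tr0 <- sequential_select(coh, rk, alpha = 0, seed = 2,
                           hyperparams = list(nrounds = 25L))
  expect_equal(max(tr0$steps$k), 3L)
  # alpha = 1: every test is significant, the whole ranking is scanned
  tr1 <- sequential_select(coh, rk, alpha = 1, seed = 2,
                           hyperparams = list(nrounds = 25L))
  expect_equal(max(tr1$steps$k), length(factors6))
  expect_equal(tr1$stop_k, tr1$steps$k[which.max(tr1$steps$auc)])
})

test_that("too-short rankings are flagged as unstoppable", {
  cat3 <- tiny_catalog()
  d <- tiny_cohort(n = 200, seed = 43)
  rk <- rank_factors(d, cat3, factors = c("greens", "club"), seed = 3,
                     hyperparams = list(nrounds = 20L))
  tr <- sequential_select(d, rk, seed = 3,
                          hyperparams = list(nrounds = 20L))
  expect_true(tr$no_stopping_possible)
  expect_equal(nrow(tr$steps), 2L)
})
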