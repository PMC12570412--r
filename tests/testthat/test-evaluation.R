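test_that("out-of-fold predictions are deterministic and honest", {
  d <- tiny_cohort(n = 120, seed = 71)
  d$outcome <- rbinom(120, 1, plogis(-1 + (d$greens == "often")))
  f <- outcome ~ greens + club
  p1 <- crossval_predictions(d, f, k = 10, seed = 5)
  expect_identical(p1, crossval_predictions(d, f, k = 10, seed = 5))
  expect_true(all(p1 > 0 & p1 < 1))

  # intercept-only model predicts the training-fold prevalence
  p0 <- crossval_predictions(d, outcome ~ 1, k = 10, seed = 5)
  expect_lt(max(abs(p0 - mean(d$outcome))), 0.05)
})

test_that("k = n cross-validation equals an explicit leave-one-out loop", {
  d <- tiny_cohort(n = 30, seed = 72)
  d$x <- rnorm(30)
  d$outcome <- rbinom(30, 1, plogis(d$x))
  d$weight <- rep(1, 30)
  got <- crossval_predictions(d, outcome ~ x, k = 30, seed = 9)
  loo <- vapply(1:30, function(i) {
    fit <- glm(outcome ~ x, binomial, data = d[-i, ])
    unname(predict(fit, newdata = d[i, , drop = FALSE], type = "response"))
  }, 0)
  expect_equal(got, loo, tolerance = 1e-10)
})

test_that("Hosmer-Lemeshow vanishes under perfect calibration and matches hand summation", {
  # constructed fixture: predictions equal group-wise observed rates
  pred <- rep(c(0.1, 0.2, 0.3, 0.4, 0.5), each = 10)
  obs <- unlist(lapply(c(1, 2, 3, 4, 5), function(k)
    c(rep(1, k), rep(0, 10 - k))))
  hl <- hosmer_lemeshow(pred, obs, n_groups = 5)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)

  set.seed(73)
  pred2 <- runif(40, 0.05, 0.95)
  obs2 <- rbinom(40, 1, pred2)
  hl2 <- hosmer_lemeshow(pred2, obs2, n_groups = 4)
  groups <- cut(pred2, unique(quantile(pred2, seq(0, 1, 0.25), type = 7)),
                include.lowest = TRUE)
  expect_equal(hl2$statistic, hl_oracle(pred2, obs2, groups),
               tolerance = 1e-10)
  expect_equal(hl2$df, 2L)
})

test_that("degenerate risk groups are merged rather than dividing by zero", {
  pred <- c(rep(0, 20), runif(40, .2, .8))
  obs <- c(rep(0, 20), rbinom(40, 1, .5))
  expect_message(hl <- hosmer_lemeshow(pred, obs, n_groups = 6), "merged")
  expect_true(is.finite(hl$statistic))
})

test_that("paired C-statistic comparison is a DeLong test with rank invariance", {
  set.seed(75)
  y <- rbinom(200, 1, .3)
  pr <- plogis(rnorm(200) + 0.5 * y)
  pn <- plogis(rnorm(200) + 1.2 * y)
  self <- suppressWarnings(c_statistic_delta(pr, pr, y))
  expect_equal(self$delta, 0)
  expect_equal(self$p, 1)
  cs <- c_statistic_delta(pr, pn, y)
  expect_equal(cs$delta, cs$c_new - cs$c_ref)
  # strictly monotone transform preserves every C-statistic
  cs2 <- c_statistic_delta(qlogis(pr), qlogis(pn), y)
  expect_equal(cs2$c_new, cs$c_new, tolerance = 1e-12)
  expect_equal(cs2$c_ref, cs$c_ref, tolerance = 1e-12)
})

test_that("NRI matches exhaustive enumeration and its components sum to the total", {
  # 8-row toy with hand-tabulated moves
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pr <- c(.2, .4, .5, .6, .3, .5, .2, .4)
  pn <- c(.3, .3, .7, .6, .2, .6, .1, .4)
  # events: up {1,3}, down {2}, same {4}  -> event NRI = 2/4 - 1/4 = 0.25
  # non-events: down {5,7}, up {6}, same {8} -> non-event NRI = 2/4 - 1/4 = 0.25
  res <- nri(pr, pn, y, n_boot = 0)
  expect_equal(res$event, 0.25)
  expect_equal(res$non_event, 0.25)
  expect_equal(res$overall, 0.5)
  orc <- nri_oracle(pr, pn, y)
  expect_equal(res[c("overall", "event", "non_event")], orc)

  set.seed(76)
  for (i in 1:20) {
    yy <- c(0, 1, rbinom(30, 1, .4))
    a <- runif(32); b <- runif(32)
    r <- nri(a, b, yy, n_boot = 0)
    expect_equal(r$overall, r$event + r$non_event, tolerance = 1e-12)
    o <- nri_oracle(a, b, yy)
    expect_equal(r$overall, o$overall, tolerance = 1e-12)
    # invariant under a common strictly monotone transform
    r2 <- nri(qlogis(a), qlogis(b), yy, n_boot = 0)
    expect_equal(r2$overall, r$overall, tolerance = 1e-12)
  }
})

test_that("NRI self-comparison is zero and bootstrap CIs bracket the estimate", {
  set.seed(77)
  y <- rbinom(150, 1, .3)
  p <- runif(150)
  self <- nri(p, p, y, n_boot = 0)
  expect_equal(unlist(self[c("overall", "event", "non_event")]),
               c(overall = 0, event = 0, non_event = 0))
  q <- plogis(qlogis(p) + 0.8 * y - 0.4)
  r <- nri(p, q, y, n_boot = 200, seed = 4)
  expect_true(r$ci["overall", "lo"] <= r$overall &&
                r$overall <= r$ci["overall", "hi"])
  expect_identical(nri(p, q, y, n_boot = 50, seed = 4)$ci,
                   nri(p, q, y, n_boot = 50, seed = 4)$ci)
  expect_error(nri(p, q, rep(0, 150)), "single class")
})
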