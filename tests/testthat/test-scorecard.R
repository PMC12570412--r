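test_that("a single binary factor recovers the 2x2 log odds-ratio", {
  # events/non-events: reference level 10/40, exposed level 30/20
  d <- data.frame(
    id = as.character(1:100),
    outcome = c(rep(1, 10), rep(0, 40), rep(1, 30), rep(0, 20)),
    weight = 1,
    greens = factor(c(rep("rarely", 50), rep("often", 50)),
                    c("rarely", "often"))
  )
  fit <- fit_weighted_logistic(d, "greens")
  expect_equal(fit$terms$beta,
               log((30 / 20) / (10 / 40)), tolerance = 1e-8)
})

test_that("unit weights reproduce the unweighted fit", {
  d <- tiny_cohort(n = 150, seed = 12)
  d$weight <- rep(1, 150)
  a <- fit_weighted_logistic(d, c("greens", "club"), use_weights = TRUE)
  b <- fit_weighted_logistic(d, c("greens", "club"), use_weights = FALSE)
  expect_equal(a$terms$beta, b$terms$beta, tolerance = 1e-10)
  expect_equal(a$terms$se, b$terms$se, tolerance = 1e-10)
  expect_false(a$weighted)
})

test_that("pathological designs are reported, not silently fitted", {
  d <- tiny_cohort(n = 80, seed = 13)
  d$outcome <- as.integer(d$greens == "often") # perfect separation
  expect_warning(
    expect_error(fit_weighted_logistic(d, "greens"), "separation"),
    "unobserved in one outcome class")
  d2 <- tiny_cohort(n = 80, seed = 14)
  d2$club <- d2$greens # aliased copy
  levels(d2$club) <- c("rarely", "often", "never")
  expect_error(suppressWarnings(
    fit_weighted_logistic(d2, c("greens", "club"))), "rank-deficient|aliased")
})

test_that("the point rule is |beta| x 10, rounded half away from zero", {
  expect_identical(points_from_beta(-0.61), 6L)
  expect_identical(points_from_beta(-0.26), 3L)
  expect_identical(points_from_beta(0), 0L)
  expect_identical(points_from_beta(0.25), 3L) # 2.5 rounds up, not truncates
  expect_identical(points_from_beta(c(-1.04, 1.04)), c(10L, 10L))
  expect_error(points_from_beta(Inf), "finite")
  set.seed(3)
  b <- rnorm(50)
  expect_identical(points_from_beta(b), points_from_beta(-b))
})

test_that("the score card assigns worked-example points and zero references", {
  d <- tiny_cohort(n = 400, seed = 15)
  lp <- -1 - 0.61 * (d$greens == "often") - 0.26 * (d$insured == "yes")
  set.seed(16)
  d$outcome <- rbinom(400, 1, plogis(lp))
  fit <- fit_weighted_logistic(d, c("greens", "insured"),
                               catalog = tiny_catalog(), use_weights = FALSE)
  # freeze the worked-example coefficients into the fit and build the card
  fit$terms$beta <- c(-0.61, -0.26)
  card <- build_scorecard(fit, tiny_catalog())
  expect_identical(card$points[card$factor == "greens" & card$level == "often"], 6L)
  expect_identical(card$points[card$factor == "insured" & card$level == "yes"], 3L)
  expect_true(all(card$points[card$is_reference] == 0L))

  # intercept shifts change no points
  fit2 <- fit; fit2$intercept <- fit$intercept + 5
  expect_identical(build_scorecard(fit2, tiny_catalog())$points, card$points)

  # positive (risk-increasing) coefficients still score but warn
  fit3 <- fit; fit3$terms$beta <- c(0.30, -0.26)
  expect_warning(card3 <- build_scorecard(fit3, tiny_catalog()),
                 "risk-increasing")
  expect_identical(card3$points[card3$factor == "greens" &
                                  card3$level == "often"], 3L)

  fit4 <- fit; fit4$terms$level[1] <- "sometimes"
  expect_error(build_scorecard(fit4, tiny_catalog()), "unknown level")
})

test_that("participant scores are sums of card points", {
  d <- tiny_cohort(n = 8, seed = 17)
  d$greens <- factor(c("rarely", "often")[c(1, 2, 1, 2, 1, 2, 1, 2)],
                     c("rarely", "often"))
  d$insured <- factor(c("no", "no", "yes", "yes", "no", "yes", "no", "yes"),
                      c("no", "yes"))
  fit <- list(terms = data.frame(factor = c("greens", "insured"),
                                 level = c("often", "yes"),
                                 beta = c(-0.61, -0.26), se = 0.1,
                                 ci_lo = NA, ci_hi = NA,
                                 stringsAsFactors = FALSE),
              intercept = -1, factors = c("greens", "insured"),
              weighted = FALSE, n = 8, sparse_cells = character())
  class(fit) <- "logistic_fit"
  card <- build_scorecard(fit, tiny_catalog())
  sc <- score_participants(d, card)
  expect_identical(sc$score, c(0L, 6L, 3L, 9L, 0L, 9L, 0L, 9L))
  d$greens[1] <- NA
  expect_message(sc2 <- score_participants(d, card), "skipped")
  expect_true(is.na(sc2$score[1]))
})

test_that("score categories follow quintile and fixed cutoff schemes", {
  u <- categorize_scores(1:100)
  expect_identical(which(u$category == "low"), 1:20)
  expect_identical(which(u$category == "high"), 81:100)

  fx <- categorize_scores(c(0, 37, 38, 63, 64, 90), scheme = "fixed",
                          cutoffs = c(37, 63))
  expect_identical(as.character(fx$category),
                   c("low", "low", "intermediate", "intermediate",
                     "high", "high"))

  # tied scores always land in one category
  tied <- c(rep(1, 10), rep(5, 30), rep(9, 10))
  ct <- categorize_scores(c(tied, 2, 3, 4))
  expect_length(unique(ct$category[c(11:40)]), 1L)

  expect_error(categorize_scores(rep(7, 50)), "5 distinct")
  expect_error(categorize_scores(1:10, scheme = "fixed", cutoffs = c(5)),
               "cutoffs")
})

test_that("higher true social advantage yields stochastically higher scores", {
  ps <- null_and_alternative_presets(seed = 51, n_participants = 3000,
                                     missingness = list(mechanism = "MCAR",
                                                        rate = 0))
  coh <- simulate_cohort(ps$alternative)
  cat29 <- default_catalog()
  fit <- fit_weighted_logistic(coh, informative_factors(), catalog = cat29)
  card <- suppressWarnings(build_scorecard(fit, cat29))
  sc <- score_participants(coh, card)
  # truth: minus the factor part of the linear predictor (protective effects)
  advantage <- -attr(coh, "linear_predictor")
  expect_gt(cor(sc$score, advantage, method = "spearman"), 0.5)
})
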