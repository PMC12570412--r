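test_that("cohort CSVs round-trip with values and missingness preserved", {
  cat3 <- tiny_catalog()
  d <- tiny_cohort(n = 10, seed = 2)
  d$club[3] <- NA
  d$outcome[5] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d, path)
  back <- read_cohort(path, cat3)
  expect_equal(nrow(back), 10L)
  expect_equal(back$club, d$club)
  expect_equal(back$outcome, d$outcome)
  expect_equal(back$weight, d$weight)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(read_cohort(path2, cat3), back)
})

test_that("unparseable cells become missing and bad rows are rejected", {
  cat3 <- tiny_catalog()
  d <- tiny_cohort(n = 6, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  raw <- d
  raw$insured <- as.character(raw$insured)
  raw$insured[2] <- "Not sure"   # mapped to missing at parse time
  raw$greens <- as.character(raw$greens)
  raw$greens[3] <- "banana"      # not a declared level: logged and missing
  write_cohort(raw, path)
  expect_message(back <- read_cohort(path, cat3), "did not match")
  expect_true(is.na(back$insured[2]))
  expect_true(is.na(back$greens[3]))

  bad <- d; bad$weight[4] <- 0
  write_cohort(bad, path)
  expect_error(read_cohort(path, cat3), "weight.*4")

  noid <- d[, setdiff(names(d), "gender")]
  write_cohort(noid, path)
  expect_error(read_cohort(path, cat3), "reserved column.*gender")
})

test_that("the disability outcome follows the any-difficulty rule", {
  expect_identical(derive_outcome(c(rep("no", 6), "yes")), 1L)
  expect_identical(derive_outcome(rep("no", 7)), 0L)
  expect_identical(derive_outcome(c(rep("no", 6), NA)), NA_integer_)
  expect_identical(derive_outcome(c(rep("no", 5), NA, "yes")), 1L)
  expect_error(derive_outcome(rep("no", 6)), "exactly 7")

  m <- rbind(rep("no", 7), c("yes", rep("no", 6)), c(rep(NA, 7)))
  expect_identical(derive_outcome(m), c(0L, 1L, NA_integer_))
})

test_that("derive_outcome is monotone: adding a yes never flips 1 to 0", {
  set.seed(9)
  for (i in 1:25) {
    items <- sample(c("yes", "no", NA), 7, TRUE, prob = c(.2, .6, .2))
    base <- derive_outcome(items)
    bumped <- items
    bumped[sample(7, 1)] <- "yes"
    expect_identical(derive_outcome(bumped), 1L)
    if (identical(base, 1L)) expect_identical(derive_outcome(bumped), base)
  }
})

test_that("complete-case filtering counts dropped rows exactly", {
  d <- tiny_cohort(n = 100, seed = 5)
  out <- complete_case_filter(d, c("greens", "club"))
  expect_identical(out$data, d)
  expect_identical(out$n_dropped, 0L)

  set.seed(11)
  rows <- sample(100, 13)
  for (r in rows) {
    col <- sample(c("greens", "club"), 1)
    d[[col]][r] <- NA
  }
  out <- complete_case_filter(d, c("greens", "club"))
  expect_equal(nrow(out$data), 87L)
  expect_equal(out$n_dropped, 13L)
  expect_false(anyNA(out$data$greens))

  expect_identical(complete_case_filter(d, character())$data, d)
  expect_error(complete_case_filter(d, "nope"), "unknown column")
})

test_that("weighted descriptives match hand arithmetic and unit-weight identity", {
  d <- tiny_cohort(n = 4, seed = 6)
  d$gender <- factor(c("men", "men", "women", "women"), c("men", "women"))
  d$greens <- factor(c("often", "rarely", "often", "rarely"),
                     c("rarely", "often"))
  d$weight <- c(2, 2, 1, 1)
  tab <- weighted_table_one(d, "greens")
  # total: often = (2+1)/6, rarely = (2+1)/6; men: 2/4 each; women: 1/2 each
  expect_equal(tab$total[tab$level == "often"], 50)
  expect_equal(tab$men[tab$level == "rarely"], 50)
  expect_equal(tab$women[tab$level == "often"], 50)

  d2 <- tiny_cohort(n = 60, seed = 7)
  d2$weight <- rep(1, 60)
  tab2 <- weighted_table_one(d2, c("club", "insured"))
  raw_pct <- 100 * prop.table(table(d2$club))
  got <- tab2$total[tab2$variable == "club"]
  expect_equal(got, as.numeric(raw_pct[tab2$level[tab2$variable == "club"]]))

  # identical distributions between genders give p near 1
  d3 <- tiny_cohort(n = 40, seed = 8)
  d3$weight <- rep(1, 40)
  d3$gender <- factor(rep(c("men", "women"), 20), c("men", "women"))
  d3$insured <- factor(rep(c("no", "yes"), each = 20), c("no", "yes"))
  p <- weighted_table_one(d3, "insured")$p_value[1]
  expect_gt(p, 0.9)

  d3$insured[] <- NA
  expect_error(weighted_table_one(d3, "insured"), "entirely missing")
})
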