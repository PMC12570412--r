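# Small in-code fixtures and independent oracles shared across tests.

tiny_catalog <- function() {
  factor_catalog(list(
    list(name = "greens", domain = "economic_stability",
         levels = c("rarely", "often"), reference = "rarely"),
    list(name = "club", domain = "community_social_context",
         levels = c("never", "monthly", "weekly"), reference = "never"),
    list(name = "insured", domain = "healthcare_system",
         levels = c("no", "yes"), reference = "no")
  ))
}

# hand-built cohort rows compatible with tiny_catalog()
tiny_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("T%03d", seq_len(n)),
    gender = factor(sample(c("men", "women"), n, TRUE), c("men", "women")),
    age_group = factor(sample(c("60-69", "70-79", "80+"), n, TRUE),
                       c("60-69", "70-79", "80+")),
    weight = runif(n, 0.5, 2),
    outcome = rbinom(n, 1, 0.3),
    smoking = factor(sample(c("never", "former", "current"), n, TRUE),
                     c("never", "former", "current")),
    drinking = factor(sample(c("none", "lt_monthly", "monthly_weekly",
                               "frequent"), n, TRUE),
                      c("none", "lt_monthly", "monthly_weekly", "frequent")),
    sleep_trouble = factor(sample(c("never", "rarely", "sometimes",
                                    "most_of_the_time"), n, TRUE),
                           c("never", "rarely", "sometimes",
                             "most_of_the_time")),
    greens = factor(sample(c("rarely", "often"), n, TRUE),
                    c("rarely", "often")),
    club = factor(sample(c("never", "monthly", "weekly"), n, TRUE),
                  c("never", "monthly", "weekly")),
    insured = factor(sample(c("no", "yes"), n, TRUE), c("no", "yes")),
    stringsAsFactors = FALSE
  )
}

# brute-force AUC by exhaustive pair counting, ties count one half
auc_pairs_oracle <- function(scores, outcome) {
  x <- scores[outcome == 1]; y <- scores[outcome == 0]
  tot <- 0
  for (xi in x) for (yj in y) tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# hand-summed Hosmer-Lemeshow statistic for a given grouping
hl_oracle <- function(predicted, observed, groups) {
  stat <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    n_g <- sum(idx); o <- sum(observed[idx]); e <- sum(predicted[idx])
    pbar <- e / n_g
    stat <- stat + (o - e)^2 / (n_g * pbar * (1 - pbar))
  }
  stat
}

# continuous NRI by explicit enumeration
nri_oracle <- function(pred_ref, pred_new, outcome) {
  ev <- outcome == 1
  up <- pred_new > pred_ref; down <- pred_new < pred_ref
  event <- sum(up & ev) / sum(ev) - sum(down & ev) / sum(ev)
  non_event <- sum(down & !ev) / sum(!ev) - sum(up & !ev) / sum(!ev)
  list(overall = event + non_event, event = event, non_event = non_event)
}
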