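test_that("code assignment mirrors the flag columns", {
  tab <- generate_cohort(tiny_spec(), seed = 1)
  expect_identical(assign_by_code(tab, "incontinent"), tab$code_incontinent)
  expect_identical(assign_by_code(tab, "continent"), tab$code_continent)
  expect_error_class(assign_by_code(tab[, 1:3], "incontinent"), "schema_error")

  tabp <- generate_cohort(tiny_spec(code_params = perfect_code_params()), seed = 1)
  expect_identical(assign_by_code(tabp, "incontinent"),
                   tabp$true_status == "incontinent")
})

test_that("threshold search matches brute force and handles edge shapes", {
  # worked example: J maximized at 0.35 (tie with 0.8 broken downward)
  r <- find_threshold(c(0.1, 0.35, 0.4, 0.8), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(r$tau, 0.35)
  expect_equal(r$j, 0.5)

  # brute-force oracle over random cases, both criteria
  set.seed(50)
  for (i in 1:20) {
    n <- 60
    p <- round(runif(n), 2)
    y <- rbinom(n, 1, p) == 1
    if (sum(y) == 0 || sum(y) == n) next
    for (crit in c("youden_j", "closest_to_corner")) {
      r <- find_threshold(p, y, crit)
      cand <- sort(unique(p))
      sens <- vapply(cand, function(t) mean(p[y] >= t), 0)
      spec <- vapply(cand, function(t) mean(p[!y] < t), 0)
      score <- if (crit == "youden_j") sens + spec - 1 else
        -((1 - sens)^2 + (1 - spec)^2)
      best_tau <- min(cand[score >= max(score) - 1e-12])
      expect_equal(r$tau, best_tau, label = paste("case", i, crit))
    }
  }

  # perfect probabilities: J = 1 at the smallest positive-class value
  rp <- find_threshold(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(rp$tau, 1)
  expect_equal(rp$j, 1)

  rc <- find_threshold(rep(0.3, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(rc$tau, 0.3)
  expect_equal(rc$j, 0)
  expect_true(rc$flagged)

  expect_error_class(find_threshold(runif(5), rep(TRUE, 5)),
                     "degenerate_input_error")
})

test_that("threshold assignment is inclusive at the boundary", {
  expect_equal(assign_by_threshold(c(0.05, 0.0922, 0.50), 0.0922),
               c(FALSE, TRUE, TRUE))
  expect_false(any(assign_by_threshold(c(0.1, 0.5), 0.6)))
})

test_that("bootstrap imputation recovers truth from degenerate probabilities", {
  tab <- generate_cohort(tiny_spec(), seed = 61)
  truth_inc <- tab$true_status == "incontinent"
  truth_con <- tab$true_status == "continent"
  p_hat <- cbind(p_incontinent = as.numeric(truth_inc),
                 p_continent = as.numeric(truth_con))
  battery <- statistic_battery()

  # identity resampling + 0/1 probabilities: every replicate is the truth
  bi <- bootstrap_impute(tab, p_hat, battery, n_boot = 5, seed = 3,
                         resample = FALSE)
  truth_stats <- compute_statistics(tab, truth_inc, battery)
  got <- bi[bi$diversion == "incontinent", ]
  expect_equal(got$estimate[match(truth_stats$name, got$statistic)],
               truth_stats$beta, tolerance = 1e-12)
  expect_equal(got$ci_low, got$ci_high, tolerance = 1e-12)

  # with resampling the CIs cover the truth
  bi_r <- bootstrap_impute(tab, p_hat, battery, n_boot = 100, seed = 4)
  for (d in c("incontinent", "continent")) {
    tr <- compute_statistics(tab, tab$true_status == d, battery)
    g <- bi_r[bi_r$diversion == d, ]
    i <- match(tr$name, g$statistic)
    cover <- mean(tr$beta >= g$ci_low[i] & tr$beta <= g$ci_high[i])
    expect_gt(cover, 0.9)
  }
})

test_that("constant probabilities impute the analytic prevalence", {
  n <- 4000
  tab <- generate_cohort(cohort_spec(n_incontinent = 50, n_continent = 50,
                                     n_none = n - 100), seed = 62)
  p_hat <- cbind(p_incontinent = rep(0.07, n), p_continent = rep(0.05, n))
  bi <- bootstrap_impute(tab, p_hat, statistic_battery(), n_boot = 60, seed = 5)
  prev_inc <- bi$estimate[bi$diversion == "incontinent" &
                            bi$statistic == "prevalence"]
  se <- sqrt(0.07 * 0.93 / n) / sqrt(60) * sqrt(2)  # resampling inflates
  expect_lt(abs(prev_inc - 0.07), 6 * sqrt(0.07 * 0.93 / n))
  prev_con <- bi$estimate[bi$diversion == "continent" &
                            bi$statistic == "prevalence"]
  expect_lt(abs(prev_con - 0.05), 6 * sqrt(0.05 * 0.95 / n))
})

test_that("shared-uniform imputation never assigns both diversion types", {
  n <- 2000
  tab <- generate_cohort(cohort_spec(n_incontinent = 40, n_continent = 40,
                                     n_none = n - 80), seed = 63)
  p_hat <- cbind(p_incontinent = rep(0.5, n), p_continent = rep(0.5, n))
  bi <- bootstrap_impute(tab, p_hat, statistic_battery(), n_boot = 20, seed = 6)
  # complementary partition: the two imputed prevalences sum to exactly 1
  # in every replicate, hence exactly 1 in the means
  s <- sum(bi$estimate[bi$statistic == "prevalence"])
  expect_equal(s, 1, tolerance = 1e-12)

  bi_ind <- bootstrap_impute(tab, p_hat, statistic_battery(), n_boot = 20,
                             seed = 6, exclusive = FALSE)
  s_ind <- sum(bi_ind$estimate[bi_ind$statistic == "prevalence"])
  expect_false(isTRUE(all.equal(s_ind, 1, tolerance = 1e-12)))
})

test_that("inestimable replicates are excluded and counted", {
  tab <- generate_cohort(tiny_spec(), seed = 64)
  n <- nrow(tab)
  p_hat <- cbind(p_incontinent = rep(0, n), p_continent = rep(0, n))
  bi <- bootstrap_impute(tab, p_hat, statistic_battery(), n_boot = 4, seed = 7)
  sex <- bi[bi$diversion == "incontinent" & bi$statistic == "sex_male", ]
  expect_equal(sex$n_used, 0L)
  expect_true(is.nan(sex$estimate))
  prev <- bi[bi$diversion == "incontinent" & bi$statistic == "prevalence", ]
  expect_equal(prev$estimate, 0)
  expect_equal(prev$n_used, 4L)

  expect_error_class(bootstrap_impute(tab, p_hat, n_boot = 1), "specification_error")
})
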