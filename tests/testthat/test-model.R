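test_that("df budget: EPV arithmetic and the binding criterion", {
  b <- compute_df_budget(n = 429000, events = 250)
  expect_equal(b$epv_df, 25)
  expect_equal(b$allowed_df, 25)            # EPV is the binding criterion
  expect_equal(b$allowed_df, b$epv_df)
  expect_true(all(c(b$precision_df, b$shrinkage_df, b$optimism_df) > b$epv_df))
  expect_equal(compute_df_budget(n = 429000, events = 100)$epv_df, 10)
  expect_error_class(compute_df_budget(1000, 0), "degenerate_input_error")
})

test_that("fractional polynomial selection recovers the generating transform", {
  # oracle: exhaustive deviance search over all 8 powers with an
  # independent BFGS fit at each power
  set.seed(10)
  n <- 5000
  x <- rlnorm(n, 1, 0.7)
  gen <- function(transform) {
    e1 <- -2 + 1.5 * transform
    e2 <- -3 + 0.8 * transform
    den <- 1 + exp(e1) + exp(e2)
    u <- runif(n)
    cls <- ifelse(u < exp(e1) / den, 1L, ifelse(u < (exp(e1) + exp(e2)) / den, 2L, 3L))
    cbind(cls == 1L, cls == 2L) * 1
  }

  for (case in list(list(tr = log(x), want = 0), list(tr = x, want = 1))) {
    Y <- gen(case$tr)
    sel <- select_fp1(x, Y)
    expect_equal(sel$power, case$want)
    powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
    dev_oracle <- vapply(powers, function(p) {
      optim_multinom_deviance(cbind(1, fp_transform(x, p, sel$shift, sel$scale)), Y)
    }, numeric(1))
    expect_equal(powers[which.min(dev_oracle)], case$want)
    expect_equal(unname(sel$deviances), dev_oracle, tolerance = 1e-4)
  }

  # constant covariate: linear by convention, flagged
  sel_const <- select_fp1(rep(3, 100), gen(rep(0, 100))[1:100, ])
  expect_equal(sel_const$power, 1)
  expect_true(sel_const$flagged)
})

test_that("fp shift makes nonpositive covariates usable", {
  x <- c(0, 0.5, 1, 4)   # zero present: shift = smallest spacing - min
  expect_equal(cystmisclass:::fp_shift_for(x), 0.5)
  expect_equal(cystmisclass:::fp_shift_for(c(-2, 1, 5)), 3 - (-2))  # spacing 3
  expect_equal(cystmisclass:::fp_shift_for(c(2, 3)), 0)
  expect_error_class(fp_transform(c(0, 1), 1, shift = 0), "specification_error")
})

test_that("forward selection keeps signal, screens noise at the alpha rate", {
  set.seed(20)
  n <- 4000
  n_rep <- 120
  noise_kept <- 0L; info_kept <- 0L
  for (r in seq_len(n_rep)) {
    informative <- rbinom(n, 1, 0.3)
    e1 <- -4 + 3 * informative
    e2 <- -4.5 + 2.5 * informative
    den <- 1 + exp(e1) + exp(e2)
    u <- runif(n)
    cls <- ifelse(u < exp(e1) / den, "incontinent",
                  ifelse(u < (exp(e1) + exp(e2)) / den, "continent", "none"))
    tab <- data.frame(true_status = factor(cls, levels = c("incontinent", "continent", "none")),
                      v_info = informative,
                      v_n1 = rbinom(n, 1, 0.5), v_n2 = rbinom(n, 1, 0.2),
                      v_n3 = rbinom(n, 1, 0.1))
    cand <- data.frame(name = c("v_info", "v_n1", "v_n2", "v_n3"),
                       rank = 1:4,
                       kind = "binary", stringsAsFactors = FALSE)
    m <- forward_select(tab, cand)
    kept <- m$trace$name[m$trace$kept]
    info_kept <- info_kept + ("v_info" %in% kept)
    noise_kept <- noise_kept + sum(kept %in% c("v_n1", "v_n2", "v_n3"))
  }
  expect_equal(info_kept, n_rep)
  rate <- noise_kept / (3 * n_rep)
  # binomial(360, 0.05) band
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
})

test_that("selection respects the df budget and empty candidate lists", {
  tab <- generate_cohort(tiny_spec(), seed = 8)
  b <- compute_df_budget(429000, 250)
  b$allowed_df <- 2
  m <- forward_select(tab, budget = b)
  expect_lte(length(m$terms), 2L)
  expect_true(any(m$trace$reason == "budget"))
  # candidates past the budget are still offered (traced), per protocol
  expect_equal(nrow(m$trace), nrow(default_candidates()))

  m0 <- forward_select(tab, candidates = default_candidates()[0, ])
  expect_length(m0$terms, 0)
  P <- predict_probabilities(m0, tab)
  frac <- as.vector(table(tab$true_status)) / nrow(tab)
  expect_equal(unname(P[1, ]), frac, tolerance = 1e-6)
  expect_equal(unname(P[nrow(tab), ]), frac, tolerance = 1e-6)
})

test_that("deviance is non-increasing along the retained sequence", {
  tab <- generate_cohort(tiny_spec(), seed = 9)
  m <- forward_select(tab)
  kept <- m$trace[m$trace$kept, ]
  expect_true(all(kept$lrt >= 0))
  expect_gt(nrow(kept), 1)
})

test_that("predicted probability triplets behave", {
  tab <- generate_cohort(tiny_spec(), seed = 12)
  m <- forward_select(tab)
  P <- predict_probabilities(m, tab)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_true(all(P >= 0 & P <= 1))

  # unremarkable admission: predicted case probabilities below prevalence
  quiet <- tab[1, ]
  quiet$code_incontinent <- FALSE; quiet$code_continent <- FALSE
  quiet$elective <- FALSE; quiet$urology_service <- FALSE
  quiet$bladder_cancer_abstract <- FALSE; quiet$bladder_cancer_registry <- FALSE
  quiet$operative_time <- 0; quiet$acute_los <- 2
  pq <- predict_probabilities(m, quiet)
  prev <- mean(tab$true_status != "none")
  expect_lt(pq[1, "p_incontinent"], prev)
  expect_lt(pq[1, "p_continent"], prev)

  expect_error_class(predict_probabilities(m, tab[, -match("code_incontinent", names(tab))]),
                     "schema_error")
})

test_that("c-statistic equals brute-force all-pairs concordance", {
  set.seed(30)
  for (i in 1:5) {
    n <- 400
    p <- round(runif(n), 2)  # force ties
    y <- rbinom(n, 1, plogis(3 * p - 1.5))
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(cstat(p, y), cstat_bruteforce(p, y), tolerance = 1e-12)
  }
  expect_error_class(cstat(runif(5), rep(TRUE, 5)), "degenerate_input_error")
})

test_that("internal validation: limits and bookkeeping", {
  # perfectly separable world: corrected c ~ 1, ICI ~ 0
  tab <- generate_cohort(tiny_spec(code_params = perfect_code_params()), seed = 14)
  cand <- default_candidates()[1:2, ]
  m <- forward_select(tab, cand)
  v <- internal_validate(m, tab, n_boot = 30, seed = 99)
  expect_true(all(v$c_statistic$corrected > 0.999))
  expect_true(all(v$ici$corrected < 0.005))
  expect_true(all(v$c_statistic$ci_low <= v$c_statistic$corrected &
                    v$c_statistic$corrected <= v$c_statistic$ci_high))

  # intercept-only model: c = 0.5 by construction
  m0 <- forward_select(tab, candidates = default_candidates()[0, ])
  v0 <- internal_validate(m0, tab, n_boot = 5, seed = 2)
  expect_equal(v0$c_statistic$apparent, c(0.5, 0.5), tolerance = 1e-12)

  expect_error_class(internal_validate(m, tab, n_boot = 1), "specification_error")
})

test_that("model JSON round-trips with identical predictions", {
  tab <- generate_cohort(tiny_spec(), seed = 16)
  m <- forward_select(tab)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict_probabilities(m2, tab), predict_probabilities(m, tab),
               tolerance = 1e-12)
  expect_equal(m2$coef, m$coef, tolerance = 1e-12)
})
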