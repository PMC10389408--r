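test_that("Kaplan-Meier equals the empirical survivor function without censoring", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km_survival_at(km, c(1, 2, 3)), c(2, 1, 0) / 3)
  withr::local_seed(4)
  for (i in 1:20) {
    t <- sample(1:12, 25, replace = TRUE)
    km <- km_estimate(t, rep(1, 25))
    grid <- 0:13
    expect_equal(km_survival_at(km, grid),
                 sapply(grid, function(u) mean(t > u)), tolerance = 1e-12)
  }
})

test_that("an all-censored cohort has survival one everywhere", {
  km <- km_estimate(c(5, 10, 20), c(0, 0, 0))
  expect_equal(km_survival_at(km, c(0, 10, 50)), c(1, 1, 1))
})

test_that("the product-limit table matches a hand computation with censoring", {
  # times 1, 2+, 3, 4+, 5, 6 -> S = 5/6, 5/8, 5/16, 0
  t <- c(1, 2, 3, 4, 5, 6)
  e <- c(1, 0, 1, 0, 1, 1)
  km <- km_estimate(t, e)
  hand <- km_hand(t, e)
  expect_equal(hand$surv, c(5 / 6, 5 / 8, 5 / 16, 0))
  expect_equal(km_survival_at(km, hand$time), hand$surv, tolerance = 1e-12)
  # right-continuous step behaviour between events
  expect_equal(km_survival_at(km, 2.9), 5 / 6)
  expect_equal(km_survival_at(km, 3.0), 5 / 8)
  expect_equal(km_survival_at(km, 36), 0)
})

test_that("log-rank is null on identical groups and symmetric in labels", {
  t <- c(2, 4, 6, 8); e <- c(1, 1, 0, 1)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  withr::local_seed(10)
  t2 <- rexp(30, 0.1); e2 <- rbinom(30, 1, 0.7); g <- rep(c("x", "y"), 15)
  swap <- ifelse(g == "x", "y", "x")
  expect_equal(logrank_test(t2, e2, g)$chisq,
               logrank_test(t2, e2, swap)$chisq, tolerance = 1e-12)
})

test_that("log-rank matches the per-event-time hypergeometric oracle", {
  # 8-patient two-group toy with censoring and a tie
  t <- c(1, 3, 3, 7, 2, 4, 6, 9)
  e <- c(1, 1, 0, 1, 1, 1, 0, 1)
  g <- rep(c("A", "B"), each = 4)
  lr <- logrank_test(t, e, g)
  oracle <- logrank_oracle(t, e, g)
  expect_equal(lr$chisq, oracle$chisq, tolerance = 1e-10)
  expect_equal(lr$p_value, oracle$p, tolerance = 1e-10)
})

test_that("log-rank detects a strong survival difference at modest n", {
  withr::local_seed(2)
  ta <- rexp(20, 0.02); tb <- rexp(20, 0.3)
  lr <- logrank_test(c(ta, tb), rep(1, 40), rep(c("a", "b"), each = 20))
  expect_lt(lr$p_value, 0.05)
  expect_error(logrank_test(ta, rep(1, 20), rep("a", 20)), "2 groups")
})

test_that("Cox recovers a known hazard ratio and reports bootstrap CIs", {
  withr::local_seed(31)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.03 * 5^x)
  cens <- runif(n, 0, 40)
  d <- data.frame(dfs_time = pmin(t, cens), dfs_event = as.integer(t <= cens),
                  x = x)
  f <- cox_fit(d, "x", n_bootstrap = 100, seed = 1)
  expect_true(f$table$ci_lower <= 5 && 5 <= f$table$ci_upper)
  expect_true(f$table$ci_lower < f$table$hr & f$table$hr < f$table$ci_upper)
  expect_true(f$table$boot_ci_lower < f$table$boot_ci_upper)
  expect_true(is.finite(f$concordance["corrected"]))
  expect_lte(f$concordance["corrected"], 1)
})

test_that("degenerate Cox designs are flagged, not silently fitted", {
  d <- data.frame(dfs_time = c(1, 2, 3, 4), dfs_event = c(1, 1, 0, 1),
                  x = c(1, 1, 1, 1))
  expect_error(cox_fit(d, "x", n_bootstrap = 0), "degenerate")
  # monotone likelihood: the covariate perfectly orders events
  withr::local_seed(5)
  n <- 40
  x <- rep(c(1, 0), each = n / 2)
  d2 <- data.frame(dfs_time = c(runif(n / 2, 0, 5), runif(n / 2, 10, 20)),
                   dfs_event = c(rep(1, n / 2), rep(0, n / 2)), x = x)
  f2 <- cox_fit(d2, "x", n_bootstrap = 0)
  expect_true(any(grepl("separation|warning", f2$flags)))
})

test_that("records with missing covariates are dropped with a count", {
  d <- data.frame(dfs_time = c(1, 2, 3, 4, 5, 6, 7, 8),
                  dfs_event = c(1, 0, 1, 1, 0, 1, 1, 0),
                  x = c(NA, 0, 1, 0, 1, 1, 0, 1))
  expect_message(f <- cox_fit(d, "x", n_bootstrap = 0), "1 record")
  expect_equal(f$n, 7)
  expect_equal(f$n_dropped, 1)
})
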