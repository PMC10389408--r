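test_that("identical groups are null for every variable type", {
  co <- data.frame(dfs_event = rep(c(0, 1), 10),
                   age = rep(c(50, 60, 70, 55, 65), each = 4),
                   n_positive = rep(c(0, 0, 1, 1), 5))
  # both groups see the same age distribution and the same flag counts
  tab <- univariate_table(co, roster = data.frame(
    variable = c("age", "n_positive"),
    type = c("continuous", "categorical")))
  expect_true(all(tab$p_value == 1))
})

test_that("a diagonal 2x2 table is highly significant", {
  co <- data.frame(dfs_event = rep(c(0, 1), each = 10),
                   n_positive = rep(c(0, 1), each = 10))
  tab <- univariate_table(co, roster = data.frame(variable = "n_positive",
                                                  type = "categorical"))
  expect_lt(tab$p_value, 0.001)
})

test_that("the continuous screen is the exact Mann-Whitney test", {
  co <- data.frame(dfs_event = c(0, 0, 0, 1, 1, 1),
                   age = c(1, 2, 3, 4, 5, 6))
  tab <- univariate_table(co, roster = data.frame(variable = "age",
                                                  type = "continuous"))
  expect_equal(tab$p_value, 0.1)  # U = 0, exact two-sided
})

test_that("Fisher's exact test replaces chi-square for sparse tables", {
  co <- data.frame(dfs_event = rep(c(0, 1), each = 6),
                   g34 = c(rep(0, 6), rep(c(0, 1), 3)))
  tab <- univariate_table(co, roster = data.frame(variable = "g34",
                                                  type = "categorical"))
  expect_equal(tab$test, "Fisher exact")
  big <- data.frame(dfs_event = rep(c(0, 1), each = 40),
                    g34 = rbinom(80, 1, 0.5))
  tab2 <- univariate_table(big, roster = data.frame(variable = "g34",
                                                    type = "categorical"))
  expect_equal(tab2$test, "chi-square")
})

test_that("unknown variable types are refused", {
  co <- data.frame(dfs_event = c(0, 1), age = c(1, 2))
  expect_error(univariate_table(co, roster = data.frame(variable = "age",
                                                        type = "ordinal")),
               "unknown variable type")
})

test_that("exact Mann-Whitney enumeration handles ties correctly", {
  # six zeros vs six positives: U = 0, p = 2 / C(12,6)
  mw <- mann_whitney(rep(0, 6), c(3, 7, 2, 9, 4, 1))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 2 / choose(12, 6), tolerance = 1e-12)
  expect_match(mw$method, "exact")
  # agreement with wilcox.test where the latter is exact (no ties)
  withr::local_seed(6)
  for (i in 1:20) {
    x <- runif(sample(3:8, 1)); y <- runif(sample(3:8, 1))
    expect_equal(mann_whitney(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # large samples fall back to the tie-corrected normal approximation
  big <- mann_whitney(rnorm(30), rnorm(30, 1))
  expect_match(big$method, "normal")
  expect_lt(big$p_value, 0.05)
})
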