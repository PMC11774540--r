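test_that("two-level factor reduces to the squared paired t test", {
  set.seed(10)
  d <- tidyr::expand_grid(subj = sprintf("S%02d", 1:10), cond = c("a", "b"))
  d$y <- rnorm(20) + ifelse(d$cond == "b", 0.8, 0)
  res <- rm_anova(d, "y", "cond", "subj")
  tt <- t.test(d$y[d$cond == "a"], d$y[d$cond == "b"], paired = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_lt(abs(res$p - tt$p.value), 1e-10)
  expect_equal(res$gg_epsilon, 1)
  expect_equal(res$p_gg, res$p)
})

test_that("one-way design matches the brute-force sums-of-squares oracle", {
  set.seed(11)
  Y <- matrix(rnorm(18, mean = rep(c(0, 0.5, 1.5), each = 6)), 6, 3)
  d <- tidyr::expand_grid(cond = c("c1", "c2", "c3"), subj = 1:6)
  d$y <- as.vector(Y)
  res <- rm_anova(d, "y", "cond", "subj")
  orc <- oracle_rm_anova_1f(Y)
  expect_equal(res$F, orc$F, tolerance = 1e-6)
  expect_equal(res$df_num, orc$df1)
  expect_equal(res$df_den, orc$df2)
  expect_equal(res$p, orc$p, tolerance = 1e-6)
  expect_equal(res$gg_epsilon, orc$eps, tolerance = 1e-6)
  expect_true(res$gg_epsilon > 0 && res$gg_epsilon <= 1)
  expect_gte(res$p_gg, res$p)
})

test_that("two-factor design agrees with stats::aov", {
  set.seed(12)
  d <- tidyr::expand_grid(subj = factor(1:8), A = factor(1:3),
                          B = factor(1:2))
  d$y <- rnorm(nrow(d)) + as.numeric(d$A) * 0.5 +
    as.numeric(d$A) * as.numeric(d$B) * 0.3
  res <- rm_anova(d, "y", c("A", "B"), "subj")
  fit <- summary(stats::aov(y ~ A * B + Error(subj / (A * B)), data = d))
  getF <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  expect_equal(res$F[res$effect == "A"], getF("Error: subj:A", "A"),
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "B"], getF("Error: subj:B", "B"),
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "A:B"], getF("Error: subj:A:B", "A:B"),
               tolerance = 1e-10)
  expect_equal(res$df_num, c(2, 1, 2))
  expect_equal(res$df_den, c(14, 7, 14))
  # eta^2 partitions a fraction of the total SS
  expect_true(all(res$eta_sq >= 0) && sum(res$eta_sq) < 1)
})

test_that("constant responses give F = 0 and replicates are averaged", {
  d <- tidyr::expand_grid(subj = 1:5, cond = c("a", "b", "c"))
  d$y <- 3
  res <- rm_anova(d, "y", "cond", "subj")
  expect_equal(res$F, 0)

  # duplicated rows (2 obs per cell) must not change the cell-mean analysis
  set.seed(13)
  d2 <- tidyr::expand_grid(subj = 1:6, cond = c("a", "b", "c"))
  d2$y <- rnorm(18)
  dup <- dplyr::bind_rows(d2, d2)
  expect_equal(rm_anova(dup, "y", "cond", "subj")$F,
               rm_anova(d2, "y", "cond", "subj")$F)
})

test_that("incomplete designs and degenerate inputs are rejected", {
  d <- tidyr::expand_grid(subj = 1:4, cond = c("a", "b", "c"))
  d$y <- rnorm(12)
  expect_error(rm_anova(d[-1, ], "y", "cond", "subj"), "missing cell")
  expect_error(rm_anova(d[d$subj == 1, ], "y", "cond", "subj"),
               "2 subjects")
  expect_error(rm_anova(d, "z", "cond", "subj"), "not found")
})

test_that("sphericity machinery flags strongly non-spherical data", {
  # heterogeneous correlations between conditions violate sphericity
  set.seed(14)
  n <- 40
  base <- rnorm(n)
  Y <- cbind(base + rnorm(n, sd = 0.1), base + rnorm(n, sd = 0.1),
             rnorm(n, sd = 3))
  d <- tidyr::expand_grid(cond = c("a", "b", "c"), subj = 1:n)
  d$y <- as.vector(Y)
  res <- rm_anova(d, "y", "cond", "subj")
  expect_lt(res$mauchly_p, 0.05)
  expect_true(res$sphericity_violated)
  expect_lt(res$gg_epsilon, 0.9)
  expect_gte(res$p_gg, res$p)
})
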