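test_that("noiseless responses reproduce the numerosity exactly", {
  set.seed(1)
  expect_equal(simulate_response(rep(5:16, 10), wf = 0), rep(5:16, 10))
  expect_error(simulate_response(8, wf = -0.1), "non-negative")
  expect_error(simulate_response(0, wf = 0.1), ">= 1")
})

test_that("responses are clamped at 1 even under extreme noise", {
  set.seed(2)
  r <- simulate_response(rep(5L, 5000), wf = 2)
  expect_true(all(r >= 1))
})

test_that("response SD matches the discrete-distribution oracle", {
  # rounding to integer responses inflates the continuous SD (wf * N);
  # the oracle enumerates the exact discrete distribution
  set.seed(3)
  r <- simulate_response(rep(8L, 1e5), wf = 0.11)
  expect_equal(sd(r), oracle_response_sd(8, 0.11), tolerance = 0.01)
  expect_equal(oracle_response_sd(8, 0.11), 0.9268, tolerance = 1e-3)

  set.seed(4)
  r <- simulate_response(rep(6L, 1e5), wf = 0.2, bias = 0.07)
  expect_equal(sd(r), oracle_response_sd(6, 0.2, 0.07), tolerance = 0.015)
})

test_that("lapses produce wild responses at the requested rate", {
  set.seed(5)
  n <- 2e4
  r <- simulate_response(rep(10L, n), wf = 0, lapse_rate = 0.1)
  wild <- r != 10
  expect_equal(mean(wild), 0.1 * (29 / 30), tolerance = 0.015)
  expect_true(all(r[wild] >= 1 & r[wild] <= 30))
})

test_that("simulator defaults carry the study's calibrated values", {
  p <- sim_params()
  expect_equal(p$wf_single_grouped, 0.09)
  expect_equal(p$wf_single_ungrouped, 0.11)
  expect_equal(unname(p$fold_increase["grouped.vsp_dt"]), 2.3)
  expect_equal(unname(p$fold_increase["grouped.aud_dt"]), 1.6)
  expect_equal(unname(p$fold_increase["ungrouped.arithm_dt"]), 1.3)
  expect_equal(unname(p$concurrent_accuracy["arithm_dt"]), 0.96)
  expect_equal(p$lapse_rate, 0.006)
  cw <- condition_wf(p)
  expect_equal(cw$wf[cw$task == "vsp_dt" & cw$arrangement == "grouped"],
               0.09 * 2.3)
  expect_equal(nrow(cw), 9) # no ungrouped single_distractor condition

  expect_error(sim_params(lapse_rate = 0.2), "lapse_rate")
  expect_error(sim_params(wf_single_grouped = 0), "positive")
  expect_error(sim_params(concurrent_accuracy = c(aud_dt = 1.2, vsp_dt = 0.9,
                                                  arithm_dt = 0.9)),
               "concurrent_accuracy")
})

test_that("the emitted design matches the experiment's trial arithmetic", {
  tr <- simulate_experiment(n_participants = 2, seed = 11)
  expect_equal(nrow(tr), 2 * 1296)
  one <- tr[tr$participant == "P01", ]
  expect_equal(nrow(one), 1296)
  counts <- table(one$task)
  expect_equal(unname(counts["single"]), 288)
  expect_equal(unname(counts["single_distractor"]), 144)
  expect_equal(sum(counts[c("single", "single_distractor")]), 432)
  expect_equal(sum(counts[c("aud_dt", "vsp_dt", "arithm_dt")]), 864)
  # every task x arrangement count is a whole number of 36-trial blocks
  ta <- table(one$task, one$arrangement)
  expect_true(all(ta[ta > 0] %% 36 == 0))
  # 12 trials per numerosity within each condition (4 blocks x 3)
  cell <- table(one$task, one$arrangement, one$numerosity)
  expect_true(all(cell[cell > 0] == 12))
  # each grouped configuration appears once per block
  grouped_single <- one[one$task == "single" & one$arrangement == "grouped", ]
  expect_true(all(table(grouped_single$configuration) == 4))

  expect_false(any(tr$task == "single_distractor" &
                     tr$arrangement == "ungrouped"))
  expect_true(all(tr$configuration[tr$arrangement == "ungrouped"] == ""))
  expect_true(all(is.na(tr$concurrent_correct[tr$task %in%
                                                c("single",
                                                  "single_distractor")])))
  expect_false(anyNA(tr$concurrent_correct[tr$task %in%
                                             c("aud_dt", "vsp_dt",
                                               "arithm_dt")]))
})

test_that("simulation is reproducible per seed and varies across seeds", {
  a <- simulate_experiment(n_participants = 1, seed = 99)
  b <- simulate_experiment(n_participants = 1, seed = 99)
  expect_identical(a, b)
  c <- simulate_experiment(n_participants = 1, seed = 100)
  expect_false(identical(a$response, c$response))
})

test_that("concurrent accuracy tracks the task-specific probabilities", {
  tr <- simulate_experiment(n_participants = 8, seed = 21)
  acc <- tapply(tr$concurrent_correct, tr$task, mean, na.rm = TRUE)
  expect_equal(unname(acc["aud_dt"]), 0.82, tolerance = 0.03)
  expect_equal(unname(acc["vsp_dt"]), 0.94, tolerance = 0.03)
  expect_equal(unname(acc["arithm_dt"]), 0.96, tolerance = 0.03)
})
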