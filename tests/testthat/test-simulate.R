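test_that("gamma non-decision sampling has the requested moments", {
  x <- sample_nondecision(0.3, 0.1, 1e5, seed = 1)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - 0.3), 3 * 0.1 / sqrt(1e5))
  expect_lt(abs(sd(x) - 0.1), 0.005)
  expect_equal(sample_nondecision(0.25, 0, 5), rep(0.25, 5))
  expect_error(sample_nondecision(-0.1, 0.1, 5), "positive")
})

test_that("flat-bound simulation is symmetric at zero drift and saturates", {
  p <- flat_params(40.4, 0.62, 0.007, 0)
  sim <- simulate_flat_ddm_trials(p, 0.007, n_per = 20000, seed = 2)
  se <- sqrt(0.25 / 20000)
  expect_lt(abs(mean(sim$choice[sim$terminated]) - 0.5), 3 * se)
  # strong drift: always rightward
  simr <- simulate_flat_ddm_trials(p, 1, n_per = 2000, seed = 3)
  expect_equal(mean(simr$choice), 1)
  expect_error(simulate_flat_ddm_trials(
    structure(list(kappa = 10, B = -1, C0 = 0, t_nd = 0),
              class = "flat_params"), 0, 10), "positive")
})

test_that("flat-bound simulation matches the closed-form mean time", {
  p <- table1_params$s1
  sim <- simulate_flat_ddm_trials(flat_params(p$kappa, p$B, p$C0, 0), 0,
                                  n_per = 50000, seed = 4)
  st <- sim$decision_time[sim$terminated]
  expect_gte(mean(sim$terminated), 0.999)
  target <- mean_decision_time(p, 0) - p$t_nd
  expect_lt(abs(mean(st) - target), 2 * sd(st) / sqrt(length(st)) + 0.001)
})

test_that("simulation is bit-identical under a repeated seed", {
  p <- flat_params(20, 0.8, 0, 0)
  a <- simulate_flat_ddm_trials(p, c(0, 0.1), 500, seed = 9)
  b <- simulate_flat_ddm_trials(p, c(0, 0.1), 500, seed = 9)
  expect_identical(a, b)
  truth <- ground_truth(flat = p, nd_mean = 0.2, nd_sd = 0.05)
  t1 <- simulate_controlled_duration_experiment(truth, 300, seed = 10)
  t2 <- simulate_controlled_duration_experiment(truth, 300, seed = 10)
  expect_identical(t1, t2)
})

test_that("degenerate collapse reproduces flat-bound behavior", {
  pc <- collapse_params(kappa = 30, C0 = 0, A0 = 0.7, B_log = 4,
                        t_beta = 0.98, mu = 0.2, sigma = 0.02)
  pf <- flat_params(30, 0.7, 0, 0)
  simc <- simulate_collapse_ddm_trials(pc, 0.1, n_per = 20000, seed = 5)
  pr <- mean(simc$choice[simc$terminated])
  expect_lt(abs(pr - choice_probability(pf, 0.1)),
            3 * sqrt(pr * (1 - pr) / 20000) + 1e-3)
  simf <- simulate_flat_ddm_trials(pf, 0.1, n_per = 20000, seed = 5)
  expect_lt(abs(mean(simc$decision_time[simc$terminated]) -
                  mean(simf$decision_time[simf$terminated])), 0.01)
})

test_that("controlled-duration experiment honors the design distributions", {
  truth <- ground_truth(flat = table1_params$s1, nd_mean = 0.131,
                        nd_sd = 0.02)
  expect_equal(nrow(simulate_controlled_duration_experiment(truth, 0)), 0)
  tr <- simulate_controlled_duration_experiment(truth, 10000, seed = 11)
  # duration marginal: P(0.8 s) = 0.75 within 3 binomial SE
  p8 <- mean(tr$duration == 0.8)
  expect_lt(abs(p8 - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  # both directions, all magnitudes present; correct consistent with sign
  expect_setequal(unique(sign(tr$coh_signed)), c(-1, 0, 1))
  nz <- tr$coh_signed != 0
  expect_equal(tr$correct[nz],
               as.integer((tr$coh_signed[nz] > 0) == (tr$choice[nz] == 1L)))
  # t_sd present iff a decision terminated, and positive
  expect_equal(is.na(tr$t_sd), tr$no_decision)
  expect_true(all(tr$t_sd[!is.na(tr$t_sd)] > 0))
  # mean t_sd decreases with |C| (chronometric signature)
  m <- tapply(tr$t_sd, abs(tr$coh_signed), mean, na.rm = TRUE)
  expect_true(all(diff(m) < 0))
})

test_that("free-response experiment couples rt and t_sd through termination", {
  truth <- ground_truth(flat = flat_params(24, 1.0, 0, 0), nd_mean = 0.3,
                        nd_sd = 0.05)
  tr <- simulate_free_response_experiment(truth, 2000, seed = 12)
  expect_true(all(!is.na(tr$rt[!tr$no_decision])))
  expect_gt(cor(tr$rt, tr$t_sd, use = "complete.obs"), 0.7)
  # zero latency spread with equal means: rt - t_sd constant
  truth0 <- ground_truth(flat = flat_params(24, 1.0, 0, 0), nd_mean = 0.3,
                         nd_sd = 0)
  tr0 <- simulate_free_response_experiment(truth0, 200, seed = 13)
  expect_equal(max(abs(tr0$rt - tr0$t_sd), na.rm = TRUE), 0)
  # choice proportions match the splitting probability within binomial error
  pf <- flat_params(24, 1.0, 0, 0)
  for (cc in c(0.064, 0.256)) {
    sub <- tr[tr$coh_signed == cc, ]
    pr <- choice_probability(pf, cc)
    expect_lt(abs(mean(sub$choice) - pr),
              3 * sqrt(pr * (1 - pr) / nrow(sub)) + 0.01)
  }
})
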