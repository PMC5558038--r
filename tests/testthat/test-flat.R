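test_that("choice probability has the logistic form and limits", {
  p <- flat_params(40.4, 0.62, 0.007, 0.131)
  expect_equal(choice_probability(p, 0.007), 0.5)
  expect_equal(choice_probability(p, 0.512),
               1 / (1 + exp(-2 * 40.4 * 0.62 * 0.505)))
  expect_equal(choice_probability(p, -1e6), 0)
  expect_equal(choice_probability(p, 1e6), 1)
  # monotone nondecreasing
  C <- seq(-0.6, 0.6, 0.01)
  expect_true(all(diff(choice_probability(p, C)) >= 0))
})

test_that("mean decision time handles the removable singularity and symmetry", {
  p <- flat_params(40.4, 0.62, 0.007, 0.131)
  expect_equal(mean_decision_time(p, 0.007), 0.62^2 + 0.131,
               tolerance = 1e-10)
  # even in C - C0, strictly decreasing in |C - C0|
  d <- c(0.01, 0.05, 0.2, 0.5)
  expect_equal(mean_decision_time(p, 0.007 + d),
               mean_decision_time(p, 0.007 - d))
  expect_true(all(diff(mean_decision_time(p, 0.007 + d)) < 0))
  # direct evaluation at printed parameters of another subject
  s3 <- table1_params$s3
  m <- s3$kappa * (0.512 - s3$C0)
  expect_equal(mean_decision_time(s3, 0.512),
               (s3$B / m) * tanh(m * s3$B) + s3$t_nd)
})

test_that("condition summaries select congruent trials around the PSE", {
  truth <- ground_truth(flat = table1_params$s1, nd_mean = 0.131,
                        nd_sd = 0.02)
  tr <- simulate_controlled_duration_experiment(truth, 3000, seed = 21)
  summ <- suppressWarnings(condition_summaries(tr))
  expect_s3_class(summ, "condition_summaries")
  expect_equal(nrow(summ), 11)
  expect_lt(abs(attr(summ, "pse")), 0.03)
  expect_true(all(summ$sem_tsd > 0))
  expect_true(all(summ$n_right <= summ$n_total))
  # single-coherence table gives one summary
  one <- tr[tr$coh_signed == 0.512, ]
  s1 <- suppressWarnings(condition_summaries(one))
  expect_equal(nrow(s1), 1)
  # complete separation: penalized fit still returns finite coefficients
  sep <- data.frame(coh_signed = rep(c(-0.1, 0.1), each = 30),
                    choice = rep(c(0L, 1L), each = 30),
                    t_sd = runif(60, 0.3, 0.6))
  ss <- suppressWarnings(condition_summaries(sep))
  expect_true(is.finite(attr(ss, "pse")))
})

test_that("chronometric fit recovers generating parameters from exact means", {
  for (nm in c("s1", "s3")) {
    p <- table1_params[[nm]]
    fit <- fit_mean_tsd(exact_summaries(p))
    expect_equal(fit$kappa, p$kappa, tolerance = 1e-4)
    expect_equal(fit$B, p$B, tolerance = 1e-4)
    expect_equal(fit$C0, p$C0, tolerance = 1e-3)
    expect_equal(fit$t_nd, p$t_nd, tolerance = 1e-4)
    expect_true(all(is.finite(fit$se)))
  }
  # too few conditions is an error; flat means flag kappa at the boundary
  expect_error(fit_mean_tsd(exact_summaries(table1_params$s1)[1:3, ]),
               "at least 4")
  # coherence-independent means: the fitted chronometric curve is flat
  # (no signal for kappa*B), whatever boundary the optimizer settles on
  flat_summ <- exact_summaries(table1_params$s1)
  flat_summ$mean_tsd <- 0.5
  ffit <- suppressWarnings(fit_mean_tsd(flat_summ))
  rng <- range(mean_decision_time(ffit, signed_coherences))
  expect_lt(diff(rng), 1e-3)
})

test_that("choice prediction from noiseless chronometric data reproduces the generating curve", {
  p <- table1_params$s1
  fit <- fit_mean_tsd(exact_summaries(p))
  pred <- predict_choice_and_loglik(fit, exact_summaries(p))
  expect_lt(max(abs(pred$prediction$p_right -
                      choice_probability(p, signed_coherences))), 1e-3)
  # kappa = 0 limit: pure chance likelihood
  p0 <- flat_params(1e-9, 0.62, 0, 0.1)
  s <- exact_summaries(table1_params$s1)
  ll0 <- predict_choice_and_loglik(p0, s)$loglik
  chance <- sum(dbinom(s$n_right, s$n_total, 0.5, log = TRUE))
  expect_equal(ll0, chance, tolerance = 1e-6)
  # empty summaries
  expect_equal(predict_choice_and_loglik(p, s[0, ])$loglik, 0)
})

test_that("shuffle test separates informative from decoupled reports", {
  truth <- ground_truth(flat = table1_params$s1, nd_mean = 0.131,
                        nd_sd = 0.02)
  tr <- simulate_controlled_duration_experiment(truth, 2000, seed = 22)
  summ <- suppressWarnings(condition_summaries(tr))
  sh <- suppressWarnings(shuffle_significance(summ, n_shuffles = 100,
                                              seed = 23))
  expect_lte(sh$p_value, 0.05)
  tr5 <- simulate_controlled_duration_experiment(truth, 2000, seed = 24,
                                                 decouple_tsd = TRUE)
  s5 <- suppressWarnings(condition_summaries(tr5))
  sh5 <- suppressWarnings(shuffle_significance(s5, n_shuffles = 100,
                                               seed = 25))
  expect_gt(sh5$p_value, 0.05)
  # degenerate: no shuffles
  expect_equal(suppressWarnings(
    shuffle_significance(summ, n_shuffles = 0))$p_value, 1)
})

test_that("joint choice-RT fit recovers parameters and motor asymmetry", {
  truth <- ground_truth(flat = flat_params(24, 1.0, 0.01, 0),
                        nd_mean = 0.30, nd_sd = 0.05,
                        nd_mean_left = 0.35, nd_mean_right = 0.25)
  tr <- simulate_free_response_experiment(truth, 3000, seed = 26)
  fit <- fit_joint_choice_rt(tr)
  expect_lt(abs(fit$kappa - 24), 2 * fit$se["kappa"] + 1)
  expect_lt(abs(fit$B - 1.0), 3 * fit$se["B"] + 0.02)
  diff_nd <- fit$t_nd_right - fit$t_nd_left
  se_diff <- sqrt(fit$se["t_nd_left"]^2 + fit$se["t_nd_right"]^2)
  expect_lt(abs(diff_nd - (-0.10)), 3 * se_diff + 0.01)
  # constrained mode pins kappa without breaking the bound estimate
  fitc <- fit_joint_choice_rt(tr, fix_kappa = 24)
  expect_equal(fitc$kappa, 24)
  expect_lt(abs(fitc$B - 1.0), 0.05)
})
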