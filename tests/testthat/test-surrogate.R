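ref_summaries <- function(seed = 51, n = 2500) {
  truth <- ground_truth(flat = table1_params$s1, nd_mean = 0.131,
                        nd_sd = 0.02)
  tr <- simulate_controlled_duration_experiment(truth, n, seed = seed)
  suppressWarnings(condition_summaries(tr))
}

test_that("beta surrogate fitting behaves across shapes", {
  summ <- ref_summaries()
  expect_error(fit_beta_surrogate(summ$C, summ$mean_tsd, 2.5), "alpha")
  # self-fit: means already of the surrogate form give R^2 = 1
  s0 <- fit_beta_surrogate(summ$C, summ$mean_tsd, 0.8)
  s_self <- fit_beta_surrogate(summ$C, s0$t_surr, 0.8)
  expect_gt(s_self$r_squared, 0.9999)
  expect_equal(s_self$t_surr, s0$t_surr, tolerance = 1e-3)
  # alpha = 1: curve piecewise-linear in |C - k3|
  s1 <- fit_beta_surrogate(summ$C, summ$mean_tsd, 1)
  x <- abs(summ$C - s1$k3) / 0.512
  expect_equal(s1$t_surr, s1$k1 + s1$k2 * pmin(x, 1), tolerance = 1e-9)
  # chronometric-like (peaked) data: small alpha fits better than the
  # squashed semicircle end of the family
  s_peak <- fit_beta_surrogate(summ$C, summ$mean_tsd, 0.05)
  s_squash <- fit_beta_surrogate(summ$C, summ$mean_tsd, 1.9)
  expect_gt(s_peak$r_squared, s_squash$r_squared)
})

test_that("surrogate sweep degrades predictions as distortion grows", {
  summ <- ref_summaries()
  sw <- surrogate_sweep(summ, alpha_grid = seq(0.01, 1.95, length.out = 11))
  expect_equal(nrow(sw), 11)
  # the least distorting shape predicts nearly as well as the data
  expect_gt(max(sw$loglr, na.rm = TRUE), -15)
  # strong distortion is far worse
  expect_lt(min(sw$loglr, na.rm = TRUE), -50)
  # logLR increases with R^2 overall
  expect_gt(cor(sw$r_squared, sw$loglr, method = "spearman"), 0.5)
  # undistorted surrogate scores exactly zero
  fit_data <- suppressWarnings(fit_mean_tsd(summ, n_starts = 5))
  ll_data <- predict_choice_and_loglik(fit_data, summ)$loglik
  expect_equal(chronoddm:::surrogate_loglr(summ$mean_tsd, summ, ll_data), 0)
})

test_that("jitter analysis preserves extremes and degrades with distortion", {
  summ <- ref_summaries()
  jit <- jitter_analysis(summ, n_jitter = 150, seed = 52)
  expect_true(all(jit$results$delta >= 0))
  expect_lt(jit$slope, 0)
  expect_lt(jit$slope_p, 0.05)
  # construction invariant: accumulating permuted gaps from the minimum
  # keeps min and max
  y <- summ$mean_tsd
  ord <- order(y)
  d <- diff(y[ord])
  set.seed(53)
  for (i in 1:20) {
    surr <- y[ord][1] + cumsum(c(0, sample(d)))
    expect_equal(min(surr), min(y))
    expect_equal(max(surr), max(y))
  }
})

test_that("cross-subject combination test enumerates 27^4 alternatives", {
  params <- lapply(table1_params[c("s1", "s2", "s3", "s4")], function(p)
    flat_params(p$kappa, p$B, p$C0, 0))
  summs <- lapply(params, exact_summaries, n_total = 400)
  res <- cross_subject_combination_test(params, summs)
  expect_equal(res$n_combinations, 531441)
  expect_equal(res$n_better, 0)  # own parameters generated the choices
  expect_error(cross_subject_combination_test(params[1:3], summs[1:3]),
               "4 subjects")
  # identical subjects: every combination ties, none strictly better
  same <- rep(params[1], 4)
  same_s <- rep(summs[1], 4)
  tie <- cross_subject_combination_test(same, same_s)
  expect_equal(tie$n_better, 0)
})
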