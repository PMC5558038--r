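# Sensitivity of the choice predictions to distortions of the mean reported
# times: beta-shaped surrogates, an interval-jitter analysis, and the
# cross-subject parameter-combination test.  (The coherence-shuffle test
# lives with the flat-bound module: shuffle_significance().)

#' Fit a reflected cumulative-beta surrogate to mean reported times
#'
#' Least-squares fit of `t = k1 + k2 * cbeta(|C - k3| / 0.512, alpha,
#' 2 - alpha)` where `cbeta` is the regularized incomplete beta integral.
#' `alpha` fixes the shape (squashed semicircle for small `alpha`, sharp
#' peak near 2); `k1`, `k2` scale and offset it and `k3` centers the peak.
#' The inner linear pair (k1, k2) is solved in closed form for each
#' candidate `k3` of a 1-D search.
#'
#' @param C signed coherences.
#' @param means observed mean times per coherence, s.
#' @param alpha beta shape in (0, 2).
#' @param k3_range search interval for the center.
#' @return list with `k1`, `k2`, `k3`, `alpha`, `r_squared`, `t_surr`
#'   (fitted curve at `C`).
#' @export
fit_beta_surrogate <- function(C, means, alpha, k3_range = c(-0.256, 0.256)) {
  if (alpha <= 0 || alpha >= 2) stop("`alpha` must be in (0, 2)")
  stopifnot(length(C) == length(means))
  basis <- function(k3) pbeta(pmin(abs(C - k3) / 0.512, 1), alpha, 2 - alpha)
  sse_of <- function(k3) {
    x <- basis(k3)
    fit <- lm(means ~ x)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(sse_of, k3_range)
  k3 <- opt$minimum
  x <- basis(k3)
  fit <- lm(means ~ x)
  t_surr <- unname(stats::fitted(fit))
  ss_tot <- sum((means - mean(means))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  list(k1 = unname(coef(fit)[1]), k2 = unname(coef(fit)[2]), k3 = k3,
       alpha = alpha, r_squared = r2, t_surr = t_surr)
}

# fit the chronometric function to surrogate means (observed SEMs retained),
# predict choice, and return the log-likelihood ratio against the
# data-based prediction
surrogate_loglr <- function(t_surr, summaries, ll_data, n_starts = 5) {
  surr <- summaries
  surr$mean_tsd <- t_surr
  fit <- tryCatch(suppressWarnings(fit_mean_tsd(surr, n_starts = n_starts)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  predict_choice_and_loglik(fit, summaries)$loglik - ll_data
}

#' Sweep of beta-surrogate shapes
#'
#' For each `alpha` on the grid: fit the surrogate to the observed means,
#' refit the chronometric function to the surrogate means, predict the
#' choice function and compare its log likelihood to the prediction based
#' on the observed means.  Undistorting shapes (`R^2` near 1) give
#' `logLR` near 0; distorting shapes give strongly negative `logLR`.
#'
#' @param summaries a [condition_summaries()] table.
#' @param alpha_grid shape grid (default 31 steps from 0.01 to 1.95).
#' @param n_starts multi-start count for the chronometric refits.
#' @return data.frame with `alpha`, `r_squared`, `loglr`.
#' @export
surrogate_sweep <- function(summaries,
                            alpha_grid = seq(0.01, 1.95, length.out = 31),
                            n_starts = 5) {
  fit_data <- suppressWarnings(fit_mean_tsd(summaries, n_starts = n_starts))
  ll_data <- predict_choice_and_loglik(fit_data, summaries)$loglik
  rows <- lapply(alpha_grid, function(a) {
    s <- fit_beta_surrogate(summaries$C, summaries$mean_tsd, a)
    data.frame(alpha = a, r_squared = s$r_squared,
               loglr = surrogate_loglr(s$t_surr, summaries, ll_data,
                                       n_starts))
  })
  do.call(rbind, rows)
}

#' Interval-jitter analysis of the choice predictions
#'
#' Ranks the observed mean times, permutes the differences between
#' consecutive ranked means, and rebuilds surrogate means by accumulating
#' the permuted differences from the shortest mean — preserving the
#' minimum, maximum, and the rank order across coherences.  Each replicate
#' yields the mean absolute distortion `Delta = mean(|t_obs - t_surr|)` and
#' the log-likelihood ratio of its choice prediction; a linear regression
#' of `logLR` on `Delta` locates the distortion at which the prediction
#' degrades to `logLR = -10`.
#'
#' @param summaries a [condition_summaries()] table.
#' @param n_jitter number of jitter replicates.
#' @param seed integer seed.
#' @param n_starts multi-start count for the refits.
#' @return list with `results` (data.frame `delta`, `loglr`),
#'   `delta_at_minus10` (s), `slope`, `slope_p` (two-sided test of zero
#'   slope).
#' @export
jitter_analysis <- function(summaries, n_jitter = 1000, seed = NULL,
                            n_starts = 5) {
  fit_data <- suppressWarnings(fit_mean_tsd(summaries, n_starts = n_starts))
  ll_data <- predict_choice_and_loglik(fit_data, summaries)$loglik
  y <- summaries$mean_tsd
  ord <- order(y)          # ties broken by signed-coherence order
  d <- diff(y[ord])
  res <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_jitter), function(b) {
      surr_sorted <- y[ord][1] + cumsum(c(0, sample(d)))
      t_surr <- numeric(length(y))
      t_surr[ord] <- surr_sorted
      data.frame(delta = mean(abs(y - t_surr)),
                 loglr = surrogate_loglr(t_surr, summaries, ll_data,
                                         n_starts))
    }))
  })
  ok <- is.finite(res$loglr)
  fit <- lm(loglr ~ delta, data = res[ok, ])
  sm <- summary(fit)$coefficients
  delta10 <- (-10 - coef(fit)[1]) / coef(fit)[2]
  list(results = res, delta_at_minus10 = unname(delta10),
       slope = unname(coef(fit)[2]), slope_p = unname(sm[2, 4]))
}

#' Cross-subject parameter-combination test
#'
#' For each target subject, every coordinate-wise combination of
#' (kappa, B, C0) drawn from the other subjects' fits (3^3 = 27 per
#' subject) yields an alternative choice prediction; combining the four
#' subjects' prediction log likelihoods in all 27^4 ways gives the null
#' ensemble against which the own-parameter combined log likelihood is
#' compared (strict inequality).
#'
#' @param params_list list of [flat_params()], one per subject (>= 4).
#' @param summaries_list list of [condition_summaries()] tables, matched to
#'   `params_list`.
#' @return list with `n_combinations`, `n_better`, `fraction_better`,
#'   `loglik_own`.
#' @export
cross_subject_combination_test <- function(params_list, summaries_list) {
  n_sub <- length(params_list)
  if (n_sub < 4) stop("need at least 4 subjects")
  stopifnot(length(summaries_list) == n_sub)

  ll_own <- numeric(n_sub)
  ll_others <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    ll_own[s] <- predict_choice_and_loglik(params_list[[s]],
                                           summaries_list[[s]])$loglik
    others <- setdiff(seq_len(n_sub), s)
    grid <- expand.grid(k = others, b = others, c0 = others)
    ll_others[[s]] <- vapply(seq_len(nrow(grid)), function(i) {
      p <- flat_params(params_list[[grid$k[i]]]$kappa,
                       params_list[[grid$b[i]]]$B,
                       params_list[[grid$c0[i]]]$C0, 0)
      predict_choice_and_loglik(p, summaries_list[[s]])$loglik
    }, numeric(1))
  }

  # total over subjects of all cross products, without materializing the
  # full grid: successive outer sums
  total <- ll_others[[1]]
  for (s in 2:n_sub) {
    total <- as.numeric(outer(total, ll_others[[s]], `+`))
  }
  own_total <- sum(ll_own)
  list(n_combinations = length(total),
       n_better = sum(total > own_total),
       fraction_better = mean(total > own_total),
       loglik_own = own_total)
}
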