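# Monte-Carlo simulation of bounded evidence accumulation and of the two
# experimental designs (controlled-duration and free-response).

# Duration / delay distribution of the controlled-duration task.
CONTROLLED_DURATIONS <- c(0.2, 0.4, 0.6, 0.8)
CONTROLLED_DURATION_PROBS <- c(0.125, 0.0625, 0.0625, 0.75)

#' Sample gamma-distributed non-decision times
#'
#' Parameterized by mean `mu` and standard deviation `sigma`, i.e. shape
#' `(mu/sigma)^2` and scale `sigma^2/mu`; guarantees strictly positive
#' latencies.  `sigma = 0` degenerates to a point mass at `mu`.
#'
#' @param mu mean, s (> 0).
#' @param sigma standard deviation, s (>= 0).
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of `n` positive latencies.
#' @export
sample_nondecision <- function(mu, sigma, n, seed = NULL) {
  stop_if_not_scalar(mu, "mu", positive = TRUE)
  stop_if_not_scalar(sigma, "sigma")
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(rep(mu, n))
  shape <- (mu / sigma)^2
  scale <- sigma^2 / mu
  with_seed(seed, rgamma(n, shape = shape, scale = scale))
}

# shared driver: simulate n paths per coherence against a bound profile
# given at step edges; drift_off_steps may be per-trial (controlled task)
sim_bounded_paths <- function(drift, drift_off_steps, bound_edges, dt) {
  n_steps <- length(bound_edges) - 1L
  res <- cpp_sim_ddm(drift, as.integer(drift_off_steps), bound_edges, dt,
                     n_steps)
  data.frame(choice = res$choice, decision_time = res$decision_time,
             terminated = res$terminated, x_final = res$x_final)
}

#' Simulate first-passage trials of the flat-bound model
#'
#' Euler-Maruyama accumulation (increments mean `kappa*(C-C0)*dt`, variance
#' `dt`) with a Brownian-bridge correction for within-step bound crossings,
#' so that choice fractions and mean first-passage times agree with the
#' closed-form expressions to Monte-Carlo error.
#'
#' @param params a [flat_params()]; `t_nd` is not added here.
#' @param coherences signed coherences to simulate.
#' @param n_per trials per coherence.
#' @param dt time step, s.
#' @param seed integer seed.
#' @param t_max simulation horizon, s; paths not absorbed by `t_max` are
#'   returned with `terminated = FALSE`.
#' @return data.frame with columns `C`, `choice` (1 right / 0 left),
#'   `decision_time`, `terminated`, `x_final`.
#' @export
simulate_flat_ddm_trials <- function(params, coherences, n_per,
                                     dt = 5e-4, seed = NULL, t_max = 10) {
  stopifnot(inherits(params, "flat_params"))
  if (params$B <= 0) stop("bound height B must be positive")
  n_steps <- as.integer(ceiling(t_max / dt))
  bound <- rep(params$B, n_steps + 1L)
  drift <- rep(params$kappa * (coherences - params$C0), each = n_per)
  C <- rep(coherences, each = n_per)
  out <- with_seed(seed, sim_bounded_paths(drift, rep(n_steps, length(drift)),
                                           bound, dt))
  cbind(C = C, out)
}

#' Simulate first-passage trials of the collapsing-bound model
#'
#' As [simulate_flat_ddm_trials()] but with time-dependent bounds
#' `+/- A(t)` from [bound_profile()]; the bridge correction uses the local
#' (linearized) bound within each step.
#'
#' @inheritParams simulate_flat_ddm_trials
#' @param params a [collapse_params()].
#' @param t_max horizon, s; defaults to the collapse time, by which all
#'   paths are absorbed.
#' @return as [simulate_flat_ddm_trials()].
#' @export
simulate_collapse_ddm_trials <- function(params, coherences, n_per,
                                         dt = 5e-4, seed = NULL,
                                         t_max = NULL) {
  stopifnot(inherits(params, "collapse_params"))
  t_max <- t_max %||% params$t_total
  n_steps <- as.integer(ceiling(t_max / dt))
  bound <- bound_profile(params, seq(0, by = dt, length.out = n_steps + 1L))
  drift <- rep(params$kappa * (coherences - params$C0), each = n_per)
  C <- rep(coherences, each = n_per)
  out <- with_seed(seed, sim_bounded_paths(drift, rep(n_steps, length(drift)),
                                           bound, dt))
  cbind(C = C, out)
}

# choice for trials that never crossed: accumulator sign; coin flip at zero
finalize_choice <- function(choice, terminated, x_final) {
  idx <- which(!terminated)
  if (length(idx)) {
    sgn <- sign(x_final[idx])
    flip <- sgn == 0
    if (any(flip)) sgn[flip] <- ifelse(runif(sum(flip)) < 0.5, 1, -1)
    choice[idx] <- as.integer(sgn > 0)
  }
  choice
}

# correct = choice congruent with sign(C); random assignment at C = 0
assign_correct <- function(C, choice) {
  correct <- as.integer((C > 0 & choice == 1L) | (C < 0 & choice == 0L))
  zero <- which(C == 0)
  if (length(zero)) correct[zero] <- rbinom(length(zero), 1L, 0.5)
  correct
}

empty_trials <- function() {
  data.frame(subject_id = character(), task = character(),
             trial_index = integer(), coh_signed = numeric(),
             duration = numeric(), delay = numeric(), choice = integer(),
             correct = integer(), t_sd = numeric(), rt = numeric(),
             left_home_early = logical(), over_clock = logical(),
             no_decision = logical(), forgot_clock = logical(),
             practice = logical())
}

#' Simulate a controlled-duration experiment
#'
#' Stimulus durations and post-stimulus delays are drawn independently from
#' \{0.2, 0.4, 0.6, 0.8\} s with probabilities \{0.125, 0.0625, 0.0625,
#' 0.75\}; direction is random with equal probability and magnitude uniform
#' over the configured coherence levels.  Evidence accumulates with
#' stimulus-driven drift while the dots are on and with zero drift
#' thereafter, until a bound crossing or the clock ceiling.  The reported
#' `t_sd` is the crossing time plus a gamma non-decision draw; reports past
#' the ceiling are flagged `over_clock`, non-terminating trials are flagged
#' `no_decision` (choice by accumulator sign, `t_sd` missing).
#'
#' @param truth a [ground_truth()].
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param subject_id label stored in the table.
#' @param dt simulation step, s.
#' @param coherence_levels magnitudes; defaults to the standard six levels.
#' @param n_practice number of initial trials flagged as practice.
#' @param decouple_tsd if `TRUE`, the simulated `t_sd` values are permuted
#'   across trials after generation, preserving their marginal distribution
#'   while severing the link to each trial's own termination (a clock
#'   strategy unrelated to decision termination).
#' @return a trial table (one row per trial) with the standard columns.
#' @export
simulate_controlled_duration_experiment <- function(truth, n_trials,
                                                    seed = NULL,
                                                    subject_id = "sim",
                                                    dt = 5e-4,
                                                    coherence_levels = NULL,
                                                    n_practice = 0L,
                                                    decouple_tsd = FALSE) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_trials == 0) return(empty_trials())
  stopifnot(n_trials > 0)
  clock_max <- truth$clock_max
  n_steps <- as.integer(ceiling(clock_max / dt))
  coherence_levels <- coherence_levels %||%
    c(0, 0.032, 0.064, 0.128, 0.256, 0.512)

  if (!is.null(truth$flat)) {
    p <- truth$flat
    kappa <- p$kappa; C0 <- p$C0
    bound <- rep(p$B, n_steps + 1L)
  } else {
    p <- truth$collapse
    kappa <- p$kappa; C0 <- p$C0
    bound <- bound_profile(p, seq(0, by = dt, length.out = n_steps + 1L))
  }

  with_seed(seed, {
    duration <- sample(CONTROLLED_DURATIONS, n_trials, replace = TRUE,
                       prob = CONTROLLED_DURATION_PROBS)
    delay <- sample(CONTROLLED_DURATIONS, n_trials, replace = TRUE,
                    prob = CONTROLLED_DURATION_PROBS)
    mag <- sample(coherence_levels, n_trials, replace = TRUE)
    dir <- ifelse(runif(n_trials) < 0.5, 1, -1)
    C <- mag * dir
    drift <- kappa * (C - C0)
    paths <- sim_bounded_paths(drift, as.integer(round(duration / dt)),
                               bound, dt)
    choice <- finalize_choice(paths$choice, paths$terminated, paths$x_final)
    correct <- assign_correct(C, choice)
    nd <- sample_nondecision(truth$nd_mean, truth$nd_sd, n_trials)
    t_sd <- ifelse(paths$terminated, paths$decision_time + nd, NA_real_)
    if (decouple_tsd) {
      obs <- which(!is.na(t_sd))
      t_sd[obs] <- t_sd[sample(obs)]
    }
    data.frame(subject_id = subject_id, task = "controlled",
               trial_index = seq_len(n_trials), coh_signed = C,
               duration = duration, delay = delay, choice = choice,
               correct = correct, t_sd = t_sd, rt = NA_real_,
               left_home_early = FALSE,
               over_clock = !is.na(t_sd) & t_sd > clock_max,
               no_decision = !paths$terminated, forgot_clock = FALSE,
               practice = seq_len(n_trials) <= n_practice)
  })
}

#' Simulate a free-response experiment
#'
#' The stimulus stays on until the accumulator crosses a bound; the reaction
#' time is the crossing time plus a gamma motor latency (optionally with
#' different means for left and right responses) and `t_sd` is the crossing
#' time plus an independent gamma clock latency.  Trials whose response
#' falls beyond the clock ceiling are flagged `over_clock`.
#'
#' @inheritParams simulate_controlled_duration_experiment
#' @return a trial table with `rt` populated.
#' @export
simulate_free_response_experiment <- function(truth, n_trials, seed = NULL,
                                              subject_id = "sim", dt = 5e-4,
                                              coherence_levels = NULL,
                                              n_practice = 0L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_trials == 0) return(empty_trials())
  clock_max <- truth$clock_max
  n_steps <- as.integer(ceiling(clock_max / dt))
  coherence_levels <- coherence_levels %||%
    c(0, 0.032, 0.064, 0.128, 0.256, 0.512)

  if (!is.null(truth$flat)) {
    p <- truth$flat
    kappa <- p$kappa; C0 <- p$C0
    bound <- rep(p$B, n_steps + 1L)
  } else {
    p <- truth$collapse
    kappa <- p$kappa; C0 <- p$C0
    bound <- bound_profile(p, seq(0, by = dt, length.out = n_steps + 1L))
  }
  mu_l <- truth$nd_mean_left %||% truth$nd_mean
  mu_r <- truth$nd_mean_right %||% truth$nd_mean

  with_seed(seed, {
    mag <- sample(coherence_levels, n_trials, replace = TRUE)
    dir <- ifelse(runif(n_trials) < 0.5, 1, -1)
    C <- mag * dir
    drift <- kappa * (C - C0)
    paths <- sim_bounded_paths(drift, rep(n_steps, n_trials), bound, dt)
    choice <- finalize_choice(paths$choice, paths$terminated, paths$x_final)
    correct <- assign_correct(C, choice)
    nd_motor <- ifelse(choice == 1L,
                       sample_nondecision(mu_r, truth$nd_sd, n_trials),
                       sample_nondecision(mu_l, truth$nd_sd, n_trials))
    nd_clock <- sample_nondecision(truth$nd_mean, truth$nd_sd, n_trials)
    rt <- ifelse(paths$terminated, paths$decision_time + nd_motor, NA_real_)
    t_sd <- ifelse(paths$terminated, paths$decision_time + nd_clock, NA_real_)
    data.frame(subject_id = subject_id, task = "free",
               trial_index = seq_len(n_trials), coh_signed = C,
               duration = ifelse(is.na(rt), clock_max, rt), delay = 0,
               choice = choice, correct = correct, t_sd = t_sd, rt = rt,
               left_home_early = FALSE,
               over_clock = !is.na(rt) & rt > clock_max,
               no_decision = !paths$terminated, forgot_clock = FALSE,
               practice = seq_len(n_trials) <= n_practice)
  })
}
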