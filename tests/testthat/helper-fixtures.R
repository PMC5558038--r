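# Shared fixtures: published flat-bound parameter sets for the
# controlled-duration task and small synthetic datasets built in code.

table1_params <- list(
  s1 = flat_params(40.4, 0.62, 0.007, 0.131),
  s2 = flat_params(35.7, 0.62, -0.053, 0.562),
  s3 = flat_params(19.2, 0.74, -0.001, 0.790),
  s4 = flat_params(24.3, 0.70, 0.018, 0.227),
  s5 = flat_params(24.6, 0.33, -0.050, 1.463))

signed_coherences <- c(-0.512, -0.256, -0.128, -0.064, -0.032, 0,
                       0.032, 0.064, 0.128, 0.256, 0.512)

# exact chronometric/choice summaries from a flat-bound parameter set
exact_summaries <- function(p, sem = 0.005, n_total = 300) {
  data.frame(C = signed_coherences, n = n_total,
             mean_tsd = mean_decision_time(p, signed_coherences),
             sem_tsd = sem,
             n_right = round(n_total *
                               choice_probability(p, signed_coherences)),
             n_total = n_total)
}

# trial table drawn from the collapsing-bound model itself (drift on
# throughout), with gamma non-decision added to the crossing times
collapse_model_trials <- function(p, n_per, seed, dt = 5e-4) {
  sim <- simulate_collapse_ddm_trials(p, signed_coherences, n_per,
                                      dt = dt, seed = seed)
  nd <- sample_nondecision(p$mu, p$sigma, nrow(sim), seed = seed + 1)
  data.frame(subject_id = "model", task = "controlled",
             trial_index = seq_len(nrow(sim)), coh_signed = sim$C,
             duration = 0.8, delay = 0.4,
             choice = ifelse(sim$terminated, sim$choice,
                             as.integer(sim$x_final > 0)),
             correct = 0L,
             t_sd = ifelse(sim$terminated, sim$decision_time + nd, NA_real_),
             rt = NA_real_, left_home_early = FALSE, over_clock = FALSE,
             no_decision = !sim$terminated, forgot_clock = FALSE,
             practice = FALSE)
}
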