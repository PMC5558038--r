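# End-to-end orchestration: simulate a cohort, apply exclusions, fit and
# predict, validate distributions, run the sensitivity and motion-energy
# analyses, and emit one JSON report.

#' Demonstration pipeline configuration
#'
#' A cohort of four "good" synthetic subjects whose reported times are the
#' termination times of their own accumulators (plus gamma latency), and
#' one decoupled subject whose clock reports are permuted across trials —
#' the in-silico analogue of a participant whose clock settings do not mark
#' decision termination.
#'
#' @param n_trials trials per subject.
#' @param seed master seed; per-subject and per-stage seeds derive from it.
#' @param out_dir optional directory for the JSON report and CSV artifacts.
#' @return a config list for [run_pipeline()].
#' @export
demo_config <- function(n_trials = 2000, seed = 1, out_dir = NULL) {
  subjects <- list(
    s1 = list(kappa = 40.4, B = 0.62, C0 = 0.007, decouple = FALSE),
    s2 = list(kappa = 35.7, B = 0.62, C0 = -0.053, decouple = FALSE),
    s3 = list(kappa = 19.2, B = 0.74, C0 = -0.001, decouple = FALSE),
    s4 = list(kappa = 24.3, B = 0.70, C0 = 0.018, decouple = FALSE),
    s5 = list(kappa = 24.6, B = 0.33, C0 = -0.050, decouple = TRUE))
  list(seed = seed, n_trials = n_trials, subjects = subjects,
       nd_mean = 0.131, nd_sd = 0.02, n_practice = 200,
       n_shuffles = 400, shuffle_starts = 5,
       stages = list(collapse = TRUE, jsd = TRUE, sensitivity = TRUE,
                     energy = TRUE),
       collapse = list(dt = 5e-3, dx_frac = 1 / 60, n_starts = 1,
                       subject = "s1"),
       energy = list(n_trials = 2766, n_boot = 500, delta = 0.133),
       jitter = list(n = 200),
       out_dir = out_dir)
}

required_config_keys <- c("seed", "n_trials", "subjects", "nd_mean", "nd_sd")

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the keys of [demo_config()].
#' @return a config list.
#' @export
read_pipeline_config <- function(path) {
  config <- yaml::read_yaml(path)
  missing <- setdiff(required_config_keys, names(config))
  if (length(missing)) {
    stop("config is missing required keys: ",
         paste(missing, collapse = ", "))
  }
  config
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> exclude -> chronometric fit -> choice prediction and
#' shuffle test -> collapsing-bound fit -> JSD with permutation null ->
#' surrogate sensitivity -> motion-energy leverage, honoring the seeds in
#' the config, and returns (and optionally writes) a structured report with
#' per-stage timings.
#'
#' @param config a list as produced by [demo_config()].
#' @return a report list (invisibly written to
#'   `file.path(out_dir, "report.json")` when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  missing <- setdiff(required_config_keys, names(config))
  if (length(missing)) {
    stop("config is missing required keys: ",
         paste(missing, collapse = ", "))
  }
  stages <- config$stages %||% list()
  report <- list(config_seed = config$seed, stages = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    list(value = v, elapsed = proc.time()[["elapsed"]] - t0)
  }

  # --- simulate + exclude + flat fit + shuffle, per subject -------------
  sim <- t_stage({
    subj <- list()
    for (i in seq_along(config$subjects)) {
      sc <- config$subjects[[i]]
      name <- names(config$subjects)[i]
      truth <- ground_truth(
        flat = flat_params(sc$kappa, sc$B, sc$C0, 0),
        nd_mean = config$nd_mean, nd_sd = config$nd_sd)
      tr <- simulate_controlled_duration_experiment(
        truth, config$n_trials + (config$n_practice %||% 0),
        seed = config$seed * 1000 + i, subject_id = name,
        n_practice = config$n_practice %||% 0,
        decouple_tsd = isTRUE(sc$decouple))
      ex <- apply_exclusions(tr)
      subj[[name]] <- list(truth = truth, trials = ex$trials,
                           exclusions = ex$report)
    }
    subj
  })
  subjects <- sim$value
  report$stages$simulate <- list(
    elapsed = sim$elapsed,
    n_retained = vapply(subjects, function(s) nrow(s$trials), numeric(1)))

  flat <- t_stage({
    lapply(seq_along(subjects), function(i) {
      s <- subjects[[i]]
      summ <- suppressWarnings(condition_summaries(s$trials))
      fit <- suppressWarnings(fit_mean_tsd(summ))
      sh <- suppressWarnings(shuffle_significance(
        summ, n_shuffles = config$n_shuffles %||% 400,
        seed = config$seed * 2000 + i,
        n_starts = config$shuffle_starts %||% 5))
      list(summaries = summ, fit = fit, shuffle = sh)
    })
  })
  names(flat$value) <- names(subjects)
  report$stages$flat_fit <- list(
    elapsed = flat$elapsed,
    shuffle_p = vapply(flat$value, function(f) f$shuffle$p_value, numeric(1)),
    params = lapply(flat$value, function(f)
      list(kappa = f$fit$kappa, B = f$fit$B, C0 = f$fit$C0,
           t_nd = f$fit$t_nd)))

  # --- collapsing-bound fit + JSD on one reference subject --------------
  if (isTRUE((stages$collapse %||% TRUE))) {
    cl <- t_stage({
      cfgc <- config$collapse %||% list()
      sname <- cfgc$subject %||% names(subjects)[1]
      tr <- subjects[[sname]]$trials
      ff <- flat$value[[sname]]$fit
      init <- collapse_params(kappa = ff$kappa, C0 = ff$C0,
                              A0 = ff$B, B_log = 0.5, t_beta = 0.5,
                              mu = config$nd_mean, sigma = max(config$nd_sd,
                                                               0.02))
      dt <- cfgc$dt %||% 5e-3
      dx <- init$A0 * (cfgc$dx_frac %||% (1 / 60))
      mle <- fit_collapse_mle(tr, init, mode = "tsd",
                              n_starts = cfgc$n_starts %||% 1,
                              dt = dt, dx = dx)
      list(subject = sname, mle = mle, dt = dt, dx = dx)
    })
    report$stages$collapse <- list(
      elapsed = cl$elapsed, subject = cl$value$subject,
      params = cl$value$mle[collapse_theta_names],
      loglik = attr(cl$value$mle, "loglik"))

    if (isTRUE(stages$jsd %||% TRUE)) {
      gj <- t_stage({
        tr <- subjects[[cl$value$subject]]$trials
        obs <- signed_tsd_histogram(tr)
        fitted <- model_tsd_histogram(cl$value$mle, tr, dt = cl$value$dt,
                                      dx = cl$value$dx)
        perm <- jsd_permutation_null(fitted, obs, n_perm = 200,
                                     seed = config$seed * 3000)
        list(jsd = perm$jsd_original, p = perm$p_value)
      })
      report$stages$jsd <- list(elapsed = gj$elapsed,
                                jsd = gj$value$jsd, p_value = gj$value$p)
    }
  }

  # --- surrogate sensitivity -------------------------------------------
  if (isTRUE(stages$sensitivity %||% TRUE)) {
    se <- t_stage({
      good <- names(subjects)[!vapply(config$subjects, function(s)
        isTRUE(s$decouple), logical(1))]
      ref <- good[1]
      summ <- flat$value[[ref]]$summaries
      sweep <- surrogate_sweep(summ)
      jit <- jitter_analysis(summ, n_jitter = config$jitter$n %||% 200,
                             seed = config$seed * 4000)
      comb <- cross_subject_combination_test(
        lapply(flat$value[good], `[[`, "fit"),
        lapply(flat$value[good], `[[`, "summaries"))
      list(sweep = sweep, jitter = jit, combination = comb)
    })
    report$stages$sensitivity <- list(
      elapsed = se$elapsed,
      loglr_best = max(se$value$sweep$loglr, na.rm = TRUE),
      jitter_slope = se$value$jitter$slope,
      jitter_slope_p = se$value$jitter$slope_p,
      combination_n = se$value$combination$n_combinations,
      combination_n_better = se$value$combination$n_better)
  }

  # --- motion-energy leverage ------------------------------------------
  if (isTRUE(stages$energy %||% TRUE)) {
    en <- t_stage({
      cfge <- config$energy %||% list()
      etr <- simulate_leverage_experiment(
        n_trials = cfge$n_trials %||% 600,
        t_nd = config$nd_mean, seed = config$seed * 5000)
      boot <- bootstrap_leverage_difference(
        etr, delta = cfge$delta %||% 0.133,
        n_boot = cfge$n_boot %||% 500, seed = config$seed * 5001)
      list(boot = boot)
    })
    report$stages$energy <- list(
      elapsed = en$elapsed,
      d_observed = en$value$boot$d_observed,
      p_value = en$value$boot$p_value,
      n_in = en$value$boot$n_in)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (name in names(subjects)) {
      write_trial_table(subjects[[name]]$trials,
                        file.path(config$out_dir,
                                  paste0("trials_", name, ".csv")))
    }
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Simulate a motion-energy reverse-correlation experiment
#'
#' Generates 800 ms weak-coherence movies, computes their half-movie
#' energies, draws a per-trial termination time, and produces choices from
#' a logistic in the stimulus energy accumulated up to that termination
#' time (each half-movie energy weighted by the fraction of that half
#' integrated before termination) plus nominal coherence.  This ties
#' choice to the stimulus exactly as a terminating accumulator would:
#' trials terminating near the midpoint give full leverage to the
#' pre-midpoint energy and none to the post-midpoint energy.
#'
#' @param n_trials number of trials.
#' @param config a [stimulus_config()].
#' @param weak_set coherence magnitudes used.
#' @param coef_energy logistic weight of the (standardized) used energy.
#' @param coef_coh logistic weight of signed coherence.
#' @param t_nd non-decision time added to termination to give `t_sd`.
#' @param seed integer seed.
#' @return trial table with `e_pre`, `e_post`, `t_theta` columns, ready for
#'   [leverage_regression()].
#' @export
simulate_leverage_experiment <- function(n_trials, config = stimulus_config(),
                                         weak_set = c(0, 0.032, 0.064),
                                         coef_energy = 3, coef_coh = 20,
                                         t_nd = 0.131, seed = NULL) {
  with_seed(seed, {
    mag <- sample(weak_set, n_trials, replace = TRUE)
    dir <- ifelse(runif(n_trials) < 0.5, 1, -1)
    C <- mag * dir
    t_theta <- runif(n_trials, 0.05, 0.79)
    e_pre <- numeric(n_trials)
    e_post <- numeric(n_trials)
    for (i in seq_len(n_trials)) {
      mv <- generate_rdm_movie(config, C[i], 0.8,
                               seed = sample.int(.Machine$integer.max, 1))
      en <- motion_energy_halves(mv)
      e_pre[i] <- en$e_pre
      e_post[i] <- en$e_post
    }
    zs <- sd(c(e_pre, e_post))
    # each half contributes in proportion to how much of it was integrated
    # before the accumulator terminated at t_theta
    w_pre <- pmax(pmin(t_theta / 0.4, 1), 0)
    w_post <- pmax(pmin((t_theta - 0.4) / 0.4, 1), 0)
    e_used <- (w_pre * e_pre + w_post * e_post) / zs
    p_right <- 1 / (1 + exp(-(coef_energy * e_used + coef_coh * C)))
    choice <- as.integer(runif(n_trials) < p_right)
    correct <- assign_correct(C, choice)
    tab <- data.frame(subject_id = "energy_sim", task = "controlled",
                      trial_index = seq_len(n_trials), coh_signed = C,
                      duration = 0.8, delay = 0.4, choice = choice,
                      correct = correct, t_sd = t_theta + t_nd, rt = NA_real_,
                      left_home_early = FALSE, over_clock = FALSE,
                      no_decision = FALSE, forgot_clock = FALSE,
                      practice = FALSE, e_pre = e_pre, e_post = e_post)
    compute_t_theta(tab, t_nd)
  })
}
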