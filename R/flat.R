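# Closed-form flat-bound drift-diffusion model: chronometric fit to mean
# subjective decision times, choice prediction, shuffle test, joint
# choice-RT fit.

#' Probability of a rightward choice under the flat-bound model
#'
#' `P(right | C) = 1 / (1 + exp(-2 kappa (C - C0) B))`: the splitting
#' probability of a drift-diffusion process between bounds at `+/- B`.
#'
#' @param p a [flat_params()].
#' @param C signed coherence (vectorized).
#' @return probabilities, monotone nondecreasing in `C`.
#' @export
choice_probability <- function(p, C) {
  stopifnot(inherits(p, "flat_params"))
  1 / (1 + exp(-2 * p$kappa * (C - p$C0) * p$B))
}

#' Mean reported decision time under the flat-bound model
#'
#' `t(C) = B / (kappa (C - C0)) * tanh(kappa (C - C0) B) + t_nd`, with the
#' removable singularity at `C = C0` evaluated analytically as `B^2 + t_nd`.
#' Even in `C - C0` and strictly decreasing in `|C - C0|`.
#'
#' @inheritParams choice_probability
#' @param t_nd optional override of the non-decision time in `p`.
#' @return mean times, s.
#' @export
mean_decision_time <- function(p, C, t_nd = NULL) {
  stopifnot(inherits(p, "flat_params"))
  t_nd <- t_nd %||% p$t_nd
  m <- p$kappa * (C - p$C0)
  tt <- ifelse(abs(m) < 1e-9,
               p$B^2 * (1 - (m * p$B)^2 / 3),  # series of B tanh(mB)/m
               (p$B / m) * tanh(m * p$B))
  tt + t_nd
}

# negative log-likelihood of condition means under Gaussian noise with the
# empirical SEMs, plus its analytic gradient; theta = (kappa, B, C0, t_nd)
flat_nll <- function(theta, C, y, sem) {
  p <- flat_params(theta[1], theta[2], theta[3], max(theta[4], 0))
  mu <- mean_decision_time(p, C)
  sum(0.5 * ((y - mu) / sem)^2 + log(sem) + 0.5 * log(2 * pi))
}

flat_nll_grad <- function(theta, C, y, sem) {
  kappa <- theta[1]; B <- theta[2]; C0 <- theta[3]
  m <- kappa * (C - C0)
  x <- m * B
  small <- abs(m) < 1e-6
  f <- ifelse(small, B^2 * (1 - x^2 / 3), (B / m) * tanh(x))
  sech2 <- 1 / cosh(x)^2
  df_dB <- ifelse(small, 2 * B, tanh(x) / m + B * sech2)
  df_dm <- ifelse(small, -2 / 3 * m * B^4,
                  -B * tanh(x) / m^2 + B^2 * sech2 / m)
  resid <- (f + theta[4] - y) / sem^2
  c(kappa = sum(resid * df_dm * (C - C0)),
    B = sum(resid * df_dB),
    C0 = sum(resid * df_dm * (-kappa)),
    t_nd = sum(resid))
}

#' Per-coherence summaries of a trial table
#'
#' Fits a two-parameter logistic (intercept + slope on coherence) to choice
#' by maximum likelihood to locate the point of subjective equality (PSE),
#' then, per signed coherence, computes the mean and SEM of `t_sd` over
#' congruent-direction trials only (rightward choices where the fitted
#' `P(right) > 0.5`, leftward otherwise) and choice counts over all trials.
#' A weak ridge penalty keeps the logistic finite under complete separation.
#'
#' @param trials trial table (exclusions already applied).
#' @param ridge ridge penalty on the logistic coefficients.
#' @return data.frame of class `condition_summaries` with columns `C`, `n`,
#'   `mean_tsd`, `sem_tsd`, `n_right`, `n_total`; the PSE is attached as
#'   attribute `pse`.
#' @export
condition_summaries <- function(trials, ridge = 1e-4) {
  stopifnot(all(c("coh_signed", "choice", "t_sd") %in% names(trials)))
  co <- fit_logistic_ridge(trials$coh_signed, trials$choice, ridge)
  pse <- -co[1] / co[2]

  out <- lapply(sort(unique(trials$coh_signed)), function(cc) {
    sub <- trials[trials$coh_signed == cc, ]
    p_right <- 1 / (1 + exp(-(co[1] + co[2] * cc)))
    congruent <- sub[sub$choice == as.integer(p_right > 0.5), ]
    tsd <- congruent$t_sd[!is.na(congruent$t_sd)]
    if (length(tsd) < 2) {
      warning(sprintf("coherence %g dropped: fewer than 2 congruent trials",
                      cc))
      return(NULL)
    }
    data.frame(C = cc, n = length(tsd), mean_tsd = mean(tsd),
               sem_tsd = sd(tsd) / sqrt(length(tsd)),
               n_right = sum(sub$choice == 1L), n_total = nrow(sub))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  attr(out, "pse") <- pse
  class(out) <- c("condition_summaries", "data.frame")
  out
}

# ML logistic fit with a weak ridge penalty (survives separation); returns
# c(intercept, slope).  glm's IRLS result is used when it is finite and
# converged, otherwise a penalized direct optimization.
fit_logistic_ridge <- function(x, y, ridge = 1e-4) {
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  co <- coef(fit)
  if (fit$converged && all(is.finite(co)) && max(abs(co)) < 1e3 &&
      ridge == 0) {
    return(unname(co))
  }
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    sum(log1p(exp(-(2 * y - 1) * eta))) + ridge * sum(b^2)
  }
  st <- co
  st[!is.finite(st)] <- 0
  st <- pmin(pmax(st, -50), 50)
  opt <- optim(st, nll, method = "BFGS")
  unname(opt$par)
}

#' Fit the chronometric function to per-coherence mean times
#'
#' Maximizes the Gaussian log likelihood of the observed mean `t_sd` per
#' signed coherence under the flat-bound expression, weighting each
#' condition by its empirical SEM.  Optimization is quasi-Newton (L-BFGS-B)
#' with analytic gradients, box constraints (`B > 0`, `t_nd >= 0`,
#' `|C0| <= 0.512`, `kappa > 0`) and multi-start from deterministic
#' perturbations of a moment-based initialization; standard errors come from
#' the inverse numerical Hessian at the optimum.
#'
#' @param summaries a [condition_summaries()] table (>= 4 conditions).
#' @param n_starts number of perturbed initializations.
#' @return a [flat_params()] with `se` filled in and attributes `loglik` and
#'   `convergence`; `kappa` estimates at the lower box bound are flagged
#'   with a warning (no chronometric signal).
#' @export
fit_mean_tsd <- function(summaries, n_starts = 10) {
  stopifnot(all(c("C", "mean_tsd", "sem_tsd") %in% names(summaries)))
  summaries <- summaries[summaries$n %||% 2 > 1, , drop = FALSE]
  if (nrow(summaries) < 4) {
    stop("need at least 4 coherence conditions to fit 4 free parameters")
  }
  C <- summaries$C; y <- summaries$mean_tsd; sem <- summaries$sem_tsd

  # moment-based start: range of y sets B^2, weak-vs-strong contrast sets kappa
  t_min <- min(y); t_max <- max(y)
  B0 <- sqrt(max(t_max - t_min, 0.02))
  k0 <- 2 / (B0 * max(abs(C)))
  starts <- list(c(k0, B0, 0, max(t_min - B0^2 / 2, 0.01)))
  fac <- c(0.3, 0.6, 1.5, 3, 6, 0.15, 10, 1, 2)
  for (i in seq_len(n_starts - 1)) {
    f <- fac[(i - 1) %% length(fac) + 1]
    starts[[i + 1]] <- c(k0 * f, B0 * (1 + 0.2 * ((i %% 3) - 1)),
                         0.02 * ((i %% 5) - 2),
                         max(t_min * (0.5 + 0.1 * (i %% 4)), 0.01))
  }

  lower <- c(1e-3, 1e-3, -0.512, 0)
  upper <- c(1e4, 10, 0.512, 5)
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    opt <- tryCatch(
      optim(st, flat_nll, gr = flat_nll_grad, C = C, y = y, sem = sem,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) {
    stop("chronometric fit failed to converge from all starts; ",
         "check that the condition means and SEMs are finite")
  }
  th <- best$par
  if (th[1] <= lower[1] * 1.01) {
    warning("kappa at its lower bound: means are coherence-independent ",
            "(no chronometric signal)")
  }
  H <- tryCatch(optimHess(th, flat_nll, gr = flat_nll_grad, C = C, y = y,
                          sem = sem),
                error = function(e) NULL)
  se <- rep(NA_real_, 4)
  if (!is.null(H)) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  }
  out <- flat_params(th[1], th[2], th[3], th[4],
                     se = setNames(se, c("kappa", "B", "C0", "t_nd")))
  attr(out, "loglik") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Predict the choice function and score it against observed choices
#'
#' Evaluates the rightward-choice probability at each condition from
#' parameters fit to the mean times alone (no choice data enters the
#' prediction) and returns the binomial log likelihood of the observed
#' choice counts under that prediction.
#'
#' @param p a [flat_params()].
#' @param summaries a [condition_summaries()] table with `n_right`,
#'   `n_total`.
#' @return list with `prediction` (data.frame of `C`, `p_right`) and
#'   `loglik` (total binomial log likelihood; 0 for an empty table).
#' @export
predict_choice_and_loglik <- function(p, summaries) {
  if (is.null(summaries) || nrow(summaries) == 0) {
    return(list(prediction = data.frame(C = numeric(), p_right = numeric()),
                loglik = 0))
  }
  pr <- choice_probability(p, summaries$C)
  ll <- sum(dbinom(summaries$n_right, summaries$n_total, pr, log = TRUE))
  list(prediction = data.frame(C = summaries$C, p_right = pr), loglik = ll)
}

#' Shuffle test of the choice prediction
#'
#' Permutes the (mean, SEM) pairs across signed coherences, refits the
#' chronometric function to each shuffled dataset, and recomputes the
#' binomial log likelihood of the observed choices under the resulting
#' prediction.  The p-value is the proportion of datasets (shuffled plus
#' original) whose log likelihood is at least that of the original.
#'
#' @param summaries a [condition_summaries()] table.
#' @param n_shuffles number of shuffled datasets (400 in the standard
#'   analysis).
#' @param seed integer seed.
#' @param n_starts multi-start count passed to the refits.
#' @return list with `p_value`, `loglik_original` and the vector
#'   `loglik_shuffled`.
#' @export
shuffle_significance <- function(summaries, n_shuffles = 400, seed = NULL,
                                 n_starts = 5) {
  fit0 <- fit_mean_tsd(summaries, n_starts = n_starts)
  ll0 <- predict_choice_and_loglik(fit0, summaries)$loglik
  if (n_shuffles == 0) {
    return(list(p_value = 1, loglik_original = ll0,
                loglik_shuffled = numeric()))
  }
  lls <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    sh <- summaries
    idx <- sample(nrow(sh))
    sh$mean_tsd <- sh$mean_tsd[idx]
    sh$sem_tsd <- sh$sem_tsd[idx]
    fit <- tryCatch(suppressWarnings(fit_mean_tsd(sh, n_starts = n_starts)),
                    error = function(e) NULL)
    if (is.null(fit)) return(-Inf)
    predict_choice_and_loglik(fit, summaries)$loglik
  }, numeric(1)))
  p <- (sum(lls >= ll0) + 1) / (n_shuffles + 1)
  list(p_value = p, loglik_original = ll0, loglik_shuffled = lls)
}

#' Joint fit of choice and mean reaction time (free-response task)
#'
#' Maximizes a composite log likelihood: a Gaussian term for the
#' per-coherence mean RT of congruent-direction trials (weighted by the
#' empirical SEMs) plus a binomial term for the choice counts.  Separate
#' left/right non-decision times absorb different motor latencies; `kappa`
#' can optionally be fixed (e.g. to the value fitted from `t_sd` in the
#' controlled-duration task).
#'
#' @param trials free-response trial table (must contain `rt`).
#' @param fix_kappa optional fixed value for `kappa`.
#' @param n_starts multi-start count.
#' @param ridge ridge for the PSE logistic.
#' @return a [flat_params()] with `t_nd_left`/`t_nd_right`, `se` and
#'   attribute `loglik`.
#' @export
fit_joint_choice_rt <- function(trials, fix_kappa = NULL, n_starts = 10,
                                ridge = 1e-4) {
  stopifnot("rt" %in% names(trials))
  trials <- trials[!is.na(trials$rt), ]
  co <- fit_logistic_ridge(trials$coh_signed, trials$choice, ridge)
  conds <- sort(unique(trials$coh_signed))

  summ <- do.call(rbind, lapply(conds, function(cc) {
    sub <- trials[trials$coh_signed == cc, ]
    p_right <- 1 / (1 + exp(-(co[1] + co[2] * cc)))
    side <- as.integer(p_right > 0.5)
    congruent <- sub[sub$choice == side, ]
    if (nrow(congruent) < 2) return(NULL)
    data.frame(C = cc, side = side, mean_rt = mean(congruent$rt),
               sem_rt = sd(congruent$rt) / sqrt(nrow(congruent)),
               n_right = sum(sub$choice == 1L), n_total = nrow(sub))
  }))
  if (is.null(summ) || nrow(summ) < 4) stop("too few conditions for the joint fit")

  nll <- function(th) {
    kappa <- if (is.null(fix_kappa)) th[1] else fix_kappa
    B <- th[2]; C0 <- th[3]; tl <- th[4]; tr <- th[5]
    p <- flat_params(kappa, B, C0, 0)
    mu <- mean_decision_time(p, summ$C) +
      ifelse(summ$side == 1L, tr, tl)
    pr <- choice_probability(p, summ$C)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    sum(0.5 * ((summ$mean_rt - mu) / summ$sem_rt)^2) -
      sum(dbinom(summ$n_right, summ$n_total, pr, log = TRUE))
  }

  t_min <- min(summ$mean_rt)
  B0 <- sqrt(max(max(summ$mean_rt) - t_min, 0.05))
  k0 <- if (is.null(fix_kappa)) 2 / (B0 * max(abs(summ$C))) else fix_kappa
  lower <- c(1e-3, 1e-3, -0.512, 0, 0)
  upper <- c(1e4, 10, 0.512, 5, 5)
  best <- NULL
  fac <- c(1, 0.3, 3, 0.6, 1.5, 6, 0.15, 10, 2, 0.08)
  for (i in seq_len(n_starts)) {
    st <- c(k0 * fac[(i - 1) %% length(fac) + 1], B0 * (1 + 0.2 * (i %% 3 - 1)),
            0, max(t_min - B0^2 / 2, 0.01) * (0.6 + 0.2 * (i %% 3)),
            max(t_min - B0^2 / 2, 0.01) * (0.6 + 0.2 * ((i + 1) %% 3)))
    st <- pmin(pmax(st, lower), upper)
    opt <- tryCatch(optim(st, nll, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("joint choice-RT fit failed to converge")
  th <- best$par
  if (!is.null(fix_kappa)) th[1] <- fix_kappa
  H <- tryCatch(optimHess(best$par, nll), error = function(e) NULL)
  se <- rep(NA_real_, 5)
  if (!is.null(H)) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  }
  out <- flat_params(th[1], th[2], th[3], t_nd = mean(th[4:5]),
                     t_nd_left = th[4], t_nd_right = th[5],
                     se = setNames(se, c("kappa", "B", "C0", "t_nd_left",
                                         "t_nd_right")))
  attr(out, "loglik") <- -best$value
  out
}
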