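# Collapsing-bound drift-diffusion model: beta-profile bounds, numerical
# first-passage densities, gamma non-decision convolution, per-trial
# likelihood, MLE, adaptive Metropolis posterior, and the correct/error
# regression of reported times.

#' Collapsing bound profile
#'
#' `A(t) = A0 * (1 - I_{t/t_total}(beta1, beta2))` where `I` is the
#' regularized incomplete beta function; `A(0) = A0` and the bound reaches
#' zero at `t_total` (the clock ceiling, 2.7 s).
#'
#' @param p a [collapse_params()].
#' @param t times, s (vectorized).
#' @return bound heights at `t`.
#' @export
bound_profile <- function(p, t) {
  stopifnot(inherits(p, "collapse_params"))
  b <- collapse_betas(p)
  tp <- pmin(pmax(t / p$t_total, 0), 1)
  p$A0 * (1 - pbeta(tp, b["beta1"], b["beta2"]))
}

#' First-passage-time density under collapsing bounds
#'
#' Propagates the transition density of a constant-drift, unit-variance
#' diffusion on a space-time grid with absorption at `+/- A(t)`
#' (Crank-Nicolson in time, centered in space, with implicit start-up
#' smoothing for the initial point mass).  Absorbed flux per step
#' accumulates into choice-conditional densities; total mass (absorbed plus
#' surviving) is conserved.
#'
#' @param p a [collapse_params()].
#' @param C signed coherence (drift is `kappa * (C - C0)`).
#' @param dt time step, s.
#' @param dx space step; defaults to `A0 / 150`.
#' @param t_max grid horizon, s (defaults to the collapse time).
#' @param mass_tol maximum tolerated mass defect before an error advising a
#'   finer grid.
#' @return an object of class `fpt_density`: list with `time` (bin
#'   centers), `dt`, `density_right`, `density_left` (s^-1), `p_right`,
#'   `p_left`, `survival`.
#' @export
fpt_density <- function(p, C, dt = 1e-3, dx = NULL, t_max = NULL,
                        mass_tol = 1e-4) {
  stopifnot(inherits(p, "collapse_params"))
  dx <- dx %||% (p$A0 / 150)
  t_max <- t_max %||% p$t_total
  n_steps <- as.integer(round(t_max / dt))
  edges <- seq(0, by = dt, length.out = n_steps + 1L)
  bound <- bound_profile(p, edges)
  drift <- p$kappa * (C - p$C0)
  res <- cpp_fpt_density(drift, bound, dt, dx, p$A0, n_steps)
  total <- res$p_right + res$p_left + res$survival
  if (abs(total - 1) > mass_tol) {
    stop(sprintf(paste("mass defect %.2e exceeds tolerance %.0e;",
                       "refine the grid (smaller dt and/or dx)"),
                 abs(total - 1), mass_tol))
  }
  structure(list(time = edges[-1] - dt / 2, dt = dt,
                 density_right = res$density_right,
                 density_left = res$density_left,
                 p_right = res$p_right, p_left = res$p_left,
                 survival = res$survival),
            class = "fpt_density")
}

#' Convolve a first-passage density with the gamma non-decision time
#'
#' Discretizes the gamma(mu, sigma) latency as per-bin masses (differences
#' of the distribution function at the bin edges) and convolves each
#' choice-conditional density with it on the same time grid.  Mass shifted
#' beyond the grid end is reported in `tail_mass`; total mass is preserved.
#'
#' @param f an [fpt_density()].
#' @param mu,sigma gamma mean and sd, s.
#' @return an `fpt_density` with an extra `tail_mass` element.
#' @export
convolve_nondecision <- function(f, mu, sigma) {
  stopifnot(inherits(f, "fpt_density"))
  n <- length(f$time)
  dt <- f$dt
  edges <- seq(0, by = dt, length.out = n + 1L)
  if (sigma <= 0) {
    shift <- as.integer(round(mu / dt))
    w <- numeric(n)
    if (shift < n) w[shift + 1L] <- 1
  } else {
    shape <- (mu / sigma)^2
    scale <- sigma^2 / mu
    # w[k]: latency mass in bin k; the beyond-grid tail stays un-assigned
    # here and is reported via tail_mass below
    w <- diff(pgamma(edges, shape = shape, scale = scale))
  }
  conv_one <- function(d) {
    mass <- d * dt
    full <- stats::convolve(mass, rev(w), type = "open")  # FFT-based
    pmax(full[seq_len(n)], 0) / dt
  }
  dr <- conv_one(f$density_right)
  dl <- conv_one(f$density_left)
  tail_mass <- (f$p_right + f$p_left) - sum(dr + dl) * dt
  structure(list(time = f$time, dt = dt, density_right = dr,
                 density_left = dl,
                 p_right = sum(dr) * dt, p_left = sum(dl) * dt,
                 survival = f$survival, tail_mass = tail_mass),
            class = "fpt_density")
}

# linear interpolation of a choice-conditional density at observed times
# (vectorized over trials of one coherence)
interp_density <- function(f, choice, t, floor = 1e-10) {
  out <- numeric(length(t))
  for (ch in c(0L, 1L)) {
    idx <- which(choice == ch)
    if (!length(idx)) next
    d <- if (ch == 1L) f$density_right else f$density_left
    out[idx] <- approx(f$time, d, xout = t[idx], rule = 2)$y
  }
  pmax(out, floor)
}

#' Log likelihood of observed (choice, time) pairs
#'
#' For each trial, the convolved choice-conditional density is evaluated at
#' the trial's reported time (`t_sd` or `rt`) by linear interpolation on the
#' grid, floored at 1e-10 s^-1.  Trials with a missing time (no reported
#' decision) contribute the surviving mass split evenly by choice.
#' Densities are cached per unique signed coherence.
#'
#' @param p a [collapse_params()].
#' @param trials trial table.
#' @param mode `"tsd"` (use `t_sd`) or `"rt"` (use `rt`, with side-specific
#'   non-decision means when `mu_left`/`mu_right` are set).
#' @param dt,dx grid resolution passed to [fpt_density()].
#' @return total log likelihood (0 for an empty table).
#' @export
dataset_loglik <- function(p, trials, mode = c("tsd", "rt"),
                           dt = 1e-3, dx = NULL) {
  mode <- match.arg(mode)
  if (nrow(trials) == 0) return(0)
  tcol <- if (mode == "tsd") trials$t_sd else trials$rt
  # the bound profile is shared by every coherence; compute it once
  dx <- dx %||% (p$A0 / 150)
  t_max <- p$t_total
  n_steps <- as.integer(round(t_max / dt))
  edges <- seq(0, by = dt, length.out = n_steps + 1L)
  bound <- bound_profile(p, edges)
  tgrid <- edges[-1] - dt / 2
  ll <- 0
  for (cc in unique(trials$coh_signed)) {
    idx <- trials$coh_signed == cc
    res <- cpp_fpt_density(p$kappa * (cc - p$C0), bound, dt, dx, p$A0,
                           n_steps)
    f0 <- structure(list(time = tgrid, dt = dt,
                         density_right = res$density_right,
                         density_left = res$density_left,
                         p_right = res$p_right, p_left = res$p_left,
                         survival = res$survival),
                    class = "fpt_density")
    if (mode == "rt" && !is.null(p$mu_left)) {
      fr <- convolve_nondecision(f0, p$mu_right %||% p$mu, p$sigma)
      fl <- convolve_nondecision(f0, p$mu_left, p$sigma)
      f <- fr
      f$density_left <- fl$density_left
    } else {
      f <- convolve_nondecision(f0, p$mu, p$sigma)
    }
    ti <- tcol[idx]
    chi <- trials$choice[idx]
    obs <- !is.na(ti)
    if (any(!obs)) {
      ll <- ll + sum(!obs) * log(max(f$survival / 2, 1e-10))
    }
    if (any(obs)) {
      ll <- ll + sum(log(interp_density(f, chi[obs], ti[obs])))
    }
  }
  ll
}

# parameter vector <-> collapse_params; shared by MLE and Metropolis
collapse_theta_names <- c("kappa", "C0", "A0", "B_log", "t_beta", "mu",
                          "sigma")

theta_to_collapse <- function(th, template = NULL) {
  collapse_params(kappa = th[1], C0 = th[2], A0 = th[3], B_log = th[4],
                  t_beta = th[5], mu = th[6], sigma = th[7],
                  mu_left = if (length(th) > 7) th[8] else NULL,
                  mu_right = if (length(th) > 7) th[6] else NULL,
                  t_total = if (is.null(template)) 2.7 else template$t_total)
}

collapse_lower <- c(0.5, -0.512, 0.05, -2, 0.02, 0.02, 1e-3)
collapse_upper <- c(200, 0.512, 5, 4, 0.98, 2, 0.8)

#' Maximum-likelihood fit of the collapsing-bound model
#'
#' Maximizes [dataset_loglik()] over (kappa, C0, A0, B_log, t_beta, mu,
#' sigma) by box-constrained quasi-Newton search with finite-difference
#' gradients and multi-start; `mode = "rt"` adds a separate left-side
#' non-decision mean (sigma shared).
#'
#' @param trials trial table with `t_sd` (or `rt`).
#' @param init a [collapse_params()] initialization.
#' @param mode `"tsd"` or `"rt"`.
#' @param n_starts number of perturbed starts.
#' @param dt,dx likelihood grid resolution.
#' @return a [collapse_params()] with attributes `loglik` and
#'   `convergence`.
#' @export
fit_collapse_mle <- function(trials, init, mode = c("tsd", "rt"),
                             n_starts = 3, dt = 2e-3, dx = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(init, "collapse_params"))
  tcol <- if (mode == "tsd") trials$t_sd else trials$rt
  if (all(is.na(tcol))) stop("all observed times are missing")

  use_sides <- mode == "rt" && !is.null(init$mu_left)
  th0 <- c(init$kappa, init$C0, init$A0, init$B_log, init$t_beta, init$mu,
           init$sigma)
  lower <- collapse_lower
  upper <- collapse_upper
  if (use_sides) {
    th0 <- c(th0, init$mu_left)
    lower <- c(lower, 0.02)
    upper <- c(upper, 2)
  }

  nll <- function(th) {
    p <- tryCatch(theta_to_collapse(th, init), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    v <- tryCatch(dataset_loglik(p, trials, mode, dt = dt, dx = dx),
                  error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else -v
  }

  fac <- c(1, 0.8, 1.25, 0.6, 1.6)
  best <- NULL
  for (i in seq_len(n_starts)) {
    st <- pmin(pmax(th0 * fac[(i - 1) %% length(fac) + 1], lower), upper)
    opt <- tryCatch(
      optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 200, factr = 1e7,
                           parscale = pmax(abs(th0), 0.05))),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best) || best$value >= 1e10) {
    stop("collapsing-bound MLE failed to converge; last trace value: ",
         if (is.null(best)) "none" else format(best$value))
  }
  out <- theta_to_collapse(best$par, init)
  attr(out, "loglik") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

# split-chain R-hat: between/within variance ratio on 2*n_chains half-chains
split_rhat <- function(draws) {
  # draws: iterations x chains matrix for one parameter
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[seq_len(half) + (n - half), , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Metropolis posterior sampling for the collapsing-bound model
#'
#' Random-walk Metropolis with a multivariate-normal proposal whose
#' covariance is adapted every 100 steps from up to 1000 trailing samples
#' during burn-in only (kept samples preserve detailed balance).  Chains
#' start in the neighborhood of the supplied mode.  Convergence is assessed
#' by the split-chain between/within variance ratio; the posterior standard
#' deviation is reported as the parameter standard error.
#'
#' @param trials trial table.
#' @param mle a [collapse_params()] mode (e.g. from [fit_collapse_mle()]).
#' @param mode `"tsd"` or `"rt"`.
#' @param n_chains,n_burn,n_keep chain configuration (defaults follow the
#'   standard analysis: 12 chains, 5000 + 5000).
#' @param seed integer seed.
#' @param dt,dx likelihood grid resolution.
#' @param init_scale relative jitter of the chain initializations.
#' @return list with `samples` (kept draws, iterations x chains x
#'   parameters), `rhat`, `posterior_sd`, `posterior_mean`,
#'   `acceptance_rate`, and `converged` (all `rhat < 1.1`); a warning is
#'   emitted when any `rhat >= 1.1`.
#' @export
metropolis_posterior <- function(trials, mle, mode = c("tsd", "rt"),
                                 n_chains = 12, n_burn = 5000, n_keep = 5000,
                                 seed = NULL, dt = 2e-3, dx = NULL,
                                 init_scale = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(mle, "collapse_params"))
  th0 <- c(mle$kappa, mle$C0, mle$A0, mle$B_log, mle$t_beta, mle$mu,
           mle$sigma)
  d <- length(th0)
  lower <- collapse_lower
  upper <- collapse_upper
  if (init_scale <= 0) stop("init_scale must be positive (degenerate chains)")

  logpost <- function(th) {
    if (any(th < lower) || any(th > upper)) return(-Inf)
    p <- tryCatch(theta_to_collapse(th, mle), error = function(e) NULL)
    if (is.null(p)) return(-Inf)
    v <- tryCatch(dataset_loglik(p, trials, mode, dt = dt, dx = dx),
                  error = function(e) -Inf)
    if (!is.finite(v)) -Inf else v
  }

  n_tot <- n_burn + n_keep
  samples <- array(NA_real_, dim = c(n_keep, n_chains, d),
                   dimnames = list(NULL, NULL, collapse_theta_names))
  acc_all <- 0
  with_seed(seed, {
    for (ch in seq_len(n_chains)) {
      th <- pmin(pmax(th0 * (1 + init_scale * rnorm(d)), lower), upper)
      lp <- logpost(th)
      if (!is.finite(lp)) { th <- th0; lp <- logpost(th) }
      prop_cov <- diag((pmax(abs(th0), 0.05) * 0.05)^2)
      cholP <- chol(prop_cov)
      hist <- matrix(NA_real_, n_tot, d)
      n_acc <- 0
      for (it in seq_len(n_tot)) {
        z <- drop(rnorm(d) %*% cholP) * (2.38 / sqrt(d))
        cand <- th + z
        lpc <- logpost(cand)
        if (is.finite(lpc) && log(runif(1)) < lpc - lp) {
          th <- cand; lp <- lpc; n_acc <- n_acc + 1
        }
        hist[it, ] <- th
        if (it <= n_burn && it %% 100 == 0 && it >= 200) {
          win <- hist[max(1, it - 999):it, , drop = FALSE]
          cv <- var(win)
          cv <- cv + diag(1e-10, d)
          ch_try <- tryCatch(chol(cv), error = function(e) NULL)
          if (!is.null(ch_try)) cholP <- ch_try
        }
        if (it > n_burn) samples[it - n_burn, ch, ] <- th
      }
      acc_all <- acc_all + n_acc / n_tot
    }
  })

  rhat <- vapply(seq_len(d), function(j) split_rhat(samples[, , j]),
                 numeric(1))
  names(rhat) <- collapse_theta_names
  flat <- matrix(samples, ncol = d)
  post_sd <- apply(flat, 2, sd)
  post_mean <- colMeans(flat)
  names(post_sd) <- names(post_mean) <- collapse_theta_names
  converged <- all(is.finite(rhat)) && all(rhat < 1.1, na.rm = TRUE)
  if (!converged) {
    warning("Metropolis chains not converged: max R-hat = ",
            format(max(rhat, na.rm = TRUE), digits = 3))
  }
  list(samples = samples, rhat = rhat, posterior_sd = post_sd,
       posterior_mean = post_mean, acceptance_rate = acc_all / n_chains,
       converged = converged)
}

#' Correct/error regression of reported decision times
#'
#' Ordinary least squares of `t_sd` on an intercept, `|C - C0|` and an
#' error indicator (0 correct, 1 incorrect), restricted to coherences with
#' at least one error; a positive indicator coefficient means slower
#' reports on errors.  Two-sided t-test of the indicator coefficient.
#'
#' @param trials trial table with `t_sd` and `correct`.
#' @param C0 coherence offset used to form `|C - C0|`.
#' @return list with `k1`, `k2`, `k3`, `se`, `p_value` (for `k3`), and
#'   `n` (trials entering the regression).
#' @export
error_tsd_regression <- function(trials, C0 = 0) {
  tr <- trials[!is.na(trials$t_sd), ]
  has_err <- tapply(tr$correct == 0L, tr$coh_signed, any)
  keep <- names(has_err)[has_err]
  tr <- tr[as.character(tr$coh_signed) %in% keep, ]
  if (nrow(tr) < 4) stop("too few trials at coherences with errors")
  absC <- abs(tr$coh_signed - C0)
  I <- as.integer(tr$correct == 0L)
  fit <- lm(tr$t_sd ~ absC + I)
  sm <- summary(fit)$coefficients
  list(k1 = unname(sm[1, 1]), k2 = unname(sm[2, 1]), k3 = unname(sm[3, 1]),
       se = unname(sm[, 2]), p_value = unname(sm[3, 4]), n = nrow(tr))
}
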