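#' Parameters of the flat-bound (parsimonious) drift-diffusion model
#'
#' The model accumulates momentary evidence with mean `kappa * (C - C0)` per
#' second and unit variance per second until the running sum reaches `+B`
#' (rightward choice) or `-B` (leftward).  The reported time exceeds the
#' crossing time by a non-decision latency `t_nd`; free-response fits may use
#' separate left/right latencies to absorb different motor delays.
#'
#' @param kappa signal-to-noise scaling of coherence (drift = `kappa*(C-C0)`).
#' @param B bound height (> 0), in accumulated-evidence units.
#' @param C0 coherence offset capturing a left/right bias.
#' @param t_nd non-decision time in seconds (>= 0).
#' @param t_nd_left,t_nd_right optional side-specific non-decision times used
#'   when fitting reaction times jointly with choice.
#' @param se optional named numeric vector of standard errors.
#' @return an object of class `flat_params`.
#' @export
flat_params <- function(kappa, B, C0 = 0, t_nd = 0,
                        t_nd_left = NULL, t_nd_right = NULL, se = NULL) {
  stop_if_not_scalar(kappa, "kappa")
  stop_if_not_scalar(B, "B", positive = TRUE)
  stop_if_not_scalar(C0, "C0")
  stop_if_not_scalar(t_nd, "t_nd")
  if (t_nd < 0) stop("`t_nd` must be >= 0")
  structure(list(kappa = kappa, B = B, C0 = C0, t_nd = t_nd,
                 t_nd_left = t_nd_left, t_nd_right = t_nd_right, se = se),
            class = "flat_params")
}

#' @export
print.flat_params <- function(x, ...) {
  cat("Flat-bound DDM parameters\n")
  v <- c(kappa = x$kappa, B = x$B, C0 = x$C0, t_nd = x$t_nd)
  if (!is.null(x$t_nd_left)) v <- c(v, t_nd_left = x$t_nd_left,
                                    t_nd_right = x$t_nd_right)
  print(round(v, 4))
  if (!is.null(x$se)) {
    cat("SE:\n"); print(round(unlist(x$se), 4))
  }
  invisible(x)
}

#' Parameters of the collapsing-bound drift-diffusion model
#'
#' Bounds start at `+/- A0` and collapse to zero at the clock ceiling
#' (2.7 s) following a regularized incomplete beta profile; the collapse
#' shape is parameterized by `B_log = log10(beta1*beta2)` (steepness) and
#' `t_beta = beta1/(beta1+beta2)` (normalized time of steepest descent).
#' Non-decision time is gamma distributed with mean `mu` and sd `sigma`;
#' reaction-time fitting may use side-specific means `mu_left`/`mu_right`.
#'
#' @param kappa,C0 as in [flat_params()].
#' @param A0 initial half-bound (> 0).
#' @param B_log `log10(beta1 * beta2)` of the beta collapse profile.
#' @param t_beta `beta1 / (beta1 + beta2)`, in (0, 1).
#' @param mu,sigma mean and sd (seconds) of the gamma non-decision time.
#' @param mu_left,mu_right optional side-specific non-decision means.
#' @param t_total time at which the collapse completes (clock ceiling), s.
#' @return an object of class `collapse_params`.
#' @export
collapse_params <- function(kappa, C0 = 0, A0, B_log = 0, t_beta = 0.5,
                            mu = 0.3, sigma = 0.05,
                            mu_left = NULL, mu_right = NULL, t_total = 2.7) {
  stop_if_not_scalar(kappa, "kappa")
  stop_if_not_scalar(A0, "A0", positive = TRUE)
  stop_if_not_scalar(B_log, "B_log")
  stop_if_not_scalar(t_beta, "t_beta")
  if (t_beta <= 0 || t_beta >= 1) stop("`t_beta` must be in (0, 1)")
  stop_if_not_scalar(mu, "mu", positive = TRUE)
  stop_if_not_scalar(sigma, "sigma")
  if (sigma < 0) stop("`sigma` must be >= 0")
  structure(list(kappa = kappa, C0 = C0, A0 = A0, B_log = B_log,
                 t_beta = t_beta, mu = mu, sigma = sigma,
                 mu_left = mu_left, mu_right = mu_right, t_total = t_total),
            class = "collapse_params")
}

#' @export
print.collapse_params <- function(x, ...) {
  cat("Collapsing-bound DDM parameters\n")
  print(round(c(kappa = x$kappa, C0 = x$C0, A0 = x$A0, B_log = x$B_log,
                t_beta = x$t_beta, mu = x$mu, sigma = x$sigma), 4))
  invisible(x)
}

# beta1, beta2 implied by (B_log, t_beta):
#   beta1*beta2 = 10^B_log, beta1/(beta1+beta2) = t_beta
collapse_betas <- function(p) {
  s <- sqrt(10^p$B_log / (p$t_beta * (1 - p$t_beta)))
  c(beta1 = p$t_beta * s, beta2 = (1 - p$t_beta) * s)
}

#' Ground truth for synthetic experiments
#'
#' Bundles the generating accumulation model (exactly one of `flat` or
#' `collapse`) with the gamma non-decision latency of the clock report and,
#' optionally, side-specific latencies for the motor response in the
#' free-response task.
#'
#' @param flat a [flat_params()] object, or `NULL`.
#' @param collapse a [collapse_params()] object, or `NULL`.
#' @param nd_mean,nd_sd mean/sd (s) of the gamma non-decision time added to
#'   bound-crossing times to produce the reported `t_sd`.
#' @param nd_mean_left,nd_mean_right optional side-specific non-decision
#'   means for reaction times (free-response task); default `nd_mean`.
#' @param clock_max clock ceiling in seconds (one full revolution).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(flat = NULL, collapse = NULL,
                         nd_mean, nd_sd, nd_mean_left = NULL,
                         nd_mean_right = NULL, clock_max = 2.7) {
  if (is.null(flat) == is.null(collapse)) {
    stop("exactly one of `flat` and `collapse` must be supplied")
  }
  if (!is.null(flat) && !inherits(flat, "flat_params")) {
    stop("`flat` must be a flat_params object")
  }
  if (!is.null(collapse) && !inherits(collapse, "collapse_params")) {
    stop("`collapse` must be a collapse_params object")
  }
  stop_if_not_scalar(nd_mean, "nd_mean", positive = TRUE)
  stop_if_not_scalar(nd_sd, "nd_sd")
  if (nd_sd < 0) stop("`nd_sd` must be >= 0")
  stop_if_not_scalar(clock_max, "clock_max", positive = TRUE)
  structure(list(flat = flat, collapse = collapse, nd_mean = nd_mean,
                 nd_sd = nd_sd, nd_mean_left = nd_mean_left,
                 nd_mean_right = nd_mean_right, clock_max = clock_max),
            class = "ground_truth")
}
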