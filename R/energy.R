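# Frequency-domain motion energy of dot movies and the reverse-correlation
# leverage analysis of choices near the putative termination time.

# cache for the empirically calibrated octant sign convention
.energy_cal <- new.env(parent = emptyenv())

# DFT frequency axis for n samples at sampling rate fs (cycles per unit)
fft_freqs <- function(n, fs) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

# integrated amplitude in the rightward/leftward octants of one movie
# segment; returns c(right, left) before any sign-convention flip.
# The octant index masks depend only on the geometry, so they are cached.
octant_amplitudes <- function(arr, frame_rate, deg_per_pixel, band) {
  d <- dim(arr)
  key <- paste(c(d, frame_rate, deg_per_pixel, band), collapse = "_")
  masks <- .energy_cal[[key]]
  if (is.null(masks)) {
    fx <- fft_freqs(d[1], 1 / deg_per_pixel)
    ft <- fft_freqs(d[3], frame_rate)
    FX <- array(fx, dim = d)
    FT <- array(rep(ft, each = d[1] * d[2]), dim = d)
    in_band <- abs(FT) >= band[1] & abs(FT) <= band[2] &
      abs(FX) >= band[3] & abs(FX) <= band[4]
    # cells with fx = 0 or ft = 0 belong to neither direction (and are
    # outside the passband anyway)
    pos <- FX > 0 & FT < 0 | FX < 0 & FT > 0
    neg <- FX > 0 & FT > 0 | FX < 0 & FT < 0
    masks <- list(pos = which(in_band & pos), neg = which(in_band & neg))
    .energy_cal[[key]] <- masks
  }
  amp <- Mod(fft(arr))
  c(right = sum(amp[masks$pos]), left = sum(amp[masks$neg]))
}

# +1 if the (fx, ft opposite-sign) octants carry rightward motion under R's
# FFT convention for this geometry, -1 otherwise; fixed once per geometry by
# a 100%-coherence calibration movie
octant_sign <- function(config, band) {
  key <- paste(config$frame_rate, config$deg_per_pixel, sep = "_")
  if (!is.null(.energy_cal[[key]])) return(.energy_cal[[key]])
  cal <- generate_rdm_movie(config, coherence_signed = 1,
                            duration = 30 / config$frame_rate, seed = 424242L)
  a <- octant_amplitudes(cal$data, config$frame_rate, config$deg_per_pixel,
                         band)
  s <- if (a["right"] >= a["left"]) 1 else -1
  .energy_cal[[key]] <- s
  s
}

#' Motion energy of the two halves of an 800 ms movie
#'
#' Applies a 3-D FFT to frames 1-30 and 31-60 separately and integrates the
#' amplitude (complex modulus) over the spatiotemporal frequency octants
#' corresponding to rightward and leftward drift, restricted to temporal
#' frequencies of 2-8 Hz and horizontal spatial frequencies of 0.5-6
#' cyc/deg (all vertical frequencies summed).  The octant-to-direction
#' assignment is fixed empirically by a 100% coherence calibration movie,
#' avoiding DFT sign-convention ambiguity.  Returns rightward-minus-
#' leftward energies for each half.
#'
#' @param movie an `rdm_movie` with exactly 60 frames.
#' @param band passband `c(f_t_lo, f_t_hi, f_x_lo, f_x_hi)` in Hz and
#'   cyc/deg.
#' @return list with `e_pre`, `e_post`, `coherence_signed`.
#' @export
motion_energy_halves <- function(movie, band = c(2, 8, 0.5, 6)) {
  stopifnot(inherits(movie, "rdm_movie"))
  d <- dim(movie$data)
  if (d[3] != 60) stop("movie must have exactly 60 frames (800 ms at 75 Hz)")
  cfg <- movie$config
  if (band[2] > cfg$frame_rate / 2 || band[4] > 1 / (2 * cfg$deg_per_pixel)) {
    stop("passband exceeds the Nyquist limit of the movie grid")
  }
  s <- octant_sign(cfg, band)
  pre <- octant_amplitudes(movie$data[, , 1:30], cfg$frame_rate,
                           cfg$deg_per_pixel, band)
  post <- octant_amplitudes(movie$data[, , 31:60], cfg$frame_rate,
                            cfg$deg_per_pixel, band)
  list(e_pre = s * unname(pre["right"] - pre["left"]),
       e_post = s * unname(post["right"] - post["left"]),
       coherence_signed = movie$coherence_signed)
}

#' Per-trial estimate of the evidence-integration endpoint
#'
#' `t_theta = t_sd - t_nd`: the reported time minus the (subject-specific)
#' non-decision latency from the chronometric fit.  Negative estimates are
#' retained but flagged.
#'
#' @param trials trial table.
#' @param t_nd non-decision time, s (scalar, or vector matched to rows).
#' @return the table with columns `t_theta` and `t_theta_negative` added.
#' @export
compute_t_theta <- function(trials, t_nd) {
  trials$t_theta <- trials$t_sd - t_nd
  trials$t_theta_negative <- !is.na(trials$t_theta) & trials$t_theta < 0
  trials
}

#' Leverage of pre- and post-midpoint motion energy on choice
#'
#' Logistic regression `P(right) = logistic(b0 + b1 E_pre + b2 E_post +
#' b3 C)` over 800 ms, weak-coherence trials whose `t_theta` lies within
#' `delta` of the stimulus midpoint (0.4 s).  `b1`/`b2` measure the
#' leverage of stimulus fluctuations before/after the midpoint, controlling
#' for nominal coherence.
#'
#' @param trials trial table with `e_pre`, `e_post`, `t_theta` columns.
#' @param delta half-width of the inclusion window on `t_theta`, s
#'   (`Inf` keeps every eligible trial).
#' @param weak_set coherence magnitudes included.
#' @param t_mid stimulus midpoint, s.
#' @param min_n below this many trials the fit is flagged and skipped.
#' @return object of class `leverage_fit`: coefficients `b0..b3`, their
#'   `se`, `delta`, `n`, and `flagged` (TRUE when no estimate is provided).
#' @export
leverage_regression <- function(trials, delta,
                                weak_set = c(0, 0.032, 0.064),
                                t_mid = 0.4, min_n = 20) {
  stopifnot(all(c("e_pre", "e_post", "t_theta") %in% names(trials)))
  keep <- trials$duration == 0.8 &
    abs(trials$coh_signed) %in% weak_set &
    !is.na(trials$t_theta) &
    abs(trials$t_theta - t_mid) <= delta
  sub <- trials[keep, ]
  flagged_fit <- function(reason) {
    structure(list(b0 = NA_real_, b1 = NA_real_, b2 = NA_real_,
                   b3 = NA_real_, se = rep(NA_real_, 4), delta = delta,
                   n = nrow(sub), flagged = TRUE, reason = reason),
              class = "leverage_fit")
  }
  if (nrow(sub) < min_n) return(flagged_fit("too few trials"))
  if (sd(sub$e_pre) == 0 || sd(sub$e_post) == 0) {
    return(flagged_fit("degenerate energy regressors"))
  }
  fit <- suppressWarnings(glm(choice ~ e_pre + e_post + coh_signed,
                              family = binomial(), data = sub))
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (!fit$converged || any(!is.finite(co)) || max(abs(co)) > 1e3) {
    return(flagged_fit("separation"))
  }
  structure(list(b0 = unname(co[1]), b1 = unname(co[2]), b2 = unname(co[3]),
                 b3 = unname(co[4]), se = unname(se), delta = delta,
                 n = nrow(sub), flagged = FALSE, reason = NULL),
            class = "leverage_fit")
}

#' @export
print.leverage_fit <- function(x, ...) {
  if (x$flagged) {
    cat(sprintf("leverage_fit (delta = %g s): flagged — %s (n = %d)\n",
                x$delta, x$reason, x$n))
  } else {
    cat(sprintf("leverage_fit (delta = %g s, n = %d)\n", x$delta, x$n))
    print(round(rbind(estimate = c(b0 = x$b0, b1 = x$b1, b2 = x$b2,
                                   b3 = x$b3), se = x$se), 4))
  }
  invisible(x)
}

#' Sweep of leverage fits across inclusion windows
#'
#' One [leverage_regression()] per tolerance; as the window widens all
#' trials enter and the pre/post distinction dissipates.
#'
#' @param trials trial table with energies and `t_theta`.
#' @param deltas window half-widths, s (default 13.3 ms steps, one video
#'   frame, up to 400 ms).
#' @inheritParams leverage_regression
#' @return data.frame with one row per `delta`: coefficients, SEs, `n`,
#'   `flagged`.
#' @export
window_sweep <- function(trials, deltas = seq(1, 30) * (1 / 75),
                         weak_set = c(0, 0.032, 0.064), t_mid = 0.4) {
  rows <- lapply(deltas, function(dd) {
    f <- leverage_regression(trials, dd, weak_set, t_mid)
    data.frame(delta = dd, b0 = f$b0, b1 = f$b1, b2 = f$b2, b3 = f$b3,
               se_b1 = f$se[2], se_b2 = f$se[3], n = f$n,
               flagged = f$flagged)
  })
  do.call(rbind, rows)
}

#' Bootstrap contrast of pre- vs post-midpoint leverage
#'
#' The observed contrast is `d = b1 - b2` fitted on trials with `t_theta`
#' within `delta` of the midpoint; the null distribution re-fits on sets of
#' the same size sampled with replacement from the complementary trials
#' (`|t_theta - t_mid| > delta`).  One-tailed p: the fraction of null
#' contrasts at least as large as the observed one.
#'
#' @inheritParams leverage_regression
#' @param n_boot number of bootstrap draws (> 0).
#' @param seed integer seed.
#' @return list with `d_observed`, `p_value`, `n_in`, `n_out`, and the
#'   vector `d_null`.
#' @export
bootstrap_leverage_difference <- function(trials, delta = 0.133,
                                          n_boot = 5000, seed = NULL,
                                          weak_set = c(0, 0.032, 0.064),
                                          t_mid = 0.4) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  fit_in <- leverage_regression(trials, delta, weak_set, t_mid)
  if (fit_in$flagged) stop("in-window leverage fit flagged: ", fit_in$reason)
  d_obs <- fit_in$b1 - fit_in$b2
  eligible <- trials$duration == 0.8 &
    abs(trials$coh_signed) %in% weak_set & !is.na(trials$t_theta)
  out_pool <- trials[eligible & abs(trials$t_theta - t_mid) > delta, ]
  if (nrow(out_pool) < 20) stop("too few out-of-window trials")
  d_null <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    res <- out_pool[sample(nrow(out_pool), fit_in$n, replace = TRUE), ]
    f <- leverage_regression(res, Inf, weak_set, t_mid, min_n = 10)
    if (f$flagged) NA_real_ else f$b1 - f$b2
  }, numeric(1)))
  d_null <- d_null[is.finite(d_null)]
  list(d_observed = d_obs, p_value = mean(d_null >= d_obs),
       n_in = fit_in$n, n_out = nrow(out_pool), d_null = d_null)
}
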