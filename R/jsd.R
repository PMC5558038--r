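# Distributional goodness of fit: signed-time histograms per (coherence,
# choice) cell, Jensen-Shannon divergence, bootstrap confidence intervals,
# and the permutation null with proportion matching and mean alignment.

#' Histogram of reported times per (signed coherence, choice) cell
#'
#' Bins `t_sd` (10 ms default) over `[0, t_max]` separately for each signed
#' coherence and choice; cell masses sum to one over the whole table, so
#' the object is a joint distribution over (coherence, choice, time).
#'
#' @param trials trial table.
#' @param bin_width bin width, s.
#' @param t_max time-axis end, s (the clock ceiling).
#' @param cells optional data.frame of `C`, `choice` fixing the cell layout
#'   (needed to compare tables that do not populate every cell).
#' @return object of class `tsd_histogram`: `edges`, `cells` (data.frame),
#'   `prob` (cells x bins matrix of masses).
#' @export
signed_tsd_histogram <- function(trials, bin_width = 0.01, t_max = 2.7,
                                 cells = NULL) {
  tr <- trials[!is.na(trials$t_sd), ]
  edges <- seq(0, t_max, by = bin_width)
  if (is.null(cells)) {
    cells <- expand.grid(C = sort(unique(tr$coh_signed)), choice = c(0L, 1L))
  }
  prob <- matrix(0, nrow(cells), length(edges) - 1L)
  for (i in seq_len(nrow(cells))) {
    sub <- tr$t_sd[tr$coh_signed == cells$C[i] & tr$choice == cells$choice[i]]
    sub <- pmin(pmax(sub, 0), t_max - 1e-9)
    if (length(sub)) {
      prob[i, ] <- tabulate(findInterval(sub, edges), length(edges) - 1L)
    }
  }
  prob <- prob / max(sum(prob), 1)
  structure(list(edges = edges, cells = cells, prob = prob),
            class = "tsd_histogram")
}

#' Model-implied histogram on the same layout
#'
#' Converts the convolved first-passage densities of a collapsing-bound
#' model into a `tsd_histogram`: each coherence's choice-conditional
#' density, weighted by that coherence's share of trials, binned on the
#' histogram grid and normalized over absorbed mass.
#'
#' @param p a [collapse_params()].
#' @param trials trial table supplying the coherence mix and cell layout.
#' @param bin_width,t_max as in [signed_tsd_histogram()].
#' @param dt,dx solver grid resolution.
#' @return a `tsd_histogram`.
#' @export
model_tsd_histogram <- function(p, trials, bin_width = 0.01, t_max = 2.7,
                                dt = 1e-3, dx = NULL) {
  tr <- trials[!is.na(trials$t_sd), ]
  obs <- signed_tsd_histogram(tr, bin_width, t_max)
  cells <- obs$cells
  edges <- obs$edges
  nb <- length(edges) - 1L
  prob <- matrix(0, nrow(cells), nb)
  wc <- table(factor(tr$coh_signed, levels = sort(unique(tr$coh_signed))))
  wc <- wc / sum(wc)
  for (cc in sort(unique(cells$C))) {
    f <- convolve_nondecision(fpt_density(p, cc, dt = dt, dx = dx, t_max = t_max),
                              p$mu, p$sigma)
    bin_of <- findInterval(f$time, edges, rightmost.closed = TRUE)
    for (ch in c(0L, 1L)) {
      i <- which(cells$C == cc & cells$choice == ch)
      if (!length(i)) next
      dens <- if (ch == 1L) f$density_right else f$density_left
      mass <- dens * f$dt
      agg <- tapply(mass, factor(bin_of, levels = seq_len(nb)), sum,
                    default = 0)
      prob[i, ] <- as.numeric(agg) * as.numeric(wc[as.character(cc)])
    }
  }
  prob <- prob / sum(prob)
  structure(list(edges = edges, cells = cells, prob = prob),
            class = "tsd_histogram")
}

#' Jensen-Shannon divergence between two signed-time histograms
#'
#' `JSD = KL(p||m)/2 + KL(q||m)/2` with `m = (p+q)/2`, log base 2, computed
#' on the pooled (cell, bin) axis by default or as a mass-weighted average
#' of per-cell contributions.  Bounded by `[0, 1]` bit; zero-probability
#' bins are handled by the mixture (no pseudocounts).
#'
#' @param p,q `tsd_histogram` objects on identical binning and cell layout.
#' @param aggregate `"pooled"` (default) or `"per_cell"`.
#' @return divergence in bits.
#' @export
jsd <- function(p, q, aggregate = c("pooled", "per_cell")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(p, "tsd_histogram"), inherits(q, "tsd_histogram"))
  if (!isTRUE(all.equal(p$edges, q$edges)) ||
      nrow(p$cells) != nrow(q$cells) ||
      !isTRUE(all.equal(p$cells$C, q$cells$C)) ||
      !isTRUE(all.equal(p$cells$choice, q$cells$choice))) {
    stop("histograms must share binning and cell layout")
  }
  kl2 <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * (log2(a[nz]) - log2(b[nz])))
  }
  if (aggregate == "pooled") {
    pv <- as.numeric(p$prob); qv <- as.numeric(q$prob)
    m <- (pv + qv) / 2
    return(0.5 * kl2(pv, m) + 0.5 * kl2(qv, m))
  }
  # mass-weighted average of per-cell divergences of the normalized shapes
  w <- rowSums(q$prob)
  total <- 0
  for (i in seq_len(nrow(p$prob))) {
    pi <- p$prob[i, ]; qi <- q$prob[i, ]
    if (sum(pi) == 0 || sum(qi) == 0) next
    pi <- pi / sum(pi); qi <- qi / sum(qi)
    m <- (pi + qi) / 2
    total <- total + w[i] * (0.5 * kl2(pi, m) + 0.5 * kl2(qi, m))
  }
  total / sum(w)
}

#' Match fitted cell masses to observed proportions
#'
#' Rescales each (coherence, choice) cell of the fitted histogram to carry
#' the observed cell's total mass, preserving the within-cell shape; this
#' removes divergence due to mispredicted error rates before comparing
#' distributions.
#'
#' @param fitted,observed `tsd_histogram` objects on the same layout.
#' @return the rescaled fitted histogram.
#' @export
match_proportions <- function(fitted, observed) {
  out <- fitted
  for (i in seq_len(nrow(fitted$prob))) {
    mass_f <- sum(fitted$prob[i, ])
    mass_o <- sum(observed$prob[i, ])
    out$prob[i, ] <- if (mass_f > 0) fitted$prob[i, ] / mass_f * mass_o
                     else 0
  }
  out
}

# integer-bin time shift of one cell's masses with edge truncation followed
# by renormalization to the original cell mass
shift_cell <- function(x, shift) {
  n <- length(x)
  mass <- sum(x)
  if (mass == 0 || shift == 0) return(x)
  y <- numeric(n)
  if (shift > 0) {
    y[(1 + shift):n] <- x[1:(n - shift)]
  } else {
    y[1:(n + shift)] <- x[(1 - shift):n]
  }
  if (sum(y) > 0) y * (mass / sum(y)) else x
}

cell_mean_bin <- function(x) {
  if (sum(x) == 0) return(NA_real_)
  sum(seq_along(x) * x) / sum(x)
}

#' Bootstrap confidence interval for the model JSD
#'
#' Resamples trials with replacement, refits via the supplied procedure,
#' and recomputes the JSD between the refit and the resampled data
#' (proportion matching applied before each divergence); returns the
#' percentile interval.
#'
#' @param trials trial table.
#' @param fit_fun function(trials) returning a `tsd_histogram` of the
#'   model fitted to that table.
#' @param n_boot bootstrap replicates (200 in the standard analysis).
#' @param seed integer seed.
#' @param probs interval probabilities.
#' @param bin_width,t_max histogram layout.
#' @return list with `point`, `ci`, and the vector `boot`.
#' @export
jsd_bootstrap_ci <- function(trials, fit_fun, n_boot = 200, seed = NULL,
                             probs = c(0.025, 0.975), bin_width = 0.01,
                             t_max = 2.7) {
  obs <- signed_tsd_histogram(trials, bin_width, t_max)
  fit0 <- fit_fun(trials)
  point <- jsd(match_proportions(fit0, obs), obs)
  if (n_boot < 1) stop("n_boot must be >= 1")
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    res <- trials[sample(nrow(trials), replace = TRUE), ]
    o <- signed_tsd_histogram(res, bin_width, t_max, cells = obs$cells)
    f <- fit_fun(res)
    jsd(match_proportions(f, o), o)
  }, numeric(1)))
  ci <- if (n_boot == 1) rep(boot, 2) else quantile(boot, probs, names = FALSE)
  list(point = point, ci = ci, boot = boot)
}

#' Permutation null for the JSD
#'
#' Permutes the fitted per-cell distributions across (coherence, choice)
#' cells; each permuted surrogate is rescaled to the observed cell masses
#' and shifted in time (integer bins) to match the observed cell mean, so
#' only the within-cell shape differs from the original assignment.  The
#' one-tailed p-value is `(N0 + 1) / (N + 1)` with `N0` the number of
#' permuted divergences less than or equal to the original.
#'
#' @param fitted,observed `tsd_histogram` objects on the same layout.
#' @param n_perm number of permutations (`N`); `0` gives `p = 1`.
#' @param seed integer seed.
#' @return list with `p_value`, `jsd_original`, `jsd_perm`.
#' @export
jsd_permutation_null <- function(fitted, observed, n_perm = 200,
                                 seed = NULL) {
  fitted_m <- match_proportions(fitted, observed)
  j0 <- jsd(fitted_m, observed)
  if (n_perm == 0) {
    return(list(p_value = 1, jsd_original = j0, jsd_perm = numeric()))
  }
  nc <- nrow(fitted$prob)
  jp <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    perm <- fitted
    perm$prob <- fitted$prob[sample(nc), , drop = FALSE]
    perm <- match_proportions(perm, observed)
    for (i in seq_len(nc)) {
      mo <- cell_mean_bin(observed$prob[i, ])
      mp <- cell_mean_bin(perm$prob[i, ])
      if (is.finite(mo) && is.finite(mp)) {
        perm$prob[i, ] <- shift_cell(perm$prob[i, ], round(mo - mp))
      }
    }
    perm$prob <- perm$prob / max(sum(perm$prob), 1e-300)
    jsd(perm, observed)
  }, numeric(1)))
  p <- (sum(jp <= j0) + 1) / (n_perm + 1)
  list(p_value = p, jsd_original = j0, jsd_perm = jp)
}
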