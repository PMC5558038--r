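#' Random-dot stimulus configuration
#'
#' Geometry and dynamics of the random-dot kinematogram: dots are plotted for
#' one frame and, `interleave` frames later, each dot of the same set is
#' either displaced along the motion axis (with probability equal to the
#' coherence magnitude) or replaced at a random position in the annulus.
#'
#' @param frame_rate display frame rate, Hz.
#' @param interleave number of interleaved, independent dot sets; a set shown
#'   on frame k is updated on frame k + interleave.
#' @param speed motion speed, deg/s.
#' @param density dot density, dots deg^-2 s^-1.
#' @param annulus_inner,annulus_outer diameters (deg) of the invisible
#'   circles bounding the dot field.
#' @param deg_per_pixel size of one movie pixel, deg.
#' @param coherence_levels magnitudes of coherence used in the experiments.
#' @return an object of class `stimulus_config`.
#' @export
stimulus_config <- function(frame_rate = 75, interleave = 5, speed = 1.25,
                            density = 16.7, annulus_inner = 1,
                            annulus_outer = 5, deg_per_pixel = 0.05,
                            coherence_levels = c(0, 0.032, 0.064, 0.128,
                                                 0.256, 0.512)) {
  stop_if_not_scalar(frame_rate, "frame_rate", positive = TRUE)
  stop_if_not_scalar(speed, "speed", positive = TRUE)
  stop_if_not_scalar(density, "density", positive = TRUE)
  if (!(annulus_outer > annulus_inner && annulus_inner > 0)) {
    stop("need annulus_outer > annulus_inner > 0")
  }
  if (any(coherence_levels < 0 | coherence_levels > 1)) {
    stop("coherence levels must lie in [0, 1]")
  }
  structure(list(frame_rate = frame_rate, interleave = as.integer(interleave),
                 speed = speed, density = density,
                 annulus_inner = annulus_inner, annulus_outer = annulus_outer,
                 deg_per_pixel = deg_per_pixel,
                 coherence_levels = coherence_levels),
            class = "stimulus_config")
}

# uniform sample of n points in the annulus (radii in deg)
runif_annulus <- function(n, r_in, r_out) {
  r <- sqrt(runif(n) * (r_out^2 - r_in^2) + r_in^2)
  th <- runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Generate a random-dot motion movie
#'
#' Simulates the interleaved random-dot algorithm: each frame plots
#' `round(density * annulus_area / frame_rate)` dots; a dot shown
#' `interleave` frames earlier is displaced by
#' `speed * interleave / frame_rate` degrees in the signed motion direction
#' with probability `|coherence_signed|`, otherwise replaced at a random
#' annulus position.  Displaced dots that leave the annulus (outer edge or
#' central hole) wrap to the opposite edge along the motion axis, conserving
#' dot count.  The movie is returned both as a binary pixel array
#' `(x, y, frame)` and as per-frame continuous dot coordinates.
#'
#' @param config a [stimulus_config()].
#' @param coherence_signed signed coherence in `[-1, 1]`; positive is
#'   rightward.
#' @param duration movie duration, s (must cover at least one frame).
#' @param seed integer seed; the movie is a deterministic function of
#'   `(config, coherence_signed, duration, seed)`.
#' @return an object of class `rdm_movie` with elements `data` (binary
#'   array), `dots` (list of per-frame coordinate matrices), `config`,
#'   `coherence_signed`, `seed`.
#' @export
generate_rdm_movie <- function(config, coherence_signed, duration, seed) {
  stopifnot(inherits(config, "stimulus_config"))
  if (abs(coherence_signed) > 1) stop("|coherence_signed| must be <= 1")
  stop_if_not_scalar(duration, "duration", positive = TRUE)
  if (is.null(config$deg_per_pixel) || !is.finite(config$deg_per_pixel)) {
    stop("`deg_per_pixel` must be set in the stimulus configuration")
  }
  n_frames <- round(duration * config$frame_rate)
  if (n_frames < 1) stop("duration is shorter than one frame")

  r_in <- config$annulus_inner / 2
  r_out <- config$annulus_outer / 2
  area <- pi * (r_out^2 - r_in^2)
  n_dots <- max(1L, as.integer(round(config$density * area / config$frame_rate)))
  step <- config$speed * config$interleave / config$frame_rate
  dxs <- step * sign(coherence_signed)
  pC <- abs(coherence_signed)

  npix <- as.integer(ceiling(2 * r_out / config$deg_per_pixel))
  data <- array(0L, dim = c(npix, npix, n_frames))
  dots <- vector("list", n_frames)

  with_seed(seed, {
    for (k in seq_len(n_frames)) {
      prev <- k - config$interleave
      if (prev >= 1) {
        xy <- dots[[prev]]
        displaced <- runif(n_dots) < pC
        if (any(displaced)) {
          xy[displaced, "x"] <- xy[displaced, "x"] + dxs
          # wrap dots that left the annulus to the opposite edge
          rr <- sqrt(xy[, "x"]^2 + xy[, "y"]^2)
          out <- displaced & rr > r_out
          if (any(out)) {
            xy[out, "x"] <- -sign(dxs) * sqrt(r_out^2 - xy[out, "y"]^2) *
              (1 - 1e-9)
          }
          inn <- displaced & rr < r_in
          if (any(inn)) {
            xy[inn, "x"] <- sign(dxs) * sqrt(r_in^2 - xy[inn, "y"]^2) *
              (1 + 1e-9)
          }
        }
        if (any(!displaced)) {
          xy[!displaced, ] <- runif_annulus(sum(!displaced), r_in, r_out)
        }
      } else {
        xy <- runif_annulus(n_dots, r_in, r_out)
      }
      dots[[k]] <- xy
      ix <- pmin(pmax(floor((xy[, "x"] + r_out) / config$deg_per_pixel) + 1, 1),
                 npix)
      iy <- pmin(pmax(floor((xy[, "y"] + r_out) / config$deg_per_pixel) + 1, 1),
                 npix)
      data[cbind(ix, iy, k)] <- 1L
    }
  })

  structure(list(data = data, dots = dots, config = config,
                 coherence_signed = coherence_signed, seed = seed),
            class = "rdm_movie")
}

#' @export
print.rdm_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("rdm_movie: %d x %d pixels, %d frames, C = %+0.3f, seed %s\n",
              d[1], d[2], d[3], x$coherence_signed, format(x$seed)))
  invisible(x)
}

#' Write / read a movie as plain text
#'
#' Stores the binary pixel array with a small key-value header
#' (`frame_rate`, `deg_per_pixel`, `coherence_signed`, `seed`, dims); one
#' text line of 0/1 characters per pixel row per frame.  Continuous dot
#' coordinates are not persisted.
#'
#' @param movie an `rdm_movie`.
#' @param path file path.
#' @return `write_movie` returns `path` invisibly; `read_movie` an
#'   `rdm_movie` (without `dots`).
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "rdm_movie"))
  d <- dim(movie$data)
  hdr <- c(sprintf("# frame_rate %.10g", movie$config$frame_rate),
           sprintf("# deg_per_pixel %.10g", movie$config$deg_per_pixel),
           sprintf("# coherence_signed %.10g", movie$coherence_signed),
           sprintf("# seed %d", as.integer(movie$seed)),
           sprintf("# dims %d %d %d", d[1], d[2], d[3]))
  body <- vapply(seq_len(d[3]), function(k) {
    paste(apply(movie$data[, , k, drop = FALSE], 1,
                function(row) paste(row, collapse = "")), collapse = "\n")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- lapply(strsplit(sub("^# ", "", hdr), " "), function(x) x)
  keys <- vapply(kv, `[[`, character(1), 1)
  get_num <- function(key) as.numeric(kv[[match(key, keys)]][-1])
  d <- as.integer(get_num("dims"))
  body <- lines[!startsWith(lines, "# ")]
  stopifnot(length(body) == d[1] * d[3])
  mat <- vapply(strsplit(body, ""), function(ch) as.integer(ch),
                integer(d[2]))
  data <- array(0L, dim = d)
  for (k in seq_len(d[3])) {
    data[, , k] <- t(mat[, (k - 1) * d[1] + seq_len(d[1])])
  }
  cfg <- stimulus_config(frame_rate = get_num("frame_rate"),
                         deg_per_pixel = get_num("deg_per_pixel"))
  structure(list(data = data, dots = NULL, config = cfg,
                 coherence_signed = get_num("coherence_signed"),
                 seed = as.integer(get_num("seed"))),
            class = "rdm_movie")
}
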