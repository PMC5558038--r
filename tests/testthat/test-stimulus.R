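test_that("movie geometry follows the density formula and the frame count", {
  cfg <- stimulus_config()
  mv <- generate_rdm_movie(cfg, 0.512, 0.8, seed = 1)
  expect_equal(dim(mv$data)[3], 60)  # 800 ms at 75 Hz
  # dots per frame: round(density * annulus area / frame rate)
  area <- pi * ((cfg$annulus_outer / 2)^2 - (cfg$annulus_inner / 2)^2)
  n_expected <- round(cfg$density * area / cfg$frame_rate)
  for (k in c(1, 17, 60)) {
    expect_equal(nrow(mv$dots[[k]]), n_expected)
    r <- sqrt(rowSums(mv$dots[[k]]^2))
    expect_true(all(r >= cfg$annulus_inner / 2 - 1e-6))
    expect_true(all(r <= cfg$annulus_outer / 2 + 1e-6))
  }
  # short movie error and unset pixel size error
  expect_error(generate_rdm_movie(cfg, 0, 0.001, seed = 1), "one frame")
  bad <- cfg; bad$deg_per_pixel <- NA_real_
  expect_error(generate_rdm_movie(bad, 0, 0.2, seed = 1), "deg_per_pixel")
})

test_that("movies are deterministic in the seed", {
  cfg <- stimulus_config()
  a <- generate_rdm_movie(cfg, 0.256, 0.4, seed = 7)
  b <- generate_rdm_movie(cfg, 0.256, 0.4, seed = 7)
  d <- generate_rdm_movie(cfg, 0.256, 0.4, seed = 8)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, d$data))
})

test_that("displaced-dot fraction matches the coherence", {
  cfg <- stimulus_config()
  step <- cfg$speed * cfg$interleave / cfg$frame_rate
  # frame-to-frame matching oracle: a displaced dot keeps its y exactly
  # (random replacement draws a fresh y almost surely); displacement is one
  # motion step in x unless the dot wrapped at the annulus edge
  count_pairs <- function(mv) {
    hits <- 0; total <- 0; exact <- 0
    n <- length(mv$dots)
    for (k in seq_len(n - cfg$interleave)) {
      from <- mv$dots[[k]]
      to <- mv$dots[[k + cfg$interleave]]
      for (i in seq_len(nrow(from))) {
        total <- total + 1
        dy <- to[, "y"] - from[i, "y"]
        j <- which(abs(dy) < 1e-12)
        if (length(j)) {
          hits <- hits + 1
          dx <- to[j, "x"] - from[i, "x"]
          if (any(abs(abs(dx) - step) < 1e-9)) exact <- exact + 1
        }
      }
    }
    c(hits = hits, total = total, exact = exact)
  }
  # full coherence: every paired dot displaced, almost all by exactly one
  # step (the rest wrapped at the annulus edge)
  mv1 <- generate_rdm_movie(cfg, 1, 0.2, seed = 7)
  r1 <- count_pairs(mv1)
  expect_equal(unname(r1["hits"]), unname(r1["total"]))
  expect_gte(unname(r1["exact"]), 0.8 * unname(r1["total"]))
  # intermediate coherence: displaced fraction within 3 binomial SE
  mv <- generate_rdm_movie(cfg, 0.512, 2.0, seed = 3)
  r <- count_pairs(mv)
  phat <- r["hits"] / r["total"]
  se <- sqrt(0.512 * (1 - 0.512) / r["total"])
  expect_lt(abs(phat - 0.512), 3 * se + 1e-12)
  # zero coherence: no dot is ever displaced
  mv0 <- generate_rdm_movie(cfg, 0, 0.4, seed = 5)
  r0 <- count_pairs(mv0)
  expect_equal(unname(r0["hits"]), 0)
})

test_that("movie text round trip preserves the pixel array and metadata", {
  cfg <- stimulus_config()
  mv <- generate_rdm_movie(cfg, -0.128, 0.2, seed = 11)
  path <- tempfile(fileext = ".txt")
  write_movie(mv, path)
  back <- read_movie(path)
  expect_identical(back$data, mv$data)
  expect_equal(back$coherence_signed, -0.128)
  expect_equal(back$config$frame_rate, cfg$frame_rate)
  unlink(path)
})
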