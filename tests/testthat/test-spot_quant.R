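test_that("a single bright pixel is the only maximum", {
  img <- matrix(0, 5, 5); img[3, 3] <- 10
  mx <- find_maxima(img, measure_config(noise_tolerance = 5))
  expect_identical(unname(mx), matrix(c(3L, 3L), ncol = 2))
})

test_that("a flat image has no maxima", {
  expect_identical(nrow(find_maxima(matrix(2, 8, 8), measure_config(noise_tolerance = 5))), 0L)
  expect_identical(nrow(find_maxima(matrix(0, 8, 8), measure_config(noise_tolerance = 0))), 0L)
})

test_that("two peaks separated by a valley are both found, row-major", {
  img <- matrix(0, 9, 9)
  img[2:4, 2:4] <- 60; img[3, 3] <- 100
  img[6:8, 6:8] <- 60; img[7, 7] <- 100
  mx <- find_maxima(img, measure_config(noise_tolerance = 50))
  expect_identical(unname(mx), matrix(c(3L, 3L, 7L, 7L), ncol = 2, byrow = TRUE))
  # exhaustive neighbourhood check: every reported maximum dominates its 8-neighbours
  for (i in seq_len(nrow(mx))) {
    r <- mx[i, 1]; c <- mx[i, 2]
    expect_true(all(img[r, c] >= img[max(1, r - 1):min(9, r + 1),
                                     max(1, c - 1):min(9, c + 1)]))
  }
})

test_that("prominence below the tolerance suppresses shoulder peaks", {
  img <- matrix(0, 9, 9)
  img[3, 3] <- 100
  img[3, 6] <- 95          # separated from the main peak by a 90-level ridge
  img[3, 4:5] <- 90
  mx <- find_maxima(img, measure_config(noise_tolerance = 10))
  expect_identical(nrow(mx), 1L)
  mx2 <- find_maxima(img, measure_config(noise_tolerance = 2))
  expect_identical(nrow(mx2), 2L)
})

test_that("plateaus collapse to a single coordinate", {
  img <- matrix(0, 7, 7)
  img[3:4, 3:4] <- 50
  mx <- find_maxima(img, measure_config(noise_tolerance = 10))
  expect_identical(nrow(mx), 1L)
  expect_identical(unname(mx[1, ]), c(3L, 3L))  # first plateau pixel, row-major
})

test_that("spot brightness follows the median-background arithmetic", {
  img <- matrix(2, 11, 11)
  img[5:7, 5:7] <- 12
  cfg <- measure_config(inner_side = 3, outer_side = 7)
  expect_equal(as.numeric(measure_spot(img, c(6, 6), cfg)), 108 - 2 * 9)
  # exact offset invariance
  expect_identical(as.numeric(measure_spot(img + 5, c(6, 6), cfg)),
                   as.numeric(measure_spot(img, c(6, 6), cfg)))
  expect_identical(as.numeric(measure_spot(img + 1234.5, c(6, 6), cfg)),
                   as.numeric(measure_spot(img, c(6, 6), cfg)))
  # linearity on a constant-background toy
  img2 <- img; img2[5:7, 5:7] <- 22
  expect_equal(as.numeric(measure_spot(img2, c(6, 6), cfg)), 180)
  expect_error(measure_spot(img, c(0, 6), cfg), class = "potkit_bounds_error")
  expect_true(attr(measure_spot(img, c(1, 1), cfg), "clipped"))
})

test_that("brightness is linear in amplitude on synthetic fields", {
  cfg <- measure_config(noise_tolerance = 1)
  amps <- c(10, 30, 100, 300, 1000, 3000, 10000)
  b <- vapply(amps, function(a) {
    f <- render_field(data.frame(row = 15, col = 15, amplitude = a, sigma = 1.5),
                      height = 29, width = 29, background = 7)
    as.numeric(measure_spot(f$image, c(15, 15), cfg))
  }, numeric(1))
  expect_gt(stats::cor(b, amps)^2, 0.999)
})

test_that("time-lapse measurement tracks static and drifting spots", {
  spot <- data.frame(row = 15, col = 15, amplitude = 500, sigma = 1.5, tau = 1e9)
  res <- render_bleach_series(spot, frames = 10, height = 31, width = 31,
                              background = 5)
  series <- measure_timelapse(res$stack, matrix(c(15L, 15L), ncol = 2),
                              measure_config(noise_tolerance = 10))[[1]]
  expect_length(series$values, 10L)
  expect_equal(series$times, 1:10)
  expect_true(all(abs(series$values - series$values[1]) / series$values[1] < 1e-6))

  # drifting spot: 1 px/frame, recovered by re-centring within radius 2
  frames <- 8
  stack <- array(0, dim = c(frames, 41, 41))
  for (t in seq_len(frames)) {
    f <- render_field(data.frame(row = 10 + t, col = 10 + t, amplitude = 500,
                                 sigma = 1.5),
                      height = 41, width = 41, background = 5)
    stack[t, , ] <- f$image
  }
  drift <- measure_timelapse(stack, matrix(c(11L, 11L), ncol = 2),
                             measure_config(noise_tolerance = 10))[[1]]
  static <- drift$values[1]
  expect_true(all(abs(drift$values - static) / static < 0.01))

  # without re-centring the drifting spot decays: the documented failure mode
  stuck <- measure_timelapse(stack, matrix(c(11L, 11L), ncol = 2),
                             measure_config(noise_tolerance = 10,
                                            recenter_radius = 0))[[1]]
  expect_lt(stuck$values[frames], 0.5 * stuck$values[1])
})

test_that("half-life interpolation follows the bracketing rule", {
  expect_equal(half_life(list(times = 1:4, values = c(100, 80, 60, 40)))$crossing_time, 3.5)
  expect_equal(half_life(list(times = 1:4, values = c(100, 80, 60, 40)))$elapsed_half_life, 2.5)
  expect_equal(half_life(list(times = 1:4, values = c(100, 60, 50, 40)))$crossing_time, 3.0)
  hl <- half_life(list(times = 1:4, values = c(100, 90, 80, 70)))
  expect_true(hl$censored)
  expect_identical(hl$last_time, 4L)
  expect_error(half_life(list(times = 1, values = 100)), class = "potkit_data_error")
  expect_error(half_life(list(times = 1:3, values = c(100, NA, 10))),
               class = "potkit_data_error")
})

test_that("half-life on sampled exponentials recovers tau", {
  for (tau in c(3, 5, 10)) {
    t <- 1:30
    b <- 100 * 2^(-(t - 1) / tau)
    hl <- half_life(list(times = t, values = b))
    expect_equal(hl$elapsed_half_life, tau, tolerance = 1e-9)
  }
  # half-value between samples: recovered within one frame interval
  tau <- 4.3
  b <- 100 * 2^(-(0:29) / tau)
  hl <- half_life(list(times = 1:30, values = b))
  expect_lt(abs(hl$elapsed_half_life - tau), 1)
})

test_that("relative brightness matches direct ratios and a bootstrap SD", {
  expect_equal(relative_brightness(50, 100)$percent, 50)
  expect_equal(relative_brightness(c(2, 4, 6), c(2, 4, 6))$percent, 100)
  expect_error(relative_brightness(1, -2), class = "potkit_data_error")
  set.seed(8)
  cond <- rnorm(200, 60, 12)
  ref <- rnorm(200, 100, 15)
  rb <- relative_brightness(cond, ref)
  boot <- replicate(1000, {
    100 * mean(sample(cond, replace = TRUE)) / mean(sample(ref, replace = TRUE))
  })
  expect_lt(abs(stats::sd(boot) - rb$sd_percent) / stats::sd(boot), 0.10)
})
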