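# Synthetic spot fields and bleaching time-lapses with known ground truth:
# the stand-in for microscope acquisitions when validating photometry and
# half-life estimation.

#' Render a synthetic spot field
#'
#' Each spot is an isotropic 2D Gaussian `A * exp(-((x-x0)^2 + (y-y0)^2) /
#' (2 sigma^2))` sampled at pixel centres on a constant background, with noise
#' applied last under `seed`. The analytic integrated flux of each spot,
#' `2 * pi * A * sigma^2`, and its finite inner-box sums are recoverable from
#' the returned ground truth. Spots closer than 3 sigma to another spot are
#' flagged `crowded` (rendered anyway).
#'
#' @param spots data frame with columns `row`, `col` (pixel-centre positions),
#'   `amplitude` (ADU) and `sigma` (px).
#' @param height,width image size in pixels.
#' @param background constant background level (ADU).
#' @param noise one of "none", "gaussian", "poisson".
#' @param noise_sd standard deviation for Gaussian noise (ADU).
#' @param gain ADU per photon for Poisson noise.
#' @param seed integer seed for the noise draw.
#' @return list: `image` (matrix), `truth` (spots plus `flux` and `crowded`).
#' @export
render_field <- function(spots, height = 256L, width = 256L, background = 0,
                         noise = c("none", "gaussian", "poisson"),
                         noise_sd = 0, gain = 1, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(all(c("row", "col", "amplitude", "sigma") %in% names(spots)))
  if (any(spots$amplitude <= 0) || any(spots$sigma <= 0) || background < 0) {
    abort_data("amplitudes and sigma must be positive, background non-negative")
  }
  if (any(spots$row < 1 | spots$row > height | spots$col < 1 | spots$col > width)) {
    abort_data("spot centres must lie inside the image")
  }
  img <- matrix(background, nrow = height, ncol = width)
  for (i in seq_len(nrow(spots))) {
    s <- spots[i, ]
    ext <- ceiling(6 * s$sigma)
    rs <- max(1L, floor(s$row - ext)):min(height, ceiling(s$row + ext))
    cs <- max(1L, floor(s$col - ext)):min(width, ceiling(s$col + ext))
    gr <- exp(-(rs - s$row)^2 / (2 * s$sigma^2))
    gc <- exp(-(cs - s$col)^2 / (2 * s$sigma^2))
    img[rs, cs] <- img[rs, cs] + s$amplitude * outer(gr, gc)
  }
  img <- with_seed(seed, apply_noise(img, noise, noise_sd, gain))
  truth <- spots
  truth$flux <- 2 * pi * truth$amplitude * truth$sigma^2
  truth$crowded <- vapply(seq_len(nrow(spots)), function(i) {
    if (nrow(spots) == 1L) return(FALSE)
    d <- sqrt((spots$row - spots$row[i])^2 + (spots$col - spots$col[i])^2)
    any(d[-i] < 3 * spots$sigma[i])
  }, logical(1))
  list(image = img, truth = truth)
}

apply_noise <- function(img, noise, noise_sd, gain) {
  switch(noise,
    none = img,
    gaussian = img + matrix(stats::rnorm(length(img), 0, noise_sd),
                            nrow = nrow(img)),
    poisson = matrix(stats::rpois(length(img), pmax(img, 0) / gain) * gain,
                     nrow = nrow(img))
  )
}

#' Render a photobleaching time-lapse
#'
#' Frame at time `t = frame * interval` scales every spot amplitude by
#' `2^(-(t - t1) / tau)` (per-spot half-life `tau`, first frame at `t1 =
#' interval`); the background is constant and noise is drawn independently per
#' frame under `seed`.
#'
#' @param spots as in [render_field()], plus a `tau` column (seconds).
#' @param frames number of frames (default 30, a 30 x 1 s acquisition).
#' @param interval frame interval in seconds.
#' @inheritParams render_field
#' @return list: `stack` (array T x H x W), `truth`, `times`.
#' @export
render_bleach_series <- function(spots, frames = 30L, interval = 1,
                                 height = 256L, width = 256L, background = 0,
                                 noise = c("none", "gaussian", "poisson"),
                                 noise_sd = 0, gain = 1, seed = NULL) {
  noise <- match.arg(noise)
  if (!"tau" %in% names(spots) || any(!is.finite(spots$tau)) || any(spots$tau <= 0)) {
    abort_data("every spot needs a positive bleaching half-life tau")
  }
  stack <- array(0, dim = c(frames, height, width))
  times <- seq_len(frames) * interval
  with_seed(seed, {
    for (f in seq_len(frames)) {
      sc <- spots
      sc$amplitude <- spots$amplitude * 2^(-(times[f] - times[1]) / spots$tau)
      fr <- render_field(sc, height, width, background, noise = "none")
      stack[f, , ] <- apply_noise(fr$image, noise, noise_sd, gain)
    }
  })
  truth <- render_field(spots, height, width, background, noise = "none")$truth
  list(stack = stack, truth = truth, times = times)
}

#' The standard synthetic validation field
#'
#' A 256 x 256 field of 100 Gaussian spots (sigma 1.5 px) on a jittered 10 x
#' 10 grid, amplitudes log-spaced from 100 to 2000 ADU on a background of
#' 100 ADU with Gaussian noise of sd 10 ADU - signal-to-noise ratios of 10 to
#' 200, comfortably above the SNR 5 floor the photometry contract assumes.
#' Spot centres sit on pixel centres so the expected inner-box sums are exact
#' finite Gaussian sums.
#'
#' @param seed integer seed (controls jitter, amplitude shuffling and noise).
#' @param noise_sd Gaussian noise sd (ADU).
#' @return as [render_field()].
#' @export
standard_field <- function(seed = 1L, noise_sd = 10) {
  with_seed(seed, {
    grid <- expand.grid(gr = seq_len(10L), gc = seq_len(10L))
    row <- 13L + (grid$gr - 1L) * 25L + sample(-4:4, 100L, replace = TRUE)
    col <- 13L + (grid$gc - 1L) * 25L + sample(-4:4, 100L, replace = TRUE)
    amplitude <- sample(round(exp(seq(log(100), log(2000), length.out = 100L))))
    spots <- data.frame(row = row, col = col, amplitude = amplitude, sigma = 1.5)
    render_field(spots, height = 256L, width = 256L, background = 100,
                 noise = "gaussian", noise_sd = noise_sd, seed = NULL)
  })
}

# expected inner-box sum for a pixel-centred Gaussian spot: finite separable
# sum of the sampled PSF over the measurement square (background-free)
expected_box_sum <- function(amplitude, sigma, inner_side) {
  h <- inner_side %/% 2L
  k <- (-h):h
  g <- sum(exp(-k^2 / (2 * sigma^2)))
  amplitude * g * g
}

#' Write / read an image stack as multi-frame TIFF
#'
#' Intensities are stored as 32-bit float samples scaled by the usual 16-bit
#' detector convention (stored value = ADU / 65535, the same mapping the tiff
#' package applies to 16-bit integer TIFFs); [read_stack_tiff()] reverses the
#' scaling, so a write/read round trip preserves ADU to float precision for
#' intensities up to 65535 ADU.
#'
#' @param stack array T x H x W (or a matrix for a single frame).
#' @param path TIFF path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns a T x H x W array in ADU.
#' @export
write_stack_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(1L, dim(stack)))
  if (max(stack) > 65535 || min(stack) < 0) {
    abort_data("stack intensities must lie in [0, 65535] ADU for TIFF storage")
  }
  frames <- lapply(seq_len(dim(stack)[1]), function(t) {
    matrix(stack[t, , ], nrow = dim(stack)[2]) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  if (!file.exists(path)) abort_lookup(sprintf("TIFF not found: %s", path))
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(frames)) frames <- list(frames)
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  out <- array(0, dim = c(length(frames), H, W))
  for (t in seq_along(frames)) out[t, , ] <- frames[[t]] * 65535
  out
}
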