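# Spot photometry and photobleaching half-life estimation.
#
# Brightness of a spot is the pixel sum of a small square centred on it minus
# the median of a larger concentric square times the inner area: median local
# background subtraction. Half-life is linear interpolation between the two
# time points bracketing half the brightness at the first exposure.

#' Measurement configuration for spot photometry
#'
#' @param inner_side side of the signal square in pixels (odd; default 5).
#' @param outer_side side of the background square in pixels (odd, larger than
#'   `inner_side`; default 15). The median is taken over the full outer
#'   square, inner pixels included; with the defaults the spot occupies well
#'   under half of it, so the median is a robust background estimate.
#' @param noise_tolerance prominence threshold (ADU) for maxima detection.
#' @param recenter_radius Chebyshev radius (px) within which a spot is
#'   re-centred on the brightest pixel frame to frame (default 2).
#' @param use_mean report the inner-square mean instead of its sum.
#' @return object of class `measure_config`.
#' @export
measure_config <- function(inner_side = 5L, outer_side = 15L,
                           noise_tolerance = 30, recenter_radius = 2L,
                           use_mean = FALSE) {
  inner_side <- as.integer(inner_side); outer_side <- as.integer(outer_side)
  if (inner_side %% 2L == 0L || outer_side %% 2L == 0L) {
    abort_data("inner_side and outer_side must be odd so squares centre on a pixel")
  }
  if (inner_side >= outer_side) abort_data("outer_side must exceed inner_side")
  if (noise_tolerance < 0) abort_data("noise_tolerance must be >= 0")
  structure(list(inner_side = inner_side, outer_side = outer_side,
                 noise_tolerance = noise_tolerance,
                 recenter_radius = as.integer(recenter_radius),
                 use_mean = isTRUE(use_mean)),
            class = "measure_config")
}

#' Find local intensity maxima by prominence
#'
#' Detects maxima whose prominence (height above the level at which their
#' catchment merges with that of a higher peak, or above the image minimum for
#' the highest peak) exceeds `cfg$noise_tolerance`. Implemented as a
#' persistence sweep: pixels are processed in decreasing intensity with
#' union-find merging of 8-connected components; a component dying at level v
#' with peak height h is a maximum iff h - v > tolerance. Plateaus contribute
#' a single coordinate (their first pixel in row-major order). A flat image
#' has zero prominence everywhere and yields no maxima.
#'
#' @param image numeric matrix (rows x cols), finite, >= 0.
#' @param cfg a [measure_config()].
#' @return integer matrix with columns `row`, `col` (1-based), sorted
#'   row-major.
#' @export
find_maxima <- function(image, cfg = measure_config()) {
  if (!is.matrix(image) || !is.numeric(image)) abort_data("image must be a numeric matrix")
  if (any(!is.finite(image))) abort_data("image contains non-finite values")
  H <- nrow(image); W <- ncol(image)
  n <- H * W
  v <- as.vector(image)                      # column-major
  # decreasing value; ties broken row-major so plateau roots are deterministic
  rws <- ((seq_len(n) - 1L) %% H) + 1L
  cls <- ((seq_len(n) - 1L) %/% H) + 1L
  ord <- order(-v, rws, cls)

  parent <- integer(n)                        # 0 = not yet activated
  peak_val <- numeric(n); peak_idx <- integer(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  accepted <- integer(0)
  tol <- cfg$noise_tolerance
  for (p in ord) {
    r <- rws[p]; cl <- cls[p]
    parent[p] <- p; peak_val[p] <- v[p]; peak_idx[p] <- p
    # activated 8-neighbours
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- cl + dc
      if (rr < 1L || rr > H || cc < 1L || cc > W) next
      q <- (cc - 1L) * H + rr
      if (parent[q] == 0L) next
      rp <- find(p); rq <- find(q)
      if (rp == rq) next
      # the component with the lower peak dies at the current level
      if (peak_val[rq] > peak_val[rp] ||
          (peak_val[rq] == peak_val[rp] && peak_idx[rq] < peak_idx[rp])) {
        dying <- rp; surv <- rq
      } else {
        dying <- rq; surv <- rp
      }
      if (peak_val[dying] - v[p] > tol) accepted <- c(accepted, peak_idx[dying])
      parent[dying] <- surv
    }
  }
  # surviving roots: prominence relative to the image minimum
  roots <- unique(vapply(which(parent == seq_len(n)), find, integer(1)))
  vmin <- min(v)
  for (rt in roots) {
    if (peak_val[rt] - vmin > tol) accepted <- c(accepted, peak_idx[rt])
  }
  if (length(accepted) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  }
  coords <- cbind(row = rws[accepted], col = cls[accepted])
  coords <- coords[order_rowmajor(coords), , drop = FALSE]
  rownames(coords) <- NULL
  coords
}

clip_square <- function(center, half, H, W) {
  r <- max(1L, center[1] - half):min(H, center[1] + half)
  c <- max(1L, center[2] - half):min(W, center[2] + half)
  list(rows = r, cols = c,
       clipped = length(r) * length(c) < (2L * half + 1L)^2)
}

#' Background-corrected brightness of one spot
#'
#' `B = sum(inner square) - median(outer square) * inner area` (or the inner
#' mean minus the median when `cfg$use_mean` is set). The median is computed
#' over the full outer square including the inner pixels. Squares reaching
#' past the image edge are clipped and flagged via the `"clipped"` attribute.
#'
#' @param image numeric matrix.
#' @param coord integer vector (row, col), 1-based.
#' @param cfg a [measure_config()].
#' @return brightness in ADU with attribute `clipped`.
#' @export
measure_spot <- function(image, coord, cfg = measure_config()) {
  H <- nrow(image); W <- ncol(image)
  coord <- as.integer(coord)
  if (coord[1] < 1L || coord[1] > H || coord[2] < 1L || coord[2] > W) {
    abort_bounds(sprintf("coordinate (%d, %d) outside a %d x %d image",
                         coord[1], coord[2], H, W))
  }
  inner <- clip_square(coord, cfg$inner_side %/% 2L, H, W)
  outer <- clip_square(coord, cfg$outer_side %/% 2L, H, W)
  px_in <- image[inner$rows, inner$cols]
  bg <- stats::median(image[outer$rows, outer$cols])
  b <- if (cfg$use_mean) mean(px_in) - bg else sum(px_in) - bg * length(px_in)
  structure(b, clipped = inner$clipped || outer$clipped)
}

#' Per-spot brightness over a time-lapse stack
#'
#' For each seed coordinate (typically [find_maxima()] on the first frame, as
#' brightness is defined at the first exposure), every frame re-centres the
#' spot on the brightest pixel within `recenter_radius` of its previous
#' position and measures it with [measure_spot()]. A spot whose measurement
#' square leaves the image is truncated there and flagged censored.
#'
#' @param stack numeric array T x H x W.
#' @param seeds integer matrix of (row, col) seeds.
#' @param cfg a [measure_config()].
#' @param frame_interval seconds between frames; the first frame is at
#'   `frame_interval` (a 1 s exposure series starts at t = 1 s).
#' @return list of `brightness_series` objects (fields spot_id, times, values,
#'   censored).
#' @export
measure_timelapse <- function(stack, seeds, cfg = measure_config(),
                              frame_interval = 1) {
  if (length(dim(stack)) != 3L) abort_data("stack must be a T x H x W array")
  Tn <- dim(stack)[1]; H <- dim(stack)[2]; W <- dim(stack)[3]
  seeds <- matrix(as.integer(seeds), ncol = 2)
  lapply(seq_len(nrow(seeds)), function(k) {
    pos <- seeds[k, ]
    times <- numeric(0); values <- numeric(0); censored <- FALSE
    for (t in seq_len(Tn)) {
      frame <- matrix(stack[t, , ], nrow = H)
      if (cfg$recenter_radius > 0L) {
        win <- clip_square(pos, cfg$recenter_radius, H, W)
        sub <- frame[win$rows, win$cols, drop = FALSE]
        best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
        pos <- c(win$rows[best[1]], win$cols[best[2]])
      }
      b <- measure_spot(frame, pos, cfg)
      if (isTRUE(attr(b, "clipped"))) { censored <- TRUE; break }
      times <- c(times, t * frame_interval)
      values <- c(values, as.numeric(b))
    }
    structure(list(spot_id = k, times = times, values = values,
                   censored = censored),
              class = "brightness_series")
  })
}

#' Photobleaching half-life by linear interpolation
#'
#' With reference brightness B0 at the first time point, finds the first
#' adjacent pair of samples bracketing B0/2 (B(t_i) >= B0/2 >= B(t_{i+1})) and
#' interpolates linearly between them. Returns the absolute crossing time and
#' the elapsed time since the first sample; if the series never falls to half,
#' the result is censored at the last observed time.
#'
#' @param series a `brightness_series`, or a list with `times` and `values`.
#' @return list: `censored`, `crossing_time`, `elapsed_half_life` (NA when
#'   censored), `last_time`.
#' @export
half_life <- function(series) {
  times <- series$times; values <- series$values
  if (length(times) < 2L) abort_data("half-life needs at least two time points")
  if (any(!is.finite(values)) || any(!is.finite(times))) {
    abort_data("non-finite values in brightness series")
  }
  if (is.unsorted(times, strictly = TRUE)) abort_data("times must be strictly increasing")
  half <- values[1] / 2
  for (i in seq_len(length(times) - 1L)) {
    if (values[i] >= half && half >= values[i + 1L]) {
      drop <- values[i] - values[i + 1L]
      frac <- if (drop == 0) 0 else (values[i] - half) / drop
      crossing <- times[i] + frac * (times[i + 1L] - times[i])
      return(list(censored = FALSE, crossing_time = crossing,
                  elapsed_half_life = crossing - times[1],
                  last_time = times[length(times)]))
    }
  }
  list(censored = TRUE, crossing_time = NA_real_,
       elapsed_half_life = NA_real_, last_time = times[length(times)])
}

#' Brightness of a condition relative to a reference, in percent
#'
#' `100 * mean(condition) / mean(reference)`, with a delta-method standard
#' deviation for the ratio of means.
#'
#' @param condition,reference numeric vectors of per-spot brightness.
#' @return list: `percent`, `sd_percent`, `n_condition`, `n_reference`.
#' @export
relative_brightness <- function(condition, reference) {
  if (length(condition) == 0L || length(reference) == 0L) {
    abort_data("both brightness vectors must be non-empty")
  }
  mc <- mean(condition); mr <- mean(reference)
  if (mr <= 0) abort_data("reference mean brightness must be positive")
  vc <- if (length(condition) > 1L) stats::var(condition) / length(condition) else 0
  vr <- if (length(reference) > 1L) stats::var(reference) / length(reference) else 0
  ratio <- mc / mr
  sd_ratio <- sqrt(vc / mr^2 + mc^2 * vr / mr^4)
  list(percent = 100 * ratio, sd_percent = 100 * sd_ratio,
       n_condition = length(condition), n_reference = length(reference))
}
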