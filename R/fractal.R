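#' Slice a recording into 2-second analysis sections
#'
#' Detection statistics are computed per section (*sc*): robust location and
#' dispersion of the frame-wise fractal dimension are taken within each
#' section, so a stridulation (which occupies a small fraction of 2 s) shows
#' up as an outlier. Sections are contiguous and non-overlapping; a trailing
#' partial section is discarded, never padded.
#'
#' @param rec an [audio_recording].
#' @param section_seconds section length in seconds (default 2).
#' @return List of sections, each a `strid_section` with `index` (1-based
#'   ordinal), `start_sample` (0-based offset into the recording) and
#'   `samples`. Attribute `discarded_samples` holds the trailing remainder.
#'   A recording shorter than one section yields an empty list with a
#'   warning.
#' @export
slice_sections <- function(rec, section_seconds = 2.0) {
  stopifnot(inherits(rec, "audio_recording"), section_seconds > 0)
  ss <- as.integer(round(section_seconds * rec$sample_rate_hz))
  n <- length(rec$samples) %/% ss
  discarded <- length(rec$samples) - n * ss
  if (n == 0L) {
    warning("recording shorter than one section; no sections emitted",
            call. = FALSE)
    return(structure(list(), discarded_samples = discarded))
  }
  if (discarded > 0L && isTRUE(getOption("stridfd.verbose", FALSE))) {
    message(sprintf("slice_sections: discarded %d trailing samples",
                    discarded))
  }
  out <- lapply(seq_len(n), function(i) {
    start <- (i - 1L) * ss
    structure(list(index = i, start_sample = start,
                   samples = rec$samples[(start + 1L):(start + ss)],
                   sample_rate_hz = rec$sample_rate_hz),
              class = "strid_section")
  })
  structure(out, discarded_samples = discarded)
}

#' Frame boundaries for a non-integer nominal frame size
#'
#' The 2 ms frame at 44.1 kHz is nominally 88.2 samples, which cannot tile
#' integer sample indices. Boundaries are placed at `round(i * frame_size)`
#' so frames are 88 or 89 samples long, the grid accumulates zero drift, and
#' an 88200-sample section yields exactly 1000 (2 ms) or 500 (4 ms) frames.
#'
#' @param section_samples number of samples in the section.
#' @param frame_size_samples nominal frame length in samples (may be
#'   non-integer); must be >= 2 and <= `section_samples`.
#' @return A `frame_grid`: list with `frame_size_samples`, `n_frames`, and
#'   `boundaries` (integer offsets `b_0 = 0 < ... < b_N = section_samples`).
#' @export
frame_boundaries <- function(section_samples, frame_size_samples) {
  if (!(frame_size_samples >= 2 && frame_size_samples <= section_samples)) {
    stop("frame size must be in [2, section length]", call. = FALSE)
  }
  n <- as.integer(round(section_samples / frame_size_samples))
  b <- as.integer(round((0:n) * frame_size_samples))
  b[n + 1L] <- as.integer(section_samples)  # exact tiling at the end
  if (any(diff(b) < 2L)) {
    stop("frame grid contains a frame with fewer than 2 samples",
         call. = FALSE)
  }
  structure(list(frame_size_samples = frame_size_samples,
                 n_frames = n, boundaries = b),
            class = "frame_grid")
}

#' Madogram fractal-dimension estimate of one frame
#'
#' The madogram is the first-order absolute-increment variogram
#' \deqn{V(l) = \frac{1}{2(n-l)} \sum_{t=1}^{n-l} |x_{t+l} - x_t|.}
#' For a self-affine signal V(l) scales like l^H, so the OLS slope of
#' log V(l) against log l over a small lag set estimates the Hurst exponent
#' and D = 2 - slope the fractal dimension. Rough, noise-like frames
#' approach D = 2; smooth ramps give D = 1. The estimator is exactly
#' amplitude-scale-free, which suits low and variable signal-to-noise soil
#' recordings. A degenerate frame (some V(l) = 0, e.g. digital silence)
#' returns D = 1 with attribute `degenerate = TRUE`.
#'
#' @param frame numeric vector of amplitudes, length >= max(lags) + 1 and
#'   >= 3.
#' @param lags integer lag set for the log-log regression (default `c(1, 2)`).
#' @return Fractal-dimension estimate (scalar).
#' @export
madogram_fd <- function(frame, lags = c(1, 2)) {
  n <- length(frame)
  if (n < 3L || n <= max(lags)) {
    stop("frame too short for madogram estimation", call. = FALSE)
  }
  v <- vapply(lags, function(l) {
    mean(abs(frame[(1 + l):n] - frame[1:(n - l)])) / 2
  }, numeric(1))
  if (any(v == 0)) {
    return(structure(1, degenerate = TRUE))
  }
  ll <- log(lags)
  lc <- ll - mean(ll)
  slope <- sum(lc * log(v)) / sum(lc^2)
  2 - slope
}

#' Frame-wise fractal-dimension series of a section
#'
#' Computes one madogram fractal dimension per frame of the given grid,
#' vectorised over frames via cumulative sums of the absolute-increment
#' series (numerically identical to calling [madogram_fd] per frame).
#'
#' @param section a `strid_section` from [slice_sections], or a plain
#'   numeric vector.
#' @param frame_size_samples nominal frame length in samples (88.2 for 2 ms,
#'   176.4 for 4 ms at 44.1 kHz).
#' @param lags madogram lag set (default `c(1, 2)`).
#' @return An `fd_series` object: list with `values` (one D per frame),
#'   `degenerate_frames` (logical), `frame_size_samples`, `section_index`.
#' @export
fd_series <- function(section, frame_size_samples, lags = c(1, 2)) {
  x <- if (inherits(section, "strid_section")) section$samples else
    as.numeric(section)
  idx <- if (inherits(section, "strid_section")) section$index else NA_integer_
  grid <- frame_boundaries(length(x), frame_size_samples)
  b <- grid$boundaries
  nf <- grid$n_frames
  lo <- b[seq_len(nf)]        # 0-based frame starts
  hi <- b[seq_len(nf) + 1L]   # 0-based frame ends (exclusive)
  logv <- matrix(NA_real_, nrow = nf, ncol = length(lags))
  zero <- matrix(FALSE, nrow = nf, ncol = length(lags))
  for (j in seq_along(lags)) {
    l <- lags[j]
    ad <- abs(x[(1 + l):length(x)] - x[1:(length(x) - l)])
    cs <- c(0, cumsum(ad))
    # pairs (t, t+l) fully inside frame i: t in (lo+1)..(hi-l)
    s <- cs[hi - l + 1L] - cs[lo + 1L]
    np <- hi - lo - l
    v <- s / (2 * np)
    zero[, j] <- v <= 0
    logv[, j] <- ifelse(zero[, j], NA_real_, log(v))
  }
  ll <- log(lags)
  lc <- ll - mean(ll)
  slope <- as.numeric(logv %*% lc) / sum(lc^2)
  d <- 2 - slope
  degen <- rowSums(zero) > 0
  d[degen] <- 1
  structure(list(values = d, degenerate_frames = degen,
                 frame_size_samples = frame_size_samples,
                 section_index = idx),
            class = "fd_series")
}

#' Robust standardisation of a fractal-dimension series
#'
#' Converts each frame's D into a fractal distance
#' \deqn{FD_f = (D_f - \mathrm{median}(D_{sc})) / \mathrm{md}(D_{sc})}
#' where md is the (unscaled) median deviation from the median,
#' `median(|D - median(D)|)`. Strongly negative FD marks frames much
#' smoother than the section's noise floor — the signature of a
#' stridulation pulse. If md = 0 (dispersion-free section, e.g. silence)
#' the series is set to all zeros and flagged degenerate: outlier detection
#' is meaningless without dispersion.
#'
#' @param d an `fd_series` or numeric vector of fractal dimensions.
#' @return A `fractal_distance_series`: list with `values`,
#'   `section_median`, `section_md`, `degenerate`, `section_index`.
#' @export
fractal_distance <- function(d) {
  vals <- if (inherits(d, "fd_series")) d$values else as.numeric(d)
  idx <- if (inherits(d, "fd_series")) d$section_index else NA_integer_
  if (length(vals) == 0L) stop("empty fractal-dimension series",
                               call. = FALSE)
  med <- stats::median(vals)
  md <- stats::median(abs(vals - med))
  if (md == 0) {
    fd <- rep(0, length(vals))
    degen <- TRUE
  } else {
    fd <- (vals - med) / md
    degen <- FALSE
  }
  structure(list(values = fd, section_median = med, section_md = md,
                 degenerate = degen, section_index = idx),
            class = "fractal_distance_series")
}

#' Linearly interpolate a series to a target length
#'
#' Piecewise-linear interpolation on the normalised index domain \[0, 1\]
#' with endpoints aligned, used to bring the 4 ms fractal-distance series
#' (500 points) onto the 2 ms grid (1000 points) before summation.
#'
#' @param series a `fractal_distance_series` or numeric vector, length >= 2.
#' @param n_out target length (default 1000).
#' @return Object of the same kind with `values` of length `n_out`.
#' @export
interpolate_to <- function(series, n_out = 1000) {
  vals <- if (inherits(series, "fractal_distance_series")) series$values
          else as.numeric(series)
  if (length(vals) < 2L) {
    stop("need at least 2 points to interpolate", call. = FALSE)
  }
  y <- stats::approx(x = seq(0, 1, length.out = length(vals)), y = vals,
                     xout = seq(0, 1, length.out = n_out))$y
  if (inherits(series, "fractal_distance_series")) {
    series$values <- y
    series
  } else {
    y
  }
}

#' Summed fractal distance of a section
#'
#' The detection statistic: the element-wise sum of the 2 ms fractal-distance
#' series and the 4 ms series interpolated to the 2 ms grid. Both frame
#' sizes capture individual stridulation pulses, so summing separates pulses
#' further (downwards) from background noise, whose FD stays near zero.
#' A section is degenerate when either constituent series is degenerate
#' (md = 0); its SFD is all zeros and it is excluded from detection.
#'
#' @param section a `strid_section` (or numeric vector of a preprocessed
#'   section's samples).
#' @param frame_sizes nominal frame lengths in samples, fine first
#'   (default `c(88.2, 176.4)` = 2 ms and 4 ms at 44.1 kHz).
#' @param lags madogram lag set.
#' @return An `sfd_series`: list with `values` (length = fine-grid frame
#'   count, 1000 at the defaults), `degenerate`, `section_index`, and the
#'   two constituent `fractal_distance_series` (`fd_fine`, `fd_coarse`).
#' @export
sfd <- function(section, frame_sizes = c(88.2, 176.4), lags = c(1, 2)) {
  stopifnot(length(frame_sizes) == 2L, frame_sizes[1] < frame_sizes[2])
  d_fine <- fd_series(section, frame_sizes[1], lags)
  d_coarse <- fd_series(section, frame_sizes[2], lags)
  fd_fine <- fractal_distance(d_fine)
  fd_coarse <- fractal_distance(d_coarse)
  n_out <- length(fd_fine$values)
  fd_coarse_i <- interpolate_to(fd_coarse, n_out)
  degen <- fd_fine$degenerate || fd_coarse$degenerate
  vals <- if (degen) rep(0, n_out) else fd_fine$values + fd_coarse_i$values
  structure(list(values = vals, degenerate = degen,
                 section_index = if (inherits(section, "strid_section"))
                   section$index else NA_integer_,
                 fd_fine = fd_fine, fd_coarse = fd_coarse_i),
            class = "sfd_series")
}

#' Simulate fractional Brownian motion
#'
#' Exact simulation via Cholesky factorisation of the fractional Gaussian
#' noise covariance, used to validate the madogram estimator: an fBm path
#' with Hurst exponent H has theoretical fractal dimension D = 2 - H.
#'
#' @param n path length.
#' @param hurst Hurst exponent in (0, 1).
#' @param n_paths number of independent paths.
#' @param seed RNG seed (integer).
#' @return Numeric matrix `n` x `n_paths`; each column one fBm path.
#' @export
simulate_fbm <- function(n, hurst, n_paths = 1, seed = 1) {
  stopifnot(n >= 2, hurst > 0, hurst < 1)
  k <- 0:(n - 1)
  acf <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                  abs(k - 1)^(2 * hurst))
  gamma_mat <- stats::toeplitz(acf)
  l <- t(chol(gamma_mat))
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n * n_paths), nrow = n)
  })
  apply(l %*% z, 2, cumsum)
}

#' Per-frame diagnostic table of a section
#'
#' Debug view of the full fractal computation on the fine (2 ms) grid:
#' both fractal-dimension series, both fractal-distance series (the 4 ms
#' one interpolated), and the summed fractal distance. Write it with
#' [utils::write.csv] to inspect a section alongside a spectrogram.
#'
#' @inheritParams sfd
#' @return A data frame with columns `section_index`, `frame_index`,
#'   `d_fine`, `d_coarse_interp`, `fd_fine`, `fd_coarse_interp`, `sfd`.
#' @export
sfd_table <- function(section, frame_sizes = c(88.2, 176.4),
                      lags = c(1, 2)) {
  s <- sfd(section, frame_sizes, lags)
  n <- length(s$values)
  d_fine <- fd_series(section, frame_sizes[1], lags)
  d_coarse <- fd_series(section, frame_sizes[2], lags)
  data.frame(
    section_index = s$section_index,
    frame_index = seq_len(n),
    d_fine = d_fine$values,
    d_coarse_interp = interpolate_to(d_coarse$values, n),
    fd_fine = s$fd_fine$values,
    fd_coarse_interp = s$fd_coarse$values,
    sfd = s$values
  )
}
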