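test_that("slice_sections tiles the recording and drops the remainder", {
  rec <- audio_recording(stats::rnorm(10 * 44100), 44100)
  secs <- slice_sections(rec)
  expect_length(secs, 5L)
  expect_equal(vapply(secs, function(s) length(s$samples), integer(1)),
               rep(88200L, 5))
  expect_equal(vapply(secs, `[[`, integer(1), "start_sample"),
               (0:4) * 88200L)

  one <- slice_sections(audio_recording(stats::rnorm(88200), 44100))
  expect_length(one, 1L)

  part <- slice_sections(audio_recording(stats::rnorm(100000), 44100))
  expect_length(part, 1L)
  expect_equal(attr(part, "discarded_samples"), 100000L - 88200L)

  expect_warning(
    short <- slice_sections(audio_recording(stats::rnorm(1000), 44100)),
    "shorter")
  expect_length(short, 0L)
})

test_that("frame grids tile sections exactly with rounded boundaries", {
  g <- frame_boundaries(88200, 88.2)
  expect_equal(g$n_frames, 1000L)
  expect_equal(g$boundaries[1:4], c(0L, 88L, 176L, 265L))
  expect_equal(g$boundaries[1001], 88200L)
  expect_true(all(diff(g$boundaries) >= 2))
  expect_equal(sum(diff(g$boundaries)), 88200L)

  g4 <- frame_boundaries(88200, 176.4)
  expect_equal(g4$n_frames, 500L)

  g2 <- frame_boundaries(100, 50)
  expect_equal(g2$boundaries, c(0L, 50L, 100L))

  expect_error(frame_boundaries(50, 100), "frame size")
})

test_that("madogram estimator matches hand computation and conventions", {
  # ramp [0,1,2,3]: V(1) = 0.5, V(2) = 1, slope 1, D = 1
  expect_equal(as.numeric(madogram_fd(c(0, 1, 2, 3))), 1)
  # constant frame: degenerate convention D = 1
  d <- madogram_fd(rep(0.7, 100))
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "degenerate"))
  expect_error(madogram_fd(c(1, 2)), "too short")
})

test_that("madogram is exactly amplitude-scale-free", {
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- stats::rnorm(200)
      c0 <- stats::runif(1, 1e-4, 1e4)
      expect_equal(as.numeric(madogram_fd(c0 * x)),
                   as.numeric(madogram_fd(x)), tolerance = 1e-9)
    }
  })
})

test_that("fd_series equals per-frame madogram_fd and flags silence", {
  withr::with_seed(3, x <- stats::rnorm(88200))
  s <- fd_series(make_section(x), 88.2)
  expect_length(s$values, 1000L)
  g <- frame_boundaries(88200, 88.2)
  picks <- c(1L, 2L, 500L, 1000L)
  for (i in picks) {
    frame <- x[(g$boundaries[i] + 1):(g$boundaries[i + 1])]
    expect_equal(s$values[i], as.numeric(madogram_fd(frame)),
                 tolerance = 1e-12)
  }
  const <- fd_series(make_section(rep(0.5, 88200)), 88.2)
  expect_true(all(const$values == 1))
  expect_true(all(const$degenerate_frames))
})

test_that("fractal distance is the md-standardised series", {
  fd <- fractal_distance(c(1.0, 1.2, 1.4, 1.6, 3.0))
  expect_equal(fd$values, c(-2, -1, 0, 1, 8))
  expect_equal(fd$section_median, 1.4)
  expect_equal(fd$section_md, 0.2)
  expect_false(fd$degenerate)

  flat <- fractal_distance(rep(1.3, 50))
  expect_true(flat$degenerate)
  expect_true(all(flat$values == 0))

  withr::with_seed(4, {
    for (i in 1:20) {
      v <- fractal_distance(stats::rnorm(101, 1.5, 0.1))
      expect_lt(abs(stats::median(v$values)), 1e-12)
    }
  })
})

test_that("linear interpolation preserves endpoints and is identity at
           matching lengths", {
  y <- interpolate_to(c(0, 1), 1000)
  expect_equal(y, seq(0, 1, length.out = 1000))

  withr::with_seed(5, v <- stats::rnorm(500))
  out <- interpolate_to(v, 1000)
  expect_length(out, 1000L)
  expect_equal(out[1], v[1])
  expect_equal(out[1000], v[500])

  expect_equal(interpolate_to(v, 500), v, tolerance = 1e-12)
  expect_error(interpolate_to(1), "at least 2")
})

test_that("sfd sums the 2 ms and interpolated 4 ms series on the fine grid", {
  withr::with_seed(6, x <- stats::rnorm(88200))
  sec <- make_section(x)
  s <- sfd(sec)
  expect_length(s$values, 1000L)
  fd2 <- fractal_distance(fd_series(sec, 88.2))
  fd4 <- interpolate_to(fractal_distance(fd_series(sec, 176.4)), 1000)
  expect_equal(s$values, fd2$values + fd4$values, tolerance = 1e-12)
  expect_lt(abs(stats::median(fd2$values)), 1e-12)

  silent <- sfd(make_section(rep(0, 88200)))
  expect_true(silent$degenerate)
  expect_true(all(silent$values == 0))

  # bit-for-bit reproducible on identical input
  expect_identical(s$values, sfd(sec)$values)
})

test_that("fBm paths recover the theoretical fractal dimension", {
  # quick sanity at one Hurst value; the full sweep runs in the
  # acceptance suite
  paths <- simulate_fbm(512, hurst = 0.5, n_paths = 50, seed = 9)
  d <- apply(paths, 2, function(p) as.numeric(madogram_fd(p)))
  expect_lt(abs(mean(d) - 1.5), 0.1)
})

test_that("the diagnostic table reproduces the sfd decomposition", {
  withr::with_seed(8, x <- stats::rnorm(88200))
  tab <- sfd_table(make_section(x, index = 3L))
  expect_equal(nrow(tab), 1000L)
  expect_equal(tab$sfd, tab$fd_fine + tab$fd_coarse_interp, tolerance = 1e-12)
  expect_equal(tab$sfd, sfd(make_section(x))$values, tolerance = 1e-12)
  expect_true(all(tab$section_index == 3L))
})
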