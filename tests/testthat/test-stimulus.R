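# Binary stimulus pipeline: bar frames, sweeps, U-schedule, camera reduction.

test_that("bar frames cover exactly the requested columns", {
  full <- make_bar_frame(0, 1000)
  expect_equal(dim(full), c(6L, 1000L))
  expect_equal(sum(full), 6000L)

  f <- make_bar_frame(100, 50)
  expect_true(all(rowSums(f) == 50L))
  expect_true(all(f[, 101:150] == 1L))
  expect_equal(sum(f[, -(101:150)]), 0L)

  # wrap-around at the right edge keeps the pixel count constant
  w <- make_bar_frame(995, 10)
  expect_true(all(rowSums(w) == 10L))
  expect_true(all(w[, c(996:1000, 1:5)] == 1L))

  expect_error(make_bar_frame(1000, 10), "bar_position")
  expect_error(make_bar_frame(0, 10, noise_prob = 1), "noise_prob")
})

test_that("frame noise is reproducible and has the binomial expectation", {
  f1 <- make_bar_frame(100, 50, noise_prob = 0.01, rng_seed = 7)
  f2 <- make_bar_frame(100, 50, noise_prob = 0.01, rng_seed = 7)
  expect_identical(f1, f2)
  f3 <- make_bar_frame(100, 50, noise_prob = 0.01, rng_seed = 8)
  expect_false(identical(f1, f3))

  # Monte-Carlo check of the expected extra ones: noise * (6000 - 6 * width)
  n_off <- 6000 - 6 * 50
  extra <- vapply(1:50, function(s) {
    sum(make_bar_frame(100, 50, noise_prob = 0.01, rng_seed = s)) - 300L
  }, integer(1))
  expected <- 0.01 * n_off
  se <- sqrt(n_off * 0.01 * 0.99 / 50)
  expect_lt(abs(mean(extra) - expected), 5 * se)

  # the caller's RNG stream is not disturbed
  set.seed(1); a <- stats::runif(1)
  set.seed(1); invisible(make_bar_frame(0, 10, 0.5, rng_seed = 99))
  expect_identical(stats::runif(1), a)
})

test_that("the release-probability schedule satisfies its three constraints", {
  # minimal mirrored schedule
  s2 <- u_schedule(2, U_min = 0.05, U_max = 0.6)
  expect_equal(s2$U1, c(0.6, 0.05))
  expect_equal(s2$U2, c(0.05, 0.6))

  for (n in c(2, 10, 200)) {
    for (bounds in list(c(0.05, 0.6), c(0.1, 0.9))) {
      s <- u_schedule(n, bounds[1], bounds[2])
      right <- s$direction == "right"
      # (a, b) mean asymmetries
      expect_gt(mean(s$U1[right]), mean(s$U1[!right]))
      expect_gt(mean(s$U2[!right]), mean(s$U2[right]))
      # (c) exact mirror multisets
      expect_identical(sort(s$U1[right]), sort(s$U2[!right]))
      expect_identical(sort(s$U2[right]), sort(s$U1[!right]))
      expect_equal(mean(s$U1[right]), mean(s$U2[!right]))
      # per-step discriminability: preferred strictly above null everywhere
      expect_true(all(s$U1[right] > s$U2[right]))
      expect_true(all(s$U2[!right] > s$U1[!right]))
      expect_true(all(s$U1 >= bounds[1] & s$U1 <= bounds[2]))
    }
  }
  expect_error(u_schedule(3), "even")
  expect_error(u_schedule(10, U_min = 0.6, U_max = 0.2), "U_min")
  expect_error(u_schedule(10, U_min = 0, U_max = 0.5), "U_min")
})

test_that("direction sequences shift the bar and label directions", {
  s <- make_direction_sequence(n_steps = 2, bar_width = 10, shift_per_step = 5)
  expect_equal(s$directions, c("right", "left"))
  expect_equal(length(s$frames), 2L)
  expect_equal((s$positions[1] - s$positions[2]) %% 1000, 5)

  # consecutive right-step frames are pure circular translations
  s4 <- make_direction_sequence(n_steps = 8, bar_width = 10, shift_per_step = 7)
  f1 <- s4$frames[[1]]; f2 <- s4$frames[[2]]
  shifted <- f1[, c(1000 - 7 + 1:7, 1:(1000 - 7))]
  expect_equal(unclass(f2), unclass(shifted), ignore_attr = TRUE)

  # identical seeds give bit-identical sequences, including noise
  a <- make_direction_sequence(n_steps = 4, noise_prob = 0.02, rng_seed = 3)
  b <- make_direction_sequence(n_steps = 4, noise_prob = 0.02, rng_seed = 3)
  expect_identical(a, b)
  expect_error(make_direction_sequence(n_steps = 5), "even")
})

test_that("the 100-row camera image collapses onto 6 OR-blocks", {
  raw <- matrix(0L, 100, 1000)
  expect_equal(sum(downsample_camera(raw)), 0L)

  # a vertical bar across all camera rows activates every unit
  raw[, 201:250] <- 1L
  f <- downsample_camera(raw)
  expect_true(all(rowSums(f) == 50L))

  # a bar confined to the first block (rows 1-17) activates only unit 1
  raw2 <- matrix(0L, 100, 1000)
  raw2[1:17, 301:310] <- 1L
  f2 <- downsample_camera(raw2)
  expect_equal(rowSums(f2), c(10L, 0L, 0L, 0L, 0L, 0L))

  expect_error(downsample_camera(matrix(0L, 99, 1000)), "100 rows")
})

test_that("frames encode into spike trains that conserve the pixel count", {
  zero <- matrix(0L, 6, 1000)
  expect_true(all(lengths(frame_to_spikes(zero)) == 0L))

  f <- make_bar_frame(100, 50)
  trains <- frame_to_spikes(f)
  expect_true(all(lengths(trains) == 50L))
  expect_equal(sum(lengths(trains)), sum(f))
  expect_equal(trains[[1]], as.numeric(100:149))  # 0-based times in ms

  # translation of the frame shifts all spike times identically
  g <- make_bar_frame(107, 50)
  expect_equal(frame_to_spikes(g)[[1]], trains[[1]] + 7)

  # noisy frames still conserve the count
  h <- make_bar_frame(0, 10, noise_prob = 0.05, rng_seed = 5)
  expect_equal(sum(lengths(frame_to_spikes(h))), sum(h))
})

test_that("frames round-trip through CSV and PGM and grayscale binarizes at 0.5", {
  tmp <- withr::local_tempdir()
  f <- make_bar_frame(10, 5, noise_prob = 0.1, rng_seed = 2)
  p1 <- file.path(tmp, "f.csv")
  write_frame_csv(f, p1)
  expect_equal(unclass(read_frame_csv(p1)), unclass(f), ignore_attr = TRUE)

  p2 <- file.path(tmp, "f.pgm")
  write_frame_pgm(f, p2)
  expect_equal(unclass(read_frame_pgm(p2)), unclass(f), ignore_attr = TRUE)

  img <- matrix(c(0, 100, 127, 128, 200, 255), 2, 3)
  expect_equal(as.vector(binarize_image(img)), c(0L, 0L, 0L, 1L, 1L, 1L))
})
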