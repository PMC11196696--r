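test_that("hamming kernel has the length forced by the radius rule", {
  # radius 0.1 s at fs 100 -> 2*10+1 = 21 taps; a unit impulse returns
  # the normalized kernel itself in the interior
  x <- c(rep(0, 30), 1, rep(0, 30))
  y <- hamming_smooth(x, radius = 0.1, fs = 100)
  kern <- signal::hamming(21); kern <- kern / sum(kern)
  expect_equal(y[21:41], as.numeric(kern))
  expect_equal(sum(y), 1)  # unit DC gain
})

test_that("unit DC gain: constant signals pass through both filters", {
  x <- rep(2.5, 60)
  expect_equal(hamming_smooth(x, 0.1, fs = 100), x)
  expect_equal(rect_filter(x, 0.1, fs = 100), x)
})

test_that("rect filter turns an impulse into a 1/21 plateau", {
  x <- c(rep(0, 30), 1, rep(0, 30))
  y <- rect_filter(x, radius = 0.1, fs = 100)
  expect_equal(y[21:41], rep(1 / 21, 21))
  expect_equal(y[c(20, 42)], c(0, 0))
})

test_that("rect filter merges closely adjoining double peaks", {
  x <- rep(0, 80); x[c(40, 43)] <- 1  # 3 samples apart, kernel length 21
  y <- rect_filter(x, radius = 0.1, fs = 100)
  top <- which(y == max(y))
  expect_true(all(diff(top) == 1))  # single contiguous maximal region
})

test_that("filters reject kernels longer than the signal", {
  expect_error(hamming_smooth(rnorm(10), 0.1, fs = 100), "longer")
  expect_error(rect_filter(rnorm(10), 0.1, fs = 100), "longer")
})

test_that("detector finds exactly the well-separated tall peaks", {
  withr::local_seed(21)
  idx <- c(100, 220, 340, 480, 600)
  x <- peaky_signal(idx, 700)
  ev <- detect_peaks(x, fs = 100)
  expect_length(ev$times, 5L)
  expect_equal(round(ev$times * 100) + 1, idx, tolerance = 1e-9)
})

test_that("the 50 ms rule keeps the higher of two close peaks", {
  x <- rep(0, 200)
  x[100] <- 0.9
  x[103] <- 0.8  # 30 ms away
  ev <- detect_peaks(x, fs = 100)
  expect_length(ev$times, 1L)
  expect_equal(ev$times, 99 / 100)
})

test_that("tied close peaks resolve to the earlier one", {
  x <- rep(0, 200)
  x[100] <- 0.9
  x[103] <- 0.9
  ev <- detect_peaks(x, fs = 100)
  expect_length(ev$times, 1L)
  expect_equal(ev$times, 99 / 100)
})

test_that("plateau maxima resolve to the plateau midpoint", {
  x <- rep(0, 100)
  x[40:44] <- 1  # 5-sample plateau, midpoint index 42
  ev <- detect_peaks(x, fs = 100)
  expect_equal(ev$times, 41 / 100)
})

test_that("empty and constant signals yield zero events with a warning", {
  expect_warning(ev <- detect_peaks(rep(0, 100), fs = 100), "constant")
  expect_length(ev$times, 0L)
  expect_warning(ev2 <- detect_peaks(numeric(0), fs = 100), "empty")
  expect_length(ev2$times, 0L)
})

test_that("detected events always respect the minimum distance", {
  withr::local_seed(22)
  for (i in 1:10) {
    x <- abs(rnorm(400))
    ev <- detect_peaks(x, fs = 100)
    if (length(ev$times) >= 2L)
      expect_true(all(diff(ev$times) >= 0.05 - 1e-12))
  }
})

test_that("full extraction recovers a synthetic walk within 20 ms", {
  sim <- simulate_walk(walk_scenario(n_steps = 8, seed = 101))
  ev <- extract_footsteps(sim$traces)
  expect_length(ev$times, 8L)
  expect_true(all(abs(ev$times - sim$truth$step_times) <= 0.02))
})

test_that("a single sensor alone recovers nearly all steps", {
  sim <- simulate_walk(walk_scenario(n_steps = 8, seed = 101))
  for (s in 1:3) {
    ev <- extract_footsteps(sim$traces[s])
    expect_gte(length(ev$times), 7L)
    expect_lte(length(ev$times), 8L)
  }
})

test_that("zero-input traces produce zero events", {
  traces <- lapply(1:3, function(i) seismic_trace(rep(0, 500), fs = 100))
  suppressWarnings(ev <- extract_footsteps(traces))
  expect_length(ev$times, 0L)
})

test_that("event lists are invariant to positive amplitude scaling", {
  sim <- simulate_walk(walk_scenario(n_steps = 8, seed = 102))
  ev1 <- extract_footsteps(sim$traces)
  for (s in c(1e-4, 7, 1e5)) {
    scaled <- lapply(sim$traces, function(tr) {
      tr$samples <- tr$samples * s
      tr
    })
    ev2 <- extract_footsteps(scaled)
    expect_identical(ev2$times, ev1$times)
  }
})

test_that("configuration validation rejects bad values and unknown keys", {
  expect_error(seismogait_config(height_percentile = 0), "percentile")
  expect_error(seismogait_config(min_distance_s = -1))
  expect_error(seismogait_config(not_a_key = 1), "unused argument")
  cfg <- seismogait_config()
  expect_equal(cfg$se_radius_s, 0.2)
  expect_equal(cfg$hamming_radius_s, 0.1)
  expect_equal(cfg$rect_radius_s, 0.1)
  expect_equal(cfg$min_distance_s, 0.05)
  expect_equal(cfg$height_percentile, 95)
  expect_equal(cfg$walkway_length_cm, 488)
  expect_equal(cfg$fs, 100)
})
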