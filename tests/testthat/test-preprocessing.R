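test_that("detrend_normalize min-max scales then removes the mean", {
  tr <- seismic_trace(c(0, 5, 10), fs = 100)
  expect_equal(detrend_normalize(tr)$samples, c(-0.5, 0, 0.5))
})

test_that("detrend_normalize output always has zero mean", {
  withr::local_seed(1)
  for (i in 1:20) {
    tr <- seismic_trace(rnorm(sample(10:200, 1), sd = runif(1, 0.1, 50)),
                        fs = 100)
    expect_lt(abs(mean(detrend_normalize(tr)$samples)), 1e-12)
  }
})

test_that("detrend_normalize is invariant to positive affine transforms", {
  withr::local_seed(2)
  for (i in 1:10) {
    x <- rnorm(100)
    a <- runif(1, 0.01, 100); b <- runif(1, -50, 50)
    y1 <- detrend_normalize(seismic_trace(x, fs = 100))$samples
    y2 <- detrend_normalize(seismic_trace(a * x + b, fs = 100))$samples
    expect_equal(y1, y2, tolerance = 1e-12)
  }
})

test_that("constant trace normalizes to zeros with a warning", {
  tr <- seismic_trace(c(3, 3, 3), fs = 100)
  expect_warning(out <- detrend_normalize(tr), "constant")
  expect_equal(out$samples, c(0, 0, 0))
})

test_that("align_traces returns identical-grid traces unchanged", {
  withr::local_seed(3)
  traces <- lapply(1:2, function(i)
    seismic_trace(rnorm(80), fs = 100, t0 = 1, sensor_id = paste0("s", i)))
  out <- align_traces(traces)
  expect_equal(out[[1]]$samples, traces[[1]]$samples)
  expect_equal(out[[2]]$samples, traces[[2]]$samples)
  expect_equal(out[[1]]$t0, 1)
})

test_that("half-sample offset alignment interpolates linear midpoints", {
  x <- as.numeric(1:10)
  a <- seismic_trace(x, fs = 100, t0 = 0)
  b <- seismic_trace(x, fs = 100, t0 = 0.005)  # half a sample late
  out <- align_traces(list(a, b))
  # common grid starts at 0.005; trace a is sampled between its own
  # samples, so values are midpoints of consecutive integers
  expect_equal(out[[1]]$samples[1:3], c(1.5, 2.5, 3.5))
  expect_equal(out[[2]]$samples[1:3], c(1, 2, 3))
})

test_that("disjoint time ranges refuse to align", {
  a <- seismic_trace(1:10, fs = 100, t0 = 0)
  b <- seismic_trace(1:10, fs = 100, t0 = 5)
  expect_error(align_traces(list(a, b)), "overlap")
})

test_that("mismatched sampling rates refuse to align", {
  a <- seismic_trace(1:10, fs = 100)
  b <- seismic_trace(1:10, fs = 90)
  expect_error(align_traces(list(a, b)), "1%")
})

test_that("aggregate_max with window 0 is the pointwise max across sensors", {
  a <- seismic_trace(c(1, 0, 0), fs = 100)
  b <- seismic_trace(c(0, 0, 1), fs = 100)
  expect_equal(aggregate_max(list(a, b), window = 0)$samples, c(1, 0, 1))
  expect_equal(aggregate_max(list(a), window = 0)$samples, a$samples)
})

test_that("aggregate_max rolling window matches a brute-force rolling max", {
  tr <- seismic_trace(c(0, 1, 0), fs = 100)
  # window of 2 samples' width: +-1 sample
  expect_equal(aggregate_max(list(tr), window = 2 / 100)$samples, c(1, 1, 1))
  withr::local_seed(4)
  x <- rnorm(60)
  out <- aggregate_max(list(seismic_trace(x, fs = 100)),
                       window = 0.08)$samples
  brute <- vapply(seq_along(x), function(i)
    max(x[max(1, i - 4):min(length(x), i + 4)]), 0)
  expect_equal(out, brute)
})

test_that("aggregate_max dominates every input and is monotone", {
  withr::local_seed(5)
  xs <- lapply(1:3, function(i) rnorm(100))
  traces <- lapply(xs, seismic_trace, fs = 100)
  agg <- aggregate_max(traces, window = 0.08)$samples
  for (x in xs) expect_true(all(agg >= x))
  xs2 <- xs; xs2[[2]] <- xs2[[2]] + abs(rnorm(100))  # raise one sensor
  agg2 <- aggregate_max(lapply(xs2, seismic_trace, fs = 100),
                        window = 0.08)$samples
  expect_true(all(agg2 >= agg))
})

test_that("aggregating a trace with itself equals its rolling max", {
  withr::local_seed(6)
  tr <- seismic_trace(rnorm(50), fs = 100)
  expect_equal(aggregate_max(list(tr, tr), window = 0.08)$samples,
               aggregate_max(list(tr), window = 0.08)$samples)
})

test_that("empty trace list is rejected", {
  expect_error(aggregate_max(list()), "empty")
})
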