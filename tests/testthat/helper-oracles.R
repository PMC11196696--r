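# Independent brute-force oracles for the morphology operators: plain
# double loops over the clipped SE support, no vectorization shared with
# the implementation.

brute_erode <- function(x, heights) {
  n <- length(x)
  r <- (length(heights) - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (k in -r:r) {
      j <- i + k
      if (j >= 1 && j <= n) best <- min(best, x[j] - heights[k + r + 1])
    }
    out[i] <- best
  }
  out
}

brute_dilate <- function(x, heights) {
  n <- length(x)
  r <- (length(heights) - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- -Inf
    for (k in -r:r) {
      j <- i - k
      if (j >= 1 && j <= n) best <- max(best, x[j] + heights[k + r + 1])
    }
    out[i] <- best
  }
  out
}

brute_opening <- function(x, h) brute_dilate(brute_erode(x, h), h)
brute_closing <- function(x, h) brute_erode(brute_dilate(x, h), h)
brute_ctf <- function(x, h) x - (brute_opening(x, h) + brute_closing(x, h)) / 2

# random SE of odd length <= 9, flat or spherical profile
random_se <- function(fs = 100) {
  half <- sample(0:4, 1)
  if (stats::runif(1) < 0.5) {
    structuring_element(half / fs, fs = fs, shape = "flat")
  } else {
    structuring_element(half / fs, fs = fs, shape = "spherical",
                        height = stats::runif(1, 0.1, 2))
  }
}

# well-separated synthetic peak train on a noise floor, for detector tests
peaky_signal <- function(peak_idx, n, width = 3, height = 1, floor_sd = 0.01) {
  x <- stats::rnorm(n, 0, floor_sd)
  for (p in peak_idx) {
    k <- seq(max(1, p - width), min(n, p + width))
    x[k] <- x[k] + height * exp(-(k - p)^2 / (2 * (width / 2)^2))
  }
  x
}
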