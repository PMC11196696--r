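#' Structuring element for 1-D grayscale morphology
#'
#' Discretizes a symmetric structuring element (SE) of the given temporal
#' radius. The `"spherical"` shape is the upper half of a circle scaled to
#' peak height `height`: `h[k] = height * sqrt(1 - (k/r)^2)` for offsets
#' `k = -r, ..., r` in samples, `r = round(radius * fs)`. The `"flat"`
#' shape has all heights zero, reducing erosion/dilation to running
#' min/max. The default 0.2 s radius matches the duration of an average
#' single footstep during human walking; at 100 Hz this gives a 41-sample
#' SE.
#'
#' @param radius SE radius in seconds (default 0.2).
#' @param fs Sampling rate in Hz the SE will be applied at.
#' @param shape `"spherical"` (default) or `"flat"`.
#' @param height Peak height of the spherical profile on the normalized
#'   amplitude scale (default 1); ignored for flat SEs.
#' @return Object of class `structuring_element` with fields `radius`,
#'   `fs`, `shape`, `height`, `heights` (odd-length symmetric numeric).
#' @examples
#' se <- structuring_element(0.2, fs = 100)
#' length(se$heights)  # 41
#' @export
structuring_element <- function(radius = 0.2, fs = 100,
                                shape = c("spherical", "flat"), height = 1) {
  shape <- match.arg(shape)
  if (radius < 0) stop("'radius' must be >= 0")
  r <- round(radius * fs)
  k <- seq.int(-r, r)
  heights <- if (shape == "flat" || r == 0L) rep(0, 2L * r + 1L)
             else height * sqrt(pmax(0, 1 - (k / r)^2))
  structure(list(radius = radius, fs = fs, shape = shape,
                 height = height, heights = heights),
            class = "structuring_element")
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("<structuring_element> %s, radius %g s @ %g Hz (%d samples)\n",
              x$shape, x$radius, x$fs, length(x$heights)))
  invisible(x)
}

# Core operators on plain numeric vectors. Boundary policy: shrinking
# window -- the min/max runs over the in-bounds part of the SE support
# only, so no extreme values are fabricated at the walk's first and last
# steps. Vectorized over SE offsets: O(n * |SE|) with vector ops.
mm_erode <- function(x, heights) {
  n <- length(x)
  r <- (length(heights) - 1L) %/% 2L
  if (length(heights) > n) stop("structuring element longer than signal")
  out <- rep(Inf, n)
  for (k in seq.int(-r, r)) {
    idx <- seq_len(n) + k
    ok <- idx >= 1L & idx <= n
    v <- rep(Inf, n)
    v[ok] <- x[idx[ok]] - heights[k + r + 1L]
    out <- pmin(out, v)
  }
  out
}

mm_dilate <- function(x, heights) {
  n <- length(x)
  r <- (length(heights) - 1L) %/% 2L
  if (length(heights) > n) stop("structuring element longer than signal")
  out <- rep(-Inf, n)
  for (k in seq.int(-r, r)) {
    idx <- seq_len(n) - k
    ok <- idx >= 1L & idx <= n
    v <- rep(-Inf, n)
    v[ok] <- x[idx[ok]] + heights[k + r + 1L]
    out <- pmax(out, v)
  }
  out
}

# Accept numeric vectors or seismic_trace objects uniformly.
morph_apply <- function(signal, f) {
  if (inherits(signal, "seismic_trace")) {
    signal$samples <- f(signal$samples)
    signal
  } else {
    f(as.numeric(signal))
  }
}

#' Grayscale erosion
#'
#' `out[i] = min_k (signal[i + k] - h[k])` over the in-bounds SE support
#' (shrinking-window boundary policy).
#'
#' @param signal Numeric vector or [seismic_trace()].
#' @param se A [structuring_element()].
#' @return Same type as `signal`.
#' @export
erode <- function(signal, se) {
  stopifnot(inherits(se, "structuring_element"))
  morph_apply(signal, function(x) mm_erode(x, se$heights))
}

#' Grayscale dilation
#'
#' `out[i] = max_k (signal[i - k] + h[k])` over the in-bounds SE support.
#' For the symmetric SEs used here, dilation is the dual of erosion:
#' `dilate(x) = -erode(-x)`.
#'
#' @inheritParams erode
#' @return Same type as `signal`.
#' @export
dilate <- function(signal, se) {
  stopifnot(inherits(se, "structuring_element"))
  morph_apply(signal, function(x) mm_dilate(x, se$heights))
}

#' Morphological opening (erosion then dilation)
#'
#' Removes positive spikes narrower than the SE; anti-extensive
#' (`opening(x) <= x`) and idempotent.
#'
#' @inheritParams erode
#' @return Same type as `signal`.
#' @export
opening <- function(signal, se) {
  stopifnot(inherits(se, "structuring_element"))
  morph_apply(signal, function(x) mm_dilate(mm_erode(x, se$heights),
                                            se$heights))
}

#' Morphological closing (dilation then erosion)
#'
#' Fills negative dips narrower than the SE; extensive
#' (`closing(x) >= x`) and idempotent.
#'
#' @inheritParams erode
#' @return Same type as `signal`.
#' @export
closing <- function(signal, se) {
  stopifnot(inherits(se, "structuring_element"))
  morph_apply(signal, function(x) mm_erode(mm_dilate(x, se$heights),
                                           se$heights))
}

#' Compound top-hat filter (CTF)
#'
#' `ctf(x) = x - (opening(x) + closing(x)) / 2`. The average of opening
#' and closing tracks the slowly varying baseline while ignoring
#' transients narrower than the SE, so subtracting it attenuates
#' low-frequency noise (building sway, sensor drift) and preserves
#' footstep transients. Unlike a bandpass filter the CTF is robust to
#' frequency mixing between noise and signal, and it attenuates baseline
#' more effectively than the one-sided white or black top-hat transforms.
#'
#' @inheritParams erode
#' @return Same type as `signal`. A constant signal maps to all zeros.
#' @export
ctf <- function(signal, se) {
  stopifnot(inherits(se, "structuring_element"))
  morph_apply(signal, function(x) {
    op <- mm_dilate(mm_erode(x, se$heights), se$heights)
    cl <- mm_erode(mm_dilate(x, se$heights), se$heights)
    x - (op + cl) / 2
  })
}
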