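#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp hclust dist quantile rnorm runif rpois fft
#'   rbinom sd var as.dendrogram order.dendrogram cor lm coef approx
#' @importFrom utils read.delim write.table head tail
NULL

# ---- reproducible substreams -------------------------------------------

# Named substream offsets: each shuffle/simulation procedure draws from its
# own deterministic stream derived from the session seed, so stages are
# individually reproducible regardless of execution order.
.substreams <- c(
  behavior = 1L, events = 2L, lfp = 3L, spikes = 4L,
  modulation = 5L, behavior_null = 6L, mi_null = 7L,
  decode_null = 8L, similarity_null = 9L, stimulus_null = 10L,
  place_null = 11L
)

#' Derive a deterministic substream seed
#'
#' Maps a session-level seed and a named analysis stage to a fixed
#' 31-bit seed, so every randomized procedure in the pipeline can be
#' re-run in isolation with identical draws.
#'
#' @param seed integer session seed.
#' @param stream one of the named substreams (e.g. `"events"`,
#'   `"modulation"`).
#' @return integer seed below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(stream %in% names(.substreams))
  off <- .substreams[[stream]]
  # splitmix-style integer hash, kept in 31-bit range
  x <- (as.numeric(seed) * 2654435761 + off * 40503) %% 2147483629
  as.integer(x)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  expr
}

# ---- signal helpers -----------------------------------------------------

#' Zero-phase Butterworth bandpass filter
#'
#' Order-3 Butterworth applied forward and backward (zero phase), so
#' detected peak times are not shifted by the filter.
#'
#' @param x numeric vector.
#' @param band numeric length-2, passband in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 3).
#' @return filtered vector, same length as `x`.
#' @export
bandpass <- function(x, band, fs, order = 3) {
  stopifnot(length(band) == 2, band[1] < band[2], band[2] < fs / 2)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  # reflect-pad so edge transients (e.g. from a DC offset) stay outside
  # the returned span; keeps detection invariant to constant offsets
  n <- length(x)
  np <- min(n - 1, ceiling(3 * fs / band[1]))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(np + 1):(np + n)]
}

# Analytic signal by the FFT method; its modulus is the envelope used for
# ripple detection. (The installed signal build does not ship hilbert().)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

envelope <- function(x) Mod(analytic_signal(x))

# Gaussian smoothing of a regularly sampled vector; kernel truncated at
# +/- 4 sigma and renormalized at the edges.
gauss_smooth <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- exp(-((-half:half)^2) / (2 * sigma_bins^2))
  n <- length(x)
  xs <- c(rep(x[1], half), x, rep(x[n], half))
  num <- stats::filter(xs, k / sum(k), sides = 2)
  as.numeric(num[(half + 1):(half + n)])
}

hanning <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# local maxima (strictly greater than both neighbours)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# ---- circular helpers ---------------------------------------------------

# signed circular difference a-b wrapped to (-L/2, L/2]
circ_diff <- function(a, b, L) {
  d <- (a - b) %% L
  d[d > L / 2] <- d[d > L / 2] - L
  d
}

wrap_pos <- function(x, L) x %% L

# ---- interval helpers ---------------------------------------------------

# intervals: data.frame(start, end), half-open [start, end)
in_intervals <- function(t, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(t)))
  idx <- findInterval(t, intervals$start)
  ok <- idx >= 1
  ok[ok] <- t[ok] < intervals$end[idx[ok]]
  ok
}

intervals_duration <- function(intervals) sum(intervals$end - intervals$start)
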