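## Shared numeric helpers: circular statistics, analytic signal, smoothing.

#' Circular mean of angles
#'
#' @param theta numeric vector of angles in radians.
#' @return circular mean in (-pi, pi].
#' @keywords internal
circMean <- function(theta) {
  stopifnot(length(theta) >= 1L)
  atan2(mean(sin(theta)), mean(cos(theta)))
}

#' Absolute circular distance between two angles
#'
#' Shortest arc length between two phase angles, in [0, pi].
#' @param a,b angles in radians.
#' @keywords internal
circDist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

## Wrap angles into (-pi, pi].
wrapPhase <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Analytic signal via FFT
#'
#' Returns the complex analytic signal of a real vector (one-sided spectrum
#' construction), whose argument is the instantaneous phase and whose modulus
#' the instantaneous amplitude.
#' @param x real numeric vector.
#' @keywords internal
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Gaussian kernel on a regular grid, truncated at +-truncSD standard
## deviations, normalized to sum 1.
gaussKernel <- function(sdBins, truncSD = 5) {
  half <- max(1L, ceiling(truncSD * sdBins))
  k <- stats::dnorm(seq(-half, half), sd = sdBins)
  k / sum(k)
}

## Convolve a vector with a kernel using reflected-edge padding; output has
## the same length as the input.
convolveReflect <- function(x, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  pad <- min(half, n - 1L)
  left <- x[seq(pad + 1L, 2L)]
  right <- x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)
  if (pad < half) { # very short input: extend by repetition of edges
    xp <- c(rep(xp[1], half - pad), xp, rep(xp[length(xp)], half - pad))
  }
  out <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

## Shuffle interspike intervals, preserving the first spike time and the
## total spike count (rate-conserving surrogate).
shuffleISI <- function(times) {
  n <- length(times)
  if (n < 3L) return(times)
  isi <- diff(times)
  times[1] + c(0, cumsum(sample(isi)))
}

## Count, for each element of `ref`, how many elements of `x` (sorted) fall
## in (ref + lo, ref + hi].
countInWindow <- function(x, ref, lo, hi) {
  findInterval(ref + hi, x) - findInterval(ref + lo, x)
}

## Gaussian-smoothed firing-rate estimate on a regular grid (Hz).
smoothedRate <- function(times, duration, dt, kernelSD) {
  nb <- floor(duration / dt)
  counts <- tabulate(floor(times[times >= 0 & times < nb * dt] / dt) + 1L,
                     nbins = nb)
  k <- gaussKernel(kernelSD / dt)
  convolveReflect(counts, k) / dt
}
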