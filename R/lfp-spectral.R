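## LFP preprocessing, Welch power spectral density, band power, and
## band-limited analytic signals.

#' Preprocess an LFP channel: downsample to 1 kHz and z-score
#'
#' An anti-aliasing low-pass (8th-order Butterworth at 80% of the target
#' Nyquist, zero-phase) is applied before resampling onto the 1 kHz grid.
#'
#' @param channel an [LFPChannel-class] with fs >= 1000 Hz.
#' @return an [LFPChannel-class] at 1000 Hz with mean 0, SD 1.
#' @export
preprocessLFP <- function(channel) {
  fs <- channel@fs
  if (fs < 1000) stop("LFP sampling rate below 1 kHz; will not upsample")
  x <- channel@samples
  fsOut <- 1000
  if (fs > fsOut) {
    bf <- signal::butter(8, (0.8 * fsOut / 2) / (fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
    nOut <- floor(length(channel@samples) / fs * fsOut)
    tOut <- (seq_len(nOut) - 1) / fsOut
    x <- stats::approx((seq_along(x) - 1) / fs, x, xout = tOut)$y
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("constant LFP signal cannot be z-scored")
  LFPChannel((x - mean(x)) / s, fs = fsOut, channelId = channel@channelId)
}

#' Welch power spectral density
#'
#' Sliding 1 s Hann windows (50% overlap), each zero-padded to 10 s, with
#' density scaling; no normalization beyond the z-scoring of the input, so
#' the integral of the PSD over frequency equals the signal variance
#' (Parseval).
#'
#' @param lfp a preprocessed [LFPChannel-class] (see [preprocessLFP()]).
#' @param windowSec analysis window length, seconds (default 1).
#' @param padSec zero-padded window length, seconds (default 10), setting
#'   the frequency grid spacing 1/padSec.
#' @return data.frame with `frequency` (Hz) and `power` (1/Hz).
#' @export
powerSpectralDensity <- function(lfp, windowSec = 1, padSec = 10) {
  x <- lfp@samples
  fs <- lfp@fs
  nw <- round(windowSec * fs)
  if (length(x) < nw) stop("signal shorter than one analysis window")
  nfft <- round(padSec * fs)
  step <- nw %/% 2L
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1)) # Hann
  scale <- 1 / (fs * sum(w^2))
  nKeep <- nfft %/% 2L + 1L
  acc <- numeric(nKeep)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, numeric(nfft - nw)))[seq_len(nKeep)]
    acc <- acc + Mod(X)^2 * scale
  }
  p <- acc / length(starts)
  ## one-sided: double everything except DC (and Nyquist for even nfft)
  p[2:(nKeep - 1L)] <- 2 * p[2:(nKeep - 1L)]
  if (nfft %% 2L == 1L) p[nKeep] <- 2 * p[nKeep]
  data.frame(frequency = (seq_len(nKeep) - 1) * fs / nfft, power = p)
}

#' Average band power
#'
#' Mean spectral density over a frequency band (mean rather than integral so
#' values are comparable across bands of different width).
#'
#' @param psd data.frame from [powerSpectralDensity()].
#' @param band numeric length-2, c(low, high) in Hz.
#' @return scalar mean power density in the band.
#' @export
bandPower <- function(psd, band) {
  if (band[2] <= band[1]) stop("inverted frequency band")
  if (band[1] < min(psd$frequency) || band[2] > max(psd$frequency))
    stop("band outside PSD frequency range")
  sel <- psd$frequency >= band[1] & psd$frequency <= band[2]
  mean(psd$power[sel])
}

#' Band-pass filter and analytic signal
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass followed by
#' the Hilbert analytic signal. Phase convention: 0 rad at the oscillation
#' peak, +-pi at the trough.
#'
#' @param lfp a 1 kHz [LFPChannel-class] (see [preprocessLFP()]).
#' @param band c(low, high) in Hz; must be below Nyquist.
#' @return list of class `AnalyticBand` with `band`, `phase` (radians,
#'   (-pi, pi]), `amplitude` (envelope), `filtered`, `fs`.
#' @export
bandpassHilbert <- function(lfp, band) {
  fs <- lfp@fs
  if (band[2] >= fs / 2) stop("band edge at or above Nyquist frequency")
  if (band[2] <= band[1]) stop("inverted frequency band")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, lfp@samples)
  a <- analyticSignal(xf)
  structure(list(band = band, phase = wrapPhase(Arg(a)), amplitude = Mod(a),
                 filtered = xf, fs = fs),
            class = "AnalyticBand")
}
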