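#' Block-wise least-squares detrending
#'
#' Offset correction: within each consecutive block of `block` samples a
#' least-squares line is fitted and subtracted; a trailing partial block is
#' detrended the same way (a single trailing sample becomes zero).
#'
#' @param x numeric voltage series (uV)
#' @param block block length in samples, default 500
#' @return detrended series, same length
#' @export
detrendBlocks <- function(x, block = 500L) {
  if (block < 2) stop("block must be >= 2 samples")
  n <- length(x)
  if (n == 0L) return(numeric())
  out <- x
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    e <- min(n, s + block - 1L)
    m <- e - s + 1L
    if (m == 1L) { out[s] <- 0; next }
    tt <- seq_len(m) - (m + 1) / 2            # centered regressor
    y <- x[s:e]
    beta <- sum(tt * y) / sum(tt * tt)
    out[s:e] <- y - mean(y) - beta * tt
  }
  out
}

# 2nd-order analog Bessel low-pass poles, -3 dB at wc (rad/s), via the
# reverse Bessel polynomial s^2 + 3 s + 3 scaled by the -3 dB frequency
# of the delay-normalized prototype.
besselLowpass2 <- function(fc, fs) {
  wn <- 1.3616541287     # -3 dB frequency of the normalized prototype
  wc <- 2 * fs * tan(pi * fc / fs)   # prewarped corner
  scale <- wc / wn
  pNorm <- c(complex(real = -1.5, imaginary = sqrt(3) / 2),
             complex(real = -1.5, imaginary = -sqrt(3) / 2))
  p <- scale * pNorm
  g <- 3 * scale^2                    # H(0) = 1
  zpg <- signal::bilinear(Sz = numeric(0), Sp = p, Sg = g, T = 1 / fs)
  signal::as.Arma(zpg)
}

#' Spike-band filtering (100-3000 Hz)
#'
#' Causal cascade of a second-order Butterworth high-pass at `low` Hz and
#' a second-order Bessel low-pass at `high` Hz. If the sampling rate does
#' not accommodate the low-pass corner (rate <= 2 * high) the corner is
#' clipped just below Nyquist with a warning.
#'
#' @param x numeric voltage series
#' @param rate sampling rate, Hz
#' @param low,high band edges, Hz
#' @return filtered series
#' @export
spikeBandpass <- function(x, rate, low = 100, high = 3000) {
  if (rate <= 0) stop("sampling rate must be positive")
  if (rate <= 2 * high) {
    high <- 0.45 * rate
    warning(sprintf("low-pass corner clipped to %.0f Hz (below Nyquist)",
                    high))
  }
  hp <- signal::butter(2, low / (rate / 2), type = "high")
  lp <- besselLowpass2(high, rate)
  y <- signal::filter(hp, x)
  as.numeric(signal::filter(lp, y))
}

# Analytic magnitude of the spike-band cascade at frequency f (continuous
# time), used for documentation and by the test oracle via the exported
# helper below.
#' Analytic magnitude response of the spike-band cascade
#' @param f frequency, Hz
#' @param low,high band edges, Hz
#' @return |H(f)| of Butterworth(2, high-pass at low) x Bessel(2, low-pass
#'   at high) in continuous time
#' @export
spikeBandGain <- function(f, low = 100, high = 3000) {
  s <- complex(imaginary = 2 * pi * f)
  wl <- 2 * pi * low
  hHp <- s^2 / (s^2 + sqrt(2) * wl * s + wl^2)
  wn <- 1.3616541287
  sp <- s * wn / (2 * pi * high)
  hLp <- 3 / (sp^2 + 3 * sp + 3)
  Mod(hHp * hLp)
}

#' Zero-phase FIR band-pass
#'
#' Windowed-sinc (Hamming) FIR band-pass applied forward and backward
#' (zero phase): passband sinusoid peak times are preserved. Filter order
#' is 3 x rate / low rounded to even (odd tap count, symmetric).
#'
#' @param x numeric series
#' @param low,high band edges, Hz (0 < low < high < rate / 2)
#' @param rate sampling rate, Hz
#' @return filtered series, same length
#' @export
zeroPhaseBand <- function(x, low, high, rate) {
  if (!(low > 0 && high > low && high < rate / 2))
    stop("invalid band: need 0 < low < high < rate/2")
  ord <- round(3 * rate / low)
  if (ord %% 2 == 1) ord <- ord + 1
  ord <- min(ord, max(2, 2 * ((length(x) - 2) %/% 2)))
  taps <- signal::fir1(ord, c(low, high) / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(signal::Ma(taps), x))
}

#' Complex Morlet wavelet scalogram
#'
#' Continuous wavelet transform magnitude |W(b, a)| with
#' W(b, a) = (1/a) Int f(t) G((t - b)/a) dt and the complex Morlet mother
#' wavelet G(x) = (pi FB)^(-1/2) exp(-x^2 / FB) exp(2 i pi FC x), using
#' scale a = 1 / frequency, discretized by direct convolution with the
#' sampled mother wavelet under zero padding. Frequencies are laid on a
#' logarithmic grid across `[freqLo, freqHi]`. Cells closer to an edge
#' than the wavelet support are flagged in the cone-of-influence mask.
#'
#' @param x numeric series
#' @param rate sampling rate, Hz
#' @param freqLo,freqHi frequency range, Hz (defaults 0.1-250)
#' @param nFreq number of frequency grid points (default 120)
#' @param fb,fc Morlet bandwidth and center frequency (defaults 5 and 1)
#' @return a [Scalogram-class]
#' @export
morletScalogram <- function(x, rate, freqLo = 0.1, freqHi = 250,
                            nFreq = 120L, fb = 5, fc = 1) {
  if (freqLo <= 0 || freqHi <= freqLo || freqHi >= rate / 2)
    stop("frequency range must lie within (0, rate/2)")
  n <- length(x)
  freqs <- exp(seq(log(freqLo), log(freqHi), length.out = nFreq))
  dt <- 1 / rate
  mag <- matrix(0, nFreq, n)
  coi <- matrix(FALSE, nFreq, n)
  xmax <- sqrt(fb * log(1e8))      # Gaussian envelope support
  warned <- FALSE
  for (i in seq_len(nFreq)) {
    a <- 1 / freqs[i]
    L <- ceiling(xmax * a / dt)
    if (2L * L + 1L > n && !warned) {
      warning("signal shorter than the longest wavelet support; edges flagged")
      warned <- TRUE
    }
    k <- (-L):L
    xx <- k * dt / a
    g <- exp(-xx^2 / fb) / sqrt(pi * fb)
    gRe <- g * cos(2 * pi * fc * xx)
    gIm <- g * sin(2 * pi * fc * xx)
    # W(b) = dt/a * sum_k f(b + k dt) G(k dt / a): cross-correlation
    wRe <- crossCorrSame(x, gRe)
    wIm <- crossCorrSame(x, gIm)
    mag[i, ] <- sqrt(wRe^2 + wIm^2) * dt / a
    edge <- min(L, n)
    if (edge > 0) {
      coi[i, seq_len(min(edge, n))] <- TRUE
      coi[i, seq.int(max(1L, n - edge + 1L), n)] <- TRUE
    }
  }
  new("Scalogram", frequencies = freqs, times = (seq_len(n) - 1L) * dt,
      magnitude = mag, coi = coi, fb = fb, fc = fc)
}

# cross-correlation sum_k x[b + k] g[k], k = -L..L, zero padded, output
# aligned with x (FFT-based)
crossCorrSame <- function(x, g) {
  n <- length(x); L <- (length(g) - 1L) %/% 2L
  full <- stats::convolve(x, g, type = "open")   # sum x[b - k] g[k] style
  # convolve(x, g, "open")[m] = sum_j x[j] g[m - j + 1]; with g symmetric
  # indexing handled by reversing g for cross-correlation:
  full[(L + 1L):(L + n)]
}

setMethod("show", "Scalogram", function(object) {
  cat(sprintf("Scalogram: %d frequencies (%.3g-%.3g Hz) x %d times, FB=%g FC=%g\n",
              length(object@frequencies), min(object@frequencies),
              max(object@frequencies), length(object@times),
              object@fb, object@fc))
})

#' Signal-to-noise ratio against a quiet window
#'
#' SNR = max |signal| over the full trace divided by the noise level of a
#' quiet (no-activity) window, with the noise level taken as the standard
#' deviation of that window.
#'
#' @param x numeric series
#' @param rate sampling rate, Hz
#' @param quietWindow c(start, end) in seconds, >= 0.1 s, inside the trace
#' @return scalar SNR
#' @export
computeSNR <- function(x, rate, quietWindow) {
  n <- length(x)
  if (diff(quietWindow) < 0.1)
    stop("quiet window must span at least 0.1 s")
  i1 <- max(1L, floor(quietWindow[1] * rate) + 1L)
  i2 <- min(n, ceiling(quietWindow[2] * rate))
  if (i1 >= i2) stop("quiet window outside the signal")
  noise <- stats::sd(x[i1:i2])
  peak <- which.max(abs(x))
  if (peak >= i1 && peak <= i2)
    warning("quiet window contains the global maximum; SNR may be meaningless")
  max(abs(x)) / noise
}
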