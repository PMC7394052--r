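#' @useDynLib gaitmuscnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft nextn approx median qchisq qt quantile rnorm runif sd
#'   var aov coef pt
NULL

#' Hamming window
#' @param n window length in samples
#' @return numeric vector of length `n`
#' @keywords internal
hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Second-order Butterworth coefficients (bilinear transform, prewarped)
#'
#' @param cutoff cutoff frequency in Hz
#' @param fs sampling rate in Hz
#' @param type "low" or "high"
#' @return list with numerator `b` and denominator `a` (a[1] = 1)
#' @keywords internal
butter2 <- function(cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("butter2: cutoff must lie strictly inside (0, fs/2)")
  K <- tan(pi * cutoff / fs)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  a <- c(1, 2 * (K^2 - 1) * norm, (1 - sqrt(2) * K + K^2) * norm)
  if (type == "low") {
    b <- c(K^2, 2 * K^2, K^2) * norm
  } else {
    b <- c(1, -2, 1) * norm
  }
  list(b = b, a = a)
}

# single-pass IIR filter (zero initial conditions), vectorized via stats::filter
filter_ba <- function(b, a, x) {
  xf <- as.numeric(stats::filter(x, b, method = "convolution", sides = 1))
  nb <- length(b)
  for (i in seq_len(min(nb - 1, length(x)))) { # zero-padded leading samples
    xf[i] <- sum(b[1:i] * x[i:1])
  }
  as.numeric(stats::filter(xf, -a[-1], method = "recursive"))
}

#' Zero-phase (forward-backward) IIR filtering with reflective edge padding
#' @param b,a filter coefficients as from [butter2()]
#' @param x numeric vector
#' @return filtered vector, same length as `x`
#' @keywords internal
filtfilt_ba <- function(b, a, x) {
  n <- length(x)
  p <- min(n - 1, 300L)
  if (p < 1) return(x)
  head_pad <- 2 * x[1] - x[(p + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - p)]
  xp <- c(head_pad, x, tail_pad)
  y <- filter_ba(b, a, xp)
  y <- rev(filter_ba(b, a, rev(y)))
  y[(p + 1):(p + n)]
}

# filtfilt over matrix columns
filtfilt_mat <- function(b, a, X) {
  apply(X, 2, function(col) filtfilt_ba(b, a, col))
}

#' Analytic signal via the frequency-domain Hilbert transform
#' @param x real numeric vector
#' @return complex vector; `Mod()` of it is the rectified amplitude envelope
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Brick-wall FFT band-pass filter
#'
#' Zeroes all Fourier bins with |f| outside `[f_lo, f_hi]`. Zero-phase by
#' construction; used for narrow-band phase extraction and band-limited noise.
#' @param x real vector
#' @param fs sampling rate Hz
#' @param f_lo,f_hi band edges in Hz (inclusive)
#' @keywords internal
fft_bandpass <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  freqs <- (0:(n - 1)) * fs / n
  freqs <- pmin(freqs, fs - freqs) # |f| for the mirrored half
  X <- fft(x)
  X[freqs < f_lo | freqs > f_hi] <- 0
  Re(fft(X, inverse = TRUE) / n)
}

#' Resample a signal to a new rate (FFT anti-alias + linear interpolation)
#' @param x numeric vector or matrix (columns are channels)
#' @param fs_from,fs_to sampling rates in Hz
#' @return resampled vector/matrix
#' @keywords internal
resample_to <- function(x, fs_from, fs_to) {
  if (is.matrix(x)) return(apply(x, 2, resample_to, fs_from = fs_from, fs_to = fs_to))
  n <- length(x)
  if (fs_to < fs_from) x <- fft_bandpass(x, fs_from, 0, 0.5 * fs_to * 0.999)
  t_old <- (0:(n - 1)) / fs_from
  n_new <- floor((n - 1) * fs_to / fs_from) + 1
  t_new <- (0:(n_new - 1)) / fs_to
  approx(t_old, x, xout = t_new, rule = 2)$y
}

#' Welch power spectral density (Hamming taper, 50% overlap)
#' @param x numeric vector
#' @param fs sampling rate
#' @param seg_len segment length in samples
#' @param nfft FFT length (zero padded if > seg_len)
#' @return list(freq, psd, K)
#' @keywords internal
welch_psd <- function(x, fs, seg_len = NULL, nfft = NULL) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- max(16, 2 * floor(n / 9 / 2)) # ~8 segments
  if (is.null(nfft)) nfft <- max(seg_len, nextn(seg_len, 2))
  F <- welch_segment_ffts(x, seg_len, nfft)
  psd <- rowMeans(Mod(F)^2)
  nb <- floor(nfft / 2) + 1
  list(freq = (0:(nb - 1)) * fs / nfft, psd = psd[1:nb], K = ncol(F))
}

# windowed, zero-padded segment FFTs as an nfft x K complex matrix
welch_segment_ffts <- function(x, seg_len, nfft, hop = NULL) {
  if (is.null(hop)) hop <- max(1, floor(seg_len / 2))
  n <- length(x)
  if (n < seg_len) stop("signal shorter than one segment")
  starts <- seq(1, n - seg_len + 1, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  segs <- vapply(starts, function(s) x[s:(s + seg_len - 1)] * w, numeric(seg_len))
  if (nfft > seg_len) segs <- rbind(segs, matrix(0, nfft - seg_len, ncol(segs)))
  stats::mvfft(segs)
}

#' Randomize Fourier phases, preserving the power spectrum
#' @param x real vector
#' @return surrogate with identical amplitude spectrum and uniform phases
#' @keywords internal
phase_randomize <- function(x) {
  n <- length(x)
  X <- fft(x)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  ph <- runif(half, 0, 2 * pi)
  rot <- complex(modulus = 1, argument = ph)
  X[2:(half + 1)] <- X[2:(half + 1)] * rot
  X[(n - half + 1):n] <- Conj(X[(half + 1):2])
  Re(fft(X, inverse = TRUE) / n)
}

# circular variance of a vector of angles: 1 - |mean unit phasor|
circular_variance <- function(phi) {
  1 - Mod(mean(complex(modulus = 1, argument = phi)))
}

# circular mean location on [0, 1) of a vector of positions in [0, 1)
circular_mean_pos <- function(pos) {
  ang <- Arg(mean(complex(modulus = 1, argument = 2 * pi * pos)))
  (ang / (2 * pi)) %% 1
}
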