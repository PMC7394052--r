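#' FastICA (symmetric, tanh contrast) on multichannel data
#'
#' Minimal fixed-point ICA used for heartbeat-artifact identification:
#' whitening by eigendecomposition of the covariance, then symmetric
#' FastICA iterations with the tanh nonlinearity.
#'
#' @param X matrix `samples x channels`
#' @param n_comp number of components (default all channels)
#' @param max_iter,tol fixed-point iteration controls
#' @param seed optional seed for the random rotation start
#' @return list `S` (samples x n_comp sources), `A` (mixing,
#'   channels x n_comp), `W` (unmixing), `center` (channel means)
#' @keywords internal
fastica_tanh <- function(X, n_comp = ncol(X), max_iter = 200, tol = 1e-5,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  cv <- crossprod(Xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-10)[seq_len(n_comp)]
  K <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), length(keep))
  Z <- Xc %*% K # whitened, samples x n_comp
  p <- ncol(Z)
  W <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W) # samples x p
    G <- tanh(WX)
    gp <- 1 - G^2
    W1 <- crossprod(G, Z) / n - diag(colMeans(gp), p) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- Z %*% t(W)
  # least-squares mixing back to sensor space: X_centered ~ S %*% t(A)
  A <- Xc_mixing(Xc, S)
  list(S = S, A = A, W = W %*% t(K), center = ctr)
}

# least-squares mixing matrix so that X_centered ~ S %*% t(A)
Xc_mixing <- function(Xc, S) {
  t(qr.solve(S, Xc))
}

# normalized autocorrelation for lags 0..max_lag via the Wiener-Khinchin
# theorem (zero-padded FFT)
autocorr_fft <- function(x, max_lag) {
  x <- x - mean(x)
  n <- length(x)
  X <- fft(c(x, numeric(n)))
  r <- Re(fft(Mod(X)^2, inverse = TRUE))[1:(max_lag + 1)]
  r / r[1]
}

#' Reduce heartbeat contamination by independent component analysis
#'
#' Decomposes the EMG into independent components and flags cardiac
#' components by two joint criteria: the raw source waveform is strongly
#' periodic (a QRS wavelet train repeats almost deterministically, so its
#' autocorrelation approaches 1 at the beat lag, whereas amplitude-modulated
#' EMG noise decorrelates within milliseconds even when its envelope is
#' stride-periodic), and the implied beat rate lies in the cardiac band
#' (0.8-1.5 Hz). Flagged sources are zeroed before back-projection.
#' Disabled (`enabled = FALSE`) it is the identity.
#'
#' @param emg matrix `samples x channels` (needs >= 8 channels)
#' @param fs sampling rate in Hz
#' @param enabled logical; FALSE returns the input untouched
#' @param cardiac_band c(lo, hi) Hz of admissible beat rates
#' @param min_periodicity autocorrelation at the beat lag required to flag a
#'   component
#' @param seed seed for the ICA start
#' @return matrix of the same shape; attribute `removed` holds the flagged
#'   component indices
#' @export
remove_heartbeat <- function(emg, fs, enabled = TRUE,
                             cardiac_band = c(0.8, 1.5),
                             min_periodicity = 0.5, seed = 1L) {
  if (!enabled) return(emg)
  if (ncol(emg) < 8) stop("remove_heartbeat: needs at least 8 channels")
  ica <- tryCatch(fastica_tanh(emg, seed = seed), error = function(e) NULL)
  if (is.null(ica)) {
    warning("remove_heartbeat: source separation failed, passing through")
    return(emg)
  }
  lag_rng <- round(fs / rev(cardiac_band)) # beat-interval lags, samples
  flagged <- which(apply(ica$S, 2, function(s) {
    ac <- autocorr_fft(s, lag_rng[2])
    lags <- lag_rng[1]:lag_rng[2]
    peak <- max(ac[lags + 1])
    peak >= min_periodicity
  }))
  S <- ica$S
  S[, flagged] <- 0
  out <- S %*% t(ica$A)
  out <- sweep(out, 2, ica$center, "+")
  dimnames(out) <- dimnames(emg)
  for (at in c("fs", "stride_period", "heel_strikes", "envelope_true"))
    attr(out, at) <- attr(emg, at)
  attr(out, "removed") <- flagged
  out
}

#' High-pass filter and rectify EMG via the analytic-signal modulus
#'
#' 2nd-order bidirectional (zero-phase) Butterworth high-pass at `cutoff`
#' (30 Hz default), then the modulus of the analytic signal per channel —
#' a smooth, strictly non-negative rectification.
#'
#' @param emg matrix `samples x channels`
#' @param fs sampling rate in Hz (> 2 * cutoff required)
#' @param cutoff high-pass cutoff in Hz
#' @return non-negative matrix of the same shape
#' @export
highpass_rectify <- function(emg, fs, cutoff = 30) {
  if (fs <= 2 * cutoff)
    stop("highpass_rectify: sampling rate must exceed twice the cutoff")
  if (!is.matrix(emg)) emg <- matrix(emg, ncol = 1)
  ba <- butter2(cutoff, fs, "high")
  hp <- filtfilt_mat(ba$b, ba$a, emg)
  out <- apply(hp, 2, function(x) Mod(analytic_signal(x)))
  dimnames(out) <- dimnames(emg)
  out
}

#' EMG amplitude envelope
#'
#' 2nd-order bidirectional Butterworth low-pass (10 Hz default) of the
#' rectified EMG; filter undershoot is clipped to zero so the envelope can
#' enter non-negative factorizations.
#'
#' @param rectified non-negative matrix `samples x channels`
#' @param fs sampling rate in Hz
#' @param cutoff low-pass cutoff in Hz
#' @return non-negative matrix of the same shape
#' @export
emg_envelope <- function(rectified, fs, cutoff = 10) {
  if (!is.matrix(rectified)) rectified <- matrix(rectified, ncol = 1)
  ba <- butter2(cutoff, fs, "low")
  out <- pmax(filtfilt_mat(ba$b, ba$a, rectified), 0)
  dimnames(out) <- dimnames(rectified)
  out
}

#' Time-normalize envelopes to a fixed number of samples per stride
#'
#' Each segment between consecutive heel strikes is linearly interpolated
#' onto exactly `N` samples, putting every stride on a common 0-100%
#' gait-cycle axis with the right heel strike at 0%.
#'
#' @param envelope matrix `samples x channels`
#' @param events `gait_events` (or numeric vector of heel-strike times, s)
#' @param fs sampling rate in Hz
#' @param N samples per normalized stride (200 by default)
#' @return array `N x channels x n_strides`
#' @export
time_normalize <- function(envelope, events, fs, N = 200) {
  times <- if (inherits(events, "gait_events")) events$times else events
  if (length(times) < 2)
    stop("time_normalize: need at least 2 heel strikes")
  if (!is.matrix(envelope)) envelope <- matrix(envelope, ncol = 1)
  n_str <- length(times) - 1
  t_axis <- (seq_len(nrow(envelope)) - 1) / fs
  out <- array(0, dim = c(N, ncol(envelope), n_str),
               dimnames = list(NULL, colnames(envelope), NULL))
  for (k in seq_len(n_str)) {
    t_new <- seq(times[k], times[k + 1], length.out = N)
    for (ch in seq_len(ncol(envelope))) {
      out[, ch, k] <- approx(t_axis, envelope[, ch], xout = t_new,
                             rule = 2)$y
    }
  }
  out
}

#' Amplitude-normalize, average per mode and concatenate into X
#'
#' For each subject and muscle, envelopes are scaled by the subject's mean
#' envelope during the fastest walking speed; strides are then averaged
#' within each (subject, coordination-mode) cell and the average strides are
#' stacked row-wise into the concatenated envelope matrix `X`
#' (`SC * N` rows by 26 muscle columns).
#'
#' @param stride_stacks list of entries `list(subject, speed_kmh, mode,
#'   strides)` with `strides` an `N x channels x n_strides` array from
#'   [time_normalize()]
#' @param fastest_speed the speed whose mean activity defines the per-muscle
#'   scale (4.0 km/h in the experimental design)
#' @return object of class `envelope_matrix`: `X`, `N`, `blocks`
#'   (data.frame subject/mode per block), `muscles`
#' @export
amplitude_normalize_average_concat <- function(stride_stacks,
                                               fastest_speed = 4.0) {
  subjects <- unique(vapply(stride_stacks, `[[`, numeric(1), "subject"))
  scale_by <- list()
  for (s in subjects) {
    fast <- Filter(function(e) e$subject == s &&
                     isTRUE(all.equal(e$speed_kmh, fastest_speed)),
                   stride_stacks)
    if (length(fast) == 0)
      stop("amplitude_normalize_average_concat: subject ", s,
           " has no trial at the fastest speed (", fastest_speed, " km/h)")
    ref <- do.call(cbind, lapply(fast, function(e) apply(e$strides, 2, mean)))
    scale_by[[as.character(s)]] <- rowMeans(ref)
  }
  rows <- list()
  blocks <- list()
  for (s in subjects) {
    modes <- unique(vapply(Filter(function(e) e$subject == s, stride_stacks),
                           `[[`, character(1), "mode"))
    for (md in modes) {
      cell <- Filter(function(e) e$subject == s && e$mode == md, stride_stacks)
      mats <- lapply(cell, function(e) {
        norm <- sweep(e$strides, 2, scale_by[[as.character(s)]], "/")
        apply(norm, c(1, 2), mean) # average strides within the trial
      })
      avg <- Reduce(`+`, mats) / length(mats)
      rows[[length(rows) + 1]] <- avg
      blocks[[length(blocks) + 1]] <- data.frame(subject = s, mode = md)
    }
  }
  X <- do.call(rbind, rows)
  em <- list(X = X, N = nrow(rows[[1]]), blocks = do.call(rbind, blocks),
             muscles = colnames(X))
  class(em) <- "envelope_matrix"
  em
}

#' @export
print.envelope_matrix <- function(x, ...) {
  cat(sprintf("<envelope_matrix> %d x %d (N = %d, %d subject-mode blocks)\n",
              nrow(x$X), ncol(x$X), x$N, nrow(x$blocks)))
  invisible(x)
}
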