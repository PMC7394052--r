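#' Prepare rectified EMG for coherence analysis
#'
#' Anti-alias filters and resamples each segment to `target_fs`, removes the
#' per-segment channel means, and concatenates all segments of one condition
#' row-wise.
#'
#' @param segments a matrix `samples x channels` or a list of such matrices
#'   (trials of the same condition), all at rate `fs`
#' @param fs input sampling rate in Hz
#' @param target_fs output rate (256 Hz by default)
#' @return matrix `samples x channels` at `target_fs` (attribute `fs`)
#' @export
imc_prepare <- function(segments, fs, target_fs = 256) {
  if (is.matrix(segments)) segments <- list(segments)
  if (length(segments) == 0) stop("imc_prepare: empty condition")
  out <- do.call(rbind, lapply(segments, function(seg) {
    rs <- resample_to(seg, fs, target_fs)
    if (!is.matrix(rs)) rs <- matrix(rs, ncol = 1)
    sweep(rs, 2, colMeans(rs))
  }))
  attr(out, "fs") <- target_fs
  out
}

# Windowed segment FFTs for every channel of a data matrix.
# Returns array nbins x K x channels for the positive-frequency bins.
channel_segment_ffts <- function(X, seg_len, nfft, hop) {
  nb <- floor(nfft / 2) + 1
  K <- length(seq(1, nrow(X) - seg_len + 1, by = hop))
  out <- array(complex(1), dim = c(nb, K, ncol(X)))
  for (ch in seq_len(ncol(X))) {
    F <- welch_segment_ffts(X[, ch], seg_len, nfft, hop)
    out[, , ch] <- F[1:nb, , drop = FALSE]
  }
  out
}

#' Welch squared coherence between two signals
#'
#' `C^2(f) = |P_xy|^2 / (P_xx P_yy)` with spectra estimated by Welch's
#' method: Hamming taper of `taper_s` seconds, 50% overlap, FFT zero-padded
#' to `nfft` samples (256 at 256 Hz gives a 1 Hz bin spacing).
#'
#' @param x,y equal-length signals at rate `fs`
#' @param fs sampling rate in Hz
#' @param taper_s taper length in seconds (0.2 s default)
#' @param nfft FFT length (default `max(fs, seg_len)` rounded up to cover
#'   the taper)
#' @return list `freq`, `coh2`, `K` (number of averaged segments), `Pxx`,
#'   `Pyy`, `Pxy`
#' @export
welch_coherence <- function(x, y, fs = 256, taper_s = 0.2, nfft = NULL) {
  stopifnot(length(x) == length(y))
  seg_len <- round(taper_s * fs)
  if (is.null(nfft)) nfft <- max(seg_len, fs) # 1 Hz bins when nfft = fs
  hop <- ceiling(seg_len / 2)
  Fx <- welch_segment_ffts(x, seg_len, nfft, hop)
  Fy <- welch_segment_ffts(y, seg_len, nfft, hop)
  K <- ncol(Fx)
  if (K < 10) warning("welch_coherence: fewer than 10 segments")
  nb <- floor(nfft / 2) + 1
  Pxx <- rowMeans(Mod(Fx[1:nb, , drop = FALSE])^2)
  Pyy <- rowMeans(Mod(Fy[1:nb, , drop = FALSE])^2)
  Pxy <- rowMeans(Fx[1:nb, , drop = FALSE] * Conj(Fy[1:nb, , drop = FALSE]))
  denom <- Pxx * Pyy
  coh2 <- ifelse(denom > 0, Mod(Pxy)^2 / denom, 0)
  if (any(denom == 0)) warning("welch_coherence: zero-power bin(s) set to 0")
  list(freq = (0:(nb - 1)) * fs / nfft, coh2 = coh2, K = K,
       Pxx = Pxx, Pyy = Pyy, Pxy = Pxy)
}

#' Squared coherence for all channel pairs of a data matrix
#'
#' Same estimator as [welch_coherence()], vectorized over all
#' `p * (p-1) / 2` channel pairs; the workhorse behind
#' [build_coherence_set()].
#'
#' @param X matrix `samples x channels`
#' @param fs,taper_s,nfft as in [welch_coherence()]
#' @param band `c(f_lo, f_hi)` Hz; only bins inside (inclusive) are returned
#' @return list `freq`, `C2` (`n_freq x n_pairs`, pairs in `i < j`
#'   lexicographic order), `K`, `pairs`
#' @export
pairwise_coherence <- function(X, fs = 256, taper_s = 0.2, nfft = NULL,
                               band = c(4, 60)) {
  seg_len <- round(taper_s * fs)
  if (is.null(nfft)) nfft <- max(seg_len, fs)
  hop <- ceiling(seg_len / 2)
  Farr <- channel_segment_ffts(X, seg_len, nfft, hop)
  pairwise_coherence_from_ffts(Farr, fs, nfft, band)
}

pairwise_coherence_from_ffts <- function(Farr, fs, nfft, band) {
  nb <- dim(Farr)[1]
  K <- dim(Farr)[2]
  p <- dim(Farr)[3]
  freq_all <- (0:(nb - 1)) * fs / nfft
  sel <- which(freq_all >= band[1] & freq_all <= band[2])
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  C2 <- matrix(0, length(sel), nrow(pairs))
  for (r in seq_along(sel)) {
    G <- Farr[sel[r], , ] # K x p
    S <- crossprod(Conj(G), G) / K # S[i,j] = mean(conj(F_i) F_j)
    Pw <- Re(diag(S))
    denom <- outer(Pw, Pw)
    Cf <- ifelse(denom > 0, Mod(S)^2 / denom, 0)
    C2[r, ] <- Cf[pairs]
  }
  list(freq = freq_all[sel], C2 = C2, K = K, pairs = pairs)
}

#' Bias-correct and significance-mask squared coherence
#'
#' Phase-randomization surrogates (identical power spectra, independent
#' uniform phases) give a zero-coherence null whose per-bin mean `mu(f)`
#' reflects the finite-sample estimator bias (about `1/K`). Under the null
#' the raw squared coherence scaled by `mu(f)` follows half a Chi-squared
#' distribution with two degrees of freedom, so bins with
#' `C^2 < mu(f) * qchisq(1 - alpha, 2) / 2` are not distinguishable from
#' chance and are set to exactly zero; surviving bins are reported as
#' `C^2 - mu(f)` (bias subtracted, floored at zero).
#'
#' @param x,y equal-length signals at rate `fs`
#' @param fs,taper_s,nfft as in [welch_coherence()]
#' @param n_surrogates number of phase-randomized surrogates (100 default)
#' @param alpha significance level of the Chi-squared mask
#' @param seed integer seed for the surrogate phases
#' @return list `freq`, `coh2_raw`, `coh2` (corrected, masked), `null_mean`,
#'   `threshold`, `K`
#' @export
surrogate_correct <- function(x, y, fs = 256, taper_s = 0.2, nfft = NULL,
                              n_surrogates = 100, alpha = 0.05, seed = 1L) {
  res <- pairwise_coherence_corrected(cbind(x, y), fs = fs, taper_s = taper_s,
                                      nfft = nfft, band = c(0, fs / 2),
                                      n_surrogates = n_surrogates,
                                      alpha = alpha, seed = seed)
  list(freq = res$freq, coh2_raw = res$C2_raw[, 1], coh2 = res$C2[, 1],
       null_mean = res$null_mean[, 1], threshold = res$threshold[, 1],
       K = res$K)
}

#' All-pairs corrected coherence for one subject-condition
#'
#' @inheritParams pairwise_coherence
#' @inheritParams surrogate_correct
#' @return list `freq`, `C2` (corrected, masked), `C2_raw`, `null_mean`,
#'   `threshold`, `K`, `pairs`
#' @export
pairwise_coherence_corrected <- function(X, fs = 256, taper_s = 0.2,
                                         nfft = NULL, band = c(4, 60),
                                         n_surrogates = 100, alpha = 0.05,
                                         seed = 1L) {
  if (n_surrogates < 20)
    warning("surrogate correction: fewer than 20 surrogates is unstable")
  set.seed(seed)
  seg_len <- round(taper_s * fs)
  if (is.null(nfft)) nfft <- max(seg_len, fs)
  hop <- ceiling(seg_len / 2)
  Farr <- channel_segment_ffts(X, seg_len, nfft, hop)
  raw <- pairwise_coherence_from_ffts(Farr, fs, nfft, band)
  null_sum <- matrix(0, nrow(raw$C2), ncol(raw$C2))
  for (s in seq_len(n_surrogates)) {
    Xs <- apply(X, 2, phase_randomize)
    Fs <- channel_segment_ffts(Xs, seg_len, nfft, hop)
    null_sum <- null_sum + pairwise_coherence_from_ffts(Fs, fs, nfft, band)$C2
  }
  null_mean <- null_sum / n_surrogates
  thr <- null_mean * qchisq(1 - alpha, df = 2) / 2
  C2 <- ifelse(raw$C2 > thr, pmax(raw$C2 - null_mean, 0), 0)
  list(freq = raw$freq, C2 = C2, C2_raw = raw$C2, null_mean = null_mean,
       threshold = thr, K = raw$K, pairs = raw$pairs)
}

#' Assemble the frequency x (SC x 325) corrected-coherence matrix
#'
#' Runs the corrected all-pairs coherence for every subject-condition and
#' concatenates the spectra column-wise: columns are ordered
#' subject-condition-major (in the order of `prepared`), muscle pair
#' (`i < j` lexicographic) minor.
#'
#' @param prepared named list, one prepared matrix (see [imc_prepare()]) per
#'   subject-condition; names like `"s1|2:1"` label the columns
#' @param fs sampling rate of the prepared signals
#' @param band analysis band in Hz (4-60 default)
#' @param taper_s,n_surrogates,alpha,seed forwarded to the corrector
#' @return object of class `coherence_set`: `freq`, `C2`, `sc` (data.frame
#'   subject/condition per block), `pairs`, `n_pairs`
#' @export
build_coherence_set <- function(prepared, fs = 256, band = c(4, 60),
                                taper_s = 0.2, n_surrogates = 100,
                                alpha = 0.05, seed = 1L) {
  stopifnot(length(prepared) >= 1)
  blocks <- vector("list", length(prepared))
  for (k in seq_along(prepared)) {
    res <- pairwise_coherence_corrected(prepared[[k]], fs = fs,
                                        taper_s = taper_s, band = band,
                                        n_surrogates = n_surrogates,
                                        alpha = alpha, seed = seed + k)
    blocks[[k]] <- res$C2
  }
  labels <- names(prepared)
  if (is.null(labels)) labels <- paste0("sc", seq_along(prepared))
  sc <- do.call(rbind, lapply(strsplit(labels, "|", fixed = TRUE), function(p) {
    data.frame(subject = p[1], condition = p[length(p)])
  }))
  out <- list(freq = res$freq, C2 = do.call(cbind, blocks), sc = sc,
              pairs = res$pairs, n_pairs = nrow(res$pairs))
  class(out) <- "coherence_set"
  out
}

#' Decompose coherence spectra into frequency components by NMF
#'
#' Applies the synergy NMF engine and rank rule to the
#' frequency x (SC x pairs) matrix with the adjusted cutoffs (55% / 4%).
#' Each component's dominant band is the contiguous run of bins at or above
#' half the profile maximum.
#'
#' @param C non-negative matrix `n_freq x n_cols`, or a `coherence_set`
#' @param freqs frequency grid (taken from the set if `C` is one)
#' @param lambda_cutoff,delta_cutoff rank-selection cutoffs in percent
#' @param max_rank largest rank scanned
#' @param n_restarts,seed NMF controls
#' @return object of class `coherence_components`: `W_coh`
#'   (`n_freq x m` spectral profiles, unit maximum), `A_coh`
#'   (`m x n_cols` weights), `m`, `lambda_profile`, `dominant_bands`
#'   (list of `c(f_lo, f_hi)`), `freqs`
#' @export
nmf_frequency_components <- function(C, freqs = NULL, lambda_cutoff = 55,
                                     delta_cutoff = 4, max_rank = 6,
                                     n_restarts = 5, seed = 1L) {
  if (inherits(C, "coherence_set")) {
    freqs <- C$freq
    C <- C$C2
  }
  if (is.null(freqs)) freqs <- seq_len(nrow(C))
  sel <- select_rank(t(C), lambda_cutoff = lambda_cutoff,
                     delta_cutoff = delta_cutoff, max_rank = max_rank,
                     n_restarts = n_restarts, seed = seed)
  fit <- sel$models[[sel$m]]
  W <- fit$W # n_freq x m, unit-max columns
  bands <- lapply(seq_len(ncol(W)), function(s) dominant_band(freqs, W[, s]))
  out <- list(W_coh = W, A_coh = fit$A, m = sel$m,
              lambda_profile = sel$lambda_profile,
              dominant_bands = bands, freqs = freqs,
              satisfied = sel$satisfied)
  class(out) <- "coherence_components"
  out
}

# contiguous run of bins >= 50% of the profile max, containing the argmax
dominant_band <- function(freqs, profile) {
  high <- profile >= 0.5 * max(profile)
  pk <- which.max(profile)
  lo <- pk
  while (lo > 1 && high[lo - 1]) lo <- lo - 1
  hi <- pk
  while (hi < length(high) && high[hi + 1]) hi <- hi + 1
  c(freqs[lo], freqs[hi])
}

#' Low-frequency coherence variant (0.6-4 Hz, 5 s taper)
#'
#' Same estimator and correction with a 5 s Hamming taper over the 0.6-4 Hz
#' range, intended for stride-rate envelope coherence that can be compared
#' with the synergy networks.
#'
#' @param X prepared matrix `samples x channels` at rate `fs`
#' @param fs sampling rate
#' @param n_surrogates,alpha,seed forwarded to the corrector
#' @return as [pairwise_coherence_corrected()]
#' @export
lowfreq_coherence <- function(X, fs = 256, n_surrogates = 100, alpha = 0.05,
                              seed = 1L) {
  seg_len <- round(5 * fs)
  if (nrow(X) < 2 * seg_len)
    stop("lowfreq_coherence: record shorter than two 5 s tapers")
  pairwise_coherence_corrected(X, fs = fs, taper_s = 5, nfft = seg_len,
                               band = c(0.6, 4), n_surrogates = n_surrogates,
                               alpha = alpha, seed = seed)
}

#' @export
print.coherence_set <- function(x, ...) {
  cat(sprintf("<coherence_set> %d freq bins x %d columns (%d blocks x %d pairs)\n",
              nrow(x$C2), ncol(x$C2), nrow(x$sc), x$n_pairs))
  invisible(x)
}

#' @export
print.coherence_components <- function(x, ...) {
  cat(sprintf("<coherence_components> m = %d; bands: %s\n", x$m,
              paste(vapply(x$dominant_bands,
                           function(b) sprintf("%g-%g Hz", b[1], b[2]), ""),
                    collapse = ", ")))
  invisible(x)
}
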