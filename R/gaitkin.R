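#' Detect heel strikes from a vertical ground reaction force trace
#'
#' A heel strike is marked at each upward crossing of a threshold equal to
#' `fraction` of the trial-mean force (8% by default). A refractory period of
#' 0.25 times the median inter-event interval suppresses double crossings
#' caused by noise on the rising edge.
#'
#' @param grf non-negative force trace (single foot), sampled at `fs`
#' @param fs sampling rate in Hz
#' @param fraction threshold as a fraction of the trial-mean force
#' @return object of class `gait_events`: `times` (s, strictly increasing),
#'   `threshold`, `side`
#' @export
detect_heel_strikes <- function(grf, fs, fraction = 0.08) {
  stopifnot(length(grf) >= 2 * fs)
  if (all(grf == 0) || mean(grf) == 0) {
    warning("detect_heel_strikes: all-zero force trace, no events")
    ev <- list(times = numeric(0), threshold = 0, side = "right")
    class(ev) <- "gait_events"
    return(ev)
  }
  thr <- fraction * mean(grf)
  above <- grf >= thr
  cross <- which(!above[-length(above)] & above[-1]) + 1L
  if (above[1]) cross <- c(1L, cross)
  times <- (cross - 1) / fs
  if (length(times) > 2) {
    refractory <- 0.25 * median(diff(times))
    keep <- times[1]
    for (tt in times[-1]) {
      if (tt - keep[length(keep)] >= refractory) keep <- c(keep, tt)
    }
    times <- keep
  }
  ev <- list(times = times, threshold = thr, side = "right")
  class(ev) <- "gait_events"
  ev
}

#' Spectral overlap between arm and leg after frequency-axis rescaling
#'
#' Both Welch power spectra are normalized to unit area; the leg spectrum's
#' frequency axis is stretched by `ratio` (so a `ratio`:1 locked pair has
#' coinciding peaks) and the overlap is the integral of the pointwise
#' minimum of the two unit-area spectra — 1 for identical spectra, 0 for
#' disjoint ones.
#'
#' @param arm,leg equal-length traces at rate `fs`
#' @param ratio frequency ratio hypothesis (1 or 2)
#' @param fs sampling rate in Hz
#' @return overlap in `[0, 1]`
#' @export
spectral_overlap <- function(arm, leg, ratio, fs) {
  stopifnot(length(arm) == length(leg))
  if (sd(arm) == 0 || sd(leg) == 0)
    stop("spectral_overlap: constant trace has no spectrum")
  arm <- arm - mean(arm)
  leg <- leg - mean(leg)
  # rescale the leg frequency axis by time-compressing the signal, so both
  # spectral peaks keep the same window-limited width and aligned peaks
  # overlap fully
  if (ratio != 1) {
    n <- length(leg)
    idx <- seq(1, n, by = ratio)
    leg <- approx(seq_len(n), leg, xout = idx, rule = 2)$y
  }
  seg_len <- floor(min(length(arm), length(leg)) / 2)
  nfft <- 4 * nextn(seg_len, 2)
  ps_a <- welch_psd(arm, fs, seg_len = seg_len, nfft = nfft)
  ps_l <- welch_psd(leg, fs, seg_len = seg_len, nfft = nfft)
  df <- ps_a$freq[2] - ps_a$freq[1]
  sa <- ps_a$psd / (sum(ps_a$psd) * df)
  sl <- ps_l$psd / (sum(ps_l$psd) * df)
  sum(pmin(sa, sl)) * df
}

#' Generalized relative phase and its circular variance
#'
#' Band-passes each trace around its dominant spectral peak (peak +/- 50%
#' bandwidth), takes instantaneous phases from the analytic signal, and
#' returns the generalized relative phase `p*phi_arm - q*phi_leg` together
#' with its circular variance (0 = perfect locking, 1 = uniform drift).
#'
#' @param arm,leg traces at rate `fs`
#' @param p,q integer locking multipliers (arm and leg respectively)
#' @param fs sampling rate in Hz
#' @param prefiltered set TRUE if the traces are already narrow-band
#' @return list `phi` (radians, unwrapped), `circvar`
#' @export
generalized_relative_phase <- function(arm, leg, p, q, fs,
                                       prefiltered = FALSE) {
  if (sd(arm) == 0 || sd(leg) == 0)
    stop("generalized_relative_phase: zero-amplitude trace")
  narrow <- function(x) {
    x <- x - mean(x)
    if (prefiltered) return(x)
    ps <- welch_psd(x, fs)
    fpk <- ps$freq[which.max(ps$psd)]
    if (fpk <= 0) fpk <- ps$freq[2]
    fft_bandpass(x, fs, 0.5 * fpk, 1.5 * fpk)
  }
  # + pi/2 references phases to the sine convention (sin(phi) rather than
  # cos(phi)), so sin vs sin examples give the expected offset
  pa <- Arg(analytic_signal(narrow(arm))) + pi / 2
  pl <- Arg(analytic_signal(narrow(leg))) + pi / 2
  phi <- p * unwrap_phase(pa) - q * unwrap_phase(pl)
  list(phi = phi, circvar = circular_variance(phi))
}

# unwrap radian phase jumps > pi
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

#' Classify the arm-leg coordination mode of a trial
#'
#' Evidence: spectral overlap at the 2:1 and 1:1 frequency-ratio hypotheses
#' and circular variance of the corresponding generalized relative phases
#' (`p = 1, q = 2` and `p = q = 1`). A mode is assigned when its overlap
#' dominates the other by more than `delta` and its relative phase is nearly
#' constant (circular variance below `v`); otherwise the trial is labelled a
#' transition (`"T"`), which shows overlap at both ratios and drifting phase.
#'
#' @param arm,leg kinematic traces at rate `fs`
#' @param fs sampling rate in Hz
#' @param delta overlap-dominance threshold (default 0.15)
#' @param v circular-variance threshold for accepted locking (default 0.2)
#' @return object of class `mode_evidence` with fields `overlap_21`,
#'   `overlap_11`, `circvar_21`, `circvar_11`, `label`
#' @export
classify_mode <- function(arm, leg, fs, delta = 0.15, v = 0.2) {
  o21 <- spectral_overlap(arm, leg, ratio = 2, fs = fs)
  o11 <- spectral_overlap(arm, leg, ratio = 1, fs = fs)
  cv21 <- generalized_relative_phase(arm, leg, p = 1, q = 2, fs = fs)$circvar
  cv11 <- generalized_relative_phase(arm, leg, p = 1, q = 1, fs = fs)$circvar
  label <- if (o21 - o11 > delta && cv21 < v) {
    "2:1"
  } else if (o11 - o21 > delta && cv11 < v) {
    "1:1"
  } else {
    "T"
  }
  ev <- list(overlap_21 = o21, overlap_11 = o11,
             circvar_21 = cv21, circvar_11 = cv11, label = label)
  class(ev) <- "mode_evidence"
  ev
}

#' @export
print.mode_evidence <- function(x, ...) {
  cat(sprintf(
    "<mode_evidence> label %s | overlap 2:1 %.2f / 1:1 %.2f | circvar 2:1 %.2f / 1:1 %.2f\n",
    x$label, x$overlap_21, x$overlap_11, x$circvar_21, x$circvar_11))
  invisible(x)
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d heel strikes (%s), threshold %.2f\n",
              length(x$times), x$side, x$threshold))
  invisible(x)
}
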