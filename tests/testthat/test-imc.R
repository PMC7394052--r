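test_that("imc_prepare resamples, centers and concatenates", {
  fs <- 2000
  t <- (0:9999) / fs
  # constant signal -> all zero after mean centering
  prep_const <- imc_prepare(matrix(1, 4000, 1), fs)
  expect_lt(max(abs(prep_const)), 1e-8)
  # 100 Hz survives the 256 Hz resampling, 140 Hz (above the new Nyquist)
  # is removed
  x <- sin(2 * pi * 100 * t) + sin(2 * pi * 140 * t)
  prep <- imc_prepare(matrix(x), fs)
  ps <- welch_psd(prep[, 1], 256, seg_len = 512)
  p100 <- ps$psd[which.min(abs(ps$freq - 100))]
  p120up <- max(ps$psd[ps$freq > 122])
  expect_gt(p100 / p120up, 100)
  # single segment: concatenation is the identity (rows preserved)
  one <- imc_prepare(matrix(rnorm(5120), ncol = 2), 512, target_fs = 256)
  expect_equal(nrow(one), 1280) # 2560 samples at 512 Hz -> half at 256 Hz
  expect_error(imc_prepare(list(), fs), "empty")
})

test_that("welch_coherence matches identities and the estimator bias", {
  set.seed(3)
  fs <- 256
  x <- rnorm(40 * fs)
  wcx <- welch_coherence(x, x, fs)
  expect_true(all(abs(wcx$coh2 - 1) < 1e-8))
  expect_equal(wcx$freq[2] - wcx$freq[1], 1) # 1 Hz bins from padded FFT
  # independent pair: mean raw C^2 ~ 1/K
  wc <- welch_coherence(x, rnorm(40 * fs), fs)
  expect_equal(mean(wc$coh2), 1 / wc$K, tolerance = 0.35)
  # coherence is invariant to channel rescaling
  y <- x + rnorm(length(x))
  expect_equal(welch_coherence(x, y, fs)$coh2,
               welch_coherence(5 * x, 0.2 * y, fs)$coh2, tolerance = 1e-10)
})

test_that("shared signal plus equal noise follows the SNR closed form", {
  set.seed(4)
  fs <- 256
  s <- rnorm(60 * fs)
  wc <- welch_coherence(s + rnorm(length(s)), s + rnorm(length(s)), fs)
  band <- wc$freq >= 4 & wc$freq <= 60
  expect_equal(mean(wc$coh2[band]), (1 / (1 + 1))^2, tolerance = 0.05)
})

test_that("surrogate correction masks chance coherence and keeps coupling", {
  set.seed(5)
  fs <- 256
  x <- rnorm(30 * fs)
  sc_ind <- surrogate_correct(x, rnorm(30 * fs), fs, seed = 1)
  expect_lt(mean(sc_ind$coh2), 0.01)
  expect_true(all(sc_ind$coh2 >= 0))
  # masked bins are exactly zero
  expect_true(any(sc_ind$coh2 == 0))
  # true coupling survives
  sc_same <- surrogate_correct(x, x, fs, seed = 1)
  band <- sc_same$freq >= 4 & sc_same$freq <= 60
  expect_true(all(sc_same$coh2[band] > 0))
  # determinism under the seed
  sc_rep <- surrogate_correct(x, x, fs, seed = 1)
  expect_identical(sc_same$coh2, sc_rep$coh2)
  expect_warning(surrogate_correct(x, x, fs, n_surrogates = 10, seed = 1),
                 "unstable")
})

test_that("build_coherence_set assembles the f x (SC x 325) matrix", {
  set.seed(6)
  fs <- 256
  prepared <- list("1|2:1" = matrix(rnorm(8 * fs * 4), ncol = 4),
                   "1|1:1" = matrix(rnorm(8 * fs * 4), ncol = 4))
  cs <- build_coherence_set(prepared, fs, band = c(4, 60),
                            n_surrogates = 25, seed = 1)
  expect_equal(nrow(cs$C2), 57) # 4-60 Hz inclusive at 1 Hz spacing
  expect_equal(ncol(cs$C2), 2 * 6) # 2 blocks x C(4,2) pairs
  expect_equal(cs$sc$condition, c("2:1", "1:1"))
  expect_equal(muscle_pairs()[325, ], c(i = 25L, j = 26L))
  expect_equal(nrow(muscle_pairs()), 26 * 25 / 2)
})

test_that("nmf_frequency_components recovers planted bands", {
  scs <- synth_coherence_set(n_sc = 4, seed = 5)
  cc <- nmf_frequency_components(scs$C, freqs = scs$freqs, n_restarts = 2,
                                 seed = 5)
  expect_equal(cc$m, 3)
  jac <- vapply(cc$dominant_bands, function(b) {
    max(vapply(scs$bands, band_jaccard, numeric(1), b2 = b))
  }, numeric(1))
  expect_true(all(jac > 0.5))
  # single planted band -> m = 1
  scs1 <- synth_coherence_set(n_sc = 4, bands = list(c(8, 22)),
                              signal_fraction = 0.57, seed = 6)
  cc1 <- nmf_frequency_components(scs1$C, freqs = scs1$freqs,
                                  lambda_cutoff = 19, delta_cutoff = 4,
                                  n_restarts = 2, seed = 6)
  expect_equal(cc1$m, 1)
})

test_that("low-frequency variant finds planted envelope co-modulation", {
  set.seed(7)
  fs <- 256
  n <- 60 * fs
  shared <- fft_bandpass(rnorm(n), fs, 2.2, 2.8) # ~2.5 Hz co-modulation
  shared <- shared / sd(shared)
  mk <- function() pmax(1 + 0.8 * shared, 0) * abs(rnorm(n))
  X <- cbind(mk(), mk())
  expect_error(lowfreq_coherence(X[1:(5 * fs), ], fs), "two 5 s tapers")
  lf <- lowfreq_coherence(X, fs, n_surrogates = 40, seed = 2)
  pk <- lf$freq[which.max(lf$C2[, 1])]
  expect_gt(lf$C2[which.min(abs(lf$freq - 2.5)), 1], 0)
  expect_true(pk >= 2 && pk <= 3)
  # no shared modulation -> near-zero corrected low-frequency coherence
  X0 <- cbind(abs(rnorm(n)), abs(rnorm(n)))
  lf0 <- lowfreq_coherence(X0, fs, n_surrogates = 40, seed = 3)
  expect_lt(mean(lf0$C2), 0.02)
})
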