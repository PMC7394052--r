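test_that("highpass_rectify matches closed-form envelopes", {
  fs <- 2000
  t <- (0:9999) / fs
  # 2nd-order Butterworth high-pass at 30 Hz applied twice (zero-phase):
  # |H(f)|^2 = 1 / (1 + (30/f)^4); a unit 50 Hz sinusoid rectifies to that
  # constant, a 5 Hz sinusoid is pushed into the stop band
  r <- highpass_rectify(cbind(sin(2 * pi * 50 * t), sin(2 * pi * 5 * t)), fs)
  core <- 1000:9000
  expect_equal(mean(r[core, 1]), 1 / (1 + (30 / 50)^4), tolerance = 0.01)
  expect_lt(mean(r[core, 2]), 0.02)
  expect_true(all(r >= 0))
  expect_error(highpass_rectify(cbind(t), fs = 50), "twice the cutoff")
  # white noise: mean modulus of the analytic signal equals the direct
  # formula sqrt(pi/2) * sd for a Gaussian narrowband-free signal
  set.seed(1)
  x <- rnorm(20000)
  env <- Mod(analytic_signal(x))
  expect_equal(mean(env), sqrt(pi / 2) * sd(x), tolerance = 0.02)
})

test_that("emg_envelope is a DC-gain-1 non-negative smoother", {
  fs <- 2000
  expect_equal(mean(emg_envelope(matrix(rep(0.7, 4000)), fs)), 0.7,
               tolerance = 1e-3)
  r <- highpass_rectify(matrix(sin(2 * pi * 50 * (0:7999) / fs)), fs)
  env <- emg_envelope(r, fs)
  expect_lt(sd(env[1000:7000]), 0.01) # smooth, near-constant
  expect_true(all(env >= 0))
})

test_that("zero-phase filtering introduces no lag in the pass band", {
  fs <- 2000
  t <- (0:7999) / fs
  x <- sin(2 * pi * 3 * t)
  ba <- butter2(10, fs, "low")
  y <- filtfilt_ba(ba$b, ba$a, x)
  lags <- -20:20
  cc <- vapply(lags, function(l) {
    idx <- 500:7500
    cor(x[idx], y[idx + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("time_normalize resamples strides exactly", {
  fs <- 100
  env <- matrix(seq(0, 1, length.out = 701), ncol = 1) # global linear ramp
  ev <- c(0, 1.4, 2.8, 4.2, 5.6, 7.0)
  tn <- time_normalize(env, ev, fs, N = 200)
  expect_equal(dim(tn), c(200L, 1L, 5L))
  # linear in, linear out (exactness on degree-1 polynomials)
  for (k in 1:5) {
    seg <- tn[, 1, k]
    fit <- lm(seg ~ seq_along(seg))
    expect_lt(max(abs(residuals(fit))), 1e-10)
  }
  # endpoints preserved
  expect_equal(tn[1, 1, 1], env[1, 1])
  expect_error(time_normalize(env, 0.7, fs), "at least 2")
})

test_that("amplitude normalization is per-subject scale invariant", {
  gt <- default_ground_truth()
  mk <- function(subject, speed, scale = 1) {
    set.seed(subject * 10 + round(speed))
    strides <- array(runif(50 * 3 * 4, 0.1, 1) * scale, c(50, 3, 4))
    list(subject = subject, speed_kmh = speed,
         mode = mode_for_speed(speed), strides = strides)
  }
  stacks <- list(mk(1, 1.0), mk(1, 4.0), mk(2, 1.0), mk(2, 4.0))
  em <- amplitude_normalize_average_concat(stacks, fastest_speed = 4.0)
  expect_equal(nrow(em$X), 4 * 50) # 2 subjects x 2 modes x N = 50
  # doubling one subject's raw amplitudes leaves their rows unchanged
  stacks2 <- stacks
  for (i in 1:2) stacks2[[i]]$strides <- stacks2[[i]]$strides * 2
  em2 <- amplitude_normalize_average_concat(stacks2, fastest_speed = 4.0)
  expect_equal(em$X, em2$X, tolerance = 1e-12)
  expect_error(
    amplitude_normalize_average_concat(list(mk(3, 1.0)), fastest_speed = 4.0),
    "fastest speed")
})

test_that("envelope of generated EMG tracks the planted activation mixture", {
  # zero noise and no common-input modulation: this isolates envelope
  # extraction fidelity (band modulation adds envelope variance by design)
  gt <- default_ground_truth(common_input_bands = list())
  emg <- generate_emg(gt, duration = 15, stride_period = 1.25, seed = 8,
                      sensor_noise_sd = 0)
  env <- emg_envelope(highpass_rectify(emg, 2000), 2000)
  target <- attr(emg, "envelope_true") %*% t(gt$weights)
  ccs <- diag(cor(env, target))
  expect_gt(min(ccs), 0.9)
})

test_that("remove_heartbeat strips a planted cardiac artifact and nothing else", {
  gt_hb <- default_ground_truth(heartbeat = list(rate_hz = 1.2,
                                                 amplitude = 3))
  emg <- generate_emg(gt_hb, duration = 18, stride_period = 1.25, seed = 4)
  expect_identical(remove_heartbeat(emg, 2000, enabled = FALSE), emg)
  cln <- remove_heartbeat(emg, 2000, seed = 2)
  ecg <- gaitmuscnet:::heartbeat_trace((0:(nrow(emg) - 1)) / 2000, 1.2)
  pw <- function(M) colSums(M * ecg)^2 / sum(ecg^2)
  expect_gt(1 - mean(pw(cln)) / mean(pw(emg)), 0.7)
  # artifact-free data passes through nearly untouched
  gt0 <- default_ground_truth()
  emg0 <- generate_emg(gt0, duration = 18, stride_period = 1.25, seed = 4)
  cln0 <- remove_heartbeat(emg0, 2000, seed = 2)
  expect_gt(min(diag(cor(emg0, cln0))), 0.99)
  expect_error(remove_heartbeat(emg0[, 1:4], 2000), "8 channels")
})
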