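# shared fixtures, built in code at test time

# small recording used by several files (cached per session)
tiny_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_recording(1, 2.5, n_strides = 12, seed = 101)
    cache
  }
})

# symmetric matrix from an upper-triangle weight vector
sym_from_ut <- function(w, n) {
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- w
  M + t(M)
}

# random non-negative symmetric layer with zero diagonal
random_layer <- function(n, density = 0.7) {
  k <- n * (n - 1) / 2
  sym_from_ut(runif(k) * rbinom(k, 1, density), n)
}

# independent trapezoid-rule oracle
trapz_ref <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

expect_symmetric_zero_diag <- function(L) {
  expect_equal(L, t(L))
  expect_true(all(diag(L) == 0))
  expect_true(all(L >= 0))
}
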