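#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes the non-negative matrix `X` (time x muscles) as
#' `X ~ t(A) %*% t(W)` in the synergy convention: muscle weights `W`
#' (muscles x m) and activation waveforms `A` (m x time). The Frobenius norm
#' is minimized by Lee-Seung multiplicative updates; the best of
#' `n_restarts` random non-negative initializations is kept. `W` columns are
#' normalized to unit maximum with the compensating scale absorbed into `A`.
#'
#' @param X non-negative matrix, rows are time points, columns muscles
#' @param m rank (1 <= m <= min(dim(X)))
#' @param n_restarts random initializations
#' @param seed integer seed
#' @param max_iter,tol update-loop controls (relative Frobenius-error change)
#' @param init optional list(W, A) extra warm-start initialization
#' @return object of class `synergy_model`: `W` (muscles x m), `A`
#'   (m x time), `m`, `lambda_total` (%), `err_trace`
#' @export
nmf_synergies <- function(X, m, n_restarts = 5, seed = 1L,
                          max_iter = 1000, tol = 1e-6, init = NULL) {
  if (any(X < 0)) stop("nmf_synergies: X must be non-negative")
  if (all(X == 0)) stop("nmf_synergies: X is all zeros (degenerate)")
  stopifnot(m >= 1, m <= min(dim(X)))
  set.seed(seed)
  Xt <- t(X) # muscles x time: Xt ~ W %*% A
  best <- NULL
  inits <- lapply(seq_len(n_restarts), function(i) {
    list(W = matrix(runif(nrow(Xt) * m, 0.1, 1), nrow(Xt), m),
         A = matrix(runif(m * ncol(Xt), 0.1, 1), m, ncol(Xt)))
  })
  if (!is.null(init)) inits <- c(list(init), inits)
  for (ini in inits) {
    fit <- nmf_mu_cpp(Xt, ini$W, ini$A, max_iter, tol)
    if (is.null(best) || fit$rel_err < best$rel_err) best <- fit
  }
  W <- best$W
  A <- best$H
  cmax <- apply(W, 2, max)
  cmax[cmax == 0] <- 1
  W <- sweep(W, 2, cmax, "/")
  A <- sweep(A, 1, cmax, "*")
  rownames(W) <- colnames(X)
  model <- list(W = W, A = A, m = m,
                lambda_total = reconstruction_quality(X, W, A),
                err_trace = best$err_trace)
  class(model) <- "synergy_model"
  model
}

#' Reconstruction quality of a factorization (percent)
#'
#' `lambda = (1 - ||X - t(W %*% A)||_F^2 / ||X||_F^2) * 100`.
#'
#' @param X data matrix (time x muscles)
#' @param W muscle weights (muscles x m)
#' @param A activations (m x time)
#' @return lambda in percent (can be negative for a poor model)
#' @export
reconstruction_quality <- function(X, W, A) {
  nx2 <- sum(X^2)
  if (nx2 == 0) stop("reconstruction_quality: ||X|| is zero")
  R <- t(X) - W %*% A
  (1 - sum(R^2) / nx2) * 100
}

#' Contribution of a single synergy (percent)
#'
#' `lambda_s = (1 - ||X - w_s a_s||_F^2 / ||X||_F^2) * 100`; may be negative
#' when a lone rank-1 term is a poor approximation, and is reported as
#' computed.
#'
#' @param X data matrix (time x muscles)
#' @param w_s muscle-weight column (length = ncol(X))
#' @param a_s activation row (length = nrow(X))
#' @return lambda_s in percent
#' @export
synergy_contribution <- function(X, w_s, a_s) {
  reconstruction_quality(X, matrix(w_s, ncol = 1), matrix(a_s, nrow = 1))
}

#' Select the number of synergies from the reconstruction-quality profile
#'
#' Fits ranks `1..max_rank` (each rank warm-started from the previous best
#' solution plus one random column, in addition to random restarts, so the
#' lambda profile is non-decreasing) and picks the smallest `m` with
#' `lambda(m) >= lambda_cutoff` while every rank up to `m` still adds at
#' least `delta_cutoff` percentage points. Defaults are the envelope
#' criteria (80% / 1.5%); the coherence decomposition uses 55% / 4%.
#'
#' @param X non-negative matrix (time x muscles/pairs)
#' @param lambda_cutoff required total reconstruction quality (%)
#' @param delta_cutoff required added value per extra synergy (%)
#' @param max_rank largest rank scanned
#' @param n_restarts,seed,max_iter,tol passed to [nmf_synergies()]
#' @return list `m`, `lambda_profile` (length `max_rank`), `models`
#'   (fitted `synergy_model` per rank), `satisfied` (logical)
#' @export
select_rank <- function(X, lambda_cutoff = 80, delta_cutoff = 1.5,
                        max_rank = 8, n_restarts = 5, seed = 1L,
                        max_iter = 1000, tol = 1e-6) {
  stopifnot(lambda_cutoff > 0, delta_cutoff > 0)
  max_rank <- min(max_rank, min(dim(X)))
  models <- vector("list", max_rank)
  lambda <- numeric(max_rank)
  prev <- NULL
  for (m in seq_len(max_rank)) {
    warm <- NULL
    if (!is.null(prev)) {
      set.seed(seed + m)
      warm <- list(W = cbind(prev$W_raw,
                             matrix(runif(nrow(prev$W_raw), 0, 0.05),
                                    ncol = 1)),
                   A = rbind(prev$A,
                             matrix(runif(ncol(prev$A), 0, 0.05), nrow = 1)))
    }
    fit <- nmf_synergies(X, m, n_restarts = n_restarts, seed = seed + m,
                         max_iter = max_iter, tol = tol, init = warm)
    # W is unit-max normalized with the scale absorbed in A, so W %*% A is
    # unchanged and warm-starting from it preserves the objective
    prev <- list(W_raw = fit$W, A = fit$A)
    models[[m]] <- fit
    lambda[m] <- fit$lambda_total
  }
  gain <- c(lambda[1], diff(lambda))
  ok <- which(lambda >= lambda_cutoff &
                vapply(seq_len(max_rank),
                       function(m) all(gain[seq_len(m)] >= delta_cutoff),
                       logical(1)))
  if (length(ok) == 0) {
    warning("select_rank: no rank satisfies the criteria; returning max_rank")
    m_sel <- max_rank
    satisfied <- FALSE
  } else {
    m_sel <- min(ok)
    satisfied <- TRUE
  }
  list(m = m_sel, lambda_profile = lambda, models = models,
       satisfied = satisfied)
}

#' Order synergies by the timing of their main activation peak
#'
#' Computes, for each synergy, the circular mean location (% gait cycle) of
#' the per-stride maximum of its activation waveform, and reorders synergies
#' by that location. Ties are broken by the row index of the largest muscle
#' weight.
#'
#' @param model `synergy_model` with `A` partitioned into strides of `N`
#' @param N samples per normalized stride
#' @return the model with `W` columns / `A` rows permuted; element
#'   `peak_location` holds the per-synergy peak position in % gait cycle
#' @export
order_synergies <- function(model, N) {
  A <- model$A
  n_str <- floor(ncol(A) / N)
  stopifnot(n_str >= 1)
  peak_pos <- vapply(seq_len(model$m), function(s) {
    locs <- vapply(seq_len(n_str), function(k) {
      seg <- A[s, ((k - 1) * N + 1):(k * N)]
      (which.max(seg) - 1) / N
    }, numeric(1))
    circular_mean_pos(locs)
  }, numeric(1))
  tie <- apply(model$W, 2, which.max)
  ord <- order(round(peak_pos, 10), tie)
  model$W <- model$W[, ord, drop = FALSE]
  model$A <- model$A[ord, , drop = FALSE]
  model$peak_location <- 100 * peak_pos[ord]
  model$ordering <- ord
  model
}

#' Match recovered synergy columns to planted ones by cosine similarity
#'
#' Exhaustive search over column permutations (fine for m <= 8) maximizing
#' the total cosine similarity — the assignment-problem oracle used to score
#' recovery despite NMF's permutation ambiguity.
#'
#' @param W_rec,W_true matrices with the same number of columns
#' @return list `perm` (recovered column matched to each true column),
#'   `cosines` (per matched pair)
#' @export
match_columns <- function(W_rec, W_true) {
  m <- ncol(W_true)
  stopifnot(ncol(W_rec) == m, m <= 8)
  cos_mat <- outer(seq_len(m), seq_len(m), Vectorize(function(i, j) {
    a <- W_rec[, i]; b <- W_true[, j]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }))
  perms <- all_permutations(m)
  scores <- apply(perms, 1, function(p) sum(cos_mat[cbind(p, seq_len(m))]))
  best <- perms[which.max(scores), ]
  list(perm = best, cosines = cos_mat[cbind(best, seq_len(m))])
}

# all permutations of 1..n as rows (n <= 8)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("<synergy_model> m = %d, lambda = %.1f%%\n",
              x$m, x$lambda_total))
  invisible(x)
}
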