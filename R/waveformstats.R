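#' Bonferroni-corrected alpha for waveform comparisons
#'
#' `base / (n_condition_pairs * n_synergies)`; with the design's three
#' condition pairs and five synergies this is 0.05 / 15 = 1/300.
#'
#' @param base uncorrected alpha
#' @param n_condition_pairs number of pairwise condition comparisons
#' @param n_synergies number of synergies compared
#' @return corrected alpha
#' @export
bonferroni_alpha <- function(base = 0.05, n_condition_pairs = 3,
                             n_synergies = 5) {
  if (n_condition_pairs < 1 || n_synergies < 1)
    stop("bonferroni_alpha: counts must be >= 1")
  base / (n_condition_pairs * n_synergies)
}

#' Paired 1D statistical parametric mapping by sign-flip permutation
#'
#' Computes the pointwise paired t statistic along the normalized gait
#' cycle and performs cluster-level inference: contiguous runs of
#' `|t|` above the cluster-forming threshold (two-sided `alpha` quantile of
#' the t distribution) are scored by their mass (sum of `|t|`), and
#' compared against the max-cluster-mass distribution under random sign
#' flips of the subject difference waveforms. Run on raw amplitudes and,
#' when `normalize = TRUE` additionally on per-subject maximum-normalized
#' waveforms.
#'
#' @param A,B matrices `subjects x N`, matched rows (same subject both
#'   conditions)
#' @param alpha corrected alpha (cluster-forming and cluster-level)
#' @param n_perm number of random sign flips
#' @param seed integer seed
#' @param normalize also run the amplitude-normalized comparison
#' @return object of class `waveform_comparison`: `clusters_amplitude` and
#'   (optionally) `clusters_normalized`, each a data.frame with
#'   `start_pct`, `end_pct`, `mass`, `p`; plus `alpha`, `t` (raw t curve)
#' @export
spm_paired <- function(A, B, alpha = 1 / 300, n_perm = 1000, seed = 1L,
                       normalize = TRUE) {
  stopifnot(is.matrix(A), is.matrix(B), all(dim(A) == dim(B)))
  if (nrow(A) < 3) stop("spm_paired: need at least 3 matched subjects")
  set.seed(seed)
  res_amp <- spm_paired_one(A - B, alpha, n_perm)
  out <- list(clusters_amplitude = res_amp$clusters, t = res_amp$t,
              alpha = alpha)
  if (normalize) {
    norm_rows <- function(M) M / pmax(apply(M, 1, max), .Machine$double.eps)
    res_nrm <- spm_paired_one(norm_rows(A) - norm_rows(B), alpha, n_perm)
    out$clusters_normalized <- res_nrm$clusters
  }
  class(out) <- "waveform_comparison"
  out
}

# core sign-flip cluster test on a difference matrix (subjects x N).
# Sign flips leave the per-point sum of squares unchanged, so the whole
# permutation t-map reduces to the matrix of flipped means.
spm_paired_one <- function(D, alpha, n_perm) {
  n <- nrow(D)
  N <- ncol(D)
  ss <- colSums(D^2)
  t_from_mean <- function(mu) {
    varr <- (ss - n * mu^2) / (n - 1)
    ifelse(varr > 0, mu / sqrt(varr / n), 0)
  }
  thr <- qt(1 - alpha / 2, df = n - 1)
  cluster_masses <- function(tv) {
    above <- abs(tv) > thr
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    idx <- which(r$values)
    data.frame(start = starts[idx], end = ends[idx],
               mass = vapply(idx, function(k) {
                 sum(abs(tv[starts[k]:ends[k]]))
               }, numeric(1)))
  }
  t_obs <- t_from_mean(colMeans(D))
  obs <- cluster_masses(t_obs)
  flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  mu_perm <- flips %*% D / n # n_perm x N flipped means
  null_max <- vapply(seq_len(n_perm), function(b) {
    cm <- cluster_masses(t_from_mean(mu_perm[b, ]))
    if (is.null(cm)) 0 else max(cm$mass)
  }, numeric(1))
  if (is.null(obs)) {
    clusters <- data.frame(start_pct = numeric(0), end_pct = numeric(0),
                           mass = numeric(0), p = numeric(0))
  } else {
    p <- vapply(obs$mass, function(m) {
      (1 + sum(null_max >= m)) / (1 + n_perm)
    }, numeric(1))
    clusters <- data.frame(start_pct = 100 * (obs$start - 1) / N,
                           end_pct = 100 * (obs$end - 1) / N,
                           mass = obs$mass, p = p)
    clusters <- clusters[clusters$p <= alpha, , drop = FALSE]
  }
  list(clusters = clusters, t = t_obs)
}

#' Repeated-measures ANOVA on network metrics with post-hoc paired tests
#'
#' Univariate ANOVA of each metric on condition with subject as random
#' factor (values are averaged over layers within subject x condition for
#' the omnibus test), followed by post-hoc paired t-tests per layer
#' (frequency component) at `posthoc_alpha`.
#'
#' @param metrics data.frame with columns `subject`, `condition`, `layer`,
#'   `value`
#' @param alpha omnibus alpha
#' @param posthoc_alpha post-hoc alpha (0.005 in the design)
#' @return list `F`, `df`, `p`, `significant`, `posthoc` (data.frame:
#'   layer, condition pair, t, p, significant)
#' @export
metric_anova <- function(metrics, alpha = 0.05, posthoc_alpha = 0.005) {
  stopifnot(all(c("subject", "condition", "value") %in% names(metrics)))
  if (length(unique(metrics$condition)) < 2)
    stop("metric_anova: need at least 2 conditions")
  if (!"layer" %in% names(metrics)) metrics$layer <- "all"
  cell <- stats::aggregate(value ~ subject + condition, metrics, mean)
  cell$subject <- factor(cell$subject)
  cell$condition <- factor(cell$condition)
  fit <- aov(value ~ condition + Error(subject), data = cell)
  tab <- summary(fit)[["Error: Within"]][[1]]
  row <- which(trimws(rownames(tab)) == "condition")
  Fval <- tab[row, "F value"]
  pval <- tab[row, "Pr(>F)"]
  # degenerate case (identical values across conditions): both the
  # condition and residual sums of squares vanish to rounding noise and the
  # F ratio is 0/0 -- report no effect
  tol <- 1e-12 * (sum(cell$value^2) + 1)
  if (!is.finite(Fval) ||
      (tab[row, "Sum Sq"] < tol && sum(tab[, "Sum Sq"]) < 2 * tol)) {
    Fval <- 0
    pval <- 1
  }
  dfs <- tab[, "Df"]
  conds <- levels(cell$condition)
  ph <- list()
  for (ly in unique(metrics$layer)) {
    for (a in seq_along(conds)) {
      for (b in seq_along(conds)) {
        if (b <= a) next
        da <- metrics[metrics$layer == ly & metrics$condition == conds[a], ]
        db <- metrics[metrics$layer == ly & metrics$condition == conds[b], ]
        common <- intersect(da$subject, db$subject)
        if (length(common) < 3) next
        va <- da$value[match(common, da$subject)]
        vb <- db$value[match(common, db$subject)]
        d <- va - vb
        if (sd(d) == 0) {
          tstat <- 0
          pp <- 1
        } else {
          tstat <- mean(d) / (sd(d) / sqrt(length(d)))
          pp <- 2 * pt(-abs(tstat), df = length(d) - 1)
        }
        ph[[length(ph) + 1]] <- data.frame(
          layer = ly, cond_a = conds[a], cond_b = conds[b],
          t = tstat, p = pp, significant = pp <= posthoc_alpha)
      }
    }
  }
  posthoc <- if (length(ph)) do.call(rbind, ph) else NULL
  list(F = Fval, df = unname(dfs), p = pval,
       significant = isTRUE(pval <= alpha), posthoc = posthoc)
}
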