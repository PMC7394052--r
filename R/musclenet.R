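#' Construct a multiplex network object
#'
#' @param layers list of square symmetric non-negative matrices with zero
#'   diagonal, all over the same node set
#' @param nodes node labels
#' @param layer_labels one label per layer
#' @return object of class `multiplex_network`
#' @export
multiplex_network <- function(layers, nodes = NULL,
                              layer_labels = names(layers)) {
  stopifnot(length(layers) >= 1)
  n <- nrow(layers[[1]])
  if (is.null(nodes)) nodes <- rownames(layers[[1]])
  if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  if (is.null(layer_labels)) layer_labels <- paste0("layer", seq_along(layers))
  layers <- lapply(layers, function(L) {
    stopifnot(nrow(L) == n, ncol(L) == n, all(L >= 0))
    stopifnot(max(abs(L - t(L))) < 1e-8)
    diag(L) <- 0
    dimnames(L) <- list(nodes, nodes)
    L
  })
  net <- list(layers = layers, nodes = nodes, layer_labels = layer_labels)
  class(net) <- "multiplex_network"
  net
}

#' Synergy multiplex network from a fitted synergy model
#'
#' Layer `j` is the one-mode projection `w_j %*% t(w_j)` of the bipartite
#' muscle-synergy graph (diagonal removed), scaled by the sum over
#' coordination modes of the trapezoidal integral of synergy `j`'s
#' activation waveform over the gait cycle (0-100%), so strongly expressed
#' synergies weigh more.
#'
#' @param model `synergy_model` (W: muscles x m, A: m x SC*N)
#' @param N samples per normalized stride
#' @param blocks optional data.frame with a `mode` column, one row per
#'   stride block of `A`; waveforms are averaged within mode before
#'   integrating. Without it every block counts as its own condition.
#' @return `multiplex_network` with `m` layers
#' @export
synergy_layers <- function(model, N, blocks = NULL) {
  m <- model$m
  n_blk <- floor(ncol(model$A) / N)
  xpct <- seq(0, 100, length.out = N)
  weights <- vapply(seq_len(m), function(s) {
    segs <- matrix(model$A[s, seq_len(n_blk * N)], N, n_blk)
    if (!is.null(blocks) && nrow(blocks) == n_blk) {
      modes <- unique(blocks$mode)
      wavs <- sapply(modes, function(md) {
        rowMeans(segs[, blocks$mode == md, drop = FALSE])
      })
    } else {
      wavs <- segs
    }
    sum(apply(as.matrix(wavs), 2, function(y) trapz(xpct, y)))
  }, numeric(1))
  layers <- lapply(seq_len(m), function(s) {
    L <- model$W[, s] %*% t(model$W[, s]) * weights[s]
    diag(L) <- 0
    L
  })
  multiplex_network(layers, nodes = rownames(model$W),
                    layer_labels = paste0("S", seq_len(m)))
}

# trapezoidal rule
trapz <- function(x, y) {
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Coherence multiplex network from fitted frequency components
#'
#' For each frequency component and condition, the per-pair component
#' weights are placed into a symmetric 26 x 26 adjacency and averaged over
#' subjects, giving an `m x n_conditions` multiplex.
#'
#' @param components `coherence_components` (A_coh: m x SC*n_pairs, columns
#'   subject-condition-major, pair minor)
#' @param sc data.frame with `subject` and `condition` per block, in column
#'   block order (e.g. from a `coherence_set`)
#' @param pairs `n_pairs x 2` pair index (i < j); default [muscle_pairs()]
#' @param nodes node labels; default [muscle_labels()]
#' @return `multiplex_network` with `m * n_conditions` layers labelled
#'   `"<component>|<condition>"`
#' @export
coherence_layers <- function(components, sc, pairs = muscle_pairs(),
                             nodes = muscle_labels()) {
  m <- components$m
  n_pairs <- nrow(pairs)
  n_nodes <- length(nodes)
  if (nrow(sc) == 0) stop("coherence_layers: missing condition blocks")
  stopifnot(ncol(components$A_coh) == nrow(sc) * n_pairs)
  conditions <- unique(sc$condition)
  layers <- list()
  labels <- character(0)
  for (s in seq_len(m)) {
    for (cond in conditions) {
      blk <- which(sc$condition == cond)
      if (length(blk) == 0) stop("coherence_layers: missing condition ", cond)
      mats <- lapply(blk, function(b) {
        v <- components$A_coh[s, ((b - 1) * n_pairs + 1):(b * n_pairs)]
        L <- matrix(0, n_nodes, n_nodes)
        L[pairs] <- v
        L + t(L)
      })
      layers[[length(layers) + 1]] <- Reduce(`+`, mats) / length(mats)
      labels <- c(labels, sprintf("C%d|%s", s, cond))
    }
  }
  multiplex_network(layers, nodes = nodes, layer_labels = labels)
}

#' Threshold a multiplex to a minimally-connected, equal-edge-count network
#'
#' Finds the largest global threshold `tau*` at which every node keeps at
#' least one supra-threshold edge in at least one layer (`tau*` equals the
#' smallest, over nodes, of the strongest incident edge weight across
#' layers). `k` is the largest per-layer count of edges at or above `tau*`;
#' every layer then keeps its `k` strongest edges (supra-threshold edges
#' first, padded with its strongest sub-threshold edges), so edge counts are
#' constant across layers.
#'
#' @param net `multiplex_network`
#' @return list `net` (thresholded), `tau`, `k`, `removed` and `kept`
#'   summaries (mean, sd, n of edge weights)
#' @export
minimally_connect <- function(net) {
  n <- length(net$nodes)
  ut <- upper.tri(matrix(0, n, n))
  # strongest incident edge per node across layers
  node_max <- apply(do.call(cbind, lapply(net$layers, function(L) {
    apply(L, 1, max)
  })), 1, max)
  tau <- min(node_max)
  k <- max(vapply(net$layers, function(L) sum(L[ut] >= tau & L[ut] > 0),
                  numeric(1)))
  removed <- numeric(0)
  kept <- numeric(0)
  new_layers <- lapply(net$layers, function(L) {
    w <- L[ut]
    pos <- which(w > 0)
    if (length(pos) < k)
      warning("minimally_connect: layer has fewer than k nonzero edges")
    ord <- pos[order(-(w[pos] >= tau), -w[pos])] # supra first, then strongest
    keep_idx <- ord[seq_len(min(k, length(ord)))]
    drop_idx <- setdiff(pos, keep_idx)
    removed <<- c(removed, w[drop_idx])
    kept <<- c(kept, w[keep_idx])
    wk <- numeric(length(w))
    wk[keep_idx] <- w[keep_idx]
    M <- matrix(0, n, n)
    M[ut] <- wk
    M + t(M)
  })
  summarize <- function(v) {
    list(mean = if (length(v)) mean(v) else NA_real_,
         sd = if (length(v) > 1) sd(v) else NA_real_, n = length(v))
  }
  list(net = multiplex_network(new_layers, net$nodes, net$layer_labels),
       tau = tau, k = k, removed = summarize(removed),
       kept = summarize(kept))
}

#' Community structure of a multiplex network (Louvain)
#'
#' Each layer is normalized to unit total weight and the layers are
#' averaged; Louvain modularity optimization runs `n_runs` times with
#' seeded starts on the aggregate and the best-modularity partition is
#' kept. Per-layer modularity is evaluated by applying that partition to
#' every layer.
#'
#' @param net `multiplex_network`
#' @param seed integer seed
#' @param n_runs Louvain restarts
#' @return object of class `muscle_partition`: `membership` (named integer
#'   vector), `modularity` (aggregate), `modularity_per_layer`
#' @export
communities_multiplex <- function(net, seed = 1L, n_runs = 10) {
  totals <- vapply(net$layers, sum, numeric(1))
  if (all(totals == 0)) stop("communities_multiplex: empty network")
  norm_layers <- lapply(net$layers, function(L) {
    if (sum(L) > 0) L / sum(L) else L
  })
  agg <- Reduce(`+`, norm_layers) / length(norm_layers)
  g <- igraph::graph_from_adjacency_matrix(agg, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best <- NULL
  for (r in seq_len(n_runs)) {
    set.seed(seed + r - 1)
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    q <- igraph::modularity(cl)
    if (is.null(best) || q > best$q) best <- list(cl = cl, q = q)
  }
  memb <- igraph::membership(best$cl)
  names(memb) <- net$nodes
  per_layer <- vapply(net$layers, function(L) {
    if (sum(L) == 0) return(NA_real_)
    gl <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    igraph::modularity(gl, memb, weights = igraph::E(gl)$weight)
  }, numeric(1))
  names(per_layer) <- net$layer_labels
  out <- list(membership = as.integer(memb), nodes = net$nodes,
              modularity = best$q, modularity_per_layer = per_layer)
  names(out$membership) <- net$nodes
  class(out) <- "muscle_partition"
  out
}

#' Weighted graph metrics of one layer
#'
#' Weights are first normalized by the layer maximum. Global efficiency is
#' the mean over node pairs of the inverse weighted shortest-path length
#' (edge length = 1 / normalized weight; disconnected pairs contribute 0).
#' Transitivity is the ratio of closed to all weighted triplets with
#' geometric-mean triangle weights. Average strength is the mean row sum of
#' the raw weights.
#'
#' @param layer symmetric non-negative matrix with zero diagonal
#' @return list `global_efficiency`, `transitivity`, `average_strength`
#' @export
layer_metrics <- function(layer) {
  n <- nrow(layer)
  if (all(layer == 0)) {
    warning("layer_metrics: all-zero layer")
    return(list(global_efficiency = 0, transitivity = 0,
                average_strength = 0))
  }
  Wn <- layer / max(layer)
  g <- igraph::graph_from_adjacency_matrix(Wn, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  eff <- mean(inv)
  Wc <- Wn^(1 / 3)
  closed <- sum(diag(Wc %*% Wc %*% Wc)) # 2 * sum over ordered triplets
  Ws <- sqrt(Wn)
  trip <- sum(rowSums(Ws)^2 - rowSums(Wn)) # ordered open+closed triplets
  trans <- if (trip > 0) closed / trip else 0
  list(global_efficiency = eff, transitivity = trans,
       average_strength = mean(rowSums(layer)))
}

#' Rand and adjusted Rand indices with a permutation p-value
#'
#' Pair-counting agreement between two partitions of the same node set; the
#' p-value is the fraction of `n_perm` label permutations of the second
#' partition reaching an adjusted Rand index at least as large as observed.
#'
#' @param p1,p2 integer/factor membership vectors over the same nodes
#' @param n_perm label permutations for the p-value (0 disables)
#' @param seed integer seed
#' @return list `rand`, `adjusted_rand`, `p_value`
#' @export
compare_partitions <- function(p1, p2, n_perm = 999, seed = 1L) {
  stopifnot(length(p1) == length(p2), length(p1) >= 2)
  obs <- rand_indices(p1, p2)
  p_val <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    null_ari <- replicate(n_perm, rand_indices(p1, sample(p2))$adjusted_rand)
    p_val <- (1 + sum(null_ari >= obs$adjusted_rand)) / (1 + n_perm)
  }
  c(obs, list(p_value = p_val))
}

rand_indices <- function(p1, p2) {
  tab <- table(p1, p2)
  n <- length(p1)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  total <- ch2(n)
  rand <- (total + 2 * sum_ij - sum_a - sum_b) / total
  expected <- sum_a * sum_b / total
  max_ind <- (sum_a + sum_b) / 2
  ari <- if (max_ind == expected) 1 else (sum_ij - expected) / (max_ind - expected)
  list(rand = rand, adjusted_rand = ari)
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(sprintf("<multiplex_network> %d nodes x %d layers (%s)\n",
              length(x$nodes), length(x$layers),
              paste(utils::head(x$layer_labels, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.muscle_partition <- function(x, ...) {
  cat(sprintf("<muscle_partition> %d communities, aggregate modularity %.3f\n",
              length(unique(x$membership)), x$modularity))
  invisible(x)
}
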