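# Global graph measures on masked individual connectomes, with
# normalization against degree-preserving rewired null networks.

#' Average node degree
#'
#' Mean over nodes of the number of incident edges with weight > 0; the
#' binary "wiring cost" of the network. Invariant to any strictly positive
#' reweighting of the edges.
#'
#' @param c a [connectome()] or weight matrix.
#' @return average binary degree, in `[0, n - 1]`.
#' @export
average_node_degree <- function(c) {
  w <- as_weight_matrix(c)
  mean(rowSums(w > 0))
}

#' Weighted clustering coefficient (network average)
#'
#' Onnela-style weighted clustering: edge weights are first scaled to
#' `(0, 1]` by dividing by the maximum weight; each node's coefficient is the
#' sum over triangles through the node of the geometric mean of the three
#' (normalized) triangle weights, divided by `k(k-1)` for binary degree `k`.
#' Nodes with degree < 2 contribute 0. For a binary network this reduces to
#' the ordinary clustering coefficient.
#'
#' @param c a [connectome()] or nonnegative symmetric weight matrix.
#' @return the network-average weighted clustering coefficient (>= 0).
#' @export
weighted_clustering <- function(c) {
  w <- as_weight_matrix(c)
  mx <- max(w)
  if (mx == 0) return(0)
  cpp_clustering_onnela(w / mx)
}

#' Weighted global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' edge length defined as the reciprocal of the edge weight (the standard
#' toolbox convention; a zero weight is an absent edge). Disconnected pairs
#' contribute 0, so the measure is defined for fragmented networks.
#'
#' @param c a [connectome()] or nonnegative symmetric weight matrix.
#' @return global efficiency (>= 0; equals 1 for a unit-weight complete
#'   graph).
#' @export
weighted_global_efficiency <- function(c) {
  cpp_global_efficiency(as_weight_matrix(c))
}

#' Degree-preserving null ensemble for a connectome
#'
#' Builds `n_null` random networks of the same size, edge count, and binary
#' degree sequence as the source network by double-edge-swap rewiring of the
#' binary topology. Weights travel with their edges (no weight reshuffling),
#' so the weight multiset is preserved while the topology is randomized.
#' Each null is produced by `swaps_per_edge * m` swap attempts; attempts
#' that would create self-loops or duplicate edges are rejected, which makes
#' rigid graphs (e.g. complete graphs) map to themselves.
#'
#' @param c a [connectome()] or weight matrix (typically after
#'   [apply_group_mask()]).
#' @param n_null number of null networks (default 100).
#' @param seed integer seed for the ensemble's RNG stream.
#' @param swaps_per_edge rewiring intensity (default 10).
#' @return an object of class `null_ensemble` with the per-null raw
#'   clustering and efficiency values, the rewired edge lists, and the
#'   shared weight vector.
#' @export
make_null_ensemble <- function(c, n_null = 100L, seed = 1L,
                               swaps_per_edge = 10L) {
  w <- as_weight_matrix(c)
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 4) stop("need at least 4 edges to build a null ensemble", call. = FALSE)
  weights <- w[ut]
  n_attempts <- as.integer(swaps_per_edge * m)
  edges0 <- cbind(as.integer(ut[, 1]), as.integer(ut[, 2]))
  res <- with_seed(seed, {
    lapply(seq_len(n_null), function(i) {
      e <- cpp_rewire(edges0, n, n_attempts)
      wn <- matrix(0, n, n)
      wn[e] <- weights
      wn[e[, 2:1, drop = FALSE]] <- weights
      list(edges = e,
           clustering = weighted_clustering(wn),
           efficiency = cpp_global_efficiency(wn),
           n_swapped = attr(e, "n_swapped"))
    })
  })
  structure(list(
    n_nodes = n,
    n_null = n_null,
    seed = seed,
    swaps_per_edge = swaps_per_edge,
    weights = weights,
    edges = lapply(res, `[[`, "edges"),
    clustering = vapply(res, `[[`, numeric(1), "clustering"),
    efficiency = vapply(res, `[[`, numeric(1), "efficiency"),
    n_swapped = vapply(res, `[[`, numeric(1), "n_swapped")
  ), class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("<null_ensemble> ", x$n_null, " nulls of ", length(x$weights),
      " edges on ", x$n_nodes, " nodes (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Null-normalized clustering and efficiency
#'
#' Divides the observed weighted clustering coefficient and global
#' efficiency by their means over the degree-matched null ensemble, giving
#' the normalized clustering coefficient (gamma, a segregation measure) and
#' normalized global efficiency (e_global, an integration measure).
#'
#' @param c the source [connectome()] the ensemble was built from.
#' @param ens a [make_null_ensemble()] result.
#' @return named list with `gamma` and `e_global`.
#' @export
normalized_measures <- function(c, ens) {
  stopifnot(inherits(ens, "null_ensemble"))
  mc <- mean(ens$clustering)
  me <- mean(ens$efficiency)
  if (mc == 0 || me == 0) {
    stop("null ensemble mean is zero; normalized measure undefined",
         call. = FALSE)
  }
  list(gamma = weighted_clustering(c) / mc,
       e_global = weighted_global_efficiency(c) / me)
}

#' All global graph measures for one masked connectome
#'
#' Computes overall connectivity (on the unmasked connectome), then masks by
#' the consensus edge mask and computes average node degree, normalized
#' clustering coefficient and normalized global efficiency.
#'
#' @param c an individual (unmasked) [connectome()].
#' @param mask an `edge_mask` from [proportional_threshold()].
#' @param n_null,seed,swaps_per_edge null-ensemble settings, see
#'   [make_null_ensemble()].
#' @return one-row data.frame with columns `overall`, `nu`, `gamma`,
#'   `e_global`, `sparsity`.
#' @export
graph_measures <- function(c, mask, n_null = 100L, seed = 1L,
                           swaps_per_edge = 10L) {
  masked <- apply_group_mask(c, mask)
  ens <- make_null_ensemble(masked, n_null = n_null, seed = seed,
                            swaps_per_edge = swaps_per_edge)
  nm <- normalized_measures(masked, ens)
  data.frame(overall = overall_connectivity(c),
             nu = average_node_degree(masked),
             gamma = nm$gamma,
             e_global = nm$e_global,
             sparsity = mask$sparsity)
}
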