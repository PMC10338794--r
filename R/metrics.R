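as_weight_matrix <- function(net) {
  if (inherits(net, "thresholded_network")) return(net$w)
  w <- as.matrix(net)
  if (nrow(w) != ncol(w)) stop("not a square weight matrix", call. = FALSE)
  w
}

check_connected_positive <- function(w) {
  n <- nrow(w)
  seen <- rep(FALSE, n); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier) > 0) {
    nb <- which(colSums(w[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  if (!all(seen)) stop("network is disconnected", call. = FALSE)
  invisible(TRUE)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node clustering is the mean geometric triangle intensity over
#' neighbor pairs: `(2 / (k_i (k_i - 1))) * sum (w'_ij w'_ih w'_jh)^(1/3)`
#' with weights rescaled by the network maximum (`w' = w / max(w)`), so
#' values lie in `[0, 1]`. Nodes with degree < 2 contribute 0. The global
#' coefficient `cp` is the mean over all nodes.
#'
#' @param net A [threshold_with_mst()] network or weight matrix.
#' @return List with `cp` (scalar) and `nodal` (per-node values).
#' @export
clustering_coefficient <- function(net) {
  w <- as_weight_matrix(net)
  if (nrow(w) == 0) stop("empty network", call. = FALSE)
  nodal <- cpp_clustering(w)
  names(nodal) <- rownames(w)
  list(cp = mean(nodal), nodal = nodal)
}

#' Characteristic path length
#'
#' Edge distance is the reciprocal of the connection weight (strong
#' correlations are short hops); `lp` is the mean shortest-path distance
#' over all unordered node pairs.
#'
#' @param net A [threshold_with_mst()] network or weight matrix.
#' @return List with `lp` (scalar) and `distances` (N x N matrix).
#' @export
characteristic_path_length <- function(net) {
  w <- as_weight_matrix(net)
  check_connected_positive(w)
  d <- cpp_distances(w)
  dimnames(d) <- dimnames(w)
  list(lp = mean(d[upper.tri(d)]), distances = d)
}

#' Nodal degree
#'
#' Binary count of incident edges per node (not weighted strength).
#'
#' @param net A [threshold_with_mst()] network or weight matrix.
#' @return Integer vector of per-node degrees.
#' @export
nodal_degree <- function(net) {
  w <- as_weight_matrix(net)
  d <- as.integer(rowSums(w > 0))
  names(d) <- rownames(w)
  d
}

#' Nodal betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node, with
#' edge distance `1/weight`, summed over unordered source-target pairs
#' (unnormalized). Equally short paths split the count.
#'
#' @param net A [threshold_with_mst()] network or weight matrix.
#' @return Numeric vector of per-node betweenness.
#' @export
betweenness_centrality <- function(net) {
  w <- as_weight_matrix(net)
  check_connected_positive(w)
  b <- cpp_betweenness(w)
  names(b) <- rownames(w)
  b
}

#' Degree-preserving (Maslov-Sneppen) rewiring
#'
#' Repeated double-edge swaps — pick edges `(a,b)` and `(c,d)`, rewire to
#' `(a,d)` and `(c,b)` when no self-loop or duplicate edge would result —
#' randomize the topology while preserving every node's degree exactly.
#' Weights travel with their edges, so the weight multiset is preserved
#' too. Attempted swaps that would violate the constraints are skipped and
#' counted (attribute `failed_swaps`).
#'
#' @param net A [threshold_with_mst()] network or weight matrix.
#' @param n_swaps Number of swap attempts (default 10 per edge).
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return A rewired network of the same class as the input.
#' @export
maslov_sneppen_rewire <- function(net, n_swaps = NULL, seed = NULL) {
  w <- as_weight_matrix(net)
  m <- sum(w[upper.tri(w)] > 0)
  if (m < 2) stop("need at least 2 edges to rewire", call. = FALSE)
  n_swaps <- n_swaps %||% (10L * m)
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_rewire(w, as.integer(n_swaps))
  dimnames(out) <- dimnames(w)
  if (inherits(net, "thresholded_network")) {
    res <- new_thresholded_network(out, net$sparsity, net$region_names)
    attr(res, "failed_swaps") <- attr(out, "failed_swaps")
    res
  } else out
}

#' Null ensemble of degree-matched random networks
#'
#' Generates `n_nulls` independent Maslov-Sneppen rewirings of the real
#' network and records each null's clustering coefficient and
#' characteristic path length, for use in [normalized_metrics()].
#'
#' @param net A [threshold_with_mst()] network or weight matrix.
#' @param n_nulls Ensemble size (default 1000).
#' @param swap_multiplier Swap attempts per edge for each null (default 10).
#' @param seed Optional integer seed.
#' @return Object of class `null_ensemble`: `cp`, `lp` (length `n_nulls`),
#'   `mean_null_cp`, `mean_null_lp`, `n_nulls`.
#' @export
null_ensemble <- function(net, n_nulls = 1000, swap_multiplier = 10,
                          seed = NULL) {
  w <- as_weight_matrix(net)
  m <- sum(w[upper.tri(w)] > 0)
  if (m < 2) stop("need at least 2 edges", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_null_global(w, as.integer(n_nulls),
                         as.integer(swap_multiplier * m))
  structure(list(cp = res[, 1], lp = res[, 2],
                 mean_null_cp = mean(res[, 1]),
                 mean_null_lp = mean(res[, 2]),
                 n_nulls = n_nulls),
            class = "null_ensemble")
}

#' Normalized small-world metrics
#'
#' `gamma` is the real clustering coefficient divided by the null-ensemble
#' mean, `lambda` the same ratio for path length, and `sigma =
#' gamma / lambda` the small-world scalar (`gamma > 1` with
#' `lambda` near 1, hence `sigma > 1`, indicates small-world organization).
#'
#' @param net A [threshold_with_mst()] network or weight matrix.
#' @param ensemble A [null_ensemble()] built from `net`.
#' @return List with `gamma`, `lambda`, `sigma`.
#' @export
normalized_metrics <- function(net, ensemble) {
  if (ensemble$mean_null_cp <= 0 || ensemble$mean_null_lp <= 0 ||
      !is.finite(ensemble$mean_null_cp) || !is.finite(ensemble$mean_null_lp))
    stop("degenerate null ensemble (non-positive mean null metric)",
         call. = FALSE)
  g <- clustering_coefficient(net)$cp / ensemble$mean_null_cp
  l <- characteristic_path_length(net)$lp / ensemble$mean_null_lp
  list(gamma = g, lambda = l, sigma = g / l)
}

#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal integral of the metric over sparsity, giving a
#' threshold-independent per-subject summary.
#'
#' @param curve Metric values, one per grid level.
#' @param grid A [sparsity_grid()] (length >= 2, matching `curve`).
#' @return Scalar AUC.
#' @export
auc_over_grid <- function(curve, grid) {
  x <- as.numeric(grid)
  if (length(curve) != length(x))
    stop("curve length ", length(curve), " != grid length ", length(x),
         call. = FALSE)
  if (length(x) < 2) stop("grid must have at least 2 levels", call. = FALSE)
  sum(diff(x) * (head(curve, -1) + tail(curve, -1)) / 2)
}

#' Full network profile of one subject
#'
#' Sweeps the sparsity grid, computes the four global metrics (clustering
#' coefficient, path length, and their null-normalized versions gamma and
#' lambda, plus sigma) and optionally the two nodal metrics (degree,
#' betweenness) at every level, and integrates each curve into an AUC.
#'
#' @param c A [pearson_connectivity()] result (or symmetric matrix).
#' @param grid A [sparsity_grid()].
#' @param n_nulls Null networks per sparsity level (default 1000).
#' @param swap_multiplier Swap attempts per edge for each null.
#' @param seed Optional integer seed governing the null ensembles.
#' @param nodal Compute nodal metrics too (default `TRUE`).
#' @return Object of class `subject_profile`: `global` (data frame with
#'   one row per sparsity: cp, lp, gamma, lambda, sigma), `degree` and
#'   `betweenness` (levels x nodes matrices, when `nodal`), and `auc`
#'   (named list: `cp`, `lp`, `gamma`, `lambda`, `sigma`, and per-node
#'   `degree`/`betweenness` vectors).
#' @export
profile_subject <- function(c, grid = sparsity_grid(), n_nulls = 1000,
                            swap_multiplier = 10, seed = NULL,
                            nodal = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  nets <- sweep_thresholds(c, grid)
  nlev <- length(nets)
  n <- length(nets[[1]]$region_names)
  glob <- matrix(NA_real_, nlev, 5,
                 dimnames = list(NULL, c("cp", "lp", "gamma", "lambda",
                                         "sigma")))
  deg <- bet <- NULL
  if (nodal) {
    deg <- matrix(NA_real_, nlev, n,
                  dimnames = list(NULL, nets[[1]]$region_names))
    bet <- deg
  }
  prof <- cpp_global_profile(lapply(nets, `[[`, "w"),
                             as.integer(n_nulls),
                             as.integer(swap_multiplier))
  g <- prof[, 1] / prof[, 3]
  l <- prof[, 2] / prof[, 4]
  glob[, "cp"] <- prof[, 1]
  glob[, "lp"] <- prof[, 2]
  glob[, "gamma"] <- g
  glob[, "lambda"] <- l
  glob[, "sigma"] <- g / l
  if (nodal) {
    for (i in seq_len(nlev)) {
      deg[i, ] <- nodal_degree(nets[[i]])
      bet[i, ] <- betweenness_centrality(nets[[i]])
    }
  }
  auc <- list(cp = auc_over_grid(glob[, "cp"], grid),
              lp = auc_over_grid(glob[, "lp"], grid),
              gamma = auc_over_grid(glob[, "gamma"], grid),
              lambda = auc_over_grid(glob[, "lambda"], grid),
              sigma = auc_over_grid(glob[, "sigma"], grid))
  if (nodal) {
    auc$degree <- apply(deg, 2, auc_over_grid, grid = grid)
    auc$betweenness <- apply(bet, 2, auc_over_grid, grid = grid)
  }
  structure(list(global = as.data.frame(cbind(sparsity = as.numeric(grid),
                                              glob)),
                 degree = deg, betweenness = bet, auc = auc,
                 subject_id = if (inherits(c, "connectivity_matrix"))
                   c$subject_id else NULL),
            class = "subject_profile")
}
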