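#' Pearson connectivity matrix from a regional time series
#'
#' @param series A [roi_timeseries()] (T >= 3, no zero-variance region).
#' @return Object of class `connectivity_matrix`: `r` (N x N symmetric
#'   Pearson matrix, unit diagonal), `region_names`, `subject_id`.
#' @export
pearson_connectivity <- function(series) {
  x <- series$data
  v <- apply(x, 2, var)
  if (any(v == 0))
    stop("zero-variance region(s): ",
         paste(series$region_names[v == 0], collapse = ", "), call. = FALSE)
  r <- cor(x)
  diag(r) <- 1
  structure(list(r = r, region_names = series$region_names,
                 subject_id = series$subject_id),
            class = "connectivity_matrix")
}

#' Sparsity threshold grid
#'
#' The default grid, 0.12 to 0.40 in steps of 0.01 (29 levels), spans the
#' range over which sparse brain networks remain estimable and small-world
#' analysis is meaningful, avoiding commitment to any single threshold.
#'
#' @param s_min,s_max,step Grid limits and spacing.
#' @return Numeric vector of class `sparsity_grid` (ascending, inclusive
#'   of both ends).
#' @export
sparsity_grid <- function(s_min = 0.12, s_max = 0.40, step = 0.01) {
  stopifnot(step > 0, s_min > 0, s_max >= s_min, s_max <= 1)
  n_steps <- floor((s_max - s_min) / step + 1e-9)
  values <- round(s_min + step * (0:n_steps), 10)
  structure(values, class = c("sparsity_grid", "numeric"))
}

#' Edge count implied by a sparsity level
#'
#' Sparsity is the fraction of realized edges among all `n(n-1)/2` node
#' pairs; the edge budget is round-half-up of `sparsity * n(n-1)/2`
#' (round-half-up keeps counts platform-stable).
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param sparsity Value in (0, 1].
#' @param require_connected If `TRUE` (default), error when the budget is
#'   below `n_nodes - 1`, the minimum for a connected network.
#' @return Integer edge count.
#' @export
edge_budget <- function(n_nodes, sparsity, require_connected = TRUE) {
  stopifnot(n_nodes >= 2, sparsity > 0, sparsity <= 1)
  budget <- as.integer(round_half_up(sparsity * n_nodes * (n_nodes - 1) / 2))
  if (require_connected && budget < n_nodes - 1)
    stop("sparsity ", sparsity, " gives ", budget, " edges; at least ",
         n_nodes - 1, " are needed to keep ", n_nodes,
         " nodes connected", call. = FALSE)
  budget
}

# Deterministic edge ranking shared by all sparsity levels of a subject:
# MST edges of the positive-weight graph first (guaranteeing connectedness
# at any admissible budget), then remaining positive edges by descending r,
# ties broken lexicographically on (i, j). Returns a data frame of edges in
# retention order.
rank_edges_mst <- function(r) {
  n <- nrow(r)
  idx <- which(upper.tri(r) & r > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no positive correlations to threshold",
                           call. = FALSE)
  w <- r[idx]
  g <- igraph::graph_from_data_frame(
    data.frame(from = idx[, 1], to = idx[, 2]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  if (igraph::components(g)$no > 1)
    stop("positive-correlation subgraph is disconnected; cannot build a ",
         "spanning backbone", call. = FALSE)
  # maximum-correlation spanning tree == MST on distance 1 - r
  mst <- igraph::mst(g, weights = 1 - w)
  in_mst <- rep(FALSE, nrow(idx))
  mst_ends <- igraph::ends(mst, igraph::E(mst))
  mst_key <- paste(pmin(as.integer(mst_ends[, 1]), as.integer(mst_ends[, 2])),
                   pmax(as.integer(mst_ends[, 1]), as.integer(mst_ends[, 2])))
  key <- paste(idx[, 1], idx[, 2])
  in_mst <- key %in% mst_key
  ord <- order(!in_mst, -w, idx[, 1], idx[, 2])
  data.frame(i = idx[ord, 1], j = idx[ord, 2], w = w[ord],
             mst = in_mst[ord])
}

new_thresholded_network <- function(w, sparsity, region_names) {
  structure(list(w = w, sparsity = sparsity,
                 edge_count = sum(w[upper.tri(w)] > 0),
                 region_names = region_names),
            class = "thresholded_network")
}

#' Threshold a connectivity matrix at one sparsity level
#'
#' Keeps the maximum-correlation spanning tree of the positive-correlation
#' graph (computed as the minimum spanning tree on distance `1 - r`), then
#' adds the remaining positive edges in descending correlation order until
#' the [edge_budget()] is reached. The result is a weighted undirected
#' network that is connected at every admissible sparsity, with weights
#' equal to the retained correlations. Negative correlations are discarded
#' by default (`negative_edges = "drop"`); `"absolute"` ranks and keeps
#' `|r|` instead.
#'
#' @param c A [pearson_connectivity()] result (or bare symmetric matrix).
#' @param sparsity Sparsity level in (0, 1].
#' @param negative_edges `"drop"` (default) or `"absolute"`.
#' @return Object of class `thresholded_network` with fields `w` (N x N
#'   weight matrix), `sparsity`, `edge_count`, `region_names`.
#' @export
threshold_with_mst <- function(c, sparsity,
                               negative_edges = c("drop", "absolute")) {
  negative_edges <- match.arg(negative_edges)
  r <- if (inherits(c, "connectivity_matrix")) c$r else as.matrix(c)
  region_names <- if (inherits(c, "connectivity_matrix")) c$region_names
                  else colnames(r) %||% sprintf("ROI%02d", seq_len(nrow(r)))
  if (negative_edges == "absolute") r <- abs(r)
  n <- nrow(r)
  budget <- edge_budget(n, sparsity)
  ranked <- rank_edges_mst(r)
  if (budget > nrow(ranked))
    stop("edge budget ", budget, " exceeds the ", nrow(ranked),
         " positive correlations available", call. = FALSE)
  keep <- ranked[seq_len(budget), ]
  w <- matrix(0, n, n, dimnames = list(region_names, region_names))
  w[cbind(keep$i, keep$j)] <- keep$w
  w[cbind(keep$j, keep$i)] <- keep$w
  new_thresholded_network(w, sparsity, region_names)
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat("Weighted undirected network:", length(x$region_names), "nodes,",
      x$edge_count, "edges (sparsity", x$sparsity, ")\n")
  invisible(x)
}

#' Threshold a connectivity matrix at every level of a sparsity grid
#'
#' Edge ranking is computed once per subject, so networks are nested: the
#' edge set at any sparsity is a subset of the edge set at any higher
#' sparsity.
#'
#' @inheritParams threshold_with_mst
#' @param grid A [sparsity_grid()].
#' @return List of [threshold_with_mst()] networks, one per grid value.
#' @export
sweep_thresholds <- function(c, grid = sparsity_grid(),
                             negative_edges = c("drop", "absolute")) {
  negative_edges <- match.arg(negative_edges)
  r <- if (inherits(c, "connectivity_matrix")) c$r else as.matrix(c)
  region_names <- if (inherits(c, "connectivity_matrix")) c$region_names
                  else colnames(r) %||% sprintf("ROI%02d", seq_len(nrow(r)))
  if (negative_edges == "absolute") r <- abs(r)
  n <- nrow(r)
  ranked <- rank_edges_mst(r)
  lapply(as.numeric(grid), function(s) {
    budget <- edge_budget(n, s)
    if (budget > nrow(ranked))
      stop("edge budget ", budget, " at sparsity ", s, " exceeds the ",
           nrow(ranked), " positive correlations available", call. = FALSE)
    keep <- ranked[seq_len(budget), ]
    w <- matrix(0, n, n, dimnames = list(region_names, region_names))
    w[cbind(keep$i, keep$j)] <- keep$w
    w[cbind(keep$j, keep$i)] <- keep$w
    new_thresholded_network(w, s, region_names)
  })
}

#' Export a thresholded network as a weighted edge list
#'
#' @param net A [threshold_with_mst()] network.
#' @return Data frame with `region_i`, `region_j`, `weight`.
#' @export
edge_list <- function(net) {
  idx <- which(upper.tri(net$w) & net$w > 0, arr.ind = TRUE)
  data.frame(region_i = net$region_names[idx[, 1]],
             region_j = net$region_names[idx[, 2]],
             weight = net$w[idx])
}
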