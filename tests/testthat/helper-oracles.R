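# Independent brute-force oracles. These deliberately share no code with
# the package: clustering by direct neighbor-pair loops, distances by
# Floyd-Warshall, betweenness by exhaustive simple-path enumeration,
# BH by the quadratic textbook definition.

ORACLE_EPS <- 1e-10

oracle_clustering <- function(w) {
  n <- nrow(w)
  wmax <- max(w)
  cc <- numeric(n)
  if (wmax <= 0) return(cc)
  h <- ifelse(w > 0, (w / wmax)^(1 / 3), 0)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      s <- s + h[i, nb[a]] * h[i, nb[b]] * h[nb[a], nb[b]]
    cc[i] <- 2 * s / (k * (k - 1))
  }
  cc
}

oracle_distances <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# all simple paths between s and t (list of vertex vectors), via DFS
all_simple_paths_bf <- function(w, s, t) {
  n <- nrow(w)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    for (u in which(w[v, ] > 0)) if (!(u %in% path)) walk(c(path, u))
  }
  walk(s)
  paths
}

oracle_betweenness <- function(w) {
  n <- nrow(w)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_simple_paths_bf(w, s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, function(p) {
      sum(1 / w[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    dmin <- min(lens)
    short <- paths[lens <= dmin + ORACLE_EPS]
    sigma <- length(short)
    for (p in short) {
      interior <- p[-c(1, length(p))]
      bc[interior] <- bc[interior] + 1 / sigma
    }
  }
  bc
}

# BH q-values straight from the step-up definition:
# q_(i) = min_{j >= i} m * p_(j) / j  (on the sorted scale)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, m * ps[j] / j)
    q_sorted[i] <- min(cand, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# enumerate all connected labeled graph topologies on n nodes; returns a
# list of binary adjacency matrices
connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1) {
    bits <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    if (sum(bits) < n - 1) next
    a <- matrix(0, n, n)
    a[pairs[bits, , drop = FALSE]] <- 1
    a <- a + t(a)
    # BFS connectivity
    seen <- rep(FALSE, n); seen[1] <- TRUE; fr <- 1
    while (length(fr) > 0) {
      nb <- which(colSums(a[fr, , drop = FALSE] > 0) > 0 & !seen)
      seen[nb] <- TRUE; fr <- nb
    }
    if (all(seen)) out[[length(out) + 1]] <- a
  }
  out
}

# random connected weighted graph on n nodes with weights from `wset`
# (wset = NULL draws continuous weights, making shortest-path ties
# measure-zero)
random_connected_graph <- function(n, wset = c(0.25, 0.5, 1),
                                   p_edge = 0.5) {
  repeat {
    a <- matrix(0, n, n)
    ut <- which(upper.tri(a))
    on <- ut[runif(length(ut)) < p_edge]
    if (length(on) < n - 1) next
    a[on] <- if (is.null(wset)) runif(length(on), 0.1, 1) else
      sample(wset, length(on), replace = TRUE)
    a <- a + t(a)
    seen <- rep(FALSE, n); seen[1] <- TRUE; fr <- 1
    while (length(fr) > 0) {
      nb <- which(colSums(a[fr, , drop = FALSE] > 0) > 0 & !seen)
      seen[nb] <- TRUE; fr <- nb
    }
    if (all(seen)) return(a)
  }
}

# random symmetric correlation-like matrix with unit diagonal whose
# positive part is connected (dense positive structure)
random_corr_matrix <- function(n) {
  x <- matrix(rnorm(n * (n + 6)), ncol = n)
  r <- cor(x)
  r
}

# tiny weighted graph as named weight matrix
wmat <- function(n, edges) {
  w <- matrix(0, n, n)
  for (e in edges) {
    w[e[1], e[2]] <- e[3]
    w[e[2], e[1]] <- e[3]
  }
  w
}
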