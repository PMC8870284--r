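# Independent brute-force implementations of the graph measures, used only as
# test oracles: Floyd-Warshall distances, exhaustive simple-path enumeration
# for shortest-path counts and betweenness, direct triangle counting for
# clustering. Deliberately naive and separate from the package's Dijkstra
# machinery.

ORACLE_TOL <- 1e-10

# Build an eeg_network directly from an adjacency matrix (bypasses
# thresholding so arbitrary graphs can be fed to the metric functions).
test_net <- function(w, mode = if (all(w %in% c(0, 1))) "binary" else "weighted") {
  w <- as.matrix(w)
  diag(w) <- 0
  m <- sum(w[upper.tri(w)] > 0)
  structure(list(w = w, density = m / (nrow(w) * (nrow(w) - 1) / 2),
                 n_edges = m, mode = mode),
            class = "eeg_network")
}

oracle_lengths <- function(w, mode) {
  len <- matrix(Inf, nrow(w), ncol(w))
  len[w > 0] <- if (mode == "binary") 1 else 1 / w[w > 0]
  diag(len) <- Inf
  len
}

oracle_floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# All simple paths from v to w as node vectors (exhaustive DFS).
oracle_simple_paths <- function(len, v, w) {
  n <- nrow(len)
  out <- list()
  walk <- function(path, node) {
    if (node == w) { out[[length(out) + 1L]] <<- path; return() }
    for (nxt in which(is.finite(len[node, ]))) {
      if (!nxt %in% path) walk(c(path, nxt), nxt)
    }
  }
  walk(v, v)
  out
}

path_len <- function(len, p) {
  if (length(p) < 2) return(0)
  sum(len[cbind(p[-length(p)], p[-1])])
}

# Shortest paths between v and w: list(d = distance, paths = list of node
# vectors attaining it within tolerance).
oracle_shortest <- function(len, v, w) {
  ps <- oracle_simple_paths(len, v, w)
  if (!length(ps)) return(list(d = Inf, paths = list()))
  ls <- vapply(ps, path_len, 0, len = len)
  dmin <- min(ls)
  list(d = dmin, paths = ps[abs(ls - dmin) <= ORACLE_TOL * max(1, dmin)])
}

oracle_metrics <- function(net) {
  w <- net$w
  n <- nrow(w)
  len <- oracle_lengths(w, net$mode)
  d <- oracle_floyd_warshall(len)

  inv <- 1 / d; inv[!is.finite(d)] <- 0; diag(inv) <- 0
  glob_node <- rowSums(inv) / (n - 1)
  glob <- sum(inv) / (n * (n - 1))

  off <- d; diag(off) <- NA
  reach <- is.finite(off)
  cp_node <- sapply(seq_len(n), function(i)
    if (!any(reach[i, ])) NaN else mean(off[i, reach[i, ]]))
  cp <- if (any(reach)) mean(off[reach]) else NaN

  a <- (w > 0) * 1
  deg <- rowSums(a)
  tri <- sapply(seq_len(n), function(h) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i != j && i != h && j != h) s <- s + a[i, j] * a[i, h] * a[j, h]
    s
  })
  cc_node <- ifelse(deg >= 2, tri / (deg * (deg - 1)), 0)

  loc_node <- sapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    dsub <- oracle_floyd_warshall(oracle_lengths(w[nb, nb, drop = FALSE],
                                                 net$mode))
    s <- 0
    for (j in seq_along(nb)) for (k in seq_along(nb))
      if (j != k && is.finite(dsub[j, k])) s <- s + 1 / dsub[j, k]
    s / (length(nb) * (length(nb) - 1))
  })

  btw <- numeric(n)
  for (v in seq_len(n - 1)) for (ww in (v + 1):n) {
    if (!is.finite(d[v, ww])) next
    sp <- oracle_shortest(len, v, ww)
    for (u in seq_len(n)) {
      if (u == v || u == ww) next
      btw[u] <- btw[u] +
        sum(vapply(sp$paths, function(p) u %in% p, TRUE)) / length(sp$paths)
    }
  }

  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  assort <- if (nrow(idx) == 0) NA_real_ else {
    k <- if (net$mode == "binary") rowSums(w > 0) else rowSums(w)
    ji <- k[idx[, 1]]; ki <- k[idx[, 2]]
    m1 <- mean((ji + ki) / 2)
    den <- mean((ji^2 + ki^2) / 2) - m1^2
    if (abs(den) < 1e-15) NaN else (mean(ji * ki) - m1^2) / den
  }

  list(d = d, glob_eff_node = glob_node, glob_eff = glob,
       char_path_node = cp_node, char_path = cp,
       clustering_node = cc_node, clustering = mean(cc_node),
       loc_eff_node = loc_node, loc_eff = mean(loc_node),
       strength_node = rowSums(w), betweenness_node = btw,
       assortativity = assort)
}

# All undirected graphs on n labelled nodes as adjacency matrices.
all_graphs <- function(n) {
  np <- n * (n - 1) / 2
  iu <- which(upper.tri(matrix(0, n, n)))
  lapply(seq_len(2^np) - 1L, function(mask) {
    bits <- as.integer(intToBits(mask))[seq_len(np)]
    w <- matrix(0, n, n)
    w[iu] <- bits
    w + t(w)
  })
}

is_connected_adj <- function(w) {
  n <- nrow(w)
  seen <- c(1L)
  frontier <- c(1L)
  while (length(frontier)) {
    nxt <- setdiff(which(rowSums(w[, frontier, drop = FALSE] > 0) > 0), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == n
}

# Small cohort config used by several end-to-end tests (short recordings,
# one state) -- keeps the planted-coupling machinery but runs in seconds.
tiny_config <- function(seed = 5, n_per_group = 4, coupling_delta = 0.3,
                        duration_s = 68, states = "eyes_open") {
  cohort_config(n_per_group = n_per_group, states = states,
                duration_s = stats::setNames(rep(duration_s, length(states)),
                                             states),
                coupling_delta = coupling_delta, seed = seed)
}

# Exhaustive two-sample rank-sum enumeration oracle: two-sided p-value over
# all choose(n_a + n_b, n_a) group assignments of the pooled midranks.
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  rk <- rank(pooled)
  n <- length(pooled)
  na <- length(a)
  obs <- sum(rk[seq_len(na)])
  combs <- utils::combn(n, na)
  stats_all <- colSums(matrix(rk[combs], nrow = na))
  centre <- na * (n + 1) / 2
  mean(abs(stats_all - centre) >= abs(obs - centre) - 1e-12)
}
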