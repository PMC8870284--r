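# The seven graph-theory measures computed on thresholded networks, in binary
# (hop-count) and weighted modes. Weighted path length uses the standard
# edge-length convention 1/weight: a stronger correlation is a shorter path.
# All-pairs shortest-path distances and path multiplicities come from a
# Dijkstra sweep with tolerance-aware tie handling; networks here are small
# (one node per electrode), so clarity wins over asymptotic speed.

REL_TOL <- 1e-10

# Edge-length matrix for a network: 1 per hop (binary) or 1/weight (weighted);
# Inf where there is no edge.
edge_lengths <- function(w, mode) {
  len <- matrix(Inf, nrow(w), ncol(w))
  has <- w > 0
  len[has] <- if (mode == "binary") 1 else 1 / w[has]
  diag(len) <- Inf  # no self-loops
  len
}

# All-pairs shortest-path distances and counts of distinct shortest paths,
# by Dijkstra from each source with path-count accumulation. Ties in path
# length are detected with a relative tolerance so weighted graphs with
# numerically equal alternatives count both routes.
apsp_counts <- function(len) {
  n <- nrow(len)
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    cnt <- numeric(n); cnt[s] <- 1
    done <- rep(FALSE, n)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (!length(cand)) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      for (v in which(is.finite(len[u, ]))) {
        if (done[v]) next
        alt <- dist[u] + len[u, v]
        tol <- REL_TOL * max(1, abs(alt))
        if (alt < dist[v] - tol) {
          dist[v] <- alt
          cnt[v] <- cnt[u]
        } else if (abs(alt - dist[v]) <= tol) {
          cnt[v] <- cnt[v] + cnt[u]
        }
      }
    }
    d[s, ] <- dist
    sigma[s, ] <- cnt
  }
  diag(d) <- 0
  list(d = d, sigma = sigma)
}

as_net <- function(net) {
  if (inherits(net, "eeg_network")) return(net)
  stop_input("expected an 'eeg_network' (see sparsity_threshold())")
}

#' All-pairs shortest paths of a network
#'
#' Distances are hop counts (binary mode) or sums of 1/weight edge lengths
#' (weighted mode); unreachable pairs are \code{Inf}. Path counts give the
#' number of distinct shortest paths per pair.
#'
#' @param net an \code{eeg_network}.
#' @return list with \code{d} (N x N distance matrix) and \code{sigma}
#'   (N x N shortest-path counts; \code{sigma[i,i]} is 1 by convention).
#' @export
network_distances <- function(net) {
  net <- as_net(net)
  res <- apsp_counts(edge_lengths(net$w, net$mode))
  dimnames(res$d) <- dimnames(res$sigma) <- dimnames(net$w)
  res
}

#' Local efficiency
#'
#' For node i with degree >= 2: the mean inverse shortest-path length between
#' i's neighbours, computed within the subgraph of those neighbours with i
#' removed (ordered pairs; unreachable pairs contribute 0). Nodes of degree
#' < 2 score 0. The network value is the mean over all N nodes.
#'
#' @param net an \code{eeg_network}.
#' @return list with \code{node} (per-node vector) and \code{network} (scalar).
#' @export
local_efficiency <- function(net) {
  net <- as_net(net)
  w <- net$w
  n <- nrow(w)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    di <- length(nb)
    if (di < 2L) next
    sub <- w[nb, nb, drop = FALSE]
    d <- apsp_counts(edge_lengths(sub, net$mode))$d
    inv <- 1 / d
    inv[!is.finite(d) | d == 0] <- 0
    diag(inv) <- 0
    eff[i] <- sum(inv) / (di * (di - 1))
  }
  names(eff) <- rownames(w)
  list(node = eff, network = mean(eff))
}

#' Clustering coefficient
#'
#' For node h with degree >= 2: the fraction of ordered neighbour pairs that
#' are themselves connected, i.e. 2 x triangles(h) / (d_h (d_h - 1)) on the
#' binary connection pattern of the thresholded network (the pattern is used
#' even in weighted mode). Degree < 2 scores 0; the network value is the mean
#' over all N nodes.
#'
#' @param net an \code{eeg_network}.
#' @return list with \code{node} and \code{network}.
#' @export
clustering_coefficient <- function(net) {
  net <- as_net(net)
  a <- (net$w > 0) * 1
  deg <- rowSums(a)
  tri2 <- diag(a %*% a %*% a)  # 2 x triangle count per node (ordered pairs)
  cc <- ifelse(deg >= 2, tri2 / (deg * (deg - 1)), 0)
  names(cc) <- rownames(net$w)
  list(node = cc, network = mean(cc))
}

#' Global efficiency
#'
#' Network value: mean of 1/L_ij over all ordered pairs i != j, with 1/Inf = 0
#' for unreachable pairs. Per-node value e_i: mean of 1/L_ij over j != i.
#'
#' @param net an \code{eeg_network}.
#' @param paths optional precomputed \code{\link{network_distances}} result.
#' @return list with \code{node} and \code{network}.
#' @export
global_efficiency <- function(net, paths = network_distances(net)) {
  d <- paths$d
  n <- nrow(d)
  inv <- 1 / d
  inv[!is.finite(d)] <- 0
  diag(inv) <- 0
  node <- rowSums(inv) / (n - 1)
  names(node) <- rownames(d)
  list(node = node, network = sum(inv) / (n * (n - 1)))
}

#' Node strength
#'
#' S(i) = sum of the weights of edges incident on i (the degree, for binary
#' networks).
#'
#' @param net an \code{eeg_network}.
#' @return per-node numeric vector.
#' @export
node_strength <- function(net) {
  net <- as_net(net)
  rowSums(net$w)
}

#' Node betweenness centrality
#'
#' NB(u) = sum over unordered node pairs \{v, w\} with u, v, w all distinct of
#' the fraction of shortest v-w paths that pass through u. Disconnected pairs
#' contribute 0. Unnormalised.
#'
#' @param net an \code{eeg_network}.
#' @param paths optional precomputed \code{\link{network_distances}} result.
#' @return per-node numeric vector.
#' @export
betweenness_centrality <- function(net, paths = network_distances(net)) {
  d <- paths$d
  sigma <- paths$sigma
  n <- nrow(d)
  nb <- numeric(n)
  for (u in seq_len(n)) {
    for (v in seq_len(n - 1)) {
      if (v == u) next
      for (w in (v + 1):n) {
        if (w == u || w == v || !is.finite(d[v, w])) next
        through <- d[v, u] + d[u, w]
        if (is.finite(through) &&
            abs(through - d[v, w]) <= REL_TOL * max(1, d[v, w])) {
          nb[u] <- nb[u] + sigma[v, u] * sigma[u, w] / sigma[v, w]
        }
      }
    }
  }
  names(nb) <- rownames(d)
  nb
}

#' Characteristic path length
#'
#' Per-node L_i: mean shortest-path distance from i to the nodes it can reach
#' (NaN when it can reach none). Network CP: mean distance over all reachable
#' ordered pairs; the count of unreachable pairs is attached as attribute
#' \code{"n_unreachable"}.
#'
#' @param net an \code{eeg_network}.
#' @param paths optional precomputed \code{\link{network_distances}} result.
#' @return list with \code{node}, \code{network}, and the unreachable ordered
#'   pair count as an attribute on \code{network}.
#' @export
characteristic_path <- function(net, paths = network_distances(net)) {
  d <- paths$d
  n <- nrow(d)
  off <- d
  diag(off) <- NA
  reach <- is.finite(off)
  node <- vapply(seq_len(n), function(i) {
    ri <- reach[i, ]
    if (!any(ri)) NaN else mean(off[i, ri])
  }, 0)
  names(node) <- rownames(d)
  vals <- off[reach]
  cp <- if (length(vals)) mean(vals) else NaN
  attr(cp, "n_unreachable") <- sum(!reach) - n  # diagonal excluded
  list(node = node, network = cp)
}

#' Degree (or strength) assortativity
#'
#' Pearson-type correlation of the degrees at the two endpoints of each edge:
#' r = [E^-1 sum j_i k_i - (E^-1 sum (j_i + k_i)/2)^2] /
#'     [E^-1 sum (j_i^2 + k_i^2)/2 - (E^-1 sum (j_i + k_i)/2)^2].
#' Binary networks use endpoint degrees; weighted networks use endpoint
#' strengths. Returns NaN for degree-regular graphs (zero denominator);
#' r < 0 is disassortative, r > 0 assortative, r = 0 uncorrelated.
#'
#' @param net an \code{eeg_network}.
#' @return scalar.
#' @export
assortativity <- function(net) {
  net <- as_net(net)
  w <- net$w
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_input("assortativity needs at least one edge")
  k <- if (net$mode == "binary") rowSums(w > 0) else rowSums(w)
  ji <- k[idx[, 1]]; ki <- k[idx[, 2]]
  m1 <- mean((ji + ki) / 2)
  num <- mean(ji * ki) - m1^2
  den <- mean((ji^2 + ki^2) / 2) - m1^2
  if (abs(den) < 1e-15) return(NaN)
  num / den
}

#' All seven graph measures of one network
#'
#' Convenience wrapper computing local efficiency, clustering coefficient,
#' global efficiency, node strength, betweenness centrality, characteristic
#' path length and assortativity in one pass (sharing the shortest-path
#' computation).
#'
#' @param net an \code{eeg_network}.
#' @return object of class \code{metric_set}: per-node vectors
#'   \code{loc_eff_node}, \code{clustering_node}, \code{strength_node},
#'   \code{betweenness_node}, \code{glob_eff_node}, \code{char_path_node};
#'   scalars \code{loc_eff}, \code{clustering}, \code{glob_eff},
#'   \code{char_path}, \code{assortativity}; and \code{n_nodes}.
#' @export
network_metrics <- function(net) {
  net <- as_net(net)
  paths <- network_distances(net)
  le <- local_efficiency(net)
  cc <- clustering_coefficient(net)
  ge <- global_efficiency(net, paths)
  cp <- characteristic_path(net, paths)
  structure(list(
    loc_eff_node = le$node, loc_eff = le$network,
    clustering_node = cc$node, clustering = cc$network,
    glob_eff_node = ge$node, glob_eff = ge$network,
    strength_node = node_strength(net),
    betweenness_node = betweenness_centrality(net, paths),
    char_path_node = cp$node, char_path = as.numeric(cp$network),
    n_unreachable = attr(cp$network, "n_unreachable"),
    assortativity = assortativity(net),
    n_nodes = nrow(net$w), mode = net$mode
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  cat(sprintf("<metric_set> %d nodes (%s mode)\n", x$n_nodes, x$mode))
  cat(sprintf("  LocE %.4g | CC %.4g | GlobE %.4g | CP %.4g | assortativity %.4g\n",
              x$loc_eff, x$clustering, x$glob_eff, x$char_path, x$assortativity))
  invisible(x)
}
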