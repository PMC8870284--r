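# Graph measures: hand-evaluated closed forms, brute-force oracle agreement,
# and structural invariants.

k_n <- function(n) matrix(1, n, n) - diag(n)
path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
star4 <- { w <- matrix(0, 5, 5); w[1, 2:5] <- w[2:5, 1] <- 1; w }
cycle4 <- { w <- matrix(0, 4, 4); for (i in 1:4) w[i, i %% 4 + 1] <- 1; w + t(w) }

test_that("shortest paths: hop counts, 1/weight lengths and path counts", {
  p <- network_distances(test_net(path3))
  expect_equal(p$d[1, 3], 2)
  expect_equal(p$sigma[1, 3], 1)

  k4 <- network_distances(test_net(k_n(4)))
  expect_true(all(k4$d[upper.tri(k4$d)] == 1))

  # weighted triangle: direct edge longer than the two-hop detour
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.2
  p <- network_distances(test_net(w, "weighted"))
  expect_equal(p$d[1, 3], 4)  # min(1/0.2, 1/0.5 + 1/0.5)
  expect_equal(p$sigma[1, 3], 1)

  # equal-length alternatives are both counted
  sq <- cycle4
  p <- network_distances(test_net(sq))
  expect_equal(p$d[1, 3], 2)
  expect_equal(p$sigma[1, 3], 2)
})

test_that("closed forms on complete graphs, paths, stars and cycles", {
  for (n in c(3, 4, 6)) {
    net <- test_net(k_n(n))
    m <- network_metrics(net)
    expect_equal(m$glob_eff, 1)
    expect_equal(m$loc_eff, 1)
    expect_equal(m$clustering, 1)
    expect_equal(m$char_path, 1)
    expect_equal(unname(m$betweenness_node), rep(0, n))
    expect_equal(unname(m$strength_node), rep(n - 1, n))
  }

  p3 <- network_metrics(test_net(path3))
  expect_equal(p3$glob_eff, 5 / 6)
  expect_equal(p3$char_path, 4 / 3)
  expect_equal(unname(p3$betweenness_node), c(0, 1, 0))
  expect_equal(p3$loc_eff, 0)  # leaves deg 1; centre's neighbours disconnected

  st <- network_metrics(test_net(star4))
  expect_equal(unname(st$betweenness_node), c(6, 0, 0, 0, 0))  # C(4,2) pairs
  expect_equal(st$assortativity, -1)
  expect_equal(st$clustering, 0)

  cy <- network_metrics(test_net(cycle4))
  expect_equal(cy$char_path, 4 / 3)  # each node's distances {1, 2, 1}
  expect_true(is.nan(cy$assortativity))  # degree-regular: 0/0
})

test_that("local efficiency follows the neighbourhood-subgraph definition", {
  # K4: every neighbourhood is complete
  expect_equal(local_efficiency(test_net(k_n(4)))$node, rep(1, 4),
               ignore_attr = TRUE)
  # node strength hand sums on a weighted triangle
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9
  w[2, 3] <- w[3, 2] <- 0.8
  w[1, 3] <- w[3, 1] <- 0.7
  expect_equal(unname(node_strength(test_net(w, "weighted"))),
               c(1.6, 1.7, 1.5))
  # empty network: all strengths 0
  expect_equal(unname(node_strength(test_net(matrix(0, 4, 4)))), rep(0, 4))
})

test_that("all metrics match brute-force oracles on every 4-node graph", {
  for (w in all_graphs(4)) {
    if (sum(w) == 0) next
    net <- test_net(w)
    m <- network_metrics(net)
    o <- oracle_metrics(net)
    expect_equal(unname(m$glob_eff_node), o$glob_eff_node, tolerance = 1e-12)
    expect_equal(m$glob_eff, o$glob_eff, tolerance = 1e-12)
    expect_equal(unname(m$loc_eff_node), o$loc_eff_node, tolerance = 1e-12)
    expect_equal(unname(m$clustering_node), o$clustering_node, tolerance = 1e-12)
    expect_equal(unname(m$betweenness_node), o$betweenness_node, tolerance = 1e-12)
    expect_equal(unname(m$char_path_node), o$char_path_node, tolerance = 1e-12)
    expect_equal(m$char_path, o$char_path, tolerance = 1e-12)
    expect_equal(m$assortativity, o$assortativity, tolerance = 1e-12)
  }
})

test_that("weighted metrics match the oracle on random weighted graphs", {
  set.seed(402)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    w <- matrix(0, n, n)
    iu <- which(upper.tri(w))
    on_edges <- sample(iu, size = sample(2:length(iu), 1))
    w[on_edges] <- runif(length(on_edges), 0.1, 1)
    w <- w + t(w)
    net <- test_net(w, "weighted")
    m <- network_metrics(net)
    o <- oracle_metrics(net)
    expect_equal(network_distances(net)$d, o$d, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(m$glob_eff, o$glob_eff, tolerance = 1e-10)
    expect_equal(unname(m$loc_eff_node), o$loc_eff_node, tolerance = 1e-10)
    expect_equal(unname(m$betweenness_node), o$betweenness_node,
                 tolerance = 1e-10)
    expect_equal(m$assortativity, o$assortativity, tolerance = 1e-10)
  }
})

test_that("weighted distances and betweenness agree with igraph", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:10) {
    n <- 6
    w <- matrix(0, n, n)
    iu <- which(upper.tri(w))
    on_edges <- sample(iu, 10)
    w[on_edges] <- runif(10, 0.2, 1)
    w <- w + t(w)
    net <- test_net(w, "weighted")
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    d_ig <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(network_distances(net)$d, d_ig, tolerance = 1e-10,
                 ignore_attr = TRUE)
    b_ig <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(unname(betweenness_centrality(net)), unname(b_ig),
                 tolerance = 1e-8)
  }
})

test_that("relabelling nodes permutes vectors and fixes scalars", {
  set.seed(9)
  w <- matrix(0, 6, 6)
  iu <- which(upper.tri(w))
  w[sample(iu, 9)] <- runif(9, 0.1, 1)
  w <- w + t(w)
  perm <- sample(6)
  m1 <- network_metrics(test_net(w, "weighted"))
  m2 <- network_metrics(test_net(w[perm, perm], "weighted"))
  for (f in c("loc_eff_node", "clustering_node", "glob_eff_node",
              "strength_node", "betweenness_node", "char_path_node"))
    expect_equal(unname(m2[[f]]), unname(m1[[f]][perm]), tolerance = 1e-12)
  for (f in c("loc_eff", "clustering", "glob_eff", "char_path", "assortativity"))
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-12)
})

test_that("adding an edge never lowers GlobE nor raises CP; bounds hold", {
  set.seed(31)
  for (rep in 1:15) {
    n <- 6
    w <- matrix(0, n, n)
    iu <- which(upper.tri(w))
    w[sample(iu, 8)] <- 1
    w <- w + t(w)
    net <- test_net(w)
    m <- network_metrics(net)
    expect_true(m$glob_eff >= 0 && m$glob_eff <= 1)
    expect_true(m$loc_eff >= 0 && m$loc_eff <= 1)
    expect_true(all(m$clustering_node >= 0 & m$clustering_node <= 1))
    if (!is.nan(m$assortativity))
      expect_true(m$assortativity >= -1 - 1e-12 && m$assortativity <= 1 + 1e-12)
    off <- which(upper.tri(w) & w == 0)
    if (!length(off)) next
    add <- sample(off, 1)
    w2 <- w
    w2[add] <- 1
    w2 <- pmax(w2, t(w2))
    m2 <- network_metrics(test_net(w2))
    expect_gte(m2$glob_eff, m$glob_eff - 1e-12)
    if (!is.nan(m$char_path) && !is.nan(m2$char_path) &&
        attr(characteristic_path(net)$network, "n_unreachable") == 0)
      expect_lte(m2$char_path, m$char_path + 1e-12)
  }
})

test_that("assortativity requires an edge; empty metric inputs are rejected", {
  expect_error(assortativity(test_net(matrix(0, 3, 3))), "at least one edge")
  expect_error(network_distances(list()), "eeg_network")
})
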