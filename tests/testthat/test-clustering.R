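test_that("modularity matches hand-derived values", {
  tri2 <- igraph::graph_from_edgelist(
    cbind(c("a", "b", "c", "d", "e", "f"), c("b", "c", "a", "e", "f", "d")),
    directed = FALSE)
  igraph::E(tri2)$weight <- 1
  memb <- stats::setNames(c(0, 0, 0, 1, 1, 1), letters[1:6])
  expect_equal(weighted_modularity(tri2, memb), 0.5)
  expect_equal(weighted_modularity(tri2, stats::setNames(rep(0, 6), letters[1:6])), 0)

  one <- igraph::graph_from_edgelist(cbind("x", "y"), directed = FALSE)
  igraph::E(one)$weight <- 1
  expect_equal(weighted_modularity(one, stats::setNames(c(0, 1), c("x", "y"))),
               -0.5)

  edgeless <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(edgeless)$name <- c("x", "y")
  expect_error(weighted_modularity(edgeless, stats::setNames(c(0, 1), c("x", "y"))),
               "edgeless")
})

test_that("modularity agrees with the dense double-sum and with igraph", {
  for (seed in 1:20) {
    g <- random_weighted_graph(sample(4:12, 1), p = 0.5, seed = seed)
    n <- igraph::vcount(g)
    memb <- stats::setNames(sample(0:2, n, replace = TRUE), igraph::V(g)$name)
    res <- sample(c(0.4, 1, 2.5), 1)
    expect_equal(weighted_modularity(g, memb, res),
                 brute_modularity(g, memb, res), tolerance = 1e-12)
    # igraph's weighted modularity as an independent implementation, res = 1
    expect_equal(weighted_modularity(g, memb),
                 igraph::modularity(g, memb[igraph::V(g)$name] + 1,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("move gain equals the exact modularity difference", {
  set.seed(2024)
  for (rep in 1:60) {
    g <- random_weighted_graph(sample(5:12, 1), p = 0.6,
                               seed = 1000 + rep)
    n <- igraph::vcount(g)
    vn <- igraph::V(g)$name
    memb <- stats::setNames(sample(0:3, n, replace = TRUE), vn)
    node <- sample(vn, 1)
    cands <- setdiff(unique(memb), memb[node])
    if (length(cands) == 0) next
    dest <- cands[sample.int(length(cands), 1)]
    res <- sample(c(0.5, 1, 2), 1)
    agg <- cluster_aggregates(g, memb, node, dest)
    a <- sum(igraph::strength(g, weights = igraph::E(g)$weight)) / 2
    after <- memb
    after[node] <- dest
    expect_equal(modularity_gain(agg, a, res),
                 brute_modularity(g, after, res) - brute_modularity(g, memb, res),
                 tolerance = 1e-12)
  }
})

test_that("degenerate moves gain nothing", {
  g <- random_weighted_graph(6, seed = 7)
  memb <- stats::setNames(c(0, 0, 1, 1, 2, 2), igraph::V(g)$name)
  # moving within the same cluster
  agg <- cluster_aggregates(g, memb, igraph::V(g)$name[1], 0)
  expect_equal(modularity_gain(agg, 10, 1), 0)
  # a zero-degree node has all K_i terms vanish
  g2 <- igraph::add_vertices(g, 1, name = "iso")
  memb2 <- c(memb, iso = 2L)
  agg2 <- cluster_aggregates(g2, memb2, "iso", 0)
  expect_equal(agg2$k_i, 0)
  expect_equal(modularity_gain(agg2, 10, 1), 0)
})

test_that("merging two singletons over a unit edge gains 0.5", {
  g <- igraph::graph_from_edgelist(cbind("x", "y"), directed = FALSE)
  igraph::E(g)$weight <- 1
  memb <- stats::setNames(c(0L, 1L), c("x", "y"))
  agg <- cluster_aggregates(g, memb, "y", 0)
  expect_equal(modularity_gain(agg, a = 1, resolution = 1), 0.5)
})

test_that("louvain handles trivial graphs", {
  solo <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(solo)$name <- "only"
  p <- louvain_cluster(solo, resolution = 1, seed = 1)
  expect_equal(p$n_clusters, 1)

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("a", "b", "c")
  p2 <- louvain_cluster(edgeless, resolution = 1, seed = 1)
  expect_equal(p2$n_clusters, 3)  # isolated nodes stay singletons
})

test_that("two 4-cliques joined by one edge split into the cliques", {
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(1, 5))
  igraph::V(g)$name <- letters[1:8]
  igraph::E(g)$weight <- 1
  p <- louvain_cluster(g, resolution = 1, seed = 11, restarts = 3)
  expect_equal(p$n_clusters, 2)
  expect_equal(length(unique(p$membership[letters[1:4]])), 1)
  expect_equal(length(unique(p$membership[letters[5:8]])), 1)
  # and this split is the exhaustive optimum of the quality function
  ex <- exhaustive_best_modularity(g)
  expect_equal(p$modularity, ex$value, tolerance = 1e-12)
})

test_that("louvain recovers planted blocks (ARI vs ground truth)", {
  skip_if_not_installed("mclust")
  set.seed(31)
  blocks <- rep(1:4, each = 10)
  n <- length(blocks)
  prob <- ifelse(outer(blocks, blocks, "=="), 0.9, 0.05)
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) <
                                      prob[upper.tri(prob)])
  g <- igraph::graph_from_adjacency_matrix(adj + t(adj), mode = "undirected")
  igraph::V(g)$name <- sprintf("v%02d", 1:n)
  igraph::E(g)$weight <- 1
  p <- louvain_cluster(g, resolution = 1, seed = 5, restarts = 3)
  ari <- mclust::adjustedRandIndex(p$membership[igraph::V(g)$name], blocks)
  expect_gte(ari, 0.9)
  # igraph's own Louvain as an independent cross-check on the same graph
  ig <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  ari_cross <- mclust::adjustedRandIndex(
    p$membership[igraph::V(g)$name], igraph::membership(ig))
  expect_gte(ari_cross, 0.9)
})

test_that("output modularity never falls below the all-singletons start", {
  for (seed in 1:10) {
    g <- random_weighted_graph(sample(6:14, 1), p = 0.4, seed = 200 + seed)
    vn <- igraph::V(g)$name
    res <- sample(c(0.5, 1, 2), 1)
    p <- louvain_cluster(g, resolution = res, seed = seed, restarts = 2)
    singletons <- stats::setNames(seq_along(vn) - 1L, vn)
    expect_gte(p$modularity,
               weighted_modularity(g, singletons, res) - 1e-12)
  }
})

test_that("lower resolution yields at least as many clusters (planted fixture)", {
  b <- generate_fixture(fixture_spec())
  g <- records_to_ddsn(b$interactions$records)
  p_low <- louvain_cluster(g, resolution = 0.3, seed = 42, restarts = 2)
  p_high <- louvain_cluster(g, resolution = 3.0, seed = 42, restarts = 2)
  expect_gte(p_low$n_clusters, p_high$n_clusters)
})

test_that("clustering is deterministic in (graph, resolution, seed, restarts)", {
  g <- records_to_ddsn(random_records(15, 8, 3, 60, seed = 77))
  p1 <- louvain_cluster(g, resolution = 1.4, seed = 9, restarts = 4)
  p2 <- louvain_cluster(g, resolution = 1.4, seed = 9, restarts = 4)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$modularity, p2$modularity)
})

test_that("clusters are renumbered by decreasing size with C0 largest", {
  g <- records_to_ddsn(random_records(20, 8, 3, 80, seed = 13))
  p <- louvain_cluster(g, resolution = 0.8, seed = 3, restarts = 2)
  sizes <- as.integer(table(p$membership))
  expect_equal(sort(unique(p$membership)), seq_along(sizes) - 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("louvain matches the exhaustive optimum on small graphs", {
  parts <- list()
  hits <- 0
  n_fix <- 40
  for (seed in seq_len(n_fix)) {
    n <- sample(5:8, 1)
    if (is.null(parts[[as.character(n)]])) {
      parts[[as.character(n)]] <- enumerate_partitions(n)
    }
    g <- random_weighted_graph(n, p = 0.5, seed = 5000 + seed)
    ex <- exhaustive_best_modularity(g, parts = parts[[as.character(n)]])
    p <- louvain_cluster(g, resolution = 1, seed = seed, restarts = 5)
    if (abs(p$modularity - ex$value) <= 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_fix, 0.95)
})
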