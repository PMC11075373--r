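named_graph <- function(edges, n, weights = NULL) {
  g <- if (missing(n)) igraph::make_graph(edges, directed = FALSE)
       else igraph::make_graph(edges, directed = FALSE, n = n)
  igraph::V(g)$name <- sprintf("N-%02d", seq_len(igraph::vcount(g)))
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  g
}

test_that("degree and weighted degree follow the handshake identities", {
  g <- build_two_mode(data.frame(
    patient_id = c("P-01", "P-01", "P-02"),
    hospital_id = c("H-01", "H-02", "H-01"),
    drug = "ZOLPIDEM", date = as.Date("2020-01-01"),
    daily_dose_mg = 5, days_supplied = 7L, stringsAsFactors = FALSE))
  tab <- degree_and_weighted_degree(g)
  expect_equal(tab$degree[tab$node == "H-01"], 2)
  expect_equal(tab$weighted_degree[tab$node == "H-01"], 2)
  expect_equal(tab$degree[tab$node == "P-01"], 2)

  tri <- named_graph(c(1, 2, 2, 3, 3, 1), weights = c(1, 2, 3))
  t2 <- degree_and_weighted_degree(tri)
  expect_setequal(t2$weighted_degree, c(4, 5, 3))
  expect_equal(sum(t2$weighted_degree), 2 * sum(1:3))
  expect_equal(sum(t2$degree), 2 * igraph::ecount(tri))

  lone <- igraph::add_vertices(tri, 1, name = "N-99")
  t3 <- degree_and_weighted_degree(lone)
  expect_equal(t3$degree[t3$node == "N-99"], 0)
  expect_equal(t3$weighted_degree[t3$node == "N-99"], 0)
})

test_that("betweenness matches closed forms on path and complete graphs", {
  path3 <- named_graph(c(1, 2, 2, 3))
  b <- betweenness_centrality(path3)
  expect_equal(unname(b), c(0, 1, 0))
  k4 <- named_graph(c(1,2, 1,3, 1,4, 2,3, 2,4, 3,4))
  expect_true(all(betweenness_centrality(k4) == 0))
})

test_that("betweenness equals exhaustive path enumeration on random graphs", {
  for (seed in 1:10) {
    rg <- random_igraph(8, p = 0.35, seed = 100 + seed)
    if (igraph::ecount(rg$graph) == 0) next
    got <- betweenness_centrality(rg$graph)
    want <- oracle_betweenness(rg$adj)
    expect_equal(unname(got), want, tolerance = 1e-10,
                 info = paste("seed", seed))
  }
})

test_that("betweenness ignores edge weights and zeroes leaves", {
  rg <- random_igraph(8, p = 0.4, seed = 55, weights = TRUE)
  g <- rg$graph
  g_scaled <- g
  igraph::E(g_scaled)$weight <- igraph::E(g)$weight * 7
  expect_equal(betweenness_centrality(g), betweenness_centrality(g_scaled))
  leaves <- which(igraph::degree(g) == 1)
  if (length(leaves) > 0) {
    expect_true(all(betweenness_centrality(g)[leaves] == 0))
  }
})

test_that("eigenvector centrality matches closed forms", {
  star <- named_graph(c(1,2, 1,3, 1,4, 1,5, 1,6))
  e <- eigenvector_centrality(star)
  expect_equal(unname(e[1]), 1)
  expect_equal(unname(e[2:6]), rep(1 / sqrt(5), 5), tolerance = 1e-7)

  k3 <- named_graph(c(1, 2, 2, 3, 3, 1))
  expect_equal(unname(eigenvector_centrality(k3)), rep(1, 3), tolerance = 1e-7)

  path3 <- named_graph(c(1, 2, 2, 3))
  expect_equal(unname(eigenvector_centrality(path3)),
               c(1 / sqrt(2), 1, 1 / sqrt(2)), tolerance = 1e-7)
})

test_that("eigenvector centrality matches dense eigendecomposition, including disconnected and weighted graphs", {
  for (seed in 1:10) {
    rg <- random_igraph(8, p = 0.3, seed = 200 + seed, weights = TRUE)
    if (igraph::ecount(rg$graph) == 0) next
    got <- eigenvector_centrality(rg$graph)
    want <- oracle_eigenvector(rg$adj)
    expect_equal(unname(got), want, tolerance = 1e-6,
                 info = paste("seed", seed))
    # strictly positive within components of size >= 2 (Perron-Frobenius),
    # zero on isolated nodes
    comp <- igraph::components(rg$graph)
    sizes <- comp$csize[comp$membership]
    expect_true(all(got[sizes >= 2] > 0))
    expect_true(all(got[sizes == 1] == 0))
  }
})

test_that("louvain recovers planted partitions and evaluates Q by formula", {
  # two disjoint K4 cliques: the planted partition has Q = 0.5 exactly
  g <- named_graph(c(1,2, 1,3, 1,4, 2,3, 2,4, 3,4,
                     5,6, 5,7, 5,8, 6,7, 6,8, 7,8))
  res <- communities_louvain(g, seed = 1)
  expect_equal(res$n_communities, 2)
  expect_equal(res$modularity, 0.5)
  expect_equal(modularity_q(g, res$membership), 0.5)

  # single edge, both nodes in one community: Q = 0
  e1 <- named_graph(c(1, 2))
  expect_equal(modularity_q(e1, c(1, 1)), 0)
  # all-in-one community on any connected network: Q = 0
  rg <- random_igraph(7, p = 0.6, seed = 77)
  expect_equal(modularity_q(rg$graph, rep(1, 7)), 0)
})

test_that("own modularity formula agrees with igraph on random partitions", {
  for (seed in 1:6) {
    rg <- random_igraph(9, p = 0.35, seed = 300 + seed, weights = TRUE)
    if (igraph::ecount(rg$graph) == 0) next
    set.seed(seed)
    memb <- sample(1:3, 9, replace = TRUE)
    expect_equal(modularity_q(rg$graph, memb),
                 igraph::modularity(rg$graph, memb,
                                    weights = igraph::E(rg$graph)$weight),
                 tolerance = 1e-12)
  }
})

test_that("louvain attains the exhaustive optimum on small planted graphs", {
  planted <- function(seed) {
    set.seed(seed)
    adj <- matrix(0, 8, 8)
    for (i in 1:3) for (j in (i + 1):4) adj[i, j] <- 1
    for (i in 5:7) for (j in (i + 1):8) adj[i, j] <- 1
    adj[4, 5] <- 1   # single bridge
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- sprintf("N-%02d", 1:8)
    g
  }
  for (seed in 1:3) {
    g <- planted(seed)
    res <- communities_louvain(g, seed = seed)
    best <- oracle_best_modularity(g)
    expect_equal(res$modularity, best, tolerance = 1e-9)
  }
})

test_that("path statistics cover connected pairs only", {
  path4 <- named_graph(c(1, 2, 2, 3, 3, 4))
  ps <- path_statistics(path4)
  expect_equal(ps$diameter, 3L)
  expect_equal(ps$average_path_length, 10 / 6)
  expect_equal(ps$connected_pair_fraction, 1)

  k5 <- named_graph(as.vector(utils::combn(5, 2)))
  ps5 <- path_statistics(k5)
  expect_equal(ps5$diameter, 1L)
  expect_equal(ps5$average_path_length, 1)

  two_edges <- named_graph(c(1, 2, 3, 4))
  pse <- path_statistics(two_edges)
  expect_equal(pse$diameter, 1L)
  expect_equal(pse$average_path_length, 1)
  expect_equal(pse$connected_pair_fraction, 2 / 6)
})

test_that("network summary matches recomputation from the exported graphml", {
  ds <- generate_dataset(generator_profile(n_hospitals = 30, n_patients = 120,
                                           seed = 5))
  g <- build_two_mode(ds$records)
  s <- summarize_network(g, seed = 9)
  expect_equal(s$average_degree, 2 * igraph::ecount(g) / igraph::vcount(g))

  f <- withr::local_tempfile(fileext = ".graphml")
  write_network(g, f, "graphml")
  g2 <- read_network(f, "graphml")
  s2 <- summarize_network(g2, seed = 9)
  expect_equal(s2$average_degree, s$average_degree)
  expect_equal(s2$average_weighted_degree, s$average_weighted_degree)
  expect_equal(s2$diameter, s$diameter)
  expect_equal(s2$average_path_length, s$average_path_length)
  expect_equal(s2$modularity, s$modularity, tolerance = 1e-12)

  ring <- named_graph(as.vector(rbind(1:6, c(2:6, 1))))
  expect_equal(summarize_network(ring)$average_degree, 2)
})

test_that("centrality table assembles all metrics per node", {
  ds <- generate_dataset(generator_profile(n_hospitals = 20, n_patients = 60,
                                           seed = 31))
  g <- build_two_mode(ds$records)
  tab <- centrality_table(g, seed = 3)
  expect_setequal(names(tab), c("node", "category", "degree",
                                "weighted_degree", "betweenness",
                                "eigenvector", "community_id"))
  expect_equal(nrow(tab), igraph::vcount(g))
  expect_equal(max(tab$eigenvector), 1)
  expect_true(all(tab$degree <= tab$weighted_degree))
})
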