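#' Network metric suite
#'
#' Node centralities (degree, weighted degree, betweenness, eigenvector),
#' Louvain modularity communities, and network-level summaries (average
#' degree, average weighted degree, diameter, average path length).
#'
#' Conventions, chosen for screening networks that are large, weighted and
#' highly fragmented:
#'
#' * Betweenness and path statistics use unweighted (hop-count) shortest
#'   paths: prescription counts are connection strengths, not distances.
#' * Betweenness is unnormalized, with each unordered pair counted once.
#' * Eigenvector centrality is computed per connected component and then
#'   rescaled globally so the maximum over all nodes is exactly 1;
#'   isolated nodes get 0. A whole-graph iteration would concentrate on
#'   one component and silently zero the others.
#' * Diameter and average path length are taken over connected node pairs
#'   only, with the connected-pair fraction reported for transparency;
#'   fragmented networks would otherwise have no finite values.
#'
#' @name narcscreen-metrics
NULL

#' Degree and weighted degree
#'
#' Degree is the incident edge count (for a hospital in the two-mode
#' network: the number of distinct patients); weighted degree is the sum
#' of incident edge weights (the number of prescriptions).
#'
#' @param graph An undirected `igraph` graph with optional edge `weight`.
#' @return Data frame: `node`, `category`, `degree`, `weighted_degree`.
#' @export
degree_and_weighted_degree <- function(graph) {
  w <- igraph::E(graph)$weight
  data.frame(
    node = igraph::V(graph)$name,
    category = vertex_category(graph),
    degree = as.integer(igraph::degree(graph)),
    weighted_degree = igraph::strength(graph,
                                       weights = if (is.null(w)) NA else w),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

vertex_category <- function(graph) {
  cat <- igraph::V(graph)$category
  if (is.null(cat)) cat <- rep(NA_character_, igraph::vcount(graph))
  cat
}

#' Unnormalized betweenness centrality
#'
#' Shortest-path betweenness over unweighted paths; each unordered pair of
#' endpoints contributes once, disconnected pairs contribute nothing.
#'
#' @param graph Undirected `igraph` graph.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(graph) {
  b <- igraph::betweenness(graph, directed = FALSE, weights = NA,
                           normalized = FALSE)
  stats::setNames(as.numeric(b), igraph::V(graph)$name)
}

#' Eigenvector centrality, per component, globally max-normalized
#'
#' Power iteration on the weighted adjacency of each connected component
#' (shifted by the identity so bipartite components converge), tolerance
#' `tol` in the sup norm, at most `max_iter` iterations; each component's
#' vector is the dominant (Perron) eigenvector. All values are then
#' rescaled so the global maximum is exactly 1; isolated nodes get 0.
#'
#' @param graph Undirected `igraph` graph with at least one edge.
#' @param tol Convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error naming the
#'   component.
#' @return Named numeric vector in `[0, 1]`.
#' @export
eigenvector_centrality <- function(graph, tol = 1e-8, max_iter = 1000L) {
  n <- igraph::vcount(graph)
  if (igraph::ecount(graph) < 1) stop("eigenvector centrality needs >= 1 edge",
                                      call. = FALSE)
  w <- igraph::E(graph)$weight
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE,
                                   attr = if (is.null(w)) NULL else "weight")
  comp <- igraph::components(graph)
  x <- numeric(n)
  for (c_id in seq_len(comp$no)) {
    members <- which(comp$membership == c_id)
    if (length(members) < 2) next   # isolated node -> 0
    Ac <- A[members, members, drop = FALSE]
    v <- rep(1 / sqrt(length(members)), length(members))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # Rayleigh-quotient shift keeps the Perron vector, keeps iterates in
      # the nonnegative cone, and damps the -lambda branch that makes
      # plain power iteration oscillate on bipartite components
      Av <- as.numeric(Ac %*% v)
      shift <- max(sum(v * Av), 1)
      v_new <- Av + shift * v
      v_new <- v_new / sqrt(sum(v_new^2))
      if (max(abs(v_new - v)) < tol) {
        v <- v_new
        converged <- TRUE
        break
      }
      v <- v_new
    }
    if (!converged) {
      stop("power iteration did not converge for component ", c_id,
           " (", length(members), " nodes)", call. = FALSE)
    }
    x[members] <- v / max(v)
  }
  if (max(x) > 0) x <- x / max(x)
  stats::setNames(x, igraph::V(graph)$name)
}

#' Louvain community detection with weighted modularity
#'
#' Runs Louvain at the given resolution with a seeded RNG (tie-breaking in
#' Louvain is stochastic) and evaluates the weighted modularity
#' \eqn{Q = \sum_c (e_c/m - (d_c/2m)^2)} directly from the partition,
#' where \eqn{e_c} is the total weight inside community c, \eqn{d_c} the
#' total weighted degree of c, and m the total edge weight.
#'
#' @param graph Undirected `igraph` graph with at least one edge.
#' @param resolution Louvain resolution (default 1).
#' @param seed RNG seed for reproducible tie-breaking.
#' @return List: `membership` (named integer vector), `n_communities`,
#'   `modularity`.
#' @export
communities_louvain <- function(graph, resolution = 1, seed = 42L) {
  if (igraph::vcount(graph) == 0) stop("empty network", call. = FALSE)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, weights = w, resolution = resolution)
  membership <- igraph::membership(cl)
  list(
    membership = membership,
    n_communities = length(unique(membership)),
    modularity = modularity_q(graph, membership)
  )
}

#' Weighted modularity of a partition
#'
#' Direct evaluation of \eqn{Q = \sum_c (e_c/m - (d_c/2m)^2)}.
#'
#' @param graph Undirected weighted `igraph` graph.
#' @param membership Community id per vertex.
#' @return Modularity Q.
#' @export
modularity_q <- function(graph, membership) {
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  m <- sum(w)
  if (m == 0) stop("modularity undefined for a network with no edges",
                   call. = FALSE)
  el <- igraph::as_edgelist(graph, names = FALSE)
  same <- membership[el[, 1]] == membership[el[, 2]]
  intra <- sum(w[same])
  strength <- igraph::strength(graph, weights = w)
  d_c <- tapply(strength, membership, sum)
  intra / m - sum((d_c / (2 * m))^2)
}

#' Path statistics over connected pairs
#'
#' Unweighted BFS distances; diameter and average path length are computed
#' over connected node pairs only, and the fraction of connected pairs is
#' returned alongside.
#'
#' @param graph Undirected `igraph` graph with at least one edge.
#' @return List: `diameter`, `average_path_length`,
#'   `connected_pair_fraction`.
#' @export
path_statistics <- function(graph) {
  n <- igraph::vcount(graph)
  if (igraph::ecount(graph) < 1) stop("path statistics need >= 1 edge",
                                      call. = FALSE)
  d <- igraph::distances(graph, weights = NA)
  vals <- d[upper.tri(d)]
  finite <- vals[is.finite(vals) & vals > 0]
  if (length(finite) == 0) stop("no connected node pair", call. = FALSE)
  list(
    diameter = as.integer(max(finite)),
    average_path_length = mean(finite),
    connected_pair_fraction = length(finite) / (n * (n - 1) / 2)
  )
}

#' Full per-node centrality table
#'
#' @param graph Undirected `igraph` graph.
#' @param resolution,seed Passed to [communities_louvain()].
#' @return Data frame: `node`, `category`, `degree`, `weighted_degree`,
#'   `betweenness`, `eigenvector`, `community_id`.
#' @export
centrality_table <- function(graph, resolution = 1, seed = 42L) {
  tab <- degree_and_weighted_degree(graph)
  tab$betweenness <- unname(betweenness_centrality(graph)[tab$node])
  eig <- if (igraph::ecount(graph) >= 1) {
    eigenvector_centrality(graph)
  } else {
    stats::setNames(numeric(nrow(tab)), tab$node)
  }
  tab$eigenvector <- unname(eig[tab$node])
  comm <- communities_louvain(graph, resolution = resolution, seed = seed)
  tab$community_id <- as.integer(unname(comm$membership[tab$node]))
  tab
}

#' Network-level summary
#'
#' Assembles average degree, average weighted degree, diameter, modularity,
#' number of communities and average path length — the network
#' characteristics panel of the two-mode analysis.
#'
#' @param graph Undirected `igraph` graph.
#' @param resolution,seed Passed to [communities_louvain()].
#' @param include_paths Compute diameter / average path length (all-pairs
#'   BFS; quadratic in nodes, can be disabled for very large networks).
#' @return One-row data frame.
#' @export
summarize_network <- function(graph, resolution = 1, seed = 42L,
                              include_paths = TRUE) {
  deg <- igraph::degree(graph)
  w <- igraph::E(graph)$weight
  strength <- igraph::strength(graph, weights = if (is.null(w)) NA else w)
  comm <- communities_louvain(graph, resolution = resolution, seed = seed)
  paths <- if (include_paths) path_statistics(graph) else
    list(diameter = NA_integer_, average_path_length = NA_real_,
         connected_pair_fraction = NA_real_)
  data.frame(
    n_nodes = igraph::vcount(graph),
    n_edges = igraph::ecount(graph),
    average_degree = mean(deg),
    average_weighted_degree = mean(strength),
    diameter = paths$diameter,
    modularity = comm$modularity,
    n_communities = comm$n_communities,
    average_path_length = paths$average_path_length,
    connected_pair_fraction = paths$connected_pair_fraction
  )
}

#' Write a per-node metric table
#' @param table Data frame from [centrality_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(table, path) {
  utils::write.table(table, path, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
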