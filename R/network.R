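#' Two-mode network construction and one-mode projection
#'
#' Prescription records induce an undirected bipartite ("two-mode") network
#' whose nodes are hospitals and patients and whose edges carry the
#' prescription count for each (patient, hospital) pair. Removing the
#' patient nodes by incidence-matrix multiplication yields the one-mode
#' hospital network, where two hospitals are joined with weight equal to
#' the number of patients they share.
#'
#' Networks are `igraph` graphs with vertex attributes `name` and
#' `category` (`"Hospital"` or `"Patient"`) and edge attribute `weight`.
#'
#' @name narcscreen-network
NULL

#' Build the two-mode hospital-patient network
#'
#' One edge per distinct (patient, hospital) pair; edge weight is the
#' number of records for the pair. Patient and hospital ids must live in
#' disjoint namespaces (the canonical `P-`/`H-` prefixes guarantee this).
#'
#' @param records Prescription record data frame.
#' @return Undirected bipartite `igraph` graph; vertex attribute `type` is
#'   `TRUE` for hospitals, and `category` spells the mode out.
#' @export
build_two_mode <- function(records) {
  pairs <- stats::aggregate(list(weight = rep(1L, nrow(records))),
                            by = list(patient_id = records$patient_id,
                                      hospital_id = records$hospital_id),
                            FUN = sum)
  patients <- sort(unique(records$patient_id))
  hospitals <- sort(unique(records$hospital_id))
  if (length(intersect(patients, hospitals)) > 0) {
    stop("patient and hospital ids overlap; cannot build a bipartite network",
         call. = FALSE)
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(patients) + length(hospitals),
                            name = c(patients, hospitals),
                            type = rep(c(FALSE, TRUE),
                                       c(length(patients), length(hospitals))),
                            category = rep(c("Patient", "Hospital"),
                                           c(length(patients), length(hospitals))))
  if (nrow(pairs) > 0) {
    edge_idx <- rbind(match(pairs$patient_id, igraph::V(g)$name),
                      match(pairs$hospital_id, igraph::V(g)$name))
    g <- igraph::add_edges(g, as.vector(edge_idx), weight = pairs$weight)
  }
  g
}

#' Project the two-mode network onto hospitals
#'
#' Computes the off-diagonal of \eqn{B^T B}, where B is the patient-by-
#' hospital incidence matrix: hospitals i and j are joined with weight
#' equal to the number of distinct patients connected to both. With
#' `weighted = TRUE` the incidence matrix carries prescription counts
#' instead of 0/1, giving \eqn{B_w^T B_w} (a sensitivity variant; shared-
#' patient counts are the default and keep one-mode weights
#' interpretable). Hospitals sharing no patients are kept as isolated
#' nodes so per-hospital reports cover every hospital.
#'
#' @param two_mode Bipartite graph from [build_two_mode()].
#' @param weighted Use prescription-weighted incidence instead of binary.
#' @return Undirected `igraph` graph over hospital nodes with edge
#'   attribute `weight`.
#' @export
project_one_mode <- function(two_mode, weighted = FALSE) {
  stopifnot(igraph::is_bipartite(two_mode))
  hosp <- igraph::V(two_mode)$name[igraph::V(two_mode)$type]
  B <- incidence_sparse(two_mode, binary = !weighted)
  cross <- Matrix::crossprod(B)          # hospital x hospital
  cross <- Matrix::triu(cross, k = 1)    # off-diagonal, upper triangle
  tri <- Matrix::summary(cross)
  tri <- tri[tri$x > 0, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(hosp), name = hosp,
                            category = "Hospital")
  if (nrow(tri) > 0) {
    g <- igraph::add_edges(g, as.vector(rbind(tri$i, tri$j)), weight = tri$x)
  }
  g
}

# Sparse patient x hospital incidence matrix of a bipartite graph.
incidence_sparse <- function(two_mode, binary = TRUE) {
  type <- igraph::V(two_mode)$type
  name <- igraph::V(two_mode)$name
  patients <- name[!type]
  hospitals <- name[type]
  el <- igraph::as_edgelist(two_mode, names = TRUE)
  w <- igraph::E(two_mode)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  # orient each edge patient -> hospital
  p_first <- el[, 1] %in% patients
  pid <- ifelse(p_first, el[, 1], el[, 2])
  hid <- ifelse(p_first, el[, 2], el[, 1])
  Matrix::sparseMatrix(
    i = match(pid, patients), j = match(hid, hospitals),
    x = if (binary) rep(1, length(w)) else w,
    dims = c(length(patients), length(hospitals)),
    dimnames = list(patients, hospitals)
  )
}

#' Export a network
#'
#' `graphml` uses igraph's writer; `gexf` writes a minimal GEXF 1.2 file;
#' `edgelist` writes the plain weighted edge-list dialect
#' (`source,target,weight,type` with `type = "undirected"`).
#'
#' @param graph An `igraph` graph with `name`, `category`, `weight`.
#' @param path Output path.
#' @param format One of `"graphml"`, `"gexf"`, `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = c("graphml", "gexf", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "edgelist") {
    el <- igraph::as_edgelist(graph, names = TRUE)
    w <- igraph::E(graph)$weight
    if (is.null(w)) w <- rep(1, nrow(el))
    df <- data.frame(source = el[, 1], target = el[, 2], weight = w,
                     type = "undirected", stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    write_gexf(graph, path)
  }
  invisible(path)
}

write_gexf <- function(graph, path) {
  name <- igraph::V(graph)$name
  category <- igraph::V(graph)$category
  if (is.null(category)) category <- rep("", length(name))
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="0" title="category" type="string"/>',
    '    </attributes>',
    '    <nodes>'), con)
  writeLines(sprintf(
    '      <node id="%s" label="%s"><attvalues><attvalue for="0" value="%s"/></attvalues></node>',
    name, name, category), con)
  writeLines(c('    </nodes>', '    <edges>'), con)
  if (nrow(el) > 0) {
    writeLines(sprintf(
      '      <edge id="%d" source="%s" target="%s" weight="%s"/>',
      seq_len(nrow(el)) - 1L, name[el[, 1]], name[el[, 2]],
      format(w, trim = TRUE, scientific = FALSE)), con)
  }
  writeLines(c('    </edges>', '  </graph>', '</gexf>'), con)
  invisible(path)
}

#' Read a network from GraphML or canonical edge-list
#'
#' @param path Input path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return An `igraph` graph.
#' @export
read_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df[, c("source", "target")],
                                     directed = FALSE)
  igraph::E(g)$weight <- df$weight
  if (all(grepl("^[HP]-", igraph::V(g)$name))) {
    igraph::V(g)$category <- ifelse(grepl("^H-", igraph::V(g)$name),
                                    "Hospital", "Patient")
    igraph::V(g)$type <- igraph::V(g)$category == "Hospital"
  }
  g
}
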