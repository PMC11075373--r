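#' Screening statistics for overprescription
#'
#' The screening layer separates two kinds of conspicuous hospitals: those
#' many flagged patients visit (high degree) and those issuing many
#' prescriptions to few patients (high weighted degree, low degree — the
#' suspected overprescribers). Its statistics are the top-k% overlap
#' between the degree and weighted-degree rankings, the Narcotics Safety
#' Index (weighted degree / degree, i.e. mean prescriptions per connected
#' patient), the four prescription-pattern quadrants, and hospital
#' size/region stratification.
#'
#' @name narcscreen-screening
NULL

#' Restrict a centrality table to hospital nodes
#'
#' @param table Data frame from [centrality_table()] or
#'   [degree_and_weighted_degree()].
#' @return The hospital rows.
#' @export
hospital_centralities <- function(table) {
  out <- table[!is.na(table$category) & table$category == "Hospital", ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

top_set <- function(table, metric, other, n_top) {
  ord <- order(-table[[metric]], -table[[other]], table$node)
  table$node[ord][seq_len(n_top)]
}

#' Overlap of the top-k% degree and weighted-degree hospital sets
#'
#' Takes the `n_top = ceiling(k_percent/100 * n_hospitals)` highest
#' hospitals under each metric (ties broken by the other metric
#' descending, then by id) and reports the fraction of hospitals common to
#' both sets. A high overlap means the busiest hospitals are also the
#' heaviest prescribers; a low overlap exposes overprescribers invisible
#' to a visit-count ranking.
#'
#' @param hospitals Hospital-restricted centrality table.
#' @param metric_a,metric_b Column names (default degree vs weighted
#'   degree).
#' @param k_percent Percentage cut (default 1).
#' @return List: `k_percent`, `n_top`, `set_a`, `set_b`,
#'   `overlap_fraction`.
#' @export
top_percent_overlap <- function(hospitals, metric_a = "degree",
                                metric_b = "weighted_degree",
                                k_percent = 1) {
  if (nrow(hospitals) < 1) stop("no hospital nodes", call. = FALSE)
  for (m in c(metric_a, metric_b)) {
    if (!m %in% names(hospitals)) stop("missing metric column: ", m,
                                       call. = FALSE)
  }
  n_top <- ceiling(k_percent / 100 * nrow(hospitals))
  set_a <- top_set(hospitals, metric_a, metric_b, n_top)
  set_b <- top_set(hospitals, metric_b, metric_a, n_top)
  list(
    k_percent = k_percent,
    n_top = n_top,
    set_a = set_a,
    set_b = set_b,
    overlap_fraction = length(intersect(set_a, set_b)) / n_top
  )
}

#' Narcotics Safety Index
#'
#' NSI = weighted degree / degree: the mean number of prescriptions per
#' connected patient. High values prioritize hospitals for inspection —
#' they prescribe much to few. Hospitals with degree 0 (possible only for
#' isolated nodes injected from attribute sidecars) are excluded with a
#' warning.
#'
#' @param hospitals Hospital-restricted centrality table.
#' @return Data frame `hospital_id`, `degree`, `weighted_degree`, `nsi`,
#'   sorted by NSI descending (ties by id).
#' @export
narcotics_safety_index <- function(hospitals) {
  zero <- hospitals$degree == 0
  if (any(zero)) {
    warning(sum(zero), " hospital(s) with degree 0 excluded from NSI")
    hospitals <- hospitals[!zero, , drop = FALSE]
  }
  out <- data.frame(
    hospital_id = hospitals$node,
    degree = hospitals$degree,
    weighted_degree = hospitals$weighted_degree,
    nsi = hospitals$weighted_degree / hospitals$degree,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$nsi, out$hospital_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prescription-pattern quadrants
#'
#' Classifies each hospital on two axes — degree and weighted degree —
#' where HIGH means membership in that metric's top-k% set (the same sets
#' as [top_percent_overlap()], keeping the quadrants consistent with the
#' overlap analysis). `HIGH_W & LOW_D` marks suspected overprescribers;
#' `HIGH_D & HIGH_W` marks hub hospitals.
#'
#' @param hospitals Hospital-restricted centrality table.
#' @param k_percent Percentage cut (default 1).
#' @return Data frame `hospital_id`, `degree`, `weighted_degree`,
#'   `quadrant` with levels `LOW_D_LOW_W`, `LOW_D_HIGH_W`, `HIGH_D_LOW_W`,
#'   `HIGH_D_HIGH_W`.
#' @export
classify_pattern <- function(hospitals, k_percent = 1) {
  ov <- top_percent_overlap(hospitals, k_percent = k_percent)
  high_d <- hospitals$node %in% ov$set_a
  high_w <- hospitals$node %in% ov$set_b
  quadrant <- ifelse(high_d & high_w, "HIGH_D_HIGH_W",
              ifelse(high_d, "HIGH_D_LOW_W",
              ifelse(high_w, "LOW_D_HIGH_W", "LOW_D_LOW_W")))
  data.frame(
    hospital_id = hospitals$node,
    degree = hospitals$degree,
    weighted_degree = hospitals$weighted_degree,
    quadrant = quadrant,
    stringsAsFactors = FALSE
  )
}

#' Stratify a hospital network by size category or region
#'
#' Per attribute category: hospital count and share, total weighted degree
#' and weighted-degree share. For regional stratification the fraction of
#' one-mode edges joining hospitals of different regions is also reported —
#' a doctor-shopping signal, since cross-region edges are patients
#' obtaining prescriptions far from home.
#'
#' @param graph Hospital network (one-mode projection), or a two-mode
#'   network (hospital nodes are selected by their `category`).
#' @param attributes Hospital attribute data frame
#'   ([load_hospital_attributes()]); hospitals without a row count as
#'   `UNKNOWN`.
#' @param by `"size_category"` or `"region"`.
#' @return List: `table` (per-category data frame with `n_hospitals`,
#'   `node_share`, `total_weighted_degree`, `weighted_degree_share`) and,
#'   for `by = "region"`, `cross_region_edge_fraction`.
#' @export
stratify <- function(graph, attributes, by = c("size_category", "region")) {
  by <- match.arg(by)
  category <- igraph::V(graph)$category
  is_hosp <- if (is.null(category)) rep(TRUE, igraph::vcount(graph)) else
    category == "Hospital"
  hosp_ids <- igraph::V(graph)$name[is_hosp]
  w <- igraph::E(graph)$weight
  strength <- igraph::strength(graph, weights = if (is.null(w)) NA else w)
  strength <- strength[is_hosp]
  attr_tab <- attach_attributes(hosp_ids, attributes)
  group <- attr_tab[[by]]

  levels_all <- unique(c(if (by == "size_category") size_categories()
                         else region_codes(), "UNKNOWN"))
  n_by <- tapply(rep(1L, length(group)), factor(group, levels = levels_all), sum)
  wd_by <- tapply(strength, factor(group, levels = levels_all), sum)
  n_by[is.na(n_by)] <- 0
  wd_by[is.na(wd_by)] <- 0
  tab <- data.frame(
    category = levels_all,
    n_hospitals = as.integer(n_by),
    node_share = as.numeric(n_by) / length(hosp_ids),
    total_weighted_degree = as.numeric(wd_by),
    weighted_degree_share = if (sum(wd_by) > 0)
      as.numeric(wd_by) / sum(wd_by) else rep(0, length(levels_all)),
    stringsAsFactors = FALSE
  )
  tab <- tab[tab$n_hospitals > 0 | tab$category != "UNKNOWN", , drop = FALSE]
  rownames(tab) <- NULL
  out <- list(table = tab)

  if (by == "region") {
    el <- igraph::as_edgelist(graph, names = TRUE)
    hosp_edges <- el[, 1] %in% hosp_ids & el[, 2] %in% hosp_ids
    el <- el[hosp_edges, , drop = FALSE]
    if (nrow(el) > 0) {
      r1 <- group[match(el[, 1], hosp_ids)]
      r2 <- group[match(el[, 2], hosp_ids)]
      out$cross_region_edge_fraction <- mean(r1 != r2)
    } else {
      out$cross_region_edge_fraction <- NA_real_
    }
  }
  out
}

#' Assemble the per-hospital screening report
#'
#' Joins centralities, NSI, quadrant label and attributes into the final
#' screening table, sorted by NSI descending.
#'
#' @param hospitals Hospital-restricted centrality table.
#' @param attributes Optional hospital attribute data frame.
#' @param k_percent Top-percent cut for the quadrants.
#' @return Data frame: `hospital_id`, `degree`, `weighted_degree`,
#'   `betweenness`, `eigenvector`, `nsi`, `quadrant`, `size_category`,
#'   `region`.
#' @export
screening_report <- function(hospitals, attributes = NULL, k_percent = 1) {
  nsi <- narcotics_safety_index(hospitals)
  quad <- classify_pattern(hospitals, k_percent = k_percent)
  out <- data.frame(
    hospital_id = hospitals$node,
    degree = hospitals$degree,
    weighted_degree = hospitals$weighted_degree,
    betweenness = if ("betweenness" %in% names(hospitals))
      hospitals$betweenness else NA_real_,
    eigenvector = if ("eigenvector" %in% names(hospitals))
      hospitals$eigenvector else NA_real_,
    stringsAsFactors = FALSE
  )
  out$nsi <- nsi$nsi[match(out$hospital_id, nsi$hospital_id)]
  out$quadrant <- quad$quadrant[match(out$hospital_id, quad$hospital_id)]
  attrs <- attach_attributes(out$hospital_id, attributes)
  out$size_category <- attrs$size_category
  out$region <- attrs$region
  out <- out[order(-out$nsi, out$hospital_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
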