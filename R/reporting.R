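#' Descriptive usage tables and the end-to-end pipeline
#'
#' @name narcscreen-reporting
NULL

#' Round half-up to a number of decimals
#'
#' Commercial rounding (0.5 always rounds away from zero for positive
#' input), the convention used by the printed usage tables: 4.7178 -> 4.72.
#'
#' @param x Numeric vector (nonnegative in this pipeline).
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-year or per-drug usage table
#'
#' Distinct-patient counts, prescription counts, and the average number of
#' prescriptions per patient (prescriptions / patients, rounded half-up to
#' two decimals) per calendar year or per drug class.
#'
#' @param records Validated record data frame.
#' @param group_by `"year"` or `"drug"`.
#' @return Data frame: `group`, `n_patients`, `n_prescriptions`,
#'   `avg_rx_per_patient`. Empty groups are omitted.
#' @export
usage_table <- function(records, group_by = c("year", "drug")) {
  group_by <- match.arg(group_by)
  key <- if (group_by == "year") format(records$date, "%Y") else records$drug
  groups <- sort(unique(key))
  out <- lapply(groups, function(g) {
    sub <- records[key == g, , drop = FALSE]
    data.frame(
      group = g,
      n_patients = length(unique(sub$patient_id)),
      n_prescriptions = nrow(sub),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out$avg_rx_per_patient <- round_half_up(out$n_prescriptions / out$n_patients, 2)
  out
}

#' Average prescriptions per patient from printed counts
#'
#' The headline usage ratio: prescriptions divided by patients, rounded
#' half-up to two decimals.
#'
#' @param n_prescriptions,n_patients Counts.
#' @return The rounded ratio.
#' @export
avg_rx_per_patient <- function(n_prescriptions, n_patients) {
  round_half_up(n_prescriptions / n_patients, 2)
}

#' Build a pipeline configuration
#'
#' @param records_path Path to the prescription record file.
#' @param attributes_path Optional hospital attribute file.
#' @param rules Rule set (default [default_ssun_rules()]).
#' @param out_dir Output directory.
#' @param drug Optional single drug to restrict to.
#' @param window Study window.
#' @param weighted_projection Use the prescription-weighted one-mode
#'   projection.
#' @param resolution Louvain resolution.
#' @param k_percent Top-percent cut for screening.
#' @param include_paths Compute diameter / average path length.
#' @param seed Seed for the (Louvain) stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(records_path, attributes_path = NULL,
                            rules = default_ssun_rules(),
                            out_dir = ".", drug = NULL,
                            window = default_study_window(),
                            weighted_projection = FALSE,
                            resolution = 1, k_percent = 1,
                            include_paths = TRUE, seed = 42L) {
  if (!is.null(drug)) drug <- match.arg(drug, drug_classes())
  structure(
    list(records_path = records_path, attributes_path = attributes_path,
         rules = rules, out_dir = out_dir, drug = drug, window = window,
         weighted_projection = weighted_projection, resolution = resolution,
         k_percent = k_percent, include_paths = include_paths,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  canon <- config
  canon$out_dir <- NULL   # analytic identity only; not where results land
  canon$rules <- lapply(canon$rules, unclass)
  canon$window <- format(canon$window, "%Y-%m-%d")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full screening pipeline
#'
#' filter -> build -> analyze -> screen, writing every artifact under
#' `out_dir`: flagged records, exceedance flags and per-drug summary, the
#' two-mode and one-mode networks (GraphML + edge list), per-node metrics,
#' the screening report, stratification tables, and a summary JSON
#' carrying the config hash and seed. All stages are a pure function of
#' (input files, config, seed); Louvain is the only seeded-stochastic
#' stage. Re-running with an identical config is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the in-memory artifacts (`records`,
#'   `flags`, `flagged`, `two_mode`, `one_mode`, `metrics`, `report`,
#'   `summary`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)

  loaded <- load_records(config$records_path, window = config$window)
  records <- loaded$records
  if (!is.null(config$drug)) {
    records <- records[records$drug == config$drug, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("stage filter: no records in scope",
                               call. = FALSE)
  say("filter: ", nrow(records), " records in scope (",
      nrow(loaded$errors), " invalid rows, ",
      loaded$n_dropped_window, " outside window)")

  attributes <- if (!is.null(config$attributes_path)) {
    load_hospital_attributes(config$attributes_path)
  } else NULL

  flags <- flag_exceedances(records, config$rules)
  flagged <- flagged_subset(records, flags)
  if (nrow(flagged) == 0) stop("stage filter: no record exceeds the rules",
                               call. = FALSE)
  say("filter: ", nrow(flags), " flags; flagged subset has ",
      nrow(flagged), " records")
  write_flags(flags, out("flags.csv"))
  write_records(flagged, out("flagged_records.csv"))
  exc_summary <- summarize_exceedance(flagged)
  utils::write.table(exc_summary, out("exceedance_summary.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")

  two_mode <- build_two_mode(flagged)
  one_mode <- project_one_mode(two_mode, weighted = config$weighted_projection)
  say("build: two-mode ", igraph::vcount(two_mode), " nodes / ",
      igraph::ecount(two_mode), " edges; one-mode ",
      igraph::vcount(one_mode), " nodes / ", igraph::ecount(one_mode),
      " edges")
  write_network(two_mode, out("two_mode.graphml"), "graphml")
  write_network(two_mode, out("two_mode_edges.csv"), "edgelist")
  write_network(one_mode, out("one_mode.graphml"), "graphml")
  write_network(one_mode, out("one_mode_edges.csv"), "edgelist")

  metrics <- centrality_table(two_mode, resolution = config$resolution,
                              seed = config$seed)
  write_metrics(metrics, out("metrics.csv"))
  net_summary <- summarize_network(two_mode, resolution = config$resolution,
                                   seed = config$seed,
                                   include_paths = config$include_paths)
  say("analyze: modularity ", round(net_summary$modularity, 3), " over ",
      net_summary$n_communities, " communities")

  hosp <- hospital_centralities(metrics)
  report <- screening_report(hosp, attributes, k_percent = config$k_percent)
  overlap <- top_percent_overlap(hosp, k_percent = config$k_percent)
  utils::write.table(report, out("screening_report.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  strat_size <- stratify(one_mode, attributes, by = "size_category")
  strat_region <- stratify(one_mode, attributes, by = "region")
  say("screen: top-", config$k_percent, "% overlap ",
      round(overlap$overlap_fraction, 3))

  summary <- list(
    schema_version = "1",
    config_hash = config_hash(config),
    seed = config$seed,
    n_records = nrow(records),
    n_flags = nrow(flags),
    n_flagged_records = nrow(flagged),
    exceedance = exc_summary,
    network = net_summary,
    overlap = overlap[c("k_percent", "n_top", "overlap_fraction")],
    cross_region_edge_fraction = strat_region$cross_region_edge_fraction,
    stratification = list(size_category = strat_size$table,
                          region = strat_region$table)
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", null = "null"),
             out("summary.json"))

  invisible(list(records = records, flags = flags, flagged = flagged,
                 two_mode = two_mode, one_mode = one_mode,
                 metrics = metrics, report = report, summary = summary))
}
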