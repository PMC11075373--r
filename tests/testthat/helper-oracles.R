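# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and, where feasible, the
# libraries) used by the package itself.

# --- safe-use window-scan oracle -------------------------------------------
# O(n^2) per patient-drug pair: every record is compared against every
# other record of its pair with explicit date arithmetic.
oracle_flags <- function(records, rules = default_ssun_rules(), gap = 7) {
  n <- nrow(records)
  out <- list()
  add <- function(i, reason) {
    out[[length(out) + 1]] <<- data.frame(
      record_index = i, patient_id = records$patient_id[i],
      hospital_id = records$hospital_id[i], drug = records$drug[i],
      reason = reason, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    rule <- rules[[records$drug[i]]]
    if (records$daily_dose_mg[i] > rule$max_daily_dose_mg) add(i, "DOSE")
  }
  pairs <- unique(records[, c("patient_id", "drug")])
  for (r in seq_len(nrow(pairs))) {
    idx <- which(records$patient_id == pairs$patient_id[r] &
                 records$drug == pairs$drug[r])
    idx <- idx[order(records$date[idx], idx)]
    rule <- rules[[pairs$drug[r]]]
    d <- as.numeric(records$date[idx])
    sup <- records$days_supplied[idx]
    m <- length(idx)

    if (is.finite(rule$max_episode_days)) {
      # group into episodes by explicit scan
      ep <- integer(m); ep[1] <- 1L
      end <- d[1] + sup[1]
      if (m > 1) for (j in 2:m) {
        if (d[j] - end > gap) { ep[j] <- ep[j - 1] + 1L; end <- d[j] + sup[j] }
        else { ep[j] <- ep[j - 1]; end <- max(end, d[j] + sup[j]) }
      }
      for (e in unique(ep)) {
        if (sum(sup[ep == e]) > rule$max_episode_days) {
          for (j in which(ep == e)) add(idx[j], "EPISODE")
        }
      }
    }
    if (is.finite(rule$max_cumulative_days)) {
      hit <- rep(FALSE, m)
      for (j in seq_len(m)) {
        inw <- which(d >= d[j] & d < d[j] + 90)
        if (sum(sup[inw]) > rule$max_cumulative_days) hit[inw] <- TRUE
      }
      for (j in which(hit)) add(idx[j], "CUMULATIVE")
    }
    if (is.finite(rule$max_events_per_30_days)) {
      for (j in seq_len(m)) {
        n_in <- sum(d[seq_len(j)] > d[j] - 30)
        if (n_in > rule$max_events_per_30_days) add(idx[j], "FREQUENCY")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(record_index = integer(0), patient_id = character(0),
                      hospital_id = character(0), drug = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$record_index, res$reason), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- projection oracle ------------------------------------------------------
# Shared-patient counts by explicit pairwise set intersection.
oracle_projection_weights <- function(records) {
  hospitals <- sort(unique(records$hospital_id))
  pat_sets <- lapply(hospitals, function(h)
    unique(records$patient_id[records$hospital_id == h]))
  names(pat_sets) <- hospitals
  out <- list()
  if (length(hospitals) >= 2) {
    for (a in 1:(length(hospitals) - 1)) {
      for (b in (a + 1):length(hospitals)) {
        shared <- length(intersect(pat_sets[[a]], pat_sets[[b]]))
        if (shared > 0) {
          out[[length(out) + 1]] <- data.frame(
            h1 = hospitals[a], h2 = hospitals[b], weight = shared,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(h1 = character(0), h2 = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# --- betweenness oracle -----------------------------------------------------
# Exhaustive simple-path enumeration (DFS), keeping only shortest paths.
# Feasible for <= 8-10 nodes.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  paths_between <- function(s, t) {
    found <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { found[[length(found) + 1]] <<- path; return(invisible()) }
      for (w in which(adj[v, ] > 0)) {
        if (!w %in% path) walk(c(path, w))
      }
    }
    walk(s)
    found
  }
  b <- numeric(n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      ps <- paths_between(s, t)
      if (length(ps) == 0) next
      lens <- vapply(ps, length, integer(1))
      shortest <- ps[lens == min(lens)]
      sigma <- length(shortest)
      for (v in setdiff(1:n, c(s, t))) {
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        b[v] <- b[v] + through / sigma
      }
    }
  }
  b
}

# --- eigenvector oracle -----------------------------------------------------
# Dense eigendecomposition per connected component, global max = 1.
oracle_eigenvector <- function(adj) {
  n <- nrow(adj)
  comp <- components_from_adj(adj)
  x <- numeric(n)
  for (members in comp) {
    if (length(members) < 2) next
    ev <- eigen(adj[members, members, drop = FALSE], symmetric = TRUE)
    v <- abs(ev$vectors[, which.max(ev$values)])
    x[members] <- v / max(v)
  }
  if (max(x) > 0) x <- x / max(x)
  x
}

components_from_adj <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in 1:n) {
    if (seen[s]) next
    stack <- s; members <- integer(0)
    while (length(stack) > 0) {
      v <- stack[[1]]; stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      members <- c(members, v)
      stack <- c(stack, which(adj[v, ] > 0 & !seen))
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# --- exhaustive modularity optimum -----------------------------------------
# Enumerate all set partitions via restricted growth strings; evaluate Q
# for each. Feasible for n <= 8 (Bell(8) = 4140).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxval) {
    if (length(prefix) == n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (v in 1:(maxval + 1)) rec(c(prefix, v), max(maxval, v))
  }
  rec(integer(0), 0L)
  out
}

oracle_best_modularity <- function(graph) {
  n <- igraph::vcount(graph)
  best <- -Inf
  for (p in all_partitions(n)) {
    q <- modularity_q(graph, p)
    if (q > best) best <- q
  }
  best
}

# --- misc -------------------------------------------------------------------
random_records <- function(n, n_patients = 4, n_hospitals = 3,
                           drug = "PROPOFOL", seed = 1) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("P-%02d", sample(n_patients, n, replace = TRUE)),
    hospital_id = sprintf("H-%02d", sample(n_hospitals, n, replace = TRUE)),
    drug = drug,
    date = as.Date("2020-01-01") + sample(0:200, n, replace = TRUE),
    daily_dose_mg = round(stats::runif(n, 1, 20), 1),
    days_supplied = sample(1:40, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

random_bipartite_records <- function(n_patients, n_hospitals, density, seed) {
  set.seed(seed)
  inc <- matrix(stats::runif(n_patients * n_hospitals) < density,
                n_patients, n_hospitals)
  idx <- which(inc, arr.ind = TRUE)
  if (nrow(idx) == 0) idx <- cbind(1, 1)
  data.frame(
    patient_id = sprintf("P-%02d", idx[, 1]),
    hospital_id = sprintf("H-%02d", idx[, 2]),
    drug = "ZOLPIDEM",
    date = as.Date("2020-01-01"),
    daily_dose_mg = 5,
    days_supplied = 7L,
    stringsAsFactors = FALSE
  )
}

random_igraph <- function(n, p, seed, weights = FALSE) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  upper <- which(upper.tri(adj))
  on <- upper[stats::runif(length(upper)) < p]
  adj[on] <- if (weights) sample(1:5, length(on), replace = TRUE) else 1
  adj <- adj + t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = if (weights) TRUE else NULL)
  igraph::V(g)$name <- sprintf("N-%02d", seq_len(n))
  list(graph = g, adj = adj)
}
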