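hosp_table <- function(degree, weighted_degree, ids = NULL) {
  n <- length(degree)
  data.frame(
    node = if (is.null(ids)) sprintf("H-%03d", seq_len(n)) else ids,
    category = "Hospital",
    degree = degree,
    weighted_degree = weighted_degree,
    stringsAsFactors = FALSE
  )
}

test_that("top-percent overlap handles identical, partial and tied rankings", {
  # identical rankings -> overlap 1
  tab <- hosp_table(degree = 100:1, weighted_degree = (100:1) * 2)
  ov <- top_percent_overlap(tab, k_percent = 2)
  expect_equal(ov$n_top, 2)
  expect_equal(ov$overlap_fraction, 1)

  # 200 hospitals, top-2 sets sharing exactly one hospital
  deg <- c(1000, 999, rep(1, 198))
  wd <- c(5000, 10, rep(5, 197), 9000)
  tab2 <- hosp_table(deg, wd)
  ov2 <- top_percent_overlap(tab2, k_percent = 1)
  expect_equal(ov2$n_top, 2)
  expect_setequal(ov2$set_a, c("H-001", "H-002"))
  expect_setequal(ov2$set_b, c("H-001", "H-200"))
  expect_equal(ov2$overlap_fraction, 0.5)

  # unit weights: weighted degree == degree -> overlap 1 by metric identity
  tab3 <- hosp_table(degree = sample(1:50), weighted_degree = 0)
  tab3$weighted_degree <- tab3$degree
  expect_equal(top_percent_overlap(tab3)$overlap_fraction, 1)

  # ceiling: 1% of 50 hospitals still yields a nonempty set
  expect_equal(top_percent_overlap(tab3, k_percent = 1)$n_top, 1)
  expect_error(top_percent_overlap(tab3, metric_a = "nope"), "missing metric")
})

test_that("overlap is invariant under row permutation and ties break deterministically", {
  set.seed(4)
  tab <- hosp_table(degree = sample(c(5, 5, 5, 4, 3, 2, 2, 1, 1, 1)),
                    weighted_degree = sample(10:1))
  ov1 <- top_percent_overlap(tab, k_percent = 30)
  perm <- tab[sample(nrow(tab)), ]
  ov2 <- top_percent_overlap(perm, k_percent = 30)
  expect_equal(ov1$set_a, ov2$set_a)
  expect_equal(ov1$set_b, ov2$set_b)
  expect_equal(ov1$overlap_fraction, ov2$overlap_fraction)
})

test_that("NSI is weighted degree over degree, ranked descending", {
  # arithmetic worked example from a published top-degree hospital
  tab <- hosp_table(degree = c(26106, 2, 10),
                    weighted_degree = c(184792, 10, 10),
                    ids = c("H-A", "H-B", "H-C"))
  nsi <- narcotics_safety_index(tab)
  expect_equal(nsi$nsi[nsi$hospital_id == "H-A"], 184792 / 26106)
  expect_equal(round(nsi$nsi[nsi$hospital_id == "H-A"], 4), 7.0785)
  # hospital with 2 patients and weights {3, 7} -> NSI 5
  tab2 <- hosp_table(degree = 2, weighted_degree = 10)
  expect_equal(narcotics_safety_index(tab2)$nsi, 5)
  # ranking is by NSI descending
  expect_equal(nsi$hospital_id, c("H-A", "H-B", "H-C"))
  # all unit weights -> NSI exactly 1 everywhere
  tab3 <- hosp_table(degree = 1:5, weighted_degree = 1:5)
  expect_true(all(narcotics_safety_index(tab3)$nsi == 1))
  # degree-zero hospitals are excluded with a warning
  tab4 <- hosp_table(degree = c(0, 2), weighted_degree = c(0, 4))
  expect_warning(out <- narcotics_safety_index(tab4), "degree 0")
  expect_equal(nrow(out), 1)
})

test_that("NSI scales linearly with one hospital's edge weights", {
  rec <- data.frame(
    patient_id = c("P-1", "P-2", "P-1"),
    hospital_id = c("H-1", "H-1", "H-2"),
    drug = "ZOLPIDEM", date = as.Date("2020-01-01") + 0:2,
    daily_dose_mg = 5, days_supplied = 7L, stringsAsFactors = FALSE)
  tab <- hospital_centralities(degree_and_weighted_degree(build_two_mode(rec)))
  nsi1 <- narcotics_safety_index(tab)
  # tripling H-1's prescriptions triples its NSI, degree unchanged
  rec3 <- rbind(rec, rec[rec$hospital_id == "H-1", ][rep(1:2, 2), ])
  tab3 <- hospital_centralities(degree_and_weighted_degree(build_two_mode(rec3)))
  nsi3 <- narcotics_safety_index(tab3)
  expect_equal(tab3$degree, tab$degree[match(tab3$node, tab$node)])
  expect_equal(nsi3$nsi[nsi3$hospital_id == "H-1"],
               3 * nsi1$nsi[nsi1$hospital_id == "H-1"])
})

test_that("quadrants reuse the top-k% sets, exhaustively and exclusively", {
  deg <- c(1000, 999, rep(10, 197), 2)
  wd <- c(5000, 30, rep(20, 197), 1000)   # H-200: 2 patients, 500 each
  tab <- hosp_table(deg, wd)
  quad <- classify_pattern(tab, k_percent = 1)
  expect_equal(quad$quadrant[quad$hospital_id == "H-001"], "HIGH_D_HIGH_W")
  expect_equal(quad$quadrant[quad$hospital_id == "H-200"], "LOW_D_HIGH_W")
  expect_equal(quad$quadrant[quad$hospital_id == "H-002"], "HIGH_D_LOW_W")
  expect_equal(quad$quadrant[quad$hospital_id == "H-100"], "LOW_D_LOW_W")
  expect_equal(nrow(quad), 200)
  expect_true(all(quad$quadrant %in% c("LOW_D_LOW_W", "LOW_D_HIGH_W",
                                       "HIGH_D_LOW_W", "HIGH_D_HIGH_W")))
  # consistency with the overlap sets
  ov <- top_percent_overlap(tab, k_percent = 1)
  expect_setequal(quad$hospital_id[quad$quadrant %in%
                                     c("HIGH_D_HIGH_W", "HIGH_D_LOW_W")],
                  ov$set_a)
})

test_that("an overprescriber lands in the high-weight / low-degree quadrant", {
  # 200 hospitals with 3 unit-weight patients each, plus one hospital with
  # only 2 patients but 500 prescriptions each
  rows <- lapply(1:200, function(h) data.frame(
    patient_id = sprintf("P-%03d-%d", h, 1:3),
    hospital_id = sprintf("H-%03d", h),
    drug = "PROPOFOL", date = as.Date("2020-01-01"),
    daily_dose_mg = 50, days_supplied = 1L, stringsAsFactors = FALSE))
  over <- data.frame(
    patient_id = rep(c("P-900", "P-901"), each = 500),
    hospital_id = "H-900", drug = "PROPOFOL",
    date = rep(as.Date("2020-01-01") + 0:499, 2),
    daily_dose_mg = 50, days_supplied = 1L, stringsAsFactors = FALSE)
  rec <- rbind(do.call(rbind, rows), over)
  g <- build_two_mode(rec)
  hosp <- hospital_centralities(degree_and_weighted_degree(g))
  quad <- classify_pattern(hosp, k_percent = 1)
  expect_equal(quad$quadrant[quad$hospital_id == "H-900"], "LOW_D_HIGH_W")
})

test_that("stratification reports node and weighted-degree shares", {
  rec <- data.frame(
    patient_id = c("P-1", "P-1", "P-2", "P-2"),
    hospital_id = c("H-1", "H-2", "H-1", "H-3"),
    drug = "ZOLPIDEM", date = as.Date("2020-01-01") + 0:3,
    daily_dose_mg = 5, days_supplied = 7L, stringsAsFactors = FALSE)
  attrs <- data.frame(hospital_id = c("H-1", "H-2", "H-3"),
                      size_category = c("CL", "CL", "GH"),
                      region = c("SEL", "SEL", "PUS"),
                      stringsAsFactors = FALSE)
  g1 <- project_one_mode(build_two_mode(rec))
  s <- stratify(g1, attrs, by = "size_category")
  cl <- s$table[s$table$category == "CL", ]
  expect_equal(cl$n_hospitals, 2)
  expect_equal(cl$node_share, 2 / 3)

  # all hospitals CL -> share 1, everything else 0
  attrs_cl <- attrs; attrs_cl$size_category <- "CL"
  s2 <- stratify(g1, attrs_cl, by = "size_category")
  expect_equal(s2$table$node_share[s2$table$category == "CL"], 1)
  expect_true(all(s2$table$weighted_degree_share[s2$table$category != "CL"] == 0))

  # region stratification reports the cross-region edge fraction
  sr <- stratify(g1, attrs, by = "region")
  # edges: H-1~H-2 (SEL-SEL), H-1~H-3 (SEL-PUS) -> 1/2 cross-region
  expect_equal(sr$cross_region_edge_fraction, 0.5)
  expect_error(stratify(g1, attrs, by = "postcode"))
})

test_that("two categories of equal size, one holding all weight, split shares 1/0", {
  rec <- data.frame(
    patient_id = c("P-1", "P-1"), hospital_id = c("H-1", "H-2"),
    drug = "ZOLPIDEM", date = as.Date("2020-01-01"),
    daily_dose_mg = 5, days_supplied = 7L, stringsAsFactors = FALSE)
  attrs <- data.frame(hospital_id = c("H-1", "H-2", "H-3", "H-4"),
                      size_category = c("CL", "CL", "GH", "GH"),
                      region = "SEL", stringsAsFactors = FALSE)
  g2 <- build_two_mode(rec)
  # add the two weightless GH hospitals as isolated nodes via projection input
  g1 <- project_one_mode(g2)
  g1 <- igraph::add_vertices(g1, 2, name = c("H-3", "H-4"),
                             category = "Hospital")
  s <- stratify(g1, attrs, by = "size_category")
  expect_equal(s$table$weighted_degree_share[s$table$category == "CL"], 1)
  expect_equal(s$table$weighted_degree_share[s$table$category == "GH"], 0)
})

test_that("appetite-like networks cross regions more than zolpidem-like ones", {
  frac_of <- function(nm, s) {
    ds <- generate_dataset(preset(nm, n_patients = 800, n_hospitals = 200,
                                  seed = s))
    g1 <- project_one_mode(build_two_mode(ds$records))
    stratify(g1, ds$hospitals, by = "region")$cross_region_edge_fraction
  }
  fa <- vapply(1:7, function(s) frac_of("appetite_like", s), numeric(1))
  fz <- vapply(1:7, function(s) frac_of("zolpidem_like", s), numeric(1))
  expect_gt(stats::median(fa), stats::median(fz))
})

test_that("screening report joins NSI, quadrant and attributes", {
  ds <- generate_dataset(preset("propofol_like", n_patients = 500,
                                n_hospitals = 150, seed = 2))
  fl <- flag_exceedances(ds$records)
  sub <- flagged_subset(ds$records, fl)
  tab <- centrality_table(build_two_mode(sub), seed = 5)
  hosp <- hospital_centralities(tab)
  rep <- screening_report(hosp, ds$hospitals, k_percent = 1)
  expect_equal(nrow(rep), nrow(hosp))
  expect_equal(rep$nsi, rep$weighted_degree / rep$degree)
  expect_true(all(rep$nsi >= 1))
  expect_false(is.unsorted(rev(rep$nsi)))
  expect_true(all(rep$size_category %in% c(size_categories(), "UNKNOWN")))
})
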