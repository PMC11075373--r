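---
title: "Screening prescription networks for overprescription of medical narcotics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening prescription networks for overprescription of medical narcotics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narcscreen)
```

## The screening problem

Medical narcotics — here appetite suppressants, zolpidem and propofol —
are dispensed under mandatory electronic reporting, so a regulator sees
every prescription. The difficulty is not data but interpretation:
hospitals with large prescription totals include both legitimate
high-volume providers and clinics channelling many prescriptions into few
patients. `narcscreen` treats the dispensing data as a network and
screens on structure rather than volume.

The analysis chain is: safe-use exceedance filtering, construction of the
undirected two-mode hospital–patient network, one-mode projection onto
hospitals, a standard network-metric suite, and screening statistics that
contrast a hospital's patient count (degree) with its prescription count
(weighted degree).

## Safe-use rules and the exceedance filter

Each drug class carries caps on up to four dimensions
(`default_ssun_rules()`):

| drug | daily dose | episode | cumulative | frequency |
|---|---|---|---|---|
| appetite suppressant | — | 28 d | 90 d / rolling 90 d | — |
| zolpidem | 10 mg/day | 28 d | — | — |
| propofol | — | — | — | 1 event / rolling 30 d |

Interpretation choices the standards leave open, fixed here and
configurable:

* "Four weeks" is 28 days, "three months" 90 days, "once a month" one
  event per *rolling* 30-day window. Calendar months would make a
  flag depend on month length.
* Rolling windows are closed on the left, open on the right: two propofol
  dispensings exactly 30 days apart are compliant, 29 days apart are not.
* A *treatment episode* joins consecutive prescriptions of one
  (patient, drug) pair when the gap between one prescription's coverage
  end (date + days supplied) and the next start is ≤ 7 days — the usual
  persistence-window convention (`episode_gap_days`).
* The dose check is per prescription; concurrent prescriptions are not
  summed into a daily total. The alternative (aggregating same-day
  coverage) would need dispensing-time resolution the data model does not
  carry.
* `flagged_subset()` keeps the **whole history** of every flagged
  (patient, drug) pair, not only the violating records, so the network
  reflects each flagged patient's full prescription pattern; a
  `whole_history = FALSE` switch gives the narrower reading.
* Per-patient summary moments use the population SD; at study scale the
  sample/population distinction is negligible, and it is configurable.

Flags are screening signals: exceeding a safe-use cap may be medically
justified, and nothing here judges clinical appropriateness.

## Networks and metrics

`build_two_mode()` aggregates records into one weighted edge per
(patient, hospital) pair. `project_one_mode()` computes the off-diagonal
of \(B^\top B\) for the binary incidence matrix \(B\): one-mode weights are
shared-patient counts. A prescription-weighted variant
(\(B_w^\top B_w\)) exists for sensitivity analysis but shared-patient
counts are the default because they stay interpretable (how many patients
connect two hospitals). Isolated hospitals survive projection so
per-hospital reports cover every hospital.

Metric conventions, chosen for large, weighted, highly fragmented
screening networks:

* **Betweenness and path statistics use unweighted hop-count paths.**
  Prescription counts are connection strengths, not travel costs;
  inverting them into distances would be an extra modeling decision.
  Betweenness is unnormalized with each unordered pair counted once.
* **Eigenvector centrality** is computed per connected component by
  shifted power iteration (Rayleigh-quotient shift; plain power iteration
  oscillates on bipartite graphs because the spectrum is symmetric), then
  rescaled globally so the maximum over all nodes is exactly 1 and
  isolated nodes are 0. Tolerance 1e-8 in the sup norm, at most 1,000
  iterations, with an explicit error naming the component on
  non-convergence.
* **Communities** come from weighted Louvain at resolution 1 with a
  seeded RNG (tie-breaking is stochastic); modularity
  \(Q = \sum_c (e_c/m - (d_c/2m)^2)\) is evaluated directly from the
  partition by `modularity_q()`.
* **Diameter and average path length** are taken over connected pairs
  only — a fragmented network has no finite whole-graph values — and the
  connected-pair fraction is reported alongside.
* Centrality screening operates on the **two-mode** network restricted to
  hospital rows: there a hospital's degree is its patient count and its
  weighted degree its prescription count, which is exactly what the
  screening statistics contrast.

## Screening statistics

With hospital-level degree and weighted degree:

* `top_percent_overlap()` takes the top `ceiling(k/100 * n)` hospitals
  under each metric and reports the shared fraction. The ceiling
  guarantees a nonempty set on small networks; ties break by the other
  metric descending, then by id, because overlap at the boundary is
  tie-sensitive. The denominator is the set size (the two lists have
  equal length).
* `narcotics_safety_index()` ranks hospitals by
  NSI = weighted degree / degree — mean prescriptions per connected
  patient. It is ≥ 1 by construction, scales linearly if a hospital
  multiplies its prescriptions per patient, and is independent of patient
  volume.
* `classify_pattern()` reuses the same top-k% sets as HIGH/LOW cuts so
  the quadrants stay consistent with the overlap analysis instead of
  introducing new thresholds. `LOW_D_HIGH_W` is the overprescriber cell,
  `HIGH_D_HIGH_W` the hub cell.
* `stratify()` reports node and weighted-degree shares per hospital size
  category or region, plus the fraction of one-mode edges joining
  different regions — patients obtaining prescriptions far from home are
  the doctor-shopping signal.

The top-k% cut is applied per drug network over hospital nodes only;
applying it over all nodes would mix patient and hospital ranking scales.

## The synthetic generator

Dispensing-level narcotics data is legally restricted, so the package
generates its own. `generator_profile()` fixes, per drug: population
sizes; a fixed hub set receiving a `hub_concentration` share of visits
(a fixed set, rather than preferential attachment, keeps hub identity
known to tests); a fraction of overprescriber hospitals whose patients'
prescription counts are multiplied by `overprescriber_boost`; shopper
patients who redraw a hospital per prescription while others reuse a
personal set of 1–2; `region_locality`, the probability a non-hub visit
stays in the patient's home region; and negative-binomial per-patient
prescription counts (`rx_count_mean`, `rx_count_dispersion`) — the
published per-patient SDs exceed the means severalfold, which rules out
Poisson counts. Dose, days-supplied and inter-event-gap marginals are
drawn so the three violation rates are met in expectation; the
gap process falls back to uniform dates for patients whose prescription
count cannot fit the window at compliant spacing (inherently frequent
users). Size categories default to a clinic-dominated distribution over
the ten institution codes; region shares default to uniform over the 16
region codes, with a Korea-like population share table available as
`korea_region_shares()` but never hard-coded.

Everything is a pure function of the profile, including its seed (R's
default RNG, seeded once per generation stage).

### Presets

The three presets encode the cross-drug contrasts the screening analysis
rests on, calibrated at 2,000 patients / 500 hospitals:

* `appetite_like` — strong hubs (0.5), weak locality (0.4), many
  shoppers: the *least* modular, most geographically dispersed network,
  with a high top-1% overlap.
* `zolpidem_like` — negligible hubs (0.08), strong locality (0.9): the
  most modular, fragmented, region-bound network; overlap stays high.
* `propofol_like` — moderate hubs plus 1.5% overprescriber hospitals at
  boost 45 and a 0.35 frequency-violation rate: heavy-tailed
  per-flagged-patient counts (median mean ≈ 7–8, SD ≈ 20–27, ratio ≈ 3)
  and a top-1% overlap near zero, because the weighted-degree ranking is
  captured by overprescribers few patients visit.

What the generator does *not* emulate: the absolute scale of the national
data (tens of millions of prescriptions; presets target shapes and
orderings, not magnitudes), seasonal/pandemic trends in prescribing,
referral structure between hospitals, and per-drug dose marginals beyond
the violation rates (no published marginals exist to calibrate against).
Passing tests therefore show that the *method* recovers planted structure
of the kinds listed, not that real networks have any particular metric
value. One known calibration gap: the zolpidem preset's flagged-count SD
(≈ 4) is lighter-tailed than the published per-patient SD for that drug
(8.3); pushing the tail heavier destroys the high degree/weighted-degree
overlap that the same analysis reports, and the overlap ordering is the
screening-relevant property, so the preset favours it.

## Numerical and degenerate-input choices

* Ratios in usage tables round half-up to 2 decimals (4.7178 → 4.72);
  base `round()` would apply banker's rounding.
* Records failing validation are collected with row numbers, not thrown;
  records outside the study window (default 2019-07-01 to 2021-06-30) are
  dropped with a count.
* Hospitals missing from the attribute sidecar stratify as `UNKNOWN`
  rather than being dropped — stratification is a reporting layer, not a
  filter.
* Degree-0 hospitals are excluded from NSI with a warning (they cannot
  occur for networked hospitals).
* Empty networks error in `communities_louvain()` and
  `path_statistics()`; a network with no connected pair errors rather
  than reporting a vacuous diameter.
* The pipeline (`run_pipeline()`) is byte-identical under a fixed config
  and seed; the summary JSON embeds a config hash and the seed.

## Problem sizes used by the test-suite and acceptance script

Oracle comparisons run on small instances where exhaustive computation is
exact: ≤ 12×12 incidence matrices against pairwise intersection counts,
≤ 8-node graphs against full path enumeration (betweenness), dense
eigendecomposition (eigenvector), and complete set-partition enumeration
(modularity optimum, Bell(8) = 4,140 partitions). The stochastic
cross-drug ordering checks use 2,000 patients and 500 hospitals with
medians over 20 seeds in the tests and 10 replicate seeds in the
acceptance script — sizes at which the orderings are stable from seed to
seed while a full run stays in the tens of seconds.

## Limitations

* Exceedance flags are screening signals only; the package deliberately
  offers no clinical or legal judgment.
* Betweenness/eigenvector conventions differ across network tools
  (normalization, weight handling, component treatment); values from
  other toolchains are comparable only after matching conventions.
* The one-mode projection discards which *patient* links two hospitals;
  patient-level follow-up needs the two-mode network.
* Louvain is a heuristic; only on the small enumeration fixtures is its
  optimum certified.
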