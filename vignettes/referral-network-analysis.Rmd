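---
title: "Methods: patient-sharing referral networks from claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-sharing referral networks from claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambnet)
```

## The model

`ambnet` treats an ambulatory care system as a directed, weighted
patient-sharing graph. The unit of observation is the office visit: a
`(patient, physician, date)` triple from administrative claims. Two modelling
rules turn visits into a network:

* **Referral rule.** Patient `p` visiting physician `v_i` and later a
  *different* physician `v_j` with an inter-visit gap inside the inclusive
  window `[7, 45]` days induces one directed referral event `v_i -> v_j`.
  The window bounds are the central tunable of the whole analysis: below 7
  days two visits usually reflect parallel care-seeking for the same
  complaint rather than a hand-off, and beyond 45 days the connection to the
  index problem fades. Every qualifying *ordered pair* of visits counts, not
  only consecutive ones — the literal reading of the rule, and the one that
  is invariant to how rows happen to be ordered; `consecutive_only = TRUE`
  gives the stricter alternative, and `unique_patients = TRUE` collapses
  repeat events of one patient on the same physician pair.
* **Follow-up rule.** A same-patient, same-physician ordered visit pair in
  the same window counts as one follow-up consultation, the longitudinality
  measure. The window is taken symmetric with the referral window by design
  (nothing in the data dictates a different one); it is configurable.

Weights attach to both levels. The vertex weight is the physician's share of
all consultations,
$Vw(v_i) = \dfrac{c(v_i)}{\sum_k c(v_k)},$
which factors as (share within specialty) × (specialty share of the system) —
both forms are implemented and agree to machine precision, a useful internal
identity check. The edge weight normalizes flow by the sender's panel:
$Ew(v_i \to v_j) = \dfrac{\#\{v_i \to v_j \text{ events}\}}{\#\{\text{distinct
patients seen by } v_i\}}.$
The denominator counts *patients*, not consultations: a high-volume physician
does not get small edge weights merely for being busy.

A physician with consultation volume strictly below
`productivity_factor` (default 0.2) times the specialty's expected volume
(specialty consultations over specialty roster headcount, zero-visit
physicians included) is flagged *low-productivity*. Such physicians stay in
the graph — their edges are real flow — but are excluded from the
physician-level Z-scores, profiling and association analyses, where they
would otherwise dominate the low tail of every count measure. Physicians with
no referral in either direction are excluded from the graph entirely; when a
physician is both, it is counted as isolated (that exclusion applies first).

## Measures and their conventions

Graph measures delegate to igraph; the package fixes the conventions that
matter for reproducibility:

* **Weighted distances** use `Ew` directly as edge length. This mirrors the
  common practice of passing weights as-is to shortest-path routines, and is
  therefore the comparable convention; `weighted_distance = "inverse_weight"`
  provides the semantically-stronger-tie-is-shorter alternative (1/Ew).
  Neither is "correct" — the choice is declared, not hidden.
* **Closeness** (in/out) is computed over reachable vertices only, normalized
  by the reachable count — the modern default for directed graphs that are
  not strongly connected. Vertices that reach nothing get `NA` and are
  mean-imputed (and flagged) before clustering.
* **Eccentricity** is unweighted, on out-reachability, ignoring unreachable
  vertices; the radius is the minimum over vertices with positive out-degree.
  This makes eccentricity a coarse integer measure, which is why its Z-scores
  typically take only a few distinct values.
* **Betweenness** counts directed ordered pairs (Brandes). The test-suite
  oracles are written against this convention and would fail under any other.
* **PageRank** uses damping 0.85 on `Ew`. **Hub/authority scores** are the
  principal singular directions of the weighted adjacency, rescaled to
  maximum 1. **Subgraph centrality** is the diagonal of the matrix
  exponential of the *undirected, unweighted* projection; **diversity** is
  the Shannon entropy of a vertex's combined incident weights over
  `log(degree)` (`NA` at degree 0, 0 at degree 1); both are undirected
  measures by construction. Local clustering uses transitivity (0 below
  degree 2, so Z-scoring stays defined) and Barrat's formulation for the
  weighted variant.
* **Z-scores** use the sample SD over the *included* (post-exclusion) set
  only. Constant columns become zeros with a warning rather than NaNs.
* The iterative eigensolvers draw random start vectors; `vertex_measures()`
  pins a local RNG seed so repeated runs agree bit for bit.

## Profiling

Vertex measures group into three constructs: *patient follow-up* (referrals
made, referrals received, follow-ups; degrees reported descriptively),
*relationship with authorities* (authority and hub scores), and *centrality*
(weighted closeness in/out, eccentricity, PageRank; subgraph centrality and
betweenness descriptive). Nearly collinear candidates are pruned by a greedy
rule — repeatedly take the pair with the largest |Pearson r| above the
threshold (default 0.8) and drop the member with the larger mean absolute
correlation to everything else — and the retained set is reported; the
clustered defaults above are the post-pruning choice.

K-means runs on **raw, untransformed values**. That is a deliberate,
documented choice: it keeps cluster centroids in interpretable units, at the
price that the largest-scale variable dominates the objective —
`standardize_inputs = TRUE` exists for sensitivity analysis. The cluster
count is chosen by maximum mean silhouette width over `k in [2, 10]` (ties to
the smaller k), with the within-cluster sum-of-squares curve reported for
inspection and a `fixed_k` override for forcing a known k. 25 random restarts
under a fixed seed make the fit deterministic.

Labels are assigned from centroids *expressed in Z units*:

* *Centrality*: composite = mean z of (PageRank, subgraph centrality,
  betweenness, closeness-in) minus mean z of (eccentricity, closeness-out);
  highest composite is `central`, lowest `peripheral`, the rest
  `intermediate`. Exact ties break deterministically toward keeping the
  larger cluster `intermediate`, with a warning.
* *Authorities*: hub z ≥ +1 → `seeks_authorities`; else authority z ≥ +0.1 →
  `is_authority`; else `balanced`.
* *Follow-up*: intensity from the follow-up z (≥ +1 strong, ≤ −0.5 weak,
  else moderate); sharing is `prevalent` when both referral z-scores are
  ≤ −0.8, else `shared`.

These thresholds are package defaults chosen so that the labeling reproduces,
from the printed centroid table of a published large-scale analysis
(`example_centroid_table()`), all twelve of its cluster labels — the
package's golden test for the rules.

## Communities

Community detection uses the two-level map equation (Infomap) on the directed
graph with `Ew` as flow weights and `Vw` as vertex weights, 10 optimization
trials under a fixed seed. A flat two-level partition matches the intended
reporting (one community per physician). The returned partition carries its
codelength and the directed weighted Newman modularity
$Q = \frac{1}{W}\sum_{ij \in \text{same}} \left[ w_{ij} -
\frac{s^{out}_i s^{in}_j}{W} \right],$
chosen as the default of the four directed/weighted variants because it uses
exactly the information the detection used. The package also evaluates the
two-level map-equation codelength of *any* partition
(`map_equation_codelength()`, smart-teleportation visit rates at
teleportation 0.15), which lets tests verify that a detected partition never
describes the random walk worse than the all-in-one module. Communities
dominated by low-productivity physicians (> 50 % of members) are detected but
filtered from reporting, since detection runs on the full network.

## Association statistics

Contingency tables use the chi-square statistic without continuity
correction and per-cell adjusted standardized residuals
$r_{ij} = \frac{O_{ij} - E_{ij}}{\sqrt{E_{ij}\,(1 - n_{i\cdot}/N)(1 -
n_{\cdot j}/N)}},$
approximately standard normal under independence. Cells are marked with
two-sided tiers (`p<0.001`, `p<0.01`, `p<0.05`, `p<0.1`) from the normal
quantiles of the residual itself — the tier apparatus describes cells, the
omnibus test describes the table. Tiers are unadjusted by default; Bonferroni
control (`bonferroni()`) is applied across families of omnibus tests, not
within a table's cells. Group comparisons delegate to `kruskal.test`,
`wilcox.test` (exact enumeration below group size 20 without ties, normal
approximation with tie correction otherwise) and `t.test`.

## The synthetic generator

`simulate_claims()` emulates the features of claims data that the pipeline
must resolve, at desk scale (defaults: 50 physicians in 5 specialties, 2,000
patients, roughly 10,000–20,000 visits; minutes, not hours):

* **Archetypes** (`specialty_archetype()`): per-specialty physician counts,
  relative volumes, follow-up and referral propensities, an authority share
  (top physicians of a specialty attract referrals with a ×5 multiplier),
  a baseline referral-target attractiveness, and a mean patient comorbidity.
  The default mix spans the behavioural space: longitudinal low-sharing
  pediatricians, authority-rich internists/cardiologists, hub-like family
  physicians, peripheral surgeons.
* **Territory**: physicians are partitioned into `n_communities` blocks
  (specialties spread round-robin so every block is clinically complete);
  each patient has a home block, and index/referral choices leave it only
  with probability `inter_community_leak` — the observed cross-block event
  fraction is Bernoulli(`leak`) by construction, which a binomial oracle
  test verifies.
* **Care paths**: each patient holds a usual (primary) physician and
  produces episodes — an index visit, then follow-up visits (same physician)
  and referral visits (different physician, never one already seen in the
  episode) at gaps uniform on `[7, 45]`, with a 10 % noise fraction at gaps
  in `[1, 6] ∪ [46, 120]` to exercise the window filter. Episodes are
  scheduled sequentially with inter-episode gaps beyond the referral window;
  otherwise the all-pairs rule would bridge unrelated episodes and drown the
  planted structure (the realized episode count is therefore capped by the
  study span). Loyalty to the primary physician follows that physician's
  follow-up propensity, mimicking how patients of longitudinal physicians
  re-enter care through them.
* **Comorbidity**: negative-binomial (size 2) with patient-level mean tied
  to the archetypes of the physicians actually visited.

What the generator does **not** emulate: calendar seasonality, true
geography, fee/financial structure, diagnosis codes, and any correlation
between referral behaviour and patient outcomes. Recovery tests passing on
synthetic data therefore certify the *pipeline* — that planted communities,
archetypes and gradients are recovered when present — not that real claims
contain such clean structure.

## Numerical and degenerate-input choices

Dates are day-resolution; gaps are integer day differences; same-day visits
to two physicians have gap 0 and are never referrals. Duplicate claim rows
are kept by default (a config switch collapses them). Zero-margin rows or
columns of a contingency table are dropped with a warning; all-identical
values make a t-test fail loudly rather than return nonsense. K-means
restarts (25) with `iter.max = 50` under a fixed seed; silhouette ties break
toward smaller k; missing metric cells are mean-imputed and flagged. PageRank
runs at igraph's default tolerance; the package's determinism tests require
bit-identical repeat runs, which the pinned eigensolver seeds guarantee.

## Problem sizes

The test suite runs the full pipeline on the default 50-physician /
2,000-patient cohort, exhaustive brute-force oracle comparisons on hundreds
of ≤ 6-vertex digraphs, and 1,000-replicate calibration simulations; the
whole suite completes in well under a minute on a single core, and the
acceptance script in a few seconds. These sizes were chosen so the planted
effects are far from the noise floor (e.g. thousands of referral events
against a 3-standard-error binomial band) while keeping iteration fast.

## Known limitations

Window-based co-visitation is not a verified referral: some edges are
coincidences of independent care-seeking, which is precisely why the window
is bounded and configurable. The raw-scale K-means convention makes the
follow-up dimension effectively volume-driven when counts dominate; the
standardized alternative is one flag away. The map-equation codelength
evaluator uses smart teleportation and can differ in absolute value from the
optimizer's internal objective (comparisons between partitions under the
*same* evaluator remain valid). And with data-driven k, semantic labels
depend on cluster granularity: forcing the published k values via `fixed_k`
is the right mode when comparing against a fixed external table.
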