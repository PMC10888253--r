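---
title: "Automated gating and classification for the 3-tube ALPS panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated gating and classification for the 3-tube ALPS panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytogate)
```

# The problem

Clinical screening for primary immunodeficiencies leans on a 10-color,
3-tube flow-cytometry panel: an ALPS-T tube (CD3, CD4, CD8, CD19, CD25,
CD45, CD127, TCRαβ, TCRγδ) for T-cell subsets and the diagnostic
TCRαβ+ CD4−CD8− double-negative T cells (DNT), an ACT-T tube (CD45RA,
CD45RO, CD69, PD1, HLA-DR plus the T-cell backbone) for naive/memory and
activation status, and an ALPS-B tube (CD19, CD27, IgD, kappa, lambda,
CD5, CD56) for B-cell maturation and NK cells.  Manual gating of these
tubes is slow and operator-dependent; `cytogate` automates the full
chain — file integrity and acquisition QC, doublet and debris exclusion,
clustering, cluster classification, subset enumeration and rule-based
flagging — deterministically, so identical inputs always produce
byte-identical reports.

The flagging layer encodes the screening rules a reviewer applies:
TCRαβ+ DNT above 1.5% of lymphocytes **or** 2.5% of CD3+ T cells
(the ALPS criterion), decreased CD45RA+ T cells (reference 30–60% of T)
with reciprocally increased CD45RO+ and decreased switched memory B cells
(<5% of B) as a DiGeorge-compatible pattern, and near-absent B cells
(≤0.1% of lymphocytes) as an XLA-compatible pattern.  Outputs are
pattern codes with quantitative rationales, never diagnoses.

# The pipeline and its assumptions

## Scale

Fluorescence is analysed on `asinh(x/150)`; scatter and time stay
linear.  The cofactor is conventional for this instrument class and is
configurable (`cg_transform`).  All densities, medians, discretizations
and classifier features live on this scale, so a gain change maps to an
additive shift.

## Acquisition-time QC

Events are divided into 50 equal-count time bins.  A bin is dropped when
its duration (inverse acquisition rate) or any channel's *mean* level
deviates from the cross-bin median by more than 5 robust (MAD) deviations.
Means, not medians, are compared: the median of a channel whose positive
fraction is near 50% flaps between modes under per-bin composition noise
(we observed ~40% false bin drops with medians on stationary synthetic
data), whereas the bin mean has √n sampling noise and still moves by
~log(gain) under a gain shift.  The acquisition floor
(`min_events_required`, default 100,000) is reported as a flag, not
enforced, so small research files still analyse.

## Doublets and debris

The singlet ridge is fit by iteratively reweighted least squares with
bisquare weights (FSC-H ~ FSC-A); an event is a doublet when its area
exceeds the ridge prediction by more than 25%.  The rule is invariant to
common rescaling of both axes.  Debris is removed below a joint
FSC-A/SSC-A cut placed at the density valley between the low-scatter mode
and the leukocyte modes (fallback: the 2% quantile floor when no
low-scatter mode exists); only events low on *both* axes are dropped.

## Five-level discretization

Each channel's transformed intensities are partitioned into
negative / dim / partial / positive / bright.  The negative mode `mu0` is
the lowest-intensity major density mode (peaks ≥5% of the tallest); its
spread is the reflected MAD of values at or below it; the negative/dim
boundary is `mu0 + 2·sigma0`, and the span up to the 99.9th percentile is
split into four equal-width bands.  Two consequences worth knowing:

* the geometry is **anchored at the negative mode** — a channel in which
  every population is positive (CD45 in this panel) collapses toward
  negative/dim codes.  Codes are only ever compared within a tube, so
  this costs nothing, but absolute level names on such channels should
  not be over-read;
* a population whose median sits almost exactly on a band boundary can
  discretize to either side; over-seeded fragments of such a population
  may then resist merging and reach the classifier as two clusters.  The
  classifier and the rule layer are indifferent to this (labels and
  predicates use `>=`/`<=` bounds), but cluster counts are not a stable
  statistic near boundaries.

## Density–phenotype clustering

Seed clusters are found by kNN mode seeking on all fluorescence markers
plus FSC-A and SSC-A concurrently (k = ⌈√n⌉ capped at 100).  Density is
the inverse mean distance to the k nearest neighbours; every event links
to its nearest higher-density neighbour within its k-neighbourhood, ties
broken by event index so the procedure is deterministic.

Distances deliberately use the **shared asinh scale** rather than
per-channel median/MAD standardization.  Robust standardization inverts
the signal geometry here: channels that separate populations are mixtures
with inflated MADs (compressing real separation), while everywhere-negative
channels have noise-sized MADs (inflating pure noise to a full unit per
dimension).  In our measurements that inversion made a 1%-abundance DNT
population indistinguishable from CD4 T cells.  Scatter channels are
rescaled to a comparable unit (95th percentile / 6).

kNN density estimates fluctuate (~1/√k), so a single population throws
off spurious local peaks.  A peak candidate is therefore re-linked to its
nearest higher-density point anywhere when *both* halves of the
population-separation criterion fail: the fine-grained density profile
along the straight segment between them never dips below `root_rho`
(default 0.5) of the candidate's density — no valley — *and* the two
events carry identical five-level codes on every marker.  Phenotype
identity is what makes this robust across dimensionalities: pure
continuity thresholds overlap between regimes (a weakly separated
NK-vs-monocyte pair and 3-d estimator noise produce similar valley
depths), while a phenotype-distinct mode is never absorbed regardless of
valley depth, however small its population.  One consequence: exact
duplication of a dataset preserves the merged cluster structure but not
necessarily the raw seed count, because the fine-density floor does not
scale under duplication.

Seed clusters merge bottom-up under the same two-criterion rule: a pair
must share its phenotype code on **all** markers and the kNN-graph saddle
density between them must exceed `rho_merge` (default 0.5) of the smaller
peak.  Codes are recomputed after every merge; the pair with the highest
saddle-to-peak ratio merges first; merging is monotone in `rho_merge`.
Clusters smaller than `max(25, 0.1% of events)` dissolve into the nearest
retained centroid.  Samples beyond 50,000 events are clustered on a
fixed-seed uniform subsample with the remainder assigned to the nearest
centroid, keeping desk-scale runtime.

## Cluster classification and refinement

The classifier operates on clusters, not events.  Features are keyed by
normalized marker name (lexicographically ordered medians and ordinal
codes, the cluster's event fraction, and scatter medians normalized by
the sample's 95th percentiles), which is what lets one model transfer
across reagent or fluorochrome changes and channel permutations.  The
forest is 200 bagged CART trees (Gini, √p features per split) with
out-of-bag accuracy recorded; it is authored in-package because no tree
ensemble package is assumed at runtime, and it reproduces bit-identically
from (store, seed).  Clusters whose top vote falls below 0.7 are flagged
`low_confidence` for manual review.  Training is append-and-retrain from
an append-only store of labeled cluster features — the reproducible
counterpart of incremental training from manually gated cases.

The forest assigns *lineages* (T/B/NK/non-T lymphocytes/monocytes);
diagnostic subsets are then resolved by auditable marker-level predicates
on cluster codes (e.g. DNT = CD4 ≤ dim & CD8 ≤ dim within T; TCRαβ+ DNT
adds TCRαβ ≥ positive; switched memory B = CD27 ≥ positive & IgD ≤ dim
within B).  Within a parent, primary children are evaluated in taxonomy
order and the first match wins, so every event has exactly one deepest
label and subset counts roll up exactly.  Subsets whose marker axis
crosses the primary partition (kappa/lambda light chains, CD45RA/RO) are
*secondary*: counted and reported, but outside the partition.

Two-tier design rationale: the cluster-level forest matches the workflow
being reconstructed and is fast; putting the diagnostic subsets in
explicit rules keeps the clinically decisive quantities (DNT, memory B)
auditable rather than buried in tree ensembles.

## Reporting

Each tube's subset table carries counts, percent-of-parent and
percent-of-lymphocytes, with the tube's own lymphocyte count as
denominator (the panel gives no cross-tube event bridge; cross-tube logic
lives only in the interpretation layer).  The ALPS flag applies strict
`>` at both thresholds; the XLA rule requires B cells ≤0.1% in every
tube carrying a B node; the DiGeorge rule is the conjunction of the
CD45RA-low, CD45RO-high and switched-memory-low flags.  The "viability"
entry is a scatter-based survival proxy (fraction of time-QC-passing
events surviving doublet/debris removal): this panel carries no viability
dye, and the report labels it accordingly.  Reports serialize to
canonical JSON — fixed key order, full numeric precision — and round-trip
byte-identically.

# The simulator: what it emulates, what it does not

`make_case()` draws per-event populations from scenario abundances, then
marker intensities from Gaussians on the transformed scale whose means
sit on the same five-level geometry the discretizer recovers (level means
0.2 / 1.8 / 3.2 / 4.6 / 6.2, spreads 0.25–0.40), inverted to raw FCS
intensities and clipped to [0, 2^20].  Scatter comes from
lymphocyte/monocyte/granulocyte modes with FSC-H = 0.95·FSC-A + noise.
Artifact injectors append doublets (channel-wise sums of two singlets
with FSC-H the pair maximum + 5% noise), debris (exponential low scatter,
near-zero fluorescence) and gain drift (one channel multiplied within a
contiguous time window), each tagging the events they touch, so every
pre-gating stage is scored against exact ground truth.

Default conditions: 20,000 events per tube, 2% doublets, 2% debris, no
drift.  Scenario worlds: `ALPS` sets TCRαβ+ DNT to 30% of T events (the
hallmark worked presentation); `DIGEORGE` sets CD45RA+ T to 8% of T and
switched memory B to 1.5% of B; `XLA` reduces B to 0.03% of events.
Batch variation multiplies template abundances by independent
Gamma(5, 5) factors and renormalizes — a symmetric Dirichlet-style jitter
about the scenario means (CV ≈ 45%), chosen so each subset has enough
between-case spread for correlations to be meaningful.

What the simulator does **not** emulate: instrument-specific detector
noise, spectral spillover (compensation is exercised separately on
synthetic matrices), autofluorescence and stain-index variation between
reagent lots, rare aberrant phenotypes, and populations genuinely
intermediate between templates.  A green parameter-recovery run
establishes that the pipeline recovers the statistical structure it
assumes — cleanly separated log-scale populations with known artifacts —
not that it matches expert gating on clinical samples.

# Validation

`parameter_recovery()` is the end-to-end experiment: per-tube forests
trained on one synthetic labeled batch (60 cases), then 60 independent
jittered cases written to FCS, read back, and pushed through the full
pipeline; per-subset Pearson correlations between estimated and true
percent-of-lymphocytes are computed across the batch, and the headline
number is the minimum r over T, B, NK, CD4 T, CD8 T and TCRαβ+ DNT,
with r ≥ 0.9 the pass bar.  `scripts/acceptance.R` reruns exactly this.

```{r, eval = FALSE}
pr <- parameter_recovery(n_train = 60, n_cases = 60,
                         n_events = 20000, seed = 1)
pr$concordance
pr$min_r
```

# Numerical choices and degenerate inputs

* Ties everywhere (density links, merge candidates, forest votes) break
  by index or label order; no stage draws random numbers at analysis
  time, so analysis is deterministic without a seed.
* A constant or dynamic-range-free channel collapses to all-negative
  with a warning rather than failing; degenerate scatter (zero variance)
  during the doublet fit is an error.
* Fewer than 500 surviving events reject the sample; fewer than 2·k
  events fall back to a single cluster.
* The empty-subset convention: a taxonomy node appears with a zero count
  while its parent is populated; children of an empty node are omitted.
  The ALPS evaluation treats an absent DNT row under a populated T-cell
  parent as zero and errors only when the T or lymphocyte rows are
  structurally missing.

# Known limitations

* NK cells in the ALPS-T tube are identified negatively (CD3−CD19−
  lymphocytes) because the tube carries no NK marker; the ALPS-B tube
  (CD56) is the canonical source for NK percentages.
* Reference ranges other than CD45RA+ T (30–60% of T) and switched
  memory B (>5% of B) ship as illustrative defaults and must be replaced
  with laboratory-validated ranges for any real use.
* The level geometry is anchored at the negative mode; channels without
  a negative population yield compressed codes (see above).
* Populations sitting exactly on a band boundary can split across two
  clusters; counts and percentages are unaffected, cluster counts are.
* The QC level test targets abrupt windowed shifts; slow monotone drift
  within the MAD envelope passes.
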