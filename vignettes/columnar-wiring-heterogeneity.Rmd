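---
title: "Quantifying heterogeneity of columnar synaptic wiring"
author: "colwire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heterogeneity of columnar synaptic wiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colwire)
```

## The problem

Columnar neurons of the fly optic lobe — Tm9, Tm1, Tm2 and their relatives —
repeat once per retinotopic column, several hundred times per optic lobe.
The textbook view treats every copy of such a cell type as identically wired.
Connectome reconstructions let that assumption be tested directly: given a
table of automatically detected synapses (one row per detection, with a
presynaptic segment id, a postsynaptic target cell, a 3D position and a
detection-confidence "cleft score") and a table of cell-type annotations, how
variable are the presynaptic inputs of a cell type from column to column, and
is there structure — motifs, subtypes, spatial organization — in that
variability?

`colwire` implements this analysis as a pipeline of small, testable stages,
together with genetically-labeled-synapse counting for light microscopy and
calcium-trace clustering, the two companion assays used to confirm wiring
and functional heterogeneity in independent animals. A synthetic-data module
generates all three kinds of input with known ground truth, so the whole
pipeline is validated end to end without any external data.

## Synapse filtering and connectivity matrices

The filtering stages run in a fixed order, each idempotent:

1. **Cleft-score filter** (`filter_cleft_score`, default ≥ 50, inclusive):
   discards low-confidence automatic detections.
2. **Redundancy removal** (`deduplicate_synapses`, default < 100 nm): the
   same synapse is sometimes detected twice at nearly the same position.
   Within each (presynaptic segment, postsynaptic cell) pair, detections
   closer than the radius are collapsed greedily in descending cleft score,
   ties broken by input order. Keeping the most confident detection is our
   choice (the convention only says redundant detections are removed); it is
   deterministic and idempotent, and a brute-force all-pairs oracle in the
   test suite confirms the greedy result exactly on small tables. Pairs at
   exactly the radius are kept ("less than" is strict).
3. **Aggregation** (`aggregate_counts`): synapses are counted per input
   *cell* (segment). Segments with no annotation are mapped to `UNKNOWN`,
   never dropped.
4. **Partner threshold** (`apply_partner_threshold`): input cells making
   fewer than 3 synapses (4 for Tm1/Tm2-style analyses) are zeroed — below
   that, fragments cannot be traced and identified reliably. The threshold
   acts per cell, before any aggregation to types.
5. **Matrix construction** (`build_connectivity_matrix`): target cells ×
   input types, in `absolute` counts, `relative` fractions or `binary`
   presence. Relative rows divide by the row's *full* post-threshold synapse
   total including `UNKNOWN`, so removing rare or unidentifiable types never
   inflates the remaining fractions; row sums are therefore ≤ 1.
6. **Presence filter** (`filter_by_presence`, default ≥ 5% of columns):
   drops types too rare to analyze. The boundary is inclusive (a type in
   exactly 5% of columns is kept); the field's usage varies between "at
   least" and "more than" 5%, and we fix the inclusive reading.

Two bookkeeping identities hold by construction and are asserted in the
tests: the absolute matrix plus the `UNKNOWN` and sub-threshold buckets
reproduces the post-deduplication synapse totals exactly (conservation), and
on synthetic data the post-filter matrix equals the generator's planted
counts cell for cell.

## Heterogeneity statistics

- **Cosine similarity** (`cosine_similarity_groups`): for every unordered
  pair of target cells within a group, cos(u, v) = u·v/(‖u‖‖v‖) of their
  input profiles. Cosine is scale-invariant per row, so absolute and
  relative matrices give identical values; profiles are non-negative, so
  values lie in [0, 1]. The "mixed" group pairs every row of one hemisphere
  with every row of the other — the simplest construction for an
  across-hemisphere comparison set. Group differences are tested with a
  two-sided Kruskal–Wallis test followed by Dunn's pairwise z tests with
  Bonferroni correction (implemented from the mean-rank formula with tie
  correction; no packaged Dunn test is used). Note the pairwise similarity
  values within a group share rows and are not independent; with hundreds of
  columns the tests are therefore anticonservative and should be read as
  descriptive, which is how the field uses them.
- **Variation** (`input_variation`): per-type mean, standard deviation and
  coefficient of variation across columns. Population (÷n) std is the
  default, sample (÷(n−1)) switchable; c.v. is undefined (NA) for a type
  with zero mean.
- **Rank order** (`rank_order`): within each column, inputs are ranked by
  count (1 = strongest), ties sharing the minimum rank ("1-1-3"
  competition ranking); absent inputs are unranked. The per-type rank range
  across columns is the readout showing that input order itself varies.

## Motif discovery

- **Input–input correlations** (`input_correlation`): Pearson r between
  type counts across columns, two-sided p from t = r√(n−2)/√(1−r²),
  Bonferroni-corrected over the unique pairs.
- **Subtypes** (`kmeans_inputs`): Euclidean k-means on count profiles
  (k = 2 exposes the two GABAergic-input-dominated subtypes when CT1 and
  Mi4 counts trade off; k = 6 for finer structure). Ten seed-derived
  restarts; deterministic given the seed.
- **PCA** (`pca_project`): types standardized to mean 0/variance 1,
  eigenvectors of the covariance matrix, scores on the top two components.
  Sign convention: the largest-magnitude loading in each component is made
  positive, so antagonistic inputs show as opposite-sign loadings.
  Zero-variance types are dropped with a warning before standardization.
- **Presence motifs** (`binarize_presence` + `hamming_cluster`): the
  always-present core inputs are removed, the rest binarized, and columns
  clustered by pairwise Hamming distance (bit differences) with an
  agglomerative tree. The tree is cut at every candidate cluster number
  (default 4–15) and the cut maximizing the mean silhouette coefficient —
  computed on the same Hamming distances — is chosen, ties to the smallest
  k. **Linkage choice**: the linkage criterion is genuinely open in this
  analysis tradition. We default to *complete* linkage: on planted-partition
  profiles at the scale of a two-hemisphere dataset (320 rows, 4 equal
  motifs, 5% bit noise) complete and Ward linkage recover the planted
  cluster number on 20/20 fixed seeds, whereas average linkage lets the
  silhouette curve drift to k+1 on about 1 seed in 20 by splitting off a
  handful of noisy rows. Average linkage remains available via the
  `linkage` argument. `summarize_motifs` then reports per-cluster presence
  fractions and flags types ≥ 90% present or ≤ 10% present as dominating a
  motif.

## Spatial mapping

Each analyzed column receives the position of the synapse nearest the
centroid of the target cell's dendritic-compartment synapses — an actual
presynaptic site, robust to asymmetric dendrite shapes. "Dendritic" is an
input flag: the compartment assignment is anatomical and cannot be derived
from the synapse table alone, so real data must supply it and the generator
plants it (axon-terminal inputs such as CT1 are flagged `axonal` and are
excluded from the centroid).

The dorsoventral split projects each hemisphere's coordinates onto their
top-2 SVD plane and draws the midline through the 2D centroid along the
first principal axis. The midline's direction convention is not fixed by
the procedure itself, so orientation is anchored by a user-supplied dorsal
reference point; with the reference given, labels are invariant to global
rotation and translation of the coordinates. Collinear inputs are an error
(no plane is defined).

`presence_map` joins presence and cell multiplicity with the coordinates,
optionally summarizing a polygonal patch (e.g. a densely analyzed region)
by its presence fraction. `join_count_test` quantifies the usual "no
apparent spatial structure" claim: the statistic is the number of
nearest-neighbor column pairs sharing a presence label, compared against a
label-permutation null (default 999 permutations, seeded). This test is an
addition of this package — the visual claim it formalizes is standard, the
permutation test is not part of the usual pipeline.

## Expansion-microscopy apposition counting

For genetically labeled samples, presynaptic puncta (e.g. Brp-short) are
detected as 26-neighborhood local intensity maxima above a threshold
(default: global Otsu; in practice thresholds are often set per sample, so
the value used is always recorded), then thinned so no two puncta are
closer than 200 nm — the separation at which nearby active-zone signals
become unresolvable in light microscopy — keeping the brighter punctum.
The dendrite channel is binarized and each punctum's exact minimum
Euclidean distance to a mask voxel is computed with anisotropic voxel
spacing honoured in nanometres. Puncta within 300 nm (inclusive) of the
mask count as synapses and are assigned to the column ROI containing their
center voxel; apposed puncta outside every ROI are kept in an `unassigned`
bucket so totals are conserved. All distances are image-space
(post-expansion) nanometres; the expansion factor is metadata for
converting to biological scale. The per-ROI counts feed a
percent-of-columns histogram of connection numbers, the standard readout
for comparing light-microscopy counts across animals with connectome
counts.

The distance computation is an exact scan over mask voxels rather than an
approximate distance transform; the test suite checks it against an
independent double-loop oracle, and shrinking the apposition threshold is
verified never to increase any ROI's count.

## Calcium-trace normalization and clustering

`delta_f_over_f` implements the mean-augmented normalization
ΔF/F₀ = (F − F₀)/(F₀ + F_mean): F₀ is the mean fluorescence during the
background-stimulus epochs, and adding the full-trace mean to the
denominator damps blow-ups for ROIs with near-zero baseline. Optional
high-pass filtering subtracts a 150-frame running-median baseline — the
customary "cutoff period" is quoted in frames, and a running median is a
robust moving-baseline estimator consistent with that frame count; the
window is configurable and the filter can be disabled. Trials are averaged
before anything else downstream, and traces are linearly interpolated to a
common 10 Hz so recordings at different frame rates can be pooled.

`zscore_traces` normalizes each trace to mean 0 and (population) standard
deviation 1, discarding amplitude so clustering sees only the time course.
`cluster_traces` then runs k-means under the correlation distance
d = 1 − corr: on z-scored traces, squared Euclidean distance is
proportional to correlation distance (‖u−v‖² = 2T(1−corr)), so standard
k-means optimizes the right objective. We use 50 restarts: this objective
has shallow local optima on realistic trace sets, and at 10 restarts about
a third of fixtures converged to a merged-cluster optimum even though a
nearest-template assignment separates them perfectly. The conventional
cluster number for this readout is 6.

## The synthetic-data module

`simulate_connectome` generates the full input to the pipeline with ground
truth. What it emulates, and the default study conditions (`"tm9"` preset):

- 170 + 150 columns in two mirrored hemispheres on a hex lattice
  (5 µm pitch), the lattice patch wider than tall as the medulla sheet is;
  per-hemisphere dorsoventral labels derive from the lattice.
- Three core inputs present in every column with per-column counts
  25 ± 7.3 (L3), 13.3 ± 7.0 (Mi4) and 15.0 ± 5.7 (CT1); CT1-like inputs
  synapse on the axon terminal (planted `axonal` compartment).
- Seventeen variable input types with presence probabilities 0.1–0.6 and
  per-cell counts around 3.5–4, so each contributes roughly 5–10% of a
  column's synapses; wide-field types (Tm16-, Dm12-like) connect with 1–4
  cells per column. Presence probabilities sum to ≈ 4.65, putting the
  realized per-column statistics near 78 synapses, 8.5 cells and 7.4 types
  from ~20 types overall.
- Counts are drawn from a discretized normal truncated below at the partner
  threshold (default 3). The count noise model is not constrained by the
  moments alone; a truncated normal matches the reported mean ± sd
  directly and guarantees every planted cell survives the cell-level
  threshold, which is what makes the planted-count ground truth exactly
  recoverable. For types whose sd is large relative to the mean
  (Mi4-like), truncation raises the realized mean by up to ~1 synapse
  above the nominal value — a deliberate trade for exact bookkeeping.
- Sub-threshold partner cells (default 18 per column, 1–2 synapses each)
  emulate the untraceable fragment floor, so above-threshold cells account
  for roughly three quarters of a column's synapses, as in
  backbone-proofread reconstructions. 3.3% of planted cells are left
  unannotated (`UNKNOWN`).
- Detection artifacts: 5% of synapses are re-emitted as near-duplicates
  (< 100 nm from their source, strictly lower cleft score) and 5% as
  low-confidence decoys (cleft score < 50). Genuine same-connection
  synapses are rejection-sampled to ≥ 100 nm separation, so
  deduplication removes exactly the injected duplicates — the filter's
  correctness can therefore be asserted with equality, not tolerance.
- Hemispheres are generated independently (mirrored lattices): columnar
  wiring statistics are not expected to differ between sides, and the
  generator builds none in.

What it does **not** emulate: cross-column identity of wide-field cells
(each planted cell lives in one column, whereas a real CT1 spans the whole
medulla), correlations between input types (types are independent by
default — planted Mi4/CT1 antagonism or presence motifs are constructed by
combining configs or with `simulate_motif_profiles`), realistic neurite
geometry, and any developmental gradient. Passing tests on this generator
therefore validate the *computations*, not biological claims about real
connectomes.

`simulate_puncta_volume` renders Gaussian puncta (σ = 120 nm) and vertical
dendrite tubes on an anisotropic voxel grid, with puncta snapped to voxel
centers so noise-free detection recovers them exactly, and tags every
punctum with its containing ROI and exact voxelized distance to the mask.
`simulate_trace_set` builds raw fluorescence as baseline + amplitude ×
template + noise over repeated trials, using six qualitatively distinct
response templates to a 2 s OFF / 2 s ON flash (sustained, transient,
slow, ON, biphasic, inhibited) with per-ROI amplitudes truncated at
positive gain.

## Numerical choices and degenerate inputs

- Tie-breaks are deterministic everywhere: dedup and puncta thinning by
  descending score/intensity then input order; local-maximum plateaus keep
  the lexicographically first voxel; silhouette ties choose the smallest k;
  rank ties share the minimum rank.
- Degenerate inputs fail loudly with the offending entity named: a target
  with no dendritic synapses, a zero-variance trace, F₀ + F_mean = 0,
  collinear coordinates, all-identical presence profiles.
- Warnings (not errors) for recoverable situations: zero-norm similarity
  rows, zero-total relative rows, empty binarized masks, excluded types
  absent from a matrix, zero-variance PCA columns.
- Problem sizes in the tests and the acceptance script — hemispheres of
  30–170 columns, volumes up to 120×120×48 voxels, 60-ROI trace sets, 10
  fixed seeds per stochastic property — were chosen so the planted effects
  are unambiguous at conventional statistical strength while each stage
  remains quick to verify.

## Known limitations

- The pairwise-similarity group tests treat dependent pairs as independent
  (as is conventional); interpret p-values descriptively.
- `label_agreement` matches clusterings by exhaustive permutation and is
  limited to ≤ 8 clusters.
- The exact distance-to-mask scan is O(puncta × mask voxels); for volumes
  much beyond 256³ with dense masks, an anisotropic distance transform
  would be the next step.
- The generator's independence assumptions (above) mean null-model
  quantities — e.g. the number of significant input–input correlations on
  default synthetic data — are trivially zero; planted-structure configs
  must be used to exercise those code paths positively.
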