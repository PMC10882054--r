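# colwire

Quantifies how variable the presynaptic inputs of a columnar visual
interneuron are across the retinotopic columns of the *Drosophila* optic
lobe. Cell types such as Tm9 repeat once per column, several hundred times
per eye; connectome reconstructions make it possible to ask whether every
copy is wired the same way. `colwire` takes a table of automatically
detected synapses (presynaptic segment, postsynaptic target cell, 3D
position in nm, detection "cleft score") plus cell-type annotations, and
produces the statistics used to characterize wiring heterogeneity — along
with the two companion assays (expansion-microscopy synapse counting and
calcium-trace clustering) and synthetic-data generators with known ground
truth that make every stage testable offline.

**Who it is for:** connectomics and circuit-physiology researchers analyzing
column-resolved input budgets of cell types, and anyone needing a tested
reference implementation of this analysis style.

## What it computes

- **Filtering → connectivity matrices.** Cleft-score cutoff (≥ 50),
  sub-100 nm redundancy removal (greedy by confidence, oracle-verified),
  per-cell partner thresholds (≥ 3 or ≥ 4 synapses), matrices in absolute /
  relative / binary mode, and a ≥ 5%-of-columns presence filter. Relative
  fractions use each row's full post-threshold total (including
  unidentified inputs) as denominator.
- **Heterogeneity.** Pairwise cosine similarity cos(u,v) = u·v/(‖u‖‖v‖)
  of input profiles within and between hemispheres or cell types, with
  Kruskal–Wallis + Dunn–Bonferroni group tests; per-input mean, std and
  c.v.; input rank order with min-tie ranks.
- **Motifs.** Pearson input–input correlations (t-test p, Bonferroni);
  k-means subtypes (k = 2 exposes antagonistic major inputs, e.g. CT1- vs
  Mi4-dominated columns); PCA of standardized relative counts; binarized
  presence profiles clustered by Hamming distance with agglomerative
  linkage, the cluster number chosen by maximizing the silhouette
  coefficient over 4–15.
- **Spatial mapping.** Column coordinates (presynaptic site nearest the
  dendritic-synapse centroid), SVD-based dorsoventral split with an
  anchored midline, per-type presence/multiplicity maps, and a join-count
  permutation test of spatial randomness.
- **Expansion microscopy.** Brp-style puncta detection (local maxima,
  200 nm minimum separation), dendrite-mask binarization (Otsu default),
  and per-column-ROI counting of puncta within 300 nm of the mask
  (anisotropy-aware exact distances).
- **Calcium traces.** Mean-augmented ΔF/F₀ = (F − F₀)/(F₀ + F_mean) with
  150-frame running-median high-pass, trial averaging and 10 Hz
  resampling; z-scoring; correlation-distance k-means (k = 6).

See `vignettes/columnar-wiring-heterogeneity.Rmd` for the full methods
account, parameter meanings and design rationale.

## Worked example

Simulate a two-hemisphere connectome at reduced scale and run the core
pipeline:

```r
library(colwire)

cfg <- connectome_config("tm9", n_columns_per_hemisphere = c(40, 35), seed = 7)
sim <- simulate_connectome(cfg)
mat <- connectivity_pipeline(sim$synapses, sim$annotations,
                             targets = sim$truth$columns$target_cell_id)
mat
#> Connectivity matrix (absolute mode): 75 target cells x 20 input types
#>   partner threshold: >= 3 synapses/cell
#>   UNKNOWN synapses: 131 | sub-threshold dropped: 1991
```

20 input types survive the 5% presence filter; the sub-threshold bucket
holds the fragment floor removed by the per-cell threshold, and together
with the matrix and the UNKNOWN bucket it reproduces the post-deduplication
synapse totals exactly.

```r
sims <- cosine_similarity_groups(mat)
aggregate(similarity ~ group, sims, function(x) round(mean(x), 3))
#>   group similarity
#> 1  left      0.829
#> 2 right      0.835
#> 3    RL      0.831
compare_groups(sims)
#> Kruskal-Wallis: H = 0.9349 , df = 2 , p = 0.627
```

Input profiles are about equally similar within the right hemisphere,
within the left, and across hemispheres — the wiring statistics do not
differ between sides of this (synthetic) brain.

```r
mp <- simulate_motif_profiles(n_rows = 160, n_motifs = 4, n_types = 17,
                              flip_rate = 0.05, seed = 7)
mr <- hamming_cluster(mp$profiles, k_range = 4:15)
mr
#> Presence-motif clustering (Hamming + agglomerative)
#>   rows: 160 | candidate k: 4-15 | chosen k: 4
#>   mean silhouette at chosen k: 0.731
label_agreement(mr$labels_chosen, mp$labels)
#> [1] 1
```

With four planted presence motifs and 5% bit noise, the silhouette curve
peaks at k = 4 and the cut recovers the planted partition perfectly.

A thin command-line wrapper over the same functions lives at
`inst/cli/colwire.R` (subcommands `simulate`, `matrix`, `heterogeneity`,
`motifs`, `appose`, `traces`).

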