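---
title: "Designing and validating gene-module FISH panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating gene-module FISH panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modulefish)
```

## The measurement idea

Conventional multiplexed FISH resolves one gene per channel or round, so dim
transcripts limit what can be imaged. A gene-module FISH assay instead
hybridizes probes against a whole *module* of co-expressed genes at once:
because co-expressed genes sit in the same cells, their photons add up in
exactly the cells the module marks, and the per-cell signal grows roughly
with the number of genes and probes while the spatial pattern stays that of
a single good marker. The cost is that a module is only useful if its genes
really are co-expressed — otherwise the channel lights up a blend of cell
types.

`modulefish` implements the computational side of this trade:

1. **Reference preparation** — QC filtering of an scRNA-seq count matrix and
   the three normalized views used downstream (`qc_filter()`,
   `normalize_views()`).
2. **Panel design** — four strategies for grouping genes into modules
   (`cell_centric_panel()`, `feature_gene_candidates()` +
   `leiden_modules()`, `nmf_program_modules()`, `hybrid_de_modules()`).
3. **Panel evaluation** — the Signal Gain / Signal Specificity Ratio model
   (`score_panel()`) and simulated re-clustering of the reference from
   module-level signals alone (`module_cell_matrix()`,
   `simulate_clustering()`, `adjusted_rand_index()`).
4. **Image quantification** — registration, corrections, mask dilation and
   per-cell averaging of multi-round module images (`quantify_stack()`).
5. **Spatial statistics** — clustering of imaged cells, crosstalk
   (`manders_overlap()`), per-cell gain over smFISH, cortical depth, and
   cell-proximity tests (`proximity_counts()`).
6. **Synthetic data** — a generator with planted ground truth
   (`simulate_reference()`, `simulate_tissue_images()`) so that every stage
   above is testable end to end without any download.

## The three matrix views

All design and evaluation math runs on three versions of the QC'd count
matrix, built by `normalize_views()`:

* `cell_scaled` — every cell's total scaled to `scale_factor`
  (default 10,000). This is the substrate for predicted signals: a probe's
  photon yield is proportional to transcript abundance, not to its log.
* `log_view` — `log(cell_scaled + 1)`, natural log. Used for differential
  expression and gene–gene correlation, where variance stabilization
  matters.
* `gene_scaled` — per-gene standardized (mean 0, sample variance 1;
  constant genes map to 0). Used for dimensionality reduction and heatmaps.

Cell filters run before gene filters in `qc_filter()` because a gene's
prevalence changes once cells are dropped. Mitochondrial genes are
recognized by the `mt-`/`MT-` prefix when no explicit flags are given.

## The signal model

For a module $P_t = \{g_1,\dots,g_n\}$ with probes per gene
$k_1,\dots,k_n$ targeting cluster $C_t$:

$$\mathrm{signal}(g_i, C_t) = k_i \cdot \overline{x}_{g_i, C_t},
\qquad
\mathrm{signal}(P_t, C_t) = \sum_i \mathrm{signal}(g_i, C_t),$$

where $\overline{x}_{g_i,C_t}$ is the mean cell-scaled expression of $g_i$
over cells in $C_t$. Two summary scores follow:

* **Signal Gain (SG)** — how much brighter the module is than a single
  gene. *General* SG divides by the reference gene's signal (appropriate
  when a marker anchors the module, as in the cell-centric strategy);
  *conservative* SG divides by the strongest gene in the module and is the
  safer default because it cannot be inflated by choosing a weak reference.
* **Signal Specificity Ratio (SSR)** — the module's signal in the target
  divided by its signal off-target: *conservative* against the single
  strongest off-target cluster (which is reported as the most likely
  crosstalk partner), *general* against the sum of all off-target clusters.
  SSR near 1 means the target is indistinguishable from its best
  off-target; as a rule of thumb modules below SSR 4 are risky.

Both scores are invariant to rescaling all $k_i$ by a constant; panel
signals are linear in the $k_i$. These identities are enforced by tests
against brute-force recomputation from the scaled counts (tolerance
$10^{-9}$).

One definitional subtlety: the specificity ratio is defined here as
target over off-target, so that *larger is more specific*. The inverse
convention appears in some descriptions of the same quantity; this package
documents and uses target/off-target throughout.

Likewise, the two Manders coefficients are implemented symmetrically
($M_2$ uses channel 2's threshold in its denominator), which is the
standard colocalization definition.

## Design strategies and their parameters

**Cell-centric** (`cell_centric_panel()`): per target type, genes with
Pearson correlation (log view) above `corr_threshold` (default 0.5) to any
reference marker; if fewer than `fallback_top` (default 15) qualify, the
top 15 by correlation are taken. Genes picked by more than one target are
removed entirely — a gene shared between two channels is crosstalk by
construction.

**Feature-gene** (`feature_gene_candidates()` + `leiden_modules()`): the
expression matrix is binarized at its single global mean
(`binarize_expression()`), low/high-prevalence genes are dropped
(`prevalence_filter()`, defaults 5 cells / 80 %), and candidates are genes
correlated above `min_corr = 0.7` with at least `min_partners = 5` others.
(Reported gene counts for this strategy also appear elsewhere with a
3-partner variant; both are plain parameters here.) A graph with edges at
$r \ge 0.6$ is partitioned with Leiden (modularity objective, resolution 1,
fixed seed). Large partitions are optionally split by average-linkage
hierarchical clustering on correlation distance $1-r$, cutting into
$k = 6$ (>30 genes), $k = 4$ (11–30), $k = 2$ (6–10) or kept intact
(<6), dropping single-gene subclusters.

**Program-based** (`nmf_program_modules()`): consumes an external
gene-by-program non-negative loading matrix (the factorization itself is
out of scope), takes the `top_n = 50` positive-loading genes per program,
and removes genes whose correlation crosses programs ($r > 0.3$ — shared
major-type markers) or fails to connect within their own program
($r < 0.02$). Cross-program pruning is iterative — the worst-offending
gene least tied to its own program is removed first — so a single leaky
gene cannot eliminate the whole partner program. The bounds apply to
signed correlations.

**Hybrid DE-seeded** (`hybrid_de_modules()`): per cluster, up to 50 DE
genes (one-vs-rest log fold-change ≥ 0.25, ranked by fold-change,
Wilcoxon rank-sum p-values reported), then greedy pruning: while the
minimum pairwise correlation is at or below 0.1, remove the gene whose
*maximum* correlation to the rest is smallest. Each iteration removes
exactly one gene, so termination is guaranteed, and the rule makes
monotone progress toward the floor. Modules below 5 genes are dropped,
as are `mt`-prefixed genes. The pruning order is one reasonable reading
of "remove the genes least correlated to the rest"; it is a documented
interpretation, not the only one.

## Image quantification choices

* **Registration** (`register_image()`): phase correlation with subpixel
  refinement by an upsampled DFT around the integer peak (default 0.02 px
  steps). The normalized cross-power spectrum is low-passed at 0.35
  cycles/px: whitening weights all frequencies equally, and the band near
  Nyquist is dominated by sampling alias and noise, which otherwise biases
  quarter-pixel shifts by about 0.1 px.
* **Shift policy** (`shift_policy()`): `per_image` applies each measured
  shift; `fov_average` discards shifts exceeding 50 px in any direction as
  registration failures and applies the mean of the survivors to every
  round.
* **Corrections**: background-round subtraction (same shifts as the module
  round, clamped at 0 — camera intensities are non-negative),
  off-mask-percentile illumination correction (default 60th percentile of
  pixels outside the cell masks), and 99th-percentile normalization. All
  percentiles use linear interpolation between order statistics so fixture
  values are exact.
* **Masks** (`dilate_masks()`): nuclei grow by Euclidean distance with
  contested pixels assigned to the nearest nucleus, so labels never merge
  and the boundary between close nuclei is equidistant.
* **Averaging** (`intensity_matrix()`): out-of-bounds pixels created by
  alignment are excluded from per-cell means rather than zero-filled
  (zero-filling biases edge cells dark); cells whose mask is emptied are
  flagged, never silently dropped.
* **Presets** (`quantify_preset()`): four named bundles mirror typical
  experiment scales — `fig2` (5 px dilation, normalization, max-channel
  filtering downstream), `fig3` (15 px, normalization, cells under the
  15th percentile of total intensity flagged), `fig4` (10 px, 20th
  percentile), `fig5` (10 px, 60th-percentile illumination correction,
  per-module band QC at the 0.2/98 percentiles with a 30-module limit,
  averaged shifts). The band QC thresholds are computed per module;
  a global variant would be a one-line change and the bounds are
  parameters.

## What the synthetic generator emulates — and what it does not

`simulate_reference()` draws negative-binomial counts (mean, dispersion
parameterization; the Poisson limit is `dispersion = Inf`) for planted cell
types with planted modules: module genes have their mean multiplied by
`fold_change` in the module's target type. Non-module genes can be given a
separate `background_mean` — real references mix weak markers with
well-expressed housekeeping genes, and the global-mean binarization
threshold of the feature-gene route only separates on- from off-state when
the transcriptome-wide mean sits clearly above a marker's off-target
baseline.

Two regimes of the defaults deserve a note, both fixed at design time:

* Whether within-module correlations on the log view clear a 0.7 bar
  depends on where counts land on the log curve. At a scale factor of
  10,000, per-count increments are small (and the log nearly linear) only
  when a cell's total counts are comparable to the scale factor, i.e. with
  thousands of genes. The correlation property tests therefore use
  a 4,000-gene configuration, while pipeline tests use compact 80-gene
  references where the binarized route carries the structure.
* Tissue rendering (`simulate_tissue_images()`) draws each cell as a disk
  on a jittered hexagonal lattice (deterministically collision-free), with
  per-module intensity equal to the cell's summed module counts, scaled by
  a smooth multiplicative illumination field, plus constant background and
  Gaussian noise; each module round is translated by its planted shift.
  Disk edges roll off smoothly over 2 px, emulating finite optical
  resolution — and keeping subpixel-rendered scenes registrable — while
  the label map covers only the full-intensity interior, which makes the
  noiseless round trip (quantified mean = planted signal) exact.

The generator does **not** model point-spread functions beyond that edge
roll-off, 3-D stacks, molecular spots, segmentation errors, cell-shape
variation, or spatially correlated autofluorescence. Passing tests
therefore show that the pipeline's math is right and robust to the noise
sources modelled here — not that it will segment or register arbitrary
real tissue.

## Clustering and the choice of resolution

Both `simulate_clustering()` (meta-gene matrix) and `cluster_cells()`
(imaged matrix) run the standard chain: z-scale features, principal
components, k-nearest-neighbour graph with shared-nearest-neighbour
Jaccard weights (pruned below 1/15), then Louvain or Leiden community
detection. The SNN weighting matters: on a plain kNN graph, modularity
optimization happily splits a tight, internally unstructured cluster.

Resolution is the one genuinely free parameter. For the synthetic
validation studies (a few hundred cells, 4–5 fully separated planted
types) we cluster at resolution 0.1 with 20 neighbours: separated types
produce disconnected graph components, and communities can never merge
across components, so a low resolution cannot blend types — it only
suppresses spurious within-type splits. On real data with thousands of
cells and genuinely adjacent populations, higher resolutions (0.6–1.2)
are the appropriate regime, as in the presets' provenance.

## Validation studies shipped with the package

The test suite and `scripts/acceptance.R` recompute, from scratch:

1. **Formula oracles** — signals, SG, SSR, the meta-gene matrix, ARI, and
   Manders coefficients against brute-force enumeration on random
   fixtures.
2. **Planted-module recovery** — 5 modules × 12 genes at fold change 8 on
   a housekeeping background, 3,000 cells, 10 seeds: the binarized
   feature-gene route recovers membership at ARI ≥ 0.9 and the designed
   panels score SG > 1 and SSR > 4 for every planted type.
3. **End-to-end imaging** — 600 cells rendered at 420×420 px with planted
   shifts (including fractional ones), background and 1.5 % noise;
   registration recovers shifts within 0.1 px, the averaging shift policy
   discards planted >50 px outliers, and clustering of the fig3-quantified
   matrix recovers the planted types at ARI ≥ 0.9.
4. **Proximity analogue** — 500 reference cells per group with query cells
   thinned two-fold within 100 µm of group B: the median fold-change lands
   in [0.4, 0.7] with a two-sided Mann–Whitney p below 10⁻⁶.

Problem sizes were chosen as the smallest at which each property is
cleanly expressed. The headline characteristics reported for module-FISH
experiments on real tissue — per-cell gains of roughly 6–39× over smFISH,
inter-channel Manders crosstalk in the 0.001–0.09 range, significant
immune depletion around specific fibroblast subtypes — derive from raw
microscope data that is not publicly deposited, so the pipeline is
validated here in this property-based, synthetic form instead.

## Known limitations

* Probe target-region selection (oligo design) is out of scope; panels
  carry probe *counts*, not sequences.
* Deep-learning segmentation is out of scope; the watershed fallback is
  basic and external label maps are first-class inputs.
* SG/SSR are point predictions; no uncertainty is attached.
* The Mann–Whitney test uses exact enumeration below 20 cells per group
  (without ties) and the tie-corrected normal approximation otherwise.
* `fov_average` assumes a shared stage error across rounds; per-round
  errors call for `per_image`.
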