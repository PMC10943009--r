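# modulefish

Panel design, evaluation and image quantification for **gene-module FISH**
— multiplexed fluorescence in situ hybridization assays that image a whole
module of co-expressed genes in one channel instead of one gene at a time.
Because co-expressed genes occupy the same cells, their signals add: a
well-chosen module is many-fold brighter than its best single marker while
keeping the marker's spatial pattern. The price is specificity — a module
whose genes leak into other cell types lights up the wrong cells — and
that trade is exactly what this package quantifies before any probe is
ordered.

Intended users: labs designing module-FISH (or marker-pool FISH) panels
from an scRNA-seq reference, and anyone processing the resulting
multi-round images into per-cell module intensities.

## What it computes

For a module $P_t=\{g_1,\dots,g_n\}$ with probes per gene $k_i$ targeting
cluster $C_t$, the predicted signal is
$\mathrm{signal}(P_t,C_t)=\sum_i k_i\,\bar{x}_{g_i,C_t}$ on the
depth-normalized count matrix. Two scores summarize a design:

* **Signal Gain** `SG = signal(P_t, C_t) / signal(g_ref, C_t)` (general;
  conservative uses the brightest module gene as the denominator) — the
  brightness advantage over single-gene FISH.
* **Signal Specificity Ratio**
  `SSR = signal(P_t, C_t) / signal(P_t, C_worst-off-target)` — how
  separable the target is from its most likely crosstalk partner. SSR ≈ 1
  means indistinguishable; below ~4 is risky.

Four design strategies produce panels (marker-anchored cell-centric
selection; feature-gene correlation-graph modules via Leiden; modules from
external NMF program loadings; hybrid DE-seeded modules with correlation
pruning), and a simulated re-clustering of the reference from module-level
meta-genes — scored by Adjusted Rand Index against the reference
annotation — predicts whether a panel can recover the known cell types.
The imaging side turns multi-round TIFF stacks plus a nuclear stain into a
QC'd cell-by-module matrix (phase-correlation registration with subpixel
refinement, background/illumination correction, nearest-nucleus mask
dilation, per-mask averaging) with downstream clustering, Manders
crosstalk, per-cell gain over smFISH, cortical-depth profiles and
cell-proximity statistics. A synthetic-data generator with planted ground
truth makes the whole chain testable offline.

## Worked example

Simulate a reference with four planted cell types and four 12-gene modules
(8× fold change on a housekeeping background), design a panel by the
feature-gene route, score it, and check that module-level measurements
would recover the cell types:

```r
library(modulefish)

cfg <- sim_config(n_cells = 1000, n_genes = 80, n_cell_types = 4,
                  modules = sim_modules(4, genes_per_module = 12, fold_change = 8),
                  baseline_mean = 2, background_mean = 8, dispersion = 10,
                  seed = 1)
sim <- simulate_reference(cfg)
views <- normalize_views(qc_filter(sim$reference, min_genes_per_cell = 20,
                                   max_genes_per_cell = 5000,
                                   min_cells_per_gene = 10))

bin  <- binarize_expression(views)
keep <- prevalence_filter(bin, min_cells = 5, max_fraction = 0.8)
corr <- pearson_matrix(bin, keep)
cand <- feature_gene_candidates(corr, min_corr = 0.7, min_partners = 5)
mods <- leiden_modules(corr[cand, cand], edge_threshold = 0.6, seed = 1)
panel <- gene_panel(mods$gene, mods$module, strategy = "feature_gene")

scores <- score_panel(views, panel, labels = views$cell_labels)
scores[, c("module", "target", "n_genes", "sg_conservative",
           "ssr_conservative", "off_target")]
#> # A tibble: 4 × 6
#>   module target n_genes sg_conservative ssr_conservative off_target
#>   <chr>  <chr>    <int>           <dbl>            <dbl> <chr>
#> 1 M1     type1       12            11.4             7.84 type4
#> 2 M2     type2       12            11.6             7.94 type1
#> 3 M3     type3       12            11.5             7.95 type4
#> 4 M4     type4       12            11.6             8.01 type1
```

Every planted module is recovered intact (12/12 genes), predicted to be
~11.5× brighter than its best single gene (conservative SG), and ~8× more
intense in its target type than in the worst off-target (conservative
SSR, comfortably above the ≈4 rule of thumb). Re-clustering the reference
from module meta-genes alone reproduces the annotation exactly:

```r
mcm <- module_cell_matrix(views, panel)
labels <- simulate_clustering(mcm, n_pcs = 4, n_neighbors = 20,
                              resolution = 0.1, seed = 1)
adjusted_rand_index(labels, views$cell_labels)
#> [1] 1
```

The imaging side closes the loop — render synthetic tissue, quantify it
back with the `fig3` preset (15 px mask dilation, 99th-percentile
normalization, 15th-percentile total-intensity QC), and cluster the
imaged cells:

```r
td  <- simulate_tissue_images(sim$truth, image_shape = c(540, 540),
                              cell_radius_px = 5, background_level = 10,
                              noise_sd = 3, seed = 2)
cbm <- quantify_stack(td$stack, nuclei = td$labels, preset = "fig3")
cbm
#> <cell_by_module> 1000 cells x 4 modules (150 flagged by QC)

imaged <- cluster_cells(cbm, resolution = 0.1, n_pcs = 4,
                        n_neighbors = 20, seed = 1)
adjusted_rand_index(imaged$cluster, sim$truth$cell_type_labels[imaged$cell])
#> [1] 1
```

`autoplot()` methods are available for score tables, cell-by-module
matrices and proximity results; `tidy()`/`glance()` turn result objects
into tibbles.

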