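# merfishkit

An R toolkit for the analysis of whole-brain MERFISH (multiplexed
error-robust fluorescence in situ hybridization) cell atlases: from barcode
codebook design and gene panel selection, through cell-level quality
control, reference integration and annotation, to spatial statistics —
niche detection, spatial gradients, proximity-based cell–cell interaction
testing and ligand–receptor screens.

## Who it is for

MERFISH images a combinatorially barcoded gene panel in situ, producing a
cell-by-gene count matrix in which every cell also has a centroid position
(µm) within a 10-µm tissue section. Labs analysing such data face a chain
of recurring tasks that this package implements as composable, tested
functions; each stage takes a plain data frame (the cell table) and/or an
`expr_set` (a cells × genes container with named layers) and returns
tibbles or small result objects with `tidy()`, `glance()` and `autoplot()`
methods. A synthetic-data generator with known ground truth (`sim_config()`,
`simulate_dataset()`) makes every stage testable without any download.

## What it implements

- **Codebook** (`build_max_codebook()`, `assign_barcodes()`): the maximal
  binary code of length 32, constant Hamming weight 4 and pairwise Hamming
  distance ≥ 4 — a Steiner quadruple system SQS(32) of size
  C(32,3)/4 = 1,240, built by the classical doubling construction.
  Weight 4 fixes the number of "on" imaging rounds per RNA; distance 4
  allows single-bit error correction. Unassigned words become blank
  barcodes that read out the false-positive rate.
- **Panel selection** (`screen_deg_candidates()`, `greedy_complete_panel()`):
  per cluster pair, genes with fold change ≥ 2, Wilcoxon p < 0.01,
  foreground expressing fraction ≥ 0.5 and > 3.3-fold fraction enrichment
  (top 50 by p per pair and direction); feasibility trimming (≥ 40 probes,
  ≤ 3,000 counts in the top cluster); greedy completion until every cluster
  pair has ≥ 3 discriminative genes per direction.
- **Preprocessing** (`preprocess_merfish()`): volume bounds per z-plane
  count ([50,1500]/[80,2500]/[100,3000] µm³ for 3/5/6 planes), volume
  normalization, per-experiment rescaling of mean total signal to 250,
  removal of the top/bottom 1% total-signal quantiles, and doublet removal
  at score > 0.25.
- **Integration** (`two_round_transfer()`): two-round anchor-based label
  transfer against a clustered scRNA-seq-style reference — balanced
  integration partitions from a subclass connectivity graph, CCA
  co-embedding (SVD of the cross-product of scaled matrices, L2-normalised),
  mutual-nearest-neighbour anchors, plurality label transfer over the 100
  nearest anchors with its fraction as confidence, per-partition
  highly-variable-gene round for subclass/cluster labels, adjusted
  confidences (product with the partition confidence; pass at ≥ 0.8 /
  ≥ 0.5), and transcriptome-wide imputation as the Gaussian-weighted
  average of the 30 nearest anchor reference cells.
- **Annotation** (`assign_neurotransmitters()`, `enrichment_score()`,
  `local_complexity()`): neurotransmitter identity from transporter counts
  (≥ 2 per cell; *Slc17a7/6/8*, *Slc32a1*, *Slc6a4*, *Slc6a3*, *Slc18a3*,
  *Slc6a5*, *Slc6a2*, *Hdc*), regional enrichment
  `score(s, r) = [n(s,r)/N(r)] / [n(s)/N]`, and the number of distinct
  subclasses among the 50 nearest spatial neighbours.
- **Spatial modules** (`two_level_modules()`): weighted local
  cell-type-composition vectors, `Weight_ij = exp(−(D_ij/D_i⁰)²)` with the
  bandwidth `D_i⁰` tied to the distance to the 5th nearest neighbour (×2
  coarse, ×1 fine), L2 normalisation and Leiden clustering; level 2 runs
  per level-1 module on neurons with concatenated subclass+cluster vectors.
- **Gradients** (`neighborhood_purity()`, `expression_axis()`,
  `gradient_correlation()`): cluster discreteness via expression-space
  neighbourhood purity, and Pearson correlation of PC1 / diffusion
  pseudotime with a spatial coordinate.
- **Interactions** (`test_interactions()`): proximal pair counts at
  R_proximal = 15 µm (strict) or 30 µm (relaxed), a local-randomization
  null (every cell displaced uniformly within 100 µm, 1,000 rounds, normal
  fit), one-sided enrichment p-values, Benjamini–Hochberg correction, and
  calls at adjusted p < 0.05 with ≥ 50 observed pairs; per-region subclass
  selection by tiered enrichment thresholds (6 in the six high-complexity
  brain divisions, 2 elsewhere, 1 for astrocytes, > 50 cells otherwise).
- **Signaling** (`test_lr_upregulation()`, `test_gene_upregulation()`):
  ligand–receptor score `S = log(1 + Π L_p · Π R_q)` between proximal cell
  pairs versus an equal-size non-proximal sample, one-sided Welch t-tests,
  BH correction, and calls at fold ≥ 2, adjusted p < 0.01 and score > 0 in
  ≥ 40% of proximal pairs; plus per-gene upregulation screens in proximal
  cells.

## Worked example

```r
library(merfishkit)

# simulate a two-section experiment with one attracted subclass pair
cfg <- sim_config(seed = 5, attraction_rules = list(
  list(type_a = "SC01", type_b = "SC02", radius = 10, strength = 0.8)))
sim <- simulate_dataset(cfg)

# five-step QC / normalisation
pp <- preprocess_merfish(sim$expr, sim$cells)
pp$qc
#> # A tibble: 3 × 5
#>   step                         n_in n_removed n_out fraction_removed
#> 1 volume_filter                5032         0  5032           0
#> 2 total_count_quantile_filter  5032       102  4930           0.0203
#> 3 doublet_filter               4930       196  4734           0.0398

# proximity-based interaction test (200 rounds shown; default 1,000)
it <- test_interactions(sim$cells, r_proximal = 15, n_rounds = 200, seed = 42)
dplyr::filter(tidy(it), significant)
#> # A tibble: 1 × 11
#>   region subclass1 subclass2 proximal_count ... fold_change pval_adjusted
#> 1 all    SC01      SC02                 638          4.37             0
```

The interaction test recovers exactly the attracted pair that the generator
planted: 638 observed proximal pairs against a null mean of ~146 (fold
change 4.4) with an adjusted p-value at machine zero; all 35 other subclass
pairs are reported but not called.

```r
cb <- assign_barcodes(sprintf("gene%04d", 1:1124), build_max_codebook(32))
cb
#> <codebook> 32-bit HW4/HD4: 1124 genes + 116 blanks = 1240 words
```

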