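---
title: "Methods: models, parameters and design choices in merfishkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in merfishkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

merfishkit analyses spatially resolved single-cell transcriptomes measured
by MERFISH: each segmented cell carries a centroid position in its tissue
section (µm), an imaged volume (µm³) and a count vector over a targeted
gene panel. This vignette documents the statistical models behind each
stage, every tunable that matters, the design decisions taken where the
methodology was genuinely open, and what the synthetic benchmark does and
does not demonstrate.

## Error-robust barcodes

MERFISH encodes each gene as a binary word over imaging rounds. With
weight exactly 4 and pairwise Hamming distance ≥ 4, a single dropped or
spurious bit is correctable and two errors are detectable.
`build_max_codebook(n)` constructs the *maximal* such code: a constant
weight-4, distance-4 code of length n is equivalent to a Steiner quadruple
system, the family of C(n,3)/4 four-subsets of bit positions in which
every three-subset occurs exactly once. The package uses the classical
doubling construction (SQS(2n) = two relabelled copies of SQS(n) plus
cross-blocks that pair equal-index one-factors of the complete graph on
each copy), with the round-robin one-factorisation, so the output is
deterministic. At 32 bits this yields 1,240 words; assigning 1,124 genes
leaves 116 blank barcodes, whose decoded counts estimate the false-positive
rate. The gene-to-word map is a seeded random draw: only the set sizes and
code invariants are meaningful, not any particular mapping.

## Gene panel selection

`screen_deg_candidates()` screens every ordered cluster pair of a
clustered reference for genes with fold change ≥ 2, p < 0.01, foreground
expressing fraction ≥ 0.5 and a > 3.3-fold expressing-fraction enrichment,
retaining the 50 smallest-p genes per pair and direction. The test behind
the p-value is the two-sided Wilcoxon rank-sum test — the de-facto standard
for single-cell differential expression; it is a parameter, not a
commitment. Thresholds are read literally: "fewer than 40 probes" excludes
39 and keeps 40; "more than 3.3-fold" requires a strict inequality; a
background fraction of zero counts as infinite enrichment.
`greedy_complete_panel()` then adds, at each step, the candidate covering
the most (pair, direction) slots still below the target of 3 genes, with
ties broken by the smallest aggregate p over the deficient slots it covers
and then lexicographically. "Discriminative power" is therefore defined
here as marginal slot coverage — a set-cover view; the greedy pick is
verified stepwise against exhaustive search in the tests.

## Quality control and normalization

Five steps, in order: (1) volume bounds of [50, 1500], [80, 2500] and
[100, 3000] µm³ for 3-, 5- and 6-z-plane measurements (spurious
segmentation fragments and z-merged cells), with boundary values retained;
(2) counts divided by imaged volume; (3) per-experiment rescaling so the
mean total per cell is exactly 250; (4) removal of cells in the strict
top/bottom 1% total-signal quantiles (R type-7 quantiles; any consistent
convention moves at most one cell per tail), applied per experiment group
to match the normalization granularity; (5) doublet removal at score
> 0.25 (scores are consumed from an external caller, never computed here).
Step 3 is idempotent and each filter is a fixed point on its own output.

## Reference integration, label transfer and imputation

Both datasets are normalised to 1,000 counts per cell, log1p-transformed
and z-scored per gene. The reference taxonomy is first cut into K balanced
*integration partitions*: a 15-nearest-neighbour graph in 100-dimensional
PCA space is collapsed to a subclass graph whose edge weights count
cross-subclass neighbour edges, and the graph is cut by recursive spectral
bisection (Fiedler-vector ordering, a balance constraint of ±20% on cell
counts, and a single-pass move refinement). A dedicated graph-partitioning
library would serve equally; the contract is only balance plus a small cut.

Co-embedding uses the diagonal-covariance form of canonical correlation
analysis universal in single-cell integration: the SVD of the
cross-product of the two scaled matrices, with both datasets projected by
the fitted gene-space maps and per-cell L2 normalisation (full-covariance
CCA is neither tractable at scale nor what the field's tools compute).
When a dataset exceeds `max_fit_cells` (100,000) the directions are fit on
a seeded downsample and the rest projected linearly. Mutual nearest
neighbours (k = 5) across the datasets are anchors. A query cell's label
is the plurality label among its 100 nearest anchor reference cells, the
plurality fraction is the confidence, and ties break to the
lexicographically smallest label. Round 2 repeats this per partition using
the partition's highly variable genes (normalised log dispersion > 0,
computed in 20 mean-expression bins). Since a subclass or cluster label is
right only when both rounds are, the final confidences are the product of
the within-partition and partition confidences; cells pass at ≥ 0.8
(subclass) and ≥ 0.5 (cluster), inclusively.

Imputation averages the log-normalised transcriptome-wide profiles of the
30 nearest anchor reference cells with Gaussian kernel weights
exp(−(d/σ)²), σ being the distance to the 30th anchor — the kernel is a
design choice where only "distance-based" weighting is prescribed, and is
recorded in the configuration.

The embedding dimensionality should track the complexity of the taxonomy
being transferred: 100 dimensions suit hundreds of subclasses and
thousands of clusters; the desk-scale benchmark (5 subclasses × 3
clusters, 200 panel genes, ~2,000 cells per side) uses 30, since
dimensions beyond the data's structure contribute only noise to
neighbour distances after L2 normalisation.

## Annotation statistics

Neurotransmitter identity is called per neuron from raw transporter counts
at ≥ 2 counts per cell (*Slc17a7*, *Slc17a6*, *Slc17a8* jointly for
glutamatergic; *Slc32a1* GABAergic; *Slc6a4* serotonergic; *Slc6a3*
dopaminergic — the transporter, deliberately not *Th*; *Slc18a3*
cholinergic; *Slc6a5* glycinergic; *Slc6a2* noradrenergic; *Hdc*
histaminergic). Flags are independent, so dual identities are possible and
calls are monotone in counts.

The regional enrichment score of a subclass is the fold change of its
within-region density over its whole-brain density. Densities need a
region-size measure; by default total cell counts proxy region volume
(the ratio form cancels the proxy when sections sample regions
proportionally), and a per-region size table can override it. By
construction, the density-weighted mean of a subclass's scores over
regions is 1. Local complexity is the number of distinct subclasses among
a cell's 50 nearest within-section neighbours.

## Spatial modules

Each cell's neighbourhood is summarised by a weighted cell-type
composition vector over its 50 nearest within-section neighbours, with
Weight_ij = exp(−(D_ij/D_i⁰)²) and a per-cell bandwidth D_i⁰ proportional
to the distance to the 5th nearest neighbour — twice that distance at the
coarse level, once at the fine level — so the kernel adapts to local
density and the vectors are invariant to global coordinate rescaling.
Vectors from all sections are pooled (composition space carries no
coordinates), L2-normalised and clustered with Leiden on a 15-NN graph.

Community detection on the kNN graph of an essentially homogeneous
neighbourhood type over-fragments it — kNN graphs of a single blob always
admit spurious communities — a problem usually resolved by expert
curation, manually merging clusters without clear spatial boundaries. The
programmatic surrogate here merges modules whose mean normalised
composition vectors have cosine similarity above 0.85, iteratively,
highest first: fragments carved from one niche have near-collinear
centroids (cosine → 1 as the 50-neighbour sums average out sampling
noise), while genuinely distinct niches, even sharing types, fall lower
(two 70/30 vs 30/70 mixtures of the same two types sit near 0.72). A
small-module merge into the spatially adjacent majority module is also
available. Level 2 re-runs the procedure per level-1 module on neurons
only, concatenating subclass- and cluster-level vectors; non-neurons keep
only level-1 ids. The Leiden resolutions (1 and 2) are exposed
configuration, as no canonical values exist.

## Spatial gradients

Cluster discreteness starts from neighbourhood purity: the fraction of a
cell's 50 nearest neighbours in expression space (a 50-dimensional PCA of
the log-normalised layer) sharing its cluster label; cluster discreteness
is the mean member purity and subclass discreteness the median over its
clusters. Fully mixed labels give purity ≈ 1/c for c clusters.
`expression_axis()` provides the one-dimensional axis correlated against a
spatial coordinate: PC1, or a pseudotime computed as the first non-trivial
eigenvector of a symmetrically normalised Gaussian kNN affinity on the PCA
embedding (a diffusion-map component). Both are sign-fixed — PC1 so its
largest-magnitude gene loading is positive, pseudotime to correlate
positively with PC1 — so repeated runs are identical. The correlation
itself is plain Pearson against any per-cell scalar (a coordinate column,
cortical depth, an anatomical-axis position); depth computation is
consumed as input, not implemented.

## Cell–cell interaction testing

Two cells interact candidately when their centroids lie within R_proximal
in the section plane: 15 µm (about one soma) for contact-level stringency,
or 30 µm for paracrine-range signalling, in which case a call additionally
requires at least one upregulated ligand–receptor pair (`add_lr_support()`).
The null preserves local density: every cell is displaced independently
and uniformly within a 100-µm disk, pairs are recounted, and 1,000 rounds
are summarised by a normal fit, giving a one-sided enrichment p-value, a
z-score and the fold change over the null mean. Displacements are
reflected at the section's bounding box: without reflection, density leaks
out of the tissue near its edges, the null undercounts pairs there, and
the test becomes anti-conservative — negligible on centimetre-scale
sections but decisive on millimetre-scale ones; reflection maps a
homogeneous pattern onto a homogeneous pattern while keeping every move
within 100 µm. Uniform-disk displacement in 2D is itself a recorded choice
(disk vs square and 2D vs 3D being open). P-values are BH-adjusted over
all (region × pair) tests of a run; calls need adjusted p < 0.05 and ≥ 50
observed pairs; depletion is reported but never called. A degenerate null
(zero variance) yields the permutation-style bound 1/(n_rounds+1) when the
observation exceeds the null mean, else 1. Per region, only subclasses
that are enriched (score ≥ 6 in the six high-complexity divisions —
anterior/posterior hypothalamus, anterior/posterior midbrain, pons,
medulla — and ≥ 2 elsewhere; ≥ 1 for astrocytes) or abundant (> 50 cells,
other non-neuronal types) are tested, after filtering to subclass transfer
confidence ≥ 0.8.

## Ligand–receptor and gene upregulation screens

The pair score is S = log(1 + Π_p L_p · Π_q R_q), natural log, each ligand
and receptor component entering once, so any missing receptor subunit
annihilates the score. Scores over all proximal cross-type pairs are
compared with an equal-size uniform sample of pairs at distance >
R_proximal (without replacement; a with-replacement fallback is flagged)
by a one-sided Welch t-test; both sender/receiver orientations are tested.
Welch's statistic is implemented in closed form with Satterthwaite degrees
of freedom because the degenerate zero-variance case needs a defined
convention (p = 0.5 at equal means); the implementation is checked against
`stats::t.test` to 1e-10. Calls require fold ≥ 2, BH-adjusted p < 0.01 and
a positive score in ≥ 40% of proximal pairs. The per-gene screen splits
type-A cells by proximity to any type-B cell and Welch-tests each highly
variable gene (same HVG rule as integration) at fold ≥ 2 and adjusted
p < 0.01. Pathway summaries report, per pathway, the pair with the highest
upregulation fold change.

The screen's inputs are an expression matrix of the caller's choosing.
Imputed expression gives transcriptome-wide coverage on real data; the
synthetic benchmark feeds measured (linear-scale) panel counts instead,
because the generator's upregulation acts on measured counts and
imputation — a reference-profile average — cannot carry a
proximity-conditional signal that the reference never contained. The
log(1+·) score compresses large products, so fold-change sensitivity is
best for moderately expressed components; the benchmark's signalling genes
are set at mean 2 counts per cell for this reason.

## The synthetic generator: what it emulates, and what it does not

`sim_config()` defines the benchmark conditions: two 1-mm² sections at
2,500 cells/mm² (≈ 5,000 cells), 8 subclasses × 2 clusters with
block-marker mean structure, negative-binomial counts with dispersion 2
scaled by log-normal cell volumes (5 z-planes, median 500 µm³), and a 4%
doublet fraction — the fraction the QC stage is expected to remove.
Domains with distinct compositions, pairwise attraction (relocation of a
fraction of one type to within a radius of the other — relocation, not
thinning, so per-type densities are conserved and the interaction null's
premise holds; hosts are drawn without replacement so the attraction
creates A–B pairing without clumping B cells onto shared hosts),
log-linear expression gradients (the benchmark slope of 0.003/µm gives a
~20-fold change across a 1-mm section, comparable to strong laminar
gradients), and proximity-conditional LR upregulation are all opt-in
rules with ground truth recorded. The LR benchmark uses sparser tissue
(480 cells/mm² over 2 × 2 mm sections) so that proximity to the partner
type remains the exception; when most cells of a type are proximal to the
partner, the non-proximal control is drawn from the same upregulated
population and no method could separate them. The integration benchmark
uses 5 subclasses × 3 clusters over a 200-gene panel with 8 cluster
markers per cluster — the discriminability a designed panel guarantees —
inside a 260-gene reference, with ~2,000 cells on each side.

What passing these benchmarks shows: the machinery is correct — exact
formulas, calibrated nulls, recovery of planted structure at realistic
noise. What it does not show: robustness to segmentation errors, spatial
artefacts correlated across neighbouring cells, batch effects between
animals or experiments, mis-registration of region labels, or taxonomies
with hundreds of subclasses; none of these are generated. Problem sizes
were chosen so the whole suite exercises every stage at a few thousand
cells per scenario — the scale at which the algorithms' asymptotics are
already representative.

## Numerical conventions

All thresholds compare as written ("less than" strict, "at least"
inclusive). kNN searches are exact brute-force in C++ with deterministic
index tie-breaks; radius counting uses a uniform grid, so results are
permutation-stable. Seeds control every stochastic step (point patterns,
count draws, CCA downsampling, Leiden, control-pair sampling); identical
seeds give identical output. BH adjustment is delegated to
`stats::p.adjust` and cross-checked in the tests against a hand-written
step-up oracle; quantiles are R type 7; Pearson correlations with a
zero-variance argument are reported as missing rather than zero.

## Known limitations

HDF5 single-cell containers are not read (MatrixMarket triplet and dense
CSV are). The balanced graph cut is a heuristic without an approximation
guarantee; at hundreds of subclasses its cut quality, not correctness, may
trail a dedicated partitioner. The cosine-similarity merge threshold
(0.85) is a surrogate for expert curation and, like any fixed threshold,
can over- or under-merge niches whose compositional contrast sits near it.
The interaction test measures co-occurrence within a radius, not synaptic
or functional connectivity, and long-range communication is invisible to
it by construction.
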