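---
title: "Methods and design notes for brainatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for brainatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`brainatlas` implements the computational stages of a whole-brain MERFISH
cell-atlas analysis as a reusable, tested R pipeline: barcode codebook
construction and gene-panel design, cell-table quality control,
anchor-based integration with a single-cell reference, region composition
statistics, spatial-module delineation, spatial gradient quantification,
and spatial-proximity cell-cell interaction inference. This vignette
explains the models behind each stage, the parameters that matter, and the
design decisions taken where the methods literature leaves choices open.
Every stage is exercised end-to-end on synthetic sections with planted
ground truth, so the whole pipeline is testable without any external data.

## Error-robust barcode codebooks

MERFISH encodes each gene as a binary barcode read out over sequential
imaging rounds. Robustness to single-bit errors requires constant Hamming
weight 4 (four "on" bits, balancing brightness) and minimum pairwise
Hamming distance 4 (single-bit errors are detectable and correctable
toward the nearest valid word). Two weight-4 words are at distance >= 4
exactly when their supports share at most two positions — equivalently,
when no 3-subset of bit positions occurs in two words. A maximal such code
on $n$ bits is a Steiner quadruple system $SQS(n)$: a family of 4-subsets
covering every 3-subset exactly once, of size $\binom{n}{3}/4$. At $n=32$
that is 4960/4 = 1240 words.

`construct_codebook()` builds the full $SQS(2^k)$ by recursive doubling:
$SQS(2n)$ consists of each $SQS(n)$ block replayed inside both point
copies, plus cross blocks $\{a_0, b_0, c_1, d_1\}$ for every ordered pair
of edges $\{a,b\}, \{c,d\}$ drawn from the same one-factor of a
round-robin one-factorization of $K_n$. The construction is verified two
ways in the test suite: `validate_codebook()` checks all pairwise
distances exhaustively, and at $n = 8$ an independent branch-and-bound
packing search (`max_code_size(8, exhaustive = TRUE)`) confirms that 14 is
not merely attained but maximal. Assigning 1124 genes to the 1240-word
32-bit code leaves 116 blank barcodes, which carry no probes and measure
the false-positive call rate of the decoding.

```{r}
cb <- construct_codebook(32)
validate_codebook(cb)$pass          # TRUE, min distance exactly 4
sum(assign_barcodes(paste0("g", 1:1124), cb, seed = 1)$is_blank)  # 116
```

## Panel selection and probe design

Candidate marker genes come from pairwise differential expression between
reference clusters (`de_genes()`): at least 2-fold change of
total-normalised means, two-sided Wilcoxon rank-sum p < 0.01, expressed
(count > 0) in at least 50% of foreground cells, and more than 3.3-fold
enrichment of the expressing fraction; the 50 best genes per direction are
kept. The rank-sum test is a deliberate default — the field's standard
non-parametric choice for single-cell differential expression — and the
test function is injectable because the fold and fraction gates dominate
the selection anyway. `trim_pool()` then drops genes that cannot host 40
encoding probes (too short) or exceed 3000 mean counts in their highest
cluster (too bright for combinatorial imaging), both read strictly from
the stated bounds. `assemble_panel()` greedily adds pooled DE genes,
always serving the worst-covered cluster pair first, until every pair has
at least 3 panel genes per direction or its candidate pool is exhausted
(exhaustion is reported, never an error).

Probe target regions (`design_target_regions()`) are 30-nt windows
filtered on GC fraction (0.40–0.60), melting temperature (66–76 °C) and
freedom from any shared 16-mer with an rRNA/tRNA index (i.e. no exact
homology longer than 15 nt), then thinned to a seeded random
non-overlapping draw of 64; transcripts that cannot host 64 fall back to
relaxed bounds (GC 0.30–0.70, Tm 61–81 °C, overlap up to 20 nt) down to a
floor of 40 probes, below which the transcript is rejected with a flag.
The Tm model is unified nearest-neighbour thermodynamics with salt and
formamide corrections (`tm_nn()`); because published hybridisation
conditions are never fully recoverable, the Tm function is an injectable
parameter and the filter logic is tested with a stub.

## Cell-table quality control

Raw segmented cells pass four steps, in order: (1) volume filter — imaged
volume outside (50, 1500) µm³ for 3 z-planes, (80, 2500) for 5, (100,
3000) for 6, all strict inequalities, removes segmentation artifacts and
unresolved z-overlaps; (2) volume normalisation then global rescaling so
the mean per-cell total is 250 counts; (3) removal of cells in the top and
bottom 1% of total counts (linear-interpolation quantiles, R's type-7
default, applied per input table); (4) an external-doublet-score hook
(score > 0.25 removed; scoring itself is upstream of this package).
Neurotransmitter identity is assigned from raw integer counts — the
threshold "at least 2 RNA counts" is a copy-number statement, so it is
applied before any normalisation — with one marker set per transmitter
group and overlapping labels allowed.

## Integration with a single-cell reference

Measured cells are co-embedded with reference cells by the cross-product
form of canonical correlation analysis used throughout the single-cell
integration literature: both matrices are total-normalised to 1000,
log1p-transformed and gene z-scored; the singular vectors of the
cells-by-cells cross-product give the canonical coordinates, computed
through the gene-space core so no large matrix is formed, with a
deterministic sign convention; gene-space linear maps project the full
datasets when the decomposition was run on a downsample (100,000 cells per
side by default). Embeddings are L2-normalised per cell. Anchors are
mutual 5-nearest-neighbour pairs across the datasets. A label transfers to
a measured cell as the majority label among its 100 nearest anchor
reference-cells in the joint PCA space, with the majority fraction as the
confidence score.

Transfer runs in two rounds. Round 1 transfers *integration partition*
labels on the measured panel. Partitions group transcriptionally close
subclasses: a 15-NN graph in 100-dimensional PCA space is collapsed to a
subclass graph whose edge weights count cross-subclass neighbour edges,
and a balanced k-way partitioner minimises the cut. The partitioner is
self-contained (exhaustive for small two-way instances, greedy with
refinement otherwise) and pluggable; the objective — balanced parts,
minimal cut — is what matters, not the specific library. The default
partition count scales as one per ~6.4 subclasses, mirroring the 306
subclasses to 48 partitions ratio of whole-brain references. Round 2 runs
inside each partition on the partition's positive-log-dispersion genes
(variance/mean of total-normalised counts above 1), in partition-local
joint PCA coordinates — a documented choice where the round-2 coordinate
system was genuinely open — and transfers subclass and cluster labels.
Final confidences multiply the round-2 score by the partition confidence,
because a fine label is only right if the partition was; cells pass at
> 0.8 (subclass) and > 0.5 (cluster).

Imputation averages the log-normalised reference profiles of each
measured cell's 30 nearest anchor reference-cells with Gaussian kernel
weights whose bandwidth is the distance to the 30th anchor — the kernel
was open ("weights based on the distance"), and an adaptive Gaussian is
the standard kNN-regression choice; it is configurable. A
nearest-centroid cosine assignment (`cosine_assign()`) provides the
independent cross-check of the transfer, as in the original analyses.

## Region statistics and spatial modules

Enrichment of a cell type in a region is the fold change of its
within-region share over its global share. Two modes exist because the
density phrasing (cells per mm³ of region) and the fraction phrasing
(share of cells) both occur in practice; fraction mode is the volume-free
default, and in that mode the type-frequency-weighted column average is
exactly 1. Local cell-type complexity counts distinct subclasses among the
50 nearest neighbouring neurons within a section. Large heterogeneous
regions can be split along the rostral-caudal axis at the midpoint of the
minimum and maximum ccfx of their cells (`split_by_ccfx()`; ties go
posterior).

Spatial modules cluster cells on distance-weighted local cell-type
composition. Each cell's 50 nearest eligible neighbours (never across
sections) are weighted $w_{ij} = \exp(-(D_{ij}/D^{(0)}_i)^2)$, where the
density-adaptive scale $D^{(0)}_i$ is twice the 5th-nearest-neighbour
distance at level 1 and the 5th-nearest-neighbour distance itself at
level 2; the per-type weight sums form the composition vector
(subclasses at level 1; subclass and cluster blocks concatenated at level
2), L2-normalised. Level 1 conventionally excludes vascular and immune
cells (spatially unstructured); level 2 runs on neurons only, separately
within each level-1 module, so level-2 modules nest by construction.

Clustering is Leiden community detection on the 15-NN graph of the
composition vectors. Two defaults deserve explanation. First, the Leiden
resolution defaults to 0.1: level-1 modules are major-region-scale
structures, and at modularity resolution 1 the k-NN graph of a
compositionally homogeneous territory fragments into arbitrary
sub-communities — a known resolution-limit effect on sparse neighbour
graphs — while a coarse resolution recovers territory-scale communities.
Second, modules whose centroid composition vectors exceed cosine
similarity 0.9 are merged by default. This is the programmatic counterpart
of the curation step in atlas practice, where clusters that do not form
compositional boundaries are merged by hand; compositionally distinct
regions sit near-orthogonal in the L2-normalised composition space, so the
merge never crosses a real boundary. Both knobs are exposed
(`resolution`, `merge_cosine`; `merge_cosine = 1` disables merging).

## Gradients and cluster discreteness

Neighbourhood purity is the fraction of a cell's 50 nearest neighbours in
expression PCA space (top 50 components of the z-scored log-normalised
matrix) sharing its cluster label; cluster discreteness is the mean purity
over the cluster, and a subclass is summarised by its median cluster
discreteness. Perfectly discrete clusters score 1; clusters drawn from a
continuum score near their frequency. The gradient axis of an expression
subset is PC1 of the standardised matrix, sign-oriented so its Pearson
correlation with a caller-supplied spatial coordinate is non-negative; a
"pseudotime" variant returns the normalised rank of the PC1 ordering — a
deliberate, documented approximation of principal-curve pseudotime, which
the PC1 option explicitly stands in for. `spatial_correlation()` reports
Pearson r with a Fisher-z 95% interval and flags zero-variance input
rather than erroring.

## Cell-cell interactions and ligand-receptor scoring

Two cells are proximal when their soma centroids lie within
$R_\text{proximal}$ (strict <): 15 µm for direct-contact-scale calls,
30 µm for paracrine-scale calls. For each subclass pair within a region,
the observed proximal pair count is compared with a local-randomization
null: in each of 1000 rounds (200 in the test fixtures; calls on the
planted fixtures are stable from 200 up) every cell is displaced to an
independent uniform position within 100 µm, preserving each type's local
density while erasing fine-scale pairing. The per-pair counts are fitted
by a normal distribution; the upper-tail probability of the observed count
is the raw p, BH-adjusted across the region's pairs; a call requires
adjusted p < 0.05 and at least 20 observed pairs. Type eligibility
follows the enrichment rules (score >= 6 in the six subdivided
brainstem/hypothalamic regions, >= 2 elsewhere for neuronal types, >= 1
for astrocytes, > 50 cells for other non-neuronal types) with cells at
subclass confidence > 0.8.

Two numerical choices keep the null honest, both visible in the type-I
calibration tests. Displacements are *reflected at the section bounding
box*: letting displaced cells spill past the tissue edge dilutes the
point density by roughly $(1 + R_\text{rand}/L)^2$ and biases the null
mean low, which inflates the false-call rate several-fold on
millimetre-scale sections; reflection preserves a uniform density exactly
and never moves a cell farther than its raw displacement, so positions
stay within 100 µm of their origin. And the observed count is discrete
while the fitted null is continuous, so the tail probability uses a 0.5
continuity correction. Raw p-values are floored at $1/(\text{rounds}+1)$
and the null standard deviation at $10^{-9}$.

The ligand-receptor score of a sender-receiver cell pair for database
pair $k$ is $S = \ln(1 + \prod_p L_p \cdot \prod_q R_q)$ over the ligand
and receptor subunits. The double-product notation in the field's usage
is read as the product of the two subunit products — the standard
multi-subunit convention; the literal reading
$(\prod L)^{|q|}(\prod R)^{|p|}$ is available behind `literal = TRUE`.
Scores over proximal pairs are compared with an equal-size seeded sample
of non-proximal pairs (sampling without replacement) by a one-sided Welch
t-test; significance needs a fold of mean scores >= 2, BH-adjusted
p < 0.01 within the type pair, and a positive score in at least 40% of
proximal pairs. Pair scores sharing a cell are not independent; the
analysis convention ignores this, and so, documentedly, does the default
here. Imputed expression is the preferred input, with measured normalised
counts as the fallback. Relaxed-radius (30 µm) interaction calls
additionally require at least one significant ligand-receptor pair.
`upregulated_genes()` applies the same Welch/BH/fold machinery to each
highly variable gene of the sender type, contrasting senders within
$R_\text{proximal}$ of any receiver against the rest.

## The synthetic-data generator

`simulation_spec()` + `simulate_section()` emulate the statistical
structure the analyses assume: homogeneous Poisson placement per
rectangular region at per-subclass intensities; negative-binomial counts
(variance $\mu + \mu^2/\theta$; $\theta = \infty$ gives Poisson) around
per-cluster mean profiles; counts proportional to a log-normal imaged
volume *before* QC, so the volume normalisation is exercised nontrivially;
planted linear gradients ($\mu \cdot (1 + s u)$ along a named axis);
planted attraction (each type-A cell spawns a type-B companion uniformly
within a radius with a given probability — a Thomas-like attractive
process); and planted ligand-receptor folds applied to the ligand genes of
senders and receptor genes of receivers that end up within the stated
radius. `default_specs()` freezes the study conditions used by the test
and acceptance suites.

Fixture conditions the methods literature does not pin down were chosen
once, on realism grounds, and frozen:

* **two_region** uses two 1 × 1 mm territories at 500 cells/mm² dominant
  density. The 50-neighbour composition scale spans ~125 µm at that
  density, so a millimetre-wide region keeps boundary mixing to a thin
  band; the planted-recovery contract (adjusted Rand index >= 0.9 against
  the true regions) holds across seeds.
* **gradient** plants a seven-fold linear gradient on 10 of 30 genes
  (base mean 10, dispersion 10) — the scale of strong laminar gradients —
  against a subclass with two well-separated clusters, giving the
  discreteness contrast its sign and margin.
* **lr_effect** uses deliberately sparse populations (70 cells/mm² in a
  2.5 × 2.5 mm section) and lowly expressed ligand/receptor transcripts
  (mean 0.5 counts), because proximity-conditional upregulation is only
  detectable when proximity is the exception: at a few hundred cells/mm²
  a 30 µm radius exposes half of all senders and the "non-proximal"
  contrast group is itself upregulated.

What the generator does **not** emulate — and hence what green tests do
not certify on real data: imaging-derived artifacts (misidentified
barcodes, segmentation errors, z-overlap doublets beyond the volume
proxy), irregular tissue shapes (regions are rectangles; the reflection
boundary is a bounding box), batch structure across animals or sections,
within-cluster expression correlation beyond the NB noise model, and
curved or non-linear gradients.

## Scales, determinism and degenerate inputs

Every stochastic step takes an explicit seed (simulation, barcode
assignment, CCA downsampling, Leiden refinement, null rounds, non-proximal
sampling); identical inputs and seeds reproduce identical outputs, and
nearest-neighbour ties break by cell index. Zero-norm composition vectors
are flagged rather than normalised; constant genes z-score to zero
columns; all-zero cells are an error at normalisation; empty regions score
0 with a flag. The benchmark problem sizes — 2,400-cell references,
~1,500-cell sections, 20-seed calibration batches, 200 null rounds — were
chosen so the full planted-truth battery, including the interaction
calibrations, completes in a few minutes while leaving clear statistical
margins; all scale parameters are arguments, and nothing in the
implementation assumes these sizes.

## Known limitations

The balanced partitioner is a heuristic above small instances (exact only
for two-way splits of up to 14 subclasses); the CCA projection for
downsampled runs is a least-squares gene-space map, accurate when the
downsample spans the expression space; module counts on real tissue
depend on the resolution and merge parameters, which should be reviewed
against anatomy rather than taken as fixed truth; the pseudotime variant
is a rank transform of PC1, not a principal curve; and interaction calls
remain association statements about soma proximity — they cannot see
long-range or synaptic communication.
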