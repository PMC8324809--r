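---
title: "Methods: transcriptional states and paracrine networks from single-neuron qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptional states and paracrine networks from single-neuron qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurostates)
```

## The problem this package addresses

Intrinsic cardiac ganglia such as the right atrial ganglionic plexus (RAGP)
contain hundreds of principal neurons whose molecular identities do not fall
into the discrete phenotype islands familiar from central nervous system
atlases. Spatially-tracked single-neuron assays — laser-capture
microdissected neurons profiled by high-throughput qPCR (hundreds of neurons
by ~240 gene assays), complemented by single-cell-scale RNA-seq of neuron
pools — instead reveal overlapping gradients of expression, extensive
co-expression of cholinergic (*Chat*) and catecholaminergic (*Th*) markers,
and combinatorial neuropeptide/receptor patterns that outline local paracrine
signaling networks.

`neurostates` implements the full analysis chain for such data: reaction-level
quality control, median-reference normalization, a transcriptional-state
model fitted by clustering and applied by template matching, distributional
differential screening between projection-defined groups (e.g. neurons that
project to the sinoatrial node, labeled by retrograde tracer, versus
unlabeled neurons), combinatorial paracrine network construction, RNA-seq
gene selection, and spatial gradient screens — together with a synthetic-data
generator that emulates the statistical structure the analysis assumes, so
every stage can be validated against known ground truth.

## Normalization model

Raw qPCR cycle thresholds (Ct; one cycle ≈ 2-fold abundance, lower =
more abundant) are normalized in two steps.

**Sample referencing.** For each sample $s$ the reference is the median Ct
of a robust reference gene set $R$ (genes with working reactions in strictly
more than 60% of samples; see `robust_gene_set()`):

$$-\Delta Ct(g,s) \;=\; \operatorname{median}_{r \in R} Ct(r,s) \;-\; Ct(g,s).$$

The median of a gene panel is used instead of individual housekeeping genes
because its pairwise-variation stability (computed by `stability_rank()`, a
geNorm-style mean standard deviation of pairwise log-ratios) beats any single
candidate. Because the reference is a per-sample median, any constant
per-sample shift — e.g. chip-level amplification offsets — cancels exactly;
this is asserted as a test invariant.

**Per-gene centering.** The second step centers each gene at its
across-sample median:

$$-\Delta\Delta Ct(g,s) \;=\; -\Delta Ct(g,s) \;-\;
  \operatorname{median}_{s'} \left(-\Delta Ct(g,s')\right).$$

The source convention for this step is ambiguous about sign; we fix the
convention so that **positive $-\Delta\Delta Ct$ means above-typical
expression of that gene**, which makes heatmaps and templates read naturally
(high = red = abundant). Per-gene medians of the output are zero by
construction (within 1e-9; asserted). Centering is pooled across animals by
default; a `groups` argument supports per-animal centering. Medians over even
counts use the midpoint convention and exclude missing values.

For presentation, `to_ct_space()` re-expresses centered values on the Ct
scale, $-(-\Delta\Delta Ct) + \operatorname{median} Ct(g)$, preserving the
normalized range while restoring the familiar "lower = more abundant"
reading; the transform round-trips algebraically.

Per-animal abundance shifts (such as a cholinergic marker running ~7 Ct
higher in one animal) are deliberately *not* corrected during normalization:
they are handled only in abundance calls, through per-(animal, gene)
threshold overrides in `call_abundance()` (default threshold Ct < 15,
override e.g. Ct < 22 for the shifted animal). All thresholds in the package
are strict inequalities; boundary cases are pinned by unit tests.

## The transcriptional-state model

The centerpiece estimator is `state_model()`, a fit/predict pair:

1. **Training.** Sample profiles (typically the tracer-labeled,
   SAN-projecting neurons of a subset of animals) are clustered by
   hierarchical clustering with complete linkage on the correlation distance
   $1 - r$ (Pearson, over pairwise-present genes, minimum overlap 3), and
   the tree is cut at $k = 7$ clusters. Cluster quality is quantified by the
   mean silhouette width under the same distance and judged against 1,000
   label permutations that preserve cluster sizes
   (`silhouette_with_null()`; $p = (1 + \#\{\text{null} \ge
   \text{obs}\})/(n_{perm}+1)$).
2. **Templates.** Each state's template is the per-gene median of its member
   profiles (missing excluded).
3. **Assignment.** Any neuron — training or held out, from any animal — is
   assigned by Pavlidis template matching (`predict()` /
   `ptm_assign()`): Pearson correlation against every template; the neuron
   joins the best-correlated state if $r_{best} \ge 0.45$ and is otherwise
   *sequestered* into a catch-all state. Ties break toward the lowest state
   index; samples with no computable correlation (overlap < 3 genes or zero
   variance) are sequestered with a warning. Raising the threshold can only
   move neurons into sequestration, never between states (a tested
   monotonicity property).
4. **Merging.** States with near-identical profiles can be combined (e.g. 7
   initial clusters merged to 6 final states). Because the original merge
   decision was a judgment call made by inspection, `merge_states()` only
   ever merges an explicit specification; `suggest_merges()` proposes
   candidates from template-template correlations but nothing is merged
   silently. Merged templates are rebuilt from the pooled training samples
   rather than averaged, which keeps the template a genuine median.

Per-state gene enrichment uses one-way ANOVA with post hoc Tukey HSD
(`state_enrichment()`): a gene is enriched in a state when it exceeds at
least two other states at Tukey-adjusted $p < 0.01$. Genes are screened
individually, with no cross-gene correction — the screen is descriptive, not
a family-wise inference.

Which gene subset feeds the clustering is a required analysis choice (the
detectable set, a curated subset, ...); the model accepts any
$-\Delta\Delta Ct$ matrix and records the training samples it used.

## Differential screening between projection groups

`ks_screen()` compares the full expression distributions of the two
projection groups per gene with the two-sample Kolmogorov–Smirnov statistic
(exact p-values when both groups have fewer than 30 values, asymptotic
otherwise), adjusts across tested genes by Benjamini–Hochberg
(`bh_adjust()`, with BY as an option), and gates by fold change: on the
$-\Delta\Delta Ct$ scale a difference of group medians $d$ corresponds to a
$2^{|d|}$-fold change, so significance requires $q < 0.01$ **and**
$2^{|d|} > 2$. Fold change on normalized values is the default; the raw-Ct
alternative is a matter of passing that matrix instead. The KS + FDR + fold
combination is deliberately conservative: under null simulations the
expected number of significant genes is essentially zero, because the fold
gate binds long before the FDR does.

## Combinatorial paracrine networks

For each neuropeptide set (defaults: *Sst*/{*Sstr1*, *Sstr2*},
*Gal*/{*Galr1*, *Galr2*}, *Npy*/{*Npy1r*, *Npy2r*}), each neuron is
**peptide+** when its peptide expression is strictly above that gene's
median across all neurons, and **receptor+** when *any* cognate receptor is
strictly above its own median (`binarize_flags()`). Values exactly at the
median, and missing values, are negative — with hundreds of neurons and
continuous values, ties are rare, but the decision must be fixed. Medians
are pooled across animals by default (a `medians` argument supports
per-animal or frozen cutoffs).

Each neuron's combined flags define its category identifier, e.g.
`Sst+R-|Gal-R+|Npy+R+`; with three sets the identifier space has exactly
$4^3 = 64$ members. (A per-set space of 4 — peptide± × receptor± — is the
only reading consistent with 64 total.) `category_census()` counts neurons
per category, retaining categories with strictly more than 10 neurons, and
`build_network()` renders the retained subtypes as a bipartite directed
graph: producer edges subtype → peptide where peptide+, receiver edges
peptide → subtype where receptor+, with node sizes carrying neuron counts
and SAN-projecting fractions (exported via GraphML or edge lists).

## RNA-seq gene selection

`filter_counts()` applies the two-stage count filter: samples with strictly
fewer than 6,000 nonzero genes are dropped as shallow, then genes nonzero in
strictly fewer than 30 surviving samples are dropped as rare. The rare-gene
sentence in the source protocol is ambiguous ("fewer than 30 nonzero
counts"); the nonzero-sample reading parallels the sample filter and is the
default, with a total-count mode provided. Upstream processing (alignment,
counting, batch correction, regularized log, quantile normalization) is out
of scope: the module consumes any pre-normalized matrix.

`pca_variable_genes()` extracts variable genes from PCA loading tails:
genes are centered (not scaled, so loadings reflect absolute expression
variability), samples are decomposed by `prcomp`, and from each of the
first 50 components the 50 most positive and 50 most negative loading genes
are pooled and deduplicated. The selection is invariant to sample order and
global scaling (tested).

`template_enrichment()` identifies tissue-specific genes in a
median-expression atlas panel by correlating each gene's tissue profile with
a binary template (1 = neuronal tissues, 0 = others) using the same
template-matching correlation machinery, keeping genes with positive $r$ and
$p < 0.01$.

## Spatial screens

`axis_density()` summarizes the 3D positions of neurons as per-axis,
per-group normalized histograms (shared breaks per axis; densities integrate
to 1). `gradient_screen()` quantifies the "no spatial gradient" claim:
Spearman correlation of each gene's expression against each coordinate,
BH-adjusted across all gene × axis tests, flagged at $q < 0.05$. The
original assessment of spatial gradients was visual; this screen is a
quantitative extension and is labeled as such. Spearman is used because
Ct-derived values are heavy-tailed.

## The synthetic-data generator

`simulate_qpcr()` generates data with the statistical structure the
analysis assumes, with ground truth for recovery tests:

* **Gradient states, not islands.** Each neuron's expected profile is a
  convex combination of $K$ state mean profiles with Dirichlet weights: the
  concentration on non-self states equals `state_softness`, so 0 gives
  discrete clusters and larger values reproduce the "single cloud" geometry
  of the real transcriptomic landscape.
* **State means.** Per-gene baselines are uniform on 10–26 Ct; each state
  elevates a random ~15% of genes by 4 Ct of abundance. These effect sizes
  are the package's choice — the source data do not quantify state
  separation — and were picked to give moderately separated states:
  clearly recoverable when discrete, overlapping when soft.
* **Co-expression.** Each configured gene pair shares a latent Gaussian
  factor whose variance is sized so the induced correlation hits the target
  $r$ given the reaction noise ($\tau^2 = \sigma^2 |r|/(1-|r|)$); pair genes
  get state-flat means so the realized correlation is governed by the factor
  alone. The default plants a *Chat*/*Th*-like pair at $r = 0.8$. Note that
  the default per-animal offset (below) deliberately confounds this pair:
  the +7 Ct *Chat* shift inflates *Chat*'s marginal variance and attenuates
  the pooled correlation to ~0.5, exactly as a real between-animal batch
  shift would; the correlation target is therefore verified with offsets
  disabled.
* **Per-animal offsets.** The default configuration shifts *Chat* by +7 Ct
  in the last of four animals, emulating an animal whose cholinergic
  abundance runs lower while preserving the expression range — the scenario
  the abundance-call override exists for.
* **Failures and labels.** Reactions fail completely at random at rate 5%
  (no failure mechanism is modeled in the source; MCAR is the simplest
  defensible choice). Projection labels are drawn per neuron with
  state-dependent probabilities (default a 0.75 → 0.25 gradient across
  states, so states mix both labels), and a configurable fraction (default
  ~20%) is relabeled "unknown", mirroring neurons assayed without tracer
  information.
* **Space.** Coordinates are uniform in an 18.8 × 19.4 × 16 mm bounding
  box, independent of state — the generator's truth is spatially
  unpatterned, which is what the gradient screen's null calibration needs.

`simulate_counts()` draws overdispersed negative-binomial counts with
state-specific means, planting a configurable fraction of shallow samples
(library size × 10⁻³) and rare genes, as fixtures for the count filters.
`simulate_tissue_panel()` plants neuronally-enriched genes in a
median-expression panel. All generators are bit-reproducible under a fixed
seed.

What the generator does *not* emulate: spatial autocorrelation of
expression, non-random failure mechanisms (e.g. abundance-dependent
dropout), chip batch structure beyond constant per-sample shifts, and
sequencing-read-level artifacts. Passing recovery tests on this synthetic
structure therefore validates the pipeline's logic and calibration, not its
robustness to every failure mode of real instruments.

## Numerical choices and edge cases

* Strict inequalities at every threshold (>30% sample failures, >20% gene
  failures, Ct < 15 abundance, >60% working reactions, $r \ge 0.45$
  assignment, census count > 10, ≥6,000 nonzero genes, nonzero in ≥30
  samples), matching the stated rules; boundary behavior is unit-tested.
* Correlations use pairwise-complete observations with a minimum overlap of
  3 genes; insufficient overlap is an error (clustering) or sequestration
  (assignment), never a silent NA.
* QC filtering is a single sample-then-gene pass. At realistic failure
  rates this is a fixed point (asserted on generated data); at extreme
  failure rates (far above the 20–30% cutoffs themselves) a second pass
  could remove more, which is documented rather than hidden behind
  iteration the source never describes.
* The outlier-sample removal step of the source protocol has no stated
  rule; it is exposed as an explicit `exclude_samples` argument, never an
  automatic heuristic.
* Degenerate genes (constant or all-missing) are excluded from tests that
  cannot handle them and reported in attributes (`"untestable"`,
  `"skipped"`) or warnings.

## Problem sizes used by the test suite and acceptance script

The shipped checks run cohorts of 400–500 neurons by 200–241 genes (the
study-scale configuration is 405 × 241 across 4 animals), 100-replicate
null calibrations at 160 neurons × 200 genes, and 1,000-permutation
silhouette nulls — sizes chosen so the full suite completes in well under a
minute per module on a laptop while keeping every statistical check at
meaningful power.

## Known limitations

* The pipeline accepts pre-normalized RNA-seq matrices; it does not
  re-implement batch correction or count normalization.
* Template matching with a fixed correlation threshold inherits the usual
  caveat that the sequestered fraction depends on the gene set and the
  threshold jointly; both are exposed as parameters.
* Enrichment and differential screens are per-gene descriptive screens, not
  joint models; they should be read as hypothesis generators.
* The silhouette permutation null preserves cluster sizes but not any
  spatial or animal structure; with strong animal effects a stratified null
  would be stricter.
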