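---
title: "Models and methods behind ampliClone"
author: "ampliClone authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ampliClone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

ampliClone analyses targeted single-cell DNA amplicon sequencing
(Tapestri-style) data downstream of read processing: its inputs are
per-cell allele-depth matrices (cells × variants, ref/alt read counts)
and per-cell amplicon read-count matrices (cells × amplicons), one pair
per bone-marrow draw.  Upstream steps — trimming, alignment, barcode
demultiplexing, read-level genotyping and ITD detection — are out of
scope; the package starts where those pipelines stop.  Because public
raw data cannot stand in for every planted scenario one needs for
validation, the package ships a first-class synthetic-data generator
whose ground truth (clone tree, fractions, dropout, doublets, copy
states) is recorded alongside every simulated dataset.

# The genotyping model

Per cell and variant, the alt-read count $k$ out of depth $n$ is
modelled as a three-component binomial mixture:

$$ k \mid \text{WT} \sim \mathrm{Bin}(n, \varepsilon), \quad
   k \mid \text{HET} \sim \mathrm{Bin}(n, 1/2), \quad
   k \mid \text{HOM} \sim \mathrm{Bin}(n, 1-\varepsilon), $$

with $\varepsilon$ the per-read miscall probability (default 0.01) and
configurable priors (default uniform).  Posteriors are computed in log
space with the convention $0\log 0 = 0$, so the caller is stable for
depths up to $10^5$ and for $\varepsilon = 0$.  The call is the
posterior argmax; exact ties break toward the lower variant burden
(WT before HET before HOM), which is conservative against false clone
discovery.  Genotype quality is phred-scaled,
$\mathrm{GQ} = \min(99, -10\log_{10}(1 - p_{\text{called}}))$, computed
from the log-sum of the two non-called posteriors for accuracy near 1.
Cells with $n < \texttt{minDepth}$ (default 10) are MISSING; their VAF
is undefined (NA), never coerced to 0.  The GQ retention default of 30
corresponds to 99.9% posterior confidence; "high quality" has no
universal quantification in this assay class, so the threshold is an
explicit, documented convention.

Allele dropout (ADO) is deliberately **not** modelled in the caller.
The clone taxonomy downstream is defined directly on per-cell
WT/HET/HOM calls, and dropout is handled where it matters — at the
clone level (below).

# Clones, dropout correction, and the fish table

A *clone* is an exact zygosity tuple over a chosen driver-variant set
(e.g. `HET/WT` in driver order).  A cell is unassigned when any driver
call is MISSING or below the GQ threshold; reported fractions are over
assigned cells.

Raw tuple fractions are biased under dropout: a heterozygous driver is
read as WT with probability $p$ (alt copy lost, or both copies lost and
only error reads remain) and as HOM with probability $p(1-p)$ (ref copy
lost), so a double-HET clone retains only
$(1 - p - p(1-p))^2 \approx 72\%$ of its cells at $p = 0.08$.
`estimateCloneFractions()` therefore treats the observed key counts as
a multinomial mixture: each candidate clone emits observed keys through
a per-driver confusion matrix

$$ T(p) = \begin{pmatrix} 1 & 0 & 0 \\
   p & (1-p)^2 & p(1-p) \\ p^2 & 0 & 1-p^2 \end{pmatrix}, $$

products over drivers, with per-time-point fractions fitted by EM and a
single dropout rate shared across time points fitted by profile
likelihood (grid step 0.01 on $[0, 0.25]$, then local refinement).

Two identifiability facts shape the estimator:

* The *saturated* model — every observed key its own clone — fits any
  data perfectly at $p = 0$, so the candidate clone set must be pruned
  before the rate is profiled.  Candidates are observed keys reaching
  `minCells` (default 5) in some time point; dropout-explainable
  phantom keys are then removed by greedy backward elimination under
  BIC, starting from a moderate rate ($p = 0.1$) and alternating
  pruning with profile refits until both stabilise.  A true clone whose
  counts exactly match the dropout leakage of an ancestor is
  fundamentally indistinguishable from that leakage and will be pruned;
  this is the price of parsimony and the reason the raw fractions stay
  available (`fractions(fish, corrected = FALSE)`).
* Doublets collapse mixed clone pairs into heterozygous-looking keys
  (any summed allele balance strictly between the call boundaries reads
  HET), biasing large-clone fractions by 1–2 points at a 3% doublet
  rate.  The mixture therefore carries doublet components — unordered
  clone pairs whose summed copies pass through the same dropout model,
  with large-depth call boundaries at balance 0.15/0.85.  The doublet
  *rate* is barely identifiable from key counts alone (doublet output
  mass lands almost entirely on existing keys), so it is a fixed model
  parameter, default 0.03, a typical droplet-chemistry figure; pass
  `doubletRate = NULL` to estimate it anyway.

`buildFishTable()` takes the union of clone keys across time points
(explicit zeros where absent), drops keys never reaching `minCells`,
and infers parents by the mutant-subset rule: the parent of clone $C$
is the clone whose mutant-variant set is the largest strict subset of
$C$'s, ties broken by larger average fraction, then lexicographic key.
Zygosity-only changes (HET→HOM at the same variant) do not count as
subsets, so homozygous clones attach to the single-mutant ancestor.
Row sums are renormalised to 1 (tolerance 1e-9 enforced by the class
validity method).

`detectRareClones()` reports non-WT keys with at least `minCells`
(default 5) cells and below `rareFraction` (default 0.01) of assigned
cells — the sub-percent regime where bulk assays are blind.  The cell
floor is what keeps dropout phantoms (which scale with their parent
clone) from being reported as rare discoveries; the spurious-HOM rate
under a pure-HET truth is itself checked against its analytic value
$p(1-p)$ in the test suite.

# Allelic burden and density clustering

`alleleBurdenMatrix()` pools per-cell VAFs across time points.  A VAF
is missing when the call is MISSING (including zero depth); variants
missing in more than half the pooled cells are dropped, and remaining
missing entries are imputed as 0.  The policy is recorded on the
object.  Imputing to zero shrinks burden for low-coverage cells and can
collect them near the origin of VAF space — visible as a small extra
cluster when depth is marginal; this is a deliberate trade-off that
keeps the pooled-cell clustering design simple and transparent.

Clustering is DBSCAN with Euclidean metric (defaults eps 0.3 in VAF
units, minSamples 20).  No suitable implementation is part of the
supported dependency set, so the package implements the classic
algorithm directly: blockwise neighbour search (the full distance
matrix is never materialised), frontier expansion from core points, and
border points attached by their lowest-index core neighbour — making
results deterministic for a given input order.  All-noise output is
legal.

# Copy-number inference

Amplicon counts carry no contiguity, so inference is per gene, never
per segment.  The pipeline is:

1. **Artifact flagging** (`flagDropoutAmplicons`): an amplicon is
   flagged when its zero-count cell fraction exceeds 0.5 or its mean
   count falls below 0.2× the panel-wide median of per-amplicon means.
   Flagged amplicons carry no ploidy values and are excluded from every
   downstream call.  Note that a *uniformly* inefficient amplicon would
   otherwise normalise away (reference cells share the inefficiency);
   the danger it poses is zero-inflation noise, which is why it is
   removed rather than rescaled.
2. **Reference cells** (`selectReferenceCells`): cells confidently wild
   type at every driver (no MISSING call, GQ ≥ threshold).  "Cells with
   neutral polymorphisms" has no operational definition in the assay
   literature; interpreting it as the somatically-WT population is this
   package's documented choice, recorded in the ploidy object's
   metadata.  Fewer than `minRefCells` (default 50) is a hard error.
3. **Normalization** (`normalizePloidy`): per cell by the cell's total
   count over non-artifact amplicons (library size), then per amplicon
   by the median of step-1 values over reference cells, times 2.
   Reference cells' per-amplicon median is 2 by construction (validity
   tolerance 1e-6); the transform is exactly invariant to per-cell
   scaling.  Medians, not means, because per-amplicon depth is heavily
   overdispersed.  Cells under `minCellReads` (default 500) total reads
   are dropped and recorded.
4. **Candidates** (`detectCandidateCnvs`): per group and gene, gene
   ploidy is the median over the group's cells of the per-cell median
   across the gene's non-artifact amplicons; loss below 1.5, gain above
   2.5 — midpoints between integer copy states.  Groups come either
   from clone keys or from unbiased clustering of the ploidy matrix
   (k-means on a 10-component PCA, k chosen by mean silhouette over
   2..8; Lloyd iterations, seeded).  Centroid clustering is used here —
   rather than the density clustering of the VAF matrix — because
   ploidy noise is continuous and the expected cluster count small.
   Both grouping modes flow through identical candidate/confirmation
   logic.
5. **Confirmation** (`confirmCnvs`): a candidate is confirmed only when
   at least 75% of the gene's non-artifact amplicons individually pass
   the threshold (per-amplicon group medians); otherwise it is labelled
   an artifact.  This encodes "a consistent drop across all of a gene's
   amplicons" while tolerating one noisy amplicon in small genes.
   Single-amplicon genes can be confirmed only on a non-flagged
   amplicon and are marked as single-amplicon evidence in the output.

`embedPloidy()` gives the 2-D view: PCA to 10 components, then a
spectral (Laplacian-eigenmap) embedding of the cells' kNN similarity
graph, implemented in-package.  Determinism is enforced by fixing
eigenvector signs and seeding the only sampled quantity — the landmark
subset used above 1500 cells, where the dense eigendecomposition is
replaced by landmark embedding plus similarity-weighted placement.

# The synthetic-data generator

`defaultTruth()` describes a five-draw serial course over a 20-gene /
127-amplicon myeloid panel: a dominant WT clone under initial therapy
(94%), expansion of a double-heterozygous IDH2/FLT3-ITD clone at
transformation, minor homozygous subclones, suppression of all mutant
clones at the final draw with none eradicated, and a one-copy DNMT3A
loss riding in the mutant clones.  Sampling per cell:

* clone ~ Categorical(fractions); with probability `doubletRate`
  (default 0.03) a partner clone is drawn and the cell's material is
  the sum of both;
* depth per amplicon ~ NegBin(mean = `meanDepth` × efficiency ×
  copies/2, size = `depthDispersion`).  The negative binomial (default
  size 3) and log-normal per-amplicon efficiencies (sdlog 0.65,
  mean 1, sampled once per truth seed) reproduce the order-of-magnitude
  per-cell per-amplicon coverage spread of real panels at the default
  mean depth of 120;
* per variant, zygosity on the clone's local copy number defines the
  allele copies (HET = one mutated parental lineage:
  $\max(1, \mathrm{round}(c/2))$ alt copies for local copy number
  $c \ge 1$); each copy drops independently with probability `pAdo`
  (default 0.08); the surviving balance $b$ gives the alt-read
  probability $b(1-\varepsilon) + (1-b)\varepsilon$, and full dropout
  emits alt reads only through $\varepsilon$ (default 0.01).  Ref + alt
  reads equal the amplicon depth exactly.

Defaults for `pAdo`, `seqError` and `doubletRate` are typical published
single-cell amplicon figures, not estimates of any particular study's
rates.  Everything is drawn from one integer seed; identical truths
give bit-identical datasets.  What the generator does **not** emulate:
read-level errors and chimeric PCR, barcode collisions, cell-quality
gradients, correlated dropout across variants within a cell, and
amplicon-efficiency drift between draws.  Passing tests on simulated
data therefore demonstrate correctness of the downstream machinery
under the stated generative model, not robustness to every failure mode
of real libraries.

# Problem sizes and numerical choices

The validation suite exercises the stated study conditions: clone
recovery on five draws of 5000 cells (dropout 0.08, error 0.01,
doublets 3%), rare-clone detection on 10,000 cells with a planted 0.8%
clone, CNV recovery on 2000 cells at 50× with a one-copy DNMT3A loss
in a 20% subclone, twenty 2000-cell null simulations for specificity,
and burden clustering on 2000 cells of two clean disjoint-homozygous
clones.  Smaller sizes (a few hundred to ~2000 cells) are used for
module-level checks where the property does not depend on scale.
Recovery is judged against the recorded per-cell truth (realized clone
draws), since the multinomial sampling of a few thousand cells already
deviates visibly from the nominal mixing fractions.

EM convergence is on max absolute fraction change (1e-7 during search,
1e-9 for the final fit, iteration-capped); the pipeline derives one
sub-seed per stochastic stage from the single run seed, and the JSON
report contains no timestamps, so a rerun of an identical configuration
is byte-identical.

# Known limitations

* Clone inference is taxonomy, not phylogeny: no likelihood over trees,
  no multi-sample joint genotyping, no doublet *detection* (doublets
  are only absorbed statistically in fraction estimation).
* The ADO correction assumes dropout acts independently per driver and
  identically across clones and time points.
* CNV calls are group-level; no per-cell integer copy states, no
  breakpoints, no LOH from allele ratios.
* Insertions are carried as variant classes (ITD = empty ref, alt of
  length ≥ 3) but never re-detected from reads.
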