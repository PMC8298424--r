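---
title: "RLoopCycle: models and methods"
author: "RLoopCycle authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RLoopCycle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Co-transcriptional R-loops -- DNA-RNA hybrids plus a displaced
single strand -- threaten genome integrity, chiefly by blocking
replication forks. Different protective factors act at different points
of the cell cycle: a co-transcriptional guard of the THO-complex type
suppresses hybrids in both G1 and S phase, while a helicase of the
Sen1 type resolves hybrids only during S phase, preferentially at loci
where transcription meets the incoming fork head-on. Distinguishing
these modes genome-wide requires comparing strand-specific hybrid maps
(DRIPc-seq-style) and DNA-damage chromatin marks (gamma-H2A
ChIP-seq-style) between conditions and phases, and relating hybrid
gains to replication-origin geometry.

RLoopCycle implements that comparison as a reusable, fully tested
pipeline on small (yeast-scale) genomes, driven by a synthetic-data
generator with planted, labelled ground truth so that every stage is
exercisable and checkable without deposited sequencing data.

# Data model

Four containers carry everything:

* `GRanges` (1-based, closed) is the universal interval currency for
  genes, peaks, gain regions and origin midpoints. BED input/output is
  converted at the boundary, so on-disk files keep the 0-based
  half-open convention. We deliberately use the native Bioconductor
  coordinate convention internally rather than 0-based arithmetic: all
  interval algebra is delegated to `GenomicRanges`, and a single
  convention at the API boundary removes a whole class of off-by-one
  defects.
* `CoverageTrack`: dense per-chromosome signal at a fixed bin width
  with a normalization tag (`raw`, `RPKM`, `WT-subtracted`,
  `RNH-scaled`). Wild-type-subtracted tracks may be negative; nothing
  is clamped, because regions where the wild type exceeds the mutant
  are themselves informative.
* `BinnedCounts`: a `RangedSummarizedExperiment` of integer counts for
  (possibly stranded) bins by samples, with one library size per
  sample.
* `MetaplotMatrix` / `AsymmetryIndex`: oriented anchors-by-positions
  signal and its downstream/upstream summary.

Stranded operations (hybrid maps) run per strand throughout; the
damage track is unstranded. Peak/region fusion is strand-aware by
default, with `ignoreStrand` available where a caller wants the
orientation-blind behaviour.

# Synthetic truth generator

`truthConfig()` fixes the study conditions; `generateAnnotation()`
realises them deterministically from one seed. The defaults are:

* Genome: 4 chromosomes of 250 kb with 5 kb terminal telomeres.
  Yeast-scale chromosome arms keep every stage (HMM, differential
  tests, metaprofiles) running in seconds to minutes while leaving
  room for 40 replication origins spaced at least 20 kb apart.
* Genes: 280 non-overlapping protein-coding genes, log-normal lengths
  (median 1.2 kb, truncated to 0.3-5 kb), random strands; 5% tRNA and
  4% snoRNA features. Expression is log-normal (sdlog 0.5) and reused
  across conditions, so expression never confounds condition
  contrasts.
* Origins: each origin is deliberately flanked by one gene per side
  within 1 kb, guaranteeing head-on (HO) and codirectional (CD)
  origin-proximal gene pools whatever the seed.
* Hybrid signal: per-bin negative-binomial counts with background mean
  5 and dispersion 0.1 at the 50 bp calling bin. On a gene's sense
  strand the mean gains `hybridScale * expression` shaped by a linear
  5'-to-3' ramp from 0.5x to 1.5x -- the simplest shape that
  reproduces the characteristic rise of hybrid signal toward the
  transcription terminator. Counts are simulated directly at bin
  level; read-level simulation would add nothing the pipeline could
  observe.
* Planted gains: 40 hpr1-type regions (active in G1 and S,
  orientation-blind), 24 sen1-type regions (active in S only; a
  fraction `piHO` = 0.8 on HO origin-proximal genes, the rest on CD
  ones, at most one per origin), 20 common regions (active in both
  mutants), each occupying one gene body and multiplying its mean by
  `fGain` = 3. The gain fold is a generator parameter, not a measured
  quantity: 3x is comfortably detectable at this depth without being
  trivial.
* Damage: baseline NB noise (mean 1 per 10 bp bin) plus, around each
  gain region active in the condition, Poisson counts totalling 2000
  spread by a Gaussian kernel (sigma 1 kb) around the region
  midpoint. The mass splits `a : (1 - a)` downstream : upstream of
  the local fork direction (away from the nearest origin midpoint);
  the hpr1-type condition uses a = 0.5 (symmetric), the sen1-type
  condition a = 0.8, giving a planted asymmetry index of
  (0.8 - 0.2)/(0.8 + 0.2) = 0.6. Placement keeps sen1-active anchors
  at least 12 kb apart: overlapping asymmetric clouds from two anchors
  flanking the same origin would otherwise leak into each other's
  upstream flanks and bias the recovered asymmetry toward zero.
* The RNase-H condition removes all hybrid signal, leaving pure
  background.

What the generator does **not** emulate: fragment-length and GC
models, mappability, replication-timing gradients, copy-number
variation along the arm, antisense transcription, and peak-shape
heterogeneity. Passing tests therefore demonstrate that the
algorithms recover planted structure under controlled noise -- not
that real libraries meet these assumptions.

All randomness flows from the single configuration seed through named
substreams (condition, phase, replicate, stage), so replicates share
the planted truth and differ only in noise, and the entire pipeline is
reproducible bit-for-bit.

# Peak calling

`fitNbHmm()` fits a two-state hidden Markov model with
negative-binomial emissions (background vs enriched) to one strand's
binned counts; chromosomes are independent chains sharing parameters.
The E-step is a scaled forward-backward pass (C++); the M-step updates
transition and initial probabilities in closed form and the NB means
and dispersions by posterior-weighted method of moments. The moment
update is not an exact M-step for the dispersion, so the fitter
verifies the log-likelihood after each iteration and retains the
previous dispersions whenever the update would lower it -- in
practice the trajectory is monotone. Iteration stops when the relative
log-likelihood change drops below `tol` (1e-4) or after `maxIter`
(200) iterations; non-convergence warns and returns the best
parameters. All-zero tracks are rejected; a fit whose two means agree
within 5% is flagged degenerate and yields no peaks.

`callPeaks()` turns posteriors into peaks: candidate runs are maximal
stretches with enriched-state posterior above 0.5; a run survives only
if its *maximum* posterior reaches 0.99999 and it spans at least
100 bp. The calling bin is 50 bp by default -- the 100 bp
minimum-length filter needs sub-100 bp resolution, and two bins per
minimum peak is the coarsest grid that provides it.
`consensusPeaks()` keeps replicate-shared signal only, as the
base-pair intersection of overlapping replicate peak pairs with the
pair's smaller maximum posterior. A multivariate joint HMM across
replicates would estimate a shared state sequence instead; since the
downstream contract only consumes peaks present in both replicates,
the univariate-per-replicate fit plus intersection delivers the same
output semantics at a fraction of the complexity.

# Differential analysis

Normalization uses trimmed-mean-of-M-values factors (trim 30% on
log-ratios, 5% on abundance, precision weighting) computed on
genome-wide 200 bp bins with `edgeR::calcNormFactors()`, after
excluding bins with a zero in any sample; factors are rescaled to
geometric mean 1 and multiply the library sizes into effective sizes.

`testRegions()` sums counts over each region (the merged-and-fused
union of the two conditions' peaks; fusion closes gaps strictly below
200 bp) and tests a common rate against per-condition rates with a
negative-binomial likelihood-ratio test (chi-square, 1 df). The
common dispersion is estimated by method of moments pooled across all
regions and replicated groups, or fixed (0.05) when no group has
replicates. Mean fits are intercept-only NB GLMs with offsets,
iterated by Fisher scoring vectorised across regions. The reported
fold change is `log2((m2 + 0.5)/(m1 + 0.5))` on normalized means; the
0.5 pseudocount bounds the fold change at zero counts.

Enrichment calls are strict threshold crossings: linear FC > 1.2 and
-log10 p > 0.6 for S-phase data sets, FC > 2 and -log10 p > 1 for G1
data sets. No multiple-testing correction is applied -- the
classification contract is a raw-p threshold filter, and we keep that
contract rather than silently substitute an FDR; the thresholds are
deliberately permissive filters feeding downstream classification,
not significance claims. Mutant-specific versus common labels come
from re-testing the merged union of both mutants' gains directly
mutant against mutant: a region enriched in one mutant over the other
(same thresholds) is specific to it, anything else common. Testing
mutant-versus-mutant directly (rather than intersecting
mutant-versus-wild-type calls) makes the specific/common boundary a
single explicit contrast; the label recovery tests confirm it
reproduces planted labels.

G1/S overlap categories compare a mutant's gain regions across phases
by simple overlap: G1 regions split into `G1` and `G1-S`, S regions
without a G1 partner are `S`; counts conserve the G1 set size.

# Annotation and gene properties

A peak annotates to a feature it overlaps, or to a feature whose
strand-relative 5' upstream window (200 bp immediately before the
start, half-open) it reaches; a peak ending exactly 200 bp before the
start is outside. Peaks may annotate to several features; class
fractions (protein-coding, tRNA, snoRNA, telomere) are therefore
non-exclusive and need not sum to one. No feature priority is
imposed. Telomeres are modelled as terminal intervals so telomeric
metaprofiles work without repeat modelling. Gain-gene properties
(median length, median expression) are compared against the genome
with two-sided Wilcoxon rank-sum tests.

# Metaprofiles and the asymmetry index

All profile extraction goes through one area-preserving resampler: the
track is treated as a piecewise-constant density, and each output cell
takes the overlap-weighted mean of the bins it covers. This single
primitive serves reference-point windows (anchor midpoint +/- flank,
any cell width), scaled gene bodies (body linearly rescaled to a fixed
number of positions, fixed-resolution flanks), and regions shorter
than the number of body positions (which simply interpolate). Cells
extending past a chromosome end are `NaN`; windows entirely off
chromosome are dropped with a notice. Minus-strand (or
leftward-fork) rows are reversed so every axis reads 5'-to-3' or
fork-upstream-to-downstream. Replicates are averaged before
profiling; averaging commutes with profiling (both are linear), which
the tests verify. Coverage is RPKM-normalised
(`count / (bin kb x million reads)`); hybrid-depleted control samples
are rescaled by their unique/total read ratio before comparison, and
mutant damage tracks are compared after subtracting the wild-type
track, without clamping.

The asymmetry index per anchor is `AI = (D - U)/(D + U)`, with `D` and
`U` the mean flank signals downstream/upstream of the fork, excluding
positions within a core radius of the anchor point; anchors with
`D + U <= 0` are excluded and counted. The summary is the mean with a
1000-resample bootstrap 95% CI. Two defaults matter:

* Core exclusion is a fixed 500 bp rather than the anchor body.
  Because the damage kernel is symmetric in distance, the
  downstream:upstream flank-mass ratio -- hence the AI -- is invariant
  to the exclusion radius; a small fixed core keeps the
  high-signal-to-noise cells nearest the anchor and halves the
  per-anchor variance relative to body-sized exclusions. The damage
  mark is a different track from the anchors' hybrid signal, so there
  is no self-signal to mask.
* For quantitative AI recovery we profile +/- 3.5 kb (3.5 kernel
  sigmas, > 99.9% of the mass). Flank cells far beyond the kernel
  contain only baseline noise, which enters `D` and `U` additively
  and shrinks the ratio toward zero; matching the flank to the kernel
  extent removes that dilution. The anchor point is the peak
  midpoint: symmetric, robust to peak length, and the natural choice
  when the plotted quantity is spreading *around* a site.

# Transcription-replication conflicts

Forks are modelled as strictly bidirectional from each origin
midpoint, with no termination modelling -- the minimal model behind a
binary HO/CD orientation call. A gene is origin-proximal when its
nearest edge is strictly closer than 1 kb to some origin midpoint
(nearest-edge, with midpoint-inside-gene giving distance zero); ties
break toward the lower-coordinate origin. The gene's side of the
origin is decided by its midpoint -- genes can straddle the midpoint,
and the midpoint rule is deterministic and testable; the razor-edge
case (gene midpoint exactly on the origin midpoint) is labelled
ambiguous and excluded with a notice. CD means gene strand equals
fork direction; HO otherwise.

Per orientation, genes count as R-loop-gain when they overlap at least
one gain region of the requested class. The 2x2 association test is
the uncorrected chi-square
`N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with one degree of freedom.
A 1-df chi-square has no native sidedness, so the one-sided p-value is
the halved two-sided tail when the observed direction matches the
alternative and its complement otherwise -- the standard directional
interpretation.

`simulateOrientationTable()` calibrates the test: a toy genome of
origins with two random-strand flanking genes each, gains drawn by
weighted sampling without replacement with head-on odds
`piHO : (1 - piHO)`. At `piHO = 0.5` that is exactly uniform
assignment -- the null of no orientation association -- which keeps
the empirical type-I error at the nominal level (a binomial draw of
the head-on gain count independent of the realised gene pools would
overdisperse the table relative to its margins and inflate
rejections).

# Pipeline, determinism, and problem sizes

`runPipeline()` wires the stages end to end; every threshold lives in
`runConfig()` (fuse 200 bp, minimum peak 100 bp, posterior cutoff
0.99999, S thresholds 1.2x / 0.6, G1 thresholds 2x / 1, upstream
200 bp, origin distance 1 kb, 200 bp counting bins, 50 bp calling
bins, 10 bp coverage bins). Outputs are plain BED/TSV plus a markdown
report carrying the configuration hash and seed; re-running a
configuration reproduces every file byte-identically. With a single
replicate the consensus step is skipped and the differential test
falls back to the fixed dispersion; the reference configuration uses
two replicates per condition in both phases.

The test suite runs the generator at two scales: a compact
configuration (2 x 80 kb, 40 genes) for unit tests and the reference
configuration (4 x 250 kb, 280 genes) for the end-to-end recovery
checks; calibration loops use 200 simulated datasets and 2000 null
regions. These sizes make the full suite convenient to run routinely
while leaving every statistical check enough resolution to be
meaningful.

# Known limitations

* The NB HMM is univariate per replicate; joint multivariate state
  estimation across samples is out of scope.
* Plain NB emissions (no zero inflation); at yeast-scale depth the
  dispersion parameter absorbs the extra zeros.
* The likelihood-ratio test with moment-estimated common dispersion is
  slightly liberal at n = 2 + 2; the calibration tests pin its type-I
  error to the 3-7% band under the reference conditions.
* Raw-p threshold filtering (by design, see above) is not a
  significance procedure.
* Fork direction ignores termination zones and fork asymmetry data;
  orientation calls near zone boundaries inherit that simplification.
* BAM ingestion is out of scope: the pipeline consumes binned counts
  and coverage (BED/bedGraph/GFF3/TSV).
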