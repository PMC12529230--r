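---
title: "Methods: characterizing nonspecific genome-wide protein occupancy"
author: "napbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing nonspecific genome-wide protein occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napbind)
```

## Scope and model

Nucleoid-associated proteins (NAPs) of archaea and bacteria bind DNA
abundantly and without strict sequence specificity, shaping chromosome
architecture. ChIP-seq of such a protein does not yield sharp motif-centered
peaks; it yields broad, kilobase-scale enrichment zones with modest fold
enrichments (roughly 1–5x over input) whose positions track base
composition, in particular AT-rich intergenic neighbourhoods that harbour
promoter elements. `napbind` implements the downstream characterization of
such occupancy from called peak tables:

1. **Summit-window context classification.** For each peak the region from
   30 bp upstream through 30 bp downstream of the summit (60 bp; the summit
   base counts as the first downstream base) is intersected with the
   intergenic interval set. A window is classified *intergenic* when
   strictly more than 30 of its bases are intergenic, otherwise *coding*.
   The strictness matters at the boundary: exactly 30 bp of intergenic
   overlap is a coding call. A window wholly inside one class is flagged
   "fully in context".
2. **Fold-enrichment categories.** Peaks are grouped as *all*, *FE >= 2*
   (the boundary value is included), *top-k* and *bottom-k* by fold
   enrichment (k = 20 by default; ties broken by contig then start so
   category membership is deterministic).
3. **AT-content enrichment.** Per category and context, summit-window AT
   fractions are compared with a genomic background by a two-sided unpaired
   t test, Welch's variant by default (the two samples have unequal
   variances by construction: 60-bp windows versus whole intervals).
   Significance is flagged at p < 0.001. A seeded permutation test
   (p = (1 + k)/(n~perm~ + 1)) is available as a distribution-free
   companion.
4. **Structure of enrichment zones.** Peaks separated by at most a
   configurable gap (default 200 bp) merge into parent regions whose
   members are lettered a, b, c, ... in start order; covered genes are
   annotated by >= 1 bp overlap; fold enrichment is regressed on peak
   width (Pearson r with the least-squares line).

In vitro counterparts of nonspecific binding are quantified separately:
EMSA saturation titrations are fitted with the single-site isotherm
$\theta = [P]/(K_D + [P])$ (Hill variant optional) by Levenberg–Marquardt
least squares with a multistart over log-spaced $K_D$ initial values — the
estimate is reported as *apparent* because ladder-type multi-site binding
violates the model; AFM topographs are plane-levelled, thresholded,
segmented into 8-connected complexes, and summarized as maximum-height
bins (0–2, 2–4, 4–6, > 6 nm), the percentage exceeding a tall-complex
cutoff (12 nm), and prominence-based foci counts per complex.

## Coordinate convention

All internal coordinates are 1-based closed intervals, the
GenomicRanges/IRanges convention, so every interval operation runs on the
standard Bioconductor containers. File-format conventions are converted at
the boundary: GFF3 is already 1-based inclusive; BED and narrowPeak are
0-based half-open on disk (the narrowPeak summit is an offset from the
0-based start, converted to an absolute 1-based position on read). The
60-bp window of a summit at position $s$ is $[s-30,\; s+29]$.

## Background construction for the AT comparison

What constitutes "the genomic background" is genuinely open. Two
constructions are provided and tagged in the output:

* `per-region` (default): one AT value per intergenic (or merged coding)
  interval. This weights every region equally regardless of length and is
  the natural reading of "the AT content of all intergenic regions".
* `windows`: AT values of randomly drawn 60-bp segments from the
  background intervals (length-weighted, seeded). This equalizes the
  measurement unit with the peak windows and hence the sampling variance.

Comparisons are emitted context-matched (intergenic-classified windows vs
intergenic background; coding vs coding) and, additionally, pooled
(`all-vs-intergenic`, `all-vs-coding`): all usable windows of a category
against each background. The pooled rows exist because a strictly
AT-driven occupancy model yields very few coding-context calls, leaving
the matched coding row under-powered (fewer than two windows makes a row
"not computable" rather than an error).

No multiple-testing correction is applied across category/context cells;
each cell is reported with its raw two-sided p.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
exercised and tested; its defaults are fixed, not tuning dials.

* **Genome** (`genome_spec()`): one 200-kb contig, 160 non-overlapping
  genes of 500–1500 bp (~80% coding, the gene density of a compact
  archaeal genome), coding bases drawn i.i.d. with P(A or T) = 0.53 and
  intergenic bases with 0.62 — the composition contrast the analyses are
  designed to detect. Intergenic space is distributed over the 161 gaps
  with gamma-distributed weights (shape 0.3): most gaps are short
  inter-operon spacers while a few become kilobase-scale intergenic
  islands, the landscape on which kilobase enrichment zones can form. The
  independent-base model carries no dinucleotide structure, codon bias or
  repeats; conclusions about those features cannot be drawn from passing
  tests.
* **Occupancy** (`occupancy_spec()`): expected fold enrichment
  $E(x) = 1 + \alpha\,\mathrm{logistic}\!\big((AT_w(x) - m)/s\big)$ with
  amplitude $\alpha = 4$, midpoint $m = 0.62$, scale $s = 0.02$ and a
  200-bp centered moving AT fraction $AT_w$. The logistic link bounds
  enrichment (maxima land in the 3–5x range over this landscape); the
  midpoint at the intergenic AT target makes occupancy discriminate
  *among* intergenic neighbourhoods rather than merely between region
  classes, which is what couples called summits to locally AT-rich
  sequence. The 200-bp window is the scale of a protected binding patch;
  a much wider average (e.g. 500 bp) decouples occupancy from the 60-bp
  summit window and washes out the AT-enrichment signal the pipeline is
  supposed to detect, so 200 bp is the package default.
* **Coverage** (`sample_coverage()`): IP depth at each position is
  Poisson(depth $\cdot E(x)/\bar E$), input is Poisson(depth), default
  depth 30 per replicate, three replicates. Each replicate's stream uses
  a child seed derived deterministically from the master seed
  (LCG-style mixing of master and stream index), so adding a replicate
  never perturbs earlier ones.
* **Toy peak caller** (`call_toy_peaks()`): replicate-averaged tracks are
  smoothed (200 bp), the depth-normalized ratio (IP+1)/(input+1) is
  thresholded at 1.5, runs closer than 100 bp merge, runs shorter than
  200 bp are dropped; the summit is the leftmost argmax and the peak FE
  the mean over the run. This is a deliberately transparent segmenter for
  simulated tracks, not a reimplementation of a production peak caller.
* **Null model** (`random_peaks()`): a flat track (α = 0) correctly yields
  no called peaks at all, so null calibration uses uniformly placed
  summits with fluctuation-scale enrichments — exactly the peak
  distribution a biasless occupancy implies.
* **EMSA / AFM**: titrations follow the isotherm with additive Gaussian
  noise clipped to [0, 1]; topographs are sums of Gaussian bumps (one per
  focus, SD `sigma_px`) on an optionally rough background. Foci of one
  complex are spaced 3 SD apart by default — resolvable as separate
  maxima yet connected above typical thresholds, as foci of a single
  DNA–protein complex are; complexes are rejection-placed with a minimum
  separation and error out beyond a packing limit.

## Numerical and degenerate-input choices

* N bases never enter AT denominators; an all-N window yields `NA` and is
  excluded (with a warning) rather than counted as zero.
* Protein identity/similarity uses the five residue classes (basic K/R/H,
  acidic D/E, polar uncharged S/T/N/Q, hydrophobic A/V/I/L/M/F/Y/W,
  special C/G/P). The denominator — all alignment columns, gaps counting
  as mismatch — is recorded in the result; an ungapped-columns variant is
  selectable because published identity figures rarely state this choice.
* The t test requires n >= 2 per sample and errors on two zero-variance
  samples; a category/context cell that cannot be tested is flagged, not
  silently dropped.
* `fit_kd` reports `converged = FALSE` with diagnostics instead of
  raising; fits are scale-equivariant in concentration units.
* KD fitting assumes monomer concentrations in nM and at least four
  titration points spanning the transition.
* The width/enrichment correlation errors on constant inputs
  (undefined r) rather than returning NaN.
* Segmentation thresholds are in nm above the least-squares background
  plane (default 1 nm, minimum area 4 px); foci need 0.5 nm prominence
  and 3 px separation by default. Published instrument-software
  pipelines also correct scan-line artefacts; only plane-levelling is
  modelled here.

## Problem sizes used in the test suite

Tests run the full pipeline on single 200-kb simulated genomes, 100-seed
KD recovery at noise SD 0.05, 200-repeat null calibrations, and ~1200
randomized brute-force oracle comparisons for the interval operations —
sizes chosen so the whole suite completes in about two minutes while the
stochastic checks retain enough replication to be meaningful.

## Known limitations

* Replicate reproducibility ("a peak overlapping a called peak in every
  replicate, FE averaged") is one of several defensible definitions; it is
  recorded in the output metadata and should not be assumed to match any
  particular published pipeline.
* Subpeak merging is a parameterized reconstruction (default gap 200 bp);
  published parent/subpeak letterings depend on the original caller's
  internals and are not claimed to be reproduced.
* The AT-only occupancy model produces almost exclusively
  intergenic-context calls among strong peaks; real NAP binding has
  additional determinants, so matched coding-context comparisons on
  synthetic data are usually under-powered.
* Apparent $K_D$ values from ladder-type EMSAs are model-dependent
  summaries, not mechanistic affinities.
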