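---
title: "Stage-resolved epigenomics of meiotic DSB hotspots: models and methods"
author: "meiohot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved epigenomics of meiotic DSB hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiohot)
library(GenomicRanges)
```

## The biology and the model

Meiotic recombination starts with programmed double-strand breaks (DSBs)
made by SPO11 at hotspots positioned by PRDM9, which methylates H3K4 at
its binding sites.  Because spermatogenesis can be synchronized and
sorted into homogeneous stages — spermatogonia (Undiff, A1, B), meiotic
S phase (mpL), then leptotene (L), zygotene (eZ/mZ/lZ), pachytene
(e1P/e2P/mP) and diplotene (D) — the life cycle of each
hotspot-associated H3K4me3 peak can be read off a presence/absence
matrix over that stage order.  `meiohot` implements that reading:

1. **De novo vs common.** A peak at a target stage is *de novo* when it
   overlaps no same-mark peak at any configured prior stage, *common*
   otherwise.  For PRDM9-mediated H3K4me3 the pipeline defaults the
   prior list to the premeiotic stages (Undiff–mpL): peaks first
   appearing in leptotene must still count as de novo (PRDM9-mediated)
   at mid-zygotene, so leptotene is deliberately *not* among the
   priors.  `splitDeNovo()` itself keeps the fully general prior list.

2. **Hotspot association.** De novo peaks overlapping a DSB hotspot
   (SPO11-oligo cluster or DMC1-ssDNA peak, consumed as interval files)
   by at least 1 bp.  No overlap fraction is imposed — the "present"
   predicate everywhere is ≥ `minBp` shared bases (default 1), a
   configurable knob because the source analyses state none.

3. **Turnover classes.** Hotspot-associated mid-zygotene peaks are
   classified from their presence over (L, mZ, lZ, e1P): present in L →
   *early-forming*; absent in L and gone by lZ → *fast-turnover*;
   absent in L, present in lZ, gone by e1P → *slow-turnover*; absent in
   L and retained through e1P → *persistent*.  Reappearing patterns
   (e.g. 0 1 0 1) are labeled *unclassified* rather than forced into a
   class: only the four canonical patterns are biologically
   interpretable, and silently coercing anomalies would hide data
   problems.  The five labels always partition the reference set.

Interpretation, briefly: early-forming marks are the widest and
strongest and are associated with a crossover-competent chromatin
state, while fast-turnover marks are narrow and weak and track
noncrossover repair; the classifier itself is purely pattern-based.

## Coordinates and containers

Intervals live in `GRanges` (1-based, closed), the Bioconductor
convention; BED half-open input and output convert at the I/O boundary
(`readBed()`/`writeBed()`, with a `oneBased` dialect flag because
deposited peak files do not always declare their convention).  Overlap,
width and abutment semantics are identical to half-open arithmetic:
BED `[100,200)` and `[200,300)` abut and do not overlap.  Sex
chromosomes stay in the data model and are removed by an explicit
`autosomalOnly()` filter, applied by default at the pipeline level —
hotspot analyses are conventionally autosome-only because PRDM9 acts
differently on the sex body.

## The NDR caller

NOMe-seq reports two orthogonal signals from one bisulfite library:
WCG (ACG/TCG) cytosines carry endogenous CpG methylation, and GCH
(GCA/GCC/GCT) cytosines carry methylation deposited in vitro by a GpC
methyltransferase on accessible chromatin.  GCG/CCG sites are excluded
outright as ambiguous between the two signals.  Every site-level
statistic applies a 3× read-depth cutoff first; region statistics
require at least 3 covered sites (undefined, never zero, below that).

Nucleosome-depleted regions are called by scanning 100-bp windows at
20-bp steps.  Each window's pooled (methylated, unmethylated) GCH
counts are tested against the whole-genome pooled counts in a 2×2
Pearson χ² without continuity correction.  Two numerical choices are
worth stating:

* The "average level significantly higher than background" requirement
  is realized as a test on *pooled counts* with one-sidedness enforced
  by fiat — windows whose unweighted mean site level does not exceed
  the background mean get p = 1, as do windows with no covered site.
  Testing the mean of per-site proportions directly is not a χ²
  quantity; pooling is the standard realization, and the window mean is
  retained as the one-sidedness gate.
* The χ² statistic is computed vectorised in closed form (hundreds of
  thousands of windows per scan); `stats::chisq.test()` serves as the
  independent oracle in the tests, never as the implementation.

Significant windows (p ≤ 1e-10) merge when overlapping or bookended —
how windows become regions is otherwise unspecified, and bookended
merging is the minimal choice consistent with the 20-bp phase.  Merged
regions are NDRs when they contain **more than 5** GCH sites and are
**longer than 140 bp**, with both filters applied post-merge to the
merged interval.  Each NDR carries its minimum window p.  NDRs
overlapping a symmetric, strand-agnostic ±1.5-kb window around any TSS
(boundary inclusive) are *proximal*, otherwise *distal*.  A hotspot
lies "within" an NDR when its center base does.

Tightening `pMax` can only shrink the significant-window set, so NDR
sets are nested under threshold tightening (tested as a property).

## Signal tracks and spike-in normalization

Reads are represented by their 5′ position and strand, extended 150 bp
3′-ward (the average sonicated fragment length), clipped at chromosome
ends and piled up.  Track values are mean per-base depth per 50-bp bin,
so partial bins contribute fractionally and total mass (value × bin
width) equals the summed clipped fragment lengths exactly — the
conservation law the tests assert.  Region-anchored matrices (±5 kb,
50-bp cells, rows rankable by e.g. SPO11-oligo density) mark
off-chromosome cells as missing rather than zero so edge regions do not
dilute mean profiles.

Spike-in factors use the minimum spike count as reference
(factor·count = min count for every sample): scaling only ever shrinks
signal and never inflates sparse samples; a per-million mode exists.
H3K9me2 dips at hotspots compare the mean density inside a hotspot of
width w with the mean of its two 2w flanks and call a dip below ratio
0.5.  Read literally, "density less than twice the flanks" is almost
always true; the implemented rule — flanks at least twice the inside —
preserves the evident intent, and the threshold is exposed as a
parameter.  A flank truncated by a chromosome end is used at its
truncated span; a vanished flank leaves the other alone; hotspots with
no usable flank or zero flank signal are skipped with a warning.

Spatial association between two peak sets is tested by tiling the
genome into 1-kb bins, classifying each bin by overlap with either set,
and applying Fisher's exact test to the 2×2 bin counts.  The tiling
construction is the simplest spatial contingency table; bin size is a
parameter.  No multiple-testing correction is applied anywhere: the
workflow uses fixed thresholds (χ² P ≤ 1e-10, upstream peak-caller
cutoffs) by design.

## The synthetic-data generator

The generator defines the study conditions the package is validated
under, at desk scale:

* genome: three 2-Mb autosomes; 30 TSS; 120 hotspots with gamma
  (shape 4, scale 150) widths and heavy-tailed gamma (shape 0.8)
  strengths, all features spaced ≥ 6 kb so planted overlaps are
  unambiguous;
* turnover classes at 27/24/10/40 per class — the full-depth study
  ratio 2700/2369/1036/4032 scaled down 100-fold — with class width
  means 2000/800/1100/1400 bp (early > persistent > slow > fast), plus
  30 common promoter peaks at TSS across all stages and 20 non-hotspot
  de novo distractors at mid-zygotene;
* NOMe table: GCH sites every 10 bp at depth 3 + Poisson(7) (mean 10),
  background level Beta with mean 0.05, planted 400-bp NDRs at mean
  0.5; 14.2% of hotspots carry an NDR at their center and all hotspots
  are elevated threefold over background; WCG sites every 100 bp at
  mean 0.7, the typical endogenous CpG level;
* signal: 20,000 fragments per stage, 10% uniform noise, the rest
  placed in peaks proportional to strength × width; an H3K9me2 track
  with 80% depletion inside hotspots; spike counts uniform in
  5,000–20,000.

Each component draws from its own stream (a fixed offset of the master
seed), so adding a component never perturbs the others, and a seed
fully determines every emitted byte (`writeBundle()` manifests are
md5-checksummed and reproducible).

What the generator does *not* emulate: read-level sequence, bisulfite
conversion error, replicate batch effects, copy-number or mappability
artifacts, and the continuous (rather than planted-categorical)
turnover behavior of real peaks.  Passing tests therefore demonstrate
the correctness of the interval logic, the caller and the
normalization under the stated effect sizes — not performance on
full-depth sequencing data, whose headline counts require the original
deposited datasets.

One emergent property deserves note: because planted hotspots are
threefold more accessible than background, some hotspot windows
legitimately pass all three NDR criteria, so the full bundle yields
more NDR calls than were planted as discrete NDRs.  Planted-NDR
sensitivity and precision are therefore measured on a generator run
without hotspot elevation — exactly the stated recovery conditions
(inside 0.5 vs background 0.05, depth 10, spacing 10 bp) — where the
validation suite requires both to exceed 0.9 at the default
thresholds.

## Problem sizes and determinism

The default configuration (6 Mb genome, ~600k GCH sites, 300k scan
windows, 500-replicate null calibrations) was chosen so a full
validation run completes in minutes on a single core while keeping
every per-window statistic well within its asymptotic regime.  All
stochastic tests fix their seeds; the Fisher-null uniformity check uses
1600 small (100-bp) features per set against 1-kb bins so that bin
memberships are effectively independent and the discrete exact test is
near-continuous under the null.

## Known limitations

* The de novo definition is overlap-based only; peak-boundary drift
  between stages can split or merge peaks in ways a summit-based
  definition would not.
* The χ² window test assumes reads are independent across sites within
  a window; clonal artifacts would inflate significance (duplicate
  removal is upstream of this package's inputs).
* `fisherOverlapTest` treats bins as exchangeable; strong spatial
  autocorrelation of features wider than the bin size makes the exact
  test anti-conservative, so bin size should exceed typical feature
  width.
* The three-way overlap summary is reference-anchored (first set);
  peaks of other sets absent from the reference cannot be subdivided
  and are tallied separately.
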