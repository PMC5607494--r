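---
title: "Nucleosome organization in hypomethylated domains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome organization in hypomethylated domains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmdnuc)
```

# The biological question

Vertebrate genomes are globally CpG-methylated, with hypomethylated
domains (HMDs) concentrated at gene promoters. Chromatin inside these
domains is organized differently from the methylated bulk: nucleosome
arrays are phased off the domain boundary, their linkers are wider and
accessible to nucleases, and the widest linker — a nucleosome-depleted
region carrying the TSS — sits at the 5' edge. The analytical question
this package addresses is whether, and how, that organization is encoded
in the DNA sequence itself: can the positions of accessible linkers be
predicted from local k-mer content, are the predictive k-mers periodic,
and is the sequence preference aligned with or opposite to the classic
global nucleosome preference (GC-rich cores, poly(dA:dT) linkers)?

# The pipeline, stage by stage

## HMD calling

An HMD is a maximal run of at least `min_cpgs = 10` consecutive CpGs (in
genome order) whose methylation ratio is strictly below
`ratio_threshold = 0.4`. "Consecutive" means no intervening covered CpG at
or above the threshold; CpGs absent from the input (no coverage) neither
break nor extend runs, and an optional `max_gap` (off by default) breaks
runs across CpG deserts. The domain interval runs from the first to the
last CpG of the run, with the end at `last position + 2` so the final CpG
dinucleotide is covered. The threshold is deliberately strict (`< 0.4`,
not `<=`).

## Accessibility and summit calling

Cut positions (5' read ends) are shifted 50 bp toward the read's 5' side
(upstream for `+` reads, downstream for `-` reads; the opposite convention
is available via a flag because the upstream reading of "toward 5' side"
is a choice, not a certainty). Coverage is the per-base cut count smoothed
with a boxcar of 73 bp — half a nucleosome footprint, wide enough to merge
the two cut shoulders of one linker without bridging adjacent linkers —
scaled to counts per million.

Full peak-calling machinery (local background models, FDR control) is not
reimplemented; summits are local coverage maxima at least
`fold_enrichment = 5` times the global median of the nonzero signal,
selected greedily by height with a 100–150 bp exclusion radius. This is a
deliberate simplification: summit detection is infrastructure here, not
the contribution, and externally produced narrowPeak summits can be
supplied to every function that consumes summits.

## Boundary anchors and metaprofiles

Each HMD boundary is anchored at the in-domain summit nearest the boundary
CpG. Only HMDs with a TSS within 1 kb are used. The boundary is labelled
5' when the TSS nearest the anchor transcribes from the methylated flank
into the domain, 3' otherwise; ties in TSS distance break toward the
domain interior. Metaprofiles average a per-base track over `[-flank,
+flank]` windows around the anchors. Windows of boundaries whose domain
interior lies at lower coordinates are reversed, so the methylated flank
is always at negative offsets and the domain interior at positive offsets
for both boundary classes — this makes the 180-vs-200 bp spacing contrast
carry the same sign on both panels, at the cost of the 3' panel's x-axis
running against genomic coordinates (the alternative genomic convention is
one `orient = FALSE` away). Undefined track positions are excluded from
both the numerator and the per-offset count, never imputed as zero: a
metaprofile must not be diluted by unsequenced gaps.

## Spacing estimation

Average nucleosome spacing is read off the autocorrelation of the dyad
metaprofile, computed separately over offsets `0..1000` (HMD side) and
`-1000..-100` (methylated side). The estimator is the lag-by-lag Pearson
autocorrelation — each lagged segment re-centered and re-scaled — rather
than the denominator-n sample ACF. The two differ by a triangular taper
`(n-k)/n`, which is irrelevant for deciding *whether* the profile is
periodic but drags the *location* of the ACF peak 1–3 bp below the true
period at these window lengths; the Pearson form is exact at the true
period of a periodic profile (for a cosine of period 200, lag 200 gives
correlation exactly 1). Because the Pearson form re-normalizes every lag,
the 2x harmonic can tie with the fundamental on noisy profiles; candidate
peaks are therefore ranked by their taper-weighted height
`acf(k)·(n-k)/n`, which restores the fundamental's precedence while
keeping exact peak lags. The search window `[100, 400]` bp excludes the
trivial short-lag peak and higher harmonics; ties break toward the smaller
lag. A `confident` flag compares the peak against a white-noise bound
(`4/sqrt(n)`).

The 5' boundary gap is measured on the accessibility metaprofile as the
distance from the anchor (offset 0, the profile maximum) to the next local
maximum at positive offsets; a local maximum must dominate a +/-20 bp
window and have prominence of at least 10% of the boundary peak's height
over the profile floor, so noise wiggles on the inter-linker plateau do
not qualify.

## The k-mer SVMs

Sequences are represented by their k-mer spectrum (counts of all
overlapping k-mers on the forward strand, k = 6 by default), scaled to
unit Euclidean norm so that sequences of different lengths are comparable
— required for the HMD-vs-methylated classifier, harmless for the
fixed-length linker classifier. Reverse-complement pooling is off by
default: the analysis distinguishes a 6-mer from its reversal, so the
orientation of the spectrum matters; a collapsed mode exists as an option.

Two training-set constructions:

* **linker vs core**: positives are 100-bp windows centered on each
  in-HMD summit; negatives are 100-bp windows centered on the midpoint of
  each pair of adjacent in-HMD summits more than 150 bp apart (far enough
  apart that a nucleosome core must lie between them). Windows crossing
  the domain edge, and windows containing N, are dropped.
* **HMD vs methylated**: positives are whole HMD sequences shorter than
  3 kb; for each, ten intervals of identical length are placed uniformly
  at random on the methylated complement of the genome (placement is
  seeded and reproducible; candidates overlapping any HMD are rejected and
  redrawn). The 10:1 class imbalance is why precision-recall curves are
  reported alongside ROC.

The classifier is a linear soft-margin SVM (L2-regularized hinge loss,
`C = 1`) trained by dual coordinate descent in compiled code. The solver
is deterministic: examples are visited cyclically in a fixed,
class-independent order (sorted by origin coordinates), no shrinking, a
projected-gradient stopping rule at `1e-4`. Two consequences are used by
the test-suite: retraining with swapped class labels yields exactly
negated weights and bias (the visiting order is label-invariant and IEEE
negation is exact), and the decision values are by construction
`w·features + b`. The bias is realized as an augmented constant feature,
i.e. it is (mildly) regularized — standard for coordinate-descent linear
SVMs, and immaterial at these scales. Chromosome-level holdout is enforced
inside `train_kmer_svm`: sequences on the holdout chromosome never reach
the optimizer.

Scoring an HMD slides a 100-bp window at 20-bp steps; the score of each
20-bp step is the mean decision value of all (up to five) windows
overlapping it, so the score track is smoother than the raw window
decisions. Score-signal agreement per HMD is Pearson correlation with a
two-sided t-distributed P value (df = n-2), reported without
multiple-testing correction because the count of raw `P < 0.05` domains is
itself the summary of interest.

## Motif periodicity

The top-10 k-mers by signed weight are scanned (forward strand,
overlapping matches included) across each HMD; all unordered pairs of
occurrence positions *within the same HMD* contribute a distance.
Distances below 3 bp are excluded — they are dominated by overlapping
occurrences of near-identical k-mers (the planted motif's single-base
shifts rank highly too) — and distances above 1 kb are not informative for
nucleosome-scale periodicity. Bin width is 10 bp; neither the cap nor the
width is dictated by anything deeper than making a 200-bp mode resolvable,
and both are configurable.

## Hard-rod occupancy

Expected nucleosome occupancy under an equilibrium model of
non-overlapping 147-bp rods: a rod starting at position `i` has Boltzmann
weight `z·exp(-E(i))` with fugacity `z` (effective nucleosome
concentration) and a pluggable per-start energy `E`. Forward partial
partition sums `F[i]` (partition function of the first `i` bases) and
backward sums `R[i]` give the exact placement probability
`P[i] = F[i-1]·z·e^{-E(i)}·R[i+147]/Z` and per-base occupancy as the sum
of `P` over covering starts. All recursions run in log space
(log-sum-exp), so megabase inputs cannot overflow; rods must lie fully
inside the sequence. The package ships a GC-fraction energy model
(`E(i) = -w·GC(window)`, the classic core preference for `w > 0`) and a
tabulated per-k-mer loader for externally fitted parameters. The
published yeast-trained dinucleotide parameters are third-party data and
are not bundled; the inversion analysis (below) runs on the GC model.

# The synthetic world

The generator emulates the statistical structure the analysis assumes,
with one master seed feeding every track. Defaults describe a 5 Mb genome
(4 chromosomes of 1.25 Mb, the last held out for testing) with 200 HMDs
of uniform length 1–3 kb:

* **Methylome**: CpGs every 50 bp outside domains with Beta(8.5, 1.5)
  ratios (mean 0.85), every 25 bp inside with Beta(2, 18) ratios (mean
  0.1); the CpG dinucleotides are physically written into the sequence.
  Occasional high draws inside domains split a called HMD — a realistic
  imperfection that is left in.
* **Nucleosome geometry**: within each domain, accessible linker centers
  start one linker half-width (30 bp) inside the 5' boundary, step once by
  `boundary_gap_5p = 250` bp (the NDR), then every `spacing_hmd = 200` bp.
  Dyads sit on an exact 200-bp lattice phased off the downstream linker
  (`dyad = next linker - 100`), so the wide NDR does not shift the
  lattice. The methylated flanks carry boundary-phased dyads every
  `spacing_meth = 180` bp out to 1 kb, then randomly phased 180-bp arrays.
  Positional noise enters through read sampling (dyad reads ~
  Normal(dyad, 15 bp), ~20 reads per nucleosome), not through the lattice
  itself — a simplification; real arrays also jitter the nucleosomes.
* **Accessibility**: ~40 cuts per linker, Normal(center, 20 bp), emitted
  as 5' read ends offset +/-50 bp by strand so that the 50-bp shift
  recenters them; sparse uniform background cuts (1 per 500 bp).
* **Sequence**: uniform background composition (GC 0.5). Linker regions
  (+/-30 bp) inside domains are GC-rich (0.65), and one of five planted
  6-mers (`GCTAAC` among them) is written at each linker center with
  probability 0.8, never inside cores. The GC elevation is a stated
  property of the modelled system — the predictive linker 6-mers are
  relatively GC-rich, which is also what makes a GC-driven occupancy
  model peak at linkers (the "inverted" preference) — and it gives the
  linker classifier a compositional signal beyond the planted motif, as
  in the real data where many 6-mers carry weight.
* **Annotations**: one TSS at each 5' boundary linker, transcribing into
  the domain; SNPs at 0.01/bp genome-wide thinned to 0.002/bp in linkers.

What a green test does *not* establish: the generator has no sequencing
error, no mappability structure, no MNase digestion bias, no nucleosome
breathing or fuzzy positioning, no CpG-density gradients at domain edges,
and its background sequence is i.i.d. — k-mer SVM performance on real
genomes will be lower and more confounded (e.g. by nuclease sequence
bias, which the real analysis cross-checked with an orthogonal assay).
Parameter recovery here validates the estimators and the plumbing, not
biological effect sizes.

# Numerical and design choices

* 0-based half-open coordinates everywhere internally; 1-based formats
  are converted at the I/O boundary.
* Undefined signal (bedGraph gaps, chromosome edges) is `NA`, excluded
  from averages.
* SNP input is BED positions, not VCF: only positions are used.
* The linear SVM is solved in-package (deterministic dual coordinate
  descent) because no linear-SVM library is part of the supported stack;
  the contract is solver-agnostic — any optimizer reaching the
  soft-margin solution would do — and is enforced by behavioural tests
  (separable-set recovery, label-swap antisymmetry, decision-value
  self-consistency), not by solver internals.
* `compare_weights` tests the top-20 linker k-mers' HMD-model weights
  against **all** k-mers (unpaired two-sided Wilcoxon), matching the
  published comparison literally rather than excluding the overlap.
* Degenerate inputs: zero-variance score or signal flags the correlation
  as degenerate rather than erroring; summit plateaus resolve to their
  leftmost point; empty HMD sets yield empty, well-typed results.
* The white-noise confidence bound (`4/sqrt(n)`) is Bonferroni-flavoured
  for ~300 candidate lags; it is a flag, not a test statistic.
* Runtime: the default end-to-end pipeline is ~70 s on one CPU; the
  test-suite runs the default world once for the acceptance criteria and
  a 300-kb world for unit tests.

# Known limitations

* The summit caller is not FDR-calibrated; quantitative DHS counts on
  real data require a real peak caller (narrowPeak import is supported).
* `SVM_hypo` negatives are drawn genome-wide outside HMDs; no attempt is
  made to match local GC or CpG density, so on real data that classifier
  partly learns CpG-island composition — as its published counterpart
  arguably does too.
* Spacing estimates are integer lags; sub-bp refinement is out of scope.
* The occupancy module exposes fugacity as a free parameter; absolute
  occupancy levels are only meaningful relative to a calibration.
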