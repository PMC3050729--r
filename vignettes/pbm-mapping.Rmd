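---
title: "PBM-mapping: scanning genomes with 8-mer E-scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PBM-mapping: scanning genomes with 8-mer E-scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbmscan)
```

## The method

A protein binding microarray (PBM) measures a transcription factor's
binding to every possible 8-mer and summarizes each as an enrichment
score (E-score) `e(o)` in `[-0.5, 0.5]`, with `e(o) = e(revcomp(o))` by
construction.  Position weight matrices built from the same data assume
per-base contributions are independent and additive; homeodomain binding
violates both assumptions (flanking bases interact with the core), which
is why PWM scores predict relative affinity poorly.

PBM-mapping skips the matrix entirely.  The score of the locus whose
first octamer starts at position $i$ is the moving average of $W$
overlapping octamers,

$$S_i = \frac{1}{W}\sum_{k=0}^{W-1} e(s_{i+k..i+k+7}),$$

so a window covers $W + 7$ bases.  Maximal runs of windows with
$S_i > \theta$ are merged into predicted sites.  Because the E-score
table is reverse-complement symmetric, $S$ is strandless: scanning one
strand suffices, and `score_profile(revcomp(s))` is exactly the reversal
of `score_profile(s)` (property-tested).

## Parameters that matter

* `window` ($W$, octamers averaged; dimensionless count): default **7**,
  the largest number of overlapping octamers that still share one common
  base, which both covers flanking-sequence effects and averages down
  array noise.  Nuclear-receptor-class factors with a longer dimeric site
  (e.g. Hnf4α) work better with $W = 6$; the sweep utilities
  (`window_size_sweep()`) exist to pick $W$ per factor from binding
  measurements.
* `threshold` ($\theta$, on the E-score scale): default **0.37** for
  Nkx2.2-class homeodomains, calibrated against gel-shift confirmation of
  predicted sites; an initial working value of 0.34 admits weak sites
  that do not bind in vitro.  Thresholds differ per factor (Hnf4α scans
  use ~0.24–0.26) and are therefore recorded in every output header.
* `cutoff` for the core census: **0.45**, the conventional "high-affinity
  octamer" E-score cutoff.
* TSS windows: promoters are taken as −2500..+1000 bp around the TSS,
  strand-aware; the proximity-enrichment window defaults to 500 bp
  upstream.

## Core analytics

The census selects octamers above the cutoff (each octamer/reverse-
complement pair counted once), then assigns each to the first core in the
configured precedence order (`AAGT` before `GAGT`) that it contains on
either strand.  Precedence matters: an octamer containing both cores is
counted with the primary core, which is the only convention under which
the per-core counts partition the top set — an identity asserted on every
run.  Group significance uses a one-sided Welch t-test of core-containing
octamer scores against the all-octamer background; the test is a design
choice (the effect sizes involved make any reasonable location test
agree).

Dual-core octamers are the 8-mers whose two disjoint tetramer halves are
each a core or a core's reverse complement; "adjacent cores" admits
exactly this tiling in 8 bp.  Overlapping core placements are not
classified.  TSS-proximity enrichment uses Fisher's exact test on the
2×2 table (gene has / has no site within the window × cohort); the exact
test is our choice and is validated against full hypergeometric
enumeration for all tables with $n \le 20$.

## Affinity regression

Fraction bound $F$ relates to the dissociation constant through
$K_d = [\mathrm{ligand}](1-F)/F$.  Modelling occupancy as a linear
function of the mapping score, $F = ax + b$, gives

$$K_d = z\,\frac{1 - (ax+b)}{ax+b},$$

with the ligand concentration $z$ treated as a free scale parameter
(it is not known for published $K_d$ sets).  `fit_kd()` minimizes
least squares on the $K_d$ scale — matching how such fits are usually
produced — via Levenberg–Marquardt with 16 multi-starts: $z$ on a
log-spaced grid bracketing the observed $K_d$ range, and, for each, $a$
and $b$ seeded by regressing the implied occupancies $z/(z+K_d)$ on the
scores.  $r^2$ is reported on the $K_d$ scale, with the occupancy-scale
value exposed alongside.  Fits whose occupancy $ax+b$ leaves $(0, 1]$
over the data range are flagged as boundary solutions.

One identifiability caveat is worth knowing.  At zero noise the three
parameters are exactly recoverable (the package demonstrates relative
errors below $10^{-6}$ across 50 random parameter draws).  Under
realistic noise, when the observed occupancies span only a narrow band
(say 0.15–0.45), $b$ and $z$ trade off along the curve: the *curve* stays
accurate where there is data, but individual parameter estimates can move
20% or more.  Interpret fitted $z$ and $b$ with care unless the data
reach high occupancy.  Probes excluded as non-binders are carried through
to the output but never used in the $r^2$.

## What the synthetic generators emulate

`make_table()` builds a full 65,536-octamer table with: a planted primary
core (base score 0.42) and weaker secondary core (0.30), matched on
either strand with primary precedence; a deterministic per-position flank
term (edge positions weighted most) plus one pairwise interaction term,
so contributions are neither independent nor additive — the structure
that defeats PWMs; optional Gaussian noise; and exact reverse-complement
symmetry imposed by mirroring the lexicographically smaller member of
each pair *after* noise.  The manifest records the symmetrized noiseless
score of every octamer, so every downstream census is predictable without
re-running the generator.

`make_genome()` rejection-samples order-0 background (GC 0.41, the
mammalian genome-wide value) until no background window reaches
`threshold - margin`, then plants hill-climbed $(W+7)$-mers whose window
average lands within 0.008 of each target score.  Sub-threshold targets
(decoys) are additionally required to stay sub-threshold when embedded in
sampled context — a core at a segment edge can otherwise lift a junction
window over the threshold for any background.  After planting, the whole
genome is re-validated with the generator's own direct window-mean
computation (kept separate from the scanner under test): above-threshold
windows must coincide exactly with supra-threshold plants.

`make_probe_set()` hill-climbs whole probes toward evenly spaced mapping
scores and generates measurements from the package's own occupancy/Kd
identities, so zero-noise fits must recover the generating parameters
exactly.

What these fixtures do *not* emulate: the rank-based noise structure of
real E-scores (real tables have heavy tails and spatial artifacts),
higher-order sequence composition of real genomes (CpG depletion,
repeats, assembly gaps), and binding-site clustering.  Passing tests
demonstrate algorithmic correctness — window arithmetic, merging,
coordinate lifting, regression — not biological performance on real
arrays, which is what the opt-in `reproduce` harness is for when the
published PBM tables are supplied.

## Numerical choices and degenerate inputs

* Octamers are encoded 2 bits/base; profiles use a vectorized moving sum
  whose agreement with naive per-window recomputation is held to
  $10^{-12}$ (in practice ~$10^{-16}$: each window sum is an independent
  short dot product, so no drift accumulates along a chromosome).
* Any window containing a non-ACGT base is masked rather than scored —
  E-scores are defined only over ACGT — and soft-masked (lowercase)
  sequence is scanned by default with an opt-in `skip_masked` flag.
* Ties for peak window or peak octamer break leftmost, making all
  outputs deterministic; chunked chromosome scanning recomputes each
  window exactly once and is byte-identical to whole-sequence scanning.
* Strict table reading treats any octamer/reverse-complement conflict as
  an error; the default averages conflicting values with a warning, to
  tolerate rounding in published downloads.
* Sequences shorter than $W+7$ raise an error naming the minimum length;
  probes shorter than a full window report a max E-score but a flagged,
  undefined mapping score.
* BED output is 0-based half-open (as are all internal coordinates), with
  scores rescaled linearly from $[\theta, 0.5]$ to 0–1000 and strand "."
  because calls are strandless.

## Validation problem sizes

The shipped validation uses: 1,000 random sequence/table pairs for the
moving-sum oracle; 10 kb genomes with 5 planted sites for recall and
precision; 50 random parameter draws for zero-noise Kd recovery; all
10,625 possible 2×2 tables with $n \le 20$ for the Fisher check; and
20-probe sets for the window sweep.  These sizes keep the full suite
comfortably within a couple of minutes on one CPU while exercising every
code path; all of them are re-run from scratch by
`scripts/acceptance.R`.

## Known limitations

* E-scores are rank-based and saturate near 0.5, so mapping scores
  compress differences among the strongest sites.
* 8-mer data limits the usable window: $W > 7$ stops helping because the
  octamers no longer share a common base.
* Genome-scale scans produce millions of calls at permissive thresholds;
  the threshold is a per-factor calibration, not a universal constant,
  and the package deliberately refuses to guess it silently (every output
  records the threshold used).
* The comparison PWM scanner implements log-odds scoring only; building
  matrices from PBM data is out of scope.
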