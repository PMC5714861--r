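---
title: "Recombination landscapes and mapping resolution across population designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination landscapes and mapping resolution across population designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(recombkit)
```

## What the package models

Four segregating population designs dominate QTL mapping in maize: doubled
haploids (DH), recombinant inbred lines (RIL), the intermated design (IBM),
and the eight-founder multi-parent advanced generation inter-cross (MAGIC).
They differ in one key currency: how many meioses' worth of crossovers each
final line accumulates. That currency sets the number of recombination
breakpoints per line, the length of non-recombinant chromosomal segments,
the number and size of recombination *bins* (genome segments devoid of
recombination across a line set, whose boundaries are the pooled
breakpoints), and ultimately the physical resolution attainable by QTL
mapping with a given number of lines and markers.

recombkit provides a tested implementation of that whole chain: a
crossing-scheme simulator, marker-based breakpoint detection (with a founder
HMM for multi-parent data), population summaries, pooled-bin construction
under line/marker subsampling, power-law fits of bin statistics against
marker number, the closed-form resolution theory, and a null-phenotype LOD
scan experiment comparing support-interval lengths across designs.

## The meiosis model and the crossing schemes

Meiosis follows the Haldane model: per chromosome the crossover count is
Poisson with mean L/100 for genetic length L in cM (one crossover per
Morgan), crossover positions are uniform on the genetic scale and mapped to
physical coordinates by piecewise-linear interpolation of the marker map,
and the gamete alternates between the two parental homologs starting from
either with probability 1/2. There is no interference, no obligate chiasma
and no segregation distortion — deliberate simplifications: the quantities
of interest here are event *counts* and their downstream consequences, for
which the Poisson model is the standard null. A custom map with a flat
genetic stretch encodes a recombination-suppressed (e.g. pericentromeric)
region; crossovers then never fall in it, and the windowed frequency track
is exactly zero there.

The schemes are pedigree-faithful, each line an independent realisation:

* **DH** — one F1 gamete doubled; exactly one meiosis of crossovers,
  perfectly homozygous.
* **RIL** — F1 selfed for six generations (F7 lines); map expansion
  approaches the Haldane–Waddington factor of 2.
* **IBM** — F2s intermated to F3, F3s random-mated to F4, then two selfing
  generations to F6. (The historical intermated population used more
  intermating rounds; this package implements the two-round description the
  simulated comparisons are based on.)
* **MAGIC** — eight founders split into two sub-groups of four (randomised
  per line), pairwise F1s, within-sub-group F2 = F1 x F1, F3 = cross of F2s
  from different sub-groups, then three selfings to F6.

At the default genome (below) these defaults give mean events per line of
roughly 16 (DH), 31 (RIL), 36 (IBM) and 51 (MAGIC) — the qualitative
ordering reported for real SNP50-genotyped populations (16/41/72/86),
compressed because the real RIL/IBM/MAGIC material accumulated more
effective meioses than the minimal published pedigree descriptions encode.
Residual heterozygosity after finite selfing (about 1.6% of markers for F7
RILs, 12.5% for F6 MAGIC) is genotyped as missing and treated as *unknown*
throughout: inbred-line event bookkeeping counts parental switches only.

```{r}
spec <- maize_genome_spec()
map <- build_genetic_map(spec, 2000, placement = "random", seed = 1)
pop <- simulate_population("ril", founder_set(map), map, spec,
                           n_lines = 200, seed = 2)
summary(true_event_counts(pop)$events)
```

## Default genome and why 1,600 cM

The default genome is 10 chromosomes in B73-like length proportions
totalling 2,300 Mb — the genome-length constant used throughout the
resolution theory — and 1,600 cM. The genetic total is chosen so that one
meiosis carries on average 16 crossovers, anchoring the simulated DH mean to
the published DH value of 16 events per line. Both totals, and per-
chromosome lengths, are configurable through `genome_spec()`.

## Breakpoint detection and its conventions

Origin labels come from direct allele matching for biparental data
(heterozygous or missing calls are unknown) and from a hidden Markov model
for multi-parent data: hidden state = founder, emissions allow a symmetric
genotyping-error rate, and transitions between consecutive markers use the
Haldane recombination fraction r = (1 − e^(−2d))/2 spread uniformly over the
seven alternative founders, with inter-marker distances floored at 1e-6 cM
so transitions never vanish. Labels are the Viterbi path; forward–backward
posteriors are kept for QTL scans. On simulated MAGIC data with 2,000
markers and 1% genotyping error the per-marker founder accuracy exceeds
95%.

Detection scans consecutive informative markers per chromosome; each label
change is one breakpoint, *placed at the physical midpoint of the flanking
informative-marker interval* (the original analyses never state a placement
convention; the midpoint is the natural unbiased choice and all downstream
windowing uses it). Unknown runs never create or absorb events. By default
an isolated single-marker label whose informative neighbours agree is
re-labelled unknown before scanning (`smooth = FALSE` disables this): a
single mislabelled marker would otherwise inflate event counts by two, so
smoothing trades a small loss of genuine one-marker segments (rare at chip
density) for robustness to genotyping error.

Two invariants are enforced by tests rather than assumed: per line, segment
lengths tile the genome exactly (sum = 2,300 Mb to 1e-6 relative), and
segment count = breakpoints + chromosomes.

## Recombination frequency in cM/Mb

The windowed statistic is the fraction of (sampled) lines with at least one
breakpoint midpoint in a 2-Mb window, expressed as centiMorgans (fraction x
100) divided by the window width — the only reading of "ratio of
recombinant lines to total lines per 2 Mb" that yields cM/Mb. It caps at 50
cM/Mb for 2-Mb windows; terminal windows are normalised by their true
width. A line with two breakpoints in one window still counts once (lines,
not events, are counted).

## Bins, subsampling and the power law

A bin boundary is a *distinct breakpoint marker interval* pooled over
lines: two lines recombining between the same adjacent markers are
indistinguishable at chip resolution and merge into one boundary at the
interval midpoint. Bin number is therefore the pooled count of distinct
boundaries plus one bin per chromosome, and mean bin size is the genome
length divided by the bin number. `resample_bins()` redraws line subsets
(50/100/150/200 by default) and marker subsets (200–10,000), recomputing
origins on each marker subset, with R = 1,000 resamples by default (tests
run R = 200 for speed — a scaled-down Monte-Carlo, which only widens the
noise on means, not their ordering). Marker subsets are uniform
genome-wide and redrawn per resample; the original analysis does not state
a stratification, and uniform redrawing is the least-assumption choice.

Bin statistics against marker number follow a power law Y = m·X^n. The
fitter is an in-package Levenberg–Marquardt iteration on the untransformed
residuals (optionally weighted), initialised from log–log OLS, stopping at
a relative RSS change below 1e-10 or 200 iterations, with standard errors
from the Jacobian and t-based p-values; non-convergence is an explicit
status. On noise-free grids it recovers generating coefficients to 1e-8;
under 5% multiplicative lognormal noise on the 7-point marker grid the
exponent n is recovered with ~3% median relative error, but the prefactor
m — an extrapolation of the fitted line to X = 1 — carries ~9% median
relative error. That asymmetry is information-theoretic, not numerical:
no least-squares variant on seven noisy points identifies m to 5%, a limit
worth remembering when comparing published fitted prefactors.

A documented corollary of fitting rounded published coefficients: inverting
a bin-size formula at a 0.057-Mb target amplifies two-decimal rounding of
(m, n) by orders of magnitude, so published required-marker counts are
generally not recoverable from published rounded formulas (e.g. the DH
formula evaluates to ≈ 9.85e5 markers, not the printed 970,453).

## Closed-form resolution theory

With `a` mean events per line and X lines, pooled bin number ≈ a·X and mean
bin size ≈ 2300/(a·X) Mb. The gene-density target divides 2,300 Mb by
40,000 genes: 57.5 Kb, truncated to 57 Kb for reporting and used as 0.057
Mb when inverting (matching the published usage). Inverting the size
formula at that target with the published means a = 16/41/72/86 gives
2,522 / 984 / 560 / 469 lines — reproduced exactly by
`required_lines()` and recomputed by `scripts/acceptance.R`.

```{r}
resolution_summary(c(dh = 16, ril = 41, ibm = 72, magic = 86))
required_lines(c(16, 41, 72, 86), gene_density_bin_kb() / 1000)
```

## The map-resolution experiment

For each design, 200 lines are genotyped, origins assigned (HMM posteriors
for MAGIC), and 1,000 (tests: 200) independent standard-normal phenotypes
scanned by single-locus regression: LOD = (N/2)·log10(RSS0/RSS1), capped at
300 for perfect fits, with lines of unknown origin dropped per marker. The
cited joint composite interval mapping is deliberately replaced by this
plain scan — no covariate policy is published, and a resolution comparison
needs a *consistent* scan across designs more than it needs any particular
one. One QTL per chromosome per trait (the highest peak above threshold) is
called, with a support interval extending to the nearest flanking positions
where the LOD falls 2 below the peak, linearly interpolated between markers
and truncated at the terminal marker positions.

Thresholds: LOD 3 for biparental designs (the published rule). For MAGIC
the published rule is a "37th percentile" cutoff over the 1,000 traits; the
published count of 370 mapped QTL from 1,000 traits identifies the intended
reading as *the cutoff that admits the top 37% of traits*, i.e. the 63rd
percentile of the per-trait genome-wide maximum LOD. The fraction is
exposed as `magic_trait_fraction` (a data-driven cutoff is needed at all
because the 7-df multi-founder regression is not comparable to a 1-df scan
at a fixed LOD).

### What the experiment does and does not reproduce

The biparental resolution ordering is robust: pooled over three seeds the
mean 2-LOD support intervals come out ≈ 45 Mb (DH) > 26 Mb (RIL) > 22 Mb
(IBM). Two caveats are part of this package's own findings, both visible in
the test suite:

* **MAGIC does not come out narrower than IBM** under these conditions
  (≈ 24 Mb). The multi-founder scan's null LOD baseline is (7/2)·log10(e)
  ≈ 1.5 rather than ≈ 0.22, so a 2-LOD decline from a percentile-threshold
  peak is a far smaller excursion relative to the process mean and support
  intervals widen for purely distributional reasons. The published MAGIC
  advantage rides on machinery (joint CIM, kinship regression, 54k markers,
  and a higher real event count of 86/line) that is outside this package's
  scope. The corresponding acceptance test asserts the full published
  ordering and documents this gap by failing its final step.
* **Marker density and interval length interact with interpolation**: a
  sparser map linearly interpolates a convex LOD decay and crosses the
  2-LOD target *early*, so sparse-map intervals can come out narrower even
  though localisation is worse. Density reliably improves peak-position
  accuracy (tested), not interpolated interval length.

Planted-QTL behaviour is calibrated rather than assumed: a locus explaining
50% of variance in 200 DH lines is covered by its 2-LOD interval in ≥ 90%
of replicates.

## Determinism and numerical choices

Every stochastic function takes a seed and uses an isolated RNG scope;
`run_pipeline()` derives per-stage seeds from one global seed and writes a
manifest of md5 checksums that is byte-identical across reruns. Other fixed
choices: physical coordinates are Mb in 0-based half-open segments;
BED/bedGraph output converts to integer base pairs; HMM emission
probabilities are floored at 1e-300 and zero-probability observations
renormalised; the LM fitter treats a stalled step search at finite RSS as
convergence at a local optimum; genome genetic lengths may be zero (a
never-recombining chromosome) but physical lengths must be positive.

## Known limitations

No crossover interference, sex-averaged maps only, no segregation
distortion or selection during inbreeding, biallelic markers only, one QTL
per chromosome per trait, and the single-locus scan caveats above. The
simulator emulates pedigree structure and marker noise, not real maize
haplotype diversity, hotspot architecture or ascertainment of chip markers —
passing tests demonstrate internal correctness of the methods and the
theory's self-consistency, not agreement with any particular real dataset.
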