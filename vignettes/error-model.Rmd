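---
title: "The lithoseq error model: photochemistry, coupling chemistry and profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The lithoseq error model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lithoseq)
```

# Overview

`lithoseq` models light-directed (maskless array) DNA synthesis as a
stochastic process on the coupling cycle and estimates its error channels
from sequencing-style reads. This vignette records the model, its
assumptions, the tunable parameters and their defaults, the numerical
conventions, and what the synthetic-data generator does and does not
emulate.

# The synthesis model

## Cycle mechanics

Bases are flowed in the fixed order A→C→G→T, repeating. A sequence is
synthesised 3'→5'; each base waits for its next slot in the flow order, so
consecutive bases are separated by a *wait number* of 1–4 cycles
(`wait_number()`, `cycles_required()`). The photomask stack
(`generate_masks()`) turns a feature's mirrors ON exactly at the cycles
where its next unsynthesised base matches the flowed base; decoding ON
cycles back to bases is an exact inverse (`decode_masks()`), a property the
test suite exercises on random panels.

## Photochemistry

Photodeprotection is first-order in radiant exposure:
yield(E) = 1 − exp(−kE). The rate constant defaults to the value that
gives 95 % yield at 3 J/cm² (`calibrate_photolysis_rate(0.95, 3)`,
k ≈ 0.9986 per J/cm²), which doubles to 99.75 % at 6 J/cm² — the
diminishing-return trade-off that makes the 5 % deletion regime a
deliberate operating point rather than a failure.

An OFF feature receives stray dose per exposure event:

```
dose = E_nominal * ( g * f_ON                        # global scatter
                   + side_leak   * n_side_ON / 4     # diffraction leakage
                   + corner_leak * n_corner_ON / 4
                   + reflection term )
```

* Global scatter is proportional to the ON-mirror fraction `f_ON` of the
  current mask — less dense layouts scatter proportionally less, which is
  why a 44 % → 11 % density drop cuts scatter-driven insertions about
  four-fold. The coefficient `g` is not directly measurable; it is
  calibrated by `calibrate_scatter()`, which fits the observed insertion
  rate as baseline + slope·g from pilot simulations (the baseline — leak,
  reflection, noise — is measured once at g = 0).
* Side/corner leakage defaults (0.5 % and 0.05 % of nominal dose with all
  neighbours ON) model cumulative diffraction into adjacent features; the
  per-neighbour contribution is the quarter-share of that cap.
* Reflection is a uniform extra dose over a configurable rectangle,
  optionally active only after a fraction of the run — the signature of a
  UV-absorber backfill evaporating and exposing a corner late in
  synthesis, which raises 5'-end insertion rates only there.

Illumination varies across the array as 1 − a·r^b with r the normalised
Euclidean radius (corners at r = 1; defaults a = 0.1, b = 4 give a flat
centre with fall-off only near the border). The radius is Euclidean rather
than max-norm so that edge midpoints are strictly brighter than corners,
matching the observed ordering centre > edge > corner; the *concentric
areas* used for spatial summaries (`concentric_area_of()`) remain
rectangular rings in max-norm, as spatial figures are conventionally drawn.

## Chemistry

Stochastic steps per molecule and cycle, in order: exposure (ON features
at the illumination-scaled nominal dose, OFF features at the stray dose);
coupling of the flowed base by any free 5'-OH anywhere in the cell
(defaults: A/C/T at 99.95 %, G at 99.7 % — G is the least efficient
phosphoramidite); optional capping of a still-free terminus (99.9 %);
optional irreversible blocking (default 0, a stand-in for chain loss by
degradation or dead mirrors — no quantitative rate is available for it, so
it stays a free parameter). Oxidation and all other cycle steps are
treated as ideal: deprotection, coupling, capping and blocking are the
identified error channels, and adding noise elsewhere would only blur the
parameter-recovery mapping.

A free terminus persists across cycles until coupled, capped or blocked —
this memory is what produces the wait-number effect: the more exposure
events between two scheduled couplings, the more chances a stray
deprotection has to insert a base.

These mechanics produce each observable:

* missed ON-cycle deprotection → the base is skipped when the next
  coupling succeeds → deletion;
* stray OFF-cycle deprotection → the flowed base couples out of schedule →
  insertion, increasing with wait number;
* failed coupling, uncapped → the next flowed base rescues the terminus →
  cycle-order substitution (G→T dominant). When the next *reference* base
  equals the rescuing base, the same failure yields one coupling for two
  scheduled slots and reads as a deletion instead — the masking effect the
  corrected efficiency estimator accounts for;
* failed coupling, capped → truncation.

## Randomness and reproducibility

One master seed; a per-feature stream is derived as
`(seed + feature_index * 1000003) mod (2^31 - 1)` and molecules are
vectorised within the feature, so results are independent of feature
iteration order and bit-reproducible for a fixed seed. Sequencing noise
(default 5 × 10⁻⁴ per base, uniform over the three alternatives) is applied
to finished reads from a separately derived stream.

# Panel design

`design_library()` uses randomised generation with repair: bases are
sampled under the homopolymer cap (default max run 3, including junctions
with the constant 5'/3' handles), duplicates are resampled, and k-mers
below the coverage floor are greedily patched into random oligos, bounded
by a retry budget. The generation algorithm is a package choice — only the
constraints (coverage floor, homopolymer cap, uniqueness) are externally
given.

When k exceeds the homopolymer cap, k-mers that themselves contain a
forbidden run cannot occur in any compliant library; the coverage floor
therefore applies to the admissible k-mers only. For k ≤ cap this
distinction vanishes. Coverage is counted on variable regions only, as
per-oligo presence (not per-occurrence), and k-mers spanning into the
constant handles are not credited.

# Alignment and event classification

Reads are aligned to their intended references by a global affine-gap
aligner (Gotoh, in C++): match +1, mismatch −2, gap open −4, gap extend −1
(a gap of length L costs open + L·extend). Tie-breaking is deterministic —
substitution preferred over indel, and indels left-normalised within
homopolymers after traceback. The test suite proves score equality against
an independent brute-force recursion oracle and against
`Biostrings::pairwiseAlignment` on short pairs.

**Truncations.** Synthesis runs 3'→5', so a capped or blocked molecule is
missing a *prefix* of the 5'→3' reference. After the optimal global
alignment is computed, the leading deletion run is reclassified as a
soft-clip and excluded from both numerator and denominator of every rate.
This is done post hoc rather than via a free end-gap state in the DP
because a free leading gap distorts scores and converts genuine left-edge
deletions into clip+mismatch combinations. The consequence is the intended
one: capping changes substitution rates but leaves deletion and insertion
rates essentially unchanged. The cost is a small systematic deletion
undercount (a missed 5'-terminal coupling is indistinguishable from a
length-1 truncation, ~0.08 percentage points at 5 % deletions on 67-mers).

**Alignment ambiguity.** Under affine scoring, two single deletions
separated by one matching base can score below one two-base deletion run
plus a mismatch, so a few percent of deletion *pairs* are reported as a run
plus a spurious substitution (deletion counts are conserved; match counts
drop). This inflates the substitution floor when deletions are frequent —
the same class of artefact that makes real per-position profiles show
alignment-driven structure — and it is why stepwise-efficiency estimation
is calibrated in a deletion-free regime.

**Readability.** Reads with alignment identity (matches over non-clipped
reference positions) below `min_identity` (default 0.5 — no external
threshold exists, so this is a package default) are excluded from rate
denominators and surface as unreadable counts and spatial blobs
(`detect_unreadable()`, 4-connected components with bounding boxes).

# Rates and estimators

All rates are percentages per reference bp of readable alignments, so
total = deletion + insertion + substitution exactly, and the read-weighted
mean over the spatial map reproduces the global rates identically.

Deletion run-length classes x1/x2/x3+ are reported both run-counted and
base-counted; base-counted is the default because the three classes then
sum to the total deletion rate, which is how a rate table stays internally
consistent. The independence benchmark `predicted_run_rate(p, L) = p^L`
(e.g. 0.16 % doubles at a 4 % single rate) is the yardstick against which
excess correlated deletions are judged.

The stepwise coupling-efficiency estimator reads the X→next(X)
substitution rate from the match matrix: naive = 100 − rate. The
corrected estimator divides the observed rate by the probability that the
base synthesised after X (its 5' neighbour in the reference) differs from
next(X), because when they coincide the failure is absorbed as a deletion
and the substitution channel under-reports. The estimator is invalid under
capping (the substitution channel is suppressed by design); the function
warns and returns the naive column only.

Insertions of length L count L bases toward the insertion rate but one
record toward the wait-number histogram; insertions at sequence ends have
no complete flank pair and are excluded from the histogram. Per-cycle
attribution of an insertion uses its 3'-flank base (the coupling after
which the stray event occurred).

# What the generator emulates, and what it does not

The generator reproduces the mechanisms this package exists to quantify:
photolysis-limited deletions, density- and wait-dependent stray-light
insertions, cycle-order substitutions with base-specific coupling, capping
truncations, correlated multi-deletions via blocking, spatial illumination
structure, and a flat sequencing-noise floor. It does not model PCR
amplification bias, adapter chemistry, read-quality scores, paired-end
merging, or sequence-dependent secondary-structure effects; real libraries
also show an alignment periodicity artefact near homopolymeric handles
that is deliberately not reproduced. Passing the recovery tests therefore
shows that the profiler correctly inverts the generator's mechanisms at
realistic rates — not that every feature of wet-lab data is captured.

Default study conditions for recovery runs: 200 features × 500 molecules
of 67-mers on a 2SZ layout (full 1024 × 768 DMD geometry), flat
illumination and no stray light unless the contrast under test requires
them. At those sizes the whole recovery suite runs in well under a minute;
problem sizes in the unit tests are chosen as the smallest that leave the
tested contrast several Monte-Carlo standard errors wide.

# Numerical conventions and degenerate inputs

Coordinates are 0-based (row, col), row-major, origin top-left; cycles are
0-based starting at A. 2SZ/4SZ feature grids are anchored at the origin
with leftover border mirrors unused. Masks are written as plain-text P1
PBM, ON = 1 (black), one file per cycle. Empty reads align as all-deletion
(or all-clip) events and fall below the readability threshold; zero-read
features are flagged missing rather than given rates; a zero denominator
is an error. The DMD default is 1024 × 768 (the XGA format; full density
786 432 features). The mirror gap default is 1 µm; diffraction-limited
resolution is not computed by this package.

# Known limitations

* The substitution floor under heavy deletions is alignment-driven and
  slightly inflates off-diagonal substitution entries; efficiency
  estimates from such data are conservative (biased low).
* Stray dose is accounted at feature granularity, not per mirror, so
  within-feature dose gradients (e.g. brighter feature interiors) are not
  modelled; the 4SZ-vs-2SZ deletion difference attributed to that effect
  is outside the model.
* `min_identity`, `min_reads`, the homopolymer cap and the blocking rate
  are package defaults without external calibration; conclusions that
  depend on them should be checked for sensitivity.
* The unreadable-blob detector is a proxy for visually identified failed
  regions, not a reproduction of any particular instance.
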