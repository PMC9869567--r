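---
title: "Statistics of ligand-induced DNA melting bubbles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistics of ligand-induced DNA melting bubbles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bubblecov)
```

## The model

Dinuclear copper complexes coordinate to two adjacent phosphate groups on
one strand of double-stranded DNA. Under dehydrating conditions the bare
helix contracts from the B form towards the denser A form; a strand coated
with complexes cannot contract where consecutive complexes *alternate
between the two strands with a one-base-pair offset* (antiphasic or
"zigzag" packing), because the braced backbone sections overlap. The
resulting tensile stress preferentially dehybridizes the weaker AT base
pairs, producing locally melted "bubbles" observable by atomic force
microscopy (AFM).

`bubblecov` models the statistics of this mechanism with three independent
ingredients and their combination:

1. **Adsorption** — random sequential adsorption (RSA) of dimers on two
   independent single-strand lattices;
2. **Sequence** — maximal AT-run statistics of the genome;
3. **Combination** — the portion of a strand where an antiphasic passage
   coincides with consecutive AT pairs, which is where the model predicts
   dissociation;
4. **Measurement** — conversions and summaries that make AFM observations
   comparable with the three curves above.

All four produce *coverage curves*: the percentage of a strand's contour
length covered by qualifying segments of length at least a threshold.

## Random sequential adsorption and jamming

Each strand is an array of binding spots (one per base pair). A molecule
occupies two adjacent free spots; deposition is irreversible and uniform
over all currently feasible adjacent free pairs; it stops at *jamming*, when
no adjacent free pair remains. The implementation draws a uniform random
permutation of the bonds and places a molecule whenever both spots of a bond
are still free — equivalent to uniform-over-feasible sequential deposition,
because a bond that is blocked once stays blocked.

Two classical results anchor the simulator and serve as test oracles:

* the expected vacancy count on a finite lattice of $n$ spots obeys
  $v_n = \frac{2}{n-1}\sum_{j=0}^{n-2} v_j$, $v_0 = 0$, $v_1 = 1$
  (`expected_jamming_vacancies()`); for $n = 3$ the vacancy fraction is
  exactly $1/3$ and for $n = 4$ exactly $1/6$;
* as $n \to \infty$ the vacancy fraction tends to $e^{-2} \approx 0.1353$.

```{r jamming}
expected_jamming_vacancies(c(3, 4)) / c(3, 4)
lat <- simulate_jammed_adsorption(48502, seed = 1)
occ <- occupancy(lat)
(sum(!occ$a) + sum(!occ$b)) / (2 * 48502) # close to exp(-2) = 0.1353
```

The two strands are filled independently: the complexes bind phosphates of
one strand only, and no cross-strand exclusion is part of the model.

## Zigzag bookkeeping

After deposition each molecule is reduced to a marker at its left spot.
A **zigzag segment** is a maximal run of consecutive spot indices at which
*exactly one* of the two strands carries a marker. Inside such a run the
markers automatically alternate strands (two markers on the same strand
cannot occupy adjacent indices — the molecules would overlap), so the run is
precisely an antiphasic passage. A run ends at an index where both strands
carry a marker (in-phase packing) or where neither does (molecule bodies or
vacancies). The bp extent of a segment is its marker span, so a passage of
$k$ molecules covers $k$ bp, and the default qualifying threshold is
**3 molecules** (at least three adversely packed complexes, spanning three
base pairs).

This reading is one of several consistent ways to turn the verbal rules
into code, and the choice matters quantitatively. Conventions we examined:

* requiring a fourth molecule per passage (thresholding at $k \ge 4$)
  removes the large population of three-molecule passages and lowers the
  coverage by several percentage points;
* counting the full molecular footprint ($k+1$ spots) instead of the marker
  span raises it by a similar amount;
* additionally requiring each marker's opposite spot to be occupied
  ("braced" edges) trims segment ends and lowers coverage substantially;
* stopping deposition before true jamming (e.g. a fixed number of random
  attempts rather than exhaustion of free pairs) lowers the curve
  continuously with the attempt budget — at jamming the coverage is maximal.

The package's canonical convention is the one described at the top of this
section (marker-span extent, a 3-molecule default threshold exposed as a
parameter, deposition always to jamming) because it follows directly from
the marker reduction, keeps
"molecules = base pairs", and preserves the jamming invariant that the test
suite asserts on every replicate (no adjacent vacancy pair). Under it, the
mean coverage by passages of $\ge 3$ molecules on 48,502-spot strands is
**41.8 % ± 0.05 (se, 100 replicates)** — the value
`scripts/acceptance.R` recomputes. Reference analyses of this system have
quoted values a few points lower; the list above documents which readings
move the number in which direction, and the under-saturation sensitivity is
the most plausible source of such differences, but we do not adopt any of
those variants because each either violates the stated deposition endpoint
(jamming) or breaks the molecule/base-pair correspondence.

## AT runs and the closed form

A sequence is reduced to a logical AT mask (`at_mask()`); maximal runs of
AT positions are extracted per record and never bridge records, because
separate FASTA records (e.g. restriction fragments) are physically separate
strands. Coverage uses the full strand length as denominator — the curves
describe contour length, not AT content.

For an independent-base model where each position is AT with probability
$p$, the fraction of positions lying in maximal runs of length $\ge t$ has
the closed form

$$C(t) = 100 \cdot (1-p)^2 \sum_{L \ge t} L\,p^L = 100\,p^t\,(t - (t-1)p),$$

implemented as `expected_at_coverage()`. At $p = 0.5$ this gives exactly
**37.5 %** for $t = 2$ and **25 %** for $t = 3$. The threshold is exposed
explicitly everywhere; the 2 bp convention is the operative one for the
37.5 % figure ("more than two subsequent AT pairs" taken as runs longer than
two *hydrogen-bonded positions*, i.e. length $\ge 2$), which the acceptance
suite verifies empirically on lambda-scale synthetic genomes.

A useful analytic corollary: for a stationary two-state Markov chain with
AT fraction $p$ and AT self-transition $a$, coverage at $t = 2$ equals
$100\,p\,a(2-a)$. Requiring 37.5 % at $p = 0.5$ forces $a = 0.5$, i.e.
independence — so for this statistic a Bernoulli(0.5) genome is not merely
a convenience but the model class the 37.5 % figure itself selects.

## The combined curve

Zigzag segments are split at every GC position inside them
(`combined_segments()`); pieces inherit the alternation property, their
molecule counts are recomputed, and the same molecule-count threshold is
applied afterwards. Splitting before thresholding is the stricter order and
matches the view of GC pairs as additional exit conditions for a passage.
The combined coverage is bounded by both marginals — an invariant asserted
replicate by replicate in the tests. On a Bernoulli(0.5) genome at study
scale it evaluates to about **7.3 % ± 0.02 (se)** at threshold 3.

## Measurements

* `derive_scale(1.42, 2)` — the mean interval between bound-complex
  protrusions (1.42 nm) spans two neighbouring phosphate–phosphate
  distances, giving **0.71 nm per bp**; all nm↔bp conversion flows through
  this `conversion_scale` object.
* `nm_to_bp()` keeps both raw (fractional) and rounded bp lengths. Rounding
  is half-up; raw values feed the curves, rounded values the histograms
  (1 bp bins). Non-positive measurements are flagged per entry rather than
  failing the batch.
* `bubble_coverage_curve()` flags its 1 bp bin: bubbles below the visual
  counting threshold of the AFM analysis are systematically missed, so that
  bin under-counts by construction.
* `distance_stats()` returns mean, sample SD and a fixed-width histogram
  (default 0.2 nm bins, matching the granularity of the measured distance
  distributions).

Observed quantities — the ~12 % dissociated contour fraction, the 1.42 nm
protrusion interval, the 2.38 nm and 2.94 nm groove pitches — are
*experimental* numbers. The package never recomputes them from images
(image analysis is out of scope); they enter only as fixture parameters for
parameter-recovery tests of the measurement and generator code.

## Synthetic data

`generate_genome()` draws AT/GC classes independently (default) or from a
first-order Markov chain parametrised by the stationary AT fraction $p$ and
the persistence $a = P(\mathrm{AT}\to\mathrm{AT})$; the GC→AT rate is then
$p(1-a)/(1-p)$, keeping $p$ stationary, and $a = p$ recovers independence.
Defaults ($p = 0.5$, independence, 48,502 bp) emulate a bacteriophage-λ-like
genome. The Markov option exists because real genomes can cluster AT runs
beyond independence; as shown above, the 2 bp coverage statistic itself is
consistent with independence at 50 % AT, but other thresholds and other
genomes need not be — which is exactly what passing tests on synthetic
genomes do *not* establish about any particular real sequence.

`generate_bubbles()` draws lengths uniformly on 1–8 nm by default (the
observed range of dissociated sectors); normal (truncated at zero by
resampling) and degenerate families are available since the true length
distribution is not identified. `generate_distances()` uses a
truncated-at-zero normal, matching the roughly unimodal measured
distributions.

All generators and the simulator take explicit seeds via
`withr::with_seed`, leaving the caller's RNG state untouched; the pipeline
derives per-replicate, per-record seeds from one master seed by a counter
scheme recorded in the run manifest, so every result is bit-reproducible.

## Numerical and design choices

* Coordinates are 0-based, half-open everywhere; `length` columns make the
  tables self-describing.
* Coverage denominators are full strand lengths; multi-record inputs pool
  length-weighted.
* End runs (touching position 0 or the last position) count as maximal
  runs; excluding them would bias short fragments.
* Degenerate inputs fail loudly: empty FASTA, header-only records,
  non-{A,C,G,T,N} characters, zero total lengths, non-positive thresholds,
  lattice shorter than one molecule.
* Test problem sizes: property tests run on strands of 200–5,000 spots and
  genomes of 10–100 kb; study-scale checks use the full 48,502 bp strand
  with 100 replicates (Monte-Carlo standard errors ≈ 0.05 percentage
  points at threshold 3).

## Limitations

* The adsorption model is purely statistical: no cooperative or anisotropic
  stacking energetics, no desorption or equilibrium rearrangement, no
  helical geometry.
* The combined condition requires AT at *every* position of a piece (split
  at each GC); a majority-based reading would give larger pieces.
* Synthetic genomes lack the long-range compositional structure of real
  genomes; conclusions at thresholds other than 2 bp transfer only to the
  extent the independence model does.
* AFM image processing (drift correction, skeletonization, persistence
  length) is out of scope; measured lengths and distances are consumed as
  plain numeric tables.
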