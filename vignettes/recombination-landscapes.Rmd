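---
title: "Calling crossovers and comparing recombination landscapes in F2 populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling crossovers and comparing recombination landscapes in F2 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xoscape)
```

## The problem

In a large-genome cereal such as barley, meiotic crossovers (COs) are not
spread evenly along chromosomes: they concentrate in the distal, gene-rich
ends while the pericentromeric third of each chromosome barely recombines.
Perturbations of meiotic genes (helicases such as RTEL1, among others) can
redistribute COs without changing their total number, and detecting such a
redistribution requires genotyping an F2 population at thousands of markers,
calling each individual's COs, building a genetic map anchored to physical
coordinates, and comparing where on the chromosome the map length sits in
two populations.

`xoscape` implements that entire chain for F2 genotype matrices from a fixed
SNP array, together with a meiosis simulator so that every stage can be
validated against a known truth.

## Crossover calling

Along each individual's chromosome (markers in physical order), a crossover
is declared whenever the genotype call changes between two consecutive
informative markers — parental homozygote to heterozygote, or the reverse. A
switch directly from one parental homozygote to the opposite one implies a
crossover in each of the individual's two gametes and is scored 2; every
other valid change is scored 1.

Array miscalls would inflate this count badly, so a change is accepted only
if it is *maintained*: the `window` (default 3) informative calls ending at
the left marker must all equal the left call, and the `window` informative
calls starting at the right marker must all equal the right call. An
isolated singleton switch therefore never produces an event.

Two boundary questions are not dictated by the counting rule itself, and
both are exposed as options:

* **Missing calls.** By default (`missing_policy = "skip_missing"`) missing
  calls are removed before windowing, so the window counts informative
  markers and an event is reported at its flanking informative markers.
  This automates what is otherwise a manual correction of missing-data
  effects inside the window. The alternative `"strict"` policy treats a
  missing call as breaking the window (the transition is simply not
  called), which is useful for sensitivity analysis.
* **Chromosome ends.** Within `window` markers of an end, the default
  (`end_rule = "truncate"`) requires only the markers that exist on that
  side (at least one). The strict alternative discards such transitions.
  Truncation is the default deliberately: distal COs are exactly the signal
  of interest in a distally concentrated landscape, and a strict rule is
  blind there.

Two valid transitions closer than `window` markers apart are both reported
if each independently satisfies its own (possibly overlapping) window; no
merging heuristic is applied. A HET-to-HET "change" does not exist (no
change of allele), which also means a double crossover event in which both
gametes recombine in the same marker interval with opposite phases is
invisible in principle — only the homozygote-to-homozygote case is
detectable, and it is what the score of 2 encodes.

The production caller is implemented over run-length encodings of the
condensed call sequence; its agreement with a literal transcription of the
rule is checked exhaustively over every call sequence of length up to 8 and
on random length-12 sequences in the test suite.

## From crossovers to a genetic map

For each consecutive marker pair the recombination fraction is

\[ r = \frac{\text{summed crossover scores in the interval}}
           {\text{individuals with data at both flanking markers}} , \]

and the interval's genetic distance follows the Kosambi map function

\[ d(\text{cM}) = 25 \,\ln\!\frac{1 + 2r}{1 - 2r} . \]

Note what this `r` is: each F2 individual carries **two** meioses, and no
division by two or maximum-likelihood F2 estimator is applied. The genome
total therefore estimates *twice* the per-gamete genetic length, which is
how such F2 map totals are conventionally printed; the parameter-recovery
test asserts exactly this factor of two. Intervals with `r >= 0.5` are
clipped to 0.49999 with a warning rather than extrapolated; intervals with
no informative individuals are recorded as missing and excluded from totals.

An event whose flanking informative markers are not physically adjacent
(missing calls in between) is assigned to the single interval containing
the physical midpoint of its flanking pair — an unbiased choice that keeps
interval totals integer-weighted.

Two presentation details are intentional. Expected crossover counts at
50 cM/CO are reported both at full precision and truncated (not rounded) to
one decimal, since that is how such counts are conventionally quoted
(1034.3 cM / 50 = 20.686, printed 20.6). Zone shares, by contrast, are
rounded to one decimal. Both code paths are pinned in the acceptance tests.

## Zones, bins, and the two-population comparison

Chromosome partitions follow the three-zone scheme used for barley: distal
Zone 1, interstitial Zone 2, proximal Zone 3, supplied as an editable TSV of
1-based inclusive segments (`genome_layout()`), because real zone boundaries
are configuration data, not code. Markers are assigned to zones by
position; intervals and crossover events by the physical midpoint of their
flanking markers.

The genome-wide profile dissects each chromosome into `n_bins` (default 50,
i.e. 2%) relative physical intervals and apportions each marker interval's
cM pro-rata by physical overlap (computed exactly, via the piecewise-linear
cumulative map), then merges chromosomes. Conservation — zone totals and
bin totals each summing to the genome map total to 1e-9 relative — is
asserted in the tests.

Two populations are compared three ways:

* **Per-zone chi-squared** on the 2x2 table population x (in-zone /
  out-of-zone) crossover scores, Pearson, 1 df, no continuity correction by
  default (counts are large in this design; a Yates flag exists). A zero
  marginal leaves the p-value undefined rather than fabricated.
* **Wilcoxon signed-rank** (two-sided; exact for up to 25 untied non-zero
  pairs, tie-corrected normal approximation otherwise; zero differences
  dropped) on paired cM values.
* **Zone shares** of crossovers and of cM, since the two bases can differ
  and printed shares do not always say which was used; both are reported.

### The pairing unit of the Wilcoxon tests

The genome- and zone-level tests pair *per-chromosome* values (7 pairs in
barley). For the per-bin tests the package defaults to pairing *shared
marker intervals within the bin* instead, and this is a deliberate design
choice worth spelling out. With only 7 chromosome pairs the exact
signed-rank null distribution is extremely coarse — its p-value support has
atoms of up to 0.125 — so per-bin p-values from chromosome pairing can
never behave like a uniformly distributed p-value under the null; no test
at conventional levels can be well calibrated on 7 pairs. When both
populations are genotyped on the same fixed array (the design this package
targets), the marker intervals are identical in both populations and form a
natural, much richer pairing unit (tens to hundreds of pairs per 2% bin).
The chromosome-level pairing remains available via
`bin_pairing = "chromosome"` for sensitivity analysis. The test suite
verifies both the null calibration (KS uniformity of per-zone chi-squared
and terminal-bin Wilcoxon p-values across replicate simulations) and the
power to detect a 10% interstitial-to-telomere shift.

## The simulator

`simulate_f2()` generates each individual as two independent gametes. Per
gamete and chromosome, crossovers form a stationary renewal process on the
genetic scale with Gamma(shape ν, rate ν) inter-event distances in Morgans:
ν = 1 is the no-interference Poisson case (the default), larger ν gives
positive interference with the event rate unchanged. Genetic positions are
mapped to bp by inverting the cumulative recombination landscape — a
piecewise-constant cM density over physical segments. Each gamete starts on
a uniformly chosen parental haplotype (F1 phase is arbitrary) and switches
at its crossover positions; the F2 genotype is the unordered pair of gamete
haplotypes. Noise is applied only after truth is recorded: calls are set
missing with probability `missing_rate`, then surviving calls are replaced
by one of the other two codes uniformly with probability
`allele_error_rate`. Coincident crossovers of the two gametes in one marker
interval are simulated faithfully, producing the hom-to-hom (score 2) and
invisible het-to-het double events discussed above. No obligate-crossover
constraint is imposed by default (no per-bivalent mechanism is assumed).

Default study conditions emulate a barley-style two-population experiment:

| parameter | default | rationale |
|---|---|---|
| individuals per population | 90 | typical surviving F2 population after QC |
| chromosomes | 7, 520–670 Mbp | barley-scale physical genome (~4.25 Gbp) |
| per-gamete chromosome length | 72 cM | genome ~504 cM per gamete, i.e. an F2 map total near 1000 cM |
| marker density | 2.6 / Mbp | ~11,000 polymorphic array markers genome-wide |
| landscape | U-shaped, sub-telomeric peak at 2–4.5% of each arm | zone shares of genetic length ≈ 51% / 46% / 3% (Z1/Z2/Z3), matching the strongly distal cereal pattern with a nearly silent pericentromere |
| allele error rate | 0.2% | plausible array miscall rate; not reported for real arrays, hence exposed |
| missing rate | 2% | plausible array missing-call rate; exposed |
| interference shape ν | 1 | simplest standard model with a Poisson limit, convenient for oracle testing |

The `shift_distal()` perturbation moves a fraction (default 10%) of Zone 2
genetic length into the terminal 2% of each arm with the total unchanged —
a minimal model of a distal redistribution phenotype.

What the simulator does *not* emulate: array hybridisation intensities and
cluster-calling artifacts (simulation starts at called genotypes),
non-uniform marker placement (real arrays are denser in distal gene-rich
regions), segregation distortion, obligate crossovers and chromatid
interference. Passing tests therefore demonstrate the correctness of the
calling/mapping/comparison machinery under a realistic but idealised
meiosis, not the quirks of any particular array chemistry.

## Quality control

"Low quality" is operationalised with explicit, configurable thresholds:
markers are dropped when monomorphic, more than 10% missing, more than 85%
heterozygous, or failing a 1:2:1 segregation chi-squared at alpha = 1e-6;
individuals when more than 20% missing or more than 80% heterozygous
(the F2 expectation is 50%, but linkage makes per-individual heterozygosity
wide: an F2 genome is a mosaic of ~15–20 parental blocks, so the ceiling
must be generous). Filtering order is fixed — markers, then individuals —
and in a two-population analysis a marker must pass in both populations,
keeping the panels identical for interval-paired tests. Reports list every
removal with its reason, statistic and threshold, and filtering is
idempotent. Exact reproduction of a particular published marker count from
a deposited dataset may require tuning these thresholds to the original
(unpublished) values.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout; BED-style exports convert
  to 0-based half-open.
* Zone segments must tile `[1, length]` exactly; a position outside every
  segment is an error, not a silent drop.
* `r >= 0.5` is clipped (warning), never extrapolated; `r < 0` is an error.
* Intervals with no informative individuals are excluded from totals with a
  warning.
* Empty chromosomes in coverage assessment count as 100% uncovered.
* The gamma-renewal sampler uses a 10-Morgan burn-in to reach
  stationarity for ν ≠ 1; ν = 1 uses the exact Poisson shortcut.
* All simulation is seed-deterministic: identical configuration and seed
  give bit-identical genotype matrices and truth records.

## Problem sizes used by the test suite

The simulations in the tests are sized to be informative but quick: the
calibration null uses 500 replicate pairs of 60-individual populations on a
~2,800-marker array; the power check 100 replicate pairs of 90-individual
populations at full ~11,000-marker density; parameter recovery 10 seeds of
200 individuals with ~14 markers/cM (dense enough that crossovers rarely
fall within one validation window of each other, which would otherwise
suppress both flanking transitions and bias the map downward); and the
caller oracle is exhaustive to length 8. These sizes are the package's
choice of a well-powered desk experiment, and all thresholds were fixed
before the experiments were run.

## Known limitations

* The per-individual `r` pools two meioses; it is a faithful rendering of
  the conventional F2 map-total presentation, not a maximum-likelihood
  per-meiosis estimator.
* Close double crossovers (within one validation window) are structurally
  undetectable, and het-to-het coincident doubles are invisible; at array
  densities of several markers per cM the resulting downward bias is well
  under 1%.
* The caller does not phase, does not assign events to a gamete of origin,
  and does not infer interference from data (the simulator's ν is an input,
  not an estimate).
* Detection power for subtle redistributions is modest at typical F2 sizes.
  The test suite's power experiment — 10% of interstitial genetic length
  moved to the terminal 2% of each arm, 90 individuals per population —
  corresponds to ~23 cM of displaced per-gamete map length and yields
  standardized effects near 2 for the zone chi-squared and terminal-bin
  Wilcoxon statistics alike, i.e. roughly coin-flip power per test at
  α = 0.05. Reliable (>80%) detection of a shift this size needs about
  twice the displaced mass or twice the population size; users planning a
  comparable experiment should treat the simulator + `shift_distal()` as a
  power calculator before growing plants.
* No multiple-testing adjustment is applied across the 50 bins by default,
  matching the conventional per-bin presentation; a Benjamini–Hochberg
  option exists on the result tibble (`p.adjust` on `tidy()` output) for
  users who want it.
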