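---
title: "Melting-curve genotyping for newborn hearing-loss screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting-curve genotyping for newborn hearing-loss screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmcascreen)
```

## The assay and its decision rule

Multicolor melting-curve analysis (MMCA) genotypes a sample by hybridising
fluorescent probes to PCR amplicons and reading the melting temperature (Tm)
of each probe-target duplex from the peak of the negative derivative
-dF/dT of fluorescence over temperature. A probe bound to its perfectly
matched (wild-type) target melts at `tm_wt`; a single-nucleotide mismatch or
small indel destabilises (or occasionally stabilises) the duplex, shifting
the melt by a characteristic offset. The calling statistic for a peak at
`tm_peak` is

    delta_tm = tm_wt - tm_peak

and a variant is called when `delta_tm` falls inside that variant's
calibrated window `delta_tm_v ± 3SD`. Negative `delta_tm_v` means the mutant
duplex melts *above* the wild type. A peak within ±1 °C of `tm_wt` is the
wild-type duplex; the package treats `[-1, 1]` as a wild-type pseudo-window
on the delta-Tm axis, and the panel validator requires every calibrated
window to stay clear of it.

The shipped panel covers 20 hearing-loss-associated variants in four genes
(GJB2, GJB3, SLC26A4 and the mitochondrial MT-RNR1) across four multiplex
reactions and up to five dye channels per reaction. Two design points are
configuration data rather than code, because the published calibration table
does not pin them down:

* **Reaction/channel layout.** The default assignment groups GJB2+GJB3 in
  reaction A, SLC26A4 in B and C, and the two MT-RNR1 probes in D,
  consistent with the table's gene grouping. SLC26A4 probes whose windows
  would collide on one dye (e.g. c.1174A>T at 6.05±0.73 and c.749T>C at
  5.1±0.97) are placed on different reactions. Any alternative layout can be
  supplied as a panel JSON file.
* **Absolute wild-type Tm values.** Only delta-Tm matters for calling;
  absolute Tm is instrument- and probe-specific. Defaults are spaced in
  58-78 °C so that the two probes sharing the ROX dye in reaction A occupy
  disjoint total Tm ranges with a 2 °C guard band, which
  `validate_panel()` enforces for any user panel.

The printed `±` half-widths are taken directly as the 3SD calling
half-widths (the calibration table's caption defines them so), not as one SD
to be tripled.

Zygosity follows the peak pattern: wild-type peak only → wild type; wild
type plus one mutant peak → heterozygote; a lone mutant peak → homozygote.
On the mitochondrial probes the same patterns are read as heteroplasmic and
homoplasmic, and the heteroplasmy fraction is estimated from melt-peak
areas,

    p = area_mut / (area_mut + area_wt),

area being preferred over height because it is insensitive to differences in
transition steepness (a height-based estimate is available via
`estimate_heteroplasmy(..., statistic = "height")`). Two distinct mutant
peaks without a wild-type peak are reported as a presumed compound
heterozygote with phase unknown — the assay cannot phase; downstream logic
treats same-gene het pairs as biallelic. Anything else (an unassigned peak,
a wild-type peak with two mutant peaks, more than three peaks) is flagged
`ambiguous` and routed to manual review rather than auto-called.

## Synthetic melt curves

No public raw data exist for this assay, so the package ships a generative
model used by every caller test:

    F(T) = baseline(T) + sum_species amplitude_s * logistic((Tm_s - T) / s) + noise

a sum of two-state duplex melts on a linear background with i.i.d. Gaussian
point noise. Heterozygotes contribute equal wild-type and mutant amplitudes
(1:1 allele ratio); mitochondrial mixtures weight the two species by
`(1 - p, p)`, which ties mutant peak height to the heteroplasmy fraction.
Defaults: grid 40-90 °C at 0.1 °C (all shipped transitions covered with a
≥10 °C margin), amplitude 1, baseline slope -0.002, noise SD 0.01 (1% of
amplitude), transition slope `s = 0.5` °C.

The transition slope deserves a note. `s = 0.5` gives a 10-90% melt width of
about 2.2 °C — a sharp but realistic probe melt. It was chosen, before the
test suite was frozen, as the steepness at which all of the following hold
simultaneously at the panel's closest calibrated spacing (|delta_tm| =
4.26 °C): twin heterozygote peaks remain resolved after the smoothing the
caller applies; the -dF/dT argmax of one transition is shifted less than
0.05 °C by its neighbour's tail (at `s = 1.2` that bias reaches ≈0.2 °C,
which would blur the calibration the windows encode); and a mutant shoulder
at heteroplasmy 0.3 is still a detectable peak. Broader transitions degrade
these properties smoothly; the simulator accepts any `transition_slope` for
sensitivity studies.

What the generator deliberately does *not* emulate: probe-specific melt
asymmetries, temperature-dependent quenching, plate effects, inter-well
amplitude variation, or correlated (1/f) instrument noise. Passing the
round-trip tests therefore shows the decision logic is correct under the
stated signal model, not that the pipeline is validated on any particular
instrument's exports.

## From raw trace to peaks

`derivative_curve()` processes one trace in three steps:

1. **Baseline.** A straight line is fitted to the post-melt plateau (the
   last 10% of grid points, the flattest region once every duplex has
   melted) and subtracted everywhere. The corrected fluorescence then decays
   to zero, so -dF/dT returns to zero on both plateaus and peak areas
   integrate to the species' amplitude shares — a property the heteroplasmy
   estimator relies on. (A single line fitted through *both* plateaus would
   subtract part of the melt step itself and leave the derivative with a
   constant negative offset and sign-broken areas.)
2. **Smoothing.** A Savitzky-Golay smoothing pass (default window 31 points
   = 3.1 °C, cubic).
3. **Differentiation.** A second Savitzky-Golay pass returning the first
   derivative (default window 21 points, quadratic), negated. Both passes
   fit local polynomials, so endpoints are extrapolated, not truncated.

The windows are matched to the peak width (FWHM ≈ 1.8 °C at `s = 0.5`) and
sit well below the smallest calibrated peak spacing (4.26 °C), so true peaks
never merge.

`detect_peaks()` keeps local maxima whose topographic prominence clears
*both* of two floors:

* a **relative floor**, `min_prominence_frac` (default 0.10) times the
  global maximum — the classical rule, which alone is fragile: in a
  50-degree trace, smoothed noise produces spurious bumps whose prominence
  (inflated by negative valleys) regularly exceeds 10% of a heterozygote's
  half-height peaks;
* a **noise floor**, `min_snr` (default 8) times the trace's estimated
  derivative noise SD. The point-noise SD is estimated robustly as
  `mad(diff(F))/sqrt(2)` and propagated through the exact white-noise gain
  of the combined filters (computed from their impulse response), so the
  floor is a calibrated absolute threshold, scales with the data (affine
  invariance is preserved) and vanishes for noise-free traces.

Surviving peaks are thinned to a minimum spacing of 1.5 °C (the higher of a
violating pair wins, ties break toward lower temperature — output order is
deterministic), and peak area is the trapezoidal integral between flanking
minima. `refine_tm()` sharpens each peak position by parabolic interpolation
through the three points around the discrete maximum; boundary peaks are
returned unrefined and flagged. With the defaults, a full-panel sweep of
every genotype at 5% amplitude noise and 200 seeded replicates per genotype
recovers over 99% of genotypes (the acceptance suite re-measures this), and
noise-free refined Tms sit within 0.1 °C of the constructed transition
centres.

The heteroplasmy estimate is reliable for fractions roughly in 0.2-0.8 at
default noise; outside that range the minority species' peak approaches the
detection floors and the call collapses to the majority state — mirroring
the real assay, where extreme heteroplasmy is indistinguishable from
homoplasmy.

## Screening logic

Genetic categories follow the screening programme's definitions: `negative`
(no call), `carrier` (heterozygous or cross-gene compound findings — and any
mitochondrial call, since mitochondrial variants are not biallelic in the
autosomal sense), `refer` (a homozygote, or two variant alleles in the same
autosomal gene, i.e. hom or a same-gene het pair). "Biallelic" is
deliberately interpreted as *same-gene*: cross-gene double heterozygotes are
carriers, which matches the cohort's placement of cross-gene pairs among
carriers with passing outcomes and of same-gene findings among the referred,
diagnosed cases. A genotype set containing an ambiguous probe returns
`review_required` instead of a category.

The hearing arm is a small state machine: an initial otoacoustic-emission
screen at 24-48 h, a second automated-ABR screen at 42 days taken by *all*
neonates regardless of the initial result, and a diagnostic work-up at 3-6
months for rescreen failures. Severity bins a diagnostic threshold as mild
(26-40 dB), moderate (41-60), severe (61-80), profound (≥81) — the printed
bins leave 80-81 dB unassigned; the package closes the gap at ≥81 =
profound. A `late_diagnosis` flag permits diagnoses outside the
rescreen-failure route (the data model supports it; the shipped fixture does
not need it, see below). Follow-up recommendations are a deterministic,
order-independent rule list (aminoglycoside avoidance and maternal-lineage
counselling for mitochondrial carriers, delayed-onset follow-up for
GJB2/SLC26A4 heterozygotes, routine follow-up for hearing-passing GJB3
carriers, diagnostic referral plus family genetic diagnosis for the refer
category).

## The packaged cohort fixture

`fixture_cohort_spec()` reconstructs the 2488-neonate study cohort from its
published marginal tables as an explicit specification: one row per
variant/zygosity group with joint (initial × second screen) outcome counts,
the genetics-negative remainder, and the 11 diagnosed cases pinned to
specific cells. `generate_cohort()` materialises it into per-neonate
records; re-aggregation reproduces every specification margin exactly, and
the tests check this bijection.

Three reconstruction choices had to be made where the published tables are
not mutually consistent:

* The per-variant carrier totals (58 for c.235delC, 39 for c.919-2A>G) and
  the cohort-wide positive count (170) each exceed the per-group outcome
  rows by exactly one for those two variants (which sum to 168 neonates).
  The fixture appends one extra heterozygote of each, passing all screens —
  the only completion consistent with the carrier totals, the 170 positives
  and the 50.0% GJB2 share.
* The outcome rows give 14 genetic-positive initial-screen referrals, while
  the running text reports 18. The fixture follows the row-level counts
  (counts win over derived percentages and text); negatives fill the
  remaining 130 of 144 initial referrals.
* Among the 11 diagnosed cases, subjects 1, 5 and 8 are listed as
  hearing-screen passers. Reading that column as the *initial* screen
  result makes every margin consistent: those three are exactly
  initial-pass/second-refer neonates (7 such exist cohort-wide), the
  second-refer counts of their genotype groups match, and subject 5 is the
  reported ototoxic-history, genetics-negative moderate case. No
  late-diagnosis flag is needed.

Where specific diagnostic thresholds are not printed, diagnosed cases are
assigned representative values inside their printed severity band
(mild/moderate → 50 dB; severe/profound → 70-75 dB, 90 dB for the two
cochlear-implant recipients); severity *bins*, not thresholds, feed all
reported statistics. Mitochondrial carriers receive a seeded heteroplasmy
fraction drawn uniformly from 0.2-0.8 — the study reports all its
mitochondrial cases as heteroplasmic without printing fractions, and this
range keeps both peaks detectable so the records survive a
simulate-and-recall round trip.

## Cohort statistics

Two allele-frequency conventions are first-class outputs because the
published frequency column mixes them: the *screening-report convention*
`carriers/(2N)` (which counts a homozygote once) reproduces most rows (e.g.
c.235delC 58/(2·2488) = 1.17%), while the c.1226G>A row (1 het + 2 hom = 5
alleles, 0.10%) only reproduces under *strict* allele counting with hom = 2.
`allele_frequencies()` reports both and flags every variant where they
differ; mitochondrial variants, having no diploid allele count, are excluded
from the strict estimate and reported as carrier proportions.

Contingency comparisons use Pearson's chi-squared (with and without Yates
correction) and the two-sided Fisher exact test in the
probability-summation convention (the sum of all tables at most as probable
as the one observed — the same convention as `stats::fisher.test`); a
tail-doubling variant is also reported since some programmes prefer it.
Tables with an expected cell below 5 carry an advisory flag; a zero margin
makes the tests undefined and is flagged instead of tested. The carrier rate
carries a Clopper-Pearson exact binomial interval.

Diagnostic yield quantifies what genetic screening adds over hearing
screening alone: among diagnosed cases, those missed by the initial hearing
screen but carrying panel variants, relative to those caught by it
(2/8 = 25.0% in the fixture), alongside prevalence per 1000 (11/2488 = 4.4).

Carrier proportions are pooled across studies with the DerSimonian-Laird
moment estimator, written out in the package (per-study effects and
variances on a chosen scale; `Q`, `tau^2`, `I^2`, random-effects weights;
back-transformed pooled estimate) and cross-checked in the tests against an
independent step-by-step evaluation and against `metafor::rma(method =
"DL")`. The default scale is the logit with a 0.5 continuity correction for
zero cells; untransformed and Freeman-Tukey double-arcsine scales (Miller's
back-transform with the harmonic-mean n) are available, since the source
figure does not state its transform. Only the machinery is in scope: the
source's pooled numbers depend on external studies' counts, which are inputs
here, not package data.

## Problem sizes and determinism

All simulations in the tests and the acceptance script run in seconds to a
few minutes on one CPU: the exhaustive noise-free sweep covers all 20
calibrated variants × {het, hom} plus the five observed double-heterozygote
combinations as whole 14-assay samples; the noisy sweep uses 200 seeded
replicates per genotype at 5% amplitude noise on the relevant probe; the
end-to-end acceptance run simulates and re-calls all 170 variant-positive
neonates plus 20 negatives under default conditions. Every stochastic step
(simulation noise, heteroplasmy draws) is seed-controlled, per-curve seeds
are derived deterministically, and reports are byte-identical across reruns
with the same seed.

## Known limitations

* The signal model is intentionally simple; vendor exports, asymmetric
  melts and correlated noise are out of scope, as are probe design and
  thermodynamic Tm prediction.
* Compound heterozygotes on one probe are called without phase; same-gene
  phase (cis/trans) cannot be resolved by melt analysis.
* Heteroplasmy estimates are area-ratio approximations, accurate to about
  ±0.05 in the detectable range under the stated model.
* The fixture reproduces published *margins*; individual-level covariates
  beyond those margins (e.g. sex of undiagnosed neonates) are not modelled.
* ACMG classifications ride along as annotation and never enter calling or
  categorisation logic.
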