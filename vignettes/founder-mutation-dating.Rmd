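---
title: "Dating founder mutations: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating founder mutations: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderage)
```

## The problem

A founder mutation is a disease variant whose present-day carriers all
descend from a single ancestral chromosome. Immediately after the
founding event every carrier chromosome bears the founder's alleles at
the markers flanking the disease locus; each subsequent meiosis gives
recombination a chance to replace the distal part of that shared segment
with background chromosome, and gives each marker a small chance to
mutate. The extent of erosion therefore carries a signal about the age
`g` of the mutation in generations. `founderage` implements two
estimators of `g` that read that signal in different ways, the
demographic arithmetic needed to interpret the result in calendar time,
and a forward simulator that generates data with known truth to validate
and calibrate both.

## Genetic map

Physical distance is converted to genetic distance at a constant rate
(default 1 cM/Mb, the genome-wide average, used when no empirical
recombination map is trusted at this scale) and then to a recombination
fraction. The map function is Haldane's,
`θ = (1 − e^{−2d})/2` with `d` in Morgans, chosen because it is the
standard no-interference default; a linear approximation `θ = d`
(capped at 0.5) is available by configuration, and at the sub-Morgan
distances of these maps the two differ negligibly. Both the per-marker
fraction to the locus (used by the single-marker estimator) and the
per-adjacent-interval fractions (used by the outward-scanning
likelihood) are stored, because the two estimators consume distance
differently. Default per-generation marker mutation rates are set by
marker type — SNP 1e-8, dinucleotide STR 5e-4, tetranucleotide STR
2e-4 — standard order-of-magnitude values, overridable per marker, since
panels mix marker classes with very different mutabilities.

## Single-marker estimator and its growth correction

With `p_D` the carrier frequency of the ancestral allele and `p_N` its
control frequency, the excess association `δ = (p_D − p_N)/(1 − p_N)`
equals the probability that a carrier chromosome still carries the
ancestral segment at that marker, assuming chromosomes that lost it are
exchangeable with the background. Under a star genealogy — every carrier
an independent line of descent of depth `g` — that probability is
`(1 − θ)^g`, so `ĝ = ln δ / ln(1 − θ)`. Three failure modes are made
explicit rather than patched over: `p_D ≤ p_N` leaves `δ ≤ 0` and no
estimate (status `undefined_excess`); markers closer than 0.1 cM have
recombination fractions too small to estimate reliably and produce
enormous, untrustworthy ages (estimated but flagged
`unstable_close_marker`, excluded from medians); and `δ = 1` (no decay
observed) gives `ĝ = 0`. Marker panels are summarised by the median
across usable markers.

The star assumption fails in a growing population: the intra-allelic
genealogy is a tree, and a recombination event on an early branch is
shared by all its descendants. The sampling distribution of `δ̂`
acquires a heavy lower tail (replicates whose early lineages recombined)
while its median shifts above `δ`, so the median age estimate is biased
*down*. The correction is additive: `Δ(θ, r, ĝ)` such that the
corrected estimate `ĝ + Δ` is median-unbiased under a Galton–Watson
genealogy at growth rate `r`. Because no closed form is exposed for this
bias, `Δ` is calibrated by simulation with the package's own branching
generator: the median estimate `m(g)` is evaluated (with common random
numbers, ≥1000 replicates per point) on an integer bisection for the
`g*` with `m(g*) = ĝ`, interpolating between the bracketing integers;
`Δ = g* − ĝ ≥ 0`. A `table` mode applies user-supplied corrections
directly, so published correction values can be reproduced exactly. When
a correction is applied to a confidence interval the same `Δ` is added
to both bounds. Two properties anchor the calibration: `Δ → 0` as
`r` grows large (the genealogy approaches a star), and slower growth
gives larger corrections. In the calibration simulations, when fewer
copies than the requested sample size survive, all surviving copies are
sampled: conditioning on a full-size sample would be infeasible at small
candidate ages, where the copy count is necessarily below the sample
size.

## The modified multi-marker likelihood

For one carrier haplotype and a candidate age `g`, each side of the
locus is scanned outward as a two-state chain. The ancestral segment
survives interval `i` (the locus flank first, then marker-to-marker
gaps) across `g` meioses with probability `(1 − θ_i)^g`; recombination
is treated as absorbing, so all markers beyond the innermost lost
interval emit independently at the control allele frequencies. While
intact, marker `j` emits the ancestral allele with probability
`(1 − μ_j)^g`; the complementary mass goes to the other allele for SNPs
(and uniformly over the other alleles for generic multi-allelic
markers), and for STRs is split equally over the one-step repeat
neighbours, so repeat lengths more than one step from the ancestral
allele must be explained by recombination. At every marker and age the
intact-state emission probabilities sum to one. The two side
likelihoods multiply; with a recurrence prior `π` the total is
`(1 − π)·L_descent + π·L_background`, allowing a carrier chromosome to
be an independent origin of the same mutation (default `π = 0`).
Haplotype uncertainty enters one level up: each carrier contributes the
probability-weighted sum of likelihoods over their possible
mutation-bearing haplotypes, as produced by phasing.

The dataset log-likelihood is maximised by direct search on an integer
grid (default 0–500 generations), so reported estimates are integers;
the 95% confidence set is all grid ages within 1.92 log-units of the
maximum (χ², 1 df). The 1-LOD convention (2.30 units) is available by
configuration. Interval bounds at the grid boundary are flagged and
should be read as "≤ low" / "≥ high"; ties at the maximum resolve to
the smallest age and are flagged.

Two design choices here were genuinely open, and both are isolated
behind the transition/emission functions so alternatives can be slotted
in. First, a double recombination that lands back on a haplotype
matching the ancestral alleles beyond the breakpoint is credited to the
background frequencies, not to descent — the absorbing approximation.
Second, marker mutation is modelled on the intact branch only; after
recombination, mutation is absorbed into the background frequencies.
Both are second-order effects at the time scales where the method is
useful, and the exhaustive enumeration oracle used in the tests encodes
the same event algebra, so the tests verify the scan implements this
model exactly (to 1e-10) rather than verifying the model itself.

The likelihood is validated three ways: a closed-form one-marker
reduction, `P(match) = (1−θ)^g + (1−(1−θ)^g)·p_N`, which the scan must
reproduce to 1e-12; exhaustive enumeration of all per-meiosis
recombination placements and mutation indicators on maps of up to three
markers and `g ≤ 5`; and parameter-recovery simulations (below).

## Phasing and the ancestral haplotype

The likelihood needs, per carrier, a distribution over possible
mutation-bearing haplotypes. A reader for PHASE-style pair listings and
a native TSV format are provided; when only genotypes are available, an
enumeration-based EM (gene counting) phases windows of up to 12 markers,
with the mutation site included as an anchor pseudo-marker at which
carriers are heterozygous — each phased configuration then identifies
its mutation-bearing chromosome. EM details: uniform initialisation
over compatible haplotypes, convergence when the largest frequency
change falls below 1e-8, iteration cap 500, deterministic (no random
restarts); the log-likelihood is checked to be non-decreasing at every
step. This EM is a deliberately simple phaser: it ignores the
coalescent structure a full phasing model exploits, which is acceptable
here because carrier haplotypes are dominated by the shared ancestral
segment. Cases and controls are phased jointly by default — an
assumption (common haplotype pool), flagged in the function
documentation. Distribution entries below 1e-6 are pruned and the rest
renormalised, bounding the weighted sums at precision far below
anything reported.

The ancestral haplotype is inferred per marker as the
probability-weighted modal allele across carriers; ties prefer the
allele most enriched relative to controls (largest `p_D/p_N`), then the
lexicographically smallest label. Control allele frequencies come from
direct counting; carrier frequencies from probability-weighted counting
over the distributions.

## The simulator: what it emulates and what it does not

The generator stands in for the undeposited case–control panels this
class of methods is applied to. A founder haplotype is drawn from a
background pool; each meiosis applies, per interval, recombination with
probability `θ_interval` — switching everything outward of the
breakpoint to a fresh pool draw — and per-marker mutation (SNP: switch;
STR: ±1 step, reflecting at the allele-range bounds). At most one
recombination per interval per meiosis (the standard small-interval
approximation). Genealogies are either `star` (independent lineages of
depth `g`, the estimators' null model) or `branching` (Galton–Watson
with Poisson(`r`) offspring, conditioned on survival by full resampling,
cap 10,000 attempts). Carrier chromosomes are sampled without
replacement from the surviving copies; controls are i.i.d. pool draws;
unphased genotypes can be emitted by pairing each carrier chromosome
with a fresh pool draw. The truth record keeps the age, ancestral
haplotype, copy-count trajectory and each sampled carrier's
ancestral-core extent, so mosaic structure is directly assertable.

Deliberate simplifications: recombination switches to an independent
pool draw rather than tracking a diploid pedigree, which matches the
background-exchangeability assumption of both estimators; the default
pool is in linkage equilibrium, so passing tests say nothing about
robustness to background LD; growth is constant-rate (no bottlenecks or
fluctuating sizes); and there is no selection at the disease locus.
These are exactly the assumptions of the models being tested, which is
the point — the simulator validates the estimators on their home
ground, not against every feature of real data.

## What the calibration studies show

Three studies, run in `analysis/05_calibration.R` and in the test
suite, characterise the estimators at the problem sizes used throughout
the package (19 markers / 12.3 Mb, 16 carriers, 109 controls, truth 17
generations at r = 1.5; one marker at θ = 0.02, 2000 carriers, truth 30,
for the star calibration; 100 replicates each, 10,000 for the
copy-count sanity checks — sizes chosen to keep every study in seconds
to minutes on one core while leaving Monte-Carlo error well inside the
assertion tolerances):

- The unconditioned Galton–Watson copy count has mean `r^g` and
  extinction frequency at the fixed point of `s = e^{r(s−1)}` (~0.417
  at r = 1.5), confirming the growth engine.
- On star-genealogy data the single-marker estimator is well
  calibrated: the median estimate lands within a few percent of truth.
- On branching-genealogy data the multi-marker likelihood's median
  point estimate recovers the truth within the expected tolerance, but
  its 95% likelihood-ratio intervals cover the truth in only about
  70–76 of 100 replicates. This is a property of the method, not of the
  implementation: the likelihood treats carriers as independent, so it
  understates the sampling variance induced by shared genealogy. Under
  the star genealogy — the model the likelihood actually assumes — the
  same intervals achieve near-nominal coverage (89–96/100 depending on
  whether the ancestral haplotype and control frequencies are estimated
  or known). Coalescent-based methods widen their intervals precisely
  by modelling genealogical variability; users should read the
  likelihood intervals accordingly.

## Known limitations

- Single-marker estimates on biallelic SNP panels are coarse: markers
  whose ancestral allele is still fixed among carriers contribute 0,
  and common background alleles leave `δ` ill-determined. STR panels,
  with rarer ancestral alleles, behave better.
- The growth correction is calibrated at one marker and transferred by
  its median across markers; it inherits the constant-growth
  assumption.
- Likelihood-ratio intervals are anti-conservative under branching
  genealogies (previous section).
- The phasing EM enumerates haplotype pairs and is limited to ~12
  marker windows; wide maps should come phased or be windowed.
- Degenerate inputs are handled explicitly: markers at the locus get
  `θ = 0` and are flagged unstable; monotone likelihoods return a
  boundary estimate with a warning; carriers impossible at every grid
  age are reported by name.
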