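# founderage

Estimating the age of a founder mutation — the number of generations
since the ancestral chromosome on which a disease variant arose — from
case–control marker data flanking the disease locus.

When all carriers of a variant descend from a single founder, they
initially share the founder's marker haplotype. Recombination erodes
this shared segment from the outside in, and marker mutation corrupts it
from within, at rates that depend on the age `g` of the mutation.
`founderage` implements the classical estimators of that age and the
simulation machinery to validate and calibrate them:

- **Single-marker LD decay.** With `p_D` the frequency of the ancestral
  (mutation-associated) allele on carrier chromosomes and `p_N` its
  frequency in controls, the excess association
  `δ = (p_D − p_N)/(1 − p_N)` decays as `(1 − θ)^g` under a star
  genealogy, giving `ĝ = ln δ / ln(1 − θ)` per marker; markers are
  summarised by their median. Estimates are undefined when `p_D ≤ p_N`
  and unstable for markers within 0.1 cM of the locus.
- **Growth (Labuda-style) correction.** In a growing population the
  intra-allelic genealogy is a branching tree, not a star; shared early
  recombination events bias the median single-marker estimate downward.
  An additive correction `Δ(θ, r, ĝ)` is calibrated by simulating
  Galton–Watson genealogies at growth rate `r` and solving (by
  bisection) for the true age whose median estimate equals the observed
  one; a table mode applies published corrections directly. The same
  `Δ` is added to point estimates and to both interval bounds.
- **Modified Goldgar multi-marker likelihood.** For each carrier the
  likelihood of the observed flanking haplotype is computed by scanning
  outward from the locus on each side: the ancestral segment survives
  each inter-marker interval over `g` meioses with probability
  `(1 − θ_int)^g`; once lost, outer markers emit at control frequencies;
  while intact, a marker emits the ancestral allele with probability
  `(1 − μ)^g` (STRs mutate ±1 repeat step). Haplotype-phase uncertainty
  enters as a probability-weighted sum over each carrier's possible
  mutation-bearing haplotypes (from PHASE-style output or the built-in
  EM phaser), and an optional recurrence prior allows a chromosome to
  carry an independent origin of the mutation. The MLE is found by
  integer grid search; 95% confidence intervals are the ages within
  1.92 log-likelihood units of the maximum.
- **Demographic arithmetic.** Growth rates from census pairs under
  `p1 = p0 · r^g`, and generation ↔ calendar-year conversion.
- **Forward simulator with known truth.** Founder haplotypes drawn from
  a background pool, eroded by per-interval recombination and per-marker
  mutation over star or Galton–Watson genealogies, with the full truth
  record (age, ancestral haplotype, copy-count trajectory, per-carrier
  ancestral-core coverage).

## Worked example

Simulate a 19-marker, 12.3 Mb panel with 16 carrier and 109 control
chromosomes, truth 17 generations at 1.5-fold growth, then estimate:

```r
library(founderage)

mk <- data.frame(
  name = sprintf("m%02d", 1:19),
  position_bp = round(seq(0, 12.3e6, length.out = 19)),
  type = "snp",
  alleles = I(replicate(19, c("1", "2"), simplify = FALSE))
)
map <- build_marker_map(mk, disease_locus_bp = round(12.3e6 / 2) + 1)
set.seed(20260927)
pool <- make_background_pool(map, n_haps = 200)

res <- run_pipeline(list(
  simulate = sim_config(g_true = 17, r = 1.5, n_cases = 16,
                        n_controls = 109, marker_map = map, pool = pool,
                        genealogy = "branching", condition = "n_cases",
                        seed = 20260927),
  methods = c("single_marker", "goldgar"),
  growth_rates = c(1.125, 1.5),
  correction = list(mode = "montecarlo", n_sims = 1000),
  grid = c(0, 200),
  seed = 101
))
res$report
```

which prints (one row per method × growth rate):

```
         method n_markers growth_rate estimate_raw delta estimate_corrected
1 single_marker        17       1.125        9.204    NA              17.35
2 single_marker        17       1.500        9.204    NA              13.25
3       goldgar        19       1.125       22.000 7.064              29.06
4       goldgar        19       1.500       22.000 2.943              24.94
  ci_low ci_high ci_width              flags
1     NA      NA       NA 2_markers_excluded
2     NA      NA       NA 2_markers_excluded
3  21.06   39.06       18
4  16.94   34.94       18
```

`estimate_raw` is the uncorrected age in generations (the likelihood
ignores population growth, so it tends to run low; here the grid MLE was
22 against a truth of 17, with raw CI [14, 32]). `delta` is the additive
growth correction — the median of the per-marker simulation-calibrated
corrections at that growth rate — and `estimate_corrected`, `ci_low`,
`ci_high` are the shifted estimate and interval. Slower assumed growth
(r = 1.125) implies a branchier genealogy and hence a larger correction.
Two of the 19 markers yield no single-marker estimate (excess
undefined, or closer than 0.1 cM to the locus) and are excluded from
the medians. `generations_to_years(17)` converts the age: 425 years,
origin about 1575 CE for a present of 2000.

The numbered scripts under `analysis/` run the full narrative —
demography, simulation, single-marker and likelihood estimation,
calibration studies — writing tables under `results/`.

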