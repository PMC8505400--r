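---
title: "Methods: water quality indices and phase comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water quality indices and phase comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverwq)
```

## The assessment problem

`riverwq` implements the index-based assessment of river water quality used
to study the effect of the 2020 COVID-19 lockdown on an industrial stretch
of the River Damodar (India): 11 sites at industrial discharge points,
sampled in three phases — pre-lockdown (December 2019), lockdown
(June 2020) and unlock (November 2020) — with 20 physico-chemical and
biological parameters per sample. Four complementary indices condense
those measurements into interpretable scores, and phase-comparison
statistics quantify how much each parameter and index changed when
industrial discharge paused.

Units follow the monitoring convention throughout: cations, anions, BOD
and DO in mg/l; heavy metals, total phosphorus and chlorophyll-a in µg/l;
electrical conductivity in µS/cm; turbidity in NTU; Secchi depth in m.

## The four indices

**Modified Water Quality Index (MWQI).** A weighted arithmetic index over
11 parameters (pH, TDS, turbidity, EC, Mg, Ca, Cl, SO4, NO3, BOD, DO).
Literature-assigned weights $AW_i$ are normalised to relative weights
$RW_i = AW_i / \sum_j AW_j$ (the 11 defaults sum to 16.95). Each
parameter is rated against its permissible limit $S_i$,
$Q_i = (C_i / S_i) \times 100$, except pH and DO, which are rated by
deviation from an ideal value $V_i$ (7.0 pH units; 14.6 mg/l, the 100%
oxygen-saturation concentration at 23 °C):
$Q_i = \frac{C_i - V_i}{S_i - V_i} \times 100$. Then
$\mathrm{MWQI} = \sum_i RW_i\, Q_i$. The rating is occasionally printed in
the applied literature with a multiplication sign between concentration
and standard; the ratio form used here is the dimensionally meaningful
one (100 = "exactly at the standard") and is the form that reproduces
the campaign's published index values. Classes: excellent (≤ 50), good
(50–100], poor (100–200], very poor (200–300], unfit for drinking
(> 300).

**Heavy-metal Pollution Index (HPI/HMI).** Over six metals (Zn, Cd, Pb,
Ni, Cr, Fe), with unit weights inversely proportional to the permissible
limit, $W_i = 1/S_i$, per-metal sub-indices $Q_i = (M_i/S_i) \times 100$,
and $\mathrm{HPI} = \sum W_i Q_i / \sum W_i$. The inverse-limit weighting
makes the index scale-invariant: expressing all concentrations and limits
in different (common) units leaves it unchanged. Classes: excellent
[0, 25], good (25, 50], poor (50, 75], very poor (75, 100], unfit for
drinking (> 100).

**Hakanson potential ecological risk (RI).** For each of Cd, Pb, Cr and
Zn, the contamination factor is the concentration over a preindustrial
reference, $C_f^i = C_s^i / C_n^i$ with
$C_n = \{\mathrm{Cd}\,1.0,\ \mathrm{Pb}\,70,\ \mathrm{Cr}\,90,\
\mathrm{Zn}\,175\}$ µg/l, and the risk factor scales it by a
toxic-response coefficient,
$E_r^i = T_r^i C_f^i$ with
$T_r = \{\mathrm{Cd}\,30,\ \mathrm{Pb}\,5,\ \mathrm{Cr}\,2,\
\mathrm{Zn}\,1\}$. The degree of contamination is $C = \sum C_f^i$ and
$\mathrm{RI} = \sum E_r^i$. Cadmium's reference of 1 µg/l combined with
$T_r = 30$ makes RI overwhelmingly cadmium-driven at this river's
concentrations. Classes: practically uncontaminated (< 150), moderately
(150–300), heavily (300–600), extremely contaminated (≥ 600).

**Carlson Trophic State Index (TSI).** The mean of three log transforms:
$TS(Sd) = 60.0 - 14.41 \ln Sd$, $TS(TP) = 14.42 \ln TP + 4.15$,
$TS(Chla) = 30.6 + 9.81 \ln Chla$. Seven classes from low oligotrophic
(< 30) to very high eutrophic (≥ 80).

## Why phase means are enough to reproduce the published values

MWQI, HPI and RI are affine functions of the concentration vector, so the
index of a phase-mean vector equals the phase mean of per-sample
indices, exactly. The per-sample field data are unpublished, but the
campaign's per-phase mean concentrations are published, so the published
phase-mean index values are recomputable at desk scale. TSI is
logarithmic, hence only near-affine: over the campaign's printed spreads
the Jensen gap is well under one TSI unit, which is the tolerance used in
the acceptance checks. `phase_means()` and `damodar_phase_stats()` expose
the published statistics as computable inputs.

```{r}
std <- default_standards()
ecological_risk(phase_means("pre_lockdown"), std)$value   # published: 537.45
mwqi(phase_means("pre_lockdown"), std)$value              # published: 310.37
pre <- phase_means("pre_lockdown")
tsi(pre[["sd"]], pre[["tp"]], pre[["chla"]])$value        # published: 61.99
```

## Numerical and design choices

**pH standard.** The BIS acceptable band for pH is 6.5–8.5. Rating pH
against the lower bound with ideal 7.0 makes the denominator $S_i - V_i$
negative, so any pH above neutral would rate negatively; the default
therefore rates against the upper bound 8.5, which also reproduces the
published pre-lockdown MWQI. `default_standards("lower")` keeps the
6.5 variant for fidelity experiments.

**Turbidity limit.** The default is 1 NTU, the BIS desirable limit the
campaign tabulates (the relaxed permissible limit is 5 NTU). Because
turbidity's rating is division by 1, MWQI is very sensitive to this
choice; it is a registry entry, not a constant, so users can override it
in the YAML config.

**Class boundaries.** Published class tables print touching ranges
("50–100", "100–200"). MWQI and HPI classes are implemented
lower-exclusive/upper-inclusive, honouring their inclusive lower anchor
classes ("≤ 50", "0–25"); RI and TSI are lower-inclusive/upper-exclusive,
honouring their strict anchors ("< 150", "< 30"). Each scheme partitions
its domain with no gaps or overlaps (property-tested).

**Missing values.** An index is computed only over its full declared
parameter set. A sample missing a member gets `NA` for that index, with a
log entry, rather than a weight-renormalised value — the assigned weights
are global constants, and silently renormalising would make index values
incomparable across samples.

**Rounding.** All comparisons and percent changes are computed on
unrounded values; rounding to two decimals happens only at presentation.

**A note on the published HMI summary values.** The campaign's published
HMI phase means cannot be derived from its published phase-mean
concentrations under the HPI formula and the tabulated limits (the
formula gives ≈ 190 for the pre-lockdown means against a published
335.29, with no choice of the stated inputs closing the gap). The package
implements the stated formula; its HMI values are therefore checked
against the formula and the classification scheme, not against those
summary numbers. The published lockdown-phase MWQI mean is similarly not
derivable from the lockdown mean concentrations; only the pre-lockdown
MWQI is used as a numerical anchor.

**A data-integrity correction.** The published dissolved-oxygen unlock
statistics print "6.344 ± 5.01", but the same table's SD percent-change
column (+12.24% from 0.49) implies an SD of 0.55. The packaged statistics
use 0.55; a coefficient of variation of 0.79 would also be physically
implausible for replicate DO measurements.

## The synthetic sampler

`generate_samples()` emulates the campaign's design — `n_sites` sites per
phase, 20 parameters, site labels S1…Sn — so the full pipeline is testable
without field data. Each parameter is drawn independently from a normal
distribution truncated below at 0 (pH to [0, 14]; Secchi depth kept
positive), with the published per-phase mean and SD as targets.

Truncation pushes the realised mean of a naively parameterised truncated
normal above its location — by about 0.12 SD for the most skewed case
(lockdown turbidity, mean/SD ≈ 1.6), which is well above sampling noise
at large n. The sampler therefore calibrates the location parameter
(by root-finding on the closed-form truncated-normal mean) so the
*distribution's* mean equals the configured target; the realised sample
mean is then an unbiased estimate of the target at any n. With
`sd = 0` every draw equals the target exactly. Draws use inverse-CDF
sampling, so a given seed yields a byte-identical dataset.

What the sampler does **not** emulate: the campaign publishes only
marginal means and SDs, so cross-parameter correlations — which the real
data certainly have (TDS–EC near unity, metals co-varying by source) —
are not imposed by default. Passing tests on synthetic data therefore
validates the index arithmetic, classification, and comparison machinery,
not distributional claims about real river data. For fidelity
experiments, the `copula_cor` argument couples the truncated marginals
through a Gaussian copula with a user-supplied correlation matrix.

```{r}
s <- generate_samples(n_sites = 11, seed = 1)
res <- run_pipeline(s)
head(res$class_table)
```

## Phase comparison statistics

`phase_describe()` uses the arithmetic mean and the sample (n−1) SD,
matching the magnitude of the published SDs. `percent_change(a, b)` is
$(b-a)/a \times 100$ from the baseline phase. `correlation_matrix()`
computes pairwise Pearson r with two-sided p-values from the
t-distribution on n−2 df (via `stats::cor.test`), starred at
p < 0.05 / 0.01 / 0.001; zero-variance parameters yield `NA` cells rather
than errors. `anova_lsd()` runs fixed-effects one-way ANOVA (omnibus F
via `stats::lm`/`stats::anova`) followed by Fisher's unadjusted
least-significant-difference pairwise t-tests on the pooled within-group
mean square at α = 0.05 — unadjusted because the procedure is the classic
protected LSD and no multiplicity correction is part of the method being
implemented.

## Problem sizes used by the test suite

The oracle-equivalence properties run each index against independently
coded brute-force one-liners on 1,000 random measurement vectors at
1e-9 relative tolerance. Generator mean-recovery is checked at
n = 1,000 sites per phase against a 3-standard-error band, and the
end-to-end generate → index → describe recovery at the study's own
n = 11. These sizes make every property statistically meaningful while
the whole suite stays interactive.

## Known limitations

* No unit auto-conversion beyond what the registry declares; inputs must
  arrive in registry units.
* No alternative WQI variants (CCME, NSF), no sediment-phase Hakanson
  variant, no seasonal Carlson corrections.
* The synthetic sampler's independence assumption (above).
* Spatial structure — river-kilometre autocorrelation, interpolated
  maps — is out of scope; results are per-site tables.
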