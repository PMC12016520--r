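---
title: "Reducing biphytane δ²H measurements to lipid/water fractionation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing biphytane δ²H measurements to lipid/water fractionation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpfrac)
```

## The measurement problem

Archaea build their membranes from isoprenoid glycerol dibiphytanyl
glycerol tetraethers (iGDGTs).  Cleaving the ether bonds of an iGDGT
releases two C₄₀ biphytane chains (BP-0 … BP-3, named for their number
of cyclopentane rings), which can be measured for their hydrogen-isotope
composition by gas chromatography–pyrolysis–isotope ratio mass
spectrometry (GC-P-IRMS).  Because lipid hydrogen partly derives from
the water in which the organism grew, the fractionation between lipid
and water,

$$
{}^2\varepsilon_{L/W} =
\left(\frac{{}^2\alpha_{L/W}}{1}\ -1\right)\cdot 1000,\qquad
{}^2\alpha_{L/W} = \frac{(^2H/^1H)_{BP}}{(^2H/^1H)_{W}} =
\frac{1000+\delta^2H_{BP}}{1000+\delta^2H_{W}},
$$

is a candidate proxy for the δ²H of ancient waters — provided it is
stable across environmental conditions.  `bpfrac` implements the full
chain from raw peak tables to study-level statistics needed to evaluate
that stability, together with a synthetic instrument/culture emulator so
that every stage can be tested without instrument output.

## Pipeline model

The reduction proceeds in fixed stages, each with explicit error
propagation (all uncertainties are 1σ, in ‰):

1. **VSMOW calibration** (`fit_calibration()`, `apply_calibration()`).
   Raw values are measured against an H₂ reference gas and distorted by
   instrument offset, scale compression, and a peak-size (linearity)
   effect.  Co-run n-alkane standards spanning −263‰ to −9‰ are fitted
   with the response-on-accepted ("inverted") regression
   $\delta_{raw} = \beta_0 + \beta_1\delta_{acc} + \beta_2 A\,
   (+\,\beta_3\delta_{acc}A)$, which is then solved for the
   accepted-scale value of each sample peak.  Fitting raw as the
   response is the standard errors-in-calibration arrangement, since
   the accepted values are (nearly) error-free; the direct orientation
   is available behind a switch for comparison.
2. **Hydrogenation correction** (`hydrogenation_correct()`).  Reducing
   the alkyl iodides to biphytanes adds hydrogen (by default 2 H onto a
   C₄₀H₈₂ skeleton — one at each cleaved ether terminus), an isotope
   dilution inverted by pool mass balance.  The δ²H of the added
   hydrogen is a required input: it depends on the H₂/catalyst batch
   and is not generally known a priori, so it is a free parameter here
   (and in the synthetic generator), never a hidden default.
3. **Averaging** (`weighted_mean()`).  Injections and biological
   replicates are combined with inverse-variance weights.  The reported
   error is the *larger* of the replicate scatter and the propagated
   measurement error — a conservative rule that prevents overconfident
   means when replicates disagree.
4. **Fractionation** (`epsilon_lw()`), computed per replicate from that
   replicate's lipid and water values and only then averaged.  Applying
   the nonlinear ε formula before averaging (rather than to averaged
   δ values) keeps treatment ε consistent with replicate-level ε to
   within rounding.
5. **Distribution metrics** (`ring_index_bp()`,
   `abundance_weighted_mean()`, `ring_difference()`).  The ring index
   is the abundance-weighted mean ring number.  Abundance-weighted
   isotope means include only moieties above 5% relative abundance
   (evaluated before exclusion, renormalised after), because minor-peak
   isotope values are unreliable.  The ring difference
   $\Delta\varepsilon/ring = (\varepsilon_X - \varepsilon_Y)/(X-Y)$ is
   evaluated for all moiety pairs $X > Y$; per-moiety summaries average
   a moiety's pairs, while the treatment-level value pools *all* pairs
   into one mean.  The pooled-pairs rule was chosen by verifying it
   against independently computed treatment tables (it is the only
   aggregation of the pairwise values consistent with them, e.g. the
   chemostat treatments give 9.2, 8.0, and 5.0 ‰/ring).
6. **Study statistics** (`condition_regression()`,
   `correlation_matrix()`, `bartlett_homogeneity()`,
   `water_h_fraction()`, `summarize_experiment()`), plus growth-rate
   fitting (`fit_growth_rate()`, with $T_D = \ln 2/\mu$).

`reduce_study()` chains stages 1–5 for in-memory tables;
`run_pipeline()` adds file I/O, the run log, and report rendering.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| abundance threshold | 0.05 | fraction | minor peaks carry unreliable isotope values; >5% is the conventional cut |
| `n_total`, `n_added` | 82, 2 | H atoms | C₄₀H₈₂ biphytane; two H added during hydrogenation |
| `delta_added` | user-set (−650 in the emulator) | ‰ | δ²H of hydrogenation H; batch-specific, must be supplied |
| `sigma_floor` | 0.5 | ‰ | keeps 1/σ² weights finite for zero-σ inputs; at the scale of water-analysis precision |
| growth window | 0.05–0.60 of max OD | fraction | approximates early-to-mid exponential phase; falls back to the full curve (with a warning) when it holds fewer than 3 points |
| calibration size terms | amplitude, linear, no interaction | — | the linearity effect is near-linear in amplitude over typical ranges; interaction term available |

## What the synthetic generator emulates — and what it does not

`generate_study()` draws treatment-level true fractionations at
−204 ± 12‰ with a +7.4‰ per-ring enrichment, growth waters in
−61…−46‰, and Dirichlet-distributed moiety abundances centred near
13/30/49/7% — the conditions of the multi-treatment culture study this
package is built around.  Instrument behaviour is offset + scale
compression + linear size effect with shot-noise-shaped repeatability
$\sigma(A) = a + b/A$ (uncertainty shrinks with peak size); the
hydrogenation dilution is applied forward exactly as the correction
inverts it.  Peaks below a detection limit are dropped, which emulates
the frequent loss of low-abundance BP-3.

It does **not** emulate chromatographic reality upstream of integrated
peaks (co-elution, baseline drift, H₃⁺ corrections), drift of the
instrument within a run, correlated errors between peaks of one
injection, or non-linear size effects.  Passing recovery tests on
synthetic data therefore demonstrates the *reduction* is correct and
well-calibrated under the stated error model, not that the error model
captures every instrument pathology.

## Numerical choices

* **Repeatability model.**  Within-run repeatability is estimated from
  standards' residuals in amplitude-quantile bins, then smoothed by a
  weighted fit of the shot-noise law $a + b/A$ (coefficients
  constrained non-negative; degenerate fits collapse to a constant
  floor).  The smoothing keeps calibrated σ monotonically non-increasing
  in amplitude, which raw binned estimates do not guarantee.  Total
  per-peak σ adds the delta-method prediction variance from the
  coefficient covariance.
* **Weighted replicate SD.**  The "max rule" compares the propagated
  σ of the weighted mean with a weighted replicate SD that reduces to
  the ordinary sample SD for equal weights.
* **σ floors.**  Zero-uncertainty inputs (e.g. noiseless synthetic
  data) would give infinite weights; a 0.5‰ floor substitutes for zero
  σ in weights only.
* **Ties and degenerate inputs.**  Ring indices reject all-zero
  abundance vectors; ring differences need two measured moieties (one
  moiety yields an empty result with a warning); Bartlett's test
  rejects zero-variance groups; calibration rejects rank-deficient
  standard sets, naming unmapped compounds.
* **Chemostat doubling times.**  For continuous cultures the dilution
  rate sets $T_D$; the exponential fit is bypassed and the set value
  used.  (Published chemostat tables can print μ values inconsistent
  with $\ln 2 / T_D$; the package never back-computes one from the
  other for chemostats.)
* **Rounding.**  Rendered report tables round ‰ values to integers and
  indices/abundances to two decimals, matching how such tables are
  printed; all internal computation is full precision.

## Design decisions on genuinely open points

* **Abundance weights** use per-replicate abundances (each culture's
  area shares, averaged per treatment); whether published tables used
  per-replicate or treatment-mean abundances is not stated, and the
  two differ by well under the table rounding for these data.
* **Size-effect covariate** defaults to peak amplitude (area
  selectable); the functional form of published calibrations is
  implemented in external processing software and not restated, so the
  linear-with-optional-interaction default is a declared choice, not a
  reconstruction.
* **Outlier standards** are kept by default; an optional robust refit
  drops |studentized residual| > 4 once and logs what it dropped.
* **Mass-balance endmembers** must be passed explicitly: the
  two-endmember water/substrate mixing model's fractionation terms are
  assumptions, and a `lower_bound` mode (substrate-path fractionation
  set to 0) gives a conservative lower bound on the water fraction.

## Problem sizes used in the test suite

Recovery and calibration tests run at deliberately modest sizes chosen
to give stable statistics quickly: noiseless end-to-end identity on
2–3 treatments × 2 replicates; 2σ coverage on 1000 noisy peaks against
a 40-run standards fit; null-calibration of the regression and Bartlett
tests at 1000 and 2000 simulated datasets; growth-rate coverage at 500
simulated curves; the Monte-Carlo check of the noise law at 1000
standards runs.

## Known limitations

* The calibration assumes standards and analytes respond identically
  to amplitude (no compound-class linearity differences).
* Error propagation is first-order throughout; for |ε| approaching
  1000‰ or very large σ the linearisation degrades.
* Pair values entering a pooled ring-difference mean share moieties, so
  the propagated σ of that mean ignores the induced correlation (as is
  conventional when errors are assumed uncorrelated).
* The water/substrate mass balance is a two-endmember linear model; it
  cannot resolve multiple substrates or exchange during biosynthesis.
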