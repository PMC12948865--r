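---
title: "Tracer mass balance for root and rhizodeposition carbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracer mass balance for root and rhizodeposition carbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizotrace)
```

## The measurement problem

Roots release a substantial part of the carbon a crop assimilates into the
soil as rhizodeposits — exudates, sloughed cells, fine root fragments —
but that flux cannot be weighed. The standard field approach labels the
crop repeatedly with ¹³CO₂ pulses during the season, then measures, at
ripening, the δ¹³C and carbon content of every compartment: grain, straw,
crown/coarse/fine roots, and soil, over several depth layers. Because the
tracer reaches the soil only through the root system, the soil's excess
¹³C — its enrichment above unlabelled reference material from the same
treatment and layer — quantifies net rhizodeposition: root-derived carbon
still present in the soil (operationally, everything in the < 0.5 mm soil
fraction, which includes fine root fragments below that size).

`rhizotrace` implements the full calculation chain from raw δ¹³C tables to
per-plot carbon budgets, together with a forward simulator of the whole
experiment so that every stage can be tested against known ground truth —
the field data themselves are typically not depositable at desk scale.

## The calculation chain

**Isotope conversions.** δ¹³C (‰ vs VPDB) is converted to the ¹³C atom
fraction via $R = R_{VPDB}(\delta/1000 + 1)$ and $\chi^{13} = R/(1+R)$,
assuming the two-isotope system. The atom excess $\chi^E$ is the atom
fraction minus that of the natural-abundance reference matched on
treatment and soil layer. The excess-¹³C mass of a pool with carbon mass
$m(C)$ (g C m⁻²) is

$$m^E(^{13}C) = \frac{\chi^E \; m(C) \; M(^{13}C)}
  {\chi(^{12}C)M(^{12}C) + \chi(^{13}C)M(^{13}C)},$$

where the denominator uses the *measured* sample's atom fractions (the
mean molar mass of its carbon). We use $M(^{12}C) = 12$ g mol⁻¹ exactly,
$M(^{13}C) = 13.0033548$ g mol⁻¹ (CODATA) and $R_{VPDB} = 0.0111802$; all
three live in a single `isotope_constants()` object, so the truncated
convention $R_{VPDB} = 0.011180$ — which changes results in the fifth
significant figure — can be swapped in reproducibly.

Negative atom excesses (a sample below its reference, possible under
measurement noise) are retained and logged rather than clipped: clipping
would bias every downstream sum.

**Root carbon and the EOM correction.** Root biomass times carbon
concentration gives root C; mass-related values (g C kg⁻¹ dry soil) are
scaled to area with $RC_S = RC_M\,\rho\,z$. Washed topsoil fine-root
samples contain extraneous organic matter (EOM) — residues of manure,
litter, fauna, preceding crops — at natural abundance (δ = −29.3‰). The
root carbon mass fraction of such a sample follows from two-pool mixing:

$$f_{RBC} = \frac{\chi^E(^{13}C_S) - \chi^E(^{13}C_{EOM})}
  {\chi^E(^{13}C_{RB}) - \chi^E(^{13}C_{EOM})},$$

which is invariant under the shared reference (it cancels in the ratio).
The correction is applied to topsoil (0–0.25 m) fine roots only; deeper
samples, washed from core material with far less organic input, pass
through uncorrected. Two choices here were genuinely open:

* *Clean-root endmember.* We use the same plot's topsoil coarse-root
  measurement as $\chi^E_{RB}$. Under the method's homogeneous-enrichment
  assumption all live root classes of a plot share one enrichment, so any
  clean root class is a valid endmember, and coarse roots are the class
  least affected by EOM.
* *Corrected excess mass.* After correction, the fine-root excess mass is
  recomputed from the clean-root atom excess applied to the corrected
  carbon ($f_{RBC} \times$ sample C), because the sample's own measured
  excess still contains the (near-zero but not exactly zero) EOM signal.

Raw $f_{RBC}$ outside $[0,1]$ — possible under noise — is clamped with a
warning and a run-log entry carrying the raw value.

**Aggregation.** Topsoil crown and coarse root C are summed into the
coarse class; in the two deeper layers the paired cores within and between
crop rows are averaged per class. A missing row-position partner is an
error (an unpaired core cannot give an unbiased layer value).

**Rhizodeposition.** Per layer, the soil and summed root excess masses
partition the tracer:

$$\%CdfR = \frac{m^E_{soil}}{m^E_{soil} + m^E_{root}} \times 100,
\qquad
qCdfR = \frac{\%CdfR \cdot RC_S}{100 - \%CdfR},$$

with $RC_S$ the layer's corrected total root C. The construction assumes
(i) homogeneous ¹³C enrichment of roots and (ii) equal enrichment of roots
and rhizodeposits; under those assumptions
$qCdfR/(qCdfR + RC_S) = \%CdfR/100$ is an algebraic identity, asserted in
the test suite to 1e-12. Whole-profile percentages are recomputed from
*summed excess masses*, not averaged across layers — mass balance is
additive, percentages are not. (Whether the original analysis summed or
averaged is not documented; summation is the choice consistent with the
mass-balance derivation, and under homogeneous enrichment the profile
qCdfR then equals the sum of layer values, which the zero-noise tests
confirm.) Layers in which both excesses are nonpositive, or the percent
falls outside $[0, 100)$, are flagged, excluded and logged rather than
propagated.

**Budgets.** Allocation coefficients express grain, straw, root and
rhizodeposition C as proportions of whole-plant C (they sum to 1);
root-to-shoot divides root C by straw C; belowground-to-aboveground
divides root + rhizodeposition C by straw + grain C. `treatment_summary()`
reports means, standard errors and drought-vs-control percent changes;
inferential mixed models are deliberately out of scope.

**Trophic classification.** Independently of the isotope chain, prokaryotic
taxa are classed as copiotrophs (rrn copy number ≥ 5) or oligotrophs
(< 5), and per-sample oligotroph:copiotroph ratios are computed from read
counts (with a taxon-count option). Taxa without an rrnDB match are
excluded from the ratio and counted separately.

## The forward simulator

`sim_config()` / `simulate_experiment()` generate the complete measurement
and reference tables of a campaign with known truth. The defaults encode
the study conditions: 3 cropping systems × 2 water regimes × 4 replicate
plots; three 0.25 m layers; applied tracer 36.5 g ¹³C m⁻²; net recovery
46% (rainfed) vs 32% (drought); ~1060 g C m⁻² net assimilated, with
rainfed allocation putting ≈ 99 g C m⁻² into roots and ≈ 237 g C m⁻² into
rhizodeposits; drought shifting allocation belowground (grain −25%, fine
roots +56%, rhizodeposition +45%, total unchanged); plant natural
abundance −28‰, soil −26‰, EOM −29.3‰; bulk densities 1300/1450/1500
kg m⁻³ and background soil C 15/8/5 g C kg⁻¹ by layer. Noise defaults are
σ_δ = 0.2‰ additive Gaussian (IRMS-scale precision) and 5% multiplicative
lognormal on masses (field sampling/subsampling variability); neither
precision is documented for the original data, so both are stated
assumptions.

The generator embodies the mass-balance model exactly, which is what makes
forward–inverse testing sharp:

* One atom excess $\chi^E$ is shared by all plant pools and the
  rhizodeposits of a plot, solved in closed form so the pool excess masses
  sum *exactly* to the recovered tracer.
* The soil δ¹³C of each layer is solved in closed form so that the
  pipeline's soil excess mass equals the rhizodeposits' excess mass
  exactly (the dilution of rhizodeposit C into the layer's background C).
* The topsoil fine-root sample's atom fraction is the carbon-weighted
  mixture of the clean-root and EOM endmembers at contamination fraction
  φ, so the pipeline's $f_{RBC}$ recovers $1-\varphi$ identically.

Consequently a zero-noise, zero-contamination simulation is inverted by
the pipeline to ≤ 1e-9 relative error in qCdfR, root C and all allocation
coefficients — any regression in the chain breaks that equality — while
noisy simulations feed `recovery_study()`, which reports bias and RMSE of
the recovered quantities over replicate campaigns and a noise grid.

What the simulator does *not* emulate: within-cell biological variability
between plots (replicate scatter is measurement noise only), per-pulse
labelling dynamics (the 11 events are summarised by the seasonal recovery
fraction), depth- or class-dependent enrichment (the method assumes it
away, and the generator follows the method), microbial turnover of
rhizodeposits, and spatial structure. Passing recovery tests therefore
demonstrate correctness of the calculation chain under the method's own
assumptions — not robustness of the method to violations of those
assumptions in real fields.

## Numerical choices and edge cases

* δ ≤ −1000‰ is rejected (it implies nonpositive ¹³C); atom fractions must
  lie strictly in (0, 1).
* $\%CdfR = 100$ makes qCdfR singular; such layers are excluded, not
  extrapolated.
* Endmember separation below 1e-12 in the mixing model raises a degenerate
  mixing error instead of returning an unstable ratio.
* All randomness is confined to the simulator behind a single integer
  seed (`withr::with_seed`), making simulated tables byte-identical across
  runs; the analysis pipeline itself is deterministic.
* Replicate seeds in `recovery_study()` are derived from the base seed by
  fixed prime strides, keeping every derived seed a valid 32-bit integer.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_experiment(sim_config(seed = 1))
res <- analyze_experiment(sim$measurements, sim$references, sim$geometry,
                          quiet = TRUE)
treatment_summary(res$profile, c("root_c", "qcdfr", "root_to_shoot"))

# parameter recovery across 100 replicate campaigns
recovery_study(sim_config(seed = 1), n_reps = 100, noise_sd_delta = 0.2)
```

Problem sizes used throughout the test suite (20 seeds × 2 plots for the
exactness sweep, 100 replicates for the Monte-Carlo recovery) were chosen
to exercise every code path with comfortably converged Monte-Carlo
estimates.

## Known limitations

* The EOM correction presumes a measurable, clean coarse-root endmember in
  the topsoil of every plot; plots without one are an error by design.
* Negative atom excesses are retained; heavily noise-dominated layers can
  therefore produce flagged exclusions rather than values.
* The oligotroph:copiotroph ratio inherits the coarseness of taxon-level
  mean rrn copy numbers; it is a community-level index, not an estimate of
  any organism's growth rate.
* Treatment summaries are descriptive (mean ± SE, percent change); no
  inference is attempted.
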