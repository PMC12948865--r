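# rhizotrace

Tracer mass-balance analysis of root and rhizodeposition carbon from
¹³CO₂ pulse-labelling field experiments.

## What it is for

Quantifying how much carbon a crop puts below ground — into roots and,
invisibly, into the soil as net rhizodeposition — requires isotope
labelling: the crop is pulse-labelled with ¹³CO₂ through the season, and
at ripening the δ¹³C and carbon content of grain, straw, crown, coarse
and fine roots and of the soil are measured over depth layers, alongside
unlabelled natural-abundance references per treatment and layer.
`rhizotrace` is for researchers running such experiments (e.g. wheat
under contrasting cropping systems and water regimes). It implements the
complete calculation chain:

* δ¹³C ↔ ¹³C atom-fraction conversions and atom excess
  $\chi^E$ against treatment- and layer-matched references;
* excess-¹³C mass per compartment,
  $m^E = \chi^E\, m(C)\, M_{13} / (\chi_{12} M_{12} + \chi_{13} M_{13})$;
* correction of topsoil fine-root carbon for extraneous organic matter
  (EOM) by two-pool isotope mixing,
  $f_{RBC} = (\chi^E_S - \chi^E_{EOM}) / (\chi^E_{RB} - \chi^E_{EOM})$;
* area scaling ($RC_S = RC_M\,\rho\,z$) and aggregation over root classes
  and row positions;
* tracer partition into net rhizodeposition,
  $\%CdfR = m^E_{soil} / (m^E_{soil} + m^E_{root}) \cdot 100$ and
  $qCdfR = \%CdfR \cdot RC_S / (100 - \%CdfR)$;
* carbon-allocation coefficients, root-to-shoot and
  belowground-to-aboveground ratios, and treatment summaries;
* a copiotroph/oligotroph classifier by rrn copy number (threshold 5)
  with per-sample community ratios.

A forward simulator (`sim_config()`, `simulate_experiment()`) generates
full measurement campaigns with known ground truth, so the whole chain is
testable without field data, and `recovery_study()` measures estimator
bias and RMSE under measurement noise. See the vignette
`vignettes/tracer-mass-balance.Rmd` for the model, its assumptions and
the design choices.

## Worked example

```r
library(rhizotrace)

sim <- simulate_experiment(sim_config(seed = 1))    # 3 systems x 2 regimes x 4 plots
res <- analyze_experiment(sim$measurements, sim$references, sim$geometry,
                          quiet = TRUE)
ts <- treatment_summary(res$profile, c("root_c", "qcdfr", "root_to_shoot"))
ts[ts$system == "all", ]
#>        variable mean_control se_control mean_treatment se_treatment pct_change
#> 1        root_c       98.115     1.0197        122.582      1.12982       24.9
#> 2         qcdfr      234.378     3.1309        361.797      5.60785       54.4
#> 3 root_to_shoot        0.249     0.0029          0.385      0.00704       54.4
```

Reading: under the rainfed control the pipeline recovers about
98 g C m⁻² of root carbon and 234 g C m⁻² of net rhizodeposition per
plot (rhizodeposits are ~70% of belowground C input); the simulated
drought raises root C by ~25% and rhizodeposition by ~54%, and the
root-to-shoot ratio climbs from 0.25 to 0.39. Per-plot and per-layer
tables are in `res$profile` and `res$layers`; every clamp or exclusion is
in `res$log`.

File-based runs use the same schemas:

```r
run_pipeline("measurements.csv", "references.csv", "geometry.csv",
             out_dir = "results")
```

or the thin CLI at `inst/cli/rhizotrace.R` with verbs `simulate`, `run`,
`recover`, `summarize`.

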