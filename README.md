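# gvsfit

Dose-response model comparison for galvanic vestibular stimulation (GVS)
data. GVS — a direct current over the mastoids — induces both ocular torsion
(toward the anode) and perceived visual tilt (away from it). If the
vestibulo-ocular reflex alone stabilised vision, tilt would stay proportional
to torsion as stimulation grows; a torsion response that saturates while tilt
keeps rising instead implies additional central processing of the vestibular
signal. `gvsfit` is for vestibular/psychophysics researchers who want to run,
audit, or extend that model comparison on the published summary data of
Zink et al. (1998) or on their own summary tables.

For each measure *T* (degrees, unsigned magnitude) versus current *V* (mA)
the package fits three candidate forms by **constrained full-grid least
squares** over nonnegative parameters:

| family     | model                    | parameters                        |
|------------|--------------------------|-----------------------------------|
| `lin`      | T = a·V + b              | slope a (deg/mA), intercept b (deg) |
| `lin-prop` | T = a·V                  | slope a (deg/mA)                  |
| `exp`      | T = b·(1 − e^(−V/a))     | rate a (mA), asymptote b (deg)    |

Fits are compared by variance explained, R² = 1 − RSS/TSS with TSS about the
series mean for every family. The default grids match the original analysis
([0, 3.5] step 0.0005 for the linear families; [0, 7] step 0.001 for the
exponential — about 49 million candidate pairs, evaluated exactly and
vectorised in a few seconds). A synthetic-study generator and
parameter-recovery experiment quantify how reliably the procedure recovers
known truths under the study's design.

## Worked example

```r
library(gvsfit)

tab <- zink1998_table()                      # published summary table
torsion <- average_bilateral(tab, "torsion") # unsigned bilateral means
head(torsion, 3)
#>   intensity_mA mean_deg    sem_deg
#> 1          1.0     1.10 0.14288690
#> 2          1.5     1.35 0.07071068
#> 3          2.0     2.05 0.18898224

fit <- gvs_fit(torsion, "exp")               # full published grid
fit
#> Full-grid least-squares fit (exp family), ocular_torsion, 8 points
#>     a     b
#> 3.722 4.714
#> RSS: 0.08883   variance explained: 98.94%
```

The rate constant a = 3.722 mA and asymptote b = 4.714° say torsion rises
with an initial slope of b/a ≈ 1.27 deg/mA but can never exceed ~4.7°;
the exponential explains 99% of the torsion variance where the directly
proportional model manages 75%. The complete comparison:

```r
report <- run_reanalysis(tab)
report
#> Model comparison: grid least-squares fits
#>
#>         measure   family     a     b    rss var_explained
#>  ocular_torsion      lin 0.483 0.912 0.5401           94%
#>  ocular_torsion lin-prop 0.672    NA 2.1103           75%
#>  ocular_torsion      exp 3.722 4.714 0.0888           99%
#>     visual_tilt      lin 1.421 0.000 0.5981           87%
#>     visual_tilt lin-prop 1.421    NA 0.5981           87%
#>     visual_tilt      exp 3.649 7.000 1.2545           73%
#>
#> Torsion-tilt combinations, RSS over 3 observed pairs (best first):
#> exp-lin exp-exp lin-lin
#>  0.5099  1.2248  1.5902
```

Tilt stays proportional (87% of variance, intercept pinned at 0) while
torsion saturates, and the torsion–tilt relationship is best captured by the
exponential-torsion + proportional-tilt combination — the signature of
central stabilisation once the reflex saturates.
`render_figures(report, "figs")` writes the RSS-surface heatmaps, the
data-with-fits overlay, and the torsion-versus-tilt comparison;
`simulate_study()` / `recovery_experiment()` generate synthetic studies and
quantify parameter recovery. `inst/scripts/reanalyze.R` wraps the whole
pipeline for shell use.

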