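# cox2quant

Quantification machinery for imaging inducible cyclooxygenase-2
(COX-2), the enzyme upregulated by neuroinflammation. The package
implements the two analysis chains such a study runs and the
synthetic-data generators needed to validate them end to end:

* **Kinetic pipeline** — reversible one/two-tissue compartment
  simulation of regional time–activity curves (TACs), construction of
  a metabolite-corrected arterial input function from timed blood
  samples, Logan graphical estimation of the distribution volume
  $V_T$ (the equilibrium tissue-to-plasma ratio), Lassen occupancy
  plots recovering drug occupancy and the nondisplaceable volume
  $V_{ND}$, and the outcome arithmetic built on them:
  $BP_{ND} = (V_T - V_{ND})/V_{ND}$, SUV and SUV-ratio measures,
  percent changes, group means.
* **FISH pipeline** — RNAscope-style image quantification: watershed
  segmentation of DAPI nuclei, median + 2 SD spot detection with size
  filtering in the Cy3 (*Cox2*) and Cy5 (*Eno2*, neuronal marker)
  channels, exclusion of dual-channel autofluorescence, ≥ 2-dot
  per-cell transcript scoring, and fold-change / colocalization
  summaries — plus a scene generator that plants nuclei, Poisson
  spot counts and artifacts with known ground truth.

The methods vignette (`vignettes/methods.Rmd`) documents the models,
the tunable parameters and the design decisions in detail.

## Worked example

Simulate a blocking experiment and recover occupancy from scratch:

```r
library(cox2quant)

inp <- simulate_input(input_model_params(), seq(0, 120, by = 0.1))
sch <- default_frame_schedule(120)

# two-tissue region with analytic V_T = 2.0
p   <- kinetic_params(K1 = 0.1, k2 = 0.1, k3 = 0.05, k4 = 0.05)
tac <- simulate_tac(p, inp, sch)
logan_vt(tac, inp, t_star = 30)
#> <logan_fit> V_T = 2.009 mL/cm3 (t* = 30 min, n = 15, r2 = 1.0000)

# eight regions sharing V_ND = 4.3, blocked at 78% occupancy,
# re-estimated by Logan and fed to the Lassen plot
rep <- run_kinetic_demo()
round(c(occupancy = rep$lassen$occupancy, v_nd = rep$lassen$v_nd), 3)
#> occupancy      v_nd
#>     0.778     4.312
```

The recovered occupancy (77.8%) and $V_{ND}$ (4.31 mL cm⁻³) sit on
the planted truth (78%, 4.3): the Logan step's small transient bias
largely cancels between conditions. The same pattern for the image
stage:

```r
scene <- generate_scene(scene_params(seed = 7))
q <- quantify_image(scene)
q$result
#> <quant_result> 'region': 95 cells, Cy3+ 0.221, Cy5+ 0.653, coloc 0.714
scene_truth_summary(scene)
#>   n_cells frac_cy3 frac_cy5 colocalization
#> 1     100     0.21     0.64      0.7619048
```

Recovered fractions track the planted truth to a couple of cells; the
single-scene colocalization (0.714 vs 0.762 planted) tightens toward
the 0.75 generator parameter when scenes are pooled, which is what
the validation suite checks.

and the headline arithmetic:

```r
head(worked_examples()[, c("operation", "computed", "printed")], 3)
#>                    operation computed printed
#> 1 percent_change(3.47, 4.59) 32.27666      32
#> 2 percent_change(3.76, 5.32) 41.48936      42
#> 3 percent_change(4.59, 3.62) -21.13290    -21
```

A thin command-line front end lives in `inst/scripts/cox2quant`
(subcommands `simulate-tac`, `fit-logan`, `lassen`, `outcomes`,
`simulate-fish`, `quantify-fish`, `demo-kinetic`, `demo-fish`,
`worked-examples`, `dump-config`).

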