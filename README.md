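# nitratemodes

Non-temporal knowledge discovery for high-frequency in-stream nitrate
records, for ecohydrologists and water-quality data scientists who have
multi-season sub-hourly sensor tables and want to know *which environmental
conditions go with unusually low or high nitrate* once seasonality is out of
the way.

The pipeline:

1. **Detrend** — each sensor series is split into a seasonal baseline and a
   high-frequency residual ("`~`" series) by a sharp Fourier low-pass filter
   (cutoff 50 days; rainfall and discharge get a zero baseline).
2. **Pareto Density Estimation** — the nitrate residual's empirical PDF is
   estimated by hypersphere counting at the Pareto radius (a low quantile of
   the pairwise-distance distribution), a kernel choice tuned for mode
   discovery.
3. **Gaussian mixture modes** — the residual is modelled as
   `f(x) = Σ wᵢ φ(x; μᵢ, σᵢ)`, fitted by EM (monotone SQUAREM-accelerated),
   with the number of modes chosen by the AIC/BIC minimum over K = 1..10 and
   goodness of fit checked by chi-square, Kolmogorov–Smirnov and QQ pairs.
4. **Bayes classification** — every time point gets a posterior and a
   low / typical / high mode label.
5. **Mode-conditioned comparison** — every covariate (discharge, groundwater
   depth, soil moisture, temperatures, radiation, rainfall, conductivity) is
   grouped by the synchronous nitrate mode and tested pairwise with
   Bonferroni-corrected Welch t-tests at α = 0.01, yielding a significance
   table plus class-wise boxplot statistics and PDE curves.

A synthetic-data module generates multivariate sensor tables with the
statistical structure the analysis assumes (Markov regime-switching nitrate
mixture, mode-coupled covariate shifts, AR(1) sensor noise, two
growing-season blocks of 15,475 + 16,721 15-min rows, 4% missing cells), so
everything is testable offline.

## Worked example

```r
library(nitratemodes)

tab <- generate_sensor_table(seed = 1)   # 32,196 x 14 synthetic sensor table
det <- detrend_table(tab)                # baselines + "~" residuals
nit <- residual_series(det, "NO3")

fit <- em_fit(nit, K = 3, n_restarts = 5, seed = 1)
print(fit)
#> <gmm_fit> K = 3, loglik = -3340.126, converged after 1385 cycle(s)
#>   weight    mean     sd
#> 1 0.0542 -0.5629 0.2423
#> 2 0.7990  0.0154 0.2084
#> 3 0.1468  0.1227 0.3658

asg <- classify(fit, nit)
print(asg)
#> <class_assignment> 30874 classified points
#>     low typical    high
#>     4.7    92.3     2.9

covars <- setdiff(names(tab$data), "NO3")
groups <- lapply(setNames(covars, covars),
                 function(v) group_by_mode(asg, det, v))
print(build_comparison(groups, alpha = 0.01))
#> <comparison_table> alpha = 0.01, Bonferroni m = 39 (global scope)
#>  variable low-typical low-high typical-high
#>       q13        n.s.  5.9e-18      2.9e-32
#>       q18        n.s.  9.4e-21      7.6e-45
#>      Wt13      0.0022     n.s.         n.s.
#>      Wt18      0.0047     n.s.         n.s.
#>       GW3        n.s.    7e-14      1.6e-19
#>      GW25        n.s.     n.s.         n.s.
#>      GW32    1.4e-302 1.1e-221         n.s.
#>      At47        n.s.     n.s.         n.s.
#>      St24        n.s.     n.s.         n.s.
#>  Smoist24    1.4e-270   1e-123      2.8e-10
#>     Sol71       3e-47  1.1e-19         n.s.
#>      rain        n.s.     n.s.         n.s.
#>     Con47    4.8e-168 1.7e-100         n.s.
```

Read: the low mode is cleanly recovered (−0.563 vs the generating −0.59,
5.4% weight); the typical/high split is weakly identified on detrended data
at this seed — EM from any start, including the generating parameters,
converges to this same optimum, a known feature of heavily overlapping
minority components (see the vignette). The comparison table still echoes
the expected pattern: the low mode pairs with a shallower riparian water
table (GW32), wetter soil (Smoist24), less radiation (Sol71) and lower
conductivity (Con47); the high mode with lower discharge (q13/q18);
rainfall is uncoupled, hence all "n.s.". On pure i.i.d. mixture draws (the
acceptance-target setting) the same fitter recovers all three means — see
the acceptance report below.

The whole chain is also one call —
`run_all(run_config(simulate = TRUE, seed = 1, outdir = "out"))` — which
writes nine plain-text artifacts (residuals, PDE curve, model-selection
table, model JSON, classification, GoF report, comparison TSV, class
summaries, manifest), or a CLI:

```sh
Rscript -e 'nitratemodes::nitrate_cli()' simulate --seed 1 --out sim.csv
Rscript -e 'nitratemodes::nitrate_cli()' detrend --in sim.csv
Rscript -e 'nitratemodes::nitrate_cli()' fit --in residuals.csv --kmin 1 --kmax 10
Rscript -e 'nitratemodes::nitrate_cli()' run --config run.json --seed 1 --outdir out
```

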