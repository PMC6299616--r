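# tbinflam

ODE modeling of the acute neuroinflammatory response to severe traumatic
brain injury, for researchers analyzing longitudinal CSF cytokine panels
and for modelers studying microglial polarization dynamics.

After severe TBI, resting microglia polarize into pro-inflammatory
(M1-like) or anti-inflammatory (M2-like) states under cytokine cues, and
the balance between the two shapes secondary tissue damage over the
first five days. Patient subgroups with similar acute CSF inflammatory
profiles can reach very different six-month outcomes; mechanistic
differences between such subgroups are what this package is built to
probe.

## The model

Seven coupled ODEs track M1- and M2-like microglia, the CSF cytokines
IL-1β, IL-12 (pro-inflammatory), IL-10, IL-4 (anti-inflammatory), and a
qualitative secondary-damage variable D:

    dM1/dt   = Rm1·mr − Rms·M1 − μ_M1·M1
    dM2/dt   = Rm2·mr + Rms·M1 − μ_M2·M2
    dIL1/dt  = k_pn1·Rp − μ_n1·IL1
    dIL12/dt = k_pn12·Rp − μ_n12·IL12
    dIL10/dt = k_tn10·Rt + k_pn10·Ra − μ_n10·IL10
    dIL4/dt  = k_tn4·Rt + k_pn4·Ra − μ_n4·IL4
    dD/dt    = (α_n12·IL12 + α_n1·IL1)/(1 + (IL10/a_∞2)²)
               + r_M1·M1 − γ_M1·M1·D − γ_M2·M2·D

where the composite rates Rm1, Rm2 (microglial activation), Rms (M1→M2
switch), Rp (pro-inflammatory release), Rt (Th2-mediated release) and
Ra (anti-inflammatory release) are Hill functions uⁿ/(Kⁿ + uⁿ) of
weighted cytokine pools with quadratic IL-10/IL-4 suppression factors,
and mr = s_mr/(Rm1 + Rm2 + μ_mr) is the quasi-steady resting pool. The
45 parameters and 7 initial conditions are estimated from binned CSF
cytokine series by penalized Nelder–Mead in log space; perturbed-restart
ensembles (×U(0.5, 1.5), 100 refits) capture fit variability, and
per-cluster parameter distributions are compared by Bhattacharyya
overlap (BC) / distance (BD = −ln BC) with a normalized local
sensitivity gate (|S| > 2, S = (Δx/Δp)·(p/x)).

## Worked example

```r
library(tbinflam)

# Three cluster archetypes (validated ground-truth parameterizations)
arch <- make_archetypes()
simulate_model(arch$cluster1$params, arch$cluster1$init,
               times = seq(0, 120, by = 24))
#>   time_h    M1    M2   IL1  IL12  IL10  IL4    D
#> 1      0 20.00  5.00 10.00  3.00 60.00 4.00 1.00
#> 2     24 27.22  6.01 11.67  6.13 43.44 0.53 3.35
#> 3     48 40.43  6.30 22.32 11.94 37.73 0.95 4.21
#> 4     72 48.86  7.72 33.48 17.48 38.06 1.16 4.54
#> 5     96 51.92  9.33 41.81 21.42 39.79 1.24 4.61
#> 6    120 51.98 10.50 45.11 22.68 41.32 1.25 4.55
```

Cluster 1's trajectory shows the high-inflammatory-load phenotype:
prolonged elevated M1, high slowly-decaying IL-10, rising IL-1β/IL-12,
and slowly accumulating damage.

```r
# Synthetic cohort with the study's sampling structure: 89 patients,
# twice-daily draws with jitter, 36% dropout, lognormal noise (CV 0.3)
coh <- simulate_cohort(arch, cohort_spec(seed = 1))
coh$n_draws
#> [1] 588        # expected ≈ 567 CSF draws

# Moving-average binning (12-h windows, 6-h steps) of one cluster
ser <- as_series_list(coh$table)
b <- bin_series(ser[vapply(ser, \(s) attr(s, "cluster") == "cluster1",
                           logical(1))])
head(b[b$analyte == "IL10", ], 4)
#>    analyte bin_center_h mean   sd   se  n
#> 39    IL10            6 56.7 17.7 4.07 19
#> 40    IL10           12 56.4 19.2 4.18 21
#> 41    IL10           18 47.7 18.1 3.85 22
#> 42    IL10           24 45.5 16.1 3.79 18

# Penalized Nelder-Mead fit (shallow budget shown for speed)
fit_model(list(params = arch$cluster1$params, init = arch$cluster1$init),
          b, fit_opts(max_iter = 100, max_evals = 150))
#> Model fit: error 107.106 (data term 7.10595 )
#>   heuristics violated: late_m2_dominance
#>   converged: FALSE  evaluations: 102
```

The error is the SD-normalized squared deviation of the model from the
bin means (7.1 over ~76 usable bins) plus one flat penalty of 100: the
cluster 1 phenotype keeps M1 above M2 throughout, violating the
late-M2-dominance fitting heuristic (see the methods vignette). From a
baseline fit, `build_ensemble()` produces the perturbed-refit ensemble,
`sensitivity_screen()` the |S| > 2 gate, and `compare_ensembles()` the
ranked BC/BD table; `run_pipeline(pipeline_config(...))` runs all stages
and writes every artifact (binned tables, fit JSONs, ensemble CSVs,
comparison tables, resolved config) to an output directory.

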