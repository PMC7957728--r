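# dynpet

Quantitative analysis of dynamic ^18^F-FDG PET/CT studies in R: two-tissue
compartment kinetic modelling, box-counting fractal dimension of
time–activity curves, SUV quantification with hottest-lesion aggregation,
and Kaplan–Meier / log-rank screening of median-dichotomized PET
parameters against progression-free survival. It is aimed at researchers
reproducing or extending dynamic-PET pharmacokinetic analyses — in
particular the melanoma/immune-checkpoint-inhibitor setting of a
25-patient cohort imaged at baseline and after two therapy cycles — and it
ships a fully seeded synthetic cohort generator so the entire pipeline
runs and is tested without any patient data.

## The models at the core

**Kinetics.** Tissue curves follow the irreversible-FDG two-tissue
compartment model

    dCf/dt = K1·Cp − (k2 + k3)·Cf + k4·Cb
    dCb/dt = k3·Cf − k4·Cb
    Ct(t)  = (1 − VB)·[h ⊗ Cp](t) + VB·Cp(t)

with the closed-form bi-exponential impulse response `h` and the influx
rate `Ki = K1·k3/(k2 + k3) ≤ K1`. `forward_2tc()` evaluates the model on a
dense 1 s grid (exact-exponential trapezoidal recursion);
`fit_2tc()` estimates `(K1, k2, k3, k4, VB)` by bounded, multi-start
weighted least squares and derives `Ki`.

**Heterogeneity.** `fd_boxcount()` measures a TAC's box-counting fractal
dimension: the curve is normalized into the unit square, occupied boxes
are counted on dyadic grids (levels 1–4), and FD is the slope of
`log N` vs `log 1/ε`, clamped to [0, 2]. Straight lines measure 1; noisy,
chaotic curves approach 2. `voi_fd()` averages voxel-level FDs over a VOI.

**Quantification and survival.** `compute_suv()`, `interval_change()`,
`select_hottest()` / `aggregate_cohort()` (mean-of-five-hottest and
single-hottest approaches), `cohort_summary()` (medians per timepoint and
the interval change of the medians), `km_estimate()`,
`inverse_km_followup()`, `dichotomize_at_median()`, `logrank_test()` and
`survival_screen()` (median splits vs PFS, deliberately unadjusted for
multiplicity). `run_pipeline()` strings all stages together and
`write_report()` emits CSV tables, KM step functions and a checksummed
JSON manifest.

## Worked example

```r
library(dynpet)

cp    <- feng_input_function()       # analytic FDG bolus input
proto <- default_protocol()          # 24 frames / 60 min
truth <- kinetic_params(K1 = 0.19, k2 = 0.53, k3 = 0.19,
                        k4 = 0.01, VB = 0.05)
truth$Ki
#> [1] 0.05013889

# simulate a noisy lesion TAC and fit it back
tac <- generate_lesion_tac(truth, cp, proto, cv = 0.05, seed = 7)
fit <- fit_2tc(tac, cp)
round(c(K1 = fit$params$K1, k3 = fit$params$k3, Ki = fit$params$Ki), 3)
#>    K1    k3    Ki
#> 0.177 0.296 0.060

# fractal dimension of a heterogeneous 16-voxel VOI
voi_fd(generate_voxel_voi(truth, h = 0.3, n_voxels = 16, cp, proto,
                          cv = 0.05, seed = 7))$voi_fd
#> [1] 1.138

# full synthetic cohort -> report tables -> survival screen
report <- run_pipeline(cohort_config(seed = 1, include_tacs = FALSE,
                                     include_vois = FALSE))
report$lesion_summary_mean5
#>   parameter baseline_median interim_median change_pct change_pct_rounded
#> 1  suv_mean          6.9767         5.7819    -17.126                -17
#> 2   suv_max          9.9488         8.0636    -18.949                -19
#> 3        K1          0.1907         0.1533    -19.612                -20
#> 4        k3          0.1896         0.1816     -4.231                 -4
#> 5        Ki          0.0493         0.0361    -26.926                -27
#> 6        FD          1.1924         1.1973      0.405                  0
```

The summary table reads like the published cohort tables: medians across
patients of the mean-of-five-hottest lesion parameters at baseline and
interim, and the percent change between the two medians (raw and rounded).
At this seed the simulated cohort reproduces the study's structure —
lesion SUV_mean falls by 17% and its median split on the interim scan
separates survival (log-rank p ≈ 0.01 in
`report$survival_screen`), while baseline parameters show no effect.

A single noisy curve fits back with `Ki` within the noise-driven scatter
(ensemble median |ΔKi|/Ki ≈ 9% at 5% noise); noiseless curves recover to
machine precision.

Per-lesion TAC files (`read_tac_csv()`/`write_tac_csv()`), cohort CSVs and
a thin command-line wrapper (`inst/cli/dynpet.R`, subcommands `simulate`
and `run-all`) round out the interface.

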