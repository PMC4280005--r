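# fluxspline

Dynamic metabolic flux analysis (dMFA) with free-knot B-spline flux
profiles.

`fluxspline` estimates smooth time courses of the specific metabolic fluxes
of a reaction network from extracellular time-course data — medium
concentrations, biomass, off-gas exchange rates — without assuming any
kinetic rate laws. It is aimed at bioprocess and systems-biology
researchers who have a stoichiometric network and noisy batch or
chemostat measurements, and want time-resolved, thermodynamically feasible
flux estimates with honest uncertainty bands.

## The method in brief

Under the pseudo-steady-state assumption the intracellular balances reduce
to `S_int v(t) = 0`, so every admissible flux vector is `v(t) = K u(t)` for
a null-space basis `K` (n x d) and `d` free fluxes `u`. The extracellular
states `x = (c_ext, c_bio)` follow

    dx/dt = S_e K u(t) (q_bio' x)   [ + D(t) (x_in - x) for a chemostat ]

Each free flux is a clamped quadratic B-spline with free internal knots.
Estimation minimizes the variance-weighted sum of squared errors
`sum_ij ((y_j(t_i) - m_ij)/sigma_ij)^2` subject to the dynamics,
nonnegative states, and nonnegative irreversible fluxes
`z = I_irr K u >= 0`. The dynamics are discretized by orthogonal
collocation on finite elements (cubic Lagrange states, 3-point right-Radau
nodes, elements between measurement times). Model complexity is selected
incrementally: starting from the shortest feasible horizon with knotless
quadratics, the algorithm inserts one knot into one flux at a time,
accepting an insertion only when it lowers the small-sample corrected
Akaike criterion

    AICc = f + 2 n_p + 2 n_p (n_p + 1) / (n_meas - n_p - 1),

windows each accepted knot to its measurement interval, and extends the
horizon measurement by measurement, warm-starting every subproblem through
profile-preserving knot insertion and spline prolongation. The final fit is
gated by a chi-square test at `n_meas - n_p` degrees of freedom, and
uncertainty comes from a parametric Monte-Carlo bootstrap (percentile
bands across re-estimated replicates). The null-space basis can be a
user-chosen rational basis, an SVD orthonormal basis, or optimized during
estimation via `d(d-1)/2` rotation parameters.

## Worked example

The bundled small-scale batch study: a synthetic 7-reaction network
(4 intracellular metabolites, substrates A and E, product F, biomass),
free fluxes {1, 4, 5}, Monod/product-inhibition reference kinetics,
21 sampling times over 20 h, near-noiseless measurements
(sigma = 1e-4).

```r
library(fluxspline)

setup <- builtin_protocol("small_low_noise")
truth <- simulate_truth(setup$model, setup$kinetics, setup$protocol)
meas  <- sample_measurements(truth, setup$map, seed = 42)
nrow(meas)
#> [1] 84

fit <- incremental_estimate(meas, setup$model, setup$map)
fit
#> <dmfa_fit> 84 measurements, n_p = 29, SSE = 148.25, AICc = 238.47
#>   knots per flux: 3/0/5; chi-square gate: FAIL (f = 148.2 vs crit 73.31, dof 55)
```

The run takes about a minute: 18 horizon iterations and 85 solved
subproblems. Eight knots were inserted in total — three into the strongly
curved substrate-uptake flux, five into the product-formation flux, none
into the nearly flat flux 4 — so the algorithm concentrates flexibility
where the profiles bend. The chi-square gate *fails by design* here: at
sigma = 1e-4 the weighted objective detects that a quadratic spline is only
an approximation of the saturating reference kinetics, even though the
profiles themselves are recovered to a fraction of a percent:

```r
times <- setup$protocol$times
idx   <- match(times, truth$times)
est   <- flux_profiles(fit, times)
ref   <- tibble::tibble(time = rep(times, each = 7),
                        flux = rep(paste0("v", 1:7), length(times)),
                        value = as.numeric(truth$v[, idx]))
flux_deviation(est, ref)
#> # A tibble: 7 x 4
#>   flux  deviation magnitude    ratio
#>   <chr>     <dbl>     <dbl>    <dbl>
#> 1 v1      0.0308      16.9  0.00183
#> 2 v2      0.0308      16.9  0.00183
#> 3 v3      0.0226      12.2  0.00184
#> 4 v4      0.00174      3.32 0.000523
#> 5 v5      0.0175      10.9  0.00160
#> 6 v6      0.0209       1.94 0.0108
#> 7 v7      0.0106       2.32 0.00456
```

`deviation` is the integrated absolute difference between the estimated and
reference profile of each reaction flux over the 20 h horizon, `magnitude`
the integrated reference profile, and `ratio` their quotient: every flux is
recovered within 1.1% of its magnitude. The per-iteration history mirrors
the algorithm's decisions:

```r
tail(fit$history, 3)
#> # A tibble: 3 x 8
#>   iteration n_time   n_p aic_before min_aic action             flux interval
#>       <int>  <int> <int>      <dbl>   <dbl> <chr>             <int>    <int>
#> 1        17     20    27       230.    235. no better minimum    NA       NA
#> 2        18     21    29       252.    238. knot inserted         1       20
#> 3        18     21    29       238.    247. no better minimum    NA       NA
```

`tidy(fit)`, `glance(fit)` and `augment(fit)` give broom-style parameter,
summary and residual tables; `autoplot(fit)` plots the flux profiles and
`plot_fit_outputs(fit)` the fitted outputs against the data. Confidence
bands:

```r
boot <- bootstrap_confidence(fit, meas, n_replicates = 1000, seed = 7)
autoplot(boot)
```

A continuous-reactor study with 68 reactions and 6 free fluxes is available
as `builtin_protocol("medium")`, and a thin command-line front end
(`inst/cli/fluxspline`) wraps `simulate`, `estimate`, `bootstrap` and
`report` for shell pipelines.

## Package layout

| Where | What |
| --- | --- |
| `R/network.R` | stoichiometry partitions, null-space bases, validity checks |
| `R/bspline.R` | clamped B-splines: evaluation, insertion, prolongation, windows |
| `R/dynamics.R` | reduced batch/chemostat model, output maps, irreversible fluxes |
| `R/collocation.R` + `src/colloc.cpp` | Radau grids, constraint assembly, exact per-element state solves |
| `R/estimation.R` | subproblem objective/solver, AICc, incremental driver, chi-square gate |
| `R/uncertainty.R` | Monte-Carlo bootstrap bands |
| `R/synthetic.R` | synthetic study networks, reference kinetics, samplers |
| `R/io.R`, `R/tidiers.R`, `inst/cli/fluxspline` | formats, broom-style accessors, plots, CLI |

The two bundled networks are synthetic reconstructions built in code (see
the methods vignette for what they do and do not reproduce).
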