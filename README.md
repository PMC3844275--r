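# lhpriming

Simulation and fitting of a two-pathway linear compartment model of
luteinising hormone (LH) secretion from pituitary gonadotrophs stimulated
by pulses of gonadotropin-releasing hormone (GnRH).

In an oestrogenised preparation, an LH surge carries a *shoulder* on its
declining phase, and a second GnRH pulse an hour after the first evokes a
markedly larger surge (*self-priming*). The model explains both with one
mechanism: a fast pathway (conceptually Ca²⁺-mediated exocytosis) drives
the acute surge through a single rate-limiting intermediate,

> d i₁/dt = a·δ(t − T₀) − p·i₁,  d[LH]/dt = i₁ − q·([LH] − L₀),

while a slow pathway (conceptually cAMP/PKA → transcription → translation)
produces, after a delay t_p = T_P − T₀, a synthesised protein

> PT(t) = m/(r − s) · (e^(−s·u) − e^(−r·u)) · H(u),  u = t − T₀ − t_p,

that multiplicatively augments the fast pathway:

> d[LH]/dt = (1 + ([OT] + PT)/a) · i₁ − q·([LH] − L₀).

The delayed synergy term produces the shoulder within a surge, the primed
response across surges, and the biphasic LH profile under constant GnRH;
a constant [OT] term models continuous oxytocin exposure (only a + [OT]
is identifiable). The package provides the closed-form kinetics and an
exact trajectory evaluator, SD-weighted nonlinear least-squares fitting
with linearised confidence intervals, a synthetic perifusion-data
generator (2-min sampling, six replicate chambers, Gaussian noise),
Monte-Carlo coverage validation, and predictive scenario simulations
(third-pulse spacing, protein-synthesis inhibition, constant GnRH).

This is intended for quantitative endocrinologists and modellers working
with perifusion time series of pulsatile hormone secretion, and as a
worked example of fitting impulse-driven linear compartment models with
delay to such data.

## Worked example

Simulate the packaged two-surge optimum and examine self-priming with a
third pulse:

```r
library(lhpriming)
pp <- params_two_surge()
run_scenario("third_pulse_60", pp)
#> Scenario 'third_pulse_60': pulses at 223.111, 283.111, 343.111 min
#>   surge 1: peak 9.113 ng/mL at t = 235.9 min (raw ratio 1.000, increment ratio 1.000)
#>   surge 2: peak 26.41 ng/mL at t = 294.0 min (raw ratio 2.898, increment ratio 2.831)
#>   surge 3: peak 30.07 ng/mL at t = 353.4 min (raw ratio 3.300, increment ratio 2.895)
```

Each surge is larger than the last: the second and third pulses ride on
the synthesised protein left by their predecessors (the *increment ratio*
corrects the raw peak ratio for slow-clearance carryover of the previous
surge's tail; it is exactly 1 for every pulse when protein synthesis is
inhibited, `run_scenario("inhibit_protein_synthesis", pp)`).

Generate a synthetic perifusion dataset and refit it:

```r
fp <- params_first_pulse()
gen <- generate_series(fp, default_figure2_design(seed = 1))
fit <- fit_parameters(gen$mean, pulse_schedule(c(223, 283)), fp,
                      mode = "unconstrained", n_starts = 3, seed = 1)
fit
#> Two-pathway LH model fit (unconstrained mode, converged in 35 iterations)
#>   81 points, weighted SSE = 18.1701, R^2 = 0.9980
#>  parameter    estimate          se       ci_low     ci_high free
#>          a   1.8594850  0.03650393  1.78673e+00   1.9322372 TRUE
#>          p   0.0939329  0.00647514  8.10280e-02   0.1068379 TRUE
#>          q   0.0615349  0.00450594  5.25545e-02   0.0705152 TRUE
#>          m  10.8946051 63.25693172 -1.15176e+02 136.9654882 TRUE
#>          r   1.7667622 10.27715874 -1.87156e+01  22.2491101 TRUE
#>          s   0.0109016  0.00415448  2.62175e-03   0.0191815 TRUE
#>         T0 222.9927296  0.09249855  2.22808e+02 223.1770789 TRUE
#>         TP 253.4784683  2.89732625  2.47704e+02 259.2528312 TRUE
#>   fixed: L0 = 0.888448 ng/mL (pre-pulse mean), OT = 0
```

The fast-pathway parameters and timing are tightly determined (the truth
here is a = 1.8001, p = 0.0846, q = 0.0641, T0 = 223); the enormous
intervals on `m` and `r` are the model being honest about a real
identifiability limit — at this noise the data constrain the protein's
envelope, not its amplitude/rate split. See the methods vignette
(`vignettes/two-pathway-lh-model.Rmd`) for the profile-likelihood
analysis behind that statement.

Oxytocin augmentation, from the packaged GnRH-only and oxytocin optima:

```r
augmentation_ratios(params_two_surge(), params_oxytocin_full())
#>  surge  basal
#> 2.2731 2.0417
```

Oxytocin scales surge drive and basal secretion by nearly the same
factor, consistent with a single multiplicative site of action that does
not touch the slow pathway.

## The analysis workflow

Numbered drivers under `analysis/` rerun the whole study over the
package's functions, writing tables and trajectories under `results/`:

1. `01_simulate_surges.R` — trajectories under the packaged optima,
   including the first-pulse fit's parameter-free prediction of the
   primed second surge.
2. `02_generate_data.R` — synthetic GnRH-only and oxytocin datasets with
   manifests.
3. `03_fit_model.R` — first-surge constrained fit + second-surge
   prediction; two-surge unconstrained fit; oxytocin (a + OT)-only
   refit; augmentation ratios.
4. `04_sensitivity.R` — Monte-Carlo interval coverage (10- and
   200-dataset scales) and per-replicate parameter comparison.
5. `05_scenarios.R` — third-pulse spacing, protein-synthesis inhibition,
   constant-GnRH input.

Run them in order from the repository root:
`for s in analysis/0*.R; do Rscript $s; done`

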