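---
title: "A two-pathway model of GnRH-induced LH secretion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-pathway model of GnRH-induced LH secretion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhpriming)
```

## The model

Luteinising hormone (LH) is released from pituitary gonadotrophs in
response to pulses of gonadotropin-releasing hormone (GnRH). In an
oestrogenised preparation the response to a second pulse an hour after the
first is markedly larger than the first (*self-priming*), and each surge
carries a secondary bulge — a *shoulder* — on its declining phase. This
package implements a deliberately minimal linear-compartment account of
both phenomena.

**Pathway I (fast).** A GnRH pulse at time $T_0$ is idealised as an
impulse that instantaneously raises a rate-limiting intermediate $i_1$ to
amplitude $a$, after which it decays:

$$i_1(t) = a\,e^{-p\,(t - T_0)}\,H(t - T_0),$$

with $H$ the Heaviside step ($H(x) = 0$ for $x \le 0$: the intermediate
jumps immediately *after* the pulse instant, not at it). LH is released in
proportion to $i_1$ and cleared at rate $q$.

**Pathway II (slow).** The same pulse also drives, after an activation
delay $t_p = T_P - T_0$, a second intermediate $i_2$ (amplitude $m$, decay
$r$) whose downstream product is a synthesised protein $PT$ with decay
$s$:

$$PT(t) = \frac{m}{r - s}\left(e^{-s u} - e^{-r u}\right) H(u),
  \qquad u = t - T_0 - t_p .$$

Conceptually Pathway I is the Ca^2+^-mediated exocytotic route and Pathway
II the cAMP/PKA/transcription route; the package models neither mechanism
explicitly, only their kinetic signatures.

**Synergy.** The protein multiplicatively augments the fast pathway:

$$\frac{d\,[\mathrm{LH}]}{dt}
  = \Big(1 + \frac{[\mathrm{OT}] + PT(t)}{a}\Big)\, i_1(t)
    - q\,\big([\mathrm{LH}] - L_0\big),$$

where $\mathrm{OT} \ge 0$ is a constant oxytocin augmentation (zero when
oxytocin is absent) and $L_0$ is basal LH. Because $PT$ lags the pulse by
$t_p$, the synergy term produces the shoulder within a surge; because $PT$
outlives the interval between pulses, it produces self-priming across
surges. For multiple pulses at times $T_i$, $i_1$ and $PT$ are the sums of
the corresponding single-pulse terms (both stages are linear); LH itself
is *not* additive across pulses whenever $m > 0$, because of the
$PT \cdot i_1$ cross-term — that nonadditivity *is* the priming.

### Parameters

| Parameter | Meaning | Units |
|---|---|---|
| `a` | Pathway-I impulse amplitude of $i_1$ (also divides the synergy term) | ng mL^-1^ min^-1^ scale |
| `p` | decay rate of $i_1$ | min^-1^ |
| `q` | LH clearance rate | min^-1^ |
| `m` | Pathway-II impulse amplitude of $i_2$ | min^-1^ scale |
| `r` | decay rate of $i_2$ | min^-1^ |
| `s` | decay rate of the synthesised protein | min^-1^ |
| `T0` | arrival time of the first pulse | min |
| `TP` | protein-synthesis activation time (first pulse); `tp = TP - T0` | min |
| `OT` | oxytocin augmentation coefficient (0 without oxytocin) | as `PT` |
| `L0` | basal LH | ng/mL |

Three optimal sets are packaged as functions:
`params_first_pulse()` (constrained fit to the first surge alone),
`params_two_surge()` (unconstrained fit to both surges), and
`params_oxytocin_full()` (all parameters refit under oxytocin; its
protein rates satisfy `r = s` exactly). Because oxytocin enters additively
with `a`, only the sum `a + OT` is identifiable in the oxytocin condition;
the packaged set stores `a` at its GnRH-only value and the remainder in
`OT`, and any other split with the same sum is observationally identical.

### Design choices in the formulation

* **Impulse input.** The experimental pulse lasts 4 min, short against
  the intermediate lifetimes ($1/p \approx 12$ min, $1/r \approx
  1$–$7$ min across the packaged sets), so the reference model treats it
  as an impulse with the dose absorbed into `a` and `m`.
  [simulate_finite_pulse()] provides the boxcar variant (unit pulse area,
  so it converges to the impulse model as the duration shrinks) to
  quantify what the idealisation neglects; with a 4-min pulse the
  difference in the simulated two-surge trajectory is at the percent
  level.
* **Basal handling.** Clearance is modelled toward basal,
  $q([\mathrm{LH}] - L_0)$, i.e. the integrated state is the deviation
  from basal, starting at zero. A literal reading of the clearance
  equation with an absolute initial condition would instead let the
  baseline decay as $e^{-qt}$ over the ~220 pre-pulse minutes, which no
  perifusion record shows. We adopt the deviation convention as the only
  one consistent with a flat baseline, without claiming it is what any
  particular earlier analysis did.
* **Degenerate protein kinetics.** The general $PT$ formula is undefined
  at $r = s$, yet the fitted oxytocin kinetics land exactly there, so the
  analytic limit $m\,u\,e^{-ru}$ is required. The implementation
  evaluates $PT$ as $m\,u\,e^{-ru}\,\phi((r-s)u)$ with
  $\phi(x) = (e^x - 1)/x$, which is algebraically identical to the
  general formula for $r \ne s$, continuous through the degeneracy, and
  free of the catastrophic cancellation the textbook form suffers as
  $r \to s$ ($\phi$ switches to a series below $|x| = 10^{-3}$).

## Numerics

The LH deviation equation is linear with a forcing that is a finite sum of
(linear-in-time) exponentials, so `simulate_lh()` evaluates it **exactly**
by superposing closed-form responses of the clearance kernel; the same
$\phi$-style kernels keep the evaluation stable when a forcing rate
collides with `q`. There is no discretisation error and a two-surge
trajectory on an 81-point grid costs well under a millisecond — which is
what makes the Monte-Carlo studies below affordable. An independent
adaptive route (`method = "ode"`, lsoda with relative tolerance $10^{-8}$,
absolute $10^{-10}$, restarted at every pulse time and every
protein-activation time so no discontinuity is stepped across) is kept as
a cross-check; the test suite holds the two routes to within $10^{-5}$
ng/mL of each other and both to within $10^{-6}$ relative of the
hand-derived double-exponential closed form in the pure-fast-pathway case.
The constant-GnRH and finite-pulse variants, which sit in no inner loop,
use the adaptive route directly.

Trajectory values within $10^{-12}$ (relative to scale) below zero are
snapped to zero: the superposition is nonnegative in exact arithmetic for
nonnegative parameters, and the snap removes only floating-point residue
while leaving any genuine negativity visible.

## Fitting

`fit_parameters()` minimises the SD-weighted residual sum of squares
$\sum_k \big((\mathrm{LH}_{\mathrm{model}}(t_k) - y_k)/\sigma_k\big)^2$
with bounded Levenberg–Marquardt (via minpack.lm); series without
per-point SDs fall back to unit weights with a notice. Internally the
timing is parametrised as $(T_0, t_p)$ so the structural requirement
$T_P > T_0$ is a plain lower bound ($t_p \ge 1$ min in constrained mode,
$> 0$ otherwise); later pulses keep their offsets from the first fixed
while $T_0$ moves. Basal `L0` is not optimised: it is fixed to the
pre-pulse mean of the series (or to a supplied value, as in the
simulation studies where the generating basal is known). The constrained
mode bounds `a, p, q, m, r, s` below by zero and confines `T0` to the
observation window; an initialisation that violates the constraints is
rejected, never silently clipped. Multi-start (default 3, seeded) perturbs
strengths, rates and the delay by up to ±20% and the clock time `T0` by
±2 min — a relative perturbation of an absolute calendar time would be
meaningless. If the model cannot be evaluated at a proposal, every
residual is set to $10^6$ (a large, finite penalty) so the optimiser can
back out.

Confidence intervals are linearised: covariance
$s^2 (J^\top J)^{-1}$ from the numeric Jacobian of the weighted residuals
at the optimum, $s^2 = \mathrm{SSE}/(n-k)$, t-quantiles with $n-k$
degrees of freedom; `TP = T0 + tp` gets a delta-method interval. The
inverse is taken by symmetric eigendecomposition with eigenvalues floored
at $10^{-12}$ of the largest, so directions the data barely constrain
yield honestly enormous standard errors rather than a failed solve. A
`variance = "known"` mode instead takes the stated SDs at face value
($\sigma^2 = 1$, normal quantile); this matters below.

`r_squared()` is the plain unweighted $1 - SS_{res}/SS_{tot}$ on the
fitted points; the weighted objective, not $R^2$, is what is optimised,
and no convention for a weighted $R^2$ is assumed.

### Identifiability: what one or two surges can and cannot pin down

Two findings from this package's own simulation studies shape everything
downstream:

* Under the **two-surge optimum** (`r = 0.80` min^-1^, a 1.25-min
  Pathway-II rise) with 2-min sampling, the profile objective is flat in
  `r` from its optimum out to `r = Inf`: the data bound `r` only from
  below, and `m` slides with it along the ridge `m/r ~ const` (the
  protein *envelope* is identified, its amplitude/rate split is not).
  Consistently, point estimates of `m` across noise replicates range over
  more than an order of magnitude at nearly identical objective values.
* Under the **first-pulse optimum** (`r = 0.15` min^-1^, a 6.7-min rise)
  the same design resolves all eight parameters, and estimates converge
  to the truth as the noise is reduced.

At realistic noise (about 1 ng/mL per replicate, ~4% of the first surge's
peak) the median relative errors of `m`, `r`, `s` are therefore tens of
percent even in the well-resolved case, while the *fitted LH trajectory*
— the identifiable functional — stays well inside the data's noise band.
The test suite asserts parameter recovery (median relative error at most
10% per parameter over 20 seeded datasets) in the information-sufficient
regime (noise SD 0.25 ng/mL per replicate, mean of six replicates) and
trajectory recovery at the full realistic noise.

## The synthetic perifusion generator

`generate_series()` emulates the reference experiment's *statistical*
structure: a noise-free model trajectory sampled every 2 min over a
200–360 min window, first pulse at 223 min and a second 60 min later, six
replicate chambers with independent additive Gaussian noise, and the
across-replicate mean reported with per-point sample SDs (the mean ± SD
form in which perifusion series are published). The default noise SD is
1 ng/mL — a package constant chosen once as visually comparable to
published replicate error bars, not a measured value; no reproduced
quantity depends on it. Negative noisy values are kept: truncation would
bias the stated noise model, and the fitting tolerates them.

The generator deliberately does **not** emulate: radioimmunoassay error
structure (heteroscedastic calibration curves — noise here is Gaussian
with the SD you specify), chamber washout/transport dynamics (the model's
`q` absorbs clearance and washout together), pulse-duration effects (the
impulse idealisation, unless you opt into `simulate_finite_pulse()`), or
between-animal variability (replicates share one truth). Green tests on
synthetic data therefore demonstrate the *estimator's* correctness under
the model's own assumptions, not the model's adequacy for any particular
tissue preparation.

## The validation machinery

`monte_carlo_coverage()` repeats the noise-refit protocol: generate
datasets from a known truth, refit, and count how often the nominal-95%
intervals contain the truth, pooled across the eight free parameters and
all datasets (10 datasets × 8 parameters = 80 intervals at protocol
scale) and also per parameter. Refits are initialised at the truth with a
single start; basal is pinned at the generating value (re-estimating it
from each noisy pre-pulse window would inject a systematic offset the
intervals do not model); the weights are the known SD of the replicate
mean, i.e. the well-specified case. The calibration-scale study (200
datasets) runs under the first-pulse truth at noise SD 0.25 ng/mL — the
regime the identifiability analysis above shows to be locally quadratic,
which is the only regime in which a *linearised* interval construction
can be expected to calibrate; under the two-surge truth no interval
method could cover `r`, whose profile is flat to infinity. The analysis
stage reports pooled coverage near 96% there.

Misspecification is probed by the `assumed_sd` argument: the data keep
their true noise while the weights understate it. This ladder must use
`variance = "known"`, because the default estimated-variance construction
is *invariant* to a uniform misstatement of the weights — $s^2$ rescales
it away — a point easy to miss when designing coverage checks. With the
known-variance construction, coverage falls monotonically (from ~0.97
through ~0.70 to ~0.49 at 1×/2×/4× understatement in the packaged test).

`per_dataset_comparison()` fits each replicate individually and asks
whether the replicate-mean 95% intervals bracket the mean-series optimum.
With eight nominal-95% intervals, all eight bracket the optimum only
about two times in three even under perfect behaviour, so the packaged
test allows one marginal exclusion. Comparing conditions fitted with a
common initialisation, oxytocin shifts only the apparent drive strength
`a` (which absorbs `OT`), leaving every kinetic parameter's interval
overlapping the GnRH-only one.

### Scenarios and peak accounting

`run_scenario()` simulates third-pulse spacings of 60 vs 180 min after
the second pulse and protein-synthesis inhibition (`m = 0`,
the kinetic signature of a translation inhibitor such as cycloheximide).
Peaks are maxima of a dense trajectory (0.1 min grid; halving the step
moves peaks by less than 0.1%) within each inter-pulse window. One
accounting subtlety: LH clearance is slow ($1/q \approx 32$ min), so the
tail of one surge is still ~25% of its peak when the next pulse arrives
60 min later, and *raw* peak ratios overstate priming — under `m = 0`
the raw second/first ratio is 1.18 with zero priming. The scenario result
therefore also reports `increment_ratios`, the per-pulse peak of the
trajectory minus what the preceding pulses alone would have produced;
under `m = 0` these are exactly 1 (the model is then linear in the
pulses), and they are the quantity the equal-peaks statements in the test
suite assert. At a 60-min third-pulse interval the third increment ratio
is ~2.9; at 180 min the protein has decayed and it is ~1.0.

Constant-GnRH input replaces the impulse by the step response
$i_1 = (aG/p)(1 - e^{-p\tau})$ and the corresponding step-driven protein
convolution; with $m > 0$ the secretion rate re-accelerates after
$t_{on} + t_p$ (a biphasic profile, detected as a second local maximum of
the slope), with $m = 0$ it is monophasic. The link between the biphasic
response and self-priming is thus the same delayed synergy term.

## Problem sizes and seeds

All stochastic tests fix their seeds. The packaged studies use: 20
datasets for recovery, 200 for calibration coverage, 20 per rung of the
misspecification ladder, 8 per rung of the noise-reduction ladder, and 6
replicates for the per-dataset comparison — sizes chosen so the whole
suite, about 300 nonlinear fits, completes in a few minutes on one core
thanks to the exact trajectory evaluator.

## Known limitations

* The model is linear by construction; saturation of the secretory
  response at high GnRH is out of scope (the original argument being that
  nonlinearity does not change the shape of the intermediate response).
* `a` and `OT` are never separately identifiable; all reporting is in
  terms of `a + OT`.
* Under sub-resolution Pathway-II kinetics (rise time below the sampling
  interval) `m` and `r` are identified only through their ratio; fits are
  still useful for trajectory prediction but their `m`, `r`, `TP`
  intervals should be read with the profile-flatness caveat above.
* Linearised intervals are trustworthy only in the locally quadratic
  regime; at realistic noise with weak slow-pathway identifiability a
  profile-likelihood or resampling interval would be required (not
  implemented).
* Basal LH is a fixed offset, not a dynamic state; slow baseline drift in
  a real perifusion run would bias `L0` and, through it, the surge
  amplitudes.
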