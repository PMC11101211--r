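---
title: "Energy-landscape models of spatial working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape models of spatial working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(memscape)
```

## The model

memscape models performance in a delayed-estimation task: a participant
sees a dot at position $x \in [0.1, 0.9]$ on a line (positions normalized
to $[0, 1]$), waits through a delay of 0, 1, 3, 6, 13 or 20 s, and
reproduces the position. The memory trace $x$ is modeled as drift–diffusion
on a one-dimensional energy landscape $E(x)$ whose negative gradient
$G(x) = -dE/dx$ is the drift profile:

$$ x \leftarrow x + \big(\beta\, G(x) + \varepsilon\big)\,dt,
   \qquad \varepsilon \sim \mathcal N(0, \sigma^2), $$

integrated by the Euler scheme with $dt = 0.1$ s. Minima of $E$ are
attractors: a flat landscape is a continuous attractor (every position
marginally stable), a two-well landscape a discrete attractor system whose
wells bias responses but stabilize them against noise.

The *plastic* variant lets the trace deform the landscape as it moves.
After every step a Gaussian depression is carved into the energy at the
current position $x_0$, which on the drift is the kernel

$$ \zeta_P(x) = (x_0 - x)\, e^{-(x_0-x)^2 / 2\sigma_P^2},
   \qquad G(x) \leftarrow G(x) + \zeta_P(x)\,\beta_P\, dt. $$

**Sign convention.** We state the kernel in the form whose energy
integral is a *negative* Gaussian — an attractive depression. This is the
form required by the mechanism it implements: the depression lets the
trace "burrow" in place, impeding descent into the attractor (preserving
stimulus information at long delays) and attracting the next trial's
trace toward the previous response (proactive interference). The
opposite sign produces a repulsive bump and inverts both phenomena; we
verified this by simulation before fixing the convention.

Between trials the deformation partially relaxes:
$G_{\text{next}}(x) = \lambda_T G_0(x) + (1 - \lambda_T) G_f(x)$, where
$G_0$ is the static profile and $G_f$ the final deformed profile of the
previous trial. $\lambda_T = 1$ is a full reset; $\lambda_T = 0.8$ is the
default carry-over used for inter-trial simulations, chosen as the value
that yields a realistic amount of proactive interference. $\lambda_T$ is
applied once per trial boundary (trials are self-paced, so wall-clock
inter-trial time is not modeled).

A task delay $d$ maps to internal simulation time $t_0 + d$: the
encoding parameter $t_0$ absorbs the time between stimulus onset and the
start of the recorded delay. Optional encoding-period parameters
(`beta_enc`, `sigma_enc`) let drift and noise differ during $[0, t_0)$;
plasticity accrues throughout, including the encoding period, since the
dynamics on $[0, t_0)$ are otherwise assumed identical to the delay
period.

## Parameters, units and defaults

| parameter | meaning | units | search range | fitted values (static / plastic) |
|---|---|---|---|---|
| $G(x)$ | drift profile, 50 grid points | line units / s | $[-5, 5]$ | — |
| $\beta$ | drift strength | – | $[0.03, 0.2]$ | 0.0481 / 0.0794 |
| $\sigma$ | noise strength (s.d. per step) | line units | $[0, 0.2]$ | 0.0821 / 0.0977 |
| $t_0$ | encoding delay | s | $[1, 4]$ | 1.22 / 2.4843 |
| $\beta_P$ | plastic weight | 1 / s | $[0.1, 15]$ | — / 9.9976 |
| $\sigma_P$ | plastic sigma | line units | $[0.015, 0.05]$ | — / 0.0218 |
| $\lambda_T$ | inter-trial decay | – | $[0, 1]$ | 0.8 (not fit) |

`params_static_fit()`, `params_static_meta()` and `params_plastic_fit()`
return the published fitted sets; `param_bounds()` the search box.

**Noise discretization.** The literal per-step update multiplies the
noise draw by $dt$, so pure diffusion has
$\mathrm{Var}(x_t) = \sigma^2 t\, dt$ rather than the Euler–Maruyama
$\sigma^2 t$. We implement the literal scaling as the default because the
fitted $\sigma$ values are only meaningful under it;
`noise_scaling = "sqrt_dt"` switches to the standard scheme for
comparison. Likewise $\sigma$ is interpreted as the noise *standard
deviation* (its "noise strength" reading), not a variance.

**Boundaries.** Positions reflect at 0 and 1, preserving probability mass
on the line. Reflection is an exact identity for interior positions, so
noiseless trajectories are bitwise reproducible.

**Drift smoothing.** The 50 fitted drift values are smoothed with a
Gaussian kernel before use so the fit does not hinge on single grid
values. The printed width of that kernel is not interpretable as stated
(its units are ambiguous at 50 bins on a unit line), so the width is a
parameter in line units, default 0.02 — about one grid spacing. The
smoothing matrix is row-renormalized, so constants are preserved exactly
and no mass leaks at the edges.

**Two-well landscape.** The idealized discrete attractor used in the
simulation and recovery studies is the cubic
$G(x) = -a(x - c_1)(x - b)(x - c_2)$ with wells at $c_{1,2} = 0.3, 0.7$
and barrier $b = 0.5$: zero crossings sit exactly at the stated points
with the stabilizing sign pattern, and the default amplitude $a = 40$
keeps $|G| < 5$ while giving a well relaxation time of a few seconds at
fitted drift strengths, so biases saturate within the 20 s task horizon.

## Behavioral statistics

* **Bias profile** (`compute_bias_profile`): mean signed error per target
  bin; 41 equal-width, non-overlapping bins spanning $[0.1, 0.9]$ (the
  printed bin width is arithmetically inconsistent with 41 bins, so the
  bin count is taken as authoritative). The overall bias at a delay is
  the maximum absolute bin bias, bootstrapped 1000 times.
* **Bias saturation curve** (`fit_bias_curve`): the default functional
  form is $B(t) = \eta(1 - e^{-\lambda t}) + B_0$, which saturates at
  $\eta + B_0$ as the interpretation of the parameters requires; the
  printed form with $(1 + e^{-\lambda t})$ decays instead and is
  available via `form = "literal"`. The rate's uncertainty comes from a
  residual bootstrap with leverage-corrected residuals, and the reported
  interval is a log-scale Student-t interval with $n - 3$ degrees of
  freedom: with only six delays the usual normal-quantile percentile
  interval covers a true rate at ~80% rather than 95% (we measured both;
  the t-interval restores nominal coverage).
* **Mutual information** (`mutual_information`): plug-in estimator on a
  12 × 12 joint over equal-width bins spanning the full line $[0, 1]$,
  natural log, cells with a zero marginal contributing zero. A discrete
  attractor with $n$ wells bounds steady-state MI at $\ln n$.
* **Response distributions** (`estimate_response_distributions`): per
  (target bin, delay), Gaussian KDE of errors on 50 bins spanning
  $[-0.25, 0.25]$, normal-reference (Silverman) bandwidth by default
  since none is stated; model-side vectors additionally pass a length-3
  moving mean to damp Monte-Carlo jitter. Degenerate cells are handled
  explicitly: no trials → uniform (logged), zero spread → point mass.
* **Proactive interference** (`pi_spatial`): Gaussian-kernel weighted
  mean error versus previous-response offset over 21 offsets in
  $[-0.3, 0.3]$, kernel variance 0.05. The curve is computed *within*
  current-target bins (50 centers on $[0.1, 0.9]$, window equal to the
  spacing) and averaged across bins weighted by trial count: on a
  pooled computation the landscape's own target-dependent bias
  correlates with the offset and masquerades as serial dependence — we
  verified by simulation that a full-reset control only comes out flat
  with the within-bin computation. `pi_temporal` reports the range
  (max − min) of the curve per delay in a reference bin, by default the
  bin with maximal range at the longest delay.
* **Attention filter** (`attention_filter`): drops trials with absolute
  error above 0.25 (a single trial's "bias" can only mean its own
  error). Idempotent by construction.

## Fitting

Data and model are both reduced to response-distribution sets and
compared by Kullback–Leibler divergence summed over all
(target bin, delay) cells. The data distribution is the reference
measure — $\mathrm{KL}(\text{data} \,\|\, \text{model})$ — which is the
likelihood-consistent direction and penalizes the model for missing
observed mass. Model bins are floored at $10^{-6}$ and renormalized so
empty Monte-Carlo bins cannot blow up the cost.

Optimization is a cyclic coordinate pattern search under the box
constraints of the table above: poll ± one mesh step per parameter,
accept the first improvement, halve the mesh after an unsuccessful
cycle. Phase 1 searches the full set (50 drift values plus dynamics
parameters, drift initialized at zero, dynamics at bound midpoints);
phase 2 re-polls only the dynamics parameters with the landscape frozen.
Every cost evaluation reuses the same per-(start, run) noise substreams
(common random numbers), sized for the largest admissible $t_0$ — without
this, pattern search on a Monte-Carlo cost surface cannot terminate
meaningfully. Parameter counts for information criteria are $k = 53$ for
the static model (50 drift + $\beta, \sigma, t_0$) and $k = 55$ for the
plastic model, + 2 for the encoding variant.

The bias-only meta fit (`fit_bias_only`) swaps the cost for
$\sum_t (B_m - B_d)^2 / B_d + (\tau_m - \tau_d)^2 / \tau_d$ with
zero-valued normalizers floored at $10^{-6}$.

Model comparison (`compare_models`) bootstraps the trials, recomputes
both fixed models' log-likelihoods per resample, and reports the
empirical probability that the information-criterion difference flips
sign, floored at $1/n_{\text{boot}}$; ties count half so identical
models score 0.5.

## The synthetic-data generator

`generate_dataset()` emulates the study conditions: 161 participants
with about 110 trials each (~17,760 trials), targets i.i.d. uniform on
$[0.1, 0.9]$, two of the six delays per participant, trials simulated
*in sequence* through `simulate_trial_sequence()` so inter-trial
structure is present whenever $\lambda_T < 1$, and ~1.2% inattentive
trials whose response is replaced by the target plus an error of
magnitude $0.25 + |U(0, 0.25)|$, signed to stay on the line (the source
data filters inattention rather than modeling it; this injection model
exists so the filter's bookkeeping is testable end-to-end). Every
dataset regenerates bit-for-bit from its spec and seed.

What the generator deliberately does not emulate: response times, skip
behavior beyond a flag, perceptual encoding noise beyond the optional
encoding-period parameters, participant heterogeneity in model
parameters, and wall-clock inter-trial intervals. Tests passing on this
synthetic data therefore establish that the pipeline recovers the
structure the model family itself generates — not that human data obeys
the model.

`generate_recovery_grid()` builds the validation mesh for the fitting
procedure: a grid of (noise, drift-strength) cells on the idealized
two-well landscape, 50 starting positions × 50 runs per cell sampled at
the six task delays, grid values spanning $[0.05, 0.18]$ — inside the
search bounds and bracketing the fitted values. Recovery fits freeze the
landscape and $t_0$ at their generating values and search
$(\beta, \sigma)$, mirroring the mesh the validation study varies.

## Problem sizes and numerical choices

The packaged analyses run at desk scale, chosen to make every stochastic
conclusion decisive at a few bootstrap standard errors: mutual
information at steady state from 10,000 simulated trials; the diffusion
law at 10,000 runs; parameter recovery on a 3 × 3 mesh (50 starts × 50
runs per cell, 100 model-side runs per cost evaluation, ~60 + 40 pattern
search evaluations per fit); proactive interference from 80 simulated
participants × 120 trials per condition, which separates the
$\lambda_T = 0.8$ carry-over from the full-reset control by more than
three bootstrap standard errors. The full-scale fit (50 drift values,
50 × 300 Monte-Carlo design, thousands of cost evaluations) is the same
code path with a larger `fit_config()`.

Tie-breaks and degenerate inputs are resolved explicitly: empty
(target bin, delay) cells become uniform distributions and are logged;
zero-spread error samples become point masses at the nearest bin; a flat
bias curve flags the rate as unidentifiable rather than returning an
arbitrary value; a fit with no cost improvement over its initialization
is returned with `converged = FALSE`, never silently.

## Known limitations

* The pooled trial table is treated as exchangeable across participants;
  there is no hierarchical per-participant model.
* $\lambda_T$ is explored, not fitted — the self-paced design leaves it
  unidentified.
* The plastic kernel is purely attractive; repulsive serial-dependence
  regimes reported elsewhere would need a different kernel shape.
* The binned MI estimator carries the usual positive small-sample bias
  (~0.01–0.02 nats at the packaged sizes); ceiling checks include an
  explicit allowance for it.
* Pattern search finds local optima; the two-phase schedule and common
  random numbers make it reproducible, not global.
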