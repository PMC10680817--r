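---
title: "Mean-field Ising quantification of brain integration and segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field Ising quantification of brain integration and segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isingseg)
```

## The model

Resting-state brain dynamics are often summarized as a balance between two
states: *integration* (widespread, coordinated signaling) and *segregation*
(localized, independent signaling). isingseg makes that two-state picture
physical by mapping it onto the order–disorder transition of a mean-field
Ising model.

Each parcellated region contributes a spin $\sigma_i(t) \in \{-1, +1\}$: the
sign of the slope of its continuous signal between consecutive time points.
The brain-wide order parameter is the **synchrony**
$s(t) = \frac{1}{N}\sum_i \sigma_i(t)$, the magnetization per spin. With
$N$ regions, $s$ lives on the parity grid $\{-1, -1+2/N, \dots, 1\}$.

The maximum-entropy distribution of the total spin $n = N_\mathrm{eff}\, s$
under a pairwise (second-moment) constraint and a uniform single-spin prior
is the mean-field form

$$P(n) = \frac{1}{Z}\binom{N_\mathrm{eff}}{(N_\mathrm{eff}+n)/2}
  e^{\lambda n^2 / N_\mathrm{eff}^2},$$

with one coupling parameter $\lambda$ and one hyper-parameter: the
**effective number of regions** $N_\mathrm{eff}$. Atlas regions are not
independent units — a 300-region parcellation behaves like a few tens of
effective units — so $N_\mathrm{eff}$ replaces the atlas size and is chosen
once per data set (see the fourth-moment scan below). `synchrony_pmf()`
evaluates $P(n)$ in log space with a max-shift, so any coupling is
overflow-free.

**Pseg** is the probability that $|s|$ falls below a threshold $s^*$
(strictly; boundary points count as integrated), and $P_\mathrm{int} = 1 -
P_\mathrm{seg}$. Empirically it is a fraction of time points
(`pseg_empirical()`); under the model it is the mass of the segregated
microstates (`pseg_model()`).

## Critical point and threshold calibration

Expanding the log-binomial around $s = 0$ gives
$\ln P(s) = \mathrm{const} + \Lambda s^2 - N_\mathrm{eff}\, s^4/12 + \dots$
with $\Lambda = \lambda - N_\mathrm{eff}/2$: the quadratic term vanishes at
$\lambda_c = N_\mathrm{eff}/2$ (`critical_lambda()`), where the synchrony
distribution turns from unimodal (disorder, segregation) to bimodal (order,
integration).

The threshold $s^*$ is fixed by requiring $P_\mathrm{seg} = 1/2$ exactly at
the critical point, which makes Pseg comparable across data sets with
different $N_\mathrm{eff}$. Solving this on the discrete parity grid is
ill-posed at two-decimal precision — the cumulative mass jumps by 5–8% per
grid point for $N_\mathrm{eff} \le 64$, and any grid-point convention
shifts the answer by $O(1/N_\mathrm{eff})$. `calibrate_s_star()` therefore
solves the half-mass equation in the continuum critical limit, where the
density at $\Lambda = 0$ is the pure quartic $\exp(-N_\mathrm{eff}
s^4/12)$ on $s \in [0, 1]$:

```{r calibration}
vapply(c(30, 40, 64), calibrate_s_star, numeric(1))
```

This yields $s^* = 0.360,\ 0.337,\ 0.301$ for $N_\mathrm{eff} = 30, 40,
64$, scaling as $s^* \approx 0.85\, N_\mathrm{eff}^{-1/4}$ (the quartic
law). The value is carried at full precision and rounded to two decimals
only for reporting.

`pseg_model()` defaults to the same continuum convention
(`method = "landau"`, density $\exp(\Lambda s^2 - N_\mathrm{eff} s^4/12)$),
so that Pseg at $(\lambda_c, s^*)$ is $1/2$ by construction at any
$N_\mathrm{eff}$. The literal strict parity-grid sum is available as
`method = "grid"`; the two agree to a few times $10^{-3}$ away from grid
jumps. The empirical Pseg always uses the strict count.

## Fitting the coupling and selecting the effective dimension

Because the maximum-entropy solution is exactly the mean-field family,
fitting $\lambda$ reduces to moment matching: `fit_lambda()` solves
$\langle s^2\rangle_\mathrm{model} = m_2^\mathrm{obs}$ by bisection
(bracket grown geometrically; tolerance $10^{-10}$ on the $m_2$ residual,
at most 200 iterations). The observed $m_2$ is computed over **all** atlas
regions; moments, not histograms, are the fitting currency — that is the
only scale-free way to compare $N = 300$ data with an $N_\mathrm{eff} = 40$
model. If $m_2^\mathrm{obs} < 1/N_\mathrm{eff}$ (sub-binomial variance) the
root is negative — a nonphysical coupling — and the subject is flagged
excluded, with the negative root retained as a diagnostic.

$N_\mathrm{eff}$ is a hyper-parameter, shared by all subjects of a data
set. `select_neff()` scans candidates (multiples of 5 by default) and
scores each by the error between observed and model fourth moments — the
next even moment the fit does not constrain (odd moments vanish by the
symmetric prior). The default objective is the cohort-level RMSE
$\sqrt{\mathrm{mean}_i (m_4^{\mathrm{obs},i} - m_4^{\mathrm{model},i})^2}$;
a sum of per-subject absolute errors is available as `objective =
"sum_abs"`, and the argmin is insensitive to the choice in every recovery
experiment we run, since both are monotone summaries of the same
per-subject errors.

## Graph-Ising simulation

`metropolis_run()` simulates single-spin-flip Metropolis–Hastings dynamics
on an explicit connectome. Coupling convention: the mean-field weight
$e^{\lambda n^2/N^2}$ counts every unordered pair twice through $n^2$, so a
graph with per-edge log-weight $J_\mathrm{edge} = 2\lambda_0/N^2$ has
graph-averaged effective coupling $\lambda = \lambda_0\, p_\mathrm{edge}$
— and on a complete graph its stationary synchrony distribution is
*exactly* `synchrony_pmf()` at that coupling, which the test suite checks
against long runs and against full state enumeration on tiny graphs.

Defaults follow the degradation protocol: $\lambda_0 = 86$ (so a
density-0.40 graph starts at $\lambda = 34.4$, just above
$\lambda_c(64) = 32$), 2500 recorded steps of 640 attempts ("10 spin flips,
64 times"; we read this as 640 independent single-spin attempts at random
nodes and record synchrony after each step's attempts — equilibrium
statistics do not depend on the schedule), random $\pm 1$ initialization,
no burn-in discarded. A `burn_in` knob exists; use $\ge 100$ steps when
measuring equilibrium moments in isolation. `edge_removal_experiment()`
removes 5 undirected edges uniformly at random per round (both directions
vanish together) for 83 rounds, re-running the dynamics each round, and
reports the Spearman correlation between average degree and Pseg.

## The synthetic cohort generator

Real multi-site fMRI cohorts are access-controlled, so the generator
produces inputs with exactly the statistical structure the analysis
assumes: per time point, a total spin drawn from the exact pmf at a planted
$(N_\mathrm{eff}, \lambda)$ (inverse-CDF; unit assignment exchangeable);
meta-units copied to $N$ region channels (remainder channels attached to
the first units); each copy flipped with probability $\varepsilon$;
continuous traces rebuilt as cumulative sums of spin-signed positive
increments (uniform on $[0.5, 1.5]$, unit mean) so binarization recovers
the planted spins exactly and ties cannot occur.

Cohort defaults are fixed once: 300 regions, 490 time points, ages uniform
on 20–80, planted $N_\mathrm{eff} = 40$, a linear coupling schedule from
$\lambda = 30$ at age 20 down to 8 at age 80 (crossing the critical value
20 in mid-life, which produces a clear rising Pseg trend), $\varepsilon =
0$, and randomized sex/handedness with zero true effect. Synchrony columns
are independent across time — the moment-matching fit only uses marginal
moments. What the generator does **not** emulate: hemodynamics, realistic
noise spectra, temporal autocorrelation, motion, or site effects. Passing
recovery tests therefore demonstrate correctness of the estimators under
the model's own assumptions, not robustness to real-data violations of
them.

## Cohort pipeline choices

- QC keeps subjects whose scan length equals the cohort's modal length,
  then applies an age cap (default 90; exact ages above it are typically
  protected information). Fit-stage exclusions (negative coupling) are
  recorded per subject; every input subject appears exactly once in the
  output with its reason.
- Age bins are left-closed 5-year intervals anchored at the floor of the
  youngest included age; each bin reports the median Pseg and a standard
  error, by default the normal-approximation median SE
  $1.2533\,\mathrm{SD}/\sqrt{n}$ (a bootstrap SE is available — the
  estimator behind published error bars is rarely stated, so both are
  kept).
- The covariate model is plain additive OLS, Pseg ~ age + sex +
  handedness, with no interactions or standardization, and p-values are
  reported without multiplicity correction (single headline statistic per
  cohort).
- Per-subject Pseg variability uses non-overlapping 60-point windows by
  default; window length is a free choice and exposed as an argument.

## Numerical and degenerate-input conventions

- Exact zero slopes binarize to $+1$ deterministically.
- Non-finite signal values abort with an error naming the subject.
- `fit_lambda` at exactly $m_2 = 1/N_\mathrm{eff}$ returns $\lambda = 0$.
- Empty graphs are legal (free spins); a removal protocol that would
  exhaust the graph truncates with a warning.
- All stochastic entry points take explicit seeds and restore the caller's
  RNG state; the Metropolis kernel draws from R's RNG so `set.seed()`
  governs compiled code too.

## Problem sizes

The shipped tests run cohorts of 30–200 subjects at 150–2000 time points,
full $2500 \times 640$ Metropolis protocols with 5-seed averages, 83-round
removal trajectories at 3 seeds, exact enumeration oracles up to
$2^{12}$ spin configurations, and $10^5$-draw sampler checks; these sizes
give Monte-Carlo errors comfortably inside every asserted tolerance while
keeping the default suite around three minutes.

## Known limitations

- The calibration fixes $\lambda_c = N_\mathrm{eff}/2$ from the Gaussian
  expansion; finite-size corrections to the critical coupling are not
  modelled, and the two-decimal thresholds carry a $\pm 0.01$ convention
  uncertainty.
- Erdős–Rényi surrogates are homogeneous: their simulated Pseg tracks the
  mean-field value at $\lambda_0 p_\mathrm{edge}$ (at $\lambda = 34.4$,
  $N = 64$ that is $\approx 0.35$, and our 5-seed simulation averages
  agree). Real diffusion-MRI connectomes are modular and hub-heavy and can
  order more strongly at equal density, i.e. start at lower Pseg; no
  synthetic graph family shipped here reproduces that, and heterogeneous
  per-edge coupling distributions are out of scope.
- Per-individual $N_\mathrm{eff}$ fitting and voxel-level scans are out of
  scope; $N_\mathrm{eff}$ is one value per data set.
- The generator's iid-in-time synchrony understates the effective
  autocorrelation of real scans; empirical moment standard errors on real
  data are larger than the iid formula suggests.
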