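# isingseg

Quantifying the balance between **integrated** (globally coordinated) and
**segregated** (locally independent) brain dynamics from parcellated
resting-state fMRI, by mapping brain signaling onto the order–disorder
transition of a mean-field Ising model.

Most integration/segregation metrics are graph-theoretic heuristics with
mutually inconsistent aging trends. isingseg instead treats the two states
as physical phases. Each region becomes a spin
$\sigma_i(t) \in \{-1, +1\}$ (the sign of the signal slope between
consecutive time points); the order parameter is the synchrony
$s(t) = \frac{1}{N}\sum_i \sigma_i(t)$. The total spin
$n = N_\mathrm{eff}\,s$ follows the maximum-entropy pairwise model

$$P(n) = \frac{1}{Z}\binom{N_\mathrm{eff}}{(N_\mathrm{eff}+n)/2}
  e^{\lambda n^2/N_\mathrm{eff}^2}$$

with a coupling strength $\lambda$ (fit per subject by second-moment
matching) and an effective region count $N_\mathrm{eff}$ (one value per
data set, selected by a fourth-moment error scan — atlases with hundreds
of regions behave like a few tens of independent units). The segregation
probability is

$$P_\mathrm{seg} = \Pr\left(|s| < s^*\right), \qquad
  P_\mathrm{int} = 1 - P_\mathrm{seg},$$

with the threshold $s^*$ calibrated per $N_\mathrm{eff}$ so that
$P_\mathrm{seg} = 1/2$ exactly at the model's critical coupling
$\lambda_c = N_\mathrm{eff}/2$. The package also ships Metropolis–Hastings
Ising dynamics on explicit connectome graphs with a random edge-removal
protocol (simulated structural degradation), and a synthetic cohort
generator with planted $(N_\mathrm{eff}, \lambda)$ and age-dependent
coupling schedules for end-to-end validation.

## Worked example

Calibrate a threshold, generate a synthetic aging cohort (80 subjects,
300 regions, planted $N_\mathrm{eff} = 40$, coupling falling linearly from
30 at age 20 to 8 at age 80), fit every subject, and test the age trend:

```r
library(isingseg)

round(calibrate_s_star(40), 2)
#> [1] 0.34

spec   <- cohort_spec(n_subjects = 80, seed = 7, t_scan = 490)
cohort <- synth_cohort(spec)
fits   <- fit_cohort(cohort$subjects, cohort$metadata, n_eff = 40)
head(fits, 3)
#>   subject_id   age     m2 lam_hat   pseg included
#> 1 SYN0001     79.3 0.0417    8.36 0.904  TRUE
#> 2 SYN0002     43.9 0.232    21.4  0.401  TRUE
#> 3 SYN0003     26.9 0.564    27.2  0.0573 TRUE
```

Old subjects (weak coupling, disordered phase) sit near
$P_\mathrm{seg} \approx 1$; young ones (strong coupling, ordered phase)
near 0; mid-life subjects near the critical value 1/2. The cohort-level
trend recovers the planted decline:

```r
glance(age_trend(fits))
#>   spearman_rho  p_value n_included n_bins outcome
#> 1        0.996 8.08e-86         80     12 pseg
```

Simulating structural degradation — an Ising system on a 64-node random
connectome at edge density 0.40 (effective coupling
$\lambda_0 p_\mathrm{edge} = 86 \times 0.40 = 34.4$, just above
$\lambda_c(64) = 32$), removing 5 random edges per round for 83 rounds —
drives the system through the transition; Pseg rises as average degree
falls:

```r
g    <- er_connectome(64, pedge = 0.4, seed = 7)
traj <- edge_removal_experiment(g, sim_config(seed = 7))
glance(traj)
#>   spearman_rho   p_value n_rounds s_star lam0
#> 1       -0.998 1.52e-104       84  0.301   86
```

`tidy()` on any result returns the underlying tibble, and `autoplot()`
draws the standard figure for pmfs, age trends, removal trajectories and
$N_\mathrm{eff}$ scans. A thin command-line wrapper over these functions
is installed at `inst/cli/isingseg.R` (subcommands `calibrate`,
`scan-neff`, `fit`, `trend`, `simulate`, `synth`).

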