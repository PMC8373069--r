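# tightropekit

Analysis toolkit for single-molecule and biochemical studies of DNA-repair
protein turnover — the kind of experiment in which a glycosylase is watched
in real time on damage-containing "DNA tightropes", its bound lifetime and
1-D motion are quantified, a second repair factor is tested for
colocalization and for its ability to push the glycosylase off its product,
and the single-molecule picture is tied back to bulk excision kinetics,
EMSA titrations and AFM volumetrics.

The package is aimed at single-molecule biophysicists and DNA-repair
biochemists who already have extracted observables (per-frame particle
positions, dwell times, band intensities, AFM height/area measurements) and
need the downstream statistics. It also ships a synthetic-data generator
with known ground truth for every observable, so the entire pipeline is
testable end to end without any raw imaging data.

## What it computes

* **Diffusion analysis.** Time-averaged mean squared displacement with
  overlapping windows,
  `MSD(nΔt) = (1/(N−n)) Σᵢ (x₍ᵢ₊ₙ₎ − xᵢ)²`,
  fitted two ways: the linear 1-D model `MSD(nΔt) = 2D(nΔt) + y` for the
  diffusion coefficient *D* (the intercept *y* absorbs static localization
  error), and log–log regression for the anomalous exponent *α*
  (`MSD ∝ t^α`). Fits with R² < 0.8 or using < 10% of the MSD plot are
  flagged invalid.
* **Dwell-time survival.** Kaplan–Meier survival curves of bound lifetimes
  with right-censoring at the observation window; half-life `t½` by
  least-squares fit of `S(t) = exp(−t·ln2/t½)` (the conventional
  survival-decay fit) or by the censored-exponential MLE
  `t½ = ln2·Σdᵢ/n_observed`, recommended under heavy censoring.
* **Motility and colocalization.** Rolling-SD phase segmentation into
  motile/stationary phases, per-particle motility calls, and two-colour
  colocalization by concurrent proximity with greedy one-to-one matching
  (fraction reported over the union of particles, Venn-style).
* **AFM volumetrics.** `Volume = (⟨H⟩ − B)·A`,
  `V_protein = V_complex − (V_DNA1 + V_DNA2)/2`, a volume-vs-MW standard
  curve, and Gaussian-mixture (EM) deconvolution of molecular-weight
  populations into monomer/dimer/co-complex species.
* **Bulk biochemistry.** EMSA lane quantification with background
  subtraction; equilibrium K_d by the exact single-site ligand-depletion
  (quadratic) model
  `f = [(E+S+K_d) − √((E+S+K_d)² − 4ES)] / (2S)`;
  pre-steady-state burst kinetics
  `P(t) = A₀(1 − e^(−k_burst·t)) + A₀·k_ss·t`; and fold-stimulation between
  condition pairs (end-point product ratio and `k_ss` ratio).

## Worked example

```r
library(tightropekit)

# a cohort at the glycosylase-alone condition, but with a 590 s half-life
cfg <- sim_config(n_particles = 100, motile_fraction = 0.10, D_true = 1e-2,
                  half_life_true = 590, alpha_true = 1.0, seed = 42)
sim <- simulate_tightrope_particles(cfg)

# diffusion analysis of one motile particle
tr <- sim$trajectories[[which(sim$truth$is_motile)[1]]]
prof <- compute_msd(tr)
fit_msd_linear(prof)
#> Diffusion fit (linear): D = 0.004688 um^2/s, alpha = -
#>   R^2 = 0.988 over 25% of the MSD plot (937 lags); valid

# dwell-time survival under a 300 s window (~72% censored here)
dw <- simulate_dwell_times(500, half_life = 590, window = 300, seed = 7)
fit_half_life(dw, "mle_censored")
#> Exponential half-life (mle_censored): 627.4 +/- 52.8 s (k = 0.0011 /s)
#>   141 observed, 359 censored

# equilibrium binding: fit a noisy 8-point EMSA titration
iso <- simulate_binding_isotherm(4, dna_total = 8,
                                 titrant = c(0, 1, 2, 4, 8, 16, 32, 64),
                                 noise_sd = 0.02, seed = 8)
fit_quadratic_kd(iso)
#> Quadratic-depletion binding fit: Kd = 4.038 +/- 0.175 nM (R^2 = 0.9987)
```

The fitted *D* for a single 300 s trajectory scatters around the 0.01
μm²/s ground truth (individual time-averaged MSD fits are noisy; cohort
means converge). The half-life estimate brackets the 590 s truth within
one standard error, and the K_d fit recovers the 4 nM truth from noisy
fraction-bound data.

`run_simulate()` writes a complete fixture directory (trajectories, dwell
records, AFM field + calibration, excision time courses, isotherm, truth
and config sidecars), and `run_report()` runs every stage over it and
returns the cohort summary (motile fraction, D/α, half-lives, colocalized
fraction, AFM species table, K_d, fold-stimulation) as JSON.

## Vignette

`vignettes/methods.Rmd` documents the models, the estimators and their
assumptions, every tunable parameter with its default and units, what the
synthetic generator does and does not emulate, and the numerical choices.
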