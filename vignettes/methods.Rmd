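---
title: "Models and estimators in tightropekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in tightropekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tightropekit)
```

# The experimental system

The package analyses single-molecule experiments in which a DNA-repair
protein (in the motivating system, the adenine glycosylase MUTYH, with the
damage sensor UV-DDB as a second factor) is imaged on long "tightrope" DNA
substrates carrying an abasic-site analogue every 2 kb. Movies of
quantum-dot-labelled protein give, after upstream kymograph extraction,
per-frame 1-D positions along the DNA. From these the pipeline derives
diffusion coefficients, anomalous-diffusion exponents, motile fractions,
bound-lifetime survival curves and two-colour colocalization; companion
bulk assays (excision kinetics, EMSA titrations) and AFM volume
measurements are quantified by the same package. Because raw imaging data
for such studies are rarely deposited, a synthetic-data generator with
known ground truth stands in for every observable, and all tests are
parameter-recovery or analytic checks against that ground truth.

# Trajectory model and diffusion estimation

## Generative model

A particle is *motile* with probability `motile_fraction`; otherwise it is
stationary at its binding site. Motile particles move by fractional
Brownian motion (fBm) with Hurst exponent $H = \alpha/2$, scaled so the
ensemble MSD is $2 D t^{\alpha}$; at $\alpha = 1$ this is an ordinary
Gaussian random walk with $\mathrm{MSD} = 2Dt$. fBm is chosen because it
is the minimal stationary-increment Gaussian process with
$\mathrm{MSD}\propto t^\alpha$: experiments report $\alpha$ without
committing to a motion model, and fBm adds no extra parameters. Every
frame receives i.i.d. Gaussian localization noise (`loc_noise_sd`,
default 0.03 um — typical quantum-dot precision; this is a configuration
assumption, not a measured property).

fBm increments are drawn by Davies–Harte circulant embedding, which is
exact in distribution and $O(n\log n)$; the implementation is validated
against the analytic fractional-Gaussian-noise autocovariance
$\gamma(k)=\tfrac12(|k{+}1|^{2H} - 2|k|^{2H} + |k{-}1|^{2H})$ and against
the Brownian special case. Bound lifetimes are exponential with mean
$t_{1/2}/\ln 2$, truncated at the observation window and flagged
right-censored; lifetimes and motion are independent draws. Particles are
placed on consecutive damage sites (`site_spacing * bp_to_um` apart;
1 kb = 0.34 um for B-DNA).

Defaults mirror the imaging condition of the motivating study:
12.5 frames/s (the instrument range was ~11–12.5 fps; one value keeps
fixtures reproducible and the rate is a parameter), 300 s window, 10%
motile, $D = 3.75\times10^{-3}$ um²/s, $\alpha = 1.19$, half-life 8900 s,
24% co-bound in two-colour mode.

## MSD and its fits

`compute_msd()` implements the overlapping-window time average
$$\mathrm{MSD}(n\Delta t) = \frac{1}{N-n}\sum_{i=1}^{N-n}
  (x_{i+n}-x_i)^2,$$
exactly as written (all $N-n$ start frames per lag), and is tested for
exact equality against a brute-force double loop.

`fit_msd_linear()` runs OLS of $\mathrm{MSD} = 2D(n\Delta t) + y$ over the
first `fit_fraction` of lags (default 0.25, a common compromise between
the bias of long lags and the variance of short ones); the intercept $y$
absorbs the $2\sigma_{loc}^2$ offset from localization noise, so $D$ is
unbiased in its presence. `fit_alpha()` regresses
$\log \mathrm{MSD}$ on $\log(n\Delta t)$ over the same range; the slope is
$\alpha$. The estimation method for $\alpha$ is a design choice (the
log–log slope is the standard estimator when only the linear-D model is
stated); non-positive MSD values are dropped before taking logs, and fewer
than 3 usable points yields an *invalid* estimate rather than an error.

Both fits carry the validity filter used in practice: estimates with
$R^2 < 0.8$ or using less than 10% of the full MSD plot are marked
`valid = FALSE` but returned, so the filter is auditable. The
`fraction_of_plot_used` is computed against the full lag range of the
profile, not the fitted subset.

Known estimator properties, measured in the test suite: per-trajectory
time-averaged fits are noisy (relative SD of $\hat D$ about 67% for
300-frame tracks at the default fit range), and the log–log $\alpha$
estimator carries a small negative bias (about $-0.04$ to $-0.08$ at 300
frames, shrinking with trajectory length) because the expectation of the
log of a fluctuating MSD lies below the log of its expectation. Recovery
tests therefore use cohort means/medians: 50-trajectory cohorts recover
the published mean $\alpha$ values within $\pm 0.1$, 400-trajectory
cohorts the published mean $D$ within 15%, and 200 trajectories of 1500
frames recover $\alpha \in \{0.8, 1.0, 1.2\}$ within 0.08 and the
generalized $D$ (from the log–log intercept) within 10%. These problem
sizes are the package's test conditions, chosen so the expected
statistical error sits well inside each tolerance.

## Phase segmentation and motility

The segmentation rule is a design choice (publications rarely state one):
the rolling standard deviation of position over `window_frames` (default
10) is compared with `motile_threshold` (default 0.09 um = 3x the default
localization noise); contiguous labels are merged and phases shorter than
`min_phase_frames` are absorbed into their longer neighbour. A particle is
*motile* iff it has at least one motile phase. On synthetic cohorts with
motile $D = 10^{-2}$ um²/s this classifier is essentially error-free for
300 s tracks; sensitivity degrades for slower or shorter motile phases
(at $D$ near $3.75\times10^{-3}$ um²/s a slow mover may stay under
threshold), which is a property of any SD-threshold rule at fixed noise.

## Colocalization

A cross-channel pair colocalizes when within `distance_threshold`
(default 0.2 um, the practical two-colour registration precision) for at
least `min_overlap_frames` (default 10) concurrent frames; qualifying
pairs are matched one-to-one greedily by ascending mean separation, ties
broken by lower particle id. The fraction is reported over the union of
particles (Venn convention). Detector-recovery runs use stationary
two-channel fields: with motile singles present, a particle diffusing
several microns over the window genuinely crosses other-channel particles
and satisfies the proximity rule, so the detected fraction on a mixed
field is an upper bound on the constructed co-bound proportion — that is a
feature of the physics the generator emulates, not a detector artefact,
and the stationary field is the controlled setting in which ground truth
is recoverable.

# Dwell-time survival and half-lives

Survival curves are product-limit (Kaplan–Meier) estimates via the
`survival` package, reducing exactly to the empirical complementary CDF
without censoring. Two half-life estimators are provided:

* `least_squares` (default, for fidelity to common practice): unweighted
  nonlinear LS of $S(t) = e^{-t\ln 2/t_{1/2}}$ to the curve. Its reported
  standard error comes from the fit covariance and is *anti-conservative*,
  because Kaplan–Meier residuals are strongly correlated; treat it as a
  curve-smoothness measure, not a sampling error.
* `mle_censored` (recommended): $\hat t_{1/2} = \ln 2\,\sum_i d_i /
  n_{\mathrm{obs}}$, the censored-exponential maximum-likelihood
  estimator, unbiased under arbitrary right-censoring, with the honest
  error $\hat t_{1/2}/\sqrt{n_{\mathrm{obs}}}$. Under a 300 s window a
  8900 s half-life leaves ~98% of records censored; the MLE remains
  unbiased within 10% there (tested over 500 replicates) and its error
  widens in proportion — mirroring the large uncertainties such
  experiments report for slow off-rates.

Records lacking an `observed` flag are auto-censored when within one frame
of the window. All-censored input gives a flat curve with a warning; a
half-life cannot be estimated and the failure names censoring as the
reason. `dissociation_frequency()` is the observed fraction with a
binomial standard error.

# AFM volumetrics

Volumes follow $V = (\langle H\rangle - B)\,A$ and, for protein–DNA
complexes, $V_{\mathrm{protein}} = V_{\mathrm{complex}} -
(V_{\mathrm{DNA1}}+V_{\mathrm{DNA2}})/2$ with the flanking-DNA volumes
measured over unbound DNA of matching length. Negative (sub-background)
volumes are flagged, never dropped silently. The volume-to-MW standard
curve is OLS over user-supplied calibration points — calibration proteins
and their MWs are data, not constants baked into the package; the shipped
fixtures use synthetic placeholder points.

Species deconvolution operates on calibrated molecular weights (the
volume-domain alternative is equivalent up to the linear map) with a
hand-written 1-D Gaussian-mixture EM: k-means initialization, 10 restarts
keeping the best log-likelihood, per-iteration log-likelihood trace
exposed (monotone non-decrease is asserted in tests), component SDs
floored at $10^{-4}$ of the data range to prevent collapse, components
reported sorted by mean, and BIC reported for information — the component
count $k$ is user-specified, not selected automatically. An independent
EM implementation (`mclust`) serves as a cross-check in the test suite,
not as the estimator. With four species at ~40 kDa minimum separation and
component SDs below a quarter of that separation, max-posterior assignment
accuracy exceeds 90%.

# Bulk biochemistry

*EMSA lanes.* Per-band background subtraction, then group percentages of
the corrected lane total, clipped at zero; percentages are invariant to
uniform intensity rescaling. Band-to-group mapping (e.g. all bound
species vs free DNA) is user-defined.

*Equilibrium binding.* The exact single-site ligand-depletion solution
$$f_{\mathrm{bound}} = \frac{(E+S+K_d) - \sqrt{(E+S+K_d)^2 - 4ES}}{2S}$$
is both the generator and the fitted model (bounded Levenberg–Marquardt,
started at the empirical half-saturation point). It is required rather
than the hyperbolic approximation because these assays run DNA at
concentrations comparable to — or far above — $K_d$; with DNA at
$K_d/100$ the quadratic reduces to $E/(E+K_d)$ within 1%. A flat isotherm
(fraction-bound span < 0.1) is rejected as unidentifiable by name. At the
sub-nM affinities typical of glycosylase–abasic-site binding, 20 nM
protein with 8 nM DNA holds >99% of the DNA bound, consistent with the
near-complete shifts such gels show.

*Burst kinetics.* $P(t) = A_0(1-e^{-k_b t}) + A_0 k_{ss} t$ — the standard
pre-steady-state glycosylase form, stated explicitly here because papers
typically cite rather than print it. $A_0$ estimates active enzyme and is
bounded above by the enzyme total when known; all parameters are bounded
at zero. Fold-stimulation between condition pairs is reported both as the
end-point product ratio and as the $k_{ss}$ ratio; the two legitimately
differ near substrate exhaustion and the package does not force them to
agree.

# Numerical and degenerate-input choices

* Uniform frame grids are enforced to 1e-9 s; MSD lags are exact frame
  counts.
* Exponential-fit identity $k \cdot t_{1/2} = \ln 2$ holds to 1e-12 by
  construction.
* `nls` survival fits use `scaleOffset = 1` so zero-residual (noiseless)
  data converge cleanly.
* Fewer than 3 usable fit points: invalid estimate, never an exception.
  Parameter-validation failures always name the offending argument.
* Greedy colocalization ties: lower particle id wins. Empty channel:
  fraction 0 with a warning flag.
* CSV readers drop malformed rows and report the count
  (`n_rows_skipped`); they never silently repair data.
* Same seed, same output: simulations are bit-identical under a fixed
  configuration seed, and the fGn spectral draw consumes a fixed 2n
  normals so streams stay aligned.

# What the generator does not emulate

No quantum-dot blinking or photophysics, no 2-D off-tightrope excursions,
no drift of the tightrope itself, no kymograph/image formation (the
pipeline starts at extracted positions), no coupling between motion and
dissociation, and no mechanistic model of facilitated dissociation — the
generator produces condition pairs (e.g. two half-lives) without asserting
a rate law connecting them. Consequently, passing recovery tests
demonstrates that the estimators are correct and well-calibrated on data
matching their assumptions; it does not validate those assumptions against
real microscope data.

# Known limitations

* The $\alpha$ estimator's small negative bias at short trajectory
  lengths is documented above; per-phase $\alpha$ fits on few-hundred-frame
  phases inherit it.
* The LS survival-fit standard error is anti-conservative (see above);
  use the MLE error for inference.
* The EM mixture can merge heavily overlapping species; $k$ is the user's
  scientific claim, with BIC only as a diagnostic.
* An 8900 s half-life constrained by a 300 s window rests on ~2% of
  events; the estimate is unbiased but its relative error is large, and
  both window length and cohort size are exposed so either regime can be
  studied.
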