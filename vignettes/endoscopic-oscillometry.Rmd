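---
title: "Endoscopic oscillometry: models, estimators and the virtual abdomen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endoscopic oscillometry: models, estimators and the virtual abdomen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscillab)
```

This vignette documents the models behind `oscillab`, the choices made
where the method description leaves latitude, and what the simulated
validation does and does not demonstrate.

## The static pressure–volume model

Stepwise CO₂ insufflation of the abdomen produces a concave
pressure–volume curve: large volume gains per hPa at low pressure,
diminishing gains at high pressure. We model the intra-abdominal volume
(IAV, litres) at insufflation pressure $p$ (hPa) as an exponential rise to
an asymptote,

$$IAV(p) = IAV_{max}\left(1 - e^{-\lambda (p - p_0)}\right),$$

with three parameters: the baseline pressure $p_0$ (hPa) at which the gas
volume is zero, the maximal volume $IAV_{max}$ (L) approached at
infinitely high pressure, and the expansion rate $\lambda$ (1/hPa)
controlling how fast the abdomen stiffens. Static compliance is the
analytic derivative

$$C_{ab,stat}(p) = \lambda\, IAV_{max}\, e^{-\lambda (p - p_0)},$$

strictly positive and strictly decreasing in $p$. The model is empirical:
it asserts nothing about tissue microstructure, only that measured
staircases (typically 8 steps from 5 to 20 hPa) are fitted with residuals
of a few tens of millilitres.

Fitting (`fit_pv_model()`) is Levenberg–Marquardt least squares on the
volume residuals. The start is deterministic and data-driven — $p_0$ at
the lowest pressure minus 1 hPa, $IAV_{max}$ at 1.1× the largest volume,
$\lambda$ from log-linearising the two extreme samples — so repeated fits
of the same data are identical without any seed. Box bounds
($p_0 \in [-20, \min p)$, $IAV_{max} \in (\max V, 10 \max V]$,
$\lambda \in (10^{-4}, 2]$) keep the exponential well conditioned; at
least 4 distinct pressures are required for 3 parameters. Extrapolation
below $p_0$ deliberately returns negative volumes (with a structured
warning) rather than clamping: the simulator's root term needs the
algebra, not a physiological value.

Cohort summaries report median and IQR per parameter. The even-$n$ median
is the mean of the two central order statistics; IQR endpoints use linear
interpolation of order statistics (R's `quantile` type 7, the "inclusive"
convention), fixed and documented because published tables rarely state
theirs. Reported precision defaults to 2 decimals for parameters and 3
for RMSE, matching how such tables are printed.

## The dynamic side: Welch impedance and the RLC model

The stimulus (`stimulus_protocol()`) concatenates single-frequency
sinusoidal segments at 0.5, 1, 2, 3 and 5 Hz with a peak-to-peak
amplitude of 3 hPa about the set IAP, sampled at 200 Hz. Exact per-band
cycle counts are not prescribed by the method beyond "4 to 10 cycles per
frequency, 20 s overall"; the default schedule (4, 4, 8, 6, 10 cycles,
i.e. 8 + 4 + 4 + 2 + 2 s) is one consistent choice and is validated as
such. Below 0.5 Hz the measurement grows slow and ventilator-coupled;
above 5 Hz gas inertia dominates the impedance — hence the band.

Each segment is analysed separately (`segment_recording()`), with its
first cycle discarded as a switching transient. Impedance at each
frequency (`estimate_impedance()`) is the Welch cross-spectral H1
estimator: Hamming-tapered windows of exactly two stimulus periods
(`round(2 f_s / f)` samples) with 50% overlap and per-window mean
removal; auto- and cross-spectra are averaged over windows and the ratio
$S_{qp}/S_{qq}$ is read at bin 2 of the window — the bin a two-period
window places the stimulus on, so no interpolation between bins is
needed. H1 is the standard noise-robust choice and reduces to the plain
Fourier ratio in the noiseless case (a property the tests assert against
an independent single-bin DFT oracle). Windows never span segment
boundaries. The magnitude-squared coherence
$|S_{qp}|^2/(S_{pp} S_{qq})$ is the per-point quality measure; with the
default schedule the 4-cycle segments support only 2 windows, the
accepted minimum, and such points are flagged `low_averaging`.

The impedance curve is inverted through the series RLC model

$$Z(f) = R + i\left(2\pi f L - \frac{1}{2\pi f C}\right),$$

where $R$ (hPa·s/L) absorbs circuit and tissue-deformation losses, $L$
(hPa·s²/L) the inertia of the gas column, and $C$ (L/hPa) — the
capacitance of the gas compartment — is the dynamic abdominal compliance.
No circuit compensation is subtracted before fitting: $R$ and $L$ are
interpreted as including the insufflation circuit, and $C$ alone is
attributed to the abdomen. The fit minimises the summed squared complex
residual over log-parameters (enforcing positivity), started
deterministically from the spectrum's own asymptotes ($R_0$ = mean
resistance; $C_0$ from the lowest-frequency reactance when negative,
0.1 L/hPa otherwise; $L_0$ from the highest-frequency reactance after
removing the compliant part). Points with coherence below 0.9 are
excluded before fitting — the method's own data exceeded 0.96, and 0.9 is
a conservative, configurable cut. A spectrum whose reactance never turns
negative carries no identifiable compliance in this band; the fit is
returned flagged `low_confidence` rather than failing.

## The virtual abdomen

`simulate_recording()` integrates

$$p_{app}(t) = R\,q + L\,\dot q + p_{el}(V) + p_{ve}, \qquad q = \dot V,$$

where $p_{el}$ is the inverse of the exponential pressure–volume curve
(elastic recoil) and, when enabled, a Kelvin element in series obeys
$\dot p_{ve} = q/c_{ve} - p_{ve}/(r_{ve} c_{ve})$. The pressure setpoint
is applied ideally — controller dynamics are out of scope — and the
measured pressure channel is the setpoint itself, as for a tightly
controlled insufflator. Integration is fixed-step classical Runge–Kutta
at 1 kHz (the rate such controllers run at), decimated to the 200 Hz
logging rate; a 2-s settling run at constant IAP precedes the stimulus
and is discarded. Halving the step changes the output by less than
$10^{-6}$ relative (asserted in the tests), so 1 kHz is comfortably
converged for this band. When $R = L = 0$ the system degenerates to
$V = p_{el}^{-1}(p_{app})$ and flow follows the chain rule analytically;
combining that degenerate case with the Kelvin element has no well-posed
state equation and is rejected with a simulation error, as are diverging
configurations (which name the offending parameters).

Defaults are chosen to land in the physiological regime the method
reports: $R = 5$ hPa·s/L and $L = 0.2$ hPa·s²/L (the centres of the
published ranges 3.8–7.1 and 0.18–0.26), sensor noise with sd 2% of each
channel's oscillation amplitude (sensor noise is not characterised in the
source; 2% keeps coherence in the high-90s regime reported), and a Kelvin
element with $c_{ve} = 2\times$ the local static compliance and
$r_{ve} = 3$ hPa·s/L. The Kelvin constants are plausibility choices, not
fits to published data (no tissue constants are published): in series
they reduce the apparent compliance at 0.5–5 Hz to roughly 0.63–0.89 of
the static value across the default cohort, which reproduces the
qualitative dynamic-below-static ordering and the curvature of the
calibration plot. At DC the Kelvin spring would *add* compliance; that
limit is never probed because the stimulus band keeps
$\omega r_{ve} c_{ve} \gtrsim 2$.

`simulate_study()` replicates the full experiment: subject parameters
drawn uniformly within the extremes of the reference cohort
($p_0 \in [1.1, 2.5]$ hPa, $IAV_{max} \in [2.79, 4.61]$ L,
$\lambda \in [0.10, 0.15]$ /hPa), 8 pressure steps from 5 to 20 hPa, one
recording and one static volume per step (80 of each by default). Static
volumes carry Gaussian measurement noise of sd 0.02 L — the scale of the
published per-subject fit residuals, which reflect model misfit more than
CT segmentation error (0.001 L) — and each subject's noise vector is
redrawn until the staircase stays strictly increasing, since every real
staircase is monotone. All randomness descends from one master seed
through the documented rule
`child = (master·100003 + subject·1009 + step·101) mod (2³¹−1)` (step 0
reserved for volume noise), so any single recording is reproducible in
isolation.

Artifacts (`inject_artifact()`) are phenomenological: ventilator
interference adds a 0.25 Hz pressure sinusoid (no diaphragm mechanics),
and tube occlusion clamps flow to zero over an interval. Both exist to
exercise the coherence-based quality control, and the tests verify they
degrade it.

## The quadratic calibration

`pair_compliances()` matches, per subject × IAP, the dynamic compliance
from each recording's RLC fit with the static compliance evaluated from
that subject's fitted pressure–volume parameters at the same IAP; pairs
form only where both sides exist, so excluded recordings drop out
naturally. `fit_quadratic()` regresses $C_{stat}$ on
$(1, C_{dyn}, C_{dyn}^2)$ by unweighted OLS — dynamic compliance is the
predictor because the curve's purpose is converting the monitorable
quantity into the reference one — and reports
$\bar R^2 = 1 - (1-R^2)(n-1)/(n-3)$. No weighting, robustness or
through-origin constraint is applied; the published intercept implies an
unconstrained fit.

## What the simulation does and does not show

The generator emulates: the nonlinear elastance and its between-subject
spread, circuit resistance and gas inertance, viscoelastic
dynamic-vs-static divergence, sensor noise, and the two artifact classes.
It does not emulate: ventilator–diaphragm mechanical coupling, CO₂
absorption and leaks (a linear drift stub exists but is off by default),
controller imperfections, body-position or neuromuscular-blockade
effects, or non-Kelvin (e.g. fractional-order) tissue rheology. Passing
tests therefore demonstrate that the estimators are correct and
well-conditioned for the physics the simulator contains — estimator
validity, not clinical validity. In particular the calibration
coefficients fitted on simulated cohorts depend directly on the chosen
Kelvin constants and must not be read as reproductions of the published
animal coefficients; only the qualitative structure (dynamic below
static, smooth quadratic relation, high adjusted $R^2$) transfers.

Problem sizes in the test suite are chosen to keep the full run in the
low minutes on one core: Monte-Carlo loops use 20–200 replicates, the
replica study its full 10 × 8 design, and parameter-recovery sweeps 100
random draws. Units are hPa, L and seconds throughout; pressure-unit
conversion (`convert_pressure()`) defaults to the rounded clinical
factor 1 hPa = 0.75 mmHg so printed equivalences (20 hPa = 15 mmHg)
reproduce exactly, with physical constants behind `physical = TRUE`.

## Known limitations

- The RLC inversion assumes a single compartment; bands wider than
  0.5–5 Hz or strongly heterogeneous abdomens would need richer models.
- Compliance identifiability hinges on negative reactance at the lowest
  stimulus frequency; very stiff abdomens (C below ~0.01 L/hPa) push the
  zero crossing out of band and are flagged rather than estimated.
- The Welch windows at 3 Hz are 133 samples (2 periods is not an integer
  sample count), so the stimulus sits 0.005 bins off bin 2; the resulting
  bias is far below the 0.5% oracle tolerance but is not exactly zero.
- `summarize_cohort()`'s IQR convention is one of several in use;
  published IQRs computed with a different convention will differ in the
  endpoints without either being wrong.
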