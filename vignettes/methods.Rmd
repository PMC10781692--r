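---
title: "Models and methods behind specdcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind specdcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the numerical and design choices behind
them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The generative model

Hidden neuronal states of $n$ regions follow a linear stochastic
differential equation

$$\dot x(t) = A\,x(t) + v(t),$$

where $A$ (Hz) is the effective connectivity matrix — entry $(i, j)$ is
the directed influence of region $j$ on region $i$ — and $v(t)$ is
endogenous fluctuation with a power-law spectral density
$G_v(f) = \alpha_s f^{-\beta_s}$. Self-connections (the diagonal) are
parameterized as $-0.5\,e^{d_i}$, so they are negative by construction and
exert stability pressure; $d_i$ are log-scale deviations from the
canonical $-0.5$ Hz.

Each region's neuronal state drives the balloon–Windkessel hemodynamic
model: a vasodilatory signal $s$ (decay $\kappa = 0.64\,s^{-1}$,
autoregulation $\gamma = 0.32\,s^{-1}$), inflow $f$, venous volume $v$
(transit time $\tau = 2$ s, stiffness $\alpha = 0.32$), and
deoxyhemoglobin $q$ (resting extraction $\rho = 0.4$), observed through
the classic BOLD equation with $V_0 = 0.04$, $k_1 = 7\rho$, $k_2 = 2$,
$k_3 = 2\rho - 0.2$. These are the widely used constants of the canonical
model; neurovascular efficacy defaults to $\varepsilon = 0.4$, which keeps
the flow excursions produced by the default fluctuation amplitude inside
the regime where the model is approximately linear, so that BOLD
fractional signal changes come out near 2–3% — a realistic magnitude.

### Spectral prediction

Spectral DCM fits the complex cross-spectral density (CSD) of the ROI
series rather than the series themselves. The predicted CSD is

$$G_y(f) = H(f)\, G_v(f)\, H(f)^{\mathsf H} + G_e(f), \qquad
  H(f) = \mathrm{diag}\,B(f)\,\bigl(i2\pi f I - A\bigr)^{-1},$$

with $B(f)$ the per-region first-order transfer function of the balloon
model linearized about its fixed point (a closed-form rational function
of $f$; derived symbolically, implemented in C++), and $G_e(f)$ a
power-law observation-noise floor. The likelihood therefore only uses the
small-signal hemodynamic kernel, while the simulator integrates the full
nonlinear model — the inversion is deliberately tested against data it
did not generate from its own linearization.

## Numerical choices

* **Integration.** Euler–Maruyama at $dt = 0.05$ s with a 60 s burn-in
  for the neuronal states — adequate for dynamics with time constants of
  a second or more (the induced spectral bias in the analysis band is
  well under the test tolerances). The balloon model is integrated with a
  Heun (RK2) step at the same $dt$: a plain Euler step at $dt = 0.05$ s
  leaves a measurable (several percent) excess in the BOLD spectrum that
  the cross-check against the analytic spectrum resolves.
* **Power-law noise** is realized by FFT shaping of white noise, which is
  exact on the simulation grid. The power law is clamped (flattened)
  below $f_{\min} = 0.008$ Hz in both the simulator and the predictor:
  neuronal fluctuations are band-limited, near-DC drifts belong to
  detrending, and an unclamped $f^{-1}$ law would put unbounded power
  into frequencies a 12-minute session cannot resolve.
* **Stability guard.** Subject-level coupling matrices are redrawn until
  every eigenvalue's real part is below $-0.2$: a network mode slower
  than about 5 s is barely sampled in one session and makes the inverse
  problem ill-conditioned, which a cohort designed for connectivity
  analysis would avoid. This is stricter than mere stability, and it is a
  property of the generator, not of the estimator.
* **CSD estimation** uses a multivariate autoregressive model of order 8
  fitted by least squares (ridge fallback when singular), evaluated on 32
  frequencies from $1/(N\,\mathrm{TR})$ to $0.25/\mathrm{TR}$; Hermitian
  by construction. Spectral features are taken before any temporal
  filtering.
* **Observation stacking.** Real and imaginary parts of the
  upper-triangular CSD entries form the observation vector. Noise
  precision hyperparameters are shared within four contiguous frequency
  bands, *crossed with entry type* (auto- vs cross-spectra). The split by
  entry type matters: auto-spectral densities are an order of magnitude
  larger than cross terms, and a precision shared across both lets the
  optimizer fit the diagonals while ignoring the cross-spectra — which
  carry all the coupling information.
* **Variational Laplace.** Gauss–Newton steps on the free energy with
  central finite differences (step $10^{-4}$), Levenberg-style damping
  escalation with acceptance only when $F$ increases, Newton updates of
  the band log-precisions (hyperprior centered, per band, on the
  precision implied by one percent of the data power — a scale-free
  choice — with variance 9, and clamped to ±12 of that center), and
  convergence when $\Delta F < 0.01$ nats for three consecutive accepted
  iterations or at 64 iterations. On a linear predictor with fixed noise
  the scheme reduces to the conjugate Gaussian update, which the test
  suite checks to $10^{-6}$.
* **Scaling.** Before inversion the estimated CSD is rescaled by a single
  global factor so its mean auto-spectral power matches the prior-mean
  prediction. A global rescaling of the data leaves $A$ invariant (it is
  absorbed by the fluctuation amplitudes) and keeps the tight
  log-amplitude priors meaningful.
* **Priors.** Couplings $\mathcal N(0, 1/64)$ Hz; self-connection
  log-deviations $\mathcal N(0, 1/256)$; fluctuation and hemodynamic
  log-parameters $\mathcal N(0, 1/64)$ — shrinkage priors of the order
  standard in spectral DCM.

## Hierarchical (PEB) layer

Each first-level posterior enters the group model as a Gaussian
likelihood with its own covariance. First-level parameters are modelled
as $X\beta$ plus random between-subject effects with covariance
$e^{-\gamma}\,\mathrm{diag}(\Sigma_0)/16$ (one precision component;
$\gamma$ estimated by maximizing the marginal free energy, with a
$\mathcal N(0, 1/16)$ hyperprior). For fixed $\gamma$ the group posterior
is a closed-form GLS estimate, which the tests verify against
precision-weighted fusion formulas. The design matrix holds a
commonalities column of ones, the pre/post session coded $\mp 0.5$, and
effect-coded, mean-centered responder contrasts for suicidal ideation and
depression; a contrast without variation is flagged non-estimable. The
responder covariates enter one joint design by default (per-contrast PEB
models remain possible by passing a different `X`).

Bayesian model reduction computes the evidence and posterior of any
tightened-prior model analytically from the full fit; "off" collapses a
prior variance to $10^{-8}$. The model search prunes greedily — each pass
evaluates switching off every remaining parameter *relative to the
current reduced model* and applies all prunings that increase evidence,
for at most 8 passes — and then enumerates the on/off combinations of the
still-on parameters whose single-parameter pruning cost is below 3 nats
(the genuinely uncertain ones), capped at $2^8$ models. Exhaustive search
over all $2^p$ models is infeasible and adds nothing once decisive
parameters are fixed. Averaging is moment-matched and evidence-weighted;
a parameter's posterior probability is the summed weight of the models
that retain it. Parameters with probability above 0.95 are labelled
significant in reports.

## Target selection and functional connectivity

The individualized stimulation target is the voxel (default granularity;
an atlas-subunit mode returns the centroid of the most anticorrelated
subunit) inside the DLPFC mask whose series is most anticorrelated with
the sgACC reference — the unweighted mean over the union of the two sgACC
atlas labels. Selection uses the pre-treatment session only, since
targets are fixed before treatment; ties break on the smallest voxel
index. Group maps are one-sample t tests on Fisher-z maps, thresholded
two-sided at p < 0.05 uncorrected and split by sign; pre-vs-post
comparisons use a paired t map with Benjamini–Hochberg correction. ROI
definition uses the baseline session. Lateral ROIs (CAU, PCUN, HIP, INS)
are restricted to the left hemisphere via the affine ($x < 0$ mm);
midline ROIs (mPFC, sgACC) keep both hemispheres. Atlas label sets are
configurable rather than hard-coded, since published parcellations vary.

## Preprocessing

Fixed stage order: discard initial volumes → (smoothing, for volume
data) → linear detrend → confound regression (Friston-24 expansion,
optional WM/CSF, optional global signal) → bandpass last. Motion
exclusion is a strict "larger than" rule at 3.5 mm / 3.5°, so boundary
values are retained; rotations are treated in degrees. The bandpass is an
order-2 Butterworth applied forward and backward (zero-phase, order-4
response); smoothing is a separable Gaussian with
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ and reflective boundaries,
which conserves the image sum exactly. Detrending is linear only — the
drift being removed is described as slow, and higher orders would eat
into the analysis band.

## What the generator does and does not emulate

The synthetic cohorts reproduce the statistical structure the analysis
relies on: study-sized cohorts (26 subjects, two sessions, TR 2 s, 350
retained volumes), subject-level coupling variation around a population
network, a treatment effect as a shift of selected couplings (default
$-0.2$ Hz on HIP→INS with between-subject s.d. 0.1), clinical scales on
the published ranges with a planted linear map from connection shifts to
BSI-CV reductions (slope $-1.5$, noise s.d. 0.1 — chosen so the planted
association is detectable at $n = 26$ but far from deterministic), and
motion tables as regressor fodder with optional planted exclusion spikes.
They do not emulate scanner physics: no k-space artifacts, susceptibility
dropout, motion-correlated signal, spatial autocorrelation beyond the
block atlas, or physiological (cardiac/respiratory) aliasing. Passing
tests therefore demonstrate the statistical machinery under the model's
own assumptions — not robustness to everything real fMRI contains.
Observation-noise defaults are chosen so that parameter recovery is
attainable (the study reports no empirical SNR to match).

## Problem sizes used by the tests

The suite inverts cohorts of 10 subjects with 4 regions and 350 volumes
for single-level recovery, and ten replicate cohorts of 12 subjects ×
2 sessions with 3 regions for the hierarchical chain — sizes at which the
full pipeline runs in minutes while leaving the estimation problem
realistically hard. Calibration checks use 10 000-voxel null maps and
analytic filter probes. The acceptance script repeats the recovery and
hierarchical experiments once each at the same sizes.

## Known limitations

* The hemodynamic likelihood is first-order: strong nonlinear regimes
  (large excursions) are outside the model, and the generator's defaults
  deliberately stay within the linear range.
* CSD estimation by AR(8) carries smoothing bias; agreement with the
  analytic spectrum is checked band-averaged, not bin-wise.
* No third-level (between-group) PEB and no leave-one-out cross-validation
  of group effects.
* Time-domain (stochastic) DCM and bilinear coupling terms are out of
  scope; the model is linear in the states throughout.
* Slice timing, realignment and spatial normalization are not
  implemented: synthetic volumes are born aligned, and real data must
  arrive already normalized.
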