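---
title: "Modelling non-invasive blood glucose from multi-path absorbance and PPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-invasive blood glucose from multi-path absorbance and PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nibgm)
```

## The measurement problem

A wearable finger-clip sensor illuminates the fingertip sequentially with
three LEDs (625, 850 and 940 nm, 15 s each) and records four channels at
200 Hz: three DC intensities from photodetectors at increasing
source–detector separation — near reflection, far reflection and
transmission — and one AC channel carrying the transmitted
photoplethysmogram (PPG). Larger source–detector separations probe deeper,
capillary-rich tissue, so the *difference* of absorbances between two paths
isolates the extra attenuation accumulated in the glucose-sensitive layer
while cancelling the unknown incident intensity $I_0(\lambda)$:

$$
\Delta A_{\mathrm{near-far}}(\lambda)
  = A_{\mathrm{far}} - A_{\mathrm{near}}
  = \log_{10}\frac{I_{\mathrm{near}}(\lambda)}{I_{\mathrm{far}}(\lambda)},
\qquad
\Delta A_{\mathrm{near-trans}}(\lambda)
  = \log_{10}\frac{I_{\mathrm{near}}(\lambda)}{I_{\mathrm{trans}}(\lambda)}.
$$

Switching the light source injects transients around the 15 s and 30 s phase
boundaries, so each phase contributes only its *stable segment*: the package
drops a guard band (default 1 s, comfortably wider than the visible
transients) at both phase ends and summarises each DC channel by its
arithmetic mean over the remaining 13 s. The mean is the minimum-variance
summary for a stable DC level; the original system's reduction (mean,
median, or instantaneous values) is not documented, and this choice is
exposed through `guard_s` rather than hidden.

The logarithm is decadic throughout — the absorbance convention — and the
same base is used for the log-energy feature for consistency.

## PPG preprocessing and the feature vector

The 940 nm transmitted PPG (good penetration, favourable glucose
correlation) is preprocessed in four checked stages; each stage refuses
inputs in the wrong state, so the chain cannot be silently reordered:

1. **Low-pass filtering**: 6th-order Butterworth design, 15 Hz cutoff,
   applied zero-phase (forward–backward) so systolic peak timing is
   preserved. The segment is padded by odd reflection (up to 300 samples)
   before filtering because a direct forward–backward IIR pass rings at the
   segment ends.
2. **Baseline removal**: a natural cubic spline through the per-beat foot
   minima (the minimum between consecutive preliminary beats) is
   subtracted. Preliminary beats are located on a drift-compensated proxy
   (signal minus a 1.2 s running mean) so slow wander cannot mask pulse
   prominence. At least three feet are required.
3. **Normalization**: min–max scaling to $[0, 1]$, removing amplitude
   differences between recordings.
4. **Peak detection**: local maxima with a minimum separation of
   $60/180$ s (no physiologic rhythm above 180 bpm) and prominence at
   least 0.3 of the normalized range.

From consecutive peak intervals the instantaneous heart-rate series
$60 f_s / \Delta\tau$ yields $HR_\mu$ and $HR_\sigma$ (sample standard
deviation, a heart-rate-variability proxy; HRV correlates negatively with
glycaemia). The first 2000 preprocessed samples (10 s) are divided into
frames of $L_{\mathrm{frame}} = 400$ samples (twice the sampling rate) with
$L_{\mathrm{overlap}} = 200$, giving
$N = \lfloor (L - L_{\mathrm{frame}}) / (L_{\mathrm{frame}} -
L_{\mathrm{overlap}}) \rfloor + 1 = 9$ frames. Per frame the package
computes

* the Kaiser–Teager energy
  $KTE(\tau) = S_f^2(\tau) - S_f(\tau + 1)\,S_f(\tau - 1)$ over interior
  samples (for a discrete sinusoid this is the constant
  $A^2 \sin^2 \Omega$, the property the unit tests pin down), and
* the log-energy $\log_{10}\bigl(\sum_\tau S_f^2(\tau) + \varepsilon\bigr)$
  with $\varepsilon = 10^{-12}$ guarding all-zero frames.

$KTE_\mu, KTE_\sigma$ are the mean and **variance** of the pooled interior
KTE values of all frames; $\log E_\mu, \log E_\sigma$ the mean and
**variance** of the nine per-frame log-energies. Variance (not standard
deviation) is used for the two shape features and standard deviation for
$HR_\sigma$, with sample ($n-1$) denominators throughout; pooling across
frames is the package's choice where the statistic's exact aggregation is
not documented. The feature vector is fixed as

$$
x_F = [HR_\mu, HR_\sigma, KTE_\mu, KTE_\sigma, \log E_\mu, \log E_\sigma,
\Delta A_{nf}^{625}, \Delta A_{nt}^{625},
\Delta A_{nf}^{850}, \Delta A_{nt}^{850},
\Delta A_{nf}^{940}, \Delta A_{nt}^{940}],
$$

twelve values whose order never changes anywhere in the package.

## The spatiotemporal fusion model

`stmf_lstm()` fits a two-branch forecaster of the glucose value $y(t)$:

* a **spatial branch** — a rectified MLP (3 layers of width 25) encoding
  the normalized feature vector $x_F(t)$ into $h_{\mathrm{MLP}}$;
* a **temporal branch** — a stacked LSTM (3 layers, hidden size 25) driven
  by the lag-1 glucose history $y(t-1)$, built on the standard gated cell

$$
\begin{aligned}
f_t &= \sigma(W_f [h_{t-1}, x_t] + b_f), &
i_t &= \sigma(W_i [h_{t-1}, x_t] + b_i), \\
o_t &= \sigma(W_o [h_{t-1}, x_t] + b_o), &
\tilde c_t &= \tanh(W_c [h_{t-1}, x_t] + b_c), \\
c_t &= f_t \odot c_{t-1} + i_t \odot \tilde c_t, &
h_t &= o_t \odot \tanh(c_t).
\end{aligned}
$$

The branch outputs are weighted by learnable scalars $\alpha_1, \alpha_2$
(initialised at 0.5 — the weights are described only as balancing the
branch contributions, so the package learns them rather than fixing them),
concatenated, and mapped to the prediction by a single fully connected
linear unit. Features and glucose are Z-score normalized with statistics
fitted **on the training triples only**; a dedicated test corrupts held-out
days and asserts the fitted model is bit-identical.

Training minimises the MSE with Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\varepsilon = 10^{-8}$), learning rate 0.01, 50 epochs. Gradients come
from full backpropagation through time, verified against central-difference
numerical gradients in the test suite. Updates use minibatches of whole
day-sequences (default 4 days per Adam step) with a seeded shuffle: with a
dataset of a few hundred triples, pure full-batch training would perform
only 50 Adam updates in 50 epochs — far too few steps for a ~15 000
parameter model at this learning rate — while day-level batching keeps
every update consistent with the within-day recurrence and keeps runs
bit-reproducible for a fixed seed. LSTM state is reset at every day
boundary; weights are initialised uniformly scaled by fan-in from one
seeded stream.

**Recursive multi-step validation** mirrors deployment, where reference
glucose is not available during the day: each held-out day is anchored at
its first reference value, and every later step feeds the model's previous
*prediction* back as the historical glucose input while the optical
features of the current step correct the accumulated drift. The first
recursive step therefore equals the teacher-forced one-step prediction
exactly — asserted in the tests.

## Evaluation

`regression_metrics()` reports RMSE, MAE (mmol/L), Pearson correlation and
MARD $= 100 \cdot \mathrm{mean}(|e|/\mathrm{ref})$ in percent. Consensus
(Parkes) error-grid analysis converts both axes to mg/dL with the factor
18.016 (the molecular weight of glucose, pinned for zone reproducibility)
and assigns zones A–E by position relative to the published piecewise-linear
zone boundaries; the type-1 variant is the default with type-2 selectable,
since the grid variant used in this problem domain is usually not stated.
Points exactly on a boundary go to the less severe zone — a conservative,
deterministic tie rule. A second, independent point-in-polygon
implementation of the same vertex table serves as an oracle in the tests.

Cross-validation comes in two forms: seeded random k-fold (10 folds for the
classical baselines: MLP, SVR with RBF kernel $C=10$, $\gamma=0.01$,
$\epsilon=0.5$, random forest with 100 depth-5 trees, XGBoost with 100
rounds at its fixed shrinkage/subsampling settings) and day-grouped k-fold
(8 folds of 2 whole subject-days) for the forecaster, so no acquisition day
ever straddles training and validation. Out-of-fold predictions are pooled
and scored once — per-fold averages would not be comparable with a single
overall figure. The ablation harness runs, on identical day folds: (A) MLP
on the 6 PPG features, (B) MLP on all 12 features, (C) the fusion
forecaster with recursive validation.

## What the synthetic study emulates — and what it does not

Clinical recordings for this problem are not redistributable, so the
package ships a seeded acquisition simulator whose planted structure makes
every stage testable:

* **Trajectories**: per-subject baselines, gamma-density-shaped
  postprandial excursions (peak 2 mmol/L one hour after each of three
  meals) and stationary AR(1) noise (sd 0.15 mmol/L, $\rho = 0.6$),
  clipped to the non-diabetic range 3.9–9.3 mmol/L; 17 samples per day
  over a 07:00–21:00 window. Four subjects over four days give the
  272-record, 16-subject-day continuous layout used throughout.
* **DC optics**: $I = I_0(\lambda)\,10^{-(A_0 + \kappa g + d)}$ per
  wavelength and path, with attenuation increasing near → far → trans
  (so intensities order correctly) and positive differential glucose
  coefficients, largest at 940 nm. The drift term $d$ is drawn **per
  record and per (wavelength, path)** with sd 0.013. Two properties of
  this noise model matter: a drift shared across wavelengths would cancel
  in cross-wavelength contrasts and make glucose exactly identifiable —
  unrealistically clean — so independence across wavelengths is what
  makes the planted inverse problem genuinely noisy; and the magnitude is
  calibrated so optical-feature-only regression lands in the
  0.7–1.0 mmol/L RMSE regime reported for wearable optical devices,
  rather than being tuned to any particular comparison outcome.
* **PPG**: two Gaussian lobes per beat (systolic plus a smaller, delayed
  dicrotic lobe — morphology is otherwise unspecified in this problem
  domain), beat rate $75 - 2g$ bpm (negative HR–glucose coupling) with
  3 bpm per-record jitter and 2% per-beat period jitter, respiratory
  baseline wander, and 0.5 s damped-oscillation transients at the LED
  switch times whose sample indices are recorded so segment selection can
  be verified against them.

Passing tests on this simulator demonstrate that the pipeline recovers
planted structure (absorbances to $10^{-6}$ noise-free, HR to 1 bpm), that
the model's gradients, normalization hygiene and recursion semantics are
correct, and that the qualitative ablation ordering — temporal fusion
beats optical-only regression beats PPG-only regression — emerges under
realistic noise. They do **not** demonstrate clinical accuracy: the
simulator has no photon-transport physics, no motion artifacts, no contact
pressure effects, no inter-subject optical variability beyond scalar
baselines, and its glucose–optics coupling is exactly log-linear.

## Numerical conventions

Indices are 1-based and ranges inclusive, the native R convention, used
consistently for samples, segments and frames. Standard deviations below
$10^{-12}$ are $\varepsilon$-guarded (constant columns normalize to 0);
the log-energy floor is $10^{-12}$; vertical segments of Parkes boundaries
are resolved with a $10^{-9}$ nudge that keeps on-the-line points in the
less severe zone; tanh saturation to $\pm 1$ in double precision is treated
as in-range. Test and example problem sizes (a 272-record study for the
ablation, smaller 2-subject studies for model-level checks, 30 training
epochs where only convergence direction matters) were chosen to exercise
the full pipeline at desk scale.

## Known limitations

The simulator's realism bounds what the package can claim, as discussed
above. The fusion model is a faithful but compact implementation: no GPU
path, no attention, no multi-lag variants beyond the recursive rollout, and
the fusion weights are simple scalars. The MLP baseline is the package's
own Adam-trained network because no installed alternative offers the
required 3-hidden-layer MSE/Adam configuration; SVR, random forest and
XGBoost wrap their canonical implementations. Day-grouped cross-validation
requires the day count to factor exactly into folds — ragged designs are
rejected rather than approximated.
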