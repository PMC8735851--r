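---
title: "Inverse muscle modeling of EMG envelopes with NARX networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse muscle modeling of EMG envelopes with NARX networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(imnet)
```

## The problem

Musculoskeletal inverse dynamics recovers joint torques from motion, but
recovering individual *muscle* excitations from joint-level signals is
ill-posed: many muscles cross each joint, so a given torque admits
infinitely many activation patterns. The classical resolution is static
optimization - a per-time-step effort-minimization under torque
constraints - which discards activation history, muscle dynamics, and
observed co-contraction.

`imnet` takes the data-driven route: a recurrent network is trained to map
five joint-level biomechanical signals - angle $\theta$, velocity
$\dot\theta$, acceleration $\ddot\theta$, joint torque $\tau_h$, and
activation torque $\tau_{act}$ - directly to the normalized surface-EMG
envelopes of the muscles crossing the joint. Once trained, the model
estimates muscle excitation for new subjects from motion capture alone, with
no electrodes.

## Model

The core is a NARX (nonlinear autoregressive with exogenous inputs)
network:

$$ y(t) = f\big[\,u(t), u(t-1), \dots, u(t-n_u+1),\;
   y(t-1), \dots, y(t-n_y)\,\big] $$

with tapped delay lines over the $n_u$ most recent input vectors (current
sample included) and the $n_y$ strictly-previous output vectors. $f$ is a
multilayer perceptron: $n_l$ hidden layers of $n_n$ logistic-sigmoid units
and a saturating linear output clamped to $[0,1]$, the range of normalized
EMG envelopes.

**Tap-count convention.** Throughout the package the input line holds
exactly $n_u$ taps and the feedback line exactly $n_y$ taps. Under this
convention the parameter count of a single-hidden-layer network is

$$ P \;=\; n_n\,(n_{in} n_u + n_{out} n_y) + n_n + n_{out}\,n_n + n_{out}, $$

each extra hidden layer adding $n_n^2 + n_n$, and the delay windows at a
50 Hz sample rate span $n_u/50$ and $n_y/50$ seconds. Alternative
conventions that include $u(t-n_u)$ as an extra tap are inconsistent with
this counting and are not used.

Two evaluation modes exist. *Open loop* (series-parallel) fills the
feedback taps with measured envelopes; given the delay windows the network
is then feedforward, which is what makes Jacobian-based training cheap.
*Closed loop* (parallel) feeds back the model's own predictions and is the
deployment mode: estimation from biomechanical inputs alone, with the
feedback line initialized to zero.

## Data preparation

Each stage is a module with the 50 Hz multichannel time series as the
common currency:

* **Kinematics** - raw joint angles are low-pass filtered at 10 Hz,
  differentiated (central differences; one-sided second-order at the ends so
  series length is preserved), and the velocity and acceleration are
  filtered at 20 and 30 Hz. All filters are 4th-order Butterworth applied
  forward-backward (zero phase), so kinematic and EMG timing stay aligned.
  A cutoff at or above Nyquist - the 30 Hz acceleration default at a 50 Hz
  marker rate - is clamped to 0.9 x Nyquist with a warning rather than
  rejected: the intent (light smoothing) is preserved and the alternative
  is an unusable filter. For 3-DoF Euler-angle input the angle-rate to
  angular-velocity map $\omega = E(q)\,\dot q$ is applied between
  differentiation and filtering; the default sequence is Z-X-Y and the
  planar task needs none of this (each channel is its own joint angle).
* **Dynamics** - closed-form planar two-link inverse dynamics
  $Q = M(q)\ddot q + C(q,\dot q)\dot q + G(q)$ for the shoulder-elbow
  chain, with a hand-held object as a point mass at the distal endpoint.
  The full 3-DoF shoulder is deliberately reduced to sagittal-plane
  elevation: only the shoulder-elevation torque feeds the network, and
  out-of-plane dynamics would add structure the downstream mapping never
  sees. Segment parameters are a template scaled by subject mass (masses),
  height (lengths), and mass x length^2 (inertias).
* **MTG** - the muscle torque generator
  $\tau_h = \tau_{act}\,\tau_a(\theta)\,\tau_v(\dot\theta) + \tau_p(\theta)$
  is inverted algebraically to produce the activation-torque input:
  $\tau_{act} = (\tau_h - \tau_p)/(\tau_a \tau_v)$. The three scaling
  curves are parametric stand-ins with the standard shapes: Gaussian
  torque-angle (peak 1 at `theta_opt`, width 1 rad), Hill-type
  torque-velocity (1 at rest, 0 at `v_max` = 12 rad/s, shape 0.25,
  C1-continuous eccentric plateau at 1.5), exponential passive torque
  (zero at `theta_ref`, odd-mirrored below). Defaults keep
  $|\tau_a\tau_v|$ well above the inversion guard (`epsilon` = 1e-3) for
  ordinary reaching motions; a guard trip is a hard, per-sample-indexed
  error because a silent near-zero division would corrupt a network input.
* **EMG** - the seven-step envelope chain: 20-500 Hz band-pass, 55-65 Hz
  band-stop, rectification, 7 Hz low-pass, per-trial per-channel maximum
  normalization, cubic resampling to 50 Hz, and exponential shaping
  $a(u) = (e^{Au}-1)/(e^{A}-1)$ (default $A=-1$; $A=0$ disables). A
  three-step preset (70 Hz high-pass, rectify, 10 Hz low-pass) is provided
  as the minimal alternative. Because cubic interpolation does not preserve
  the maximum sample, the envelope is re-clipped and re-normalized after
  resampling so the unit-maximum contract holds exactly at 50 Hz. The
  first and last 0.25 s carry zero-phase edge transients and are flagged
  for trimming.

**Zero-phase filtering.** All stages share one zero-phase routine:
odd-reflection padding plus steady-state initial conditions for the causal
Butterworth passes, with the pad scaled to the filter's settle time. This
guarantees unit DC gain and clean behavior on constant signals, which
off-the-shelf zero-padded forward-backward filtering does not.

## Training

Open-loop training is nonlinear least squares, solved by
Levenberg-Marquardt: per epoch the full residual vector and its analytic
Jacobian (backpropagation through the teacher-forced network) give the
damped Gauss-Newton step $\Delta w = -(J^\top J + \mu I)^{-1} J^\top e$. A
step is accepted only if training MSE decreases ($\mu \leftarrow 0.1\mu$),
otherwise $\mu \leftarrow 10\mu$ and the step is retried; the run aborts
at $\mu > 10^{10}$. Defaults: $\mu_0 = 0.001$, at most 200 epochs,
early stopping after 100 epochs without a new validation best, and the
returned model carries the *best-epoch* weights, not the last.

Numerical choices worth knowing:

* **Input standardization.** Raw inputs span radians (~1) to newton-meters
  (~tens); per-column standardization (estimated on the training windows,
  stored in the model) keeps the sigmoid layer out of saturation. All
  affine input maps are absorbable by the first layer, so this changes
  conditioning, not expressiveness.
* **Initialization.** Weights are uniform on $[-0.5, 0.5]$ scaled by
  $1/\sqrt{\text{fan-in}}$; the output bias starts at the center of the
  saturation range. Starting at 0 can place every pre-activation below
  the clamp, in which case the error gradient is identically zero and LM
  cannot move at all.
* **Multi-start.** LM is a local method and a minority of random inits
  land in poor basins. With `n_starts > 1`, `lm_train` probes each start
  for `max_epochs/(2 n_starts)` epochs, then spends the remaining budget
  on the start with the best validation MSE. `max_epochs` caps the total
  accepted epochs across all phases, so the budget stays comparable to a
  single run.
* **Warm-up.** The first $\max(n_u - 1, n_y)$ samples of every trial only
  fill delay lines and are excluded from all losses and metrics; trial
  boundaries reset the delay lines.
* **Metrics.** Performance is the regression R: 100 x Pearson correlation
  between flattened targets and predictions; training loss is plain MSE.

## Model selection

* **Grid search** over $(n_u, n_y, n_l, n_n)$ - default ranges 1-10,
  1-10, 1-3, 10-50 by 5, a flat Cartesian product (2700 configurations;
  multi-layer entries share one node count). Budgets are expressed in
  epochs per configuration (default 30) rather than wall-clock, so results
  are hardware-independent. Ranking is by all-data R, ties broken by fewer
  parameters, then enumeration order.
* **Subject-wise k-fold CV** - folds partition subjects, never samples, so
  every score measures generalization to unseen individuals.
* **Per-channel estimability** - one single-output model per EMG channel on
  the pooled data, ranked by R; this is how the well-estimated muscles are
  selected before the final configuration search.
* **Sequential backward selection** - phase 1 records the full-input
  baseline; each later phase trains one model per remaining input with
  that input removed and eliminates the input whose removal *helps most*
  (least dominant), down to a single survivor. The dominance order is the
  elimination order reversed. The ANN mode (taps $(1,0)$ - the direct,
  history-free mapping) is the default for sensitivity analysis; an RNN
  mode with full delays is available. Candidate fits that degenerate (for
  example constant predictions, for which R is undefined) score $-\infty$
  rather than aborting the loop.

## Synthetic cohorts

Because no public dataset accompanies this kind of shoulder pick-and-place
protocol, the `synthetic_data` module generates full cohorts with the
statistical structure the pipeline expects. Defaults describe the study
conditions: 17 subjects, 12 trials of 20 s at a 0.4 Hz pick-place cadence,
anthropometrics drawn from mass 72.25 +/- 29.85 kg and height 1.66 +/-
0.16 m truncated at +/-2 SD, 11 named shoulder-girdle EMG sites, raw EMG
at 1500 Hz, 15 dB additive-noise SNR and a 60 Hz interferer at 20% of
signal RMS (surface recordings in the 10-20 dB range with visible mains
pickup are the realistic regime this emulates).

Trajectories are piecewise minimum-jerk (quintic) cycles between jittered
waypoints; joint torque comes from the package's own inverse dynamics and
activation torque from the MTG inversion, so the five inputs are mutually
consistent by construction. Two target modes:

* **mechanistic** - true activations are rectified signed shares of the
  activation torque through a 40 ms first-order lag, with an
  agonist/antagonist split, a 5% co-contraction floor, and per-subject
  per-muscle gains; raw EMG is a 20-450 Hz Gaussian carrier
  amplitude-modulated by the activation plus mains and white noise. This
  exercises the whole preparation chain realistically.
* **narx_teacher** - targets are produced by a fixed reference NARX
  (1 hidden layer, 10 nodes, taps 3/5) run closed-loop on the standardized
  biomechanical inputs. The teacher's weights are scaled (input gain 6,
  output gain 3, biases in [0.3, 0.6]) so its outputs occupy a
  non-degenerate range of $[0,1]$: the mode exists to guarantee the
  mapping is *inside* the model class and identifiable, making recovery
  failures attributable to the implementation rather than the data.

What the generator does **not** emulate: real motor-unit statistics,
electrode placement and crosstalk, soft-tissue artifact, target-contact
reaction forces, fatigue, or out-of-plane motion. Passing recovery tests
therefore demonstrates correctness of the algorithms and identifiability
under the assumed structure - not field accuracy on laboratory data.

## Problem sizes used by the test suite

The packaged tests run the full algorithms at reduced scale, chosen as the
smallest sizes at which each property is cleanly identifiable: teacher
recovery uses 17 subjects x 1 trial x 8 s (a 60-epoch budget with 3
starts), selection tests use 1-2 subjects with a few hundred samples and
single-digit epoch budgets, and the end-to-end pipeline smoke test uses 4
subjects x 4 s. The defaults of `cohort_spec()` remain the full study
conditions.

## Known limitations

* Training materializes the full residual Jacobian
  ($N_{res} \times P$); practical up to a few thousand parameters and a
  few hundred thousand residuals, which covers the configuration grid but
  not large multi-layer networks.
* Closed-loop training (backpropagation through the feedback loop) is out
  of scope; models that are excellent open-loop are almost always stable
  closed-loop here, but no stability guarantee exists.
* The MTG scaling-curve coefficients are parametric stand-ins, not fitted
  experimental curves; swap them via `mtg_params()` if calibrated values
  are available.
* The planar two-link reduction ignores scapular kinematics and 3-D
  shoulder rotation; the Euler-rate machinery is provided but the bundled
  dynamics are sagittal-plane only.
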