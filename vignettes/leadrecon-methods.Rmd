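---
title: "Methods: universal 12-lead reconstruction from a chest patch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: universal 12-lead reconstruction from a chest patch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`leadrecon` studies how well the standard 12-lead ECG can be synthesised
from three bipolar chest leads taken off a four-electrode patch, using one
transformation shared by all subjects ("universal coefficients"). The
package contains both halves of that study: a forward simulator that
generates cohorts with known ground truth, and the
reconstruction/evaluation pipeline itself.

### Forward model

Cardiac electrical activity is represented by one or more current dipoles
inside an infinite homogeneous volume conductor. A dipole with moment
$\mathbf{p}(t)$ (mA·cm) at $\mathbf{r}_0$ produces the surface potential

$$\varphi(\mathbf{r}, t) =
  \frac{\mathbf{p}(t) \cdot (\mathbf{r} - \mathbf{r}_0)}
       {4 \pi \sigma \lVert \mathbf{r} - \mathbf{r}_0 \rVert^{3}},$$

with $\sigma = 0.2$ S/m. Two consequences shape everything downstream:
potentials are *linear* in the instantaneous moment, and superposition holds
over sources. With a single dipole and no noise, every channel is an exact
linear combination of the three moment components, so the 35-channel chest
matrix has rank 3 and a least-squares reconstruction from any non-degenerate
chest-lead triplet is exact. The test suite uses this regime as a physics
oracle (per-lead CC of 1 for all 99 shape-family combinations).

We chose the infinite homogeneous medium over a boundary-element torso
because it preserves exactly the linear structure the reconstruction
exploits while staying desk-scale. The cost is geometric realism: the
bounded torso's surface concentrates potential at distant electrodes, which
the $1/d^2$ decay of the free medium does not. Two accommodations follow:

* Limb electrodes sit at their torso-proximal equivalents (shoulders,
  left hip) rather than on the limbs, as wireless limb placements do;
  at true limb distances the free-medium potentials would be negligible.
* The default dipole origin (2.7, −8, −11.6) cm (x toward the subject's
  left, y anterior, z superior; chest plane at y = 0) lies deliberately off
  the grid's mirror planes. A dipole exactly midway between electrode
  columns makes the chest-lead triplet of a mirror-symmetric combination
  exactly rank-2 — a measure-zero artifact of round-number geometry that no
  real heart position exhibits.

### Beat morphology and the cohort

The dipole trajectory is a periodic sum of Gaussians per axis (P, QRS, T),
with peak moments of roughly 0.2, 2.0 and 0.7 mA·cm and a QRS axis pointing
left–inferior–anterior; these magnitudes put chest potentials near 1 mV,
the textbook scale. The realistic ("multi") source mode adds a second,
smaller dipole displaced a few cm with its own morphology, plus independent
per-beat log-normal amplitude modulation of each source (SD 0.05). This is
what makes the universal reconstruction *imperfect*: the two transfer
geometries mix differently from beat to beat and subject to subject, so no
single linear (or small nonlinear) map is exact — emulating why
correlations below 1 are observed on real cohorts.

Inter-subject variability: heart position jitter (SD 1 cm per axis),
orientation jitter (SD 8°), and log-normal amplitude scale (SD 0.15), all
drawn from a per-subject seed so a subject's geometry is identical across
sessions. Noise per session: white noise (SD 10 µV), baseline wander
(100 µV at 0.25 Hz) and powerline interference (20 µV), random phase per
channel. These values were fixed once as plausible resting-ECG magnitudes;
they are engineering defaults, not measured quantities.

What the generator does **not** emulate: real anatomy and inhomogeneous
conductivities, respiration and motion, electrode–skin impedance drift, and
pathological morphologies. Passing tests therefore demonstrate that the
pipeline's algebra, statistics and selection machinery are correct and that
its qualitative behaviour (shape ordering, weak leads III/aVL) matches the
physics — not that a particular CC level would be attained on humans.

## The pipeline

1. **Filtering.** Second-order Butterworth bandpass, 0.5–35 Hz, applied
   forward and backward (zero phase) with odd-reflection padding. The first
   and last 2 s of every scored segment are excluded from metric windows
   (`edge_trim_s`); filtering is linear, so it preserves the rank-3
   structure of oracle data.
2. **Segments and merging.** One uniformly random, seeded segment per
   recording (20 s by default), concatenated in subject order. Session 1
   forms the training merge, session 2 the test merge — no cross-validation
   is added, because the object of study is a single universal coefficient.
3. **Lead algebra.** `I = LA − RA`, `II = LL − RA`, `III = LL − LA`;
   `aVR = −(I+II)/2`, `aVL = (I−III)/2`, `aVF = (II+III)/2`;
   `Vi = precordial_i − WCT` with `WCT = (LA+RA+LL)/3`. The Einthoven
   (`I − II + III = 0`) and Goldberger (`aVR + aVL + aVF = 0`) closures hold
   to floating-point precision by construction and are asserted on all
   simulated recordings.
4. **Chest leads.** From four electrodes, the three leads are each
   non-reference electrode minus a common reference, chosen as the lowest
   id. Any fixed reference spans the same 3-dimensional lead space, so
   fitted-model CC/RMSE are unaffected; a test asserts this by refitting
   against a triplet referenced to the highest id.
5. **Standardization.** Chest leads are standardized to zero mean / unit SD
   using *training* statistics only, reused verbatim on the test merge —
   test-set leakage would be inconsistent with a deployable universal
   coefficient. MLR targets stay in µV (so coefficients carry units); ANN
   targets are standardized with training statistics and predictions
   inverted, so RMSE is always reported in µV.

## Transformation models

**MLR.** Ordinary least squares of the 12 leads on the 3 standardized chest
leads plus bias, via QR; rank-deficient chest-lead matrices are rejected
with an explicit error (see the symmetry remark above for when that can
genuinely happen).

**ANN.** A 3–6–12 feedforward network, logistic-sigmoid hidden layer, fixed
at 6 hidden units (exposed as `ann_hidden` for sweeps). Weights are
initialized uniformly in ±1/√fan-in from a per-member seed; for the default
linear output the output layer is then warm-started by least squares on the
initial hidden activations. Plain full-batch descent from random output
weights spends hundreds of epochs recovering what is essentially the best
linear readout of the random features; the warm start removes that plateau
while keeping training deterministic per seed and preserving member
diversity through the random hidden layer. Training is full-batch gradient
descent with a bold-driver step (grow 10% on acceptance, halve on a loss
increase), which makes the recorded loss trace non-increasing by
construction; it stops at `max_epochs` (2000 by default), on a relative
plateau below 10⁻⁸ for 10 accepted steps, or on step-size underflow.
Divergence (non-finite loss) raises an error.

**Output activation.** The default is linear. A softmax output is provided
as a configurable mode, but a softmax constrains the 12 outputs to a
positive simplex and cannot represent signed voltages; it exists for
completeness and for comparing against toolbox conventions that label a
regression readout "softmax". All shipped analyses use the linear mode.

**Ensemble.** The network is trained five times with distinct seeds and
predictions are averaged pointwise before inversion to µV. By convexity of
squared error, the ensemble's MSE never exceeds the members' mean MSE; the
suite asserts this on every fitted combination.

## Evaluation and selection

CC, RMSE and R² are computed per subject and per lead on each subject's
test segment (edges trimmed); per-lead aggregates are the subject mean and
median. ICC(2,1) — two-way random effects, absolute agreement, single
measures — is computed from the pooled (time sample) × (reference,
reconstruction) table per lead. Bland–Altman bias, ±1.96 SD limits and the
difference-on-mean slope summarise agreement at selected combinations.

Selection: the **meanCC** score is the mean of the 12 per-lead mean CCs and
the **minCC** score their minimum (subjects are averaged first; the minimum
runs over leads, matching how per-lead weaknesses such as aVL are usually
discussed). Ties break deterministically by the lowest id quadruple.
min ≤ mean holds for every combination by construction and is asserted.

Statistical comparisons: shape families are compared by two-sided Wilcoxon
signed-rank tests on (subject × lead) pairs at each family's selected
combination — exact distribution for ≤ 25 untied pairs, normal
approximation with continuity correction otherwise; identical pairs are a
signalled degenerate case. The position analysis is a per-lead one-way
ANOVA of per-subject CCs across a base combination and its valid one-step
shifts. No multiple-testing correction is applied by default.

**Robustness.** Each triangle combination is scored by the average
selection metric of its one-electrode-shifted variants (up/down/left/right)
that remain on the grid; interior triangles average exactly four
neighbours, boundary ones fewer. The unshifted position is excluded by
default (`robustness_include_self` includes it), since the question is what
happens when the patch is *misplaced*.

## Problem sizes

The full study design — 14 subjects × 2 sessions, 250 Hz, 120 s recordings,
20 s segments — is the package default. The shipped tests and
`scripts/acceptance.R` run a scaled variant chosen once for desk-scale
turnaround: 14 × 2 subjects at 100 Hz, 40 s recordings, 10 s segments
(training merge of 14,000 samples), ANN capped at 120 epochs, and the
physics oracle on 3 noiseless subjects. The exhaustive 52,360-combination
MLR scan is supported (`families = "all"`) but not exercised by default;
the ANN always runs the 99 shape-family combinations only.

## Known limitations

* The free-medium forward model understates far-field structure; absolute
  CC/RMSE levels are not comparable to human data, only orderings and
  mechanisms are.
* Whole-segment CC is used (not per-beat); with nonstationary beats the two
  differ slightly.
* The ICC pools time samples as rating targets, treating samples as
  exchangeable; serial correlation within beats makes its nominal
  uncertainty optimistic (the point estimate is unaffected).
* Recordings are read/written as columnar CSV only; binary physiological
  formats are out of scope.
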