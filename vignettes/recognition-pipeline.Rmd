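---
title: "Recognizing scheduled rehabilitation exercises from wearable IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing scheduled rehabilitation exercises from wearable IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The recognition problem

Home-based physiotherapy programs prescribe simple, slow, cyclic lower-limb
exercises — hip flexion while lying, side-lying hip abduction, seated knee
extension, prone knee flexion, ankle dorsiflexion, standing heel raises.
A clinician tracking adherence remotely needs to know, from a single
wearable inertial sensor (3-axis accelerometer + 3-axis gyroscope), *which*
scheduled exercise a cycle of movement corresponds to, and whether the
movement stayed within the expected range. `rehabrecog` implements that
pipeline end to end: signal simulation, tilt-angle preprocessing,
feature extraction, two multiclass recognizers, evaluation, and a pattern
bank for deployment.

Each exercise follows a fixed four-phase motion guide (rest, rise to the
target posture, 5-s hold, return), completing one cycle in 11 s. At the
default 100 Hz sampling rate a cycle is 1100 samples — the unit of
recognition.

## Tilt angles and relative data

Because the exercises are slow, the accelerometer essentially measures the
gravity direction in the sensor frame (quasi-static regime). Sensor
orientation is summarized by tilt angles, in either of two conventions:

- **projected** (inclinometer) angles
  $\theta_i = \arctan\!\big(a_i / \sqrt{a_j^2 + a_k^2}\big)$,
- **included** angles between the acceleration vector and each base axis,
  $\theta_i = \arcsin(a_i / \lVert a \rVert)$, which satisfy
  $\sin^2\theta_x + \sin^2\theta_y + \sin^2\theta_z = 1$.

All downstream analysis uses *relative* angles: the mean angle over the
first 0.5 s of a cycle (the rest posture) is subtracted per axis. This
removes inter-individual posture offsets, and it makes the two conventions
practically interchangeable for classification — both are monotone
functions of the underlying limb excursion, so class rankings of
aggregate features agree (a property the test suite checks on noiseless
data). The included convention is the default; `projected` is available by
flag. The 0.5-s reference window (rather than a single initial sample) is
a noise-robustness choice: it averages ~50 samples of rest posture.

Gyroscope channels are generated, stored and carried through the
interchange CSV, but the recognizers use angle-derived features only: for
slow scheduled motions the relative angle separates the classes far better
than rate signals do.

## The synthetic motion generator

No public recordings exist for this task, so the package ships a
first-class generator that defines the study conditions. One cycle is
produced by tilting the sensor along a fixed per-exercise direction in the
(y, z) included-angle plane:

$$\theta_{y}(t) = \theta_{y,0} + m_y\,\big(A\,s(t) + \tau(t)\big), \qquad
  \theta_{z}(t) = \theta_{z,0} + m_z\,\big(A\,s(t) + \tau(t)\big)$$

with $(m_y, m_z)$ a unit "axis mix", $A$ the range of motion (ROM),
$s(t)$ a smoothstep ($3u^2 - 2u^3$) rest–rise–hold–return envelope
(C¹-continuous, as slow voluntary motion is), and
$\tau(t) = 1^\circ \sin(2\pi \cdot 1.5\,t)\, s(t)$ a small physiological
tremor riding on the motion envelope. The tremor guarantees the signals
are not piecewise-polynomial — pure smooth ramps can yield fewer than
three intrinsic mode functions, degenerating the frequency-domain
features. The acceleration is the unit gravity vector consistent with the
included angles (so $\lVert a\rVert = 1$ g exactly before noise); the
gyroscope reads the angle derivatives.

Tunable parameters (units, defaults, why):

| parameter | default | rationale |
|---|---|---|
| ROM per exercise | 60, 35, 70, 45, 28, 20° | distinct amplitudes in the physiological range of each movement |
| axis mix per exercise | (1,0), (.71,.71), (0,1), (.6,−.8), (0,−1), (−.71,.71) | six distinct directions so the classes occupy separate regions of the (y-sum, z-sum) plane, as planar exercises with different movement planes do |
| `rom_scale` | 1 | global subject-strength multiplier |
| `rom_cycle_cv` | 0.05 | ~5% cycle-to-cycle ROM variability, typical of voluntary motion |
| `acc_noise_sd` | 0.01 g | consumer MEMS accelerometer noise at 100 Hz |
| `gyro_noise_sd` | 0.5 °/s | consumer MEMS gyroscope noise |
| `timing_jitter_sd` | 0.1 s | imperfect adherence to phase boundaries; the 11-s total is kept fixed because segmentation assumes fixed-length cycles |
| tremor | 1° at 1.5 Hz | low-amplitude physiological tremor |

What the generator does **not** emulate: biomechanically accurate limb
dynamics (the quasi-static model ignores motion acceleration),
sensor-specific noise spectra (noise is white Gaussian), drift and
temperature effects, misplaced or rotated sensors, and free-living
non-cyclic activity. Perfect recognition on this synthetic data therefore
demonstrates that the pipeline is correct and that the feature geometry
separates the designed classes; it does not by itself establish
performance on real patients, where inter-subject ROM differences and
protocol deviations dominate.

## The 63 features

Each 1100 × 3 segment yields 21 features per axis:

- **15 time-domain statistics**: sum, absolute sum, sum of squares, mean,
  absolute mean, median, quartile distance (Q3 − Q1), min, max, range,
  mean absolute deviation, population standard deviation and variance
  (1/n), skewness and kurtosis.
- **6 frequency-domain features**: the marginal-Hilbert-spectrum area
  centroid frequency and energy of each of the first three IMFs
  (`IMF1_f … IMF3_e`).

Numerical conventions worth stating: skewness and kurtosis are the
standardized moments *with* the 1/n factor,
$SK = \tfrac1n \sum ((x-\mu)/\sigma)^3$ and likewise $KT$ — the raw sums
$\sum((x-\mu)/\sigma)^k$ grow linearly with segment length and would make
the statistic depend on the sampling rate, so the normalized form is used.
Quartiles use R's default interpolated (type-7) quantiles. A constant
series has $\sigma = 0$; its skewness and kurtosis are reported as 0 with
a warning rather than NaN, so degenerate axes do not poison a feature
table. Variance is the population (1/n) form, matching the 1/n convention
of the other moments.

Fifteen fixed feature patterns (subsets of the 63 keys) are provided;
the small y/z aggregate patterns — (3) `{ysum, zsum}`, (6)
`{yavg, zavg}`, and their unions (5), (8), plus (12) which adds the IMF3
centroid features — are the recommended recognizer inputs for planar
exercises. x-axis features carry little signal for motion in the y/z
plane but are retained for completeness (patterns 1, 2, 9–11, 13).

## EMD and the marginal-spectrum centroid

The empirical mode decomposition follows the classic sifting procedure:
cubic-spline envelopes through the local maxima and minima, subtract the
envelope mean, iterate until the candidate is an IMF. Choices the
literature leaves open, fixed here:

- **Boundary handling**: two extrema are mirror-reflected about each end
  before spline fitting — the standard end-effect mitigation.
- **Stopping rule**: the IMF condition (|#extrema − #zero crossings| ≤ 1)
  *and* a Cauchy criterion $\sum(h_{k-1}-h_k)^2 / \sum h_{k-1}^2 < 0.25$,
  with at most 100 sifting iterations (the counting condition alone can
  cycle indefinitely).
- **Termination**: decomposition stops when the residue has fewer than 3
  extrema ("monotonic-like", robust to float noise) or after 3 IMFs — the
  slow cyclic motions carry no useful structure in later modes.
- Reconstruction $\sum_j \mathrm{IMF}_j + \text{residue} = x$ is exact by
  construction and asserted to 1e-6 relative in the tests.

Each IMF then passes through Hilbert analysis: analytic signal by FFT,
instantaneous frequency as the central difference of the unwrapped phase
(clipped to [0, Nyquist]), energy $A(t)^2$. The outer 5% of samples at
each end are discarded — both the Hilbert transform and the phase
derivative are unreliable at the boundaries; for a pure tone this retains
90% of the theoretical energy $A_0^2 T$, which the tests verify. The
marginal spectrum accumulates $A(t)^2\,dt$ into 0.05-Hz bins (the
exercises live below ~2 Hz, so sub-0.1-Hz resolution is needed there),
and each IMF is summarized by the **area centroid** of that spectrum: the
energy-weighted mean frequency, paired with the total area (= total
energy). Reading the centroid's second coordinate as total energy — rather
than the geometric y-centroid $\sum h^2/2 / \sum h$, which is also
available behind a flag — keeps the feature in energy units, consistent
with deriving a power by dividing by the segment duration.

## The two recognizers

**SVM.** A one-versus-one reduction over binary soft-margin SVMs with the
third-order polynomial kernel, kernel scale 1 and box constraint 1
(libsvm via e1071; 6 classes → 15 binary learners). Features are z-scored
before kernel evaluation — with a kernel scale of 1 this is not optional,
since raw features span orders of magnitude (a segment sum is ~10⁴
degree-samples, an IMF energy ~10⁰). Binary decision values are
sigmoid-calibrated and combined by pairwise coupling into per-class
posterior scores summing to 1; the label is the argmax, ties broken
toward the smallest label. The calibration's internal cross-validation is
run under a fixed RNG substream so that refitting identical data is
reproducible.

**ANFIS.** A zero-order Sugeno fuzzy system initialized by subtractive
clustering with influence range 0.8 (of the normalized unit range),
squash factor 1.25, accept ratio 0.5, reject ratio 0.15, and Gaussian
membership functions. Clustering runs on the joint input + output space
(inputs min-max normalized, labels scaled to [0, 1]) so that the rules are
class-aware; each center seeds one rule with membership width
$\sigma = r_a/\sqrt{8}$ per input — the standard subtractive-clustering
convention. Consequents are constants (first-order linear consequents are
available by config). Hybrid training alternates, for 30 epochs, an exact
least-squares solve for the consequents (ridge-stabilized against
near-duplicate rules) with one normalized-gradient step on all membership
centers and widths; the step size starts at 0.01 and adapts ×1.1 after an
improving epoch, ×0.9 after a worsening one, and the best-RMSE state is
returned. Thirty epochs is deliberately modest: the least-squares step
does most of the work on well-clustered data, and the RMSE path is
recorded so a user can extend training when it has not flattened.
Inference is the weighted average of rule consequents; when every rule
fires below 1e-12 the input is outside the membership support and the
model signals "out of inferring range" rather than extrapolating — such
segments count as misclassified in evaluation. The crisp output decodes
to a label by round-half-up clamped to [1, 6], so values in
[k − 0.5, k + 0.4] map to label k.

## Evaluation and tracking

Cross-validation is stratified: each class's segments are spread evenly
over the k folds (shuffled under a fixed seed), which keeps the
balanced-class design intact in every fold. The confusion matrix is
reduced one-versus-rest per class to TP/FN/FP/TN, from which accuracy,
sensitivity (TPR) and FPR = 1 − specificity are exact count ratios; 0/0
is reported as NA rather than silently coerced. ROC curves are
one-versus-rest threshold sweeps with trapezoidal AUC; the sweep is
verified in the tests against the pairwise-comparison (Mann–Whitney)
definition at 1e-9. The ANFIS produces a single ordinal crisp value, not
per-class scores; its OVR score for class k is defined as
$-|\hat v - k|$, the natural distance-based surrogate.

Traceable-diagram records flag a segment as an outlier when the SVM label
differs from the scheduled label, or when the ANFIS crisp value leaves
the scheduled label's band [k − 0.5, k + 0.4]. These per-segment records
(CSV in `fig_log`) are what a dashboard would plot against the dashed
label bounds.

## Problem sizes and runtime

The packaged experiments use 65 cycles per exercise (390 segments) for
5-fold cross-validation and 30 per exercise (180 segments) for testing —
a realistic week of supervised recording per subject. Feature extraction
dominates runtime (~0.1 s per segment, almost entirely EMD sifting);
the full 390-segment pipeline with both recognizers completes in well
under a minute on one core. The `scripts/acceptance.R` script reruns the
whole chain from a seed and writes the headline numbers as JSON.

## Known limitations

- The quasi-static tilt model breaks down for fast or ballistic motions;
  acceleration- and angular-velocity-derived features would be needed
  there and are not implemented.
- Segmentation assumes the schedule's fixed 11-s cycle; free-form
  repetitions would need cycle detection (e.g. dynamic time warping),
  which is out of scope.
- The ANFIS scales poorly in the number of input features: rule count is
  set by clustering, but membership products in high dimensions push test
  points outside the inferring range (pattern 1 with 63 inputs is not a
  practical ANFIS input, matching its intended use with 2–8 features).
- Synthetic validation bounds what can be claimed about real subjects;
  see the generator section above.
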