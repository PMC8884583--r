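---
title: "Channel-wise seizure detection, tracking and onset-zone lateralization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-wise seizure detection, tracking and onset-zone lateralization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In focal epilepsy a seizure originates in a discrete seizure onset zone
(SOZ) and spreads over time to involve other brain areas.  Scalp EEG is the
first modality used to evaluate these patients, but clinical annotations are
coarse: an onset and offset time for the whole recording, and at best a
hemisphere (left/right) and a coarse head region for the SOZ.  `ictrack`
implements a channel-wise deep network that is trained from exactly this
kind of weak label yet produces predictions at the resolution of individual
electrodes and one-second windows — a map of where and when seizure
activity appears — together with a lateralization and an anterior/posterior
classification of the onset zone.

## Model

Every electrode's signal is cut into one-second non-overlapping windows
$X_i[t]$ (electrode $i$, window $t$).  Three components, all with parameters
*shared across electrodes*, turn these into per-channel seizure
probabilities:

1. **Encoder.**  A 3-layer 1D CNN applied to each window: 20 kernels of
   length 7 (padding 3), LeakyReLU, max-pooling (kernel 2) and batch
   normalization in the first layer; 20 kernels of length 3 (padding 1)
   with LeakyReLU, batch normalization and an identity residual connection
   in each of layers 2 and 3; global average pooling over time yields a
   length-20 embedding $h_i[t]$.
2. **Tracker.**  The embedding sequence of each electrode runs through a
   bidirectional LSTM with 40 hidden units per direction (80-dimensional
   outputs $o_i[t]$), capturing the minute-scale evolution of ictal
   rhythms.  Weights are tied across electrodes so no scalp location is
   privileged.  The *No-BLSTM* ablation replaces this stage by the
   identity, so the classifier sees window-local features only.
3. **Classifier.**  A softmax over {baseline, seizure} of an affine map of
   $o_i[t]$, giving $P(Y_i[t] = 1 \mid X)$.

Because nothing mixes information across channels inside the network, the
architecture is exactly channel-permutation equivariant and its parameter
count is independent of the montage size.  Both properties are asserted in
the test suite.

### Aggregation: learning electrode-level maps from recording-level labels

The recording-level detection trace is the channel-wise maximum
$$P(\hat Y[t]=1 \mid X) = \max_i P(\hat Y_i[t]=1 \mid X),$$
so the network registers a seizure as soon as any one electrode enters the
seizure state.  This is what lets ordinary onset/offset annotations train
electrode-level behaviour: during backpropagation the max routes each
window's gradient to the currently most seizure-like channel (the
subgradient of the max).

For localization, positive first differences of the trace mark transitions
into seizure, $\Delta[t] = \max(\hat y[t{+}1] - \hat y[t],\, 0)$, and the
channel-level onset score weights each electrode's activity by that onset
mass:
$$P(L_i = 1 \mid X) \;=\;
  \frac{\sum_t \Delta[t]\, P(\hat Y_i[t{+}1]=1 \mid X)}
       {\sum_j \sum_t \Delta[t]\, P(\hat Y_j[t{+}1]=1 \mid X)}.$$
Summing these scores over the electrodes of a zone (left/right hemisphere,
or anterior/posterior head region) gives the zone posterior pair used for
training with a cross-entropy against the clinical label.

Two indexing conventions needed fixing here, because a literal reading of
the two formulas together would require a trace value before the first
window: the increments are defined over the $T-1$ consecutive-window
transitions, and each transition weights the channel activity at the
*later* window — the seizure activity at the moment just entered.  No
onset mass is imputed at the first window: a recording already in seizure
when it starts contributes nothing, which is deliberate (localization
inputs are clipped to start 15 s before onset, so this situation signals
bad input rather than an onset).  The brute-force oracle tests pin this
convention.

### Zone partitions

The montage is the 16-electrode lateral 10–20 set (the midline electrodes
Fz/Cz/Pz can be appended but are excluded from both partitions and their
onset mass is discarded with the pair renormalized, so training targets
remain proper distributions).  Hemispheres follow the odd/even 10–20
convention.  The anterior zone holds the frontal row (Fp1, Fp2, F3, F4,
F7, F8); the posterior zone holds central, temporal, parietal and occipital
electrodes.  F7/F8 sit on the frontal/temporal border and must live in
exactly one zone; they are placed anterior here because they are F-row
electrodes, and `region_partition(overrides = )` lets a user move them.
The C row is posterior, grouping with the temporal/parietal foci.

## Training

Detection training minimizes the window-wise binary cross-entropy between
the max-pooled trace and the 0/1 clinician annotation, averaged over
windows (the reduction is a package choice; the loss is defined per
window).  The published schedule is the default: 50 epochs, weight decay
1e-4, batches of 4 recordings, learning rate 0.01 halved every 20 epochs.
Training recordings are trimmed to 2 minutes of pre- and post-seizure
context; evaluation uses full recordings.  Localization fine-tunes the
detection models for another run of the schedule on 45-s clips
($[{\rm onset}-15, {\rm onset}+30)$ s) with the combined objective
$\lambda_{sz}\,\mathrm{CE}_{det} + \mathrm{CE}_{zone}$; $\lambda_{sz}$ can
be swept.

Choices the sources leave open, made once here:

* **Optimizer**: plain stochastic gradient descent (the minimal reading of
  "learning rate ... reduced by a factor of 0.5"); gradients are averaged
  over the recordings of a batch.
* **Gradient clipping**: the global gradient norm is capped at 5 per step,
  a standard stabilizer for recurrent networks; `train_config(grad_clip =
  Inf)` disables it.
* **Batch normalization**: statistics are computed per forward pass over
  all channel-instances, windows and positions jointly; running estimates
  (momentum 0.1) are frozen at inference.  In layer 1 the listing order
  conv → LeakyReLU → max-pool → batch-norm is followed literally.
* **Initialization**: fan-in-scaled uniform weights, identity batch-norm —
  the standard defaults of mainstream deep-learning libraries.
* **Cross-validation**: leave-one-patient-out; every recording of the
  held-out patient is excluded from training, asserted in code.

## Threshold calibration and scoring

The detection threshold is calibrated per fold on the training data: the
smallest observed trace value whose false-positive window time per baseline
hour stays within a budget of 2 minutes per hour.  Event scoring then takes
maximal runs of supra-threshold windows as predicted seizures: an interval
overlapping an annotated seizure is a true positive (post-seizure run-on is
not penalized, since offsets are clinically unreliable), an interval lying
entirely in baseline is a false positive, and latency is the first
overlapping interval's start minus the annotated onset, clipped at zero.
The false-positive rate is denominated in total recording hours (the
alternative, baseline-only hours, is computable from the same outputs).
Predicted intervals separated by a single sub-threshold window are not
merged: the tracker already smooths the trace, and no post-hoc smoothing is
applied.  Window-level metrics (sensitivity, specificity, AU-ROC, AU-PR)
are computed per recording and averaged with their standard deviation.

One degenerate corner is worth noting: with detection defined as
`trace >= theta`, an all-zero trace admits no *observed* threshold within
budget (everything fires at `theta = 0`), so calibration then returns a
value just above the maximum observed probability; the `1 + 1e-6` sentinel
is reserved for traces that reach certainty on baseline.

## The synthetic study

Clinical seizure EEG with SOZ annotations is not publicly available, so the
package ships a seedable generator whose defaults define the study
conditions used by the test suite: 8 patients × 3 recordings of 600 s at
200 Hz on the lateral 10–20 montage, patients balanced over the four
(hemisphere × region) onset-zone combinations.  Each recording holds one
seizure of 30–120 s with at least 30 s of margin.  Background activity is
1/f-shaped noise plus a shared common-mode component; at onset, 1–3 onset
electrodes inside the patient's zone start an amplitude-ramped 3–7 Hz
rhythm (5 s ramp, slow amplitude waxing), and every other electrode joins
after an exponential propagation delay (mean 5 s) with amplitude
attenuation increasing with distance from the onset zone (relative
amplitudes 1 / 0.8 / 0.55 / 0.3 for onset channels, same zone, half-matching
zones, and opposite zones).  The fully developed rhythm is 4× the
background standard deviation — a clearly separable seizure, chosen so that
recovery failures indicate implementation defects rather than an
intrinsically ambiguous signal.  Rare high-amplitude tapered transients
(2/min) emulate movement artifact.

What the generator does **not** emulate: realistic volume conduction and
electrode covariance, ictal morphology beyond a ramped rhythm (no spike-wave
complexes, no frequency evolution), state changes (sleep/wake), electrode
pops, or the heavy class imbalance and multi-focal cases of clinical
cohorts.  Passing the recovery checks therefore demonstrates that the
implementation can learn detectable spatio-temporal structure from weak
labels — not that clinical performance figures would be reproduced.

The recovery checks themselves run leave-one-patient-out training at 10
epochs (a reduced version of the published 50-epoch schedule; the loss
curve is still descending but held-out AU-ROC is already far above the
acceptance bar) and fine-tune localization for 10 further epochs at
$\lambda_{sz} = 0.6$.  These sizes are the package's chosen trade-off
between fidelity to the full schedule and a test suite that runs on one
CPU in tens of minutes.

## Numerical choices

* The network runs in single precision; an identical double-precision path
  exists and is used by the finite-difference gradient checks in the test
  suite (every analytic gradient — convolutions, batch-norm through its
  batch statistics, LSTM, max-pool routing, the onset-map chain — is
  verified against central differences).
* Probabilities entering cross-entropies are clipped at 1e-7; the gradient
  at the softmax logits uses the numerically stable form `(p - y) / T`.
* Batch-norm uses eps 1e-5 and biased batch variance.
* Ties in the channel max route the gradient to the first maximal channel;
  pooled ties keep the earlier sample.
* Zero-variance channels abort normalization with an error naming the
  channel; degenerate onset maps (no positive increment anywhere) return
  the uniform distribution and carry a `degenerate` flag rather than NaNs.
* The C++ core is written for a memory-bandwidth-bound single-CPU setting:
  convolutions in layers 2/3 run as cache-blocked shifted GEMMs on the
  layer inputs (no im2col buffer), layer 1 is a fused
  conv/LeakyReLU/pool pass, batch-norm inputs are reconstructed
  algebraically in the backward pass instead of being cached, and the large
  activation buffers live in a reused arena.

## Preprocessing

The fixed conditioning chain is resample to 200 Hz (anti-aliased
polyphase), zero-phase 4th-order Butterworth bandpass 0.5–30 Hz (the band
is prescribed; the filter family and order are the package's choice of
standard clinical practice), clamping of values beyond 2 SD from the
channel mean (clipping, not deletion, keeps the time axis contiguous for
the tracker; statistics are per channel over the full recording, computed
after filtering), z-normalization per channel, and windowing into 1-s
non-overlapping segments with any-overlap seizure labels and the trailing
partial window dropped.

## Known limitations

* The simulator is a test substrate, not a clinical surrogate; none of the
  quantities computed on it should be read as clinical performance.
* Max-pool aggregation trains only the currently most seizure-like channel
  per window; with very many silent channels convergence of per-channel
  suppression can be slow.
* The anterior/posterior split is a coarse two-zone partition; border
  onsets (fronto-temporal) are inherently ambiguous under it.
* EDF support covers the 16-bit signal layout with one sampling rate per
  file; clinical metadata beyond channel labels is ignored, and annotations
  travel in a CSV sidecar.
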