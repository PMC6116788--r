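---
title: "Unsupervised liquid computing: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised liquid computing: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spilinc)
```

## The model

A *liquid* is a sparse, randomly and recurrently connected population of
excitatory and inhibitory spiking neurons. Input neurons project through
plastic synapses onto the excitatory population; the recurrent fabric
(e→e, e→i, i→e, i→i) is fixed at generation time. Because the input
synapses — not the recurrent ones — are adapted with spike-timing-dependent
plasticity (STDP), individual excitatory neurons become selective for
recurring input patterns, and the class of a test input can be read
directly from excitatory spike counts without a trained readout layer.
A single such network is a Liquid-SNN; an ensemble of smaller liquids,
each trained on an overlapping segment of the input, is a SpiLinC.

### Neurons

Neurons are current-based leaky integrate-and-fire units with an adaptive
threshold. Between events, the membrane potential relaxes exponentially
toward the resting potential with time constant $\tau_{mem}$, and the
excitatory and inhibitory post-synaptic currents decay with
$\tau_{syn,e} = 2$ ms and $\tau_{syn,i} = 1$ ms. A neuron fires when its
potential exceeds $\theta_{base} + \theta_{adapt}$; it is then reset to
$V_{rst}$, barred from firing for the refractory period $t_{refrac}$, and
its threshold offset $\theta_{adapt}$ grows by $\theta_{+}$ (decaying with
the very slow $\tau_\theta$). This homeostasis equalizes firing rates
across the competing excitatory population — the property the
`test-dynamics` suite checks as a falling coefficient of variation of
per-neuron spike counts over training.

The simulator is clock-driven with exact exponential-decay updates per
step (forward-Euler leak factors would distort the decay at the 0.5 ms
step; the exact factors make one step of `dt` identical to two steps of
`dt/2` for the pure-decay terms). The per-step order is a fixed,
documented contract: deliver the spikes emitted in the previous step into
the synaptic currents, decay all state, integrate `i_exc − i_inh` into
the membrane potential, then test the threshold. Spikes therefore
propagate with a one-step delay, which resolves same-step causality in
the recurrent graph deterministically. Weights are in units of membrane
depolarization per step; the model has no physical current scale.

The excitatory defaults (`lif_params()`: $\tau_{mem}=100$ ms,
$V_{rest}=V_{rst}=-65$ mV, $\theta_{base}=-52$ mV, $\theta_{+}=0.05$ mV,
$\tau_\theta=10^7$ ms, $t_{refrac}=5$ ms) and inhibitory defaults
(`lif_params_inhibitory()`: $\tau_{mem}=10$ ms, $V_{rst}=-45$ mV, fixed
threshold $-40$ mV, $t_{refrac}=2$ ms) are the standard values of the
two-layer unsupervised-SNN lineage this architecture descends from; the
adaptive threshold applies to the excitatory population only, since only
it competes for input representations.

### Plasticity

Input synapses follow the power-law weight-dependent STDP rule

$$\Delta w = \eta\,\left[e^{-(t_{post}-t_{pre})/\tau} -
\mathrm{offset}\right]\,[w_{max}-w]^{\mu}$$

applied at post-spike instants, pairing each input synapse's most recent
pre-spike in the current presentation with the post-spike
(nearest-neighbor pairing; the offset term is what depresses
uncorrelated synapses). Weights are hard-clipped to $[w_{min}, w_{max}]$.
With the illustrated parameters ($\tau = 15$ ms, offset $= 0.4$) the rule
changes sign at $-\tau\ln(\mathrm{offset}) \approx 13.74$ ms: pre-spikes
within ~14 ms of the post-spike potentiate, older ones depress. Task
presets: image-like $\eta = 0.005$, offset $= 0.4$; speech-like
$\eta = 10^{-4}$, offset $= 0$ — with a zero offset no weight is ever
depressed, so input sparsity is preserved rather than increased during
training. Pre-spike timestamps are cleared at presentation boundaries to
prevent spurious cross-pattern correlations. Depression uses the same
$[w_{max}-w]^\mu$ factor as potentiation (the rule is one expression),
with clipping at $w_{min}$.

### Topology and synapse accounting

Connectivity between any two neuron groups is Bernoulli: an
`n_pre × n_post` uniform(0,1) matrix thresholded at `percent/100`.
Self-connections are not excluded from the e→e and i→i blocks (the
construction is over the full square matrix). The expected synapse count
of one liquid is the closed form implemented by `count_synapses()`; for
an ensemble it is the per-liquid count times the number of liquids,
since liquids share no synapses. The expectation can be fractional —
realized networks report their actual mask counts via
`realized_synapse_count()`, and the test suite checks the two agree to
binomial precision over seeds.

Ensemble input partitions overlap: two vertical image halves of width
`w/2 + overlap/2` (default overlap 4 columns, mirroring 28×28 images
split into 28×16 halves), the analogous horizontal halves (a 4-liquid
ensemble uses both pairs), and consecutive channel blocks for
channel-type input (39 channels in two blocks of 30 share 21 channels —
two disjoint blocks of 30 cannot exist in 39, so the overlap is forced;
it is configurable). `inputs_per_liquid()` gives the expected number of
connected inputs per liquid, which shrinks with ensemble size — the
reason very large ensembles stop learning useful features.

`effective_synapse_count()` counts input weights above a pruning
threshold $\epsilon$; the default $\epsilon = 0.01\,w_{max}$ is a small
fraction of the ceiling chosen to separate background-pixel synapses
(driven toward 0 by the offset term) from retained ones. No published
threshold exists for this accounting; the default is the package's
choice and is a parameter everywhere it is used.

### Encoding

Image intensities in $[0, 255]$ map linearly to Poisson rates in
$[0, 63.75]$ spikes/s; a rate maps to a per-step firing probability
$p = \mathrm{rate}/1000 \times t_{step}$ (0.031875 at full intensity and
$t_{step} = 0.5$ ms), held constant over the 350 ms presentation. Channel
envelopes are normalized by the sample's global maximum intensity —
read as one scalar per sample rather than per-frame maxima, so relative
channel energies are preserved — and used directly as per-step firing
probabilities over a 750 ms presentation, resampled to the simulation
grid by zero-order hold (the frame rate of real cochleagram front-ends
varies; holding each frame is the simplest contract and is exact for
frame durations that are multiples of the step). Spikes are independent
Bernoulli draws per neuron per step.

### Training, tagging, and inference

Training presents the dataset cyclically (samples replicated as needed)
for a configured number of presentations. Membrane state, synaptic
currents, refractory timers and the pre-spike cache reset between
presentations; adaptive thresholds persist throughout training and are
frozen — not reset — at test time, so test-phase excitability reflects
training-phase homeostasis. Labels never enter the weight update; they
only accumulate per-neuron, per-class training spike counts
(the unsupervised contract, tested by permuting labels and comparing
weight trajectories bit-for-bit).

After training, each excitatory neuron with nonzero training activity is
tagged with its top one (image-like) or two (speech-like) classes by
cumulative training spike count; silent neurons are untagged and excluded
from group sizes. Classes with fewer training presentations are not
rebalanced — tagging uses raw cumulative counts. At test time the
per-class average spike count over each tag group is computed per
liquid; the ensemble's resultant average is the plain mean over liquids
(a liquid with no neurons tagged $j$ contributes 0 and the divisor stays
the number of liquids); the prediction is the argmax. A neuron carrying
two tags contributes its full spike count to both groups. All argmax
ties break toward the lowest class index, deterministically, with a
warning. False-negative and false-positive percentages follow the
column/row-sum-minus-diagonal definitions on a predicted × actual
confusion matrix.

## Synthetic data: what it emulates, and what it does not

The generator provides desk-scale stand-ins for the two modalities:
binary oriented-bar glyphs at intensity 255 with independent per-pixel
flip noise (image-like), and Gaussian channel-bump trajectories —
sweeps, steady bands, pulsed bands — with multiplicative intensity noise
and circular temporal jitter (speech-like). Templates are deterministic
functions of class index and shape, so tests can reference them; the
default conditions are 4 classes on 12×12 images and 4 classes on
20-channel × 100-frame envelopes, with flip/noise level 0.1 — at that
level a nearest-template classifier still exceeds 90%, which bounds what
the liquid can be asked to learn.

These fixtures have the statistical structure the method assumes
(class-specific spatial/temporal intensity patterns under rate coding)
but none of the within-class variability of handwritten digits or the
speaker variability and phonetics of spoken-digit corpora. Passing the
synthetic acceptance runs demonstrates that the mechanism — STDP-driven
selectivity, tagging, ensemble pooling — works end to end; it does not
certify accuracy figures on real corpora, which require liquids of
thousands of neurons and $10^4$–$10^5$ presentations.

## Study conditions and numerical choices

The end-to-end classification checks train a 400-neuron single liquid
(320 excitatory : 80 inhibitory, the image-task 4:1 ratio) on the
4-class glyph set for 2,000 presentations, and a two-liquid ensemble of
200 neurons per liquid on vertical halves (overlap 4 columns, ensemble
input connectivity 50%) under the same schedule — sizes at which a full
training run takes a few minutes on one CPU. Held-out evaluation uses 10
fresh samples per class from a different generator seed. The ensemble
check asks for accuracy within 10 percentage points of the equal-size
single liquid, the direction of the published comparable-accuracy claim.

Other choices worth knowing:

* **Units and integration.** `v += i_exc − i_inh` per step, currents
  step-wise constant; no conductances, no axonal delays, no
  sub-millisecond solvers.
* **Simultaneous pre-spikes** sum linearly into the current.
* **Refractory neurons** keep integrating their membrane; only the
  threshold test is gated.
* **Train/test synaptic time constants are identical.** The lineage's
  swapped-constant trick for test-phase excitability is not modeled; no
  mechanism for a phase-dependent change is defined here.
* **RNG discipline.** Topology generation, training and evaluation each
  take explicit seeds and restore the caller's RNG stream; ensemble
  liquid $i$ derives its stream as `seed + i − 1`. Identical seeds give
  bit-identical rasters, weights and metrics.
* **Degenerate inputs.** All-zero envelopes normalize to all-zero (no
  division); all-zero inputs produce zero spikes; empty class averages
  are 0, and an all-zero average vector predicts class 1 via the tie
  rule, with a warning.
* **Serialization.** Topologies and checkpoints are saved as RDS,
  datasets/rasters/metrics as CSV/YAML with shape sidecars.

## Limitations

Pure R, single-threaded: a presentation of 350 ms at the 0.5 ms step on
a 400-neuron liquid costs ~0.1 s, so liquids of $10^4$ neurons and
$10^5$ presentations are out of reach here. The readout-layer extension,
cochlear front-end, and learned recurrent connectivity are out of scope.
Accuracy on real MNIST/TI46-scale data is not reproduced by this
package's tests and is not claimed.
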