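---
title: "Spatio-temporal associative memory with spiking neural cubes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal associative memory with spiking neural cubes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(stamcube)
```

## The problem and the model

Multichannel brain recordings — EEG channels or fMRI voxels sampled over
time — carry class information jointly in *where* and *when* activity
happens. `stamcube` learns such data in a brain-inspired spiking pipeline
whose trained state behaves as an associative memory: once the full
spatio-temporal pattern is stored, a partial cue (a shorter time window, a
subset of channels) retrieves enough of it to classify. The pipeline has
three stages.

**Spike encoding.** Real-valued series are turned into ternary event trains
by the step-forward rule. Each (sample, variable) series is min–max
normalized to [0, 1], smoothed with a centered moving average (window 5,
clipped at the boundaries), and tracked by a baseline $B$ initialized at the
first filtered value. At each later step, if the signal reaches $B+\theta$ a
$+1$ spike is emitted and $B$ moves up by $\theta$; if it falls to
$B-\theta$, a $-1$ spike and $B$ moves down; otherwise no spike. Decoding is
the exact inverse, $\hat s(t) = B_0 + \theta\sum_{u\le t}\mathrm{pol}(u)$.

**Reservoir.** Neurons sit at 3D coordinates from a template. Directed
connections are drawn independently with probability
$p_{a,b} = C\,e^{-d^2(a,b)/\lambda^2}$ (optionally cut off beyond a radius,
with a separate long-distance probability). Dynamics are discrete-time leaky
integrate-and-fire: $u \leftarrow u(1-\ell) + \text{input} +
\sum_i w_{i\to j}\,[i \text{ fired at } t-1]$, firing at $u \ge \vartheta$
with reset and refractory period. During unsupervised training each step
applies spike-timing-dependent plasticity with nearest-spike pairing:
potentiation $A_+e^{(t_{pre}-t_{post})/\tau_+}$ for causal pairs, depression
$-A_-e^{-(t_{pre}-t_{post})/\tau_-}$ for anti-causal ones, zero for
simultaneous spikes. Weight changes persist across samples — the evolved
connectivity is the long-term memory.

**Readout.** The deSNN layer stores one output neuron per training sample:
weights initialize by first-spike rank order, $w_j = \alpha\,
\text{Mod}^{\text{order}(j)}$, then drift up/down with the neuron's later
spiking. A query is encoded the same way and classified by K-nearest
neighbours over the stored weight vectors (Euclidean distance divided by
$\sigma$).

**Recall conditions and RMA.** `truncate_temporal()` keeps the first
$\lfloor f\cdot T\rfloor$ steps (at least one); `mask_variables()` silences
dropped channels at the input without touching the trained structure.
Accuracy under a partial condition, $A_r$, is compared to the full
condition's accuracy $A_f$ *under the same split mode* as
$\mathrm{RMA} = A_r/A_f$. Resubstitution (train and validate on all samples)
measures association accuracy; a seeded stratified 50/50 holdout measures
generalization accuracy. Taking $A_f$ from the same split mode is what makes
a generalization RMA of, say, 76/80 = 0.95 meaningful.

## Parameters

| Parameter | Default | Units / range | Role |
|---|---|---|---|
| `spike_threshold` θ | 0.5 | normalized signal units | encoder sensitivity |
| `window_size` | 5 | time steps | pre-encoding smoothing |
| `C`, `lambda` | 1, 2.5 | —, template units | wiring probability scale and decay |
| `max_distance` | 3 | template units | hard wiring cutoff (3 × lattice spacing) |
| `inhibitory_fraction` | 0.2 | probability | share of inhibitory neurons |
| `ldc_probability` | 0 | probability | long-distance connections beyond the cutoff |
| `w0`, `w_max` | 0.1, 1 | weight units | initial magnitude cap, learning clip |
| `leak_rate` | 0.002 | per step | multiplicative membrane leak |
| `firing_threshold` | 0.5 | potential units | LIF threshold |
| `refractory_time` | 6 | time steps | post-spike silent window |
| `a_plus`, `a_minus` | 0.01 | weight units | STDP amplitudes ("STDP rate") |
| `tau_plus`, `tau_minus` | 10 | time steps | STDP decay constants |
| `iterations` | 1 | passes | unsupervised passes over the whole sample sequence |
| `input_gain` | 1 | potential units | current per input spike |
| `mod`, `alpha` | 0.8, 1 | —, weight units | rank-order geometric code |
| `drift_up`, `drift_down` | 0.005 | weight units/step | post-first-spike drift |
| `k_neighbors`, `sigma` | 1, 1 | —, distance units | readout vote and distance scale |

The defaults are a standard EEG-scale operating point for this model family;
they are deliberately conservative (single training pass, weak plasticity)
and all flow from one `stam_config()` object that serializes losslessly to
YAML/JSON. A single global `seed` fans out to stage seeds as
`(seed × 100 + offset) mod 2³¹` with fixed per-stage offsets (wiring,
splits, generators), so a configured run is reproducible end to end;
unseeded wiring is an error by contract.

## Design decisions in the open corners

Several choices were genuinely open; the package fixes them as follows.

- **θ on normalized signals.** The threshold is interpreted in normalized
  [0, 1] units (normalization on by default) so one θ is comparable across
  variables with different physical scales.
- **Smoothing.** The pre-encoding filter is a centered moving average of
  width `window_size`, clipped at the series boundaries. Boundary windows
  are shorter, so boundary means move more; see the round-trip bound below.
- **Tie rules.** A signal exactly at $B\pm\theta$ emits a spike; simultaneous
  pre/post spikes contribute zero STDP; first-spike ties in the rank-order
  code share ascending ranks broken by neuron index. All three make the
  pipeline deterministic without an RNG.
- **Baseline initialization.** The encoder baseline starts at the first
  filtered value, not at zero, which avoids a spurious burst at onset.
- **Directed connections, no delays.** STDP is asymmetric in pre/post, so
  connections are directed; spikes arrive one step after emission and no
  further synaptic delay is modelled.
- **Inhibition.** A neuron is inhibitory with probability 0.2 (the
  conventional cortical 80/20 split), making all its outgoing weights
  negative. STDP updates magnitudes, so excitatory weights never become
  negative and inhibitory ones never positive.
- **Refractory semantics.** A neuron that fires at $t$ neither integrates
  nor fires for the next `refractory_time` steps (membrane held at reset);
  it is eligible again at $t + \text{refractory} + 1$.
- **Input gain 1.** One input spike reaches the firing threshold (0.5) of
  its mapped neuron, guaranteeing input drive propagates into the reservoir.
- **Training iterations.** "One iteration" means one pass over the whole
  sample sequence, with weights carried across samples.
- **Truncation floors.** A time fraction keeps
  $\max(1, \lfloor f\cdot T\rfloor)$ steps — a recall on 80% of a 128-step
  window uses 102 steps.
- **λ = 2.5 lattice units with cutoff 3.** The probability scale C is 1 and
  the cutoff is three lattice spacings, giving mostly-local connectivity
  with a realized out-degree of a few dozen on unit-spaced grids; λ was
  fixed once at a conventional small-world radius for this family.
- **SNR formula.** The two-class ranking uses
  $|\mu_1-\mu_2|/(\sigma_1+\sigma_2)$ over per-sample time-means (population
  σ), the conventional form for this pipeline; a per-timepoint variant is
  available via `aggregate = "per_timepoint"`. Zero spread with equal means
  gives SNR 0; zero spread with distinct means is guarded to a large finite
  cap (10⁶) instead of ∞.
- **Biomarker profiles.** `connectivity_profile()` expects one cube trained
  per class and averages |weight| over connections whose *both* endpoints
  lie within a radius (default: the wiring cutoff) of each input neuron.
  Profile summaries always use the arithmetic mean; note that in the bundled
  published reference table (`sentence_connectivity_reference()`) the
  negative-sentence row's printed average does not equal the arithmetic mean
  of its values, while the affirmative row's does — the table is shipped
  verbatim and the discrepancy documented rather than hidden.
- **Input mapping.** Variables map to their nearest template neurons,
  greedily in order with collisions pushed to the next-nearest unused
  neuron. The pipeline additionally rescales electrode bounding boxes onto
  the template bounding box (`rescale_inputs = TRUE`) so a small montage
  spreads over the reservoir instead of crowding its centre.

## Numerical behaviour worth knowing

**Encoder round trip.** Decoding tracks the *filtered* signal to within θ at
every point provided the filtered signal never moves more than θ per step
once the baseline has caught up. After [0, 1] normalization and window-5
smoothing, per-step increments are at most 0.25 at the clipped boundaries
and 0.2 in the interior, both below the default θ = 0.5, so the bound holds
unconditionally at the defaults. With a much smaller θ or no smoothing, a
fast signal can outrun the single-spike-per-step code and the bound becomes
approximate.

**Degenerate inputs.** Constant series under normalization map to constant 0
and encode silently (no division by zero). A sample that evokes no reservoir
spikes encodes to the all-zero readout vector; distinct samples can then
collide at distance zero, and the nearest-neighbour tie resolves to the
earliest stored neuron. Relatedly, the smoothing window interacts with
signal frequency: oscillations whose period approaches the window width are
strongly attenuated before thresholding and may encode silently. Keep the
fastest class-relevant rhythm at a period of at least roughly twice the
window.

**Read-only recall.** Evaluation simulates with learning off and never
mutates the fitted object; the test suite asserts this by hashing the model
before and after recall.

## What the synthetic generators emulate — and what they do not

`gen_eeg()` produces 60 samples × 14 channels × 128 steps in 3 balanced
classes by default: a class-specific oscillation (class identity shifts the
frequency by 2·`effect` cycles per window on informative channels), a shared
slow background drift, and white noise, on a two-ring scalp-like montage.
Class information is put in *frequency* rather than mean level because
min–max normalization erases per-series offsets — a mean-coded class would
vanish before encoding. With `effect = 0` the classes are exchangeable by
construction.

`gen_fmri()` produces 40 trials × 200 voxels × 16 volumes spanning 8 s in 2
classes: informative voxels carry a canonical double-gamma
hemodynamic-response shape whose amplitude differs by `effect` between
classes; the rest is white noise; voxels sit on a 3D grid. 200 voxels is a
deliberate desk-scale stand-in for a whole-brain voxel set — the
select-then-classify workflow (SNR ranking, then reservoir training on the
selected voxels) is preserved at a size where every test runs in seconds.

Neither generator models volume conduction/lead fields, 1/f spectra,
artifacts, inter-subject variability, or BOLD physiology beyond the response
shape. Tests passing on these fixtures therefore demonstrate that the
*mechanics* — encoding fidelity, wiring statistics, plasticity arithmetic,
recall degradation, selection recovery — are correct, not that any clinical
accuracy would be attained on real recordings.

## Problem sizes used by the test suite

The packaged checks run the full pipeline at the reference EEG shape
(60 × 14 × 128) on a 7×7×7 reservoir — small enough to finish in seconds on
one core while preserving every structural property — and use 3³–4³ lattices
with about a dozen samples for unit-level checks. The default configuration
ships with an 11×11×11 lattice (1331 neurons), the closest cube to the
~1500-neuron anatomical templates this architecture is usually paired with.
Wiring statistics are validated empirically: over 2000 seeded
initializations of a 3-neuron template, realized connection frequencies stay
within three standard errors of $C e^{-d^2/\lambda^2}$.

## Known limitations

- One output neuron per training sample makes the readout memory grow
  linearly with the training set; there is no merging of similar neurons.
- Recall on very short prefixes (below ~30% of the window) often leaves too
  few spikes for a stable rank-order code; accuracy then approaches chance.
- The grid template is a geometric stand-in: region labels pass through from
  user-supplied coordinate CSVs, but no anatomical atlas is bundled, so
  profile rows are named by variable, not brain area.
- Holdout generalization at the default desk scales is noisy (30 training
  samples); association accuracies are the stable quantities there.
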