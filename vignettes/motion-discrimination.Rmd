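---
title: "Short-term plasticity and motion-direction discrimination: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-term plasticity and motion-direction discrimination: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpmotion)
```

# The model

`stpmotion` simulates direction discrimination in a microcircuit of leaky
integrate-and-fire (LIF) units whose synapses obey the Tsodyks–Markram model
of short-term plasticity (STP). The state of each synapse is the pair
$(u, x)$: $u$ is the running release probability (a proxy for presynaptic
residual calcium) and $x$ the fraction of neurotransmitter resources
available. Between presynaptic spikes

$$\frac{du}{dt} = \frac{U - u}{\tau_f}, \qquad
  \frac{dx}{dt} = \frac{1 - x}{\tau_d},$$

and at each presynaptic spike $u \mathrel{+}= U(1-u)$ followed by the release
of a fraction $u\,x$ of the resources, which is subtracted from $x$. The
synaptic efficacy is the product $u\,x$; it gates the current into
postsynaptic unit $i$,

$$I_i(t) = A \sum_j w_{ij}\, u_j(t)\, x_j(t),$$

over a binary bidirectional connectivity matrix $w$ with self-connections.
Membrane potentials follow
$\tau_m \dot V_i = -(V_i - V_\mathrm{rest}) + R_m I_i$, spike at
$V_i \ge \theta$, reset to $V_\mathrm{rest}$, and stay there for an absolute
refractory period $\tau_\mathrm{arp}$.

The circuit sees the world through an emulated camera: a direction step is a
$6 \times 1000$ binary frame whose row $j$ is delivered to synapse $j$ as an
all-or-none spike train, one spike per black pixel, so a bar of width $b$
columns produces a $b$-ms, 1-kHz presynaptic burst whose onset time is the
bar's horizontal position. External inputs drive the synapses directly; unit
spikes do not re-enter the synapses (a `recurrent_spikes` flag enables that
alternative wiring).

## Why the circuit discriminates direction

In the facilitation-dominated regime used here ($\tau_f = 750$ ms
$\gg \tau_d = 50$ ms) a burst drives $u$ close to 1 regardless of $U$, while
$x$ collapses and then recovers within $\sim 3\tau_d$. After the burst the
efficacy $u\,x \approx u$ relaxes from $\approx 0.93$ back to $U$ with the
slow constant $\tau_f$, so for several hundred milliseconds the efficacy —
and with it the current $R_m A \sum w\, u x$ — *exceeds its resting level*.
The time this post-burst current spends above the firing threshold grows
with $U$. Because each direction step assigns the upper-band $U$ to the
subpopulation whose preferred direction matches the stimulus, that
subpopulation fires longer and faster, and the mean-rate comparison (the
LED readout) recovers the motion direction.

At rest the continuous current $R_m A \cdot 3U \le 14.04$ mV (three
within-subpopulation inputs at $U \le 0.6$) stays just below the 15-mV
threshold distance, so silent inputs never fire the circuit; this is why
`U_max = 0.6` is an upper bound worth respecting rather than a free dial.

Note a consequence of the current being a continuous function of $(u, x)$:
with an all-zero frame the membrane settles at
$V_\mathrm{rest} + R_m A \sum_j w_{ij} U_j$, not at $V_\mathrm{rest}$ — a
constant subthreshold depolarization with no spikes. The alternative reading
(current only at presynaptic spike times) cannot reproduce any firing under
the default parameter tables, because the efficacy collapses within the
first two milliseconds of a 1-kHz burst; the continuous reading is therefore
the one implemented.

# Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `tau_f` | 750 | ms | facilitation recovery (relaxation of $u$ to $U$) |
| `tau_d` | 50 | ms | depression recovery (relaxation of $x$ to 1) |
| `U` | per step | — | resting/initial release probability |
| `A` | 0.039 | — | current gain (doubled to 0.078 in the two-unit circuit) |
| `theta` | −55 | mV | spike threshold |
| `V_rest` | −70 | mV | resting and reset potential |
| `R_m` | 200 | mV/current | membrane resistance scale factor |
| `tau_m` | 30 | ms | membrane time constant |
| `tau_arp` | 2 | ms | absolute refractory period |
| `dt` | 1 | ms | integration step |
| `T` | 1000 | ms | direction-step duration |
| `n_steps` | 200 | — | direction steps (100 right, then 100 left) |
| `bar_width` | 10 | columns (= spikes/step) | width of the moving bar |
| `shift_per_step` | 5 | columns | bar displacement per step |
| `noise_prob` | 0 | — | off-bar pixel flip probability |
| `U_min`, `U_max` | 0.05, 0.6 | — | release-probability schedule bounds |

`R_m` is treated as a plain scale factor: the STP current is dimensionless,
so only the product $R_m A$ is physically meaningful; both are kept
configurable for traceability to the reference tables.

## The release-probability schedule

Each step recruits a pair $(U_1, U_2)$ for the two subpopulations.
`u_schedule()` uses two half-band linear ramps: preferred values run from
$U_{\max}$ down to $c + w/4$ and null values from $U_{\min}$ up to $c - w/4$,
with $c$ the band centre and $w = U_{\max} - U_{\min}$; right steps assign
(preferred, null) and left steps swap the pair. This construction was chosen
over full-range mirrored ramps because it guarantees three properties *at
once and exactly*: the directional mean asymmetry for each subpopulation, an
elementwise preferred-minus-null gap of at least $w/4$ on every single step
(so each step remains individually decidable, not just on average), and the
mirror property — the multiset of $U_1$ over right steps equals the multiset
of $U_2$ over left steps, making the two subpopulation/preferred-direction
release-probability schedules identical. A full-range ramp with a
step-reversed copy satisfies the mirror property but *not* the mean
asymmetry (a reversed ramp has the same mean), which is why it was rejected.

## Choice of stimulus defaults

The bar geometry is not dictated by the model, so the defaults were fixed
once on two grounds. First, the stimulus being emulated is a thin vertical
line: 10 of 1000 columns (1% of the field). Second, the resulting operating
point is the physiologically sensible one: $\sim 15$ spikes/s in the
preferred and $\sim 3.5$ spikes/s in the null direction, the range observed
for direction-selective V1 neurons, with the null response present but weak.
Wider bars (e.g. 50 columns) push the null-direction response up until the
activity windows of the two subpopulations overlap so much that their
spike-count correlation loses its negative sign; the thin-bar regime keeps
the two subpopulations' active epochs nearly disjoint. These defaults are
the package's definition of the standard experiment and are not adjusted per
analysis.

# Numerical choices

* **Integration.** The microcircuit uses forward Euler at `dt = 1` ms for
  both the synaptic variables and the membranes. `stp_simulate_train()`
  additionally offers exact event-driven integration (closed-form
  exponentials between spikes); the test suite verifies that Euler at
  `dt = 0.01` ms agrees with the closed form to within $10^{-3}$ in both
  variables over random spike trains.
* **Within-step order.** Per time step: (1) synaptic relaxation, then spike
  jumps for synapses whose pixel is 1 (so the event-driven limit is
  recovered as `dt` → 0); (2) currents from the just-updated state;
  (3) LIF update. A spike at time $s$ is applied in the step ending at the
  first sample time $\ge s$; a jump exactly at a sample time is applied
  before sampling.
* **Jump ordering at a spike.** The released fraction uses the post-jump
  $u$ (`use_post_jump_u = TRUE`), the standard convention for facilitating
  synapses; the pre-jump reading is available behind the flag because the
  resource-drop term is ambiguous about it.
* **Clamping.** After every update $u$ and $x$ are clamped to $[0, 1]$ to
  absorb floating-point drift; trajectory functions count and report
  clamping events (attribute `n_clamped`). The dynamics themselves preserve
  the bounds, so clamping is a guard, not a correction.
* **Refractoriness.** While refractory the membrane is held at
  $V_\mathrm{rest}$ and the clock decrements by `dt`; integration resumes on
  the step after the clock reaches zero. Consecutive spikes are therefore
  separated by at least $\tau_\mathrm{arp}$.
* **Per-step reset.** Each direction step re-initializes $u = U$ (the
  step's scheduled value), $x = 1$, $V = V_\mathrm{rest}$; this is the
  published protocol (each step "recruits" a new pair of initial release
  probabilities). `carry_over_state = TRUE` preserves state across steps
  instead.
* **Ties.** `decide_direction()` returns `"undecided"` on an exact rate tie
  rather than defaulting to a direction.
* **Zero-variance units.** A silent unit has an undefined Pearson
  correlation; such pairs are excluded from the within/between means and the
  unit indices are reported.
* **SCC concatenation scope.** By default the 1-ms count series of all 200
  steps are concatenated before correlating; `scope = "right"`/`"left"`
  restricts to one direction's steps, since either convention is defensible.

# What the synthetic stimuli do and do not emulate

The generator reproduces the *structure* of the robot's camera pipeline:
binarized frames, the 6 × 1000 reduction (and the 100 × 1000 → 6 × 1000
OR-block reduction in `downsample_camera()`, blocks of 17/17/17/17/16/16
rows), constant spike count per step, discrete per-step bar shifts with
wrap-around at the field edges, and optional uniform salt noise
(`noise_prob`) standing in for luminance fluctuations. It does not emulate
real-world optics: correlated noise (glare, monitor angle), luminance
calibration, RGB capture, or continuous motion within a step. Passing tests
therefore demonstrate the model's behaviour under the idealized stimulus
protocol, not robustness to real camera input; the `noise_prob` axis gives a
first-order handle on the latter.

The experiments are desk-scale by construction — 6 units × 200 steps ×
1000 ms at 1-ms resolution (≈ 1.2 M unit updates, seconds on one CPU) — and
the test suite reuses one cached default run for the experiment-level
checks.

# The two-unit control

`build_two_unit()` gives the fully bidirectionally connected pair with
self-connections. Both units then receive identical summed input
($u_1 x_1 + u_2 x_2$) whenever their external trains are identical, so their
membranes and rasters coincide sample by sample and the spike-count
correlation of the pair is exactly 1: the pair acts as a single
subpopulation and cannot represent two opposing direction preferences. Its
gain is doubled (`gain_scale = 2`, i.e. $A = 0.078$) so that its activity
falls in the same range as the six-unit circuit's — with the single-circuit
gain the two synapses per unit cannot depolarize the membrane by the
required 15 mV at all.

# Known limitations

* Vesicle release is deterministic (the trial-averaged model); stochastic
  release and its trial-to-trial variability are out of scope.
* The LIF/STP update is first-order Euler at 1 ms; the closed-form engine
  covers single synapses only, not the full circuit.
* The between-subpopulation spike-count correlation under the default
  protocol is negative but small in magnitude: with deterministic rasters
  and 1-ms bins its size is limited by coincidence probabilities, so its
  *sign*, not its magnitude, is the meaningful output.
* The six-unit cross-link set defaults to the single reciprocal pair 3–4,
  the minimal connected choice consistent with "more connected within than
  between"; alternative link sets are accepted but their effect on the SCC
  structure is not characterized.
* Rate comparisons use arithmetic subpopulation means over an onset-to-end
  window by default; the onset-skip convention for evoked recordings is
  supported through the `window` argument rather than applied implicitly.
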