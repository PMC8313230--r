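---
title: "Temporal computing with spike-frequency adapting networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal computing with spike-frequency adapting networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

sfanet simulates recurrent networks of discrete-time leaky integrate-and-fire
(LIF) neurons with a step of $\delta t = 1$ ms. Neuron $j$ integrates its
synaptic current $I_j$ with membrane constant $\tau_m$,

$$V_j(t+\delta t) = \alpha V_j(t) + (1-\alpha)\,R_m I_j(t) - v_{th}\,z_j(t)\,\delta t,
\qquad \alpha = e^{-\delta t/\tau_m},$$

spikes ($z_j = 1$) whenever its normalised potential
$(V_j - A_j)/A_j$ is non-negative, is then silenced for an absolute
refractory period of 3–5 ms (the membrane keeps integrating), and is reset by
subtraction of $v_{th}$. The synaptic current is the delayed weighted spike
sum $I_j(t) = \sum_i W^{in}_{ji} x_i(t-1) + \sum_i W^{rec}_{ji} z_i(t-1)$
(all delays 1 ms).

Spike-frequency adaptation (SFA; the GLIF$_2$ mechanism) makes the firing
threshold a second hidden state:

$$A_j(t) = v_{th} + \beta a_j(t), \qquad
a_j(t+\delta t) = \rho_j a_j(t) + (1-\rho_j) z_j(t)\delta t, \qquad
\rho_j = e^{-\delta t/\tau_{a,j}}.$$

Every spike raises the threshold by $\beta(1-\rho_j)$ mV and the increment
decays with $\tau_a$ (hundreds of milliseconds to seconds). Setting
$\beta = 0$ recovers the plain LIF neuron exactly (a tested invariant);
$\beta < 0$ gives the dual enhanced-excitability (ELIF) model in which
spiking transiently *lowers* the threshold. Because sustained firing can
drive an ELIF threshold negative, the batched simulator floors $A$ at
$0.01\,v_{th}$; the scalar `spike_function()` kernel still rejects
non-positive thresholds.

Short-term synaptic plasticity follows the classical utilisation/resource
model: a facilitation trace $u'$ (time constant $F$), utilisation
$u = U + u'$, a depression trace $r'$ (time constant $D$), resources
$r = 1 - r'$, and a momentary efficacy $W^{rec} u r$. The pre-update
utilisation enters both increment terms. Because $U$, $F$, $D$ are shared
per presynaptic neuron, the per-synapse state collapses to a per-presynaptic
state, which the batched simulator exploits. `stp_step()` retains the
general per-synapse form.

## Units and the adaptation-strength convention

All dynamic state is kept in mV and ms. The membrane resistance is fixed at
1 G$\Omega$ and absorbed into the weight units, so it never appears as a
number. Input and recurrent weights are *stored* in volts (initialised
i.i.d. $\mathcal N(0, w_0^2/n_{\text{aff}})$ with $w_0 = 1$ V) and converted
to mV inside the dynamics; readout weights are dimensionless scores. Two
consequences, both deliberate:

* a unit stored weight delivers a $(1-\alpha)\cdot 1000/\sqrt{n}$ mV
  post-synaptic potential, which puts a randomly initialised 60-neuron
  network in an active (tens of Hz) regime that the firing-rate regulariser
  then pulls down to the target rate;
* the published Adam learning-rate schedules (initial rate $10^{-2}$)
  act on weights of order $1/\sqrt{n}$, which is the scale they were
  calibrated for.

Adaptation strengths are quoted in the literature in "mV" but only produce
the described dynamics (visible inter-spike-interval growth under a step
current, threshold excursions comparable to the baseline threshold) when
read as values of order volts: with the trace increment $(1-\rho)$ per
spike, a per-spike threshold jump of order 1 mV requires $\beta \sim 10^3$
mV. sfanet therefore treats $\beta$ as a plain mV quantity and its task
presets use values of order 1000–4000 mV, i.e. per-spike jumps of 1–12 mV.
For the 200 ms-delay STORE-RECALL preset, where no adaptation strength is
published, the default is $\beta = 2500$ mV (jump $\approx 12$ mV): short
time constants need larger increments for the imprint to survive the delay,
and the steady-state threshold elevation $\beta \cdot \text{rate} \cdot
\delta t$ is then comparable across presets.

## Training

`snn()` optimises input, recurrent and readout weights (and the readout
bias) jointly with backpropagation through time. The spike non-linearity is
non-differentiable; its derivative is replaced in the backward pass by the
dampened triangular pseudo-derivative
$\gamma \max(0, 1 - |v_{\text{norm}}|)$ with $\gamma = 0.3$. Everything
else — including the reset term and the threshold dynamics, through which
gradients travel across seconds without touching the dampened spike
derivative more than twice — is differentiated exactly. The refractory gate
carries no gradient. The backward pass is a hand-derived adjoint recursion
implemented in C++; the test suite checks it against an independent
forward-mode tangent-propagation oracle on a small episode to $10^{-6}$
relative error, and verifies the central mechanism directly: across a
500 ms silent gap the gradient of an early input weight is non-zero if and
only if the neuron adapts.

The total loss is

* the task loss, evaluated only in decision windows: summed-per-bit binary
  cross-entropy of window-averaged sigmoid readouts (STORE-RECALL), or mean
  cross-entropy of softmax readouts (taken at the window end for
  duplication/reversal and sequential MNIST, or over window-mean firing
  rates for 12AX);
* plus a firing-rate regulariser
  $c_{reg}\sum_j (\bar r_j - r_{\text{target}})^2$ with the rate averaged
  over batch and episode (coefficients 0.001–15 and targets 10–20 Hz per
  task, as published);
* minus an optional entropy bonus on the sigmoid outputs (coefficient 0.3,
  20-D task). The bonus is *subtracted*, i.e. high output entropy is
  rewarded early in training; its inclusion is stated for the 20-D task
  without a sign, and the subtractive reading is the one that aids
  convergence.

The optimiser is Adam with the original default moments
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$). Schedules
(stepwise decay, the 20-D geometric ramp from $10^{-5}$ to $10^{-2}$ over
200 iterations, early stopping at 1% training error) are part of
`train_config()`. Runs are reproducible bit for bit from the config seed.
Thresholds and time constants are never trained. Networks with STP synapses
can be simulated but not trained: backpropagating through per-synapse
facilitation/depression state would require storing $O(n^2 T)$ history,
and no experiment here needs it.

The readout trace is the unnormalised spike filter
$s(t) = \kappa s(t-1) + z(t)$, $\kappa = e^{-\delta t/\tau_{out}}$
($\tau_{out}$ = 20 ms, or 250 ms for duplication/reversal). With the
area-normalised variant $(1-\kappa)z$ the readout scale is ~20-fold
smaller and the sigmoid readouts cannot reach confident values within the
published 400-iteration schedule; the unnormalised filter is the convention
under which the published schedules behave as described.

## Task generators

All inputs are procedural Poisson population codes (Bernoulli per
millisecond at the population rate); no external data is needed.

**1-D STORE-RECALL** (40 channels: 10 STORE, 10 RECALL, 2×10 value; 50 Hz
active rate). STORE and RECALL activate in alternation with probability
0.09 per presentation step; the value bit is population-coded *during
STORE steps only* and the target at each RECALL is the most recently stored
bit. Two generator choices deserve note. First, episodes are
rejection-sampled to contain at least one complete STORE→RECALL pair, since
an episode without a RECALL carries no loss mask or decision. Second, the
value is presented only with the STORE command: the continuous distractor
stream is a documented feature of the 20-D task, and with a continuous
stream in the 1-D task any network can sit at the ~65% accuracy of a
"report the last seen bit" shortcut, which matches neither the published
LIF nor SFA accuracies; the minimal hand-wired demonstration circuit also
shows value input only during STORE.

**20-D STORE-RECALL** (88 channels: 4 STORE, 4 RECALL, 20 bits × 4 neurons,
2 per binary state; 400 Hz active rate; 10 steps of 200 ms; command
probability 0.2). A fresh 20-bit string is shown at every non-RECALL step;
value channels are silent during RECALL. Generalisation is enforced by
dictionaries: a fixed test dictionary of 20 strings with pairwise Hamming
distance ≥ 5, and per-batch training dictionaries of 40 random strings each
at distance ≥ 5 from every test string (training strings are not
constrained against each other). Dictionary construction is bounded
rejection sampling and errors out rather than looping forever.

**12AX** (8 symbols × 5 one-hot channels; 90 symbols of 500 ms). Episodes
concatenate random realisations of the generating expression
`[12][ABCXYZ]{1,10}((A[CZ]{0,6}X|B[CZ]{0,6}Y)|([ABC][XYZ])){1,2}` — every
choice uniform — truncated at 90 symbols, and are rejected unless they
contain 4–23 digits. The label function (R exactly when a symbol closes the
context-appropriate A…X or B…Y subsequence with only C/Z in between) is
validated against an independent backward-scanning oracle. No
active-population firing rate is published for this task; the default is
50 Hz, configurable.

**Duplication/Reversal** (35 symbols × 5 channels: 31 letters, end-of-string
`*`, prompt `?`, two task cues; active rate 200 Hz against a 2 Hz
background). Slot layout — cue, 5 symbols, EOS, 5 prompts, 500 ms each — is
a configurable default, since it is only shown graphically in the source
material. Targets during the prompt slots are the input string or its
reversal; the headline metric is the episode-level success rate.

**Sequential MNIST encoder.** Images stream pixel-by-pixel (row-wise,
1 ms per pixel); input channel $i$ of 80 owns the threshold $i/81$ and
spikes exactly when the gray value crosses it between consecutive pixels,
in either direction. The first pixel has no predecessor and emits nothing.
Images themselves are not shipped (external dataset); `smnist_task()`
wraps user-supplied arrays.

## Analyses

The **negative-imprinting demo** hand-wires the two-neuron circuit
($\beta(1-\rho) \approx 2.5$ mV per spike, $\tau_a = 1200$ ms,
$v_{th} = 5$ mV, no recurrence): STORE+value coincidence drives the
cross-wired neuron, RECALL drives both, and the stored value is read from
which neuron fires *more* at recall — the one that did not acquire an
imprint. Weights were chosen so that one active input population alone
stays subthreshold (3–6 mV of drive), STORE+value spikes reliably (9 mV),
and RECALL (8 mV) clears the resting but not a freshly imprinted threshold.

**Cross-period decoding** fits an SVM (grid search over
linear/polynomial/RBF kernels and costs 0.1–1000, cross-validated on the
training episodes only) on per-neuron spike counts in one task period and
evaluates on disjoint episodes in the same or a different period. Features
are spike counts because the source analysis names only "network spiking
activity"; labels are the identity of the stored dictionary string.

**Three-way ANOVA categorisation** takes one data point per episode (a
randomly chosen input-period serial position, to keep points independent),
labels it (task × position × symbol; 310 conditions at full scale),
balances conditions by subsampling, discards neurons with mean rates
outside 2–60 Hz, and computes a balanced full-factorial ANOVA for every
neuron at once using the closed-form sums of squares of the balanced
design. The implementation is vectorised across neurons because per-neuron
`aov()` fits on a 41,850 × 310 design for hundreds of neurons are
impractical; `stats::aov` serves as the independent oracle in the test
suite (agreement to $10^{-8}$). Effect sizes use
$\omega^2 = (SS_e - df_e MS_{err})/(SS_{tot} + MS_{err})$; a neuron joins
every category with $p < 0.001$ and $\omega^2 > 0.14$, and its preferred
condition is the triple with the largest Welch $t$ against all remaining
samples at $p < 0.001$.

**Peak sorting** boxcar-smooths trial-averaged rates (50 ms default),
orders neurons by argmax time with ties to the earliest bin, and returns
the peak-normalised matrix.

## Problem sizes and what the tests show

The desk-scale reproduction trains the 60-neuron, 200 ms-delay
STORE-RECALL networks exactly on the published schedule (400 iterations,
batch 64) and evaluates 2048 fresh episodes; one run takes about two
minutes on one CPU. Over three seeds the SFA network reaches 99.3–99.8%
recall accuracy (published: 99.92%). The identically trained LIF-only
network reaches 75–77% (published: 96.7%): its training and test accuracy
coincide, it solves delays up to ~100 ms and sits near chance beyond, and
tripling the schedule lifts it to ~87% — so the shortfall is convergence
speed of the persistent-activity solution, not model capacity. Notably the
published table also reports LIF at chance for every delay ≥ 2 s, so the
96.7% cannot reflect delay-invariant attractor dynamics either; the exact
conditions behind that number are not recoverable from the text, and the
package reports its faithful result instead.

The full 20-D STORE-RECALL, 12AX and duplication/reversal schedules
(thousands to tens of thousands of iterations on networks of 200–500
neurons with multi-second episodes) are shipped as exact
`paper_experiment(..., scale = "paper")` configurations intended for larger
hardware. The test suite runs scaled-down smoke versions (shorter episodes,
smaller networks, hundreds of iterations, minutes each) and asserts
far-above-chance performance: ≥ 60% feature-recall on a 5-step 20-D task
(chance 50%) plus decodability of the stored string from RECALL-period
spike counts, an R-versus-L ranking AUC ≥ 0.7 on short 12AX episodes
(chance 0.5; at this scale the argmax decision can remain at the majority
class even while the ranking is clearly learned), and ≥ 25% per-symbol
accuracy on a 3-symbol, 8-letter duplication/reversal task (chance 12.5%).
Passing smokes demonstrate that the implementations learn the intended
structure, not that they reach the published end-point accuracies; and none
of the synthetic generators model trial-to-trial correlations, neuron
heterogeneity beyond $\tau_a$, or noise sources of biological recordings.

## Numerical choices and degenerate inputs

* Order of operations per step: current → membrane update → spike test →
  reset → adaptation/STP update with the step's spike. The spike test uses
  the pre-reset potential; the stored potential is post-reset.
* The refractory gate clamps both the spike and its pseudo-derivative; the
  membrane and adaptation variables keep evolving.
* Argmax decisions break ties towards the lowest index; peak sorting
  towards the earliest bin.
* Initial state of every episode: $V = a = 0$, STP at its fixed point
  ($u = U$, $r = 1$), no refractoriness — state is reset between episodes.
* The probability inside every cross-entropy is clamped to
  $[10^{-7}, 1-10^{-7}]$.
* Training aborts with a diagnostic on non-finite gradients, and reports
  divergence if the loss exceeds ten times its initial value for 50
  consecutive iterations; the forward pass aborts on a non-finite membrane
  potential.
* The batched simulator requires $\delta t = 1$ ms (the published setting);
  the single-step kernels accept any positive $\delta t$.
* `sample_tau_a()`'s power law is $p(\tau) \propto \tau^{-k}$ truncated to
  `[lower, upper]` with $k = 1$ (log-uniform) by default; the family is
  named in the source material without exponent or cutoff, so both are
  configuration with documented defaults (lower cutoff 1 ms).

## Known limitations

* Training through STP synapse state is unsupported (simulation only).
* The ELIF threshold floor ($0.01 v_{th}$) is a pragmatic guard; the model
  itself does not bound the threshold away from zero.
* Full-scale 12AX and duplication/reversal training is out of reach of a
  single CPU session; only their smoke versions are exercised by tests.
* `encode_smnist()` places thresholds uniformly; data-dependent placements
  are not implemented.
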