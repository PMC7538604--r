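---
title: "An olfactory-bulb attractor pipeline for one-shot odor learning under occlusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An olfactory-bulb attractor pipeline for one-shot odor learning under occlusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulbsim)
```

## The problem

A chemosensor array sampling a natural environment never sees one odor at a
time. Ligands from background sources compete for the same receptors — they
may activate, partially occupy, or block them — so at any moment a large,
unpredictable fraction of the array reports values that have nothing to do
with the source of interest, while plume turbulence modulates the rest.
`bulbsim` models how the circuitry of the mammalian main olfactory bulb
(MOB) can solve this: learn an odor category from a single presentation,
keep learning new odors without damaging old memories, and recognize known
odors when roughly half of the input channels are corrupted.

This vignette is the package's methods account: the model stage by stage,
the parameters that matter and why their defaults are what they are, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations.

## Odor scenes

An odor source is an `OdorSignature`: a point in the unit *N*-cube
("R-space") giving its drive on each of *N* receptor types.
`make_signature()` draws a sparse signature — exactly
`round(sparsity * N)` nonzero entries, each uniform on (0, 1]. Defaults are
*N* = 72 (a typical chemosensor-array size) and sparsity 0.5: odors do not
activate all receptor types. Mixtures are available through `mix_scenes()`
with either additive-saturating agonism or single-site competitive binding
with one global dissociation constant `K`; per-ligand efficacy pharmacology
is deliberately out of scope.

Two degradations model the environment:

* **Bernoulli occlusion** (`apply_bernoulli_occlusion()`): exactly
  `round(fraction * N)` channels, chosen uniformly without replacement, are
  replaced by independent uniform draws on [0, 1]; all other channels are
  returned bit-identical. This is the receptor-competition model: a
  background ligand may drive a receptor high, low, or anywhere between,
  independent of the foreground odor. The study conditions use fractions of
  0.4–0.6, where roughly half the array is lying.
* **Plume noise** (`apply_plume_noise()`): each channel is multiplied by
  `max(0, 1 + g)`, `g ~ N(0, sigma)`, and clipped to [0, 1]. Real plume
  fluctuation statistics are odor- and geometry-specific, so `sigma` is a
  free parameter (experiments here default it to 0) rather than a guessed
  constant; the multiplicative form preserves zeros, which a plume also
  cannot activate.

Occlusion and plume noise are applied on the sensor scale — to the drive
vector, before the concentration gain — so that replacements live on the
same [0, 1] range as the clean channel activities, as they do for a
physical sensor array.

## OSN sampling: extending the dynamic range

A single receptor with Hill cooperativity `n >= 1` spans only
`log10(81) / n` ≈ 1.9 decades of concentration between 10% and 90%
activation. `sample_population()` pools `n_sibling = 30` sibling OSNs whose
EC50s are spaced log-uniformly over `ec50_spread_decades = 4` decades
(deterministic spacing by default for exact reproducibility; a seeded
random variant is available). The pooled dose–response has reduced
effective cooperativity and a measured 10–90% range of ≈ 3.7 decades
(`dynamic_range_log10()`); with zero spread it reduces *exactly* to the
single Hill unit. Four decades is a stand-in: the biological literature
attributes the spread to heterogeneous spare receptor capacity without
quantifying its range, so the span is a configurable parameter, not a
claim.

Because every channel shares the same population binding curve, the
glomerular pattern equals the signature scaled by one concentration-
dependent gain. This factorization is what the next stage exploits.

## Glomerular conditioning

`normalize_columns()` rescales the pattern so its across-column mean equals
`target_mean = 0.25`, which removes the shared concentration gain exactly:
any uniform positive scaling of the input yields an identical output. An
all-zero scene cannot be normalized and is flagged (`blank_scene`) instead.
Values pushed above 1 are hard-clipped with a warning (a ratio-preserving
rescale is available as `clip = "soft"`).

`ntce_transform()` then applies per column
`gain * x − stringency * A * x^m / (x^m + k^m)` with defaults `gain = 1`,
`A = 0.5`, `k = 0.2`, `m = 2`. The saturating inhibition term makes the
response negative on the interval (0.1, 0.4) of normalized input and
positive above 0.4: strongly driven columns fire, moderately driven columns
are inhibited below baseline, weak columns effectively stay silent. On a
similarity series this reproduces the classic chemoreceptive-field profile
— excitation at the preferred odor, below-baseline suppression for its
nearest neighbors (the "surround"), indifference to distant odors
(`surround_profile()`) — with similarity defined in R-space, not by
anatomical adjacency; permuting column order permutes the output and
changes nothing else. `stringency` multiplies `A` and is the
neuromodulatory knob: 0 disables contrast enhancement entirely.

Two gain-control details matter for noise robustness and were the decisive
design choices of this implementation:

* **Peak referencing.** The NTCE partition must judge "weak/moderate vs
  strong" relative to the active ensemble. Mean-normalization alone does
  not achieve this under occlusion: replacing silent channels with random
  values inflates total activity, and the fixed crossover then swallows
  genuinely strong columns. The pipeline therefore divides the normalized
  pattern by its maximum before the nonlinearity
  (`drive_gain = "relative"`, the default). Unoccluded channels are thereby
  restored to their clean effective values, and the excited/suppressed
  partition becomes a function of the activation profile rather than of the
  background level. Disabling this (`"absolute"`) reproduces the fragile
  behavior and is retained only for comparison.
* **Relative phase.** The signed MTC drive is likewise divided by its
  maximum before phase encoding, so spike phases express relative drive.

The ET/PG/sSA microcircuitry that implements normalization and feedforward
inhibition biologically is abstracted to its algorithmic effect; no
glomerular-layer kinetics are simulated, and a presentation is a single
sniff snapshot.

## Phase coding

`encode_phase()` discretizes one gamma cycle into `bins_per_cycle = 8`
phase bins. Drive at or below `spike_threshold = 0.1` (including every
NTCE-suppressed, negative drive) is silent; above it, stronger drive maps
to an earlier bin via `floor((1 − drive)/(1 − θ) · bins)`. Only a minority
of MTCs participate in any one cycle — with the defaults, roughly 15–25 of
72 columns spike on a clean signature. With `mtc_per_column > 1`, column
duplicates read the normalized activation through additive excitability
offsets (total spread `excitability_spread`), sampling the NTCE
nonlinearity at several effective thresholds; the default is a single MTC
per column, which the study conditions did not require exceeding.

## The EPL attractor

`epl_network()` holds the learning machinery. Granule cells are born naive
with heterogeneous coincidence thresholds `k` (uniform on {3..6}) and an
early window covering the first `bins − 1` phase bins; MTC→GC excitation is
topologically unrestricted while each GC inhibits only its home column
(25 GCs per MTC, the anatomical ratio).

**Learning** (`train_one_shot()`) stores a clean phase pattern in one shot:
every naive GC whose window captures at least `k` spiking MTCs commits
permanently to the class; its synapses from those MTCs are potentiated and
all others depressed to zero — the fixed-point consequence of asymmetric
STDP, rather than a continuous kernel the source circuit literature does
not specify. Committed weights are immutable; `neurogenesis_replenish()`
restores the naive pool (constitutive adult neurogenesis), and `bulb_fit()`
does so automatically before each training presentation. Online learning is
therefore structural: nothing that happens later can touch an earlier
memory, which the tests assert bitwise.

**Recall** (`denoise()`) runs the gamma dynamics for
`cycles_per_presentation = 5` cycles. Each cycle:

1. A committed GC fires when at least `k` of its potentiated inputs spike
   *near their stored phases* — within `lag_tolerance = 2` bins on either
   side. STDP potentiated each synapse at the phase its MTC spiked during
   learning, so the receptive field is configural in time; a purely
   spatial count was tried first and had no selectivity at this density
   (every class fired on every cycle).
2. Every firing GC delays, by one bin, spikes in its column that are
   inconsistent with its class signature, and vetoes delays of consistent
   ones. "Consistent" means at the stored bin or up to `lag_tolerance`
   bins later — inhibition can only delay spikes, so a lagged member spike
   is evidence, not noise, while a spike earlier than its stored bin is
   walked back onto it cycle by cycle. Protection wins over delay:
   a learned assembly shields its own members from cross-class inhibition.
   (Winner-take-all and evidence-graded alternatives were evaluated and
   performed worse; the comparison lives in the test history, and the
   protection rule is the package's choice.)
3. Spikes delayed past the last bin fall silent. Spurious spikes thus walk
   off the end of the cycle while the learned pattern is held in place:
   stored signatures are exact fixed points, and the Hamming distance to
   the eventual winner is non-increasing over cycles on ≥ 99% of random
   occluded inputs.

**Readout** (`classify()`): per class, the fraction of MTCs whose
final-cycle state matches the stored signature (silent matching silent;
spikes matching within the lag tolerance). The argmax label is returned if
it reaches `min_similarity = 0.5`, else `UNKNOWN`; ties break to the
lexicographically lowest label. The decision statistic is the package's
own choice — the source literature reports identification without fixing
one.

## Evaluation harness and problem sizes

`run_identification_experiment()` reproduces the headline study at desk
scale: 10 synthetic 72-channel signatures, trained sequentially with one
presentation each, tested under 50% occlusion with 20 independent draws per
odor. An odor is "reliably identified" when ≥ 90% of its draws are correct
(the criterion is a package choice; the literature gives none). With the
defaults, all 10 odors are identified — accuracy 0.99–1.00 depending on
seed — and `run_occlusion_sweep()` over 10–80% holds ≥ 90% overall accuracy
up to 60–70% occlusion. `forgetting_curve()` shows the probe odor's
accuracy exactly unchanged through nine subsequent trainings while an
overwriting mean-template learner decays within two or three; and
`nn_baseline()` (1-NN on raw glomerular patterns) confirms the synthetic
task is information-complete at these noise levels — the interesting claim
is not that the task is solvable but that this circuit solves it online and
one-shot. These sizes (10 odors × 20 draws, 8-point sweeps) keep any single
experiment in the low minutes on one CPU and are the sizes the test suite
runs.

## What the generator does and does not emulate

The synthetic scenes reproduce the statistical skeleton the circuit is
hypothesized to exploit: sparse receptor signatures on the unit cube,
multiplicative concentration scaling through shared ligand-receptor
binding, channel-replacement interference, and multiplicative plume
fluctuation. They do not reproduce: correlated responses of chemically
related sensors (real array channels are far from independent), sensor
drift and decay, temporally structured plume dynamics (noise here is
i.i.d. per presentation), respiratory theta structure, or real mixture
pharmacology beyond the two rules above. Passing the suite therefore shows
that the circuit implements the intended computation under the assumed
statistics — not that a physical array with correlated, drifting sensors
would reach the same numbers.

## Numerical choices and degenerate inputs

* All randomness flows from one integer seed through named substreams
  (`substream_seed()`), so every artifact is exactly reproducible and
  independent draws never share a stream; library code restores the
  caller's RNG state.
* `encode_phase()` adds 1e-9 before `floor()` to keep exact bin boundaries
  (e.g. drive 0.55 with 8 bins) from falling to the lower bin through
  floating-point underflow.
* EC50 spacing is deterministic by default so population curves carry no
  sampling error; `dynamic_range_log10()` measures ranges by monotone
  interpolation on a 4001-point log-grid.
* Degenerate inputs: all-zero scenes are flagged rather than normalized;
  an all-silent phase pattern is absorbing under recall; training a
  duplicate label errors (committed memories are immutable) while `force`
  with an identical pattern is a no-op; an exhausted or unreachable naive
  pool raises a typed condition (`epl_pool_exhausted`) naming the remedy.
* Ties in `classify()` break lexicographically; ties in GC window/threshold
  draws are just repeated values.

## Limitations

The model is an algorithmic abstraction: no membrane dynamics, oscillator
biophysics, or bulb–cortex feedback loop; inhibition is a one-bin delay
operator rather than a conductance; category representations are fixed
points, so within-category variance (generalization gradients, hierarchical
categories) is outside its reach — extending the attractor toward manifold-
like representations would require a richer inhibitory learning rule than
the recruit-and-freeze scheme used here. Recall can delete spurious spikes
but never restore occluded ones, so similarity ceilings degrade gracefully
with occlusion rather than re-completing the pattern. Finally, the
acceptance-scale results are synthetic-scene results; see the section above
for what that does and does not license.
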