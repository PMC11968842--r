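---
title: "Methods: the quiescence-modulation screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the quiescence-modulation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quiescreen)
```

quiescreen asks a single scientific question of brain-wide calcium imaging
data from freely moving *C. elegans*: which neuron classes change their
activity when the animal enters behavioral quiescence, beyond what the
temporal structure of quiescence bouts alone would produce by chance? This
vignette is the package's own account of the statistical model behind that
question, the tunable parameters, the numerical choices, and what the test
suite does and does not establish.

## Behavioral state model

Quiescence is treated as a binary behavioral state detected from three
channels measured at a regular sampling rate: locomotion speed (mm/s), the
derivative of head curvature (rad/s), and pharyngeal pumping rate (Hz). A
time point is *sub-threshold* when

* speed `< speed_max` (default 0.01 mm/s, the measurement noise floor),
* |curvature derivative| `< curvature_deriv_max` (default 0.1 rad/s), and
* pumping `<= pumping_max` (default 0 Hz — comparison is inclusive so an
  exact-zero threshold admits zero pumping),

and a *bout* is a maximal run of sub-threshold points lasting strictly
longer than `min_duration_s` (default 8 s). Points inside shorter
sub-threshold runs are annotated active: brief pauses are not quiescence.
Duration is measured as run length divided by the sampling rate, so the rule
generalizes across acquisition rates; the strict inequality is applied with
a relative guard of 1e-9 against floating-point noise in the rate, which can
never promote a run of exactly the minimum duration.

The curvature channel can be disabled (`bout_criteria(use_curvature =
FALSE)`) for recordings where only speed and pumping are available; the
default includes it.

Two practical complications are handled explicitly. *Missing samples*: runs
of at most 2 missing points take the nearest neighbour's sub-threshold
value; longer gaps are forced active, which splits the recording into
independent segments that no bout can span — mirroring analyses restricted
to usable registration segments. *Multirate acquisition*: behavior cameras
typically run faster than fluorescence volumes (16 Hz vs 4 Hz here), so
`align_annotation()` resamples a bout annotation onto the volume time base
by nearest-neighbour state lookup and then re-applies the minimum-duration
rule at the target rate.

## The quiescence-modulation index

For one neuron in one recording, with fluorescence normalized by its mean
over the usable time points (`normalize_traces()`), the index is

$$\mathrm{QMI} \;=\; \frac{1}{Q}\sum_{q} F_q \;-\; \frac{1}{A}\sum_{a} F_a,$$

the mean normalized fluorescence over the $Q$ time points inside quiescent
bouts minus the mean over the $A$ active time points. Positive values mean
more activity during quiescence. Mean normalization makes the index
invariant to positive rescaling of raw fluorescence (gain, expression
level); inverting the state labels negates it; it is undefined when either
state is empty, in which case the observation is dropped and logged.

Aggregation to *neuron classes* follows anatomical convention: left/right
members of a class are the same functional unit, so their normalized traces
are averaged point-wise into one unit per animal (`merge_lr()`; the
alternative of keeping them as two observations is available via
`merge = "separate"`). Dorsal/ventral members innervate different muscles
and are kept separate. Observations with identification confidence below 3
(on the 1–5 annotation scale) are excluded, and a class is tested only when
it contributes at least `min_observations = 4` units across animals — i.e.
observed more than 3 times.

## The surrogate null

The null hypothesis is not "no structure" but "a trace with exactly this
temporal structure, paired with quiescence bouts with exactly their temporal
structure, at random alignment". It is materialized by a two-state Markov
chain fitted by maximum likelihood to the pooled per-animal binary state
sequences (`fit_markov_chain()`); a hidden Markov model with identity
emissions on a binary observable reduces exactly to this chain, and geometric
sojourn times reproduce the bout/run length statistics of the real behavior.
The stationary distribution has the closed form
$\pi_{\mathrm{quiescent}} = p_{\mathrm{enter}} / (p_{\mathrm{enter}} +
p_{\mathrm{exit}})$ and initializes every synthetic sequence.

Per replicate, **one** synthetic binary vector is drawn per animal and
shared by all classes (`simulate_null_qmis()`): the surrogate is behavioral,
so cross-class dependence within an animal is preserved. Each raw chain draw
is then passed through the same strict minimum-bout-duration rule as the
real behavior — quiescent runs not exceeding 8 s are set active. This step
matters: a real annotation can never contain a 3-second "bout", so leaving
short runs in the surrogate would give the simulated QMIs systematically
heavier tails (replicates with a handful of quiescent points have
high-variance indices) and make the screen conservative. With the filter,
synthetic vectors are bona fide quiescence annotations drawn from the same
structural family as the real ones, and the null p-values are calibrated —
which the packaged calibration study verifies directly.

Each unit's QMI is recomputed against its animal's (filtered) synthetic
vector and averaged within class, giving one simulated mean QMI per class
per replicate; the default is 10,000 replicates. A replicate whose
synthetic vector would leave any unit with zero quiescent or zero active
points — including filtered vectors with no surviving bout, the surrogate
analogue of an animal that displayed no quiescence — is redrawn for that
animal, up to 100 consecutive redraws (beyond that the chain is
pathological and the run errors out naming the animal). The chain fit uses
pseudocount 0 by default: a state that was never observed is reported as a
degenerate fit rather than silently regularized.

## Empirical p-values and their calibration

Each class's real mean QMI is ranked among its simulated mean QMIs:

$$p \;=\; \frac{\max\!\bigl(1,\; \min(\#\{s \ge r\},\, \#\{s \le r\})\bigr)}{n_{\mathrm{sims}}},$$

the smaller tail count (ties inclusive), floored at one count. A real value
more extreme than all 10,000 replicates therefore gets $p = 0.0001$. This
min-tail convention has a consequence worth stating plainly: under a
continuous null the statistic $\min(U, 1-U)$ of a uniform rank $U$ satisfies
$P(p \le t) \approx 2t$, so these p-values are uniform on $(0, \tfrac12]$
rather than $(0,1]$ — anti-conservative by a factor of two relative to a
nominal uniform. Benjamini–Hochberg at level $q$ applied to them therefore
controls the false discovery rate at about $2q$, not $q$. The package keeps
the min-tail rule as the default because it is the one consistent with the
screen's printed extreme-case value; the classical doubled-tail variant is
available (`tail = "doubled"` in `screen_config()`), and the calibration
tests in this package check uniformity of $2p$ and bound the realized false
discovery proportion by $2q$ plus Monte-Carlo error, both derived before any
simulation was run.

Multiple testing uses standard step-up Benjamini–Hochberg (via
`stats::p.adjust`), flagging classes at `fdr = 0.05` by default.

## The synthetic-data generator

`simulate_quiescence_dataset()` emulates the statistical structure the
screen assumes, so every stage is testable without any imaging data:

* **Study conditions as defaults.** 8 animals; fluorescence volumes at 4 Hz
  with behavior 4× faster; 117–176 segmented neurons per animal of which
  40–121 are identified against a synthetic class catalog (60% of classes
  L/R paired, 12% with D/V variants); identification confidence drawn with
  probabilities (0.05, 0.10, 0.15, 0.30, 0.40) for scores 1–5, so roughly
  85% of identifications survive the confidence filter.
* **Bout structure.** The latent state is a two-state Markov chain at the
  volume rate with `p_enter = 0.01`, `p_exit = 0.02` per step: mean active
  runs of 25 s, mean quiescent bouts of 12.5 s, stationary quiescent
  fraction 1/3. The study does not print its transition rates; these values
  were chosen once as realistic for infected animals that switch frequently
  while staying under the quality-control ceiling of half the recording
  quiescent, and are not revisited.
* **Subject selection.** Imaging subjects are animals that displayed
  quiescence during the recording, and animals quiescent for more than half
  of it are discarded for registration quality. The generator applies the
  same two rules: a drawn animal with no annotated bout (`min_bouts = 1`)
  or with quiescent fraction above `max_quiescent_fraction = 0.5` is
  redrawn (bounded). Both rules can be disabled.
* **Channels.** Behavior channels are written strictly sub-threshold on
  latent quiescent steps and supra-threshold (speed always) on active
  steps, so the ground-truth annotation is *exactly* what
  `detect_quiescence_bouts()` + `align_annotation()` recover — generation
  and detection are inverse by construction, which the tests verify.
* **Neural traces.** A neuron of a class with effect size $d$ has raw trace
  $B\,(1 + d\,s_t) + \varepsilon_t$, $\varepsilon_t \sim N(0,
  \sigma^2)$, truncated at 0 because fluorescence is non-negative; $s_t$ is
  the *bout-filtered* ground-truth state, so the injected modulation is
  precisely what the QMI measures. Noise-free, the expected QMI after mean
  normalization is $d / (1 + d \bar s)$ — the closed form the recovery
  tests compare against. Default `noise_sd = 0.05` on `baseline_mean = 1`.
  The default effect map is empty (a pure null); effect sizes are free
  parameters, not estimates, because the amplitude distribution of real
  modulated neurons is unknown.
* **Seeding.** One root seed expands deterministically into per-animal,
  per-purpose streams (`state`, `channels`, `labels`, `traces`), so adding
  an animal never perturbs another's data, and the null-simulation streams
  follow a documented per-animal contract that an independent script can
  reproduce exactly.

What the generator does **not** emulate: image formation, segmentation and
registration errors (traces arrive clean), identification mistakes (labels
are correct by construction, only confidence varies), photobleaching or
motion artifacts, non-Gaussian fluorescence noise, and any correlation
between neurons beyond the shared behavioral state. Passing tests therefore
establish that the *statistics* are implemented and calibrated correctly,
not that the pipeline is robust to real-world imaging pathology.

## Numerical and design choices

* Intervals are half-open, 0-based sample index pairs `[start, end)`
  everywhere, so `end - start` is the sample count and durations are exact.
* Timestamps must be regular within a relative tolerance of 1e-3 of the
  median interval; anything worse is rejected with the offending rows named
  rather than silently resampled.
* The event-triggered average uses the sample (n−1) standard deviation
  across events, reporting 0 for a single event; partial windows are
  dropped and logged, and per-animal event sets are pooled with a proper
  pooled-variance combination.
* Bootstrap intervals for assay fractions are percentile intervals with
  resample size equal to the sample size (10,000 resamples by default);
  resampling is over animals, with plate-level resampling as an option,
  since the original unit of resampling is not stated. Chi-square
  comparisons default to no continuity correction, with Yates correction
  behind a flag, and Bonferroni adjustment multiplies by the stated family
  size, capped at 1.
* `empirical_pvalue` counts ties into both tails, the only choice that
  makes the degenerate all-ties case return exactly 1.

## Problem sizes used by the test suite

The packaged calibration studies run at sizes chosen to make the
Monte-Carlo answer decisive while keeping the suite quick to run on one
core: 480 time points per animal (2 min at 4 Hz), 1,000 surrogate
replicates per screen, 20 seeded pure-null screens for the calibration
check, 50 seeded runs for the effect-recovery study (effect 0.3 in 5 of 120
classes), and 10^5-step sequences for the Markov round-trip. The
full-scale defaults (8-min recordings, 10,000 replicates) are exercised
end-to-end by the acceptance script's p-value floor computation.

## Known limitations

* The screen tests classes, not individual neurons; a class with
  heterogeneous members can average away real modulation.
* The pooled Markov fit assumes animals share bout statistics; a per-animal
  fit is available but leaves short recordings with noisy estimates.
* The min-tail p-value's factor-two anti-conservatism is inherent to the
  chosen convention (see above); users who need nominal FDR control should
  either use `tail = "doubled"` or halve the FDR level.
* Mean normalization is the only trace preprocessing; slow drift or
  bleaching will leak into the QMI if present in the input.
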