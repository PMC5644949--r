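---
title: "Quantifying sleep homeostasis: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sleep homeostasis: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnostat)
```

somnostat quantifies homeostatic sleep need from epoch-scored sleep
recordings and relates it to imaging and behavioral markers. This
vignette explains the models behind the package, the tunable parameters
and why their defaults are what they are, what the bundled synthetic-data
generator does and does not emulate, and the numerical conventions that
matter when comparing outputs across laboratories.

## The quantification chain

The canonical electrophysiological marker of sleep pressure is EEG
delta power (slow-wave activity) in NREM sleep: it is high after
extended wakefulness and dissipates across sleep. The package implements
the full chain from scored recordings to that marker and its
correlates:

1. **Hypnograms** — vigilance states scored in fixed epochs (4 s for
   mouse WAKE/NREM/REM; 20 s for human W/N1/N2/N3/REM), with artifact
   flags and zeitgeber timestamps (ZT0 = light onset).
2. **Spectra** — one power spectral density per epoch at 0.25 Hz
   resolution, either supplied directly or computed from epoched EEG
   with `compute_psd()` (single Hann taper per 4-s epoch, one-sided,
   no within-epoch averaging — this matches the 0.25 Hz resolution
   exactly; Welch-style averaging within an epoch would change the
   bias/variance trade-off and is deliberately not offered).
3. **State bookkeeping** — `time_in_state_per_hour()`,
   `accumulated_difference()` (the cumulative recovery-minus-baseline
   rebound curves), `stage1_percentage()`, `first_nrem_episode()`.
4. **Spectral markers** — `band_power()`, `total_power_reference()`,
   `delta_timecourse()`, `first_episode_markers()`.
5. **Imaging and behavior** — `dv_norm()` PET availability ratios with
   `global_availability()`, CRLB-gated MRS tables (`crlb_filter()`),
   Y-maze alternation and habituation scores.
6. **Inference** — Spearman/Pearson correlation pairs, Bonferroni and
   Holm multiplicity control, paired t tests, median splits, and a thin
   repeated-measures ANOVA contract (`stats::aov`) used to gate
   post-hoc tests.

## Vigilance-state-weighted normalization

Absolute EEG power differs between animals for reasons unrelated to
sleep (electrode impedance, skull geometry). The package therefore
normalizes state-specific power by a per-animal **total power
reference**: the area under the baseline PSD curve (0.75–49 Hz by
default) is computed per vigilance state over artifact-free,
non-transition epochs, each state's area is weighted by that state's
share of contributing epochs in baseline, and the weighted areas are
summed. Dividing state-specific power by this reference yields
dimensionless relative power. Two conventions matter and are fixed:

* **Transition epochs** (epochs whose neighbours differ in state) are
  excluded from all state-specific spectral statistics — their EEG is a
  mixture of states. `mark_transition_epochs()` returns the stable-epoch
  mask; the first and last epochs are always unusable.
* **Band edges** are closed on both sides (bin centers with
  `lo <= f <= hi` are included) and band power integrates PSD × the
  0.25 Hz bin width. A plain bin sum differs only by the constant 0.25,
  which cancels in every normalized quantity.

The identity `sum(normalized state area × state fraction) = 1` holds on
the baseline used to build the reference by construction and is
enforced in the test suite to 1e-9.

## The equal-epoch delta-power time course

Because NREM sleep is unevenly distributed across the light:dark cycle,
averaging delta power in fixed clock-time bins would mix intervals with
very different epoch counts. `delta_timecourse()` instead subdivides
each recording segment into intervals containing **equal numbers of
clean NREM epochs**: 12 intervals per 12-h light phase, 6 per dark
phase, and 8 for the 6-h post-deprivation light phase (more intervals
where the dynamics of interest are fastest). Within a segment, interval
counts differ by at most one; the remainder epochs are assigned to the
earliest intervals — a deterministic, order-preserving rule. Each
interval is plotted at the mean ZT of its contributing epochs, and its
value is expressed as a percentage of the baseline reference: the mean
delta power of clean NREM epochs with ZT in [8, 12) — the late light
phase, where delta power is lowest — averaged over the two baseline
days with equal weight per day.

Whether the PSD "area" for the reference should run to 49 or 100 Hz is
not standardized across laboratories; the default is 0.75–49 Hz
(`somnostat_config()$psd_area_band`), and the choice is configurable.
Normalized quantities are insensitive to it in practice.

Outlier screening (`detect_outlier_recordings()`) flags animals whose
summary value deviates from the group mean by more than 2 SD, with mean
and SD taken over all animals in a single pass. Note that a single-pass
rule cannot flag anything in very small groups (the largest attainable
z with n animals is `(n-1)/sqrt(n)`, i.e. < 2 for n ≤ 5); it behaves
sensibly at the cohort sizes (n ≈ 8) it is meant for.

## Process S and the synthetic generator

The generator exists so that every analysis stage can be tested against
known ground truth. It is deliberately phenomenological:

* **Architecture**: sleep-wake sequences are a first-order Markov chain
  over WAKE/NREM/REM at the 4-s epoch level, with one transition matrix
  per lighting phase. Direct WAKE→REM transitions are disabled by
  default (they are physiologically anomalous in healthy rodents) but
  the matrices are user-settable. The default protocol is 48 h
  baseline, 6 h sleep deprivation from light onset of day 3 (all epochs
  forced to WAKE), and 18 h recovery. The paper-scale phenotypes are
  expressed as presets: the wild-type preset raises sleep propensity
  throughout recovery (net sleep gain ≈ +85 min by the end of
  recovery), the knock-out preset shows the light-phase rebound but
  suppresses sleep in the recovery dark phase (net loss ≈ −30 min);
  heterozygotes are intermediate. Stationary distributions of the
  default matrices give roughly 40/50/10 % W/N/R in the light phase
  and 75/21/4 % in the dark, with bout lengths of a few minutes —
  plausible values, since bout-length statistics are rarely reported
  and were not fitted to any specific dataset.
* **Pressure**: the classical two-process Process S — exponential
  build-up towards an upper asymptote during WAKE and REM (time
  constant `tau_i`) and exponential decay towards a lower asymptote in
  NREM (`tau_d`). Defaults `tau_i` = 8 h and `tau_d` = 2 h sit in the
  range estimated for inbred mouse strains; asymptotes 280 % and 60 %
  of the baseline reference bracket the observed dynamic range of
  normalized delta power. The per-epoch update is implemented in closed
  form over runs of constant state, which is algebraically identical to
  the epoch-by-epoch iteration and fast enough to sit inside an
  optimizer loop.
* **Emission**: each epoch receives its state's template spectrum; NREM
  delta-band bins are scaled by S/100, and every epoch is multiplied by
  a mean-one log-normal factor `exp(sigma·Z − sigma²/2)` (power is
  positive, so multiplicative log-normal noise is the natural model;
  the mean-one construction keeps expected delta power exactly
  proportional to S). Artifacts are i.i.d. flags at a 2 % default rate.
* **Seeds**: every generator is a pure function of (parameters, seed);
  one master seed spawns deterministic per-stream child seeds, so a
  change in one stream never perturbs another.

`fit_sleep_pressure()` inverts the chain: it simulates S along the
known hypnogram for candidate parameters, pushes the trajectory through
the identical interval-binning and normalization, and minimizes the
squared distance to the observed time course. Because the time course
is self-normalized, the absolute pressure scale is unidentifiable; the
upper asymptote is fixed at 100 and `la_frac`, `s0_frac` are estimated
as fractions. On noise-free simulations the time constants are
recovered to within a fraction of a percent; at emission noise
sigma = 0.2 the 20-seed median error stays under 10 %.

The human cohort generator plants (i) a global availability increase
(default +0.05 on a baseline DV_norm of 1.51, ≈ +3.3 %) and (ii) a rank
correlation `rho` between global availability and first-episode
slow-wave activity. `rho` is defined on the Spearman scale: the latent
normal factors receive Pearson correlation `2·sin(pi·rho/6)`, the
bivariate-normal value whose population Spearman equals `rho`, so the
planted value is directly recoverable by the rank-based inference the
package uses. Recovery is assessed with the Fisher-z interval using the
Bonett–Wright standard error `sqrt((1 + r²/2)/(n − 3))`, which accounts
for the larger sampling variance of the rank correlation.

**What the generator does not emulate:** circadian modulation beyond
the binary light/dark switch; REM-sleep homeostasis; spectral
signatures of sleep deprivation outside the delta band; scanner- or
session-level covariance in the imaging tables; and any mechanistic
link between the Markov architecture and Process S (in the generator,
state sequences drive pressure but pressure does not feed back on state
probabilities — real animals show such feedback). Passing tests on
synthetic data therefore demonstrate correctness of the quantification
chain, not validity of the generator as a model of biology.

## Inference conventions

* **Correlations**: Spearman with average ranks for ties is primary;
  Pearson is reported alongside. p-values are exact permutation values
  below n = 10 (without ties) and t/AS89 approximations otherwise.
* **Multiplicity**: the regional correlation family (9 regions × 2
  conditions = 18 tests) is gated at `alpha/18` = 0.00278; metabolite
  and post-hoc t-test families use Holm's step-down adjustment.
* **Median split**: subjects at or below the median go to the low
  group. The convention is arbitrary but must be fixed; group sizes are
  attached so ties straddling the median are visible.
* **Paired t on EEG power** is offered on log10-transformed values, the
  scale on which EEG power is approximately normal. No automatic
  normality-test-then-transform search is performed: only the
  documented log10 option exists, which keeps the analysis path
  deterministic.
* **RM-ANOVA** is a deliberately thin wrapper over `stats::aov` with an
  `Error(subject)` stratum — it exists to gate post-hoc tests, not to
  be a general mixed-model engine. Sphericity correction is off;
  effects with zero sum of squares report F = 0 rather than 0/0.
* **First NREM episode**: the episode starts at the first NREM run
  reaching 15 min and ends at the onset of the first REM episode of at
  least 5 min (standard NREM-REM cycle conventions). Both thresholds
  are exposed because absolute first-episode power depends on them.
* **Artifact policy**: artifact epochs are excluded from spectral
  statistics everywhere; for state *durations* the exclusion is applied
  too by default (internal consistency), but `exclude_artifacts =
  FALSE` restores wall-clock bookkeeping.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything at full
protocol scale: 72-h recordings of 64,800 4-s epochs with 196-bin
spectra generate in a few seconds, and a complete
simulate–analyze–refit cycle takes well under a minute on one CPU.
Cohort-level checks use the emulated study sizes (23 imaging subjects;
8 mice per genotype) with 20-seed or 200-replicate Monte Carlo designs.
`scripts/acceptance.R --seed N --out file.json` re-derives the headline
quantities from scratch at any seed; identical seeds give byte-identical
simulated tables.

## Known limitations

* EDF/proprietary polysomnography containers are not read; recordings
  arrive as the generic hypnogram/spectra tables documented in the I/O
  functions (storage formats of commercial scoring software vary and
  are rarely archival).
* PET inputs are pre-extracted ROI activity concentrations; no
  image-space processing is performed. "Global" availability from a
  region table is the unweighted mean of the 18 regional ratios unless
  a whole-brain VOI row is supplied — the two definitions differ
  slightly and the one used is recorded on the result.
* MRS concentrations are consumed as fitted estimates with CRLBs;
  spectral fitting, water referencing, and tissue correction happen
  upstream.
* The pressure fit assumes the hypnogram that generated the time
  course is available and trustworthy; scoring errors propagate into
  the time constants.
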