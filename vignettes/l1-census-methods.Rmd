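---
title: "Methods: classifying and quantifying layer-1 interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and quantifying layer-1 interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1census)
```

Neocortical layer 1 (L1) is populated exclusively by GABAergic interneurons.
`l1census` implements the quantitative analyses used to take a census of these
cells: a firing-pattern classifier built on inter-spike-interval (ISI)
regression, a 44-feature morphometric battery over SWC reconstructions with
supervised and unsupervised cluster validation, IPSP and gap-junction analysis
of paired recordings with GABA-receptor-type classification, and circuit-level
connection statistics. Because no raw recordings are publicly deposited for
this preparation, the package also ships seeded generators that synthesize
every input with known ground truth; the test suite exercises the full
pipeline as parameter-recovery experiments.

## Firing-pattern (e-type) classification

For each cell the ISIs of a step-evoked spike train are regressed against
their position in the train (ordinary least squares of `ISI ~ index`). Two
statistics drive a fixed decision tree:

* **RMS error** of the regression (root mean square of residuals, ms). A poor
  fit (RMS > 30 ms) marks the stuttering/irregular group: stuttering (cSTUT)
  if the train contains at least one *silent period* — an ISI strictly longer
  than 100 ms — otherwise irregular (cIR).
* **Slope** (ms per AP index) for well-fit trains: a slope of at least
  1 marks accommodation (cAC), smaller slopes non-accommodation (cNAC).

Bursting (bNAC) is tested before the slope, because a burst is defined
independently of accommodation and its short ISIs would otherwise corrupt the
interpretation of the fit: a train opening with four rapid spikes whose first
three ISIs average strictly less than 25 ms is a `burst4` subtype; otherwise a
first ISI of at most 25 ms is a `doublet`. The regression is still computed on
all ISIs, including the burst. All thresholds (`rms_threshold = 30`,
`slope_threshold = 1`, `gap_threshold = 100` ms, the 25 ms burst bounds) are
arguments of `classify_etype()` with these defaults.

The "sum of the RMS error" wording in the source protocol is ambiguous for
multi-sweep data; we interpret it as the RMS of residuals of one
representative sweep, which makes the statistic directly comparable to the
reported per-class means (approximately 29 and 20 ms for the two well-fit
classes, 339 and 46 ms for the stuttering/irregular group).

```{r etype}
tr <- generate_spike_response(etype_gen_defaults("cSTUT", seed = 1))
classify_etype(detect_spikes(tr))
```

### Spike detection and AP features

Spike detection is a dV/dt threshold (default 20 mV/ms) with a minimum peak
voltage (-10 mV) and a 2 ms refractory merge; the protocol source does not
specify a detection method, so these are standard conventions, configurable.
AP amplitude is measured threshold-to-peak; rise and fall times between the
20% and 80% amplitude crossings (the same kinetic convention the source states
for synaptic potentials); "duration" is the full width at the threshold
voltage; the fast AHP is threshold voltage minus the post-spike minimum.
Passive properties come from hyperpolarizing steps (peak and steady-state
input resistance, with the steady state defined as the last 20% of the step)
and from a single-exponential fit to a delta-pulse decay. The rheobase is the
smallest step amplitude of a calibration family that elicits at least one
spike.

### The spike-train generator

Synthetic voltage responses place an analytic spike template — a
difference-of-exponentials upstroke/downstroke whose full width at half
maximum is calibrated by root finding, plus a slower
difference-of-exponentials after-hyperpolarization — at spike times realized
from per-type ISI models (`etype_gen_defaults()`):

| type | ISI model |
|---|---|
| cAC | base 30 ms, slope 2.5 ms/AP, jitter SD 2 ms |
| cNAC | base 35 ms, slope 0.1, jitter 2.5 ms |
| bNAC (burst4) | initial ISIs 8/9/10 ms, then cNAC-like at 40 ms |
| bNAC (doublet) | first ISI 15 ms, then cNAC-like |
| cSTUT | spiking ISIs ~38 ms, two silent periods ~190 ms |
| cIR | bimodal mixture of short (8-18 ms) and long (80-98 ms) ISIs |

The cSTUT values follow the reported class statistics (mean silent period
about 193 ms over ~38 ms spiking ISIs). For cIR a truncated log-normal cannot
simultaneously keep every gap under the 100 ms stutter bound and push the
regression RMS reliably above the 30 ms threshold, so the generator uses a
bimodal short/long mixture instead: it is irregular (CV > 0.6), never opens
with a doublet, and yields RMS well above threshold. The default spike
template is 80 mV threshold-to-peak (an overshooting spike from a -65 mV
baseline), 2 ms half-width, 12 mV AHP. Sweeps are 2 s at 10 kHz; the source
states sampling rates of 5-10 kHz but no sweep duration, so the duration is a
configurable default.

The round-trip property — classify the trace of every generated type back to
its label — holds for at least 95% of 200 seeded cells (measured ~99%).

## Morphometrics

Reconstructions are standard SWC trees (soma = 1, axon = 2, dendrite = 3)
with y pointing from white matter toward the pia. Slice shrinkage is
corrected by rescaling z from the measured post-processing thickness back to
the original 300 um; in-plane shrinkage (0-10%) is not corrected.

Arbors decompose into *segments* between branch points, with centrifugal
branch order starting at 1 for the trunk. Conventions worth stating because
the upstream definitions are proprietary and unpublished:

* Arbor cable is the set of edges whose both endpoints lie in the arbor; the
  soma-attachment edge is not counted as neurite length.
* Tortuosity of a segment is path length over end-to-end chord; the cell value
  is the unweighted mean over segments.
* Spatial moments are length-weighted: the first moment is the centroid offset
  from the soma per axis, the second the length-weighted SD per axis, both
  computed from exact per-edge closed forms (tested against a 0.1 um
  discretization oracle).
* **Density** is total arbor length divided by the volume of the axis-aligned
  bounding box of the arbor (with an area fallback, flagged, when the box is
  degenerate). A convex-hull volume would also be defensible; the box is
  deterministic, cheap, robust to collinear point sets, and differs from the
  hull only by a shape factor. No formula is published for this feature, so
  this is a documented package convention, not a compatibility claim.
* Branch angles per bifurcation: *local* (between first child points),
  *maximum* (between full daughter chords), *planar* (between the chords
  projected onto the least-squares plane through both daughters — for
  straight daughters this equals the 3D chord angle), and *local-spline*
  (directions smoothed over the first five points). Trifurcations take the
  pairwise maximum. Cells average over bifurcations before any cross-cell
  statistics.

`compute_feature_vector()` emits the canonical 44-feature battery (soma
cross-section, 22 dendritic and 21 axonal features; see
`morphometric_feature_names()`), plus branch-angle means and, when bouton
markers are supplied, bouton density (markers per um of axon). Every feature
is tested against an independent naive re-traversal oracle on random trees,
and the battery obeys the expected invariances (translation, uniform scaling,
90-degree rotation swapping H and V).

### The morphology generator

Each class (`mtype_gen_defaults()`) grows dendritic and axonal arbors as
branching trees of segments whose path lengths are Gamma-distributed around
the class mean and whose tortuosity is imposed exactly, per segment, by a
calibrated sinusoidal displacement around a straight chord. Growth is
confined to a class-specific bounding box matching the reported extents
(e.g. HAC axon 826 x 202 um; DAC axon reaching 602 um vertically); directions
bounce off the walls at segment granularity, so per-segment tortuosity is
unaffected. Axon trunks leave the soma in alternating horizontal directions
with a small outward drift — L1 axons elongate within the layer — and
segments of order <= 3 always bifurcate so the branching process cannot go
extinct at the trunk; beyond that, bifurcation is Bernoulli per segment end
up to the class's maximum order. DAC cells additionally grow a straight
collateral descending past 100 um below the soma. Generated class means are
recovered by the morphometry module within 15% (extents), 20% (segment
lengths) and 10% (tortuosity); the recovery tests use 12 seeds per class.

What the generator does *not* emulate: somatic contours (somas are single
spheres sized to the class cross-section), diameter tapering, boutons,
spines, and any correlation structure between features beyond what the box
and branching parameters induce. Passing recovery tests therefore show that
the *measurement* pipeline is correct, not that the generator reproduces
biological covariation.

## Cluster validation of the morphological classes

`znormalize()` z-scores each feature (constant features are dropped with a
warning). `flag_outliers()` marks any cell with a |z| above 2 SD and reports
the offending features. `feature_power()` rates features by the one-way
between-class share of total sum of squares (eta squared, `var_ratio`)
alongside the pooled within-class variance; the source's "Variance"/"Var
ratio" columns are undefined there, so these definitions are documented
conventions. The two high-CV tortuosity features are dropped by default
(`drop_features()`) before normalization. `run_pca()` wraps `prcomp`;
`run_lda()` is Fisher LDA via `MASS::lda`, with an in-package
ridge-regularized path when the within-class scatter is singular.

`crossvalidate_randomized()` implements the overfitting control: ten rounds
of stratified ten-fold cross-validation on the actual labels, and the same
design on ten label-shuffled replicates. Two comparisons are reported:

* the Welch two-sample t-test of actual versus pooled randomized fold scores
  (`t_statistic`, `p_value_pooled`) — the published procedure. Fold scores
  within a design are *not* independent (they share one label assignment),
  and we measured this comparison rejecting on more than half of pure-noise
  datasets at nominal 5%; it is kept for descriptive comparability.
* the primary `p_value`: a calibrated randomization test referring the actual
  mean CV accuracy to the distribution of per-randomization mean accuracies
  via a one-sample t statistic (J - 1 degrees of freedom, one-sided). Under
  label-free data the actual labeling is exchangeable with the shuffles, so
  the test holds its nominal level (measured 2/100 rejections at 5%), while
  separated classes give vanishingly small p-values.

`lda_group_study()` reruns the validation under class-grouping scenarios
(dropping a class, merging the two neurogliaform classes), mirroring how the
robustness of the six-class scheme is probed.

## Synaptic physiology

Paired recordings hold the postsynaptic cell near -57 mV to increase the
chloride driving force (E_Cl ~ -69 mV from the solutions used).
`average_sweeps()` forms the baseline-subtracted mean trace;
`extract_ipsp()` measures amplitude peak-to-peak (baseline to deepest
trough), 20-80% rise on the onset flank, 80-20% decay on the recovery flank,
width at half amplitude, onset at the 5% crossing, latency from the last
presynaptic spike at or before onset, CV as sample SD over mean of per-sweep
amplitudes, and the deflection integral (charge). Detection requires the
trough to exceed a noise floor of five baseline SDs of the mean trace
(floored at 0.05 mV): the statistic is a maximum over the whole post-stimulus
window, so a 3-sigma bound would fire on pure noise.

`classify_receptor()` encodes the receptor logic: a single-AP response with
rise below 60 ms indicates GABA-A; absence of a single-AP response with a
train-evoked slow-rise response indicates GABA-B (such connections require
trains at a minimum frequency, 40 Hz); a fast single-AP response *plus* an
excess slow component in the train response indicates GABA-A+B. The slow
component is detected by a charge ratio — the train integral compared with
the linear prediction of `n_spikes` times the single-AP integral, declaring a
slow component when the excess is at least 20% of the total — because the
compound fast response dominates the 20-80% decay window and defeats a
decay-time comparison.

`fit_rise_time_mixture()` is an in-package EM fit of a two-component normal
mixture (median-split initialization, non-decreasing log-likelihood by
construction, likelihood-ratio statistic against the single-Gaussian fit),
used for the bimodal rise-time histogram. `measure_rundown()` fits geometric
amplitude decay per repetition on the log scale; perforated-patch recordings
are expected near ratio 1 (no rundown). `coupling_coefficient()` and
`gj_analyze()` measure electrical coupling from hyperpolarizing steps as the
post/pre steady-state deflection ratio, bidirectionally, with a Welch test
for symmetry. `pharmacology_account()` decomposes block-sequence amplitudes
(baseline, GABA-A antagonist, plus GABA-B antagonist, washout) into fast and
slow components, residual and recovery fraction.

### The connection generator

The fast component is a biexponential kernel (rise 5 ms, decay 40 ms, 2 mV)
per presynaptic spike. The slow component is a minimal metabotropic cascade:
spikes feed a transmitter pool decaying with tau 80 ms; the pool gates a slow
conductance through a 4-site cooperative Hill function whose half-activation
sits just below the pool level a sustained 40 Hz train reaches, so single
spikes produce responses below the detection floor while 40 Hz trains open
the gate; the gate is convolved with a slow kernel (rise 80 ms, decay 300 ms,
onset delay 15 ms), giving the sigmoidal rise and slow decay characteristic
of GABA-B responses. Sub-threshold drive (e.g. 20 Hz) produces a partially
activated, small response rather than a hard zero — the threshold is a
cooperativity effect, not a switch. Whole-cell rundown scales repetition k by
(1 - rate)^(k-1), with rate 0.1 by default; perforated-patch specs force rate
0. Sweeps end 1.5 s after the last spike (a configurable default; the source
protocol specifies a recovery pulse 500 ms after the train but no sweep
duration).

## Circuit statistics

`connection_probability()` is the exact count ratio with a Clopper-Pearson
95% interval, with a directed mode (each ordered direction of a pair is one
test — 248 connections over 2 x 1568 ordered tests reproduces the reported
7.9%) and an undirected mode for gap junctions (82/1568 = 5.2%).
`crosstab_me_types()` joins the two classifications on cell id and reports
counts, exact fractions and the modal morpho-electrical type.
`detect_appositions()` marks putative synaptic contacts where a presynaptic
axon point lies within 3 um (3D) of a postsynaptic soma or dendrite point
with |dz| <= 1 um — the "same focal plane" criterion is qualitative, so these
thresholds are configurable defaults — deduplicates contacts within 2 um,
and reports somatic/dendritic fractions. `nernst()` computes reversal
potentials from the solution recipes (every divalent-cation chloride salt
contributes two chloride ions). `build_report()` and `run_l1_demo()` bundle
the stages into a reproducible JSON report.

```{r demo, eval = FALSE}
report <- run_l1_demo(seed = 1, out = "l1_report.json")
print(report)
```

## Numerical choices and limitations

* Sample (n-1) standard deviations throughout; ties in the cross-tabulation's
  modal type resolve to the first in row-major order.
* Problem sizes in the test suite: 200 cells for the firing-type round trip,
  12 seeds per class for morphometric recovery, 20 random trees for the
  feature oracle, 100 pure-noise datasets for the validation-test level,
  200 populations of 1568 pairs for interval coverage.
* The generators are statistical stand-ins, not biophysics: no conductance
  or cable modelling, no network simulation, no reconstruction from image
  stacks. Agreement on synthetic data validates the estimators and decision
  rules, not the biological claims.
* Printed group sizes in the source material are internally inconsistent in
  places (e.g. e-type counts summing to 99 against a reported 98, 31 + 110
  connections against a reported 142); the package reports raw counts and
  exact ratios and makes no attempt to reconcile them.
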