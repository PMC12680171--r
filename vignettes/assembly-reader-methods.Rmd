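---
title: "Detecting cell assemblies and their downstream readers: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cell assemblies and their downstream readers: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblyreader)
```

`assemblyreader` implements a pipeline for asking whether brief
co-activations of neuronal ensembles ("cell assemblies") in one brain
structure are read out by downstream neurons ("readers") in another, and
whether that readout is genuinely collective — stronger than the summed
effect of the individual member neurons, selective for member identity,
robust to partial activation (pattern completion), able to discriminate
overlapping ensembles (pattern separation), and plastic across learning.
This vignette describes the model behind each stage, the tunable
parameters, the synthetic data used to validate the pipeline, and the
design decisions taken where the methodology left genuine freedom.

## 1. Assembly detection

Spike trains restricted to the analysis epochs (typically slow-wave sleep)
are binned at 15 ms and z-scored per unit (`bin_and_zscore()`). Bins are
half-open `[t, t + w)`, left-aligned to each epoch's start, and epochs are
binned independently so no bin spans a gap between non-contiguous sleep
periods — otherwise spikes on the two sides of a gap would count as
coincident. Z-scoring statistics are computed only over in-epoch bins.
Units with zero count variance cannot be z-scored and are dropped; units
below 0.05 Hz are dropped as well because their z-scores are dominated by
single spikes (the threshold is a `min_rate_hz` argument).

Eigenvalues of the correlation matrix of the z-scored matrix are compared
with the upper edge of the Marčenko–Pastur distribution,
`(1 + sqrt(n_units / n_bins))^2`, the largest eigenvalue expected from an
equally sized matrix of independent noise. Each supra-bound eigenvalue
signals one candidate assembly. A fixed-point independent component
analysis (symmetric decorrelation, `tanh` contrast) is run on the
whitened projection of the matrix onto the significant subspace, and the
mixing columns, mapped back to unit space, are the assembly weight
vectors. Weights are scaled to unit norm with the sign convention that the
largest absolute weight is positive.

Three choices here were open and are fixed as follows:

* the number of extracted components equals the number of supra-bound
  eigenvalues, the ICA is initialized from a fixed seed (`ica_seed`), and
  near-duplicate components (`|cosine| > 0.95`) are deduplicated keeping
  the one with better membership separation — ICA is rotation-ambiguous
  and can return the same source twice;
* the contrast function is `tanh` (log-cosh) with symmetric decorrelation
  and a convergence tolerance of `1e-8` on the unmixing rotation, standard
  fastICA defaults;
* assemblies are matched across data halves, timescales, or epochs by
  greedy maximal absolute cosine with a 0.7 acceptance threshold.

Members are the units whose absolute weights fall in the upper group of
Otsu's threshold (exhaustive maximization of inter-class variance), and
the inter-class to total variance ratio ("effectiveness") quantifies the
separation. Assemblies whose member weights carry both signs are
discarded: their activation strength is high when one subgroup fires
*without* the other, so a downstream response to them is uninterpretable
as coincidence readout; empirically they are larger and worse-separated,
consistent with ICA failures.

Detection is validated three ways: split-half cross-validation
(`split_half_crossvalidate()`, weight correlation across independently
detected halves against a weight-shuffle null), peer prediction
(`peer_prediction_gain()`, cross-validated prediction of each member from
its co-members), and member cross-correlograms
(`member_synchrony_ccg()`, modes at brief lags for member pairs). For the
peer-prediction error we use the *mean* absolute held-out error, not a
bin-wise median: binned spike trains are sparse enough that the median
absolute error sits on the empty-bin point mass and is identical for
aligned and shuffled pairings, making a median-based gain identically
zero for members and non-members alike.

## 2. Activation strength and events

The instantaneous activation strength of an assembly is the quadratic
form `A(t) = z(t)' P z(t)`, where `z(t)` are the members' spike counts in
a sliding window (15 ms wide, stepped by 1 ms), standardized with the
mean and variance of non-overlapping bins at the same width so the trace
is on the detection scale, and `P` is the outer product of the member
weights with the diagonal zeroed — a burst in a single member contributes
nothing; only cross-member coincidence does. Only member activity enters
the computation: including all units lets unrelated high-rate cells
produce spurious peaks (`compare_member_vs_all_strength()` quantifies
this as the fraction of members coactive around detected peaks).

Events are maximal runs of the trace above the 95th percentile of the
strictly-above-baseline values, where the baseline is the trace median
(a point mass at the empty-window value; ties at the median are excluded
so the threshold cannot collapse onto it). The event peak is the run
midpoint; recruited members are those with a spike within half a window
of the peak (this attribution window is needed by the completion and
leave-out analyses and is configurable). The threshold is computed per
assembly per analysis epoch set.

One behavior of this rule is worth knowing: the percentile adapts to the
data. When an assembly is strong and frequent, the above-baseline mass is
dominated by its own events and the threshold rises into the upper range
of their strengths, so the extracted events are the top slice of the true
co-activations (high precision, reduced count). When chance coincidences
dominate — higher background rates, sparser ensembles — the threshold
settles near the chance-coincidence level and event counts track the true
incidence closely. Both regimes appear in the validation suite.

## 3. Reader detection

For each assembly–reader pair, `compute_peth()` builds a trials × 200
matrix of reader spike counts in 10-ms bins over ±1 s around activation
peaks; PETHs with fewer than 30 spikes are not testable. Null PETHs are
built by independently permuting the time bins within each trial row
(`shuffle_bands()`, 200 repeats): each trial keeps its spike count, and
only the temporal alignment to the event is destroyed. (Permuting whole
columns of the trial matrix would leave the column sums — the PETH —
unchanged; within-trial permutation is the only non-degenerate reading.)
The pointwise band is the per-bin 95th percentile of the null sums; the
global band, which controls for multiple comparisons across the 200 bins,
is the 95th percentile of the per-shuffle maxima. A pair is significant
when the PETH (a) exceeds the pointwise band in at least one bin in the
10–30 ms response window, (b) exceeds the global band at its maximum, and
(c) has its unique mode at a positive delay, i.e., the reader fires after
the assembly. The per-bin response score `(m − mean_null) / sd_null`
supports split-half stability checks, and `delay_profile()` histograms
the first bin crossing both bands across pairs.

## 4. Collective coding: supralinearity and identity selectivity

To ask whether a reader's response to collective events exceeds the sum
of individual member influences, `fit_linear_readout()` fits, for every
delay on a ±1 s grid (5-ms step), an identity-link least-squares model of
the reader's spike count at that delay on the vector of member spike
counts in timescale-width bins around member trigger spikes emitted
*outside* activation runs. Applied to the triggers *inside* runs, the
model yields the linear prediction η(Δt); the supralinearity index is
`S(Δt) = (mean observed − mean η) / η(20 ms)`.

Two numerical choices matter here. First, the trigger spike is excluded
from its own member's count column, so the constant term carries the
(well-estimated) response to a single member spike and the member columns
measure only the extra effect of co-occurring spikes; with the trigger
included, no zero-count rows exist, the intercept and slopes are nearly
confounded, and at ~1 Hz member rates the extrapolated η(20 ms) is noise
that turns non-positive in a large fraction of runs. The conditional form
leaves the additive surrogate (below) at exactly `S = 0` and makes the
normalizer stable. Second, the Gaussian identity link follows from the
readout being defined as the matrix product of weights and counts.

Two surrogate readers calibrate the index: a *perfect* reader
(`simulate_perfect_reader()`) that fires once 20 ms after every event
recruiting at least half the members (using half of the largest observed
coactive subset when that is smaller than the full assembly), and an
*independent* reader (`simulate_independent_reader()`), the pooled member
trains shifted +20 ms. The perfect reader shows large positive `S(20 ms)`
against its −500 ms baseline; the independent reader sits at zero.

`timescale_scan()` repeats detection and the supralinearity analysis at
multiple bin widths, matching "the same" assembly across scales by
cosine, and — because a brief assembly also fits in any larger bin —
excludes, at each scale, all epochs containing activations of the same
assembly at briefer scales in the scan. The observed and predicted curves
are concatenated into one vector for z-scoring so scales are comparable.
The whole-trace 1-ms slide is kept at every scale; coarser steps blur run
boundaries and leak near-event spikes into the training set.

Identity selectivity is tested by comparing reader responses to two
spikes from two *different* members (AB) against two spikes from the
*same* member (AA) at matched inter-spike delays
(`find_ab_aa_events()`, `ab_aa_response()`). Event pairs must be
consecutive in the merged train (no intervening A or B spike) and
pairing is disjoint, scanning left to right — a spike consumed by one
event cannot seed the next. The two PETHs are z-scored jointly
(concatenated mean and sd) and differenced. A coincidence-detecting
reader prefers AB over AA only for delays inside its integration window;
an aggregate-rate reader is indifferent at every delay. One caveat
discovered with the generator: when strong planted population events are
present, brief-delay AB pairs occur preferentially *inside* those events,
where other members also spike, so even a rate reader shows AB > AA.
The AB/AA validation condition therefore uses members at cortical
background rates with chance coincidences only; this is also the regime
in which the contrast isolates pair-level identity selectivity.

## 5. Pattern completion and separation

Completion asks how the reader's response grows with the fraction of
members active. Because single-member "activations" can never cross a
zero-diagonal strength threshold, combination events are found directly
from the member spike trains: `find_subset_events()` splits the merged
member train into maximal clusters with inter-spike gaps at most one
timescale; each cluster is one event whose combination is its set of
distinct members and whose reference time is its spike-time mean. Mean
10–30 ms responses per distinct combination (at least 20 events each),
expressed relative to the reader's baseline rate, are normalized by the
complete-assembly response and fit with a sigmoid
`F(x) = 1 / (1 + exp(-k (x - x0)))` by bounded multistart least squares
(`k` in (0, 100], `x0` in [0, 1]); the parameter-free proportional model
is `F(x) = x` after the same normalization — the only scale on which the
two goodness-of-fit values are comparable. The boost is the excess of
each normalized response over proportionality, summarized in tertiles of
the active fraction.

Separation uses two statistics on baseline-subtracted 10–30 ms response
rates floored at zero (both statistics assume nonnegative responses): the
Hoyer sparsity of a unit's response vector across simultaneously recorded
assemblies, compared with the mean sparsity over 1,000 shuffles of
assembly identity across pooled activations (`sparsity_increase()`); and
the discrimination index `d = (r1 − r2) / (r1 + r2)` between a reader's
paired assembly and an overlapping assembly (shared members at least 25%
of each, both larger than 2 members), declared significant when `d`
exceeds the 95th percentile of 1,000 label shuffles
(`discrimination_index()`). The relative sparsity increase `(H − H0)/H0`
is numerically unstable when both H and H0 are near zero (a unit driven
almost identically by every assembly); such units are reported but their
ratio should not be over-interpreted.

## 6. Learning-related changes and the hierarchical bootstrap

Pre/post coupling changes are tested per pair by the difference in mean
10–30 ms response between post- and pre-epoch activations, against a null
built by permuting epoch labels over the pooled activations
(`response_change()`, 1,000 permutations, two-sided at 0.05). Assemblies
are detected on the concatenated epochs and their events split by epoch,
which guarantees the "same" assembly is compared. Rates of changed pairs
between conditions are contrasted with a 2×2 chi-squared test without
continuity correction, falling back to Fisher's exact test when an
expected cell is below 5 (`compare_change_rates()`).

`hierarchical_bootstrap()` resamples with replacement animals, then
sessions within each drawn animal, then observations within each drawn
session (draw counts equal to observed counts at each level) and returns
percentile intervals of the resampled statistic. Percentile intervals
undercover when the top level has very few units — measured ~90% at 4
animals versus ~95% at 10 in nested Gaussian simulations — a standard
small-n property of the scheme worth keeping in mind for small cohorts;
the package's coverage validation uses a 10-animal design.

## 7. The synthetic generator

`generate_session()` produces the study conditions every stage is tested
against: two structures of 30 units, 30-minute epochs, log-normal
background rates (median 1 Hz, σ = 0.5 on the log scale), a shared
sinusoidal rate modulation (amplitude 0.3 at 0.8 Hz) standing in for the
slow global fluctuations of sleep that the identity shuffle must survive,
five disjoint 5-member assemblies in structure A co-activating within a
15-ms timescale at 1.5 Hz with 0.75 per-member recruitment (at least one
member per event), and one collective reader in structure B per assembly,
firing at event time + Normal(20 ms, 3 ms). Member event spikes are
jittered uniformly on ±timescale/2 around the event time, keeping the
detected peak centered on the planted time so planted 20-ms delays read
out as ~20 ms. Reader spikes are *added to* the reader's background
train, as real responses ride on baseline firing; exactly one spike per
recruited member per event keeps every downstream analysis interpretable.

Collective readers respond with probability
`p_max · logistic(steepness · (fraction active − midpoint))`, defaults
`p_max = 0.6`, midpoint 0.4, steepness 10: a reader that responds
near-fully once roughly two of five members co-fire, i.e., a
pattern-completing reader in the sense of the half-rule; a midpoint at
half the assembly would leave the normalized response below
proportionality through the mid-tertile and the planted phenomenon would
not be completion. "Independent" readers fire after every member spike
with fixed probability; "coincidence" readers fire after consecutive
spikes of two distinct members within the timescale. `generate_cohort()`
adds per-animal log-rate offsets (σ = 0.2) to induce the nested
correlation the bootstrap must respect; `generate_pre_post()` repeats the
generative process in two epochs with per-coupling response-probability
multipliers in the second.

What the generator does *not* emulate: bursting and refractoriness,
rate-dependent spike sorting artifacts, non-stationary assemblies,
membership drift, multi-spike member responses, and readers embedded in
the same structure as their assembly. Passing tests therefore show the
statistics behave as designed under a controlled ground truth, not that
real recordings satisfy the generative assumptions.

## 8. Validation problem sizes

The test suite exercises: recovery and reader detection on 20 seeded
default sessions (100 planted assemblies and couplings); null calibration
on ~500 uncoupled pairs (200 permutations each) and on ~600 exchangeable
pre/post pairs; the supralinearity dissociation on 20 perfect/independent
surrogate pairs; the timescale scan on four 60-minute low-incidence
sessions (scales 15/25/50 ms); completion on ~20 assembly–reader pairs
and separation on 10 sessions with 50%-overlapping assemblies; the
pre/post double dissociation on 12 + 12 pre/post sessions; and bootstrap
coverage on 500 nested simulations of 10 × 4 × 15 observations. These
sizes were chosen so the full suite runs on a laptop in well under half
an hour while keeping binomial noise on every rate assertion below the
margin being asserted.

## 9. Known limitations

* The activation-event threshold adapts to the composition of the trace
  (section 2); detected event counts are not comparable across datasets
  with very different coincidence structure.
* The linear-readout training set excludes only *detected* activation
  runs; when detection misses many collective events (strong-assembly
  regime), the "linear" model partially absorbs the collective response
  and S is conservative for real readers. The surrogate-based
  dissociation is unaffected.
* ICA is run once from a fixed seed; pathological mixing (duplicated or
  mixed-sign components) is handled by deduplication and the mixed-sign
  filter rather than restarts.
* The permutation null for pre/post changes assumes activation-level
  exchangeability within a pair; slow drifts in baseline rate between
  epochs will register as coupling changes.
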