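---
title: "Methods: from gaze streams to two-domain correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gaze streams to two-domain correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculonet)
```

## The problem

Oculomotor control tasks - the antisaccade task (look away from a suddenly
appearing peripheral stimulus) and the Go/NoGo task (saccade to the stimulus
on a green cue, hold fixation on a red cue) - probe inhibitory control and
visual-motor integration, functions that are degraded in schizophrenia
spectrum disorders. Neurocognitive batteries probe overlapping constructs
psychometrically. `oculonet` implements the full computation path from raw
gaze samples and battery scores to a two-domain correlation network over
twelve measures:

* six cognitive scores - verbal memory (VM), digit sequencing (DS), token
  motor task (TMT), verbal fluency (VF), symbol coding (SC), Tower of
  London (TL);
* six oculomotor summaries - per-subject medians of antisaccade latency
  (ASLs) and antisaccade error latency (ASELs), antisaccade error
  proportion (ASEs), Go latency median (GnGLs), NoGo error latency median
  (GnGELs) and NoGo error proportion (GnGEs).

Nodes are measures; edges are pairwise Pearson correlations that survive a
gate - either statistical significance ("full" network) or magnitude
("thresholded" network, |r| > 0.4) - and centrality is plain degree. The
package ships the published correlation tables for these twelve measures as
plain-CSV fixtures, so the network stage can be run as an exact worked
example, and a calibrated synthetic-cohort generator so that every upstream
stage (event detection, scoring, statistics) is exercised end to end
without access to clinical recordings.

## Event detection

Gaze is sampled at 250 Hz. Saccades and fixations are identified by a
composite of the two classic threshold algorithms:

1. **Velocity pass (I-VT-like).** Positions are smoothed with a centred
   moving average (default 5 samples), and angular speed at sample *i* is
   the central difference of the smoothed positions over ±2 samples.
   Contiguous runs with speed ≥ 30 deg/s become saccade candidates.
   A candidate is accepted if it lasts ≥ 12 ms *and* contains at least one
   sample at twice the onset threshold (≥ 60 deg/s).
2. **Dispersion pass (I-DT-like).** The remaining spans, split at invalid
   samples, are grouped greedily into fixations: the smallest window
   covering 50 ms is grown while its dispersion (x-range + y-range of the
   smoothed positions) stays within 1.0 deg. Spans qualifying as neither
   are left unlabelled.

The peak-velocity validation is the one structural element beyond the
textbook forms. A single velocity threshold applied to noisy 250 Hz data
produces spurious short runs once fixation noise approaches 0.3 deg RMS;
requiring the run to reach twice the threshold removes essentially all of
them (0 wrong saccade counts in 400 simulated trials at 0.3 deg noise,
versus ~12% without it) while leaving real saccades untouched - a 15 deg
saccade peaks above 400 deg/s, and even a 2 deg saccade above 120 deg/s.
Two-threshold validation of candidate runs is standard practice in adaptive
saccade detectors. All five constants are exposed as `detection_params()`.

Two numerical consequences are worth knowing. First, smoothing plus the
±2-sample difference attenuates the *reported* peak velocity of a 54 ms
saccade by roughly 9%; onset and offset timing, which the scoring stage
uses, are unaffected beyond about two sample periods (8 ms). Applications
that need main-sequence-grade peak velocities should call
`compute_velocity(rec, smoothing_window = 1, span = 1)`. Second, invalid
samples split events rather than being interpolated - the detector never
fabricates data.

## Trial scoring

The primary saccade of a trial is the first detected saccade with onset at
or after stimulus onset and amplitude ≥ 2 deg (the amplitude gate makes
scoring immune to residual micro-events). Its latency is onset minus
stimulus onset, and trials with latency < 80 ms or > 900 ms are discarded
outright - anticipations and lapses, regardless of direction.

* Antisaccade: horizontal direction opposite the stimulus → correct;
  toward it → reflexive error; no primary saccade → miss.
* Go: saccade within ±22.5 deg of the direction to the stimulus → correct
  (half the 45 deg angular spacing of the 8-location diamond); elsewhere →
  error; withheld → miss, which counts as an incorrect trial in Go
  accuracy.
* NoGo: withheld → correct; any qualifying saccade breaks fixation and is
  an error, its latency recorded as an error latency.

Performance accuracy (PA) is correct responses over counted trials. The
denominator convention is genuinely open: we exclude discarded trials from
both numerator and denominator by default, so PA measures decision quality
among analysable trials, and expose `denominator = "all"` as the
alternative. Per-subject medians over non-discarded trials produce the six
oculomotor measures; a subject with zero errors of a kind has a missing
error-latency median (not zero), which pairwise-complete correlation
handles downstream.

## Statistical layer and subject exclusion

Group contrasts use the pooled-variance Student's t (Welch by flag), the
variance F-test with a two-sided p, Kruskal-Wallis with tie correction,
and Pearson correlation with the exact t transform. These delegate to the
standard R implementations behind a uniform result type with strict
preconditions; the test suite verifies each against independently coded
textbook-formula oracles to 1e-10.

Before accuracy-latency correlations, each group's regression of latency
median on accuracy is screened with the four standard influence measures
for a simple linear fit (p = 2 parameters): leverage hᵢ = 1/n + (xᵢ-x̄)²/Sxx
flagged above 3p/n, internally studentized residuals flagged beyond |2|,
Cook's D flagged above the 50th percentile of F(p, n-p), and DFITS flagged
beyond 2√(p/n). Any flag marks the subject for exclusion, and the pipeline
report lists every excluded subject with the triggering criteria - the
exclusion narrative is auditable from the artifacts alone.

## Network construction

`correlation_table()` computes pairwise-complete Pearson r, p and n for all
66 pairs of the twelve measures (pairs with fewer than 3 complete
observations are marked missing with a warning). Two gates build graphs
from it:

* **Full network** - an edge where p < α (default 0.05). When only printed
  significance codes are available, codes at or below α qualify; at the
  default this excludes the p < 0.1 marks. We adopted the significance
  reading of "full" deliberately: it exactly reproduces the published
  verbal edge lists (VF connected to ASLs, GnGLs and GnGELs; VM only to
  GnGEs; TL only to ASLs), which an all-correlations or p < 0.1 rule would
  contradict.
* **Thresholded network** - an edge where |r| > τ (default 0.4), strictly.
  Applied to printed two-decimal coefficients this is unambiguous except
  for one documented tension in the source: DS-TMT prints 0.39, so the
  strict rule gives DS no edge to TMT even though the accompanying text
  implies one. We follow the printed table and leave the discrepancy
  documented rather than resolved.

Degree is the only centrality; `central_nodes()` returns all maximum-degree
nodes so ties are explicit, and `cross_domain_degree()` restricts neighbours
to the opposite domain. On the shipped tables the thresholded two-domain
network has exactly three cross-domain edges (ASLs-SC, GnGLs-SC, ASEs-DS,
all negative), ASELs is isolated, and SC is the unique most central node
with degree 7.

Graphs export to GraphML (node attribute `domain`; edge attributes
`weight`, `sign`, `sig_code`) or a two-section tab-separated edge list;
both re-import losslessly, including isolated nodes.

## The synthetic cohort

The generator emulates the study conditions at two levels.

**Measure level.** Subjects are drawn from a per-group multivariate normal
over the twelve measures whose marginal moments are the published
group-level values (cognitive means/SDs; latency means/SDs; error
proportions matched to the published medians with SD ≈ IQR/1.349) and whose
correlation matrix is the 12×12 target assembled from the shipped tables.
That matrix is already positive definite (smallest eigenvalue 0.216); had
it not been, `nearest_correlation()` repairs by eigenvalue clipping at a
small floor followed by rescaling to unit diagonal - deterministic
standard practice. Controls reuse the patient correlation structure, since
only patient correlations are published and the network stage is
patients-only. Impossible values are clipped (scores at 0, proportions to
[0, 1], latencies at 80 ms). Clipping the patient error proportions (mean
0.10, SD 0.158) censors about a quarter of the mass at zero and attenuates
their correlations by up to ~0.03-0.04 at n = 5000 - inside the ±0.05
recovery band the tests enforce, but visible; the marginals of real error
proportions are right-skewed rather than normal, and this generator does
not attempt to model that skew.

**Gaze level.** Each subject receives full 80-trial designs per task
(antisaccade: 40 left/40 right pseudorandomized; Go/NoGo: 8 diamond
locations × 10, balanced 5 Go + 5 NoGo per location so both margins are
exact), fixation intervals uniform on 2000-4000 ms, intertrial gaps on
2000-3000 ms, and stimulus eccentricity 15 deg for both tasks (the
antisaccade eccentricity is the published value; the Go/NoGo eccentricity
is not printed, so the same 15 deg is used). Subject accuracies are
logit-normal, location at the published group median and scale fitted to
the published quartiles on the logit scale. Latencies are shifted lognormal
- shift fixed at the 80 ms analysis floor, lognormal component solved for
the published mean/SD - truncated to the (80, 900) ms analysis window by
resampling: latencies outside that window are exactly the trials the
analysis discards, so an embedded "correct" label is never invalidated by
the filter. Error latencies use the published error means, which are lower
than the correct-response means. Misses occur with probability 0.02; misses
are reported to exist in this paradigm without a printed rate, and 2% is a
realistic omission rate for instructed saccade tasks. Saccade trajectories
are raised-cosine displacements with main-sequence duration
2.2 ms/deg × amplitude + 21 ms, plus white Gaussian position noise
(default 0.15 deg).

What the generator does **not** emulate: blinks, pupil dynamics, head
movement, calibration drift, corrective saccades, temporally correlated
tracker noise, or skewed/zero-inflated marginals for error measures.
Passing round-trip tests therefore demonstrate that the detector and
scorer recover what this generator embeds - clean single-saccade trials
under white noise up to 0.3 deg - not performance on clinical recordings.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed and restores the RNG state
afterwards; a pipeline run is regenerable bit-identically from its config
and seed, and the run report embeds a config hash and carries no
timestamps. The shipped verification uses these sizes, chosen to make the
Monte-Carlo error small relative to each tolerance: correlation recovery at
n = 5000 subjects (sampling SD of r below 0.015 per cell) and at the study
size n = 93 against 3-standard-error bands; type-I calibration of Pearson
and t at 10,000 null replicates of n = 30 (binomial SD of the rate
estimate 0.0022 against the [0.040, 0.060] acceptance band); and the
detect-score round trip over 1000 trials at the 0.3 deg noise bound with a
≥ 99% label-agreement requirement.

## Known limitations

* The composite detector's constants are design choices (standard I-VT/I-DT
  values), not a reconstruction of the proprietary system used to collect
  the original recordings; with 250 Hz data there is no blink handling
  beyond validity flags.
* The full gaze-level cohort at published group sizes (134 subjects × 160
  trials) produces ~30 M samples; the pipeline handles it, but the test
  suite and examples run smaller cohorts. Measure-level simulation is the
  intended tool for correlation-structure work.
* Published patient-level statistics that depend on the unavailable raw
  recordings (specific H and R values) are out of scope; the pipeline
  computes the same kinds of statistics on synthetic cohorts without
  claiming to reproduce those numbers.
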