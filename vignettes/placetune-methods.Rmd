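---
title: "Methods: from raw calcium traces to place-field tuning dynamics and population manifolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw calcium traces to place-field tuning dynamics and population manifolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placetune)
```

`placetune` analyses one-photon calcium imaging of hippocampal CA1 recorded
while a mouse freely explores an elevated O-shaped circular track (50 cm
outer diameter, 5 cm lane, 20 fps imaging, 15-minute sessions). The package
covers four stages — calcium-event detection, place-field detection with
per-visit selectivity and tuning latency, cross-session map comparison, and
Laplacian-eigenmaps population embedding — plus a synthetic-data generator
that makes every stage testable by parameter recovery. This vignette is the
package's own account of the science in each stage: the models, their
assumptions, the tunable parameters, and the design decisions taken where
the method left room.

## Conventions

Time is in seconds, positions in cm, angles in radians in $[0, 2\pi)$.
Track bins are 1-based; bin $b$ of $n$ is the half-open sector
$[(b-1), b) \cdot 2\pi/n$. All time intervals are half-open $[a, b)$.

## Synthetic sessions

The generator emulates the study conditions, not the raw imaging: it
produces position series and fluorescence traces directly, skipping motion
correction and source extraction (those belong to upstream tools and are out
of scope).

**Trajectory.** A run-and-reverse walk along the track centerline: constant
speed, direction reversing as a Bernoulli event per second with probability
`turn_prob`, and smooth radial jitter clipped to the lane. Only angular
position matters downstream, so a 1-D centerline walk with radial noise is
sufficient. Defaults: one lap per 47 s (about 19 laps per 15-minute
session, matching reported exploration rates) and `turn_prob = 0.02`/s —
direction changes are a free parameter of the behaviour, not calibrated to
any dataset; 0.02 gives roughly 15–20 reversals per session, enough that
both travel directions are sampled.

**Tuning.** Ground-truth place cells fire as an inhomogeneous Poisson
process (one Bernoulli draw per frame at `rate/fps`) whose rate is a von
Mises bump: $r(\theta) = r_\text{out} + (r_\text{in} - r_\text{out})
\exp[\kappa(\cos(\theta - \theta_0) - 1)]$ with $\kappa = 1/w^2$. Any
unimodal bump would do — the analysis detects fields, it does not model
their shape. Tuning latency is emulated by an `onset_time`: before it the
cell fires uniformly at the spatial average of its tuned rate, after it the
tuned rate applies. This yields a known ground-truth specialization visit
for recovery tests. Defaults: width 0.3 rad, rates 1.0 / 0.05 events/s —
roughly one transient per pass through the field, sparse background —
chosen as typical CA1 event statistics at 20 fps.

**Traces.** Each spike adds a two-exponential transient
$A\,(1-e^{-\Delta/t_\text{on}})\,e^{-\Delta/t_\text{off}}$
($\Delta = t - t_0$), amplitudes log-normal with CV 0.3 (positive support,
simple), linear superposition, additive i.i.d. Gaussian noise, baseline 0.
A constant baseline offset would be irrelevant because event detection is
median-based. Defaults $t_\text{on} = 0.1$ s, $t_\text{off} = 0.6$ s match
slow GCaMP-family kinetics; `noise_sigma = 0.062` puts the peak of a
unit-amplitude transient at SNR 10. Kernels are truncated 20 decay
constants after onset (relative error $< 10^{-8}$).

## Event detection

Per trace, the threshold is the median plus 4 (slow sensors: GCaMP6s,
NCaMP7, FGCaMP7) or 5 (fast: GCaMP7f) raw median absolute deviations — raw,
without the 1.4826 normal-consistency factor, since the integer multipliers
are defined on the raw MAD. The threshold is computed once from the
original trace and not re-estimated from residuals: subtraction lowers the
working trace, and re-estimating would let the threshold drift.

At each upward threshold crossing a transient model is fitted by bounded
Levenberg–Marquardt over a local window (0.5 s before the crossing to
$4\,t_\text{off}^\text{floor}$ after). Fits with $R^2 \ge 0.8$ over the
window and $A > 0$ are accepted; accepted fits are subtracted from a working
copy and the trace is re-scanned until nothing more is accepted. Crossings
within 2 frames of an accepted onset are skipped to prevent duplicate fits.
The decay constant is bounded below by the sensor floor (0.5 s slow, 0.2 s
fast).

Two further constraints deal with overlapping transients, which a single
unbounded kernel would otherwise absorb whole:

* **Physiological bounds.** The rise constant is capped at 0.3 s and the
  decay constant at $5\,t_\text{off}^\text{floor}$. Without the caps, one
  fitted kernel with an inflated rise or decay can swallow a run of
  overlapping transients and leave a sub-threshold residual.
* **Re-rise truncation and cascading.** After the first peak inside the fit
  window, the first point where the trace rises more than 3.5 MADs above
  its running minimum marks the onset region of a following transient; the
  fit window is truncated at that valley, and after the accepted fit is
  subtracted the valley is queued as the next fit candidate. During dense
  event bursts the working trace can stay above threshold across several
  transients, so no new upward *threshold* crossing appears — the cascade
  recovers those events and removes the systematic bias toward the first
  event of a burst.

Starting values are data-driven (decay from the 1/e fall time after the
peak; amplitude from the peak height divided by the kernel peak factor,
since $A$ is a prefactor, not the realised peak). Optimizer failures reject
the candidate silently — a failure to fit is evidence of no event, not an
error. On the 1000-transient benchmark at peak SNR 8 the detector reaches
sensitivity $\ge 0.95$ with FDR $\le 0.05$ and a median onset error well
under one frame.

The threshold is applied to the traces as given (no $\Delta F/F$
re-baselining), and the fit window extent is configurable; neither choice is
dictated by the method itself.

## Place fields, selectivity and tuning latency

Event counts (not occupancy-normalised rates — the per-visit selectivity
check below replaces occupancy corrections, which require sustained running
speeds) are binned into the 20 sectorial bins at the interpolated event
angle, smoothed circularly with a Gaussian of $\sigma = 1.25$ bins,
normalized to peak 1, and thresholded at 0.5. Each maximal circular run of
supra-threshold bins is a putative field: its centre is the
smoothed-value-weighted circular centroid of the run, its interval the run
plus one bin on each side. Fields wider than half the track are discarded
(an all-supra-threshold map has no field). A cell may own several fields.
Fields are omnidirectional; direction of travel is ignored because free
exploration gives unequal direction statistics.

**Attendances.** A visit to a field is a maximal interval with the animal's
angular bin inside the field interval; out-of-field excursions shorter than
1 s (configurable) do not split a visit, since positional jitter at bin
edges would otherwise fragment them. Each visit carries its flanking
out-of-field intervals (to the previous and next visit), so a visit plus
flanks is "the surrounding lap".

**Selectivity.** The per-visit score is (events inside the visit) /
(events in visit plus flanks). A silent lap (denominator 0) is scoreless:
it is evidence of inactivity, not of non-selectivity, and is excluded from
the smoothed sequence rather than scored 0 (configurable choice). Score
sequences are smoothed with a Gaussian of $\sigma = 1$ visit with
reflective (edge-repeated) boundaries — the sequence is not circular.
Visits with smoothed score above 0.5 are *relevant*. A field is a confirmed
place field when it has at least three consecutive relevant visits
(consecutive within the retained, scored sequence). The tuning latency is
`n_spec` — the number of visits strictly before the first visit of that run
(0 if the run starts at the first visit) — and `t_spec`, the entry time of
that visit. Where the rule left choices open we took: `t_spec` is the
*start* of the first relevant run; gaps from scoreless visits do not break
consecutiveness (they are absent from the retained sequence).

## Cross-session comparison

Cells matched across sessions (the match table is an input, produced by an
upstream ROI-registration tool) contribute one field shift each if they are
single-field place cells in both sessions — multi-field cells are excluded
from shift statistics and only categorised in the transition table. The
shift is the minimal signed circular difference of field centres, in bins.

**Map retention.** A retained map concentrates shifts in a sharp
zero-centred peak; full remapping spreads them uniformly over the circle.
The default test (`logic = "peak"`) bins shifts into unit-width bins,
merges adjacent bins with expected counts below 5, and computes a
chi-square statistic against the uniform null: $p < \alpha$ means a
significant zero-centred (normal-like) concentration, i.e. retention —
"significantly similar to a normal around zero". This direction is well
calibrated: zero-mean normal shifts ($\sigma = 1$ bin, $n = 100$) classify
as retained and circular-uniform shifts as not-retained, each in
$\ge 90\%$ of simulations. The alternative (`logic = "normality"`) tests
the histogram against a zero-mean normal with sd estimated from the data
and calls the map retained when normality is *not* rejected; it keeps sharp
peaks retained but has little power against broad alternatives, because the
fitted normal absorbs the spread. Degenerate (all-identical) and
underpowered ($n < 10$) shift sets are flagged.

**Latency shifts.** Per-cell `n_spec` differences between sessions are
compared between groups (retained-map versus remapped animals) with an
unpaired Student's t-test.

## Population manifold

Cells with at least 5 detected events enter the activity matrix; traces are
block-averaged in non-overlapping windows of $w = 8$ frames (0.4 s), giving
$T_\mathrm{eff} = \lfloor T/w \rfloor$ population vectors in $\mathbb{R}^N$.
Raw filtered traces are used, not binarised events (configurable). $w$ is in
frames; results for $w \in \{2, 4, 8\}$ differ little because the calcium
signal hardly changes within a window. No per-cell normalisation is applied
by default.

Each window connects to its $k$ nearest neighbours by Euclidean distance;
the adjacency is symmetrized by logical OR (so $k$ is the minimum degree,
not the exact one). If the graph is disconnected, the largest component is
kept when at most 5% of nodes are lost; otherwise the reduction fails with
an "increase k" error. $k$ should be as small as the connectivity rule
allows — too large a $k$ breaks the local-linearity premise of the
embedding; `choose_k()` picks the smallest viable candidate from
$\{5, 10, 15, 20, 30\}$.

The embedding solves the generalized eigenproblem $L v = \lambda D v$ with
$L = D - A$, via the symmetric normalized form
$D^{-1/2} L D^{-1/2} u = \lambda u$, $v = D^{-1/2} u$, solved densely
(LAPACK). Eigenvalues are ascending; the single zero eigenvalue with
constant eigenvector is verified (more than one numerical zero means a
disconnected graph and is an error, tolerance $10^{-8}$) and dropped; the
next $m$ eigenvectors are the coordinates. Eigenvector sign is fixed by
making the largest-magnitude component positive. PCA (column-centred SVD
projection) provides the linear baseline.

**Residual variance.** $RV = 1 - \rho^2$, where $\rho$ is the Pearson
correlation between pairwise Euclidean distances of window positions (mean
$(x, y)$ per window) and of embedding coordinates, over the
strictly-upper-triangular entries. $RV$ is invariant to rotation,
translation and uniform scaling of either set. The sliding variant
recomputes graph + embedding + RV on 250 s slices (stride 25 s, 10% of the
window — the stride is a free choice). The unselectivity score (one minus
the across-field mean of interpolated raw selectivity, boxcar-smoothed over
250 s) is the single-cell counterpart against which RV is compared via
cosine similarity across animals.

## Numerical choices and degenerate inputs

* Constant traces have MAD 0: the threshold degenerates to the constant
  and a warning is raised; an all-zero trace yields no events.
* Gaussian smoothing kernels are truncated at $4\sigma$ and renormalised;
  circular smoothing wraps, score smoothing reflects with the edge value
  repeated.
* Bin assignment uses half-open sectors, so boundary events go to the
  upper bin deterministically; ties in nearest-neighbour distances resolve
  by index order (they have measure zero for continuous data).
* The circular centroid is the vector mean of bin-centre angles weighted by
  smoothed values; signed circular differences live in $[-n/2, n/2)$.
* Eigen-decomposition is dense symmetric LAPACK; at the default
  $T_\mathrm{eff} = 2250$ (15 min, $w = 8$) it takes seconds. No
  out-of-sample extension is provided — embedding new data requires
  rebuilding the graph.

## What the tests do and do not show

All recovery benchmarks run on the synthetic generator, so they validate
the pipeline against data whose ground truth is known and whose artefacts
are controlled: Poisson spiking with von Mises tuning, linear transient
superposition, stationary Gaussian noise, and a constant-speed
run-and-reverse walk. Real recordings add slow baseline drift,
motion-correction residuals, crosstalk between nearby ROIs, amplitude
nonstationarity, and behaviourally structured occupancy; passing the
recovery suite does not certify performance under those effects. Problem
sizes were chosen to keep the full suite comfortably inside a desktop run:
the detector benchmark uses 1000 transients at peak SNR 8; centre recovery
uses 100 cells at contrast 10:0.1 events/s over a 15-minute session with
`turn_prob = 0.1` (both travel directions must be sampled, otherwise the
entry side of each field is over-represented among detected events);
latency recovery uses 40 cells at 1:0.01 events/s — the same 100:1
contrast at rates whose transients remain individually resolvable given
the 0.6 s decay (at 10 events/s in-field, transients fuse into bursts and
per-visit event counts compress); the ring-recovery session uses 300 cells
for 15 minutes with $k = 15$, $m = 2$; the cell-count trend uses 10 seeds
of 450 s sessions with nested subsamples of 25–300 cells.

## Known limitations

* Discrete-event detection is ill-posed above a few events per second for
  slow indicators; sustained bursts are recovered as fewer, larger events.
* The selectivity score shares flank events between adjacent fields of
  different cells scored independently; scores are not comparable across
  fields with very different visit statistics.
* The retention test needs tens of matched single-field place cells for
  useful power; with fewer it flags itself underpowered.
* Laplacian eigenmaps cost $O(T_\mathrm{eff}^3)$ here (dense solver) and
  provide no out-of-sample mapping.
* A cell whose true field straddles the disc of excluded widths (more than
  half the track) is unrecoverable by construction.
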