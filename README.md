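# placetune

Tuning dynamics of hippocampal place fields and population manifolds from
calcium imaging.

## The problem

When a mouse explores a novel environment, CA1 place cells acquire their
spatial tuning remarkably fast — some fields exist from the very first visit
to a location, others need several. Quantifying *how fast* requires a
pipeline that goes from raw one-photon fluorescence traces to per-visit
statistics of spatial firing, and from single cells to the population: does
the joint activity of a few hundred neurons already encode the geometry of
the environment?

`placetune` implements that pipeline for free exploration on a circular
O-shaped track (50 cm outer diameter, 5 cm lane, 20 sectorial bins, 20 fps
imaging), for researchers analysing miniscope recordings of hippocampal
populations — and for anyone who wants a fully testable reference
implementation, since the package ships a synthetic-data generator with
known ground truth for every stage.

## What it computes

* **Calcium events.** Each trace is thresholded at its median plus 4–5 raw
  median absolute deviations (by indicator speed class) and every upward
  crossing is fitted with the two-exponential transient
  `f(t) = A (1 − e^(−Δ/t_on)) e^(−Δ/t_off)`, `Δ = t − t0`, by bounded
  Levenberg–Marquardt; fits with `R² ≥ 0.8` are accepted and locally
  subtracted so overlapping transients can each be scored.
* **Place fields.** Spatial event counts per bin, circular Gaussian
  smoothing (`σ = 1.25` bins), normalization to peak 1, threshold 0.5;
  each supra-threshold run ±1 bin is a field (fields wider than half the
  track are discarded).
* **Selectivity and tuning latency.** For every attendance of a field, the
  score `n_in / n_lap` (events in the visit over events in the visit plus
  flanking intervals); scores smoothed with a Gaussian (`σ = 1` visit);
  a field is confirmed after ≥ 3 consecutive relevant (smoothed > 0.5)
  visits, and its tuning latency is reported as `n_spec` (visits before
  that run) and `t_spec` (seconds).
* **Cross-session comparison.** Signed circular field shifts of matched
  single-field place cells, a chi-square map-retention test, and t-tests on
  `n_spec` shifts between retained-map and remapped animals.
* **Population manifold.** Block-averaged population vectors (`w = 8`
  frames), an exact-k-nearest-neighbour graph symmetrized by OR, the
  Laplacian-eigenmaps generalized eigenproblem `L v = λ D v` (`L = D − A`),
  a PCA baseline, and the residual variance `RV = 1 − ρ²(D_high, D_low)`
  between pairwise distances in physical space and in the embedding —
  globally, in 250 s sliding windows, and as a function of cell count.

## Worked example

Simulate a 10-minute session with 30 place cells, half of them tuned only
after 200 s, then run the full pipeline:

```r
library(placetune)

geom  <- track_geometry()                      # 50 cm O-track, 20 bins
cells <- place_cell_population(30, in_field_rate = 2, out_field_rate = 0.05,
                               onset_time = c(rep(0, 15), rep(200, 15)))
ses   <- simulate_session(cells, geom, duration = 600, turn_prob = 0.05,
                          seed = 42)

events <- detect_events(ses$traces, sensor = "gcamp6s")
events
#> # A tibble: 3,581 × 6
#>   cell_id    t0     A    t_on t_off   gof
#>   <chr>   <dbl> <dbl>   <dbl> <dbl> <dbl>
#> 1 cell001 0.127 2.64  0.0990  0.587 0.976
#> 2 cell001 1.44  0.476 0.00356 0.968 0.858
#> 3 cell001 1.53  1.39  0.115   0.5   0.953
#> # i 3,578 more rows

ana <- analyze_place_fields(events, ses$trajectory, geom)
glance(ana)
#> # A tibble: 1 × 8
#>   n_cells n_fields n_place_fields n_place_cells frac_single_field ...
#> 1      30       34             23            23                 1
```

All 30 cells yield events; 23 fields pass the three-consecutive-relevant-
visit rule. The session-level tuning statistics from the same `glance()`
row: 47.8% of confirmed fields were selective from their first attendance
(`frac_first_attendance = 0.478`), the mean tuning latency was 2.8 visits
(`mean_n_spec = 2.78`) or 128 s (`mean_t_spec = 128.4`) — the delayed half
of the population drags the average up, which is exactly what the
per-field `tidy(ana)` table lets you dissect.

The population embedding of the same session:

```r
act <- prepare_activity(ses$traces, events, w = 8, min_events = 5)
emb <- laplacian_eigenmaps(knn_graph(act, choose_k(act)), m = 2)
pos <- window_positions(ses$trajectory, w = 8)
residual_variance(pos, emb)
#> <rv_result> residual variance 0.4354 (rho = 0.7514, n = 1500 windows)
```

With only 30 cells the ring geometry is reconstructed coarsely
(RV ≈ 0.44); the acceptance benchmarks below show RV dropping under 0.1
as the population grows to a few hundred cells, with PCA consistently
worse than the Laplacian embedding — the nonlinearity matters.
`autoplot(emb, positions = pos)` draws the embedding coloured by true
track angle.

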