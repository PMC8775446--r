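# Shared synthetic fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A 20-cell tiled place-cell session at the high-contrast recovery
# conditions (10:0.1 events/s, SNR 10), with detected events.
fixture_recovery_session <- function() {
  memoise_fixture("recovery", function() {
    geom <- track_geometry()
    cells <- place_cell_population(20,
      in_field_rate = 10, out_field_rate = 0.1
    )
    ses <- simulate_session(cells, geom,
      duration = 600, fps = 20,
      turn_prob = 0.05, seed = 101
    )
    ses$events <- detect_events(ses$traces, "gcamp6s")
    ses
  })
}

# A constant-speed, no-reversal lapping trajectory (useful for attendance
# and binning tests where geometry must be exact).
fixture_lapping_trajectory <- function(duration = 300, fps = 20,
                                       lap_time = 50) {
  geom <- track_geometry()
  n <- duration * fps
  theta <- (seq_len(n) - 1) / fps / lap_time * 2 * pi
  theta <- theta %% (2 * pi)
  tibble::tibble(
    t = (seq_len(n) - 1) / fps,
    x = geom$radius * cos(theta),
    y = geom$radius * sin(theta),
    theta = theta,
    speed = geom$circumference / lap_time
  )
}

# True field centre of each cell expressed in continuous bin units (bin
# centres at integers), matching detect_place_fields()'s `center`.
true_center_bins <- function(cells, geometry) {
  cells$field_center / (2 * pi) * geometry$n_bins + 0.5
}

# Circular center error in bins.
center_error_bins <- function(center, truth, n_bins) {
  abs(((center - truth + n_bins / 2) %% n_bins) - n_bins / 2)
}
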