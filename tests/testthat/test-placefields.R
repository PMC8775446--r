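# Place fields: spatial maps, field detection, attendances, selectivity,
# tuning latency.

make_map <- function(smoothed, cell_id = "c1") {
  tibble::tibble(
    cell_id = cell_id, bin = seq_along(smoothed),
    count = NA_integer_, smoothed = smoothed
  )
}

test_that("events are assigned to half-open sectorial bins", {
  geom <- track_geometry()
  # stationary trajectories pin the interpolated angle exactly
  traj_at <- function(theta) {
    tibble::tibble(
      t = seq(0, 10, by = 0.05), theta = theta,
      x = geom$radius * cos(theta), y = geom$radius * sin(theta)
    )
  }
  ev <- tibble::tibble(cell_id = "c1", t0 = c(1, 2, 3))
  m0 <- bin_events(ev, traj_at(0), geom)
  expect_equal(m0$count[m0$bin == 1], 3)
  expect_equal(sum(m0$count), 3)

  # an event exactly on a bin boundary belongs to the upper bin
  mb <- bin_events(ev, traj_at(2 * pi / 20), geom)
  expect_equal(mb$count[mb$bin == 2], 3)

  # one event at each bin centre -> each bin counts 1
  traj <- fixture_lapping_trajectory(duration = 50, lap_time = 50)
  centers <- (seq_len(20) - 0.5) * 2 * pi / 20
  t_at <- vapply(centers, function(th) traj$t[which.min(abs(traj$theta - th))],
    numeric(1)
  )
  m1 <- bin_events(tibble::tibble(cell_id = "c1", t0 = t_at), traj, geom)
  expect_true(all(m1$count == 1))
})

test_that("circular smoothing is symmetric, uniform-preserving and matches the oracle", {
  geom <- track_geometry()
  delta <- c(rep(0, 7), 1, rep(0, 12))
  sm <- smooth_normalize(make_map(NA)[0, ] |>
    dplyr::bind_rows(tibble::tibble(
      cell_id = "c1", bin = 1:20, count = delta
    )), sigma_bins = 1.25)$smoothed
  expect_equal(max(sm), 1)
  expect_equal(which.max(sm), 8)
  for (j in 1:6) {
    expect_equal(sm[((8 - j - 1) %% 20) + 1], sm[((8 + j - 1) %% 20) + 1],
      tolerance = 1e-12
    )
  }

  unif <- smooth_normalize(
    tibble::tibble(cell_id = "c1", bin = 1:20, count = rep(3, 20)), 1.25
  )$smoothed
  expect_equal(unif, rep(1, 20), tolerance = 1e-12)

  set.seed(2)
  x <- rpois(20, 4)
  got <- smooth_normalize(
    tibble::tibble(cell_id = "c1", bin = 1:20, count = x), 1.25
  )$smoothed
  want <- oracle_smooth_circular(x, 1.25)
  expect_equal(got, want / max(want), tolerance = 1e-12)

  # two equal deltas 10 bins apart -> two identical bumps
  two <- smooth_normalize(
    tibble::tibble(
      cell_id = "c1", bin = 1:20,
      count = as.numeric(1:20 %in% c(3, 13))
    ), 1.25
  )$smoothed
  expect_equal(two[1:10], two[11:20], tolerance = 1e-12)
})

test_that("field detection applies the width rule on the circle", {
  geom <- track_geometry()
  # single 3-bin bump -> field of width 5 (run + 1 bin each side)
  sm <- rep(0.1, 20)
  sm[9:11] <- c(0.8, 1, 0.8)
  f <- detect_place_fields(make_map(sm), geom)
  expect_identical(nrow(f), 1L)
  expect_equal(f$width_bins, 5L)
  expect_equal(f$center_bin, 10L)
  expect_setequal(f$bins[[1]], 8:12)

  # 9-bin run expands to 11 > 20/2 -> excluded
  wide <- rep(0.1, 20)
  wide[5:13] <- 0.9
  expect_identical(nrow(detect_place_fields(make_map(wide), geom)), 0L)

  # two separated bumps -> two fields for the same cell
  two <- rep(0.05, 20)
  two[3] <- 1
  two[14:15] <- 0.9
  f2 <- detect_place_fields(make_map(two), geom)
  expect_identical(nrow(f2), 2L)
  expect_identical(f2$cell_id, c("c1", "c1"))

  # everything above threshold -> whole-circle run fails the width test
  expect_identical(
    nrow(detect_place_fields(make_map(rep(0.9, 20)), geom)), 0L
  )

  # a run wrapping the origin keeps a contiguous circular interval
  wrap <- rep(0.1, 20)
  wrap[c(20, 1, 2)] <- 1
  fw <- detect_place_fields(make_map(wrap), geom)
  expect_identical(nrow(fw), 1L)
  expect_setequal(fw$bins[[1]], c(19, 20, 1, 2, 3))
  expect_true(fw$center_bin %in% c(20, 1, 2))
})

test_that("field centroids follow a rotation of the whole session by one bin", {
  ses <- fixture_recovery_session()
  geom <- ses$geometry
  shift <- 2 * pi / geom$n_bins
  traj_rot <- ses$trajectory
  traj_rot$theta <- (traj_rot$theta + shift) %% (2 * pi)
  traj_rot$x <- geom$radius * cos(traj_rot$theta)
  traj_rot$y <- geom$radius * sin(traj_rot$theta)

  # an event whose angle falls exactly on a bin boundary can legitimately
  # resolve to different bins before and after the floating-point rotation;
  # the equivariance property concerns interior events, so boundary-grazing
  # events are excluded from the comparison set
  dth <- diff(ses$trajectory$theta)
  dth <- dth - 2 * pi * round(dth / (2 * pi))
  unwrapped <- ses$trajectory$theta[1] + cumsum(c(0, dth))
  th_ev <- approx(ses$trajectory$t, unwrapped,
    xout = ses$events$t0, rule = 2
  )$y %% (2 * pi)
  frac <- (th_ev / (2 * pi) * geom$n_bins) %% 1
  interior <- pmin(frac, 1 - frac) > 1e-3
  events <- ses$events[interior, ]

  m1 <- spatial_event_map(events, ses$trajectory, geom)
  m2 <- spatial_event_map(events, traj_rot, geom)
  f1 <- detect_place_fields(m1, geom)
  f2 <- detect_place_fields(m2, geom)
  expect_identical(nrow(f1), nrow(f2))
  j <- dplyr::inner_join(
    dplyr::select(f1, "cell_id", "field_id", c1 = "center"),
    dplyr::select(f2, "cell_id", "field_id", c2 = "center"),
    by = c("cell_id", "field_id")
  )
  d <- ((j$c2 - j$c1 - 1 + 10) %% 20) - 10
  expect_true(all(abs(d) < 1e-9))
})

test_that("attendance epochs follow track geometry", {
  geom <- track_geometry()
  field <- tibble::tibble(
    cell_id = "c1", field_id = 1L, center = 10, center_bin = 10L,
    width_bins = 5L, start_bin = 8L, bins = list(8:12)
  )
  # constant-speed full laps: one epoch per lap
  traj <- fixture_lapping_trajectory(duration = 300, lap_time = 50)
  att <- field_attendances(traj, field, geom)
  expect_identical(nrow(att), 6L)
  expect_equal(att$visit, 1:6)
  expect_true(all(att$t_enter < att$t_exit))
  expect_true(all(diff(att$t_enter) > 0))
  # flanks tile the session: each flank ends where the next visit starts
  expect_equal(att$flank_end[-6], att$t_enter[-1])

  # a mouse sitting inside the field the whole session: a single epoch
  sit <- tibble::tibble(
    t = seq(0, 100, by = 0.05), theta = (9.5 - 0.5) * 2 * pi / 20,
    x = 1, y = 1
  )
  att_sit <- field_attendances(sit, field, geom)
  expect_identical(nrow(att_sit), 1L)
  expect_equal(att_sit$t_enter, 0)

  # never entering the field: no epochs
  away <- tibble::tibble(
    t = seq(0, 100, by = 0.05), theta = 0, x = 1, y = 0
  )
  expect_identical(nrow(field_attendances(away, field, geom)), 0L)
})

test_that("brief out-of-field excursions are debounced into one visit", {
  geom <- track_geometry()
  field <- tibble::tibble(
    cell_id = "c1", field_id = 1L, center = 10, center_bin = 10L,
    width_bins = 5L, start_bin = 8L, bins = list(8:12)
  )
  inside <- (10 - 0.5) * 2 * pi / 20
  outside <- 0
  theta <- c(
    rep(inside, 100), rep(outside, 10), # 0.5 s excursion
    rep(inside, 100), rep(outside, 100), # 5 s excursion
    rep(inside, 100)
  )
  traj <- tibble::tibble(
    t = (seq_along(theta) - 1) / 20, theta = theta, x = 0, y = 0
  )
  att <- field_attendances(traj, field, geom, debounce = 1)
  expect_identical(nrow(att), 2L)
})

test_that("selectivity scores match the stated ratios and the oracle", {
  epoch <- tibble::tibble(
    cell_id = "c1", field_id = 1L, visit = 1L,
    t_enter = 10, t_exit = 20, flank_start = 0, flank_end = 35
  )
  score_of <- function(times) {
    ev <- tibble::tibble(cell_id = "c1", t0 = times)
    selectivity_scores(ev, epoch)$raw
  }
  expect_equal(score_of(c(11, 15, 19.999)), 1) # all events inside the visit
  expect_equal(score_of(c(12, 13, 2, 30)), 0.5) # 2 in, 2 in the flanks
  expect_equal(score_of(c(2, 30)), 0) # none inside
  expect_true(is.na(score_of(c(40, 50)))) # silent lap -> scoreless

  set.seed(3)
  for (i in 1:20) {
    times <- runif(15, 0, 40)
    expect_identical(
      score_of(times),
      oracle_selectivity(times, 10, 20, 0, 35)
    )
  }
})

test_that("tuning latency follows the three-relevant-epoch rule", {
  mk_scores <- function(raw, t_enter = seq_along(raw) * 10) {
    tibble::tibble(
      cell_id = "c1", field_id = 1L, visit = seq_along(raw),
      t_enter = t_enter, t_exit = t_enter + 5,
      flank_start = t_enter - 5, flank_end = t_enter + 10,
      n_in = NA_integer_, n_total = 1L, raw = raw
    )
  }
  # perfect from the first attendance
  lat <- tuning_latency(smooth_selectivity(mk_scores(c(1, 1, 1))))
  expect_true(lat$is_place_cell)
  expect_identical(lat$n_spec, 0L)
  expect_equal(lat$t_spec, 10)

  # never selective
  lat0 <- tuning_latency(smooth_selectivity(mk_scores(rep(0, 6))))
  expect_false(lat0$is_place_cell)
  expect_true(is.na(lat0$n_spec))

  # 8-vector against the independent brute-force oracle
  raw <- c(0, 0, 0, 0, 1, 1, 1, 1)
  sc <- smooth_selectivity(mk_scores(raw))
  expect_equal(sc$smoothed, oracle_smooth_reflect(raw, 1), tolerance = 1e-12)
  j <- oracle_first_run(oracle_smooth_reflect(raw, 1) > 0.5, 3)
  lat8 <- tuning_latency(sc)
  expect_identical(lat8$n_spec, j - 1L)
  expect_equal(lat8$t_spec, j * 10)

  # scoreless epochs are excluded from the smoothed sequence
  raw_na <- c(0.9, NA, 0.9, 0.9, 0)
  sc_na <- smooth_selectivity(mk_scores(raw_na))
  expect_true(is.na(sc_na$smoothed[2]))
  expect_equal(sc_na$smoothed[!is.na(raw_na)],
    oracle_smooth_reflect(raw_na[!is.na(raw_na)], 1),
    tolerance = 1e-12
  )
  lat_na <- tuning_latency(sc_na)
  # run of 3 relevant scored visits starts at visit 1 of the originals
  expect_identical(lat_na$n_spec, 0L)
})

test_that("raising any raw score never loses relevant epochs", {
  set.seed(4)
  base <- runif(10)
  mk <- function(raw) {
    tibble::tibble(
      cell_id = "c1", field_id = 1L, visit = seq_along(raw),
      t_enter = seq_along(raw) * 10, t_exit = seq_along(raw) * 10 + 5,
      flank_start = 0, flank_end = 100,
      n_in = NA_integer_, n_total = 1L, raw = raw
    )
  }
  n_rel <- function(raw) sum(smooth_selectivity(mk(raw))$relevant)
  for (i in seq_along(base)) {
    bumped <- base
    bumped[i] <- min(1, bumped[i] + 0.3)
    expect_gte(n_rel(bumped), n_rel(base))
  }
})

test_that("scores stay within [0, 1] on a full synthetic session", {
  ses <- fixture_recovery_session()
  ana <- analyze_place_fields(ses$events, ses$trajectory, ses$geometry)
  sc <- ana$scores
  expect_true(all(sc$raw >= 0 & sc$raw <= 1, na.rm = TRUE))
  expect_true(all(sc$smoothed >= -1e-12 & sc$smoothed <= 1 + 1e-12,
    na.rm = TRUE
  ))
  expect_identical(
    sc$relevant[!is.na(sc$smoothed)],
    (sc$smoothed > 0.5)[!is.na(sc$smoothed)]
  )
  # summary invariants
  s <- tidy(ana)
  expect_true(all(s$width_bins <= 10))
  expect_true(all(is.na(s$n_spec) | s$n_spec >= 0))
  expect_true(all(xor(is.na(s$n_spec), s$is_place_cell)))
})

test_that("immediate high-contrast place cells are recovered within one bin", {
  ses <- fixture_recovery_session()
  geom <- ses$geometry
  ana <- analyze_place_fields(ses$events, ses$trajectory, geom)
  s <- tidy(ana)
  truth <- true_center_bins(ses$cells, geom)
  errs <- vapply(unique(s$cell_id), function(cid) {
    min(center_error_bins(
      s$center[s$cell_id == cid],
      truth[match(cid, ses$cells$cell_id)], geom$n_bins
    ))
  }, numeric(1))
  expect_gte(length(errs), 18) # nearly all 20 cells detected
  expect_gte(mean(errs <= 1), 0.9)
})
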