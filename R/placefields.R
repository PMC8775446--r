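# Place-field detection and tuning-latency analysis: spatial event maps over
# the track's sectorial bins, field extraction from the smoothed normalized
# map, per-attendance selectivity scoring, and the three-relevant-epoch rule
# with tuning latency (n_spec in visits, t_spec in seconds).

# Interpolate angular position (unwrapped, then wrapped) at arbitrary times.
interp_theta <- function(traj, times) {
  wrap_angle(approx(traj$t, unwrap_angle(traj$theta), xout = times,
    rule = 2
  )$y)
}

#' Bin calcium events into sectorial track bins
#'
#' Assigns each event to the bin containing the animal's interpolated angular
#' position at the event onset and counts events per bin. Bins are half-open
#' sectors (see [angle_to_bin()]); the output contains every bin for every
#' cell present in `events`, including zero counts.
#'
#' @param events Event tibble with columns `cell_id` and `t0` (e.g. from
#'   [detect_events()]).
#' @param traj Trajectory tibble (`t`, `theta`).
#' @param geometry A [track_geometry()].
#' @return A tibble with columns `cell_id`, `bin`, `count`.
#' @export
bin_events <- function(events, traj, geometry) {
  dt <- median(diff(traj$t))
  if (nrow(events) > 0 &&
    (min(events$t0) < min(traj$t) - 1e-9 ||
      max(events$t0) > max(traj$t) + dt)) {
    abort("event times fall outside the trajectory time range")
  }
  if (nrow(events) == 0) {
    return(tibble(cell_id = character(0), bin = integer(0), count = integer(0)))
  }
  cells <- sort(unique(events$cell_id))
  grid <- tidyr::expand_grid(cell_id = cells, bin = seq_len(geometry$n_bins))
  ev <- mutate(events,
    bin = angle_to_bin(interp_theta(traj, .data$t0), geometry)
  )
  counts <- summarise(group_by(ev, .data$cell_id, .data$bin),
    count = dplyr::n(), .groups = "drop"
  )
  out <- left_join(grid, counts, by = c("cell_id", "bin"))
  mutate(out, count = ifelse(is.na(.data$count), 0L, .data$count))
}

#' Smooth and normalize a spatial event map
#'
#' Circular (wrap-around) Gaussian smoothing of the per-bin event counts with
#' `sigma_bins` in bin units, then division by the per-cell maximum so the
#' peak equals 1.
#'
#' @param map Tibble from [bin_events()] (`cell_id`, `bin`, `count`).
#' @param sigma_bins Gaussian sigma in bins.
#' @return The map with an added `smoothed` column in \[0, 1\].
#' @export
smooth_normalize <- function(map, sigma_bins = 1.25) {
  if (nrow(map) == 0) return(mutate(map, smoothed = numeric(0)))
  map <- arrange(map, .data$cell_id, .data$bin)
  out <- group_by(map, .data$cell_id)
  out <- mutate(out, smoothed = {
    s <- smooth_circular(.data$count, sigma_bins)
    m <- max(s)
    if (m > 0) s / m else s
  })
  ungroup(out)
}

#' Spatial event map: bin, smooth and normalize in one call
#'
#' @inheritParams bin_events
#' @inheritParams smooth_normalize
#' @return A tibble with columns `cell_id`, `bin`, `count`, `smoothed`.
#' @export
spatial_event_map <- function(events, traj, geometry, sigma_bins = 1.25) {
  smooth_normalize(bin_events(events, traj, geometry), sigma_bins)
}

# Maximal contiguous circular runs of above-threshold bins. Returns a list of
# integer vectors of bin indices (in circular order). If every bin is above
# threshold the single whole-circle run is returned.
circular_runs <- function(above) {
  n <- length(above)
  if (!any(above)) return(list())
  if (all(above)) return(list(seq_len(n)))
  # rotate so position 1 is below threshold, then ordinary run-length runs
  start <- which(!above)[1]
  rot <- c(start:n, seq_len(start - 1L))
  r <- rle(above[rot])
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  runs <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i]) runs[[length(runs) + 1L]] <- rot[begins[i]:ends[i]]
  }
  runs
}

#' Detect place fields in a smoothed spatial event map
#'
#' Finds maximal contiguous circular runs of bins whose smoothed, normalized
#' value exceeds `threshold`. Each run is one putative field: its centre is
#' the circular centroid of the run's bin-centre angles weighted by the
#' smoothed values, and its bin interval is the run expanded by one bin on
#' each side. Fields whose expanded width exceeds half the track are
#' discarded (an all-above-threshold map therefore yields no field). A cell
#' may own multiple fields.
#'
#' @param map Tibble from [spatial_event_map()] (needs `smoothed`).
#' @param geometry A [track_geometry()].
#' @param threshold Detection threshold on the normalized map.
#' @return A tibble with one row per field: `cell_id`, `field_id` (1-based
#'   within cell), `center` (continuous bin-unit position; bin centres sit at
#'   integers), `center_bin` (nearest bin), `width_bins`, `start_bin` and a
#'   `bins` list-column with the field's bin interval in circular order.
#' @export
detect_place_fields <- function(map, geometry, threshold = 0.5) {
  n <- geometry$n_bins
  stopifnot(!is.null(map$smoothed))
  res <- list()
  for (cid in unique(map$cell_id)) {
    sm <- arrange(filter(map, .data$cell_id == cid), .data$bin)$smoothed
    runs <- circular_runs(sm > threshold)
    fid <- 0L
    for (run in runs) {
      width <- length(run) + 2L
      if (width > n / 2) next
      lead_bin <- ((run[1] - 2L) %% n) + 1L
      trail_bin <- ((run[length(run)]) %% n) + 1L
      interval <- c(lead_bin, run, trail_bin)
      ang <- bin_center_angle(run, geometry)
      w <- sm[run]
      ctr_angle <- atan2(sum(w * sin(ang)), sum(w * cos(ang)))
      center <- wrap_angle(ctr_angle) / (2 * pi) * n + 0.5
      if (center >= n + 0.5) center <- center - n
      center_bin <- ((round(center) - 1) %% n) + 1
      fid <- fid + 1L
      res[[length(res) + 1L]] <- tibble(
        cell_id = cid, field_id = fid, center = center,
        center_bin = as.integer(center_bin), width_bins = width,
        start_bin = lead_bin, bins = list(as.integer(interval))
      )
    }
  }
  if (length(res) == 0) {
    return(tibble(
      cell_id = character(0), field_id = integer(0), center = numeric(0),
      center_bin = integer(0), width_bins = integer(0),
      start_bin = integer(0), bins = list()
    ))
  }
  bind_rows(res)
}

#' Attendance epochs of place fields
#'
#' For each field, the maximal time intervals during which the animal's
#' angular position lies inside the field's bin interval. Out-of-field
#' excursions shorter than `debounce` seconds do not split an epoch
#' (positional jitter at bin edges would otherwise fragment visits). Each
#' epoch carries its flanking out-of-field intervals: `flank_start` is the
#' exit time of the previous epoch (or session start) and `flank_end` the
#' entry time of the next (or session end).
#'
#' @param traj Trajectory tibble (`t`, `theta`).
#' @param fields Field tibble from [detect_place_fields()].
#' @param geometry A [track_geometry()].
#' @param debounce Minimum out-of-field gap, in seconds, that separates two
#'   visits.
#' @return A tibble with columns `cell_id`, `field_id`, `visit` (1-based),
#'   `t_enter`, `t_exit`, `flank_start`, `flank_end` (seconds; intervals are
#'   half-open).
#' @export
field_attendances <- function(traj, fields, geometry, debounce = 1) {
  fps <- 1 / median(diff(traj$t))
  session_end <- traj$t[nrow(traj)] + 1 / fps
  bins <- angle_to_bin(traj$theta, geometry)
  out <- list()
  for (i in seq_len(nrow(fields))) {
    inside <- bins %in% fields$bins[[i]]
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    enter <- traj$t[begins[r$values]]
    exit_idx <- ends[r$values]
    exit <- ifelse(exit_idx < nrow(traj), traj$t[exit_idx + 1L], session_end)
    if (length(enter) == 0) next
    # merge visits separated by out-of-field gaps shorter than debounce
    keep_e <- enter
    keep_x <- exit
    merged_e <- keep_e[1]
    merged_x <- keep_x[1]
    if (length(keep_e) > 1) {
      for (j in 2:length(keep_e)) {
        if (keep_e[j] - merged_x[length(merged_x)] < debounce) {
          merged_x[length(merged_x)] <- keep_x[j]
        } else {
          merged_e <- c(merged_e, keep_e[j])
          merged_x <- c(merged_x, keep_x[j])
        }
      }
    }
    k <- length(merged_e)
    out[[length(out) + 1L]] <- tibble(
      cell_id = fields$cell_id[i], field_id = fields$field_id[i],
      visit = seq_len(k), t_enter = merged_e, t_exit = merged_x,
      flank_start = c(0, merged_x[-k]),
      flank_end = c(merged_e[-1], session_end)
    )
  }
  if (length(out) == 0) {
    return(tibble(
      cell_id = character(0), field_id = integer(0), visit = integer(0),
      t_enter = numeric(0), t_exit = numeric(0),
      flank_start = numeric(0), flank_end = numeric(0)
    ))
  }
  bind_rows(out)
}

#' Per-attendance selectivity scores
#'
#' For each attendance epoch, the ratio of the cell's events inside the epoch
#' to its events in the epoch plus both flanking out-of-field intervals
#' (the surrounding lap). A score of 1 means the cell fired exclusively in
#' its field on that visit; 0 means it fired only outside. If the cell fired
#' nowhere on that lap (denominator 0) the score is undefined (`NA`): a
#' silent lap is evidence of inactivity, not of non-selectivity, and such
#' epochs are excluded from the smoothed sequence.
#'
#' @param events Event tibble (`cell_id`, `t0`).
#' @param attendance Attendance tibble from [field_attendances()].
#' @return The attendance tibble with added `n_in`, `n_total` and `raw`
#'   (in \[0, 1\] or `NA`).
#' @export
selectivity_scores <- function(events, attendance) {
  ev_by_cell <- split(events$t0, events$cell_id)
  n_in <- integer(nrow(attendance))
  n_tot <- integer(nrow(attendance))
  for (i in seq_len(nrow(attendance))) {
    tt <- ev_by_cell[[attendance$cell_id[i]]]
    if (is.null(tt)) {
      n_in[i] <- 0L
      n_tot[i] <- 0L
      next
    }
    n_in[i] <- sum(tt >= attendance$t_enter[i] & tt < attendance$t_exit[i])
    n_tot[i] <- sum(tt >= attendance$flank_start[i] & tt < attendance$flank_end[i])
  }
  mutate(attendance,
    n_in = n_in, n_total = n_tot,
    raw = ifelse(n_tot > 0, n_in / n_tot, NA_real_)
  )
}

#' Smooth selectivity-score sequences
#'
#' Gaussian smoothing (sigma in epoch-index units, reflective boundaries) of
#' each field's sequence of scored visits; `NA` (scoreless) visits are
#' excluded from the sequence before smoothing and stay `NA`. A visit is
#' `relevant` when its smoothed score exceeds `threshold`.
#'
#' @param scores Tibble from [selectivity_scores()].
#' @param sigma Gaussian sigma in epoch-index units.
#' @param threshold Relevance threshold on the smoothed score.
#' @return The scores tibble with added `smoothed` and `relevant` columns.
#' @export
smooth_selectivity <- function(scores, sigma = 1, threshold = 0.5) {
  scores <- arrange(scores, .data$cell_id, .data$field_id, .data$visit)
  out <- group_by(scores, .data$cell_id, .data$field_id)
  out <- mutate(out, smoothed = {
    sm <- rep(NA_real_, dplyr::n())
    ok <- !is.na(.data$raw)
    if (any(ok)) sm[ok] <- smooth_reflect(.data$raw[ok], sigma)
    sm
  })
  ungroup(mutate(out, relevant = .data$smoothed > threshold))
}

# Start position (in the retained, scored sequence) of the first run of at
# least min_run consecutive TRUEs; NA if none.
first_relevant_run <- function(relevant, min_run) {
  if (length(relevant) == 0) return(NA_integer_)
  r <- rle(relevant)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_run)
  if (length(hit) == 0) NA_integer_ else begins[hit[1]]
}

#' Classify place fields and compute tuning latency
#'
#' A putative field is a confirmed place field when its smoothed selectivity
#' sequence contains a run of at least `min_run` consecutive relevant visits
#' (consecutive within the retained, scored sequence). The tuning latency is
#' reported both as `n_spec` — the number of attendance epochs strictly
#' before the first epoch of that run (0 when the run starts at the first
#' visit) — and as `t_spec`, the entry time of that epoch in seconds.
#'
#' @param scores Tibble from [smooth_selectivity()].
#' @param min_run Minimum number of consecutive relevant visits.
#' @return One row per field: `cell_id`, `field_id`, `n_visits`, `n_scored`,
#'   `is_place_cell`, `n_spec`, `t_spec` (`NA` unless `is_place_cell`).
#' @export
tuning_latency <- function(scores, min_run = 3) {
  scores <- arrange(scores, .data$cell_id, .data$field_id, .data$visit)
  grp <- group_by(scores, .data$cell_id, .data$field_id)
  summarise(grp,
    n_visits = dplyr::n(),
    n_scored = sum(!is.na(.data$raw)),
    n_spec = {
      ok <- !is.na(.data$raw)
      j <- first_relevant_run(.data$relevant[ok], min_run)
      if (is.na(j)) NA_integer_ else .data$visit[ok][j] - 1L
    },
    t_spec = {
      ok <- !is.na(.data$raw)
      j <- first_relevant_run(.data$relevant[ok], min_run)
      if (is.na(j)) NA_real_ else .data$t_enter[ok][j]
    },
    .groups = "drop"
  ) %>%
    mutate(is_place_cell = !is.na(.data$n_spec)) %>%
    select(
      "cell_id", "field_id", "n_visits", "n_scored",
      "is_place_cell", "n_spec", "t_spec"
    )
}

#' Full place-field analysis of one session
#'
#' Chains [spatial_event_map()], [detect_place_fields()],
#' [field_attendances()], [selectivity_scores()], [smooth_selectivity()] and
#' [tuning_latency()] with the standard parameters.
#'
#' @param events Event tibble (`cell_id`, `t0`).
#' @param traj Trajectory tibble.
#' @param geometry A [track_geometry()].
#' @param sigma_bins Spatial smoothing sigma in bins.
#' @param map_threshold Field-detection threshold on the normalized map.
#' @param score_sigma Selectivity smoothing sigma in epochs.
#' @param score_threshold Relevance threshold on the smoothed score.
#' @param min_run Minimum consecutive relevant visits for a place field.
#' @param debounce Attendance debounce in seconds.
#' @return An object of class `pf_analysis`: a list with `map`, `fields`,
#'   `scores`, `summary` (fields joined with latency), `geometry`, `params`.
#'   `tidy()` returns the per-field summary; `glance()` one-row session
#'   statistics.
#' @export
analyze_place_fields <- function(events, traj, geometry,
                                 sigma_bins = 1.25, map_threshold = 0.5,
                                 score_sigma = 1, score_threshold = 0.5,
                                 min_run = 3, debounce = 1) {
  map <- spatial_event_map(events, traj, geometry, sigma_bins)
  fields <- detect_place_fields(map, geometry, map_threshold)
  attendance <- field_attendances(traj, fields, geometry, debounce)
  scores <- smooth_selectivity(
    selectivity_scores(events, attendance),
    score_sigma, score_threshold
  )
  latency <- tuning_latency(scores, min_run)
  summary <- left_join(
    select(fields, -"bins"), latency,
    by = c("cell_id", "field_id")
  )
  structure(
    list(
      map = map, fields = fields, scores = scores, summary = summary,
      geometry = geometry,
      params = list(
        sigma_bins = sigma_bins, map_threshold = map_threshold,
        score_sigma = score_sigma, score_threshold = score_threshold,
        min_run = min_run, debounce = debounce
      )
    ),
    class = "pf_analysis"
  )
}

#' @export
print.pf_analysis <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<pf_analysis> %d cells with events, %d fields, %d confirmed place fields (%d place cells)\n",
    g$n_cells, g$n_fields, g$n_place_fields, g$n_place_cells
  ))
  invisible(x)
}

#' @rdname analyze_place_fields
#' @param x A `pf_analysis` object.
#' @param ... Unused.
#' @export
tidy.pf_analysis <- function(x, ...) x$summary

#' @rdname analyze_place_fields
#' @export
glance.pf_analysis <- function(x, ...) {
  s <- x$summary
  pc <- filter(s, .data$is_place_cell)
  tibble(
    n_cells = length(unique(x$map$cell_id)),
    n_fields = nrow(s),
    n_place_fields = nrow(pc),
    n_place_cells = length(unique(pc$cell_id)),
    frac_single_field = if (nrow(pc) > 0) {
      mean(table(pc$cell_id) == 1)
    } else NA_real_,
    frac_first_attendance = if (nrow(pc) > 0) mean(pc$n_spec == 0) else NA_real_,
    mean_n_spec = if (nrow(pc) > 0) mean(pc$n_spec) else NA_real_,
    mean_t_spec = if (nrow(pc) > 0) mean(pc$t_spec) else NA_real_
  )
}
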