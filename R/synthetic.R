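# Synthetic sessions: trajectory, ground-truth place cells, spike trains and
# rendered calcium traces with known parameters, so every downstream stage can
# be validated by parameter recovery.

#' Circular track geometry
#'
#' Describes an elevated O-shaped circular track of the kind used for free
#' exploration experiments: an annulus given by its outer diameter and lane
#' width, divided into `n_bins` sectorial bins for spatial analysis.
#'
#' @param outer_diameter Outer diameter of the annulus in cm.
#' @param width Lane width in cm; must satisfy `outer_diameter > 2 * width`.
#' @param n_bins Number of sectorial bins (at least 4).
#' @return An object of class `track_geometry` with fields `outer_diameter`,
#'   `width`, `n_bins`, the centerline `radius` and `circumference` (cm), and
#'   `bin_width` (radians).
#' @examples
#' geom <- track_geometry() # 50 cm diameter, 5 cm lane, 20 bins
#' geom$circumference
#' @export
track_geometry <- function(outer_diameter = 50, width = 5, n_bins = 20L) {
  if (!(outer_diameter > 2 * width && width > 0)) {
    abort("invalid geometry: need outer_diameter > 2 * width > 0")
  }
  if (n_bins < 4) abort("n_bins must be at least 4")
  radius <- (outer_diameter - width) / 2
  structure(
    list(
      outer_diameter = outer_diameter,
      width = width,
      n_bins = as.integer(n_bins),
      radius = radius,
      circumference = 2 * pi * radius,
      bin_width = 2 * pi / n_bins
    ),
    class = "track_geometry"
  )
}

#' @export
print.track_geometry <- function(x, ...) {
  cat(sprintf(
    "<track_geometry> O-shaped track: %.0f cm outer diameter, %.0f cm lane, %d bins\n",
    x$outer_diameter, x$width, x$n_bins
  ))
  invisible(x)
}

#' Map angular position to a sectorial track bin
#'
#' Bins are 1-based, half-open sectors: bin `b` covers angles in
#' `[(b-1), b) * 2*pi / n_bins`.
#'
#' @param theta Angles in radians (any range; wrapped internally).
#' @param geometry A [track_geometry()].
#' @return Integer bin indices in `1:n_bins`.
#' @export
angle_to_bin <- function(theta, geometry) {
  n <- geometry$n_bins
  b <- floor(wrap_angle(theta) / (2 * pi) * n) + 1L
  pmin.int(as.integer(b), n) # guard wrap_angle(2*pi - eps) rounding
}

# Centre angle of each bin (radians).
bin_center_angle <- function(bin, geometry) {
  (bin - 0.5) * geometry$bin_width
}

#' Simulate a run-and-reverse trajectory on the circular track
#'
#' The animal runs along the track centerline at constant speed, reversing
#' direction as a Bernoulli event per second with probability `turn_prob`
#' (approximated per frame), with small smooth radial jitter inside the lane.
#' This emulates free exploration "in arbitrary directions": only angular
#' position matters downstream.
#'
#' @param geometry A [track_geometry()].
#' @param duration Session duration in seconds.
#' @param fps Frame rate in Hz.
#' @param mean_speed Running speed in cm/s. The default completes one lap in
#'   47 s, which yields roughly 19 laps in a 15-min session.
#' @param turn_prob Probability per second of reversing direction, in \[0, 1\].
#' @param radial_sd Standard deviation of the radial jitter in cm; jitter is
#'   clipped so the position stays inside the lane.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A tibble with columns `t` (s), `x`, `y` (cm), `theta` (radians in
#'   \[0, 2*pi)) and `speed` (cm/s), one row per frame.
#' @examples
#' traj <- simulate_trajectory(track_geometry(), duration = 60, seed = 1)
#' head(traj)
#' @export
simulate_trajectory <- function(geometry, duration = 900, fps = 20,
                                mean_speed = NULL, turn_prob = 0.02,
                                radial_sd = 0.8, seed = NULL) {
  if (duration <= 0 || fps <= 0) abort("duration and fps must be positive")
  if (turn_prob < 0 || turn_prob > 1) abort("turn_prob must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  mean_speed <- mean_speed %||% (geometry$circumference / 47)
  n <- as.integer(round(duration * fps))
  omega <- mean_speed / geometry$radius # rad/s

  # Reversal draws first so the reversal count is reproducible from the seed.
  u <- runif(n)
  direction <- cumprod(ifelse(u < turn_prob / fps, -1, 1))

  dtheta <- direction * omega / fps
  theta <- wrap_angle(cumsum(dtheta))

  # Smooth radial jitter: AR(1)-filtered Gaussian noise, clipped to the lane.
  z <- rnorm(n)
  jitter <- as.numeric(stats::filter(z, 0.95, method = "recursive"))
  s <- sd(jitter)
  if (is.na(s) || s == 0) s <- 1
  jitter <- jitter / s * radial_sd
  half_lane <- geometry$width / 2 - 0.25
  jitter <- pmin(pmax(jitter, -half_lane), half_lane)
  r <- geometry$radius + jitter

  tibble(
    t = (seq_len(n) - 1) / fps,
    x = r * cos(theta),
    y = r * sin(theta),
    theta = theta,
    speed = rep(mean_speed, n)
  )
}

#' Ground-truth place-cell population
#'
#' Builds a table of simulated cells with known tuning. Place cells fire as an
#' inhomogeneous Poisson process whose rate is a von Mises bump of width
#' `tuning_width` centred on `field_center`, scaled between `out_field_rate`
#' and `in_field_rate`. Before `onset_time` a place cell fires uniformly at
#' the spatial average of its tuned rate, which emulates delayed tuning
#' (tuning latency); non-place cells always fire uniformly.
#'
#' @param n_cells Number of cells.
#' @param prop_place Proportion of cells that are place cells.
#' @param centers `"tile"` spaces field centres evenly around the track,
#'   `"random"` draws them uniformly; or a numeric vector of angles.
#' @param tuning_width Bump width in radians (the von Mises concentration is
#'   `1 / tuning_width^2`).
#' @param in_field_rate,out_field_rate Event rates in events/s; must satisfy
#'   `in_field_rate > out_field_rate >= 0`.
#' @param onset_time Seconds after which firing becomes selective (scalar or
#'   per-cell vector).
#' @param seed Optional integer seed (used when `centers = "random"`).
#' @return A tibble with one row per cell: `cell_id`, `is_place_cell`,
#'   `field_center`, `tuning_width`, `in_field_rate`, `out_field_rate`,
#'   `onset_time`.
#' @export
place_cell_population <- function(n_cells, prop_place = 1, centers = "tile",
                                  tuning_width = 0.3, in_field_rate = 1,
                                  out_field_rate = 0.05, onset_time = 0,
                                  seed = NULL) {
  if (n_cells < 1) abort("n_cells must be positive")
  if (!(all(in_field_rate > out_field_rate) && all(out_field_rate >= 0))) {
    abort("need in_field_rate > out_field_rate >= 0")
  }
  if (any(tuning_width <= 0)) abort("tuning_width must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_place <- round(n_cells * prop_place)
  is_pc <- c(rep(TRUE, n_place), rep(FALSE, n_cells - n_place))
  if (is.numeric(centers)) {
    ctr <- rep_len(wrap_angle(centers), n_cells)
  } else if (identical(centers, "tile")) {
    ctr <- (seq_len(n_cells) - 1) / max(1, n_place) * 2 * pi
    ctr <- wrap_angle(ctr)
  } else if (identical(centers, "random")) {
    ctr <- runif(n_cells, 0, 2 * pi)
  } else {
    abort("centers must be 'tile', 'random' or a numeric vector of angles")
  }
  tibble(
    cell_id = sprintf("cell%03d", seq_len(n_cells)),
    is_place_cell = is_pc,
    field_center = ifelse(is_pc, ctr, NA_real_),
    tuning_width = rep_len(tuning_width, n_cells),
    in_field_rate = rep_len(in_field_rate, n_cells),
    out_field_rate = rep_len(out_field_rate, n_cells),
    onset_time = rep_len(onset_time, n_cells)
  )
}

# von Mises tuning profile: rate(theta) scaled between out and in rates.
tuned_rate <- function(theta, center, width, in_rate, out_rate) {
  kappa <- 1 / width^2
  out_rate + (in_rate - out_rate) * exp(kappa * (cos(theta - center) - 1))
}

# Spatial average of the tuned rate over a uniform occupancy:
# E[exp(kappa*(cos - 1))] = I0(kappa) * exp(-kappa).
mixture_rate <- function(center, width, in_rate, out_rate) {
  kappa <- 1 / width^2
  out_rate + (in_rate - out_rate) * besselI(kappa, 0, expon.scaled = TRUE)
}

#' Sample spike trains from ground-truth tuning
#'
#' Inhomogeneous Poisson sampling along the trajectory, approximated as one
#' Bernoulli draw per frame with probability `rate / fps`. Place cells use
#' their von Mises tuned rate after `onset_time` and the uniform mixture rate
#' before it; non-place cells use the mixture rate throughout.
#'
#' @param traj Trajectory tibble from [simulate_trajectory()].
#' @param cells Cell table from [place_cell_population()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `cell_id` and `t` (spike times in seconds,
#'   sorted within cell).
#' @export
sample_spikes <- function(traj, cells, seed = NULL) {
  if (nrow(cells) == 0) abort("cells must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  fps <- 1 / median(diff(traj$t))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    mix <- mixture_rate(
      cl$field_center %||% 0, cl$tuning_width,
      cl$in_field_rate, cl$out_field_rate
    )
    if (isTRUE(cl$is_place_cell)) {
      rate <- tuned_rate(
        traj$theta, cl$field_center, cl$tuning_width,
        cl$in_field_rate, cl$out_field_rate
      )
      rate[traj$t < cl$onset_time] <- mix
    } else {
      rate <- rep(mix, nrow(traj))
    }
    p <- rate / fps
    if (any(p > 1)) {
      warn("per-frame spike probability exceeds 1; rate is too high for fps")
      p <- pmin(p, 1)
    }
    fire <- runif(nrow(traj)) < p
    out[[i]] <- tibble(cell_id = cl$cell_id, t = traj$t[fire])
  }
  bind_rows(out)
}

#' Parameters of the calcium transient kernel and trace noise
#'
#' The transient kernel is `A * (1 - exp(-d/t_on)) * exp(-d/t_off)` for
#' `d = t - t0 >= 0` (fast rise, slow exponential decay). Amplitudes are
#' drawn per spike from a log-normal with mean `amplitude_mean` and
#' coefficient of variation `amplitude_cv`; i.i.d. Gaussian noise of sd
#' `noise_sigma` is added to the summed transients.
#'
#' @param t_on Rise time constant in seconds (> 0).
#' @param t_off Decay time constant in seconds (>= `t_on`).
#' @param amplitude_mean Mean spike amplitude in trace units.
#' @param amplitude_cv Coefficient of variation of the amplitude.
#' @param noise_sigma Additive Gaussian noise sd in trace units. The default
#'   0.062 gives peak SNR 10 for a unit-amplitude transient with the default
#'   kernel.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(t_on = 0.1, t_off = 0.6, amplitude_mean = 1,
                          amplitude_cv = 0.3, noise_sigma = 0.062) {
  if (t_on <= 0 || t_off < t_on) abort("need t_off >= t_on > 0")
  if (noise_sigma < 0) abort("noise_sigma must be non-negative")
  structure(
    list(
      t_on = t_on, t_off = t_off, amplitude_mean = amplitude_mean,
      amplitude_cv = amplitude_cv, noise_sigma = noise_sigma
    ),
    class = "kernel_params"
  )
}

#' Peak time and peak value of the transient kernel
#'
#' The kernel `(1 - exp(-d/t_on)) * exp(-d/t_off)` attains its maximum at
#' `d = t_on * log(1 + t_off/t_on)`; the peak value times the amplitude is
#' the realised transient height, which defines the SNR relative to
#' `noise_sigma`.
#'
#' @param t_on,t_off Kernel time constants in seconds.
#' @return A list with `t_peak` (s) and `peak` (unit-amplitude peak value).
#' @export
kernel_peak <- function(t_on = 0.1, t_off = 0.6) {
  tp <- t_on * log(1 + t_off / t_on)
  list(t_peak = tp, peak = (1 - exp(-tp / t_on)) * exp(-tp / t_off))
}

#' Render calcium traces from spike trains
#'
#' Each spike adds one transient kernel with a log-normal amplitude;
#' transients sum linearly; Gaussian noise is added; the baseline is 0.
#'
#' @param spikes Spike tibble (`cell_id`, `t`) from [sample_spikes()].
#' @param kernel A [kernel_params()].
#' @param fps Frame rate in Hz.
#' @param duration Session duration in seconds; all spikes must fall before
#'   it.
#' @param cell_ids Cells to render (rows of the output); defaults to the
#'   cells present in `spikes`. Cells without spikes get pure-noise traces.
#' @param seed Optional integer seed.
#' @return A numeric matrix, cells x frames, with `rownames` the cell ids and
#'   an `fps` attribute.
#' @export
render_traces <- function(spikes, kernel = kernel_params(), fps = 20,
                          duration, cell_ids = NULL, seed = NULL) {
  if (nrow(spikes) > 0 && any(spikes$t >= duration)) {
    abort("all spike times must be strictly less than duration")
  }
  if (!is.null(seed)) set.seed(seed)
  cell_ids <- cell_ids %||% sort(unique(spikes$cell_id))
  n <- as.integer(round(duration * fps))
  tgrid <- (seq_len(n) - 1) / fps
  support <- round(20 * kernel$t_off * fps) # kernel < 1e-8 beyond 20 decay constants
  cv <- kernel$amplitude_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(kernel$amplitude_mean) - sdlog^2 / 2

  traces <- matrix(0, length(cell_ids), n,
    dimnames = list(cell_ids, NULL)
  )
  for (ci in seq_along(cell_ids)) {
    st <- spikes$t[spikes$cell_id == cell_ids[ci]]
    y <- numeric(n)
    if (length(st) > 0) {
      amps <- if (cv > 0) rlnorm(length(st), meanlog, sdlog) else
        rep(kernel$amplitude_mean, length(st))
      for (si in seq_along(st)) {
        i0 <- floor(st[si] * fps) + 1L
        idx <- i0:min(n, i0 + support)
        y[idx] <- y[idx] +
          calcium_kernel(tgrid[idx], st[si], amps[si], kernel$t_on, kernel$t_off)
      }
    }
    if (kernel$noise_sigma > 0) y <- y + rnorm(n, 0, kernel$noise_sigma)
    traces[ci, ] <- y
  }
  attr(traces, "fps") <- fps
  traces
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper chaining [simulate_trajectory()], [sample_spikes()]
#' and [render_traces()] under a single seed.
#'
#' @param cells Cell table from [place_cell_population()].
#' @param geometry A [track_geometry()].
#' @param duration Session duration in seconds.
#' @param fps Frame rate in Hz.
#' @param kernel A [kernel_params()].
#' @param turn_prob,mean_speed Passed to [simulate_trajectory()].
#' @param seed Integer seed for the whole session.
#' @return A list of class `pf_session` with elements `trajectory`, `spikes`,
#'   `traces`, `cells`, `geometry` and `fps`.
#' @export
simulate_session <- function(cells, geometry = track_geometry(),
                             duration = 900, fps = 20,
                             kernel = kernel_params(), turn_prob = 0.02,
                             mean_speed = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traj <- simulate_trajectory(geometry, duration, fps,
    mean_speed = mean_speed, turn_prob = turn_prob
  )
  spikes <- sample_spikes(traj, cells)
  traces <- render_traces(spikes, kernel, fps, duration,
    cell_ids = cells$cell_id
  )
  structure(
    list(
      trajectory = traj, spikes = spikes, traces = traces,
      cells = cells, geometry = geometry, fps = fps
    ),
    class = "pf_session"
  )
}
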