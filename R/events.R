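# Calcium-event detection: robust MAD thresholding of each trace, then
# iterative bounded Levenberg-Marquardt fitting of a two-exponential transient
# model at every upward threshold crossing, with local subtraction of accepted
# fits so overlapping transients can each be scored.

#' Sensor profile for event detection
#'
#' Slow indicators (GCaMP6s, NCaMP7, FGCaMP7) use a 4-MAD threshold and a
#' 0.5 s lower bound on the decay constant; the fast GCaMP7f uses 5 MADs and
#' a 0.2 s bound.
#'
#' @param sensor One of `"gcamp6s"`, `"gcamp7f"`, `"ncamp7"`, `"fgcamp7"`.
#' @param mad_multiplier,t_off_floor Optional overrides of the class defaults.
#' @return An object of class `sensor_profile` with fields `name`,
#'   `speed_class`, `mad_multiplier` and `t_off_floor` (seconds).
#' @examples
#' sensor_profile("gcamp7f")
#' @export
sensor_profile <- function(sensor = c("gcamp6s", "gcamp7f", "ncamp7", "fgcamp7"),
                           mad_multiplier = NULL, t_off_floor = NULL) {
  sensor <- match.arg(sensor)
  speed_class <- if (sensor == "gcamp7f") "fast" else "slow"
  mad_multiplier <- mad_multiplier %||% if (speed_class == "fast") 5 else 4
  t_off_floor <- t_off_floor %||% if (speed_class == "fast") 0.2 else 0.5
  if (t_off_floor <= 0) abort("t_off_floor must be positive")
  structure(
    list(
      name = sensor, speed_class = speed_class,
      mad_multiplier = mad_multiplier, t_off_floor = t_off_floor
    ),
    class = "sensor_profile"
  )
}

#' @export
print.sensor_profile <- function(x, ...) {
  cat(sprintf(
    "<sensor_profile> %s (%s): threshold %g MADs, t_off >= %g s\n",
    x$name, x$speed_class, x$mad_multiplier, x$t_off_floor
  ))
  invisible(x)
}

#' Calcium transient model
#'
#' The two-exponential transient `f(t) = A * (1 - exp(-d/t_on)) *
#' exp(-d/t_off)` for `d = t - t0 >= 0` and 0 before onset. `A` is the
#' multiplicative prefactor, not the realised peak (see [kernel_peak()]).
#'
#' @param t Time points in seconds.
#' @param t0 Onset time in seconds.
#' @param A Amplitude prefactor.
#' @param t_on,t_off Rise and decay time constants in seconds.
#' @return Model values at `t`.
#' @export
calcium_kernel <- function(t, t0 = 0, A = 1, t_on = 0.1, t_off = 0.6) {
  d <- t - t0
  y <- numeric(length(t))
  pos <- d > 0
  y[pos] <- A * (1 - exp(-d[pos] / t_on)) * exp(-d[pos] / t_off)
  y
}

#' Robust event threshold from the raw median absolute deviation
#'
#' Returns `median(trace) + multiplier * median(|trace - median(trace)|)`.
#' The MAD is raw (no normal-consistency factor). A constant trace has MAD 0;
#' the threshold then equals the constant and a warning is raised.
#'
#' @param trace Numeric fluorescence series (length >= 2).
#' @param multiplier MAD multiplier (4 for slow sensors, 5 for fast).
#' @return The threshold in trace units.
#' @examples
#' mad_threshold(c(1, 2, 3, 4, 5), 4) # median 3, MAD 1 -> 7
#' @export
mad_threshold <- function(trace, multiplier = 4) {
  if (length(trace) < 2) abort("trace must have length >= 2")
  med <- median(trace)
  mad_raw <- median(abs(trace - med))
  if (mad_raw == 0) {
    warn("trace MAD is zero (constant or near-constant trace); threshold is degenerate")
  }
  med + multiplier * mad_raw
}

# Raw MAD alone (dispersion scale used for the re-rise truncation rule).
raw_mad <- function(trace) median(abs(trace - median(trace)))

#' Fit one calcium transient near a threshold crossing
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of
#' [calcium_kernel()] over a local window around `t0_init`: from
#' `window_before` seconds before the crossing to `4 * t_off_floor` after,
#' truncated at trace ends. The decay constant is bounded below by the sensor
#' `t_off_floor` and the rise constant above by `t_on_max` (rise times of
#' GECI transients are fast; an unbounded rise lets one kernel absorb two
#' overlapping transients). Goodness of fit is the coefficient of
#' determination R^2 over the window.
#'
#' @param trace Numeric trace for one cell; time of sample `i` is
#'   `(i - 1) / fps`.
#' @param fps Frame rate in Hz.
#' @param t0_init Initial onset guess in seconds (typically the threshold
#'   crossing time).
#' @param profile A [sensor_profile()].
#' @param window_before Seconds of trace included before `t0_init`.
#' @param window_end Optional index of the last sample of the fit window
#'   (used by [detect_events()] to stop before the next transient's rise).
#' @param t_on_max Upper bound on the rise constant in seconds.
#' @param t_off_max Upper bound on the decay constant in seconds; bounds keep
#'   one fitted kernel from absorbing a run of overlapping transients.
#' @return A list of class `calcium_fit`: `t0`, `A`, `t_on`, `t_off`, `gof`,
#'   `converged`, `n` (window length). Optimizer failure gives
#'   `converged = FALSE` and `gof = NA` (the candidate event is simply not
#'   accepted; no error is raised).
#' @export
fit_event <- function(trace, fps, t0_init, profile = sensor_profile(),
                      window_before = 0.5, window_end = NULL,
                      t_on_max = 0.3, t_off_max = 5 * profile$t_off_floor) {
  n <- length(trace)
  tgrid <- (seq_len(n) - 1) / fps
  i_lo <- max(1L, floor((t0_init - window_before) * fps) + 1L)
  i_hi <- window_end %||% min(n, floor(t0_init * fps) + 1L +
    as.integer(round(4 * profile$t_off_floor * fps)))
  i_hi <- min(n, i_hi)
  st <- tgrid[i_lo:i_hi]
  sy <- trace[i_lo:i_hi]
  failed <- list(
    t0 = NA_real_, A = NA_real_, t_on = NA_real_, t_off = NA_real_,
    gof = NA_real_, converged = FALSE, n = length(sy)
  )
  class(failed) <- "calcium_fit"
  if (length(sy) < 6) return(failed)

  # data-driven starting values: decay constant from the 1/e fall time after
  # the peak, amplitude from the peak height corrected by the kernel peak
  # factor (A is a prefactor, not the realised peak)
  med <- median(trace)
  pk_idx <- which.max(sy)
  pk_height <- max(sy[pk_idx] - med, 1e-3)
  t_off_start <- profile$t_off_floor
  if (pk_idx < length(sy)) {
    fall <- which(sy[pk_idx:length(sy)] - med < pk_height / exp(1))[1]
    if (!is.na(fall) && fall > 1) {
      t_off_start <- min(max((fall - 1) / fps, profile$t_off_floor), t_off_max)
    }
  }
  t_on_start <- min(0.1, t_on_max / 2)
  start <- c(
    t0 = t0_init - 1 / fps,
    A = pk_height / kernel_peak(t_on_start, t_off_start)$peak,
    t_on = t_on_start,
    t_off = t_off_start
  )
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      lower = c(max(t0_init - window_before, 0), 1e-6, 1e-3, profile$t_off_floor),
      upper = c(min(t0_init + 0.2, tgrid[n]), Inf, t_on_max, t_off_max),
      fn = function(p) sy - calcium_kernel(st, p[1], p[2], p[3], p[4]),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed)
  p <- fit$par
  ss_tot <- sum((sy - mean(sy))^2)
  gof <- if (ss_tot > 0) 1 - sum(fit$fvec^2) / ss_tot else NA_real_
  structure(
    list(
      t0 = unname(p[1]), A = unname(p[2]), t_on = unname(p[3]),
      t_off = unname(p[4]), gof = gof, converged = TRUE, n = length(sy)
    ),
    class = "calcium_fit"
  )
}

# Detection loop for a single trace. Returns a tibble of accepted events.
detect_events_cell <- function(trace, fps, profile, gof_min, t_on_max,
                               t_off_max, refractory_frames, rise_eps_mads,
                               max_passes) {
  n <- length(trace)
  threshold <- suppressWarnings(mad_threshold(trace, profile$mad_multiplier))
  mad0 <- raw_mad(trace)
  rise_eps <- max(rise_eps_mads * mad0, 1e-9)
  win_after <- as.integer(round(4 * profile$t_off_floor * fps))
  work <- trace
  t0s <- numeric(0)
  rows <- list()

  for (pass in seq_len(max_passes)) {
    added <- 0L
    above <- work > threshold
    queue <- which(above & !c(FALSE, above[-n]))
    qi <- 1L
    while (qi <= length(queue)) {
      ci <- queue[qi]
      qi <- qi + 1L
      tc <- (ci - 1) / fps
      if (length(t0s) && any(abs(t0s - tc) < refractory_frames / fps)) next
      i_end <- min(n, ci + win_after)

      # Truncate the window at the first distinct re-rise after the first
      # peak, so a following overlapping transient is excluded from the fit.
      seg <- work[ci:i_end]
      valley <- NA_integer_
      if (length(seg) >= 3) {
        is_peak <- seg >= c(seg[-1], -Inf) & seg >= c(Inf, seg[-length(seg)]) &
          seg > threshold
        pk <- which(is_peak)[1]
        if (!is.na(pk) && pk < length(seg)) {
          run_min <- Inf
          v_idx <- NA_integer_
          for (j in (pk + 1L):length(seg)) {
            if (seg[j] < run_min) {
              run_min <- seg[j]
              v_idx <- j
            }
            if (seg[j] - run_min > rise_eps) {
              valley <- ci + v_idx - 1L
              i_end <- valley
              break
            }
          }
        }
      }

      # Whatever this fit's outcome, a detected re-rise is the next
      # transient's onset candidate: without it, one rejected fit would
      # leave the rest of a supra-threshold burst unscanned (the trace
      # never re-crosses the threshold from below inside a burst).
      if (!is.na(valley) && valley < n && !(valley %in% queue)) {
        queue <- append(queue, valley, after = qi - 1L)
      }
      f <- fit_event(work, fps, tc,
        profile = profile, window_end = i_end, t_on_max = t_on_max,
        t_off_max = t_off_max
      )
      if (!isTRUE(f$converged) || is.na(f$gof)) next
      if (f$gof >= gof_min && f$A > 0) {
        rows[[length(rows) + 1L]] <- tibble(
          t0 = f$t0, A = f$A, t_on = f$t_on, t_off = f$t_off, gof = f$gof
        )
        t0s <- c(t0s, f$t0)
        sub_idx <- max(1L, floor(f$t0 * fps)):n
        work[sub_idx] <- work[sub_idx] -
          calcium_kernel((sub_idx - 1) / fps, f$t0, f$A, f$t_on, f$t_off)
        added <- added + 1L
      }
    }
    if (added == 0L) break
  }
  if (length(rows) == 0) {
    return(tibble(
      t0 = numeric(0), A = numeric(0), t_on = numeric(0),
      t_off = numeric(0), gof = numeric(0)
    ))
  }
  arrange(bind_rows(rows), t0)
}

#' Detect calcium events in fluorescence traces
#'
#' Scans each trace for upward crossings of its MAD threshold (computed once
#' from the original trace), fits a transient at each crossing with
#' [fit_event()], accepts fits with R^2 at or above `gof_min`, subtracts each
#' accepted fit from a working copy, and re-scans until no further events are
#' accepted. Crossings closer than `refractory_frames` frames to an accepted
#' onset are skipped.
#'
#' @param traces Cells x frames numeric matrix (rownames are cell ids), or a
#'   single numeric trace.
#' @param sensor Sensor name passed to [sensor_profile()], or a ready-made
#'   profile object.
#' @param fps Frame rate in Hz; defaults to the matrix's `fps` attribute.
#' @param gof_min Minimum goodness of fit for acceptance (events with R^2
#'   exactly at the threshold are accepted).
#' @param t_on_max Upper bound on the rise constant in seconds.
#' @param t_off_max Upper bound on the decay constant in seconds; defaults to
#'   `5 * t_off_floor` for the chosen sensor.
#' @param refractory_frames Minimum separation between fitted onsets, frames.
#' @param rise_eps_mads Re-rise sensitivity for window truncation, in raw
#'   MADs of the trace.
#' @param max_passes Safety cap on subtraction re-scans per trace.
#' @return A tibble with columns `cell_id`, `t0` (s), `A`, `t_on` (s),
#'   `t_off` (s), `gof`, sorted by `cell_id` then `t0`. Eventless traces
#'   contribute no rows.
#' @examples
#' tr <- calcium_kernel(seq(0, 10, by = 0.05), t0 = 2, A = 5)
#' detect_events(tr, fps = 20)
#' @export
detect_events <- function(traces, sensor = "gcamp6s",
                          fps = attr(traces, "fps"),
                          gof_min = 0.8, t_on_max = 0.3, t_off_max = NULL,
                          refractory_frames = 2, rise_eps_mads = 3.5,
                          max_passes = 60) {
  if (is.null(fps)) abort("fps is required (no fps attribute on traces)")
  profile <- if (inherits(sensor, "sensor_profile")) sensor else
    sensor_profile(sensor)
  t_off_max <- t_off_max %||% 5 * profile$t_off_floor
  if (is.null(dim(traces))) {
    traces <- matrix(traces, nrow = 1, dimnames = list("cell1", NULL))
  }
  if (any(!is.finite(traces))) abort("traces must be finite")
  ids <- rownames(traces) %||% sprintf("cell%03d", seq_len(nrow(traces)))
  res <- vector("list", nrow(traces))
  for (i in seq_len(nrow(traces))) {
    ev <- detect_events_cell(
      traces[i, ], fps, profile, gof_min, t_on_max, t_off_max,
      refractory_frames, rise_eps_mads, max_passes
    )
    if (nrow(ev) > 0) ev$cell_id <- ids[i]
    res[[i]] <- ev
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(
      cell_id = character(0), t0 = numeric(0), A = numeric(0),
      t_on = numeric(0), t_off = numeric(0), gof = numeric(0)
    ))
  }
  arrange(select(out, "cell_id", "t0", "A", "t_on", "t_off", "gof"),
    .data$cell_id, .data$t0
  )
}
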