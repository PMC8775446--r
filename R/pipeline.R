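# End-to-end session orchestration: one configuration object holding the
# standard constants of every stage, and run_session() chaining event
# detection -> place fields -> manifold embedding -> residual variance into
# a serializable report.

#' Session analysis configuration
#'
#' Collects every tunable parameter of the pipeline with its standard value:
#' spatial map smoothing sigma 1.25 bins and threshold 0.5; selectivity
#' smoothing sigma 1 epoch, relevance threshold 0.5 and three-consecutive-
#' relevant-epoch rule; manifold window `w = 8` frames, minimum 5 events per
#' cell, 2-D embedding, 250 s sliding window.
#'
#' @param sensor Sensor name (see [sensor_profile()]).
#' @param fps Frame rate in Hz.
#' @param sigma_bins,map_threshold Spatial-map parameters.
#' @param score_sigma,score_threshold,min_run Selectivity parameters.
#' @param debounce Attendance debounce in seconds.
#' @param w,min_events,k,m Manifold parameters; `k = NULL` selects the
#'   smallest viable candidate via [choose_k()].
#' @param rv_window,rv_stride Sliding residual-variance window and stride in
#'   seconds.
#' @param compute_sliding_rv Whether [run_session()] also computes the
#'   sliding residual-variance series.
#' @return A list of class `session_config`.
#' @export
session_config <- function(sensor = "gcamp6s", fps = 20,
                           sigma_bins = 1.25, map_threshold = 0.5,
                           score_sigma = 1, score_threshold = 0.5,
                           min_run = 3, debounce = 1,
                           w = 8, min_events = 5, k = NULL, m = 2,
                           rv_window = 250, rv_stride = 25,
                           compute_sliding_rv = FALSE) {
  cfg <- list(
    sensor = sensor, fps = fps, sigma_bins = sigma_bins,
    map_threshold = map_threshold, score_sigma = score_sigma,
    score_threshold = score_threshold, min_run = min_run,
    debounce = debounce, w = w, min_events = min_events, k = k, m = m,
    rv_window = rv_window, rv_stride = rv_stride,
    compute_sliding_rv = compute_sliding_rv
  )
  stopifnot(fps > 0, sigma_bins > 0, w >= 1, min_events >= 0, m >= 1)
  structure(cfg, class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, format(x[[nm]] %||% "auto")))
  }
  invisible(x)
}

#' Run the full analysis pipeline on one session
#'
#' Detects calcium events, analyses place fields and tuning latency, embeds
#' population activity with Laplacian eigenmaps and measures the residual
#' variance of the track-geometry reconstruction. All stages are
#' deterministic, so reruns on identical inputs yield identical reports.
#'
#' @param traces Cells x frames trace matrix (with `fps` attribute or
#'   `config$fps`).
#' @param traj Trajectory tibble.
#' @param geometry A [track_geometry()].
#' @param config A [session_config()].
#' @param events Optional precomputed event tibble (skips detection).
#' @return An object of class `session_report`: list with `config`,
#'   `config_hash`, `events`, `analysis` (a `pf_analysis`), `embedding`,
#'   `rv`, `sliding_rv` (optional) and `stats` (the one-row summary also
#'   returned by `glance()`).
#' @export
run_session <- function(traces, traj, geometry = track_geometry(),
                        config = session_config(), events = NULL) {
  fps <- attr(traces, "fps") %||% config$fps
  if (is.null(events)) {
    events <- detect_events(traces, sensor = config$sensor, fps = fps)
  }
  analysis <- analyze_place_fields(
    events, traj, geometry,
    sigma_bins = config$sigma_bins, map_threshold = config$map_threshold,
    score_sigma = config$score_sigma,
    score_threshold = config$score_threshold,
    min_run = config$min_run, debounce = config$debounce
  )

  embedding <- NULL
  rv <- NULL
  srv <- NULL
  if (nrow(events) == 0) {
    warn("no calcium events detected; manifold stage skipped")
  } else {
    manifold <- tryCatch(
      {
        activity <- prepare_activity(traces, events,
          w = config$w,
          min_events = config$min_events, fps = fps
        )
        k <- config$k %||% choose_k(activity)
        g <- knn_graph(activity, k)
        emb <- laplacian_eigenmaps(g, config$m)
        pos <- window_positions(traj, config$w)
        list(emb = emb, rv = residual_variance(pos, emb),
          activity = activity, pos = pos, k = k
        )
      },
      error = function(e) {
        warn(paste("manifold stage skipped:", conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(manifold)) {
      embedding <- manifold$emb
      rv <- manifold$rv
      if (isTRUE(config$compute_sliding_rv)) {
        srv <- sliding_rv(manifold$activity, manifold$pos,
          window = config$rv_window, stride = config$rv_stride,
          k = manifold$k, m = config$m
        )
      }
    }
  }

  ana_stats <- glance(analysis)
  stats <- mutate(ana_stats,
    n_events = nrow(events),
    rv = if (!is.null(rv)) rv$rv else NA_real_,
    k = if (!is.null(embedding)) embedding$k else NA_integer_
  )
  structure(
    list(
      config = config, config_hash = rlang::hash(unclass(config)),
      events = events, analysis = analysis, embedding = embedding,
      rv = rv, sliding_rv = srv, stats = stats
    ),
    class = "session_report"
  )
}

#' @export
print.session_report <- function(x, ...) {
  cat("<session_report>\n")
  print(as.data.frame(x$stats), row.names = FALSE)
  invisible(x)
}

#' @rdname run_session
#' @param x A `session_report`.
#' @param ... Unused.
#' @export
glance.session_report <- function(x, ...) x$stats

#' @rdname run_session
#' @export
tidy.session_report <- function(x, ...) tidy(x$analysis)

#' Serialize a session report to JSON
#'
#' Writes the summary statistics, per-field table and (when present) the
#' global residual variance, keyed by the configuration hash so outputs are
#' traceable to their parameters.
#'
#' @param report A `session_report`.
#' @param path File path.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    config = unclass(report$config),
    config_hash = report$config_hash,
    stats = as.list(report$stats),
    fields = report$analysis$summary,
    rv = if (!is.null(report$rv)) report$rv$rv else NULL
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}
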