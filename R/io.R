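# Plain-text readers and writers for the pipeline's tables. All tables
# round-trip through CSV; the trace matrix stores its frame rate in a
# '# fps: <value>' comment line so a file is self-describing.

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Write / read a trace matrix as wide CSV
#'
#' One row per cell (`cell_id`, then one column per frame); the frame rate is
#' stored in a leading `# fps:` comment line.
#'
#' @param traces Cells x frames matrix with an `fps` attribute.
#' @param path File path.
#' @return `read_traces_csv()` returns the matrix with rownames and `fps`
#'   attribute restored; `write_traces_csv()` returns `path` invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  fps <- attr(traces, "fps")
  if (is.null(fps)) abort("traces must carry an fps attribute")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps: %.10g", fps), con)
  df <- data.frame(
    cell_id = rownames(traces) %||% sprintf("cell%03d", seq_len(nrow(traces))),
    unname(as.data.frame(traces)),
    check.names = FALSE
  )
  names(df) <- c("cell_id", sprintf("f%d", seq_len(ncol(traces))))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# fps:", first)) {
    abort("trace CSV must start with a '# fps: <value>' line")
  }
  fps <- as.numeric(sub("^# fps:", "", first))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  check_columns(df, "cell_id", "trace CSV")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cell_id
  dimnames(m)[[2]] <- NULL
  attr(m, "fps") <- fps
  m
}

#' Write / read an event table as CSV
#'
#' Columns: `cell_id`, `t0`, `A`, `t_on`, `t_off`, `gof`. On read the table
#' is validated and, if `t0` is unsorted within a cell, sorted with a
#' warning.
#'
#' @param events Event tibble.
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  check_columns(events, c("cell_id", "t0", "A", "t_on", "t_off", "gof"),
    "event table"
  )
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  check_columns(df, c("cell_id", "t0", "A", "t_on", "t_off", "gof"),
    "events CSV"
  )
  unsorted <- any(vapply(split(df$t0, df$cell_id), is.unsorted, logical(1)))
  if (unsorted) {
    warn("event times were not sorted within cell; sorting on read")
  }
  arrange(df, .data$cell_id, .data$t0)
}

#' Write / read a trajectory as CSV
#'
#' Columns: `t`, `x`, `y`, `theta` (and `speed` if present).
#'
#' @param traj Trajectory tibble.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  check_columns(traj, c("t", "x", "y", "theta"), "trajectory")
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  check_columns(df, c("t", "x", "y", "theta"), "trajectory CSV")
  df
}

#' Read a cross-session cell match table
#'
#' Two columns of cell ids (session A, session B); produced upstream by ROI
#' registration across sessions and consumed here as given.
#'
#' @param path File path.
#' @return A tibble with columns `cell_a`, `cell_b`.
#' @export
read_match_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path, colClasses = "character"))
  if (ncol(df) < 2) abort("match CSV must have two columns of cell ids")
  names(df)[1:2] <- c("cell_a", "cell_b")
  df[, 1:2]
}

#' Write / read a ground-truth cell table as JSON
#'
#' Serialises the output of [place_cell_population()] so simulated sessions
#' can be archived with their ground truth.
#'
#' @param cells Cell tibble from [place_cell_population()].
#' @param path File path.
#' @export
write_cells_json <- function(cells, path) {
  check_columns(cells, c(
    "cell_id", "is_place_cell", "field_center", "tuning_width",
    "in_field_rate", "out_field_rate", "onset_time"
  ), "cell table")
  jsonlite::write_json(cells, path, auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_cells_json
#' @export
read_cells_json <- function(path) {
  df <- as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  check_columns(df, c(
    "cell_id", "is_place_cell", "field_center", "tuning_width",
    "in_field_rate", "out_field_rate", "onset_time"
  ), "cells JSON")
  df
}

#' Write / read track geometry as JSON
#'
#' @param geometry A [track_geometry()].
#' @param path File path.
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(
    geometry[c("outer_diameter", "width", "n_bins")], path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  track_geometry(g$outer_diameter, g$width, g$n_bins)
}
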