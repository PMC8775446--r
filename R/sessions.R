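# Cross-session comparison of cognitive maps: place-field shifts of matched
# cells, the map-retention chi-square test, and n_spec shift statistics.

#' Place-field shifts of matched cells across sessions
#'
#' For cells matched across two sessions that are single-field place cells in
#' both, computes the signed minimal circular difference between field
#' centres (session B minus session A) in bins, together with the shift in
#' tuning latency `n_spec`. Cells that are a place cell in only one session
#' are excluded here; see [field_fate()] for those categories.
#'
#' @param summary_a,summary_b Per-field summaries (`tidy()` of a
#'   [analyze_place_fields()] result) for the two sessions.
#' @param match Two-column data frame of matched cell ids (`cell_a`,
#'   `cell_b`); the mapping must be one-to-one.
#' @param n_bins Number of track bins.
#' @return A tibble with `cell_a`, `cell_b`, `center_a`, `center_b`,
#'   `shift_bins` in \[-n_bins/2, n_bins/2), `nspec_a`, `nspec_b`,
#'   `nspec_shift`.
#' @export
field_shifts <- function(summary_a, summary_b, match, n_bins = 20) {
  names(match)[1:2] <- c("cell_a", "cell_b")
  if (anyDuplicated(match$cell_a) || anyDuplicated(match$cell_b)) {
    abort("match must be a one-to-one mapping")
  }
  single <- function(s) {
    pc <- filter(s, .data$is_place_cell)
    counts <- table(pc$cell_id)
    filter(pc, .data$cell_id %in% names(counts)[counts == 1])
  }
  a <- single(summary_a)
  b <- single(summary_b)
  m <- filter(match, .data$cell_a %in% a$cell_id, .data$cell_b %in% b$cell_id)
  if (nrow(m) == 0) {
    return(tibble(
      cell_a = character(0), cell_b = character(0),
      center_a = numeric(0), center_b = numeric(0), shift_bins = numeric(0),
      nspec_a = integer(0), nspec_b = integer(0), nspec_shift = integer(0)
    ))
  }
  ia <- a[match(m$cell_a, a$cell_id), ]
  ib <- b[match(m$cell_b, b$cell_id), ]
  tibble(
    cell_a = m$cell_a, cell_b = m$cell_b,
    center_a = ia$center, center_b = ib$center,
    shift_bins = circ_signed_diff(ia$center, ib$center, period = n_bins),
    nspec_a = ia$n_spec, nspec_b = ib$n_spec,
    nspec_shift = ib$n_spec - ia$n_spec
  )
}

#' Cross-session fate of matched cells
#'
#' Categorises each matched cell pair by whether it is a place cell in both
#' sessions, only one, or neither ("N, not a place cell").
#'
#' @inheritParams field_shifts
#' @return A tibble with `cell_a`, `cell_b` and `fate` in
#'   `c("both", "only_a", "only_b", "neither")`.
#' @export
field_fate <- function(summary_a, summary_b, match) {
  names(match)[1:2] <- c("cell_a", "cell_b")
  pc_a <- unique(filter(summary_a, .data$is_place_cell)$cell_id)
  pc_b <- unique(filter(summary_b, .data$is_place_cell)$cell_id)
  mutate(as_tibble(match),
    fate = dplyr::case_when(
      cell_a %in% pc_a & cell_b %in% pc_b ~ "both",
      cell_a %in% pc_a ~ "only_a",
      cell_b %in% pc_b ~ "only_b",
      TRUE ~ "neither"
    )
  )
}

#' Map-retention test on a distribution of field shifts
#'
#' Decides whether a cognitive map was retained between two sessions from
#' the histogram of place-field shifts (unit-width bins over the signed
#' circular bin range; adjacent bins with expected counts below 5 are
#' merged, the standard chi-square validity rule). A retained map
#' concentrates shifts in a sharp zero-centred (normal-like) peak; full
#' remapping spreads them uniformly over the circle.
#'
#' `logic = "peak"` (the default) decides `retained = p < alpha` with the
#' chi-square statistic measuring deviation of the shift histogram from the
#' uniform (fully remapped) null: a small p means significant concentration
#' around zero, i.e. a normal-like peak. This rule is well calibrated —
#' zero-mean-normal shifts are classified retained and circular-uniform
#' shifts not-retained, each with high probability. `logic = "normality"`
#' instead tests the histogram against a zero-mean normal with sd estimated
#' from the shifts and calls the map retained when that normality hypothesis
#' is *not* rejected (`p > alpha`); this variant keeps sharp peaks retained
#' but has little power against broad alternatives, because the fitted
#' normal absorbs the spread.
#'
#' @param shifts Tibble from [field_shifts()] or a numeric vector of shifts
#'   in bins.
#' @param alpha Significance level.
#' @param n_bins Number of track bins (shift support is
#'   `[-n_bins/2, n_bins/2)`).
#' @param logic Retention decision rule; see Details.
#' @return An object of class `retention_test`: list with `statistic`, `df`,
#'   `p_value`, `retained`, `n`, `sd`, `alpha`, `logic`, `flags` (character;
#'   `"underpowered"` when n < 10, `"degenerate"` when all shifts are
#'   identical).
#' @export
retention_test <- function(shifts, alpha = 0.05, n_bins = 20,
                           logic = c("peak", "normality")) {
  logic <- match.arg(logic)
  s <- if (is.data.frame(shifts)) shifts$shift_bins else as.numeric(shifts)
  n <- length(s)
  flags <- character(0)
  if (n < 10) flags <- c(flags, "underpowered")
  s_sd <- if (n > 1) sd(s) else 0
  if (s_sd == 0) flags <- c(flags, "degenerate")

  breaks <- seq(-n_bins / 2, n_bins / 2, by = 1)
  observed <- as.vector(table(cut(s, breaks, right = FALSE,
    include.lowest = TRUE
  )))

  if (logic == "peak") {
    expected <- rep(n / n_bins, n_bins)
    n_par <- 0L
  } else {
    if (n == 0 || s_sd == 0) {
      # a point mass is trivially a degenerate zero-centred normal
      out <- list(
        statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
        retained = TRUE, n = n, sd = s_sd, alpha = alpha, logic = logic,
        flags = flags
      )
      class(out) <- "retention_test"
      return(out)
    }
    p_edges <- pnorm(breaks, mean = 0, sd = s_sd)
    expected <- n * diff(p_edges)
    # fold the normal tails beyond the circular range into the end bins
    expected[1] <- expected[1] + n * p_edges[1]
    expected[length(expected)] <- expected[length(expected)] +
      n * (1 - p_edges[length(p_edges)])
    n_par <- 1L # sd estimated from the data
  }

  # merge adjacent bins until every expected count is at least 5
  obs <- observed
  exp <- expected
  i <- 1L
  while (i <= length(exp) && length(exp) > 1L) {
    if (exp[i] < 5) {
      j <- if (i == length(exp)) i - 1L else i + 1L
      exp[j] <- exp[j] + exp[i]
      obs[j] <- obs[j] + obs[i]
      exp <- exp[-i]
      obs <- obs[-i]
      i <- 1L
    } else {
      i <- i + 1L
    }
  }
  df <- max(1L, length(exp) - 1L - n_par)
  statistic <- sum((obs - exp)^2 / exp)
  p_value <- pchisq(statistic, df, lower.tail = FALSE)
  retained <- if (logic == "peak") p_value < alpha else p_value > alpha
  structure(
    list(
      statistic = statistic, df = df, p_value = p_value,
      retained = retained, n = n, sd = s_sd, alpha = alpha, logic = logic,
      flags = flags
    ),
    class = "retention_test"
  )
}

#' @export
print.retention_test <- function(x, ...) {
  cat(sprintf(
    "<retention_test> n = %d shifts, chi-square = %s (df = %s), p = %s -> %s (%s logic)%s\n",
    x$n, format(x$statistic, digits = 4), format(x$df),
    format(x$p_value, digits = 4),
    if (isTRUE(x$retained)) "map retained" else "remapped",
    x$logic,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""
  ))
  invisible(x)
}

#' @rdname retention_test
#' @param x A `retention_test` object.
#' @param ... Unused.
#' @export
tidy.retention_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = as.numeric(x$df %||% NA),
    p.value = x$p_value, retained = x$retained,
    n = x$n, sd = x$sd, logic = x$logic,
    flags = paste(x$flags, collapse = ",")
  )
}

#' @rdname retention_test
#' @export
glance.retention_test <- function(x, ...) tidy(x)

#' Compare n_spec shifts between groups of cells
#'
#' Unpaired two-sample Student's t-test of the per-cell change in tuning
#' latency (`nspec_shift`, session B minus session A) between two groups,
#' e.g. cells from retained-map versus remapped animals.
#'
#' @param data Data frame with an `nspec_shift` column and a two-level
#'   `group` column (or supply two numeric vectors via `x` and `y`).
#' @param x,y Alternative interface: numeric vectors of n_spec shifts for
#'   the two groups.
#' @return A one-row tibble: `estimate` (mean difference, first group minus
#'   second), `statistic` (t), `df`, `p.value`, `n1`, `n2`.
#' @export
nspec_shift_test <- function(data = NULL, x = NULL, y = NULL) {
  if (!is.null(data)) {
    g <- factor(data$group)
    if (nlevels(g) != 2) abort("group must have exactly two levels")
    x <- data$nspec_shift[g == levels(g)[1]]
    y <- data$nspec_shift[g == levels(g)[2]]
  }
  if (sd(c(x - mean(x), y - mean(y))) == 0) {
    # degenerate: no within-group variance
    return(tibble(
      estimate = mean(x) - mean(y),
      statistic = if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf,
      df = length(x) + length(y) - 2,
      p.value = if (mean(x) == mean(y)) 1 else 0,
      n1 = length(x), n2 = length(y)
    ))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  tibble(
    estimate = unname(tt$estimate[1] - tt$estimate[2]),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p.value = tt$p.value, n1 = length(x), n2 = length(y)
  )
}
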