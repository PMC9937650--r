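#' Arena geometry
#'
#' @param radius Arena radius in mm; default 45 (a 9 cm diameter circular
#'   arena).
#' @param offset_deg Angular offset of the first quadrant boundary, degrees.
#' @return An object of class `arena_geometry`.
#' @export
arena_geometry <- function(radius = 45, offset_deg = 0) {
  if (radius <= 0) abort("radius must be positive", class = "mblearn_config_error")
  structure(list(radius = radius, offset_deg = offset_deg),
            class = "arena_geometry")
}

#' Test window for performance-index scoring
#'
#' Memory tests last `duration` seconds and only the final `score_last`
#' seconds are scored (default: last 30 s of a 60 s test).
#'
#' @param start Test start time in seconds.
#' @param duration Test duration in seconds (default 60).
#' @param score_last Length of the scored final span in seconds (default 30).
#' @return An object of class `test_window`.
#' @export
test_window <- function(start = 0, duration = 60, score_last = 30) {
  if (score_last <= 0 || score_last > duration) {
    abort("score_last must lie in (0, duration]", class = "mblearn_config_error")
  }
  structure(list(start = start, duration = duration, score_last = score_last),
            class = "test_window")
}

#' Assign arena quadrants to positions
#'
#' Quadrants are half-open 90-degree sectors counted counter-clockwise from
#' the geometry's angular offset: quadrant k covers
#' `[offset + (k-1)*90, offset + k*90)` degrees. Quadrants 1 & 3 and 2 & 4
#' are the diagonal pairs. A point exactly at the arena centre has no
#' defined angle; it is assigned the quadrant of angle 0 and flagged in the
#' `"ambiguous"` attribute of the result.
#'
#' @param x,y Positions in arena-centred mm (vectorised).
#' @param geometry An [arena_geometry()].
#' @return Integer vector of quadrants in `1:4` with a logical attribute
#'   `ambiguous` marking exact-centre points.
#' @export
assign_quadrant <- function(x, y, geometry = arena_geometry()) {
  r <- sqrt(x^2 + y^2)
  if (any(r > geometry$radius + 1e-9)) {
    abort("point(s) outside the arena radius", class = "mblearn_domain_error")
  }
  at_center <- r == 0
  theta <- atan2(y, x) * 180 / pi
  theta[at_center] <- 0
  rel <- (theta - geometry$offset_deg) %% 360
  q <- as.integer(rel %/% 90) + 1L
  attr(q, "ambiguous") <- at_center
  q
}

#' Performance index from trajectory frames
#'
#' Per scored frame, PI = (flies in the two odorised diagonal quadrants -
#' flies in the other two quadrants) / total flies; the returned value is the
#' mean of the per-frame PIs over the final `score_last` seconds of the test
#' window. Flies are counted by position alone; identity is not used.
#'
#' @param frames Tibble with columns `time_s`, `x_mm`, `y_mm` (and
#'   optionally `fly_id`).
#' @param odor_quadrants The odorised diagonal pair, `c(1, 3)` or `c(2, 4)`.
#' @param window A [test_window()]; frames with
#'   `time_s` in `[start + duration - score_last, start + duration)` are
#'   scored.
#' @param geometry An [arena_geometry()].
#' @return A single PI in `[-1, 1]`.
#' @examples
#' f <- tibble::tibble(time_s = 0, x_mm = c(10, 10, -10), y_mm = c(10, 10, 10))
#' performance_index(f, window = test_window(0, 1, 1))
#' @export
performance_index <- function(frames, odor_quadrants = c(1L, 3L),
                              window = test_window(),
                              geometry = arena_geometry()) {
  if (!identical(sort(as.integer(odor_quadrants)), c(1L, 3L)) &&
      !identical(sort(as.integer(odor_quadrants)), c(2L, 4L))) {
    abort("odor_quadrants must be the diagonal pair c(1,3) or c(2,4)",
          class = "mblearn_argument_error")
  }
  t0 <- window$start + window$duration - window$score_last
  t1 <- window$start + window$duration
  scored <- frames |>
    dplyr::filter(.data$time_s >= t0, .data$time_s < t1)
  if (nrow(scored) == 0) {
    abort("no frames fall inside the scoring span", class = "mblearn_data_error")
  }
  scored$quadrant <- as.integer(
    assign_quadrant(scored$x_mm, scored$y_mm, geometry))
  per_frame <- scored |>
    dplyr::summarise(
      n_odor = sum(.data$quadrant %in% odor_quadrants),
      n_total = dplyr::n(),
      .by = "time_s")
  if (any(per_frame$n_total == 0)) {
    abort("scored frame with zero flies", class = "mblearn_data_error")
  }
  mean((2 * per_frame$n_odor - per_frame$n_total) / per_frame$n_total)
}

#' Average the performance indices of a reciprocal experiment pair
#'
#' Each experiment is repeated with odor positions/roles swapped and the two
#' PIs are averaged, cancelling position bias and innate odor preference.
#'
#' @param pi_a,pi_b PIs from the matched reciprocal pair.
#' @return Their arithmetic mean.
#' @export
reciprocal_average <- function(pi_a, pi_b) {
  if (length(pi_a) != 1 || length(pi_b) != 1 ||
      is.na(pi_a) || is.na(pi_b)) {
    abort("both members of the reciprocal pair are required",
          class = "mblearn_argument_error")
  }
  (pi_a + pi_b) / 2
}

#' Area-normalised radial index
#'
#' The mean over flies and frames of `(r_i / r_arena)^2`, where `r_i` is a
#' fly's distance from the arena centre. For flies distributed uniformly
#' over the disk the expected value is 1/2 (and the expected `r/R` is
#' `1/sqrt(2)`); deviations towards 1 indicate net displacement towards the
#' wall, i.e. upwind, since arena air flows from the periphery to a central
#' outlet.
#'
#' @param frames Tibble with `x_mm`, `y_mm`.
#' @param geometry An [arena_geometry()].
#' @return A value in `[0, 1]`.
#' @export
area_normalized_index <- function(frames, geometry = arena_geometry()) {
  if (nrow(frames) == 0) abort("frames is empty", class = "mblearn_data_error")
  mean((frames$x_mm^2 + frames$y_mm^2) / geometry$radius^2)
}

#' Upwind displacement time series
#'
#' For each time point, the mean area-normalised index of that frame minus
#' the index at stimulus onset. Positive values indicate net outward
#' (upwind) movement relative to onset.
#'
#' @param frames Tibble with `time_s`, `x_mm`, `y_mm`.
#' @param geometry An [arena_geometry()].
#' @param onset Stimulus (LED or odor) onset time in seconds; must fall
#'   within the recording.
#' @return A tibble with columns `time_s` and `upwind` in `[-1, 1]`.
#' @export
upwind_displacement <- function(frames, geometry = arena_geometry(), onset) {
  if (nrow(frames) == 0) abort("frames is empty", class = "mblearn_data_error")
  tt <- sort(unique(frames$time_s))
  if (onset < min(tt) || onset > max(tt)) {
    abort("onset lies outside the recording", class = "mblearn_argument_error")
  }
  by_t <- frames |>
    dplyr::summarise(
      index = mean((.data$x_mm^2 + .data$y_mm^2) / geometry$radius^2),
      .by = "time_s") |>
    dplyr::arrange(.data$time_s)
  onset_idx <- which.min(abs(by_t$time_s - onset))
  by_t |>
    dplyr::transmute(time_s = .data$time_s,
                     upwind = .data$index - by_t$index[onset_idx])
}
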