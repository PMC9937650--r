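#' Gaussian-kernel instantaneous firing rate
#'
#' Convolves a spike train with a Gaussian kernel (default SD 50 ms): the
#' rate at grid time `t` is the sum over spikes of the normal density
#' centred at each spike time. The kernel integrates to one per spike, so
#' the rate series integrates to the spike count; the kernel is truncated
#' at +/- 5 SD (mass error < 1e-6). No renormalisation is applied at the
#' recording edges.
#'
#' @param spike_times Numeric vector of spike times in seconds.
#' @param span Length-2 numeric, the recording span `c(t0, t1)` over which
#'   the rate grid is laid.
#' @param sd Kernel standard deviation in seconds (default 0.05).
#' @param step Grid step in seconds (default 0.01).
#' @return A tibble with columns `time_s` and `rate_hz`.
#' @examples
#' instantaneous_rate(c(1, 1.2), span = c(0, 2))
#' @export
instantaneous_rate <- function(spike_times, span, sd = 0.05, step = 0.01) {
  if (sd <= 0 || step <= 0) {
    abort("sd and step must be positive", class = "mblearn_argument_error")
  }
  grid <- seq(span[1], span[2], by = step)
  rate <- numeric(length(grid))
  half <- 5 * sd
  for (s in spike_times) {
    lo <- findInterval(s - half, grid) + 1L
    hi <- findInterval(s + half, grid)
    if (hi < lo) next
    idx <- lo:hi
    rate[idx] <- rate[idx] + dnorm(grid[idx], mean = s, sd = sd)
  }
  tibble(time_s = grid, rate_hz = rate)
}

#' Odor-evoked spike count with spontaneous-rate subtraction
#'
#' Counts spikes inside the response window and subtracts the expected
#' spontaneous count, `spontaneous_rate * window length`; the result may be
#' negative. When `spontaneous_rate` is not supplied it is estimated from a
#' pre-stimulus span ending at the window onset (default length 5 s).
#'
#' @param spike_times Numeric vector of spike times in seconds.
#' @param window Length-2 numeric `c(start, end)` in seconds; spikes in
#'   `[start, end)` are counted. Typical lengths are 1.2 s for a 1 s odor
#'   and 20.6 s for a 20 s odor.
#' @param spontaneous_rate Spontaneous rate in Hz; estimated from
#'   `spontaneous_span` when `NULL`.
#' @param spontaneous_span Pre-stimulus span `c(t0, t1)` used for the
#'   estimate; default the 5 s ending at `window[1]`.
#' @param span Optional recording span `c(t0, t1)`; when supplied, a window
#'   outside it is an error.
#' @return Evoked spike count (real, possibly negative).
#' @examples
#' evoked_spike_count(seq(0.05, 1.15, length.out = 10), window = c(0, 1.2),
#'                    spontaneous_rate = 2)
#' @export
evoked_spike_count <- function(spike_times, window,
                               spontaneous_rate = NULL,
                               spontaneous_span = NULL,
                               span = NULL) {
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("window must be c(start, end) with end > start",
          class = "mblearn_argument_error")
  }
  if (!is.null(span) && (window[1] < span[1] || window[2] > span[2])) {
    abort("response window lies outside the recording span",
          class = "mblearn_argument_error")
  }
  if (is.null(spontaneous_rate)) {
    if (is.null(spontaneous_span)) {
      spontaneous_span <- c(max(window[1] - 5, span[1] %||% (window[1] - 5)),
                            window[1])
    }
    len <- diff(spontaneous_span)
    if (len <= 0) {
      abort("spontaneous span has non-positive length",
            class = "mblearn_argument_error")
    }
    spontaneous_rate <- sum(spike_times >= spontaneous_span[1] &
                              spike_times < spontaneous_span[2]) / len
  }
  n_in <- sum(spike_times >= window[1] & spike_times < window[2])
  n_in - spontaneous_rate * diff(window)
}

#' Mean depolarisation over a response window
#'
#' Subtracts the mean baseline value from the trace and averages the
#' baseline-subtracted signal over the response window (e.g. 0-20.6 s from
#' odor onset for a 20 s odor).
#'
#' @param trace Tibble with columns `time_s` and `value` (e.g. membrane
#'   potential in mV).
#' @param window Length-2 numeric `c(start, end)`; samples with `time_s` in
#'   `[start, end)` are averaged.
#' @param baseline Length-2 numeric `c(start, end)` pre-stimulus span whose
#'   mean defines the baseline.
#' @return Mean depolarisation in the units of `value`.
#' @export
response_magnitude <- function(trace, window, baseline) {
  tt <- trace$time_s
  for (sp in list(window, baseline)) {
    if (length(sp) != 2 || sp[2] <= sp[1] ||
        sp[1] < min(tt) - 1e-9 || sp[2] > max(tt) + 1e-9) {
      abort("window and baseline spans must lie inside the recording",
            class = "mblearn_argument_error")
    }
  }
  in_win <- tt >= window[1] & tt < window[2]
  in_base <- tt >= baseline[1] & tt < baseline[2]
  if (!any(in_win) || !any(in_base)) {
    abort("window or baseline span contains no samples",
          class = "mblearn_argument_error")
  }
  mean(trace$value[in_win]) - mean(trace$value[in_base])
}

#' Background-subtracted dF/F with trial averaging
#'
#' Per trial: subtracts the background ROI series from the signal ROI
#' series, takes the mean of the subtracted signal over a pre-stimulus
#' baseline span (default the 30 s before stimulation) as F0, and returns
#' `(signal - background - F0) / F0`. The per-sample mean across trials of
#' the same condition is returned alongside the per-trial series.
#'
#' @param trace Tibble with columns `trial`, `time_s`, `value`,
#'   `background`.
#' @param onset Stimulation onset time in seconds.
#' @param baseline_s Length of the pre-stimulus baseline span in seconds
#'   (default 30); the span is `[onset - baseline_s, onset)` and must fit
#'   the recording.
#' @return A list of class `dff_result`: `trials` (tibble `trial`,
#'   `time_s`, `dff`) and `mean` (tibble `time_s`, `dff`).
#' @export
delta_f_over_f <- function(trace, onset, baseline_s = 30) {
  req <- c("trial", "time_s", "value", "background")
  if (!all(req %in% names(trace))) {
    abort(paste0("trace must have columns: ", paste(req, collapse = ", ")),
          class = "mblearn_argument_error")
  }
  b0 <- onset - baseline_s
  if (b0 < min(trace$time_s) - 1e-9) {
    abort("baseline span does not fit the recording before onset",
          class = "mblearn_argument_error")
  }
  trials <- trace |>
    dplyr::mutate(s = .data$value - .data$background) |>
    dplyr::group_by(.data$trial) |>
    dplyr::group_modify(function(df, key) {
      in_base <- df$time_s >= b0 & df$time_s < onset
      if (!any(in_base)) {
        abort("no samples in the baseline span", class = "mblearn_data_error")
      }
      f0 <- mean(df$s[in_base])
      if (f0 <= 0) {
        abort(sprintf("baseline fluorescence F0 = %.3g is not positive", f0),
              class = "mblearn_data_error")
      }
      tibble(time_s = df$time_s, dff = (df$s - f0) / f0)
    }) |>
    dplyr::ungroup()
  trial_mean <- trials |>
    dplyr::summarise(dff = mean(.data$dff), .by = "time_s") |>
    dplyr::arrange(.data$time_s)
  structure(list(trials = trials, mean = trial_mean,
                 onset = onset, baseline_s = baseline_s),
            class = "dff_result")
}

#' @export
print.dff_result <- function(x, ...) {
  cat("<dff_result>", dplyr::n_distinct(x$trials$trial), "trials,",
      nrow(x$mean), "samples; onset", x$onset, "s, baseline",
      x$baseline_s, "s\n")
  cat("  trial-mean peak dF/F:", signif(max(x$mean$dff), 4), "\n")
  invisible(x)
}
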