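#' Map a performance index to a choice probability
#'
#' PI equals `p - (1 - p)` when every fly chooses one of the two odor pairs,
#' so `p = (PI + 1) / 2`. The result is clipped to `[eps, 1 - eps]` so the
#' subsequent log-odds stay finite at `|PI| = 1`.
#'
#' @param pi_value Performance index values in `[-1, 1]` (vectorised).
#' @param eps Clip bound, default `1e-3`.
#' @return Probabilities in `[eps, 1 - eps]`.
#' @export
pi_to_prob <- function(pi_value, eps = 1e-3) {
  if (any(!is.finite(pi_value)) || any(abs(pi_value) > 1 + 1e-12)) {
    abort("PI values must be finite and lie in [-1, 1]",
          class = "mblearn_argument_error")
  }
  pmin(1 - eps, pmax(eps, (pi_value + 1) / 2))
}

#' Natural log-odds of a choice probability
#'
#' `R = log(p / (1 - p))`, the log-probability ratio of choosing the
#' reinforced stimulus. Combined activation of several memory compartments
#' is modelled as additive in this quantity.
#'
#' @param p Probabilities strictly inside `(0, 1)` (vectorised).
#' @return Log-odds values.
#' @export
log_odds <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("probabilities must lie strictly inside (0, 1)",
          class = "mblearn_argument_error")
  }
  log(p / (1 - p))
}

# Align a target curve and basis curves on shared (phase, trial) points,
# averaging replicate PI values per point.
align_curves <- function(target, basis, test_points = NULL) {
  target <- as_tibble(target) |>
    dplyr::summarise(pi = mean(.data$pi), .by = c("phase", "trial"))
  basis <- as_tibble(basis) |>
    dplyr::summarise(pi = mean(.data$pi), .by = c("driver", "phase", "trial"))
  drivers <- unique(basis$driver)

  pts <- if (is.null(test_points)) {
    target |> dplyr::select("phase", "trial")
  } else {
    as_tibble(test_points) |> dplyr::distinct(.data$phase, .data$trial)
  }
  wide <- pts |>
    dplyr::left_join(target, by = c("phase", "trial")) |>
    dplyr::rename(target = "pi")
  for (d in drivers) {
    bd <- basis |>
      dplyr::filter(.data$driver == d) |>
      dplyr::select("phase", "trial", "pi")
    wide <- wide |>
      dplyr::left_join(bd, by = c("phase", "trial")) |>
      dplyr::rename(!!d := "pi")
  }
  miss <- wide |>
    dplyr::filter(dplyr::if_any(dplyr::everything(), is.na))
  if (nrow(miss) > 0) {
    pts_txt <- paste(miss$phase, miss$trial, sep = ":", collapse = ", ")
    abort(paste0("curves are not all defined at test point(s): ", pts_txt),
          class = "mblearn_alignment_error")
  }
  list(wide = wide, drivers = drivers)
}

#' Decompose a composite memory curve into non-negative driver components
#'
#' Transforms the target and each basis PI curve to log-odds
#' (`R = log(p/(1-p))`, `p = (PI+1)/2`, clipped at `eps`) and solves the
#' non-negative least-squares problem
#' `min ||R_target - sum_i w_i R_basis_i||^2, w_i >= 0`, with no intercept
#' (R = 0 is chance by construction). This reflects the model in which
#' combined activation of several dopaminergic compartments contributes a
#' behavioural bias that is additive in log-probability ratio.
#'
#' @param target PI curve tibble with columns `phase`, `trial`, `pi`
#'   (replicates averaged per test point).
#' @param basis Tibble of basis curves with columns `driver`, `phase`,
#'   `trial`, `pi`.
#' @param test_points Optional tibble (`phase`, `trial`) selecting the test
#'   points entering the fit; default: every test point of the target.
#'   Points missing from any curve raise an alignment error naming them.
#' @param eps Probability clip bound passed to [pi_to_prob()].
#' @return An object of class `pi_decomposition`: weights, residual sum of
#'   squares, and the fitted vs observed log-odds per test point. Use
#'   [tidy()] for the weight table and [glance()] for fit summaries.
#' @examples
#' curves <- gen_pi_curves(synth_config(seed = 1, noise_sd = 0))
#' fit <- nnls_decompose(curves$composite, curves$basis)
#' tidy(fit)
#' @export
nnls_decompose <- function(target, basis, test_points = NULL, eps = 1e-3) {
  al <- align_curves(target, basis, test_points)
  wide <- al$wide
  drivers <- al$drivers
  if (nrow(wide) < length(drivers)) {
    warn(sprintf("only %d test points for %d basis curves; fit is underdetermined",
                 nrow(wide), length(drivers)))
  }
  to_r <- function(p) log_odds(pi_to_prob(p, eps = eps))
  b <- to_r(wide$target)
  A <- vapply(drivers, function(d) to_r(wide[[d]]), numeric(nrow(wide)))
  A <- matrix(A, nrow = nrow(wide), dimnames = list(NULL, drivers))

  sol <- pracma::lsqnonneg(A, b)
  w <- as.vector(sol$x)
  names(w) <- drivers
  fitted_r <- as.vector(A %*% w)
  structure(
    list(weights = w,
         rss = sum((b - fitted_r)^2),
         fitted = tibble(phase = wide$phase, trial = wide$trial,
                         r_observed = b, r_fitted = fitted_r),
         eps = eps,
         log_base = "natural",
         drivers = drivers),
    class = "pi_decomposition")
}

#' @export
print.pi_decomposition <- function(x, ...) {
  cat("<pi_decomposition>", length(x$weights), "drivers,",
      nrow(x$fitted), "test points\n")
  cat("  weights:", paste(names(x$weights), signif(x$weights, 3),
                          sep = "=", collapse = ", "), "\n")
  cat("  residual sum of squares:", signif(x$rss, 4), "\n")
  invisible(x)
}

#' @describeIn nnls_decompose One row per driver with its fitted weight.
#' @param x A `pi_decomposition` object.
#' @param ... Unused.
#' @method tidy pi_decomposition
#' @export
tidy.pi_decomposition <- function(x, ...) {
  tibble(driver = names(x$weights), weight = unname(x$weights))
}

#' @describeIn nnls_decompose One-row fit summary (rss, points, drivers).
#' @method glance pi_decomposition
#' @export
glance.pi_decomposition <- function(x, ...) {
  tibble(rss = x$rss, n_points = nrow(x$fitted),
         n_drivers = length(x$weights),
         n_active = sum(x$weights > 0))
}

# ---- memory-dynamics indices ------------------------------------------------

# Pull PI values of one phase ordered by trial; error when absent.
phase_pis <- function(curve, phase, n_required = NULL) {
  cv <- as_tibble(curve) |>
    dplyr::filter(.data$phase == !!phase) |>
    dplyr::arrange(.data$trial)
  if (!is.null(n_required) && nrow(cv) < n_required) {
    abort(sprintf("need at least %d '%s' test points, found %d",
                  n_required, phase, nrow(cv)),
          class = "mblearn_data_error")
  }
  cv$pi
}

# Ratio with an undefined-denominator guard: returns NA flagged by warning.
guarded_ratio <- function(num, den, what) {
  if (!is.finite(den) || den <= 0) {
    warn(paste0(what, " is undefined: denominator is not strictly positive"))
    return(NA_real_)
  }
  num / den
}

#' Memory-dynamics indices of a performance-index curve
#'
#' Five dimensionless ratios summarising a driver line's memory dynamics
#' over the training / extinction / reversal / re-reversal / reactivation
#' protocol:
#'
#' * `learning_rate()`: PI after the first (10 s) training divided by the
#'   peak PI over training trials 1-5.
#' * `training_persistency()`: PI after the 5th training over the same peak.
#' * `memory_persistency()`: mean of the 12 extinction-phase tests after the
#'   first training trials over the same peak.
#' * `reactivation_resistance()`: mean of the last three tests following
#'   LED reactivation without odor, divided by the PI after the 5th
#'   re-reversal conditioning.
#' * `early_test_persistency()`: mean of the 3rd-6th tests divided by the
#'   1st test PI (computed on the phase named by `phase`).
#'
#' Each index is defined only when its denominator is strictly positive;
#' undefined values are returned as `NA` with a warning, never coerced.
#'
#' @param curve PI curve tibble with columns `phase`, `trial`, `pi` for a
#'   single driver.
#' @return A single ratio (or `NA` when undefined).
#' @examples
#' curves <- gen_pi_curves(synth_config(seed = 1, noise_sd = 0))
#' learning_rate(curves$composite)
#' @export
learning_rate <- function(curve) {
  tr <- phase_pis(curve, "training", 5)
  guarded_ratio(tr[1], max(tr[1:5]), "learning_rate")
}

#' @rdname learning_rate
#' @export
training_persistency <- function(curve) {
  tr <- phase_pis(curve, "training", 5)
  guarded_ratio(tr[5], max(tr[1:5]), "training_persistency")
}

#' @rdname learning_rate
#' @export
memory_persistency <- function(curve) {
  tr <- phase_pis(curve, "training", 5)
  ex <- phase_pis(curve, "extinction", 12)
  guarded_ratio(mean(ex[1:12]), max(tr[1:5]), "memory_persistency")
}

#' @rdname learning_rate
#' @export
reactivation_resistance <- function(curve) {
  rr <- phase_pis(curve, "re-reversal", 5)
  re <- phase_pis(curve, "reactivation", 3)
  guarded_ratio(mean(utils::tail(re, 3)), rr[5], "reactivation_resistance")
}

#' @rdname learning_rate
#' @param phase Which phase holds the repeated tests (default
#'   `"extinction"`).
#' @export
early_test_persistency <- function(curve, phase = "extinction") {
  te <- phase_pis(curve, phase, 6)
  guarded_ratio(mean(te[3:6]), te[1], "early_test_persistency")
}

#' All five memory-dynamics indices as a tibble
#'
#' @inheritParams learning_rate
#' @return A tibble with columns `index`, `value`, `defined`.
#' @export
memory_indices <- function(curve) {
  fns <- list(
    learning_rate = learning_rate,
    training_persistency = training_persistency,
    memory_persistency = memory_persistency,
    reactivation_resistance = reactivation_resistance,
    early_test_persistency = early_test_persistency)
  vals <- purrr::map_dbl(fns, function(f) {
    withCallingHandlers(
      tryCatch(f(curve), mblearn_data_error = function(e) NA_real_),
      warning = function(w) invokeRestart("muffleWarning"))
  })
  tibble(index = names(fns), value = unname(vals),
         defined = is.finite(unname(vals)))
}
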