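#' Generate a synthetic connectome with a planted hub interneuron
#'
#' Builds a neuron table (MBONs, DANs, interneurons) and a synapse-count edge
#' list in which one randomly chosen interneuron is planted as a
#' high-connectivity hub: it receives `hub_in_frac` of all MBON->interneuron
#' synapses and emits `hub_out_frac` of all interneuron->DAN synapses.
#' Non-hub edge counts are drawn from a shifted negative binomial, so counts
#' are overdispersed and strictly positive. The planted hub is always
#' labelled cholinergic, emulating the excitatory hub phenotype the
#' downstream screen is designed to find; other interneurons draw their
#' transmitter from `nt_probs`.
#'
#' @param cfg A [synth_config()].
#' @return A [connectome()] whose `metadata` records the full planted ground
#'   truth (`hub_id`, `hub_cell_type`, seed, generator parameters).
#' @examples
#' cn <- gen_connectome(synth_config(seed = 1))
#' cn$metadata$hub_cell_type
#' @export
gen_connectome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_child_seed(cfg$seed, 101L, {
    mbons <- tibble(
      neuron_id = sprintf("mbon_%03d", seq_len(cfg$n_mbons)),
      cell_type = sprintf("MBON%02d", seq_len(cfg$n_mbons)),
      class = "MBON", predicted_nt = "glutamate")
    dans <- tibble(
      neuron_id = sprintf("dan_%03d", seq_len(cfg$n_dans)),
      cell_type = sprintf("PAM%02d", seq_len(cfg$n_dans)),
      class = "DAN", predicted_nt = "dopamine")
    ints <- tibble(
      neuron_id = sprintf("int_%03d", seq_len(cfg$n_interneurons)),
      cell_type = sprintf("INT%03d", seq_len(cfg$n_interneurons)),
      class = "interneuron",
      predicted_nt = sample(names(cfg$nt_probs), cfg$n_interneurons,
                            replace = TRUE, prob = cfg$nt_probs))
    hub_idx <- sample.int(cfg$n_interneurons, 1L)
    ints$predicted_nt[hub_idx] <- "acetylcholine"
    hub_id <- ints$neuron_id[hub_idx]

    draw_counts <- function(n) {
      rnbinom(n, size = cfg$edge_count_dispersion, mu = 8) + 1L
    }
    # Sparse random block of edges between two neuron-id sets.
    random_block <- function(pre_ids, post_ids, p_edge) {
      grid <- expand.grid(pre_id = pre_ids, post_id = post_ids,
                          stringsAsFactors = FALSE)
      keep <- runif(nrow(grid)) < p_edge
      grid <- grid[keep, , drop = FALSE]
      if (nrow(grid) == 0) return(NULL)
      tibble(pre_id = grid$pre_id, post_id = grid$post_id,
             synapse_count = draw_counts(nrow(grid)))
    }
    # Hub edges sized so the hub carries `frac` of the block's total count.
    hub_block <- function(partner_ids, frac, base_total, hub_is_post) {
      if (frac <= 0 || base_total <= 0) return(NULL)
      total <- max(length(partner_ids), round(frac * base_total / (1 - frac)))
      alloc <- as.vector(rmultinom(1, total, rep(1, length(partner_ids))))
      keep <- alloc > 0
      if (!any(keep)) return(NULL)
      if (hub_is_post) {
        tibble(pre_id = partner_ids[keep], post_id = hub_id,
               synapse_count = alloc[keep])
      } else {
        tibble(pre_id = hub_id, post_id = partner_ids[keep],
               synapse_count = alloc[keep])
      }
    }

    other_ints <- ints$neuron_id[-hub_idx]
    m2i <- random_block(mbons$neuron_id, other_ints, p_edge = 0.5)
    i2d <- random_block(other_ints, dans$neuron_id, p_edge = 0.5)
    m2i_hub <- hub_block(mbons$neuron_id, cfg$hub_in_frac,
                         sum(m2i$synapse_count), hub_is_post = TRUE)
    i2d_hub <- hub_block(dans$neuron_id, cfg$hub_out_frac,
                         sum(i2d$synapse_count), hub_is_post = FALSE)
    # sparse feedback edges so the bidirectional >=100 screen is exercised
    i2m <- random_block(ints$neuron_id, mbons$neuron_id, p_edge = 0.05)
    d2i <- random_block(dans$neuron_id, ints$neuron_id, p_edge = 0.05)

    edges <- dplyr::bind_rows(m2i, i2d, m2i_hub, i2d_hub, i2m, d2i)
    meta <- list(
      generator = "gen_connectome",
      seed = cfg$seed,
      hub_id = hub_id,
      hub_cell_type = ints$cell_type[hub_idx],
      hub_in_frac = cfg$hub_in_frac,
      hub_out_frac = cfg$hub_out_frac,
      n_mbons = cfg$n_mbons, n_dans = cfg$n_dans,
      n_interneurons = cfg$n_interneurons,
      edge_count_dispersion = cfg$edge_count_dispersion,
      nt_probs = as.list(cfg$nt_probs))
    connectome(dplyr::bind_rows(mbons, dans, ints), edges, metadata = meta)
  })
}

#' Simulate fly trajectories in a circular arena
#'
#' Discrete-time drift--diffusion walk inside a disk of radius
#' `cfg$arena_radius` with a reflecting boundary. When `cfg$odor_bias` is
#' positive each fly drifts, by that many mm per frame, towards the nearer of
#' two anchor points placed at half-radius in the centres of the odorised
#' diagonal quadrant pair; `odor_bias = 0` gives an unbiased random walk and
#' hence an expected performance index of zero.
#'
#' @param cfg A [synth_config()].
#' @param odor_quadrants Length-2 integer vector, the odorised diagonal
#'   quadrant pair: `c(1, 3)` or `c(2, 4)`.
#' @param duration Recording duration in seconds.
#' @return A tibble with columns `time_s`, `fly_id`, `x_mm`, `y_mm`, with
#'   `frame_rate * duration` frames per fly; attribute `metadata` echoes the
#'   planted parameters.
#' @export
gen_trajectories <- function(cfg, odor_quadrants = c(1L, 3L), duration) {
  stopifnot(inherits(cfg, "synth_config"))
  if (duration <= 0) abort("duration must be positive",
                           class = "mblearn_config_error")
  if (!identical(sort(as.integer(odor_quadrants)), c(1L, 3L)) &&
      !identical(sort(as.integer(odor_quadrants)), c(2L, 4L))) {
    abort("odor_quadrants must be the diagonal pair c(1,3) or c(2,4)",
          class = "mblearn_config_error")
  }
  with_child_seed(cfg$seed, 202L, {
    R <- cfg$arena_radius
    n <- cfg$n_flies
    n_frames <- max(1L, round(duration * cfg$frame_rate))
    centers_deg <- (odor_quadrants - 1) * 90 + 45
    ax <- (R / 2) * cospi(centers_deg / 180)
    ay <- (R / 2) * sinpi(centers_deg / 180)

    r0 <- R * sqrt(runif(n))
    th0 <- runif(n, 0, 2 * pi)
    x <- r0 * cos(th0)
    y <- r0 * sin(th0)
    xs <- matrix(NA_real_, n_frames, n)
    ys <- matrix(NA_real_, n_frames, n)
    for (f in seq_len(n_frames)) {
      if (cfg$odor_bias > 0) {
        d1 <- (x - ax[1])^2 + (y - ay[1])^2
        d2 <- (x - ax[2])^2 + (y - ay[2])^2
        tx <- ifelse(d1 <= d2, ax[1], ax[2])
        ty <- ifelse(d1 <= d2, ay[1], ay[2])
        dx <- tx - x; dy <- ty - y
        dn <- pmax(sqrt(dx^2 + dy^2), 1e-9)
        x <- x + cfg$odor_bias * dx / dn
        y <- y + cfg$odor_bias * dy / dn
      }
      x <- x + rnorm(n, 0, cfg$step_sd)
      y <- y + rnorm(n, 0, cfg$step_sd)
      r <- sqrt(x^2 + y^2)
      over <- r > R
      if (any(over)) {
        # radial reflection: fold the overshoot back inside the wall
        r_new <- 2 * R - r[over]
        r_new[r_new < 0] <- 0
        sc <- r_new / r[over]
        x[over] <- x[over] * sc
        y[over] <- y[over] * sc
      }
      xs[f, ] <- x
      ys[f, ] <- y
    }
    out <- tibble(
      time_s = rep((seq_len(n_frames) - 1) / cfg$frame_rate, each = n),
      fly_id = rep(seq_len(n), times = n_frames),
      x_mm = as.vector(t(xs)),
      y_mm = as.vector(t(ys)))
    attr(out, "metadata") <- list(
      generator = "gen_trajectories", seed = cfg$seed,
      odor_bias = cfg$odor_bias, odor_quadrants = odor_quadrants,
      arena_radius = R, n_flies = n, frame_rate = cfg$frame_rate,
      step_sd = cfg$step_sd, duration = duration)
    out
  })
}

#' Standard optogenetic memory-dynamics test schedule
#'
#' The phase/trial grid on which synthetic PI curves are evaluated,
#' following the full optogenetic protocol: 5 training trials, 12
#' extinction tests, a reversal phase of 5 conditioning trials followed by
#' 12 tests (trials 1-17), a re-reversal phase of the same shape, and 3
#' reactivation tests after LED-only stimulation (54 test points).
#'
#' @return A tibble with columns `phase` and `trial`.
#' @export
default_protocol <- function() {
  dplyr::bind_rows(
    tibble(phase = "training", trial = 1:5),
    tibble(phase = "extinction", trial = 1:12),
    tibble(phase = "reversal", trial = 1:17),
    tibble(phase = "re-reversal", trial = 1:17),
    tibble(phase = "reactivation", trial = 1:3))
}

# Deterministic basis PI value for one driver at one protocol point.
# Reversal/re-reversal phases hold 5 conditioning trials followed by
# extinction-style tests (trials 6+).
basis_pi_value <- function(pi_max, learn_rate, decay_rate, react_drop,
                           phase, trial) {
  train <- function(k) pi_max * (1 - exp(-learn_rate * k))
  phase_curve <- function(k, sign) {
    if (k <= 5) sign * train(k) else sign * train(5) * exp(-decay_rate * (k - 5))
  }
  switch(phase,
    training = train(trial),
    extinction = train(5) * exp(-decay_rate * trial),
    reversal = phase_curve(trial, -1),
    `re-reversal` = phase_curve(trial, 1),
    reactivation = train(5) * exp(-react_drop * trial),
    abort(paste0("unknown phase: ", phase), class = "mblearn_config_error"))
}

#' Generate per-driver basis PI curves and a composite mixture curve
#'
#' Each driver's deterministic curve follows a saturating-exponential
#' learning phase and exponential decay during extinction/reactivation, with
#' per-driver rate constants from `cfg$basis_curves`. The composite curve is
#' built by summing `planted_weights` x driver log-odds at every test point
#' and mapping back to PI through the logistic; `cfg$n_replicates`
#' replicate-group curves are drawn by adding Gaussian noise of sd
#' `cfg$noise_sd` in PI space and clipping to `[-1, 1]`, and their
#' per-point mean is the composite curve, mirroring a study that averages
#' PI curves over fly groups before analysis.
#'
#' @param cfg A [synth_config()].
#' @param protocol Test-point schedule tibble (`phase`, `trial`); defaults to
#'   [default_protocol()].
#' @return A list with tibbles `basis` (`driver`, `phase`, `trial`, `pi`),
#'   `replicates` (per-group noisy curves) and `composite` (their per-point
#'   mean, the curve a study would analyse), plus `metadata` recording the
#'   planted weights.
#' @export
gen_pi_curves <- function(cfg, protocol = default_protocol()) {
  stopifnot(inherits(cfg, "synth_config"))
  basis <- cfg$basis_curves |>
    dplyr::cross_join(protocol) |>
    dplyr::mutate(pi = purrr::pmap_dbl(
      list(.data$pi_max, .data$learn_rate, .data$decay_rate,
           .data$react_drop, .data$phase, .data$trial),
      basis_pi_value)) |>
    dplyr::select("driver", "phase", "trial", "pi")

  r_mat <- basis |>
    tidyr::pivot_wider(names_from = "driver", values_from = "pi") |>
    dplyr::select(dplyr::all_of(cfg$basis_curves$driver)) |>
    as.matrix()
  r_mat <- apply(r_mat, 2, function(p) log_odds(pi_to_prob(p)))
  r_comp <- as.vector(r_mat %*% cfg$planted_weights)
  pi_comp <- 2 * plogis(r_comp) - 1

  reps <- with_child_seed(cfg$seed, 303L, {
    purrr::map_dfr(seq_len(cfg$n_replicates), function(rep) {
      noisy <- pi_comp + rnorm(length(pi_comp), 0, cfg$noise_sd)
      protocol |>
        dplyr::mutate(replicate = rep, pi = pmin(1, pmax(-1, noisy)))
    })
  })
  composite <- reps |>
    dplyr::summarise(pi = mean(.data$pi), .by = c("phase", "trial"))
  list(
    basis = basis,
    composite = composite,
    replicates = reps,
    metadata = list(generator = "gen_pi_curves", seed = cfg$seed,
                    planted_weights = cfg$planted_weights,
                    drivers = cfg$basis_curves$driver,
                    noise_sd = cfg$noise_sd,
                    n_replicates = cfg$n_replicates, log_base = "natural"))
}

#' Generate a Poisson spike train and a fluorescence trace with known truth
#'
#' The spike train is an inhomogeneous Poisson process at `baseline_rate`
#' outside the stimulus window and `evoked_rate` inside it. The fluorescence
#' trace is `background + baseline + transient + noise`, where the transient
#' is a stimulus-locked exponential decay whose true peak dF/F
#' (`amplitude / baseline`) is recorded in the metadata.
#'
#' @param cfg A [synth_config()].
#' @param baseline_rate,evoked_rate Spike rates in Hz (>= 0).
#' @param window Length-2 numeric, stimulus window `c(on, off)` in seconds.
#' @param duration Recording length in seconds.
#' @param n_trials Number of trials for both modalities.
#' @param f_background,f_baseline Background and baseline fluorescence
#'   levels (arbitrary units).
#' @param f_amplitude Transient amplitude at stimulus onset.
#' @param f_tau Transient decay time constant in seconds.
#' @param f_noise_sd Gaussian noise sd added to the signal ROI.
#' @param frame_interval Fluorescence sampling interval in seconds
#'   (default 1/1.07, i.e. a 1.07 Hz frame rate).
#' @return A list: `spikes` tibble (`trial`, `spike_time_s`), `trace` tibble
#'   (`trial`, `time_s`, `value`, `background`), `span = c(0, duration)`,
#'   and `metadata` (true peak dF/F, rates, window).
#' @export
gen_physiology <- function(cfg, baseline_rate = 5, evoked_rate = 30,
                           window = c(30, 31), duration = 61,
                           n_trials = 10L,
                           f_background = 10, f_baseline = 90,
                           f_amplitude = 90, f_tau = 3,
                           f_noise_sd = 0, frame_interval = 1 / 1.07) {
  stopifnot(inherits(cfg, "synth_config"))
  if (baseline_rate < 0 || evoked_rate < 0) {
    abort("spike rates must be non-negative", class = "mblearn_config_error")
  }
  if (length(window) != 2 || window[2] <= window[1] ||
      window[1] < 0 || window[2] > duration) {
    abort("window must be c(on, off) inside the recording",
          class = "mblearn_config_error")
  }
  with_child_seed(cfg$seed, 404L, {
    draw_segment <- function(t0, t1, rate, trial) {
      k <- rpois(1, rate * (t1 - t0))
      if (k == 0) return(NULL)
      tibble(trial = trial, spike_time_s = sort(runif(k, t0, t1)))
    }
    spikes <- purrr::map_dfr(seq_len(n_trials), function(tr) {
      dplyr::bind_rows(
        draw_segment(0, window[1], baseline_rate, tr),
        draw_segment(window[1], window[2], evoked_rate, tr),
        draw_segment(window[2], duration, baseline_rate, tr)) |>
        dplyr::arrange(.data$spike_time_s)
    })

    tgrid <- seq(0, duration, by = frame_interval)
    # lock the transient to the first frame at/after stimulus onset so the
    # planted peak amplitude is attained at a sample
    t_on <- tgrid[which(tgrid >= window[1])[1]]
    trace <- purrr::map_dfr(seq_len(n_trials), function(tr) {
      transient <- ifelse(tgrid >= t_on,
                          f_amplitude * exp(-(tgrid - t_on) / f_tau), 0)
      tibble(trial = tr, time_s = tgrid,
             value = f_background + f_baseline + transient +
               rnorm(length(tgrid), 0, f_noise_sd),
             background = f_background)
    })
    list(
      spikes = spikes, trace = trace, span = c(0, duration),
      metadata = list(
        generator = "gen_physiology", seed = cfg$seed,
        baseline_rate = baseline_rate, evoked_rate = evoked_rate,
        window = window, n_trials = n_trials,
        dff_peak_true = f_amplitude / f_baseline,
        stim_onset = window[1], frame_interval = frame_interval))
  })
}
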