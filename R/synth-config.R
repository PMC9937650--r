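#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable parameter of the synthetic connectome, arena
#' trajectory, performance-index (PI) curve and physiology generators into a
#' single validated object. The same `seed` always yields byte-identical
#' output; each generator expands the global seed by a fixed private offset,
#' so adding one generator to a script never perturbs the draws of another.
#'
#' @param seed Integer seed controlling all generators.
#' @param n_interneurons,n_mbons,n_dans Neuron counts per class (>= 1).
#' @param hub_in_frac Fraction of all MBON->interneuron synapses routed
#'   through the planted hub interneuron, in `[0, 1)`.
#' @param hub_out_frac Fraction of all interneuron->DAN synapses emitted by
#'   the planted hub, in `[0, 1)`.
#' @param edge_count_dispersion Size parameter of the negative-binomial edge
#'   count distribution; smaller values give heavier overdispersion, matching
#'   the count heterogeneity of real connectomes.
#' @param nt_probs Named categorical probabilities over the six major fly
#'   neurotransmitters, used to label interneurons; must sum to 1.
#' @param arena_radius Arena radius in mm (default 45, a 9 cm circular arena).
#' @param n_flies Number of flies per simulated movie.
#' @param frame_rate Video frame rate in Hz (default 30).
#' @param odor_bias Drift strength lambda >= 0, in mm per frame, pulling
#'   flies towards the odorised quadrant pair; 0 gives an unbiased walk.
#' @param step_sd Diffusion step standard deviation in mm per frame.
#' @param basis_curves Tibble of per-driver PI-curve shape parameters with
#'   columns `driver`, `pi_max`, `learn_rate`, `decay_rate`, `react_drop`
#'   (see [default_basis_curves()]).
#' @param planted_weights Non-negative mixing weights, one per basis driver,
#'   used to build the composite curve in log-odds space.
#' @param n_replicates Number of replicate fly-group curves drawn for the
#'   composite; their per-point mean is the analysed curve (default 12,
#'   matching typical group counts per driver line).
#' @param noise_sd Gaussian noise sd applied to each replicate PI value.
#'
#' @return An object of class `synth_config` (a named list).
#' @examples
#' cfg <- synth_config(seed = 1)
#' cfg$planted_weights
#' @export
synth_config <- function(seed = 1L,
                         n_interneurons = 50L,
                         n_mbons = 5L,
                         n_dans = 10L,
                         hub_in_frac = 0.4,
                         hub_out_frac = 0.4,
                         edge_count_dispersion = 1,
                         nt_probs = c(acetylcholine = 0.40, GABA = 0.20,
                                      glutamate = 0.20, dopamine = 0.10,
                                      serotonin = 0.05, octopamine = 0.05),
                         arena_radius = 45,
                         n_flies = 20L,
                         frame_rate = 30,
                         odor_bias = 0,
                         step_sd = 3,
                         basis_curves = default_basis_curves(),
                         planted_weights = c(0.5, 0.2, 0.1, 0, 0, 0),
                         n_replicates = 12L,
                         noise_sd = 0.05) {
  stop_cfg <- function(msg) abort(msg, class = "mblearn_config_error")

  counts <- c(n_interneurons = n_interneurons, n_mbons = n_mbons,
              n_dans = n_dans, n_flies = n_flies)
  if (any(counts < 1)) {
    stop_cfg(paste0("counts must be >= 1; offending: ",
                    paste(names(counts)[counts < 1], collapse = ", ")))
  }
  if (hub_in_frac < 0 || hub_in_frac >= 1 || hub_out_frac < 0 || hub_out_frac >= 1) {
    stop_cfg("hub_in_frac and hub_out_frac must lie in [0, 1)")
  }
  if (abs(sum(nt_probs) - 1) > 1e-8) stop_cfg("nt_probs must sum to 1")
  if (!all(names(nt_probs) %in% NT_LEVELS)) {
    stop_cfg("nt_probs names must be among the six major neurotransmitters")
  }
  if (arena_radius <= 0) stop_cfg("arena_radius must be positive")
  if (odor_bias < 0) stop_cfg("odor_bias must be non-negative")
  if (step_sd <= 0) stop_cfg("step_sd must be positive")
  if (edge_count_dispersion <= 0) stop_cfg("edge_count_dispersion must be positive")
  if (length(planted_weights) != nrow(basis_curves)) {
    stop_cfg("planted_weights must have one entry per basis driver")
  }
  if (any(planted_weights < 0)) stop_cfg("planted_weights must be non-negative")
  if (n_replicates < 1) stop_cfg("n_replicates must be >= 1")
  if (noise_sd < 0) stop_cfg("noise_sd must be non-negative")

  structure(
    list(seed = as.integer(seed),
         n_interneurons = as.integer(n_interneurons),
         n_mbons = as.integer(n_mbons),
         n_dans = as.integer(n_dans),
         hub_in_frac = hub_in_frac,
         hub_out_frac = hub_out_frac,
         edge_count_dispersion = edge_count_dispersion,
         nt_probs = nt_probs,
         arena_radius = arena_radius,
         n_flies = as.integer(n_flies),
         frame_rate = frame_rate,
         odor_bias = odor_bias,
         step_sd = step_sd,
         basis_curves = basis_curves,
         planted_weights = planted_weights,
         n_replicates = as.integer(n_replicates),
         noise_sd = noise_sd),
    class = "synth_config")
}

#' Default per-driver learning/decay shapes for synthetic PI curves
#'
#' One row per optogenetic driver line, in the order used for composite
#' decomposition. `MB043C` targets the alpha1 compartment and is
#' parameterised slow and stable (low `learn_rate`, near-zero `decay_rate`);
#' the remaining drivers are fast and transient, mirroring the qualitative
#' contrast between teacher and student compartments. The remaining rate
#' constants were fixed by an identifiability criterion: over the default
#' protocol they minimise the worst per-driver noise amplification of the
#' log-odds basis matrix (largest diagonal entry of the inverse Gram matrix
#' ~2), so a planted mixture stays recoverable from noisy group means.
#'
#' @return A tibble with columns `driver`, `pi_max`, `learn_rate`,
#'   `decay_rate`, `react_drop`.
#' @export
default_basis_curves <- function() {
  tibble(
    driver     = c("MB032B", "MB213B", "MB312C", "MB043C", "MB109B", "MB315C"),
    pi_max     = c(0.70, 0.65, 0.50, 0.70, 0.60, 0.60),
    learn_rate = c(0.60, 0.45, 1.60, 0.25, 1.90, 1.60),
    decay_rate = c(0.40, 1.30, 0.07, 0.005, 0.50, 0.12),
    react_drop = c(1.15, 0.90, 0.13, 0.05, 1.40, 0.80))
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  connectome:", x$n_mbons, "MBONs,", x$n_interneurons, "interneurons,",
      x$n_dans, "DANs; hub fractions", x$hub_in_frac, "/", x$hub_out_frac, "\n")
  cat("  arena: radius", x$arena_radius, "mm,", x$n_flies, "flies @",
      x$frame_rate, "Hz, odor_bias", x$odor_bias, "\n")
  cat("  curves:", nrow(x$basis_curves), "drivers, planted weights (",
      paste(signif(x$planted_weights, 3), collapse = ", "), "), noise_sd",
      x$noise_sd, "\n")
  invisible(x)
}

# Run `code` under a child seed derived from the global seed by a fixed
# per-generator offset, restoring RNG state afterwards.
with_child_seed <- function(seed, offset, code) {
  withr::with_seed(as.integer(seed) + as.integer(offset), code)
}
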