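# mblearn

Analysis toolkit for studying how dopaminergic subsystems of the
*Drosophila* mushroom body (MB) interact during **second-order
conditioning** — the paradigm in which a stimulus previously paired with
reward becomes itself an effective reinforcer. It is aimed at systems
neuroscientists working with connectome exports, four-field olfactory-arena
behaviour, optogenetic memory-dynamics protocols, and
electrophysiology/dopamine-imaging recordings.

The package covers four analyses plus a synthetic-data module:

1. **Connectome pathway mining.** From neuPrint-style neuron and
   synapse-count tables: screen interneuron cell types by total synapses
   with MBONs and DANs (inclusive threshold, default ≥ 100), enumerate
   simple feedforward pathways MBON → (≤ 2 interneurons) → DANs with a
   per-hop synapse threshold, annotate hops with predicted
   neurotransmitters, rank cholinergic types by output onto reward DANs,
   and flag hub interneurons as outliers of the input × output scatter.
2. **Arena behaviour.** Performance index from trajectory tables,

   PI = (N_odor − N_other) / N_total,

   averaged per frame over the final 30 s of a 60 s test, with reciprocal
   averaging to cancel position bias; the area-normalised radial index
   mean (r/R)², which is 1/2 under uniform occupancy; and onset-anchored
   upwind displacement.
3. **Memory dynamics.** Five indices of learning/extinction dynamics
   (learning rate, training persistency, memory persistency, reactivation
   resistance, early-test persistency), and the decomposition of a
   composite memory curve into driver components. PI values are mapped to
   choice probabilities p = (PI + 1)/2 and to log-odds
   R = log(p/(1 − p)); the composite curve is modelled as
   R_target ≈ Σᵢ wᵢ R_i with wᵢ ≥ 0 (non-negative least squares, no
   intercept), reflecting behavioural bias that is additive in
   log-probability ratio.
4. **Physiology signals.** Gaussian-kernel instantaneous firing rates
   (SD 50 ms), evoked spike counts with spontaneous-rate subtraction over
   1.2 s / 20.6 s response windows, baseline-subtracted response
   magnitudes, and background-subtracted ΔF/F with a 30 s pre-stimulus
   baseline and per-sample trial averaging.
5. **Synthetic data.** Deterministic generators for connectomes with a
   planted hub interneuron, arena trajectories with tunable odor-quadrant
   bias, composite PI curves built as log-odds mixtures with planted
   non-negative weights, and Poisson spike trains / fluorescence
   transients — every planted parameter is recorded in metadata, so each
   downstream analysis can be validated by round trip.

See `vignettes/mblearn-methods.Rmd` for the models, parameter defaults and
design decisions.

## Worked example

```r
library(mblearn)
cfg <- synth_config(seed = 1)

# --- connectome screen: find the hub interneuron -------------------------
cn <- gen_connectome(cfg)
cand <- core_interneurons(cn)            # >= 100 total synapses with MBONs/DANs
dans <- unique(cn$neurons$cell_type[cn$neurons$class == "DAN"])
scatter <- input_output_scatter(cn, "MBON01", dans, cand)
scatter[scatter$outlier, ]
#> # A tibble: 1 × 5
#>   cell_type     x     y product outlier
#> 1 INT048      149  1587  236463 TRUE
cn$metadata$hub_cell_type
#> [1] "INT048"
```

The screen retains the cell types with at least 100 total synapses with
MBONs and DANs, and the planted hub (`INT048`) is flagged as the outlier of
the input × output product — the package's recovery of the
"prominent hub interneuron" motif.

```r
# --- composite memory curve: decomposition and indices -------------------
curves <- gen_pi_curves(cfg)             # planted weights (0.5, 0.2, 0.1, 0, 0, 0)
fit <- nnls_decompose(curves$composite, curves$basis)
fit
#> <pi_decomposition> 6 drivers, 54 test points
#>   weights: MB032B=0.442, MB213B=0.212, MB312C=0.0455, MB043C=0.0183, MB109B=0.045, MB315C=0.0436
#>   residual sum of squares: 0.05662

memory_indices(curves$composite)
#> # A tibble: 5 × 3
#>   index                   value defined
#> 1 learning_rate           0.514 TRUE
#> 2 training_persistency    0.988 TRUE
#> 3 memory_persistency      0.187 TRUE
#> 4 reactivation_resistance 0.200 TRUE
#> 5 early_test_persistency  0.346 TRUE
```

With noisy group curves (SD 0.05 over 12 replicate groups) the fitted
weights land near the planted (0.5, 0.2, 0.1, 0, 0, 0); at `noise_sd = 0`
they are recovered to machine precision with residual ~1e-30. The indices
read the composite's dynamics: it learns about twice as slowly as its
fastest component (learning rate 0.51), barely declines during training
(0.99), and extinguishes strongly across the 12 post-training tests
(memory persistency 0.19).

Plots: `autoplot(fit)` shows observed vs fitted log-odds,
`plot_pi_curves(curves$basis)` the driver curves,
`plot_io_scatter(scatter)` the screen.

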