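---
title: "Circuit mining and memory-curve decomposition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circuit mining and memory-curve decomposition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mblearn)
library(dplyr)
```

`mblearn` implements the computational pipeline used to study how
dopaminergic subsystems of the *Drosophila* mushroom body (MB) interact
during second-order conditioning: mining a hemibrain-style connectome for
feedforward MBON → interneuron → DAN pathways, quantifying four-field
olfactory-arena behaviour, summarising memory dynamics from
performance-index (PI) curves, decomposing a composite memory curve into
non-negative driver components in log-odds space, and quantifying spike
trains and dopamine-sensor fluorescence. A synthetic-data module generates
all of these inputs with planted, recorded ground truth, so the entire
pipeline is testable without any external download.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic generators do and
do not emulate.

## Connectome screening and pathway enumeration

The connectome is a neuron table (`neuron_id`, `cell_type`, `class`,
`predicted_nt`) plus a directed synapse-count edge list. Analyses operate
at the **cell-type level**: counts are summed over member neurons of a
type, matching how connectome studies report types rather than individual
bodies. A per-neuron view is available by working directly on the edge
list.

**Candidate screen** (`core_interneurons()`). An interneuron cell type is a
candidate when its total synapses with the designated MBON and DAN types —
inputs received from them *plus* outputs sent to them — reach a threshold,
100 by default, inclusively. The two directions are summed because the
screen is phrased in terms of total connections with both populations;
MBONs, DANs and Kenyon cells are never candidates themselves.

**Pathway enumeration** (`enumerate_pathways()`). Every simple path from a
source MBON type through at most two interneuron types to a target DAN type
is enumerated by bounded depth-first search, keeping a path only when every
hop carries at least `min_edge_count` synapses. The default
`min_edge_count` is 1 and is configurable, since published circuit diagrams
do not state the cut-off used to draw arrows. Intermediate nodes are
restricted to non-MBON/DAN/KC types and no node repeats; with hop counts
bounded at two interneurons the search always terminates, including on
cyclic graphs. Each hop is annotated with the presynaptic type's predicted
transmitter. Transmitter labels are annotations for interpretation —
acetylcholine excitatory, GABA inhibitory, glutamate inhibitory with the
caveat that its net effect can be excitatory through indirect routes — and
are never used to prune paths.

**Pathway strength** (`pathway_strength()`). The literature draws arrow
widths but defines no scalar path score, so one is defined here: the
default `min_hop` rule is the bottleneck synapse count (the weakest hop
bounds the throughput of a feedforward chain); `geometric_mean` is
provided as a smoother alternative. Parallel pathways between the same
endpoints aggregate by summing per-path strengths. Pathways are returned
sorted by strength, ties broken lexicographically so output is
deterministic.

**Hub detection** (`input_output_scatter()`). Candidates are plotted as
inputs-from-source (x) versus outputs-to-target-DANs (y); rows in the top
quantile of the x·y product (default top 1%) are flagged as outliers. The
product criterion mirrors how hub interneurons are spotted by eye in such
scatters — exceptional on both axes at once. The quantile is a convention
of this package, configurable, since the original identification was by
inspection.

## Arena behaviour

The four-field arena is a disk (default radius 45 mm, i.e. a 9 cm
diameter) divided into four 90° sectors; opposite sectors form the two
diagonal pairs that carry the two odors. Sector boundaries are half-open,
counter-clockwise from a configurable angular offset, so a fly exactly on
a boundary ray is assigned deterministically; the exact centre has no
angle and is assigned the sector of angle 0 and flagged ambiguous.

The **performance index** of a frame is
\[
\mathrm{PI} = \frac{N_\text{odor} - N_\text{other}}{N_\text{total}},
\]
counting flies by position only (occupancy counting is identity-free).
The reported PI is the mean of per-frame PIs over the final 30 s of a 60 s
test window (both configurable); per-frame averaging rather than pooled
counting follows the phrasing of the index as a mean of per-frame ratios.
Each experiment is repeated with odor roles/positions swapped and the two
PIs averaged (`reciprocal_average()`), cancelling position bias and innate
odor preference.

The **area-normalised index** is the mean of \((r_i/r_\text{arena})^2\);
under a spatially uniform distribution its expectation is exactly 1/2 (and
the mean of \(r/R\) is \(1/\sqrt 2\)), giving a parameter-free calibration
point that the test suite verifies by Monte Carlo. **Upwind displacement**
subtracts the index at stimulus onset from the index at each time point;
the sign convention is outward-positive, because arena air flows from the
periphery to a central outlet, so outward movement is upwind.

## Memory dynamics and the log-odds decomposition

A PI maps to the probability of choosing the reinforced stimulus by
\(p = (\mathrm{PI}+1)/2\), the inverse of \(\mathrm{PI} = p - (1-p)\).
The behavioural bias is expressed as the natural log-odds
\(R = \log\!\big(p/(1-p)\big)\); chance is \(R = 0\). Probabilities are
clipped to \([\varepsilon, 1-\varepsilon]\) with \(\varepsilon = 10^{-3}\)
(configurable) so that \(R\) stays finite at \(|\mathrm{PI}| = 1\). The
base of the logarithm is recorded in the fit output; weights scale with
the base but their ratios and zeros do not.

`nnls_decompose()` models the composite memory curve of a driver that
activates several dopaminergic compartments as **additive in log-odds**:
\[
R_\text{target}(t) \approx \sum_i w_i\, R_i(t), \qquad w_i \ge 0,
\]
and estimates the weights by non-negative least squares (Lawson–Hanson,
via `pracma::lsqnonneg`) with no intercept, since \(R=0\) is chance by
construction. Design choices where the published analysis is silent:

* **Test points.** The fit uses every test point present in both target
  and basis curves by default; a `test_points` selector restricts it.
  Points missing from any curve raise an alignment error naming them.
* **Replicates.** Multiple PI values per test point are averaged before
  fitting (group-mean curves), matching how published curves are means
  over fly groups.
* **Early points.** The first (10 s) training point is included even
  though such points may fit poorly; no down-weighting is applied.

Five **memory-dynamics indices** summarise a curve over the
training / extinction / reversal / re-reversal / reactivation protocol:
learning rate (first-training PI over the peak of training trials 1–5),
training persistency (5th-training PI over that peak), memory persistency
(mean of the 12 extinction tests over that peak), reactivation resistance
(mean of the last three post-reactivation tests over the 5th re-reversal
conditioning PI), and early-test persistency (mean of tests 3–6 over test
1). Each index is defined only when its denominator is strictly positive;
undefined values are returned as `NA` with a warning and flagged in
`memory_indices()`, never coerced to a number. All five equal 1 on a flat
positive curve.

## Physiology signals

* `instantaneous_rate()` convolves spikes with a Gaussian kernel
  (SD 50 ms by default), evaluated on a uniform grid. The kernel is
  truncated at ±5 SD (mass error below \(10^{-6}\)) and not renormalised
  at recording edges; the integral of the rate equals the spike count away
  from the edges.
* `evoked_spike_count()` counts spikes in a response window — 1.2 s for a
  1 s odor, 20.6 s for a 20 s odor — and subtracts the spontaneous
  expectation, rate × window length. The spontaneous rate is estimated
  from a configurable pre-stimulus span (default 5 s) when not supplied;
  results may be negative for suppressed responses.
* `response_magnitude()` averages the baseline-subtracted trace over the
  response window, with a configurable pre-stimulus baseline span.
* `delta_f_over_f()` subtracts a background ROI series, takes the mean of
  the subtracted signal over the 30 s before stimulation as \(F_0\), and
  returns \((s - F_0)/F_0\) per trial plus the per-sample mean across
  trials. A non-positive \(F_0\) is a loud data error, never a silent
  `NaN`.

## The synthetic-data generators

Each generator is a pure function of a `synth_config()`, whose single seed
expands into fixed per-generator child seeds — adding one generator to a
script never changes another's draws — and every planted parameter is
echoed in an output metadata record.

**Connectome.** MBONs (glutamatergic), DANs (dopaminergic) and
interneurons with transmitters drawn from `nt_probs`. Edge counts are a
shifted negative binomial (`size = edge_count_dispersion`, default 1;
mean ≈ 9), overdispersed as real connectome counts are and dense enough
that interneuron totals straddle the 100-synapse screen, so the threshold
filter is exercised on both sides. One random interneuron is planted as a
hub carrying `hub_in_frac` of MBON→interneuron and `hub_out_frac` of
interneuron→DAN synapses (default 0.4 each) and is always labelled
cholinergic, emulating the excitatory-hub phenotype the screen is designed
to find.

**Trajectories.** A discrete-time drift–diffusion walk in the arena disk
with reflecting boundary: per frame, Gaussian steps of SD 3 mm plus, when
`odor_bias` λ > 0, a drift of λ mm towards the nearer of two anchors at
half-radius in the odorised quadrant pair. This is the simplest model
with a tunable expected PI; λ = 0 gives expected PI exactly 0 by symmetry.
The null-bias Monte-Carlo check uses 20 000 flies over 5 frames
(\(10^5\) fly-frames): flies are independent while frames within a fly are
autocorrelated, so many short trajectories, not one long one, drive the
estimator's convergence.

**PI curves.** Each driver has a deterministic basis curve: saturating
exponential learning \(\mathrm{PI}_{\max}(1 - e^{-k\,\text{trial}})\)
during conditioning, exponential decay during extinction-style tests, a
sign-flipped copy in the reversal phase, and a per-driver decay after
reactivation. The default protocol is 5 training trials, 12 extinction
tests, reversal and re-reversal phases of 5 conditioning trials plus 12
tests each, and 3 reactivation tests (54 points). The composite curve is
built by summing planted non-negative weights × driver log-odds, mapping
back through the logistic, then drawing `n_replicates` (default 12)
noisy group curves (Gaussian noise in PI space, SD `noise_sd` = 0.05,
clipped to \([-1, 1]\)) whose per-point mean is the analysed curve — the
same group-mean structure as published curves.

The default driver rate constants deserve a note. The α1 driver
(`MB043C`) is pinned slow and stable a priori (learning rate 0.25, decay
0.005), the defining teacher-compartment phenotype. The remaining
constants were fixed once by an identifiability criterion: over the
default protocol they minimise the worst per-driver noise amplification
\(\max_i \sqrt{[(A^{\top}A)^{-1}]_{ii}}\) of the log-odds basis matrix
(≈ 2 for the adopted design). Saturating-exponential families are
intrinsically collinear in log-odds space, and a careless choice of rates
makes the planted mixture unidentifiable no matter how good the solver is;
the adopted design keeps planted weights recoverable to ±0.05 from
group-mean curves at the default noise level.

**Physiology.** Spike trains are piecewise-homogeneous Poisson
(baseline rate outside, evoked rate inside the stimulus window);
fluorescence traces are background + baseline + a stimulus-locked
exponential transient + optional noise, sampled at the 1.07 Hz imaging
frame rate, with the transient locked to the first frame at/after onset so
the planted peak ΔF/F (amplitude/baseline) is attained at a sample.

**What the generators do not emulate.** Real hemibrain degree
distributions, neuron morphology and hemisphere truncation; real fly
locomotor statistics (speeds, wall-following, interactions); the
idiosyncratic shapes of real memory curves beyond the
saturating/decaying family; photobleaching, motion artefacts and sensor
kinetics. Passing tests therefore demonstrate correctness of the
*formulas and algorithms* on data with the assumed structure, not
robustness to every property of real recordings.

## Numerical conventions and degenerate inputs

* Ties: quadrant boundaries half-open; pathway ordering breaks strength
  ties lexicographically; modal transmitter per cell type breaks ties
  alphabetically.
* Degenerate inputs: empty spike trains give zero rates; an empty
  cholinergic field gives an empty ranking, not an error; a scored frame
  with zero flies, a missing curve point, or a non-positive \(F_0\) are
  loud, classed errors.
* Problem sizes in the standard checks (chosen for tight Monte-Carlo
  bounds at interactive run times): \(10^6\) points for the uniform-disk
  closed forms, 100 random graphs of ≤ 30 nodes for enumeration-vs-oracle
  equality, 50 generator seeds for weight recovery, 20 for hub recovery,
  \(10^5\) fly-frames for the null-bias bound.

## Known limitations

* The decomposition assumes additivity in log-odds; synergistic effects
  of co-activated compartments (e.g. concurrent suppression of
  punishment-coding DANs) are outside the model and show up as residual.
* Weight recovery tolerances hold for the default generator conditions;
  heavier noise, fewer replicates or more collinear basis families widen
  them, as quantified by the basis-matrix amplification factor above.
* The candidate screen and enumeration operate on cell types; neurons of
  one type with heterogeneous connectivity are not distinguished.
* Trajectory-derived statistics assume already-tracked positions in
  arena-centred mm; video processing and fly detection are out of scope.

## A worked pipeline

```{r pipeline}
cfg <- synth_config(seed = 1)

# connectome screen and hub recovery
cn <- gen_connectome(cfg)
cand <- core_interneurons(cn)
dans <- unique(cn$neurons$cell_type[cn$neurons$class == "DAN"])
scatter <- input_output_scatter(cn, "MBON01", dans, cand)
scatter[scatter$outlier, ]
cn$metadata$hub_cell_type

# pathways out of a teacher MBON
enumerate_pathways(cn, "MBON01", dans[1], max_interneurons = 1,
                   min_edge_count = 20)

# composite memory curve: decomposition and indices
curves <- gen_pi_curves(cfg)
fit <- nnls_decompose(curves$composite, curves$basis)
tidy(fit)
glance(fit)
memory_indices(curves$composite)
```
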