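---
title: "Input-driven neuronal classification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Input-driven neuronal classification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the stimulus and neuron models, the fitting and clustering procedures,
the parameters that matter, and the places where the design was genuinely
open and a decision had to be made. Nothing here reports an empirical
number that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The question and the pipeline

Functional classification of neurons usually relies on features measured
under a conventional step-and-hold (SH) current protocol. But a neuron in
a circuit never receives a current step; it receives a fluctuating
barrage of synaptic input. The pipeline in this package compares
classifications obtained under the two regimes and asks which
electrophysiological attribute families carry distinct versus redundant
information when neurons are driven by a physiologically realistic
frozen-noise (FN) input.

The stages are: stimulus generation (`generate_fn_current`,
`generate_sh_protocol`), GLIF simulation (`simulate_glif`), GLIF fitting
(`fit_glif`), feature extraction (`ap_feature_vector`, `compute_sta`,
`extract_waveforms`), graph clustering (`build_knn_graph`,
`louvain_cluster`, `select_resolution`, `ecg_cluster`), agreement
statistics (`cluster_likelihood`, `compare_labelings`,
`cosine_summary`), and the multi-set factor model (`fit_mcfa`,
`variance_report`, `feature_importance`). `run_protocol_comparison()` and
`run_attribute_comparison()` chain them into the two headline analyses.

## 2. Stimuli

**Frozen noise.** A binary hidden state switches as a Markov chain
sampled on the stimulus grid with per-sample switching probability
`dt/tau`. The protocol names only a single time constant, so the chain is
symmetric: dwell times are exponential with mean `tau` in both states
(250 ms for slowly responding, putatively excitatory neurons; 50 ms
otherwise). Each of `n_units` Poisson units (1000 at full scale) fires at
its on- or off-state rate; the pooled, weight-summed spike train is
convolved with a causal exponential kernel of 5 ms decay and unit
amplitude at the spike sample — implemented exactly as a first-order
recursive filter. The per-unit rates are free parameters of the protocol; the generator
draws `q_off ~ U(1, 10) Hz` and a gain `q_on/q_off ~ U(0.5, 2)` per unit,
which yields a mixture of on- and off-preferring units with signed
weights `w_i = log(q_on/q_off)`; both ranges are configuration values.
Sampling is exact but vectorized: the pooled per-sample count is Poisson
at the summed state rate and each spike is attributed to a unit with
probability proportional to its rate, which is distributionally identical
to independent per-unit trains.

The injected current is `scale * drive + baseline`. Neither factor is
fixed by the protocol; by default `scale` is set so the current's standard deviation
equals 50 pA (`target_sd`), a typical fluctuation amplitude for somatic
injection, and `baseline` is a per-class archetype value (see §6).

**Step and hold.** Ten 500-ms rectangular depolarizing steps, equally
spaced from 40 pA to 400 pA, holding potential −70 mV, padded with 100 ms
of zero current on each side so onset features are measurable.

## 3. GLIF simulation

Forward-Euler integration at the stimulus resolution with stochastic
spiking at hazard `λ = λ0 exp[(V − V_T)/ΔV]` per step
(`P(spike) = 1 − exp(−λ dt)`). After a spike the voltage is clamped to
`V_reset` for `t_ref` and integration resumes from `V_reset` with the
Euler step taken at the final clamped sample — this convention matters:
it guarantees that every retained sample of a simulated trace satisfies
the subthreshold difference equation exactly, so the fitter is unbiased
(an earlier draft that duplicated the reset value for one extra sample
produced a spurious fast component in the fitted adaptation kernel).

The adaptation current η and threshold movement γ are rectangular-basis
expansions: 10 bins with log-spaced edges over a 500-ms support (fine
near the spike where the kernels vary fastest; 10 000 samples at 20 kHz).
Basis bins are mapped to integer sample ranges once (`eval_kernel`,
`basis_sample_breaks`) and the same integer binning builds the fitter's
spike-history regressors, so simulation and fitting are bit-consistent.

The point-process model produces no action-potential waveform of its own.
Because downstream stages (peak detection, waveform features, the reset
extraction) need one, a parameterized triangular template — rise to a
+35 mV peak at the spike sample, fall to `V_reset` — is pasted over the
reset window. The template never alters the recorded spike times. Rise
and fall times are class archetypes (broad ~1.4 ms base for the
excitatory-like class, narrow ~0.5 ms for the inhibitory-like class). A
warning is emitted if the per-step hazard `λ·dt` ever exceeds 0.2, the
signal that `dt` is too coarse for the hazard approximation.

## 4. GLIF fitting

Three stages, all restricted to a training window from the start of the
trial (default 100 s; applied to both subthreshold and threshold stages,
since a single training set is the natural reading):

1. **Reset voltage** — the spike-triggered average voltage at
   `peak + t_ref`, requiring `t_ref` (default 4 ms) below the minimum
   inter-spike interval.
2. **Subthreshold regression** — ordinary least squares of the
   forward-difference `dV/dt` on `[V, 1, I, f(1), …, f(K)]`, excluding
   samples within `(t_spike − 5 ms, t_spike + t_ref)` of any spike. The
   injected current is included as a regressor with coefficient `1/C`:
   without it the capacitance is not identifiable from the voltage trace
   alone. Coefficients map to `C = 1/b_I`, `g_L = −b_V C`,
   `E_L = −b_1/b_V`, `a_k = −b_k C`. Basis bins never visited by a spike
   history are dropped from the design (their coefficients are zero by
   construction); a genuinely collinear design raises an error naming the
   offending columns. The solve uses normal equations — the design is
   millions of rows by ~13 columns, and the data are simulated at
   double precision, so the squared condition number is harmless.
3. **Threshold likelihood** — with the model subthreshold voltage
   integrated from stage-2 parameters (observed spike times forcing the
   resets), the log-linear reparametrization
   `log λ = log λ0 + b_V V + b_0 + Σ_p b_p f(p)` makes the point-process
   likelihood a concave Poisson-GLM objective, maximized by Newton
   iterations with step halving (voltage column centred for
   conditioning; gradient-norm tolerance 1e−8, 200-iteration cap; bins
   within `(t_spike, t_spike + t_ref]` excluded from the integral term).
   Then `ΔV = 1/b_V`, `V_T* = −b_0 ΔV`, `γ_p = −b_p ΔV`.

**Ridge on the threshold kernel.** Basis bins in which no spike is ever
observed while their history regressor is active have a likelihood that
increases monotonically as the corresponding coefficient walks to
infinity (the rate in that bin is driven to zero). The early post-spike
bins are in this regime almost by construction, because the refractory
period removes most of their support. A small L2 penalty (`ridge = 1e−2`)
on the kernel coefficients only — never on `ΔV` or `V_T*` — keeps those
directions bounded and restores quadratic Newton convergence, at a bias
that is negligible for identified bins (the data terms there are larger
by several orders of magnitude).

The subthreshold fit quality is `R² = 1 − SSE/SST` on the
exclusion-filtered samples; fits with `R² ≤ 0.7` are flagged `excluded`
and still returned. A minimum of 10 spikes is required for the threshold
stage; below that the MLE is ill-conditioned.

At the package's validation scale (20 neurons, 100 s at 20 kHz, noiseless
subthreshold dynamics) the round trip recovers C, g_L, E_L within 5%,
`V_reset` within 0.5 mV and `V_T*` within 1 mV for at least 90% of
neurons, with adaptation-kernel cosine similarity ≥ 0.9
(`tests/testthat/test-acceptance.R`, `scripts/acceptance.R`).

## 5. Feature extraction

Spikes are voltage peaks with height ≥ 20 mV. A minimum peak
separation of 80 ms, sometimes quoted for this protocol, would be
incompatible with retaining spikes at inter-spike intervals down to
3 ms; the default is therefore 4 ms — 80 samples at 20 kHz, the likely
intended unit — and it is a visible argument. Waveforms are cut 2 ms before / 3 ms
after the peak (5-ms form) or 5 ms both sides (10-ms form, used for the
putative excitatory/inhibitory split); spikes flanking an interval
< 3 ms are discarded as burst-contaminated.

The 22 action-potential attributes follow a fixed, documented order
(`ap_feature_names`): current at first spike, AP count, time to first
spike, firing rate, ISI mean/median/min/max, instantaneous rate
(reciprocal of the mean ISI), threshold first/mean/median/max/min (the
voltage where `dV/dt` first reaches 25 mV/ms, searched up to 5 ms before
the peak), and width/amplitude mean/median/max/min (width between
threshold crossings around the peak, linearly interpolated; amplitude
peak minus threshold). For FN trials the windows span the whole trial;
for SH trials AP count and rate come from the 500-ms window of the
highest step, time-to-first-spike and current-at-first-spike from the
lowest spiking step, and per-spike statistics pool spikes from all
sweeps (the sweeps are pooled, not concatenated — a convention this
package fixes explicitly).

The spike-triggered average is the mean 100-ms stimulus segment ending at
the sample before each spike peak (spikes without a full preceding window
are dropped), then z-scored against its own mean and SD and scaled to
unit L2 norm. No whitening or regularization. The per-vector (not
population-level) standardization follows the wording that the operation
acts on "the STA vector".

## 6. The synthetic population

The generator emulates the experimental recording conditions: per-neuron
paired FN (360 s at 20 kHz at full scale) and SH trials, and a population
of two broad classes. The archetypes live in shipped YAML profiles
(`inst/extdata/paper_scale.yaml`, `test_scale.yaml`), not in code:

* **E-like** (weight 186/312): broad spike template, strong slow
  adaptation (η amplitude 60 pA, 120-ms decay), τ_m ≈ 20 ms, driven by
  the slow (250 ms) hidden state with a 200-pA baseline — fires below
  5 Hz under the default drive.
* **I-like** (weight 126/312): narrow template, weak fast adaptation
  (12 pA, 30 ms), τ_m ≈ 10 ms, fast (50 ms) hidden state, 160-pA
  baseline — fires above 10 Hz.

Baselines were calibrated once by simulating the archetypes across a
baseline grid and picking the values that put the class rates in those
physiological bands; they are conditions of the synthetic study, not
tuning knobs. Class allocation is deterministic largest-remainder
rounding of the mixture weights (so 312 neurons give exactly 186 + 126),
with the order shuffled under the master seed. Per-neuron parameters are
independent truncated normals around the archetype means.

What the generator does **not** emulate: real waveform diversity beyond
rise/fall geometry (no afterdepolarization, no amplitude adaptation
within bursts), electrode artifacts, drift, or drug conditions. Passing
tests therefore demonstrate that the pipeline recovers structure it can
represent, not that real recordings will separate as cleanly. In
particular the putative E/I split — clusters of 10-ms mean waveforms
labeled inhibitory when the cluster's median firing rate exceeds 10 Hz
and its median AP width is below 0.5 ms (the underlying broad/narrow
rule is qualitative; these thresholds are configuration values)
— is reliable at full scale but can misassign neurons in small, short
test-scale populations, where mean waveforms are noisy and clusters can
straddle the archetypes.

The reduced `test_scale` profile shortens trials to 10 s with a 200-unit
presynaptic pool but keeps 20 kHz: sub-millisecond spike shapes are
undersampled at lower rates and the waveform stages degrade, which is a
property of the measurement, not of the population.

## 7. Graph clustering

Attribute matrices are standardized per column (population SD;
zero-variance columns are dropped with a warning rather than producing
NaNs) and row-normalized to unit L2. The clustering substrate is the
high-dimensional fuzzy k-nearest-neighbour graph of the UMAP
construction — exact Euclidean kNN (k = 20, distance parameter 0.1
recorded for completeness), per-point membership strengths
`exp(−(d − ρ_i)/σ_i)` calibrated so they sum to `log2(k)`, symmetrized by
`a + a' − a a'`. The 2-D embedding is deliberately not part of the
clustering path (it is plot-only), which also makes graph construction
deterministic.

Louvain community detection runs at resolution γ; the modularity reported
for any labeling is always recomputed by direct evaluation of the
generalized modularity on the adjacency, independent of the optimizer.
The formula is evaluated on the symmetrized graph with in-degree equal to
out-degree (the degree-based null uses `d_i d_j`). Resolution selection
follows the stability protocol: for each γ in 0–5 by 0.5, 25 Louvain runs
on random 90% node subsamples (90% and 80% are both common choices;
0.9 is the default and the fraction is an argument),
recording mean ± SD of modularity and cluster count; the selected γ
maximizes mean modularity over strictly positive γ (γ = 0 has a
degenerate single-community optimum and is recorded but excluded). Each
subsample run keeps the best of 3 restarts by recomputed modularity, so
the stability statistics reflect the data rather than Louvain's
node-order tie-breaking; the final full-graph run keeps the best of
`n_repeats` restarts. Note that on kNN graphs the generalized modularity
typically decreases with γ, so the scan tends to select the smallest
positive grid value; occasionally a 90% subsample's max-modularity
partition at that resolution genuinely splits one planted component,
which is visible as a small nonzero cluster-count SD.

The ensemble variant (ECG) generates k = 16 first-level Louvain
partitions with randomized vertex order, reweights each edge to
`w* + (1 − w*) ·` (co-clustering frequency) if the edge lies in the
graph's 2-core and to the floor `w* = 0.05` otherwise, and runs a final
Louvain pass on the reweighted graph.

Agreement statistics are own implementations validated against
brute-force enumeration (and, for ARI, against `mclust`): the
row-normalized cluster-likelihood matrix; ARI; AMI under the permutation
model with arithmetic-mean normalization; block-averaged cosine
similarity matrices, where within-cluster blocks of a single labeling
average only the strict upper triangle; and the three-group
(within-class ×2, across-class) cosine value sets handed to standard
omnibus tests (`oneway.test` et al.), which are not reimplemented.

## 8. MCFA

The multi-set model is a factor model with block-structured loadings:
stacking the latent vector `u = (z, x_1, …, x_M)`, each set's features
load on `z` (shared, dimension d) and on their own `x_m` (private,
dimension k_m; default 2, and 1 for sets of ≤ 8 features, matching the
convention that low-dimensional sets get one private factor). EM computes
exact posterior moments of `u` given all sets and maximizes the expected
complete-data likelihood per set, preserving the zero blocks; the
marginal log-likelihood is evaluated by Woodbury/determinant-lemma
identities (never forming a p × p covariance) and asserted non-decreasing
every iteration, with a tolerance of `1e−5·(|ℓ|+1)` for floating-point
wobble in near-degenerate fits. Residual variances are floored at 1e−4:
the adaptation-current set sampled from K rectangular basis coefficients
contains thousands of exactly duplicated columns, and an unfloored ψ
collapses and destroys the conditioning of the Woodbury solve.

Initialization: shared loadings from the top-d principal components of
the concatenated standardized data (scores scaled to unit variance),
private loadings from per-set residual principal components, ψ from
residual diagonals — a concrete instantiation of correlation-based
initialization with an average-variance constraint, for which no single
canonical recipe exists.

The shared dimension d is a user decision. `select_shared_dim()` reports
per-set and pooled counts of correlation-matrix eigenvalues above a noise
threshold under two rules: `one_plus_ratio` uses `1 + p/N` (a
conservative heuristic, the default) and `mp_edge` uses the
Marchenko–Pastur bulk edge `(1 + sqrt(p/N))²`, the standard random-matrix
choice; the two disagree and both are reported.

Variance reporting divides `Σ W²`, `Σ L²`, `Σ ψ` by the empirical total
feature variance per set, so the three percentages sum to ~100 at
convergence. Feature importance uses the single-mode posterior mean
`E[z | y_m]` under the marginal model for set m alone — implemented as
the standard Gaussian conditional mean, which fixes where ψ enters the
projection — and scores
each shared dimension by the mean pairwise correlation of the single-mode
posteriors across sets.

## 9. Validation scales and numerical choices

The test suite and the acceptance script run at deliberately chosen
problem sizes: GLIF recovery at 20 neurons × 100 s × 20 kHz (the fit is
insensitive to longer windows); clustering recovery on a 400-point,
4-component Gaussian mixture at 5-SD separation with the full resolution
scan; STA validation on a linear-filter neuron — no adaptation, reset
placed at the operating voltage and a low (~8 Hz) rate so the reset
erases little filter memory, since each reset truncates the neuron's
effective input memory at the preceding inter-spike interval — over
1500 s of white noise (~12 000 spikes); MCFA recovery at N = 500 with a
60/30/10 shared/private/residual split, and the headline ranking
construction at the full attribute dimensions (22 / 6 / 10 000 / 2 000,
N = 312). Degenerate inputs are handled explicitly throughout: empty
spike trains, zero-variance features and traces, kernels without support,
singleton clusters, and rank-deficient designs all produce typed errors
or flagged results rather than NaNs.

## 10. Known limitations

* The GLIF forward model pastes a stereotyped template for the spike
  shape; waveform-based analyses on synthetic data therefore probe the
  template parameters, not true AP biophysics.
* The threshold-kernel ridge introduces a small bias in γ for bins with
  very few post-spike observations; the clustering six-vector does not
  include γ, so downstream analyses are unaffected.
* The generalized-modularity resolution scan is close to degenerate on
  fuzzy kNN graphs (see §7); the scan's value lies in the stability
  profile more than in the argmax itself, and a fixed γ = 1 is the
  conventional default when the scan is skipped.
* AMI's expected-MI term is exact but O(levels²·n) per pair; for very
  large populations with many clusters it becomes the slowest agreement
  statistic.
* The putative E/I rule depends on two thresholds (10 Hz, 0.5 ms) that
  are reasonable for cortical data but are not universal.
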