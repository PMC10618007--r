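---
title: "Stochastic olfactory population codes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic olfactory population codes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfstoch)
```

## The scientific problem

Third-order olfactory neurons — Kenyon cells (KCs) of the fly mushroom body
and principal cells of the mouse piriform cortex — respond sparsely to
odors, but not consistently: across repeated presentations of the same
odor, a small core of cells responds in most trials while a much larger
cohort responds in only one or a few. Cells responding in more than half
of an odor's trials are called *reliable*; cells responding in at least one
but at most half are *unreliable*. This package implements the complete
analysis chain around that observation:

1. significance-thresholded response detection and reliability
   classification from trial-resolved ΔF/F tensors;
2. the population statistics of the stochastic code — per-trial and
   per-odor class fractions, the *overlap* statistic for odor pairs, and
   maximum-likelihood Gamma fits of the reliability, response-size and
   overlap distributions;
3. a linear rate-firing model of the PN → KC → APL winner-take-all (WTA)
   circuit with multiplicative noise at six loci, used to ask where the
   trial-to-trial variability originates;
4. an associative-learning model of KC→MBON synaptic depression that
   quantifies what reliable and unreliable cells each contribute to odor
   discrimination under short ("normal") and long ("extended") training;
5. reliability-class-masked odor decoders (LDA, kNN, linear SVM) scored by
   accuracy and a rank-based all-to-all AUC.

Everything runs on a seeded synthetic-data generator that emulates the
statistical structure of the recordings, so the full chain is testable
without any downloaded data.

## The synthetic-data generator

`generate_responses()` draws, for every (cell, odor):

* a latent response probability $p$ from a Gamma distribution truncated to
  $[0,1]$ by rejection sampling. The fly preset uses shape 0.64, scale
  0.42; the mouse preset shape 0.64, scale 0.17. (The mouse scale is
  reported inconsistently at the source — 0.17 in the figure caption and
  0.28 in the text; the preset takes the caption value.)
* a base amplitude $G$ from the response-size Gamma (fly: shape 0.77,
  scale 0.28), in ΔF/F units.

On each trial the cell responds with probability $p$; responding trials
add an amplitude $G\,e^{b (p - \bar p)}$ to the response window, where
$b$ (`amplitude_coupling`, default 1.5) sets the exponential coupling of
expected response size to reliability and $\bar p$ is the mean of the
truncated reliability distribution (centering makes the coupling
amplitude-neutral for an average cell). The exponential form mirrors the
observed log-linear relation between mean response and reliability; the
source reports only the quality of that fit, not its coefficients, so $b$
is a package choice, fixed once. Every frame carries i.i.d. Gaussian
baseline noise (`baseline_sd`, default 0.05 ΔF/F — small enough that most
configured responses clear the 2.33-SD detection threshold, large enough
that detection is non-trivial).

Two numerical points deserve emphasis:

* **Truncation bias.** Because ~4% of the fly reliability Gamma's mass
  lies above 1, the truncated latent probabilities are not exactly
  Gamma-distributed: a plain ML refit of the latent field recovers the
  shape to within ~9% but understates the scale by ~25%. Recovery checks
  therefore run against `draw_preset_values()`, which samples the
  configured (untruncated) distribution; the latent field inside a tensor
  is documented as truncated.
* **Frame grid.** The generator is species-agnostic: the fly-like grid is
  20 baseline frames + 5 response frames of 0.5 s (10 s baseline, 2.5 s
  response window), the mouse-like grid 22 + 10 frames of 0.453 s. All
  analysis code works in frames, never seconds.

`generate_correlated_pair()` builds two-odor panels with a target Pearson
correlation between trial-averaged population vectors. The two odors'
latent reliability and amplitude fields share a Gaussian copula; the
copula correlation is calibrated by bisection against short simulations at
the same cell and trial counts, and the realization kept is the first
within ±0.1 of the target. Because the copula couples cells monotonically,
the cells shared between similar odors are predominantly the
high-reliability ones — the feature of real similar odor pairs that drives
the overlap and learning analyses. Targets that the cell count cannot
support raise an error rather than silently clipping.

What the generator does **not** emulate: imaging artifacts (motion,
neuropil contamination), temporal response dynamics within the window,
adaptation across trials, and correlated baseline noise across cells.
Tests passing on synthetic data therefore validate the statistical
machinery, not the imaging pipeline upstream of it.

## Response detection and classification

A cell-trial counts as responding when its mean ΔF/F over the response
window exceeds the baseline mean by 2.33 baseline SDs (the one-sided
Gaussian 1% point; `threshold_sd` is configurable, and
`threshold_sensitivity()` re-runs the chain over a threshold grid).

The baseline statistics are computed from means over non-overlapping
baseline sub-windows of the response-window length, so that the compared
quantities have equal sampling variance. One trial's baseline yields only
4 such windows on the fly grid, and a 2.33-SD threshold estimated from 3
degrees of freedom has a ~5% false-positive rate instead of the nominal
~1%; the default therefore pools sub-windows across all trials and odors
of a cell (`baseline_scope = "cell"`, 24+ windows), which restores the
intended tail (~1.5% measured on pure-noise tensors). Per-trial baselines
and raw per-frame statistics remain available as options. Cells with zero
baseline variance are flagged and excluded rather than divided by.

Classification follows the more-than-half rule: *reliable* >
`n_trials / 2` responses, *unreliable* in $[1, n_trials/2]$ (an exact half
is unreliable), *silent* otherwise; the three classes partition the
population for every odor. The expected response of a cell-odor is the
trial-mean of (indicator × amplitude), i.e. response probability times
mean significant amplitude. Population fractions are reported per trial
(class members responding in that trial) and per odor (class members over
all trials), with the denominator — all imaged cells or responsive cells
only — always an explicit argument, since the two conventions are used for
different analyses. SEMs are reported both over odor-trial pairs and over
odor means, as the appropriate reduction differs by figure style.

The overlap of a cell for an odor pair is $p_A p_B$, its probability of
responding to both odors (a 4-of-6 and 2-of-6 responder scores
$8/36 = 0.22$). `fit_gamma()` wraps a two-parameter maximum-likelihood
Gamma fit (location fixed at zero) with a Kolmogorov–Smirnov goodness
statistic, and `cumulative_frequency()` provides the nonparametric
cumulative curve used for plotting such distributions. Similar /
dissimilar odor-pair labels default to $r > 0.5$ and $r \le 0.15$; 0.18 is
an accepted alternative dissimilar bound (the two give the same
partition in practice), and both the trial-pair-mean and averaged-vector
correlations are always reported side by side since the latter runs
systematically higher.

## The winner-take-all circuit model

The rate model wires 50 projection-neuron (PN) types to 150 KCs (2,000
for full-mushroom-body runs): per KC, a claw count from Binomial(8, 0.85)
(zero draws redrawn), a uniformly sampled PN type per claw, and a claw
strength from Gamma(4, 4). Odors are exponential PN rate vectors. Every
KC exchanges the same number of unit-strength synapses with the single
inhibitory APL neuron in both directions, drawn uniformly on 5–30 per KC
(mean 17.5, matching the anatomical mean of ~15–20 within the reported
5–38 range; the anatomical correlation between the two directions is
implemented as identity since its magnitude is unreported).

A trial is one feedforward–inhibit–rectify pass:

$$K_i = \Big[\sum_j P_j s_{ji} - \mathrm{APL} \cdot s_{A K_i} \cdot g\Big]_+,
\qquad \mathrm{APL} = \sum_i K_i\, s_{K_i A},$$

with a KC threshold $t$ (default 0, as used for parameter exploration)
applied to the feedforward drive before the APL step. The equations are
mutually recursive in principle; the single-pass evaluation matches their
one-shot algebra, and the implementation deliberately avoids iterating to
a fixed point (an iterated variant changed none of the reported statistics
in exploratory runs but costs a multiple of the runtime).

The gain $g$ is calibrated by root bracketing so that the **noiseless**
mean active fraction across the odor panel hits a target in the 6–11%
band (±0.5 percentage points); the active fraction is monotone
non-increasing in gain, which the calibration exploits and the tests
assert.

Multiplicative noise $x \mapsto x(1+\eta)$, $\eta \sim N(0,\sigma)$, fresh
every trial, can enter at six loci: PN rates, PN→KC synapses, KC rates,
KC→APL synapses, the APL rate, and APL→KC synapses. The single- and
multi-synapse WTA variants differ only in the synaptic loci: in the
single-synapse variant all of a KC's APL synapses share one noise draw;
in the multi-synapse variant each unit synapse draws independently, so a
KC's summed coupling becomes $n(1+\bar\eta)$ with
$\mathrm{sd}(\bar\eta) = \sigma/\sqrt{n}$ — computed exactly in that form.
This is the mechanistic heart of the model: per-synapse noise averages out
over ~7 claws or ~17 APL synapses, while noise in the APL *rate* (source
noise) reaches every KC unattenuated. The tests measure both facts
directly on the simulator.

Default noise levels are fixed at the physiologically motivated values:
PN 0.25 (mid of the reported 0–50% band), all synaptic loci 0.20 (mid of
15–25%), KC 0.45 (rate noise in PNs and KCs is reported up to 50%, and KC
noise trades off inversely with APL noise in the successful region), APL
0.28 (the centre of the successful configurations). Under these defaults
the calibrated 150-KC multi-synapse model reproduces the five
experimental characteristics of the stochastic code — reliable:unreliable
ratio per trial 0.72, reliable 5.3% and unreliable 7.2% per trial,
reliable 6.1% and unreliable 29% per odor — within the ±25% band used by
`evaluate_characteristics()` (the acceptance band itself is a package
default; the source never states one). A single noisy locus does not
suffice: with every other locus silent, APL noise capped at 0.30 leaves
the ratio near 1.1, and feedforward PN noise needs $\sigma$ near 1.0 to
approach 0.72 — the ordering that identifies the WTA circuit, not sensory
noise, as the variability source. `parameter_sweep()` runs grids over
noise configurations × gain targets with replicate circuits and scores
each row, and its `summary()` ranks configurations by relative distance
to the characteristic targets.

One statistic runs systematically ~10% high: reliable cells per odor
(6.6–6.9% against 6.1%), because model reliable cells are slightly less
trial-consistent than recorded ones, so borderline 4-of-6 responders
inflate the per-odor count. It is reported as computed.

## The learning and discrimination model

Each KC synapses onto an approach and an avoid MBON with equal initial
weights $w_0 = 1$. Reinforcement depresses one of them per training
trial — reward the avoid weight, punishment the approach weight — by
$\delta \cdot r_x$ with a floor at zero, where $r_x$ is the cell's response
that trial. $\delta$ and $w_0$ are never stated at the source; the default
$\delta = 0.25$ is calibrated so a typical reliable cell saturates within
the normal 12-trial regime (a 6-trial preset is equally supported by the
literature; 12 is the default here). Training regimes: normal = 12
trials, extended = 100.

A cell's contribution to discriminating rewarded odor A from punished
odor B on an A test trial is
$D_x = p_x(A)\,(w_{x\to\mathrm{approach}} - w_{x\to\mathrm{avoid}})$, and
the population score is $\sum_x D_x$. Two training modes exist: the full
stochastic mode resamples each cell's response per trial from its
response probability (seeded), and the simplified-saturation mode sets
reliable-cell weights to zero after normal training and additionally
unreliable-cell weights after extended training — the closed-form limit
that full training approaches for large $\delta$ (asserted in the tests).

Whether class-restricted sums should be signed or absolute is not
specified at the source; the package exports both. The convention used in
the tests and pipeline: per-pair class discrimination uses the *signed*
sum (a negative $D_x$ pushes the wrong behavior and is not useful
discrimination), while the change-by-reliability-level analysis uses
absolute contributions. Under these conventions the model reproduces the
observed pattern: unreliable-cell discrimination rises from normal to
extended training for every pair, reliable-cell discrimination never
rises (and falls from dissimilar to similar pairs, since reliable cells
of similar odors overlap), and the per-level improvement on similar pairs
peaks at reliability 1 and declines with reliability. The profile is
asserted as peak-plus-negative-trend rather than strict stepwise
monotonicity, which single-realization scatter does not support even in
the recorded data.

## Decoders and the all-to-all AUC

`mask_by_class()` zeroes, per odor, all cells outside the requested
reliability class for that odor (a cell reliable for one odor and
unreliable for another is kept only for the first). Decoding uses
stratified k-fold cross-validation with 20% folds; class probabilities
come from LDA posteriors (`MASS::lda`, with zero-within-class-variance
features dropped), kNN vote fractions (`caret::knn3`, $k = 3$), or a
softmax over mean pairwise decision values for the linear SVM
(`e1071::svm`, cost 1 — decision values rather than Platt scaling, which
is unstable at ~5 training trials per class). $k$ and the SVM cost are
defaults recorded in the output metadata, not reported values.

The pairwise AUC follows the rank-sum form: pooling the predicted
probabilities of class $i$ for test trials of classes $i$ and $j$,
$\mathrm{AUC}(i|j) = (S_i - n_i(n_i+1)/2) / (n_i n_j)$ with midranks on
ties, which keeps the exact Mann–Whitney equivalence (verified
exhaustively against a brute-force pair-comparison oracle in the tests).
The unordered pair score averages both directions and the all-to-all AUC
is the unweighted mean over pairs.

## Pipeline, I/O, determinism

`run_pipeline()` chains the stages under one configuration object with a
mandatory global seed; per-stage seeds derive from it, every artifact
records the configuration hash and seed, and identical configurations
yield byte-identical JSON summaries. Tensors serialize to a long-format
CSV (`cell, odor, trial, frame, dF_F` plus commented metadata) that
round-trips losslessly; incomplete grids are rejected with an explicit
error rather than padded. Loaders for the HDF5/NWB layouts of the
deposited recordings are declared but decline with an informative error:
no HDF5 or NWB interface is available to this package, and exporting to
the long CSV is the supported path.

All randomness flows through explicit seeds via `withr::with_seed`, so no
function disturbs the caller's RNG state.

## Problem sizes and limitations

The shipped tests run the fly preset at 80–300 cells, circuits at 150 KCs
(5,000 for connectivity statistics), sweeps of up to ~40 configurations ×
10 replicates, and Gamma recovery at $10^5$ draws — sizes chosen so the
statistical assertions are stable across seeds while the whole suite runs
in well under a minute. Known limitations: no spiking or temporal
dynamics in the circuit model (rate-based, one-shot WTA); no mouse
circuit variant; the synthetic generator's trial noise is simpler than
real imaging noise, which makes synthetic odor panels easier to decode
than recorded ones (the decoder tests therefore assert orderings, never
the recorded AUC values); and the "resize/move the cloud" conceptual
models have no stated update rules and are deliberately not implemented.
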