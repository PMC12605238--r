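---
title: "Multi-domain brain-network graph convolution for personalized motor-imagery prediction: models and design choices"
author: "mdgcn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mdgcn methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Motor-imagery (MI) brain-computer interfaces decode imagined movements
from sensorimotor EEG rhythms, but subjects differ widely in which
imagined *action* (e.g. cutting, grasping, writing) they can imagine
effectively. The action a subject imagines best — their "strong"
action — yields the clearest lateralized event-related
desynchronization (ERD) and therefore the highest left-vs-right
decoding accuracy. Finding that action by running full MI experiments
for every candidate action is slow; this package instead predicts it
from *cognitive-task* EEG, which is quick to record, exploiting the
observed correlation between cognitive responses to an action and MI
performance for the same action.

The pipeline has four stages:

1. **Ground truth from MI data.** For each action, the subject's MI
   trials (12 sensorimotor channels, 6 s, 8–30 Hz band) are decoded
   left-vs-right with common spatial patterns (CSP, 2 filter pairs)
   feeding a 4-100-50-10-2 feed-forward network under stratified
   ten-fold cross-validation (72 training / 8 test trials for the
   80-trial design). The action with the highest mean decoding
   accuracy is labeled *strong*; the rest are *weak*. The subject's 75
   cognitive trials inherit these labels (25 strong / 50 weak).
2. **Multi-domain brain networks.** Each preprocessed cognitive trial
   (19 channels × 1000 samples) becomes three graphs over the same 19
   nodes: a *time-domain* graph (40-point block-averaged waveforms,
   absolute-Pearson adjacency), a *frequency-domain* graph (Welch band
   power in 1–4 / 4–8 / 8–13 / 13–20 Hz, phase-locking-value
   adjacency), and a *spatial-domain* graph (CSP log-variance
   features, normalized-Manhattan similarity adjacency).
3. **Three-branch spectral GCN.** Each domain graph passes through two
   first-order Chebyshev graph-convolution layers (32 then 16 units,
   ReLU, dropout 0.5) and a global mean pool; the three 16-vectors are
   concatenated, batch-standardized, and classified strong/weak by a
   dense softmax layer.
4. **Voting and evaluation.** Per-action counts of "strong"
   predictions elect the subject's personalized action. Evaluation is
   subject-independent: leave-one-subject-out cross-validation (LOSO),
   with the held-out subject's MI-derived labels used only for
   scoring.

## Spectral graph convolution

For a weighted adjacency $A \in [0,1]^{S\times S}$ with degree matrix
$D$, the normalized Laplacian $\tilde L = I - D^{-1/2} A D^{-1/2}$ has
eigenvalues in $[0, 2]$. A spectral filter $g_\theta$ acts in the
eigenbasis of $\tilde L$ and is approximated by Chebyshev polynomials
$T_m$ of the rescaled operator $2\tilde L/\lambda_{max} - I$. At order
$K = 1$ the layer collapses to the renormalization-trick propagation

$$ H^{(l+1)} = \sigma\!\left( \tilde D^{-1/2} (A + I) \tilde D^{-1/2}
H^{(l)} W^{(l)} \right), $$

which is what the package uses by default; $K = 2$ adds the $T_2$ term
with $\lambda_{max}$ fixed at the bound 2 rather than computed per
graph (one eigensolve per trial per epoch would dominate runtime and
the bound only rescales the polynomial argument). Every adjacency
carries a unit diagonal before $A + I$ is formed; self-loops are thus
slightly heavier than in the textbook formulation, which is harmless
because the propagation matrix is renormalized.

The $K=1$ layer is verified in the test suite against a dense oracle
that explicitly eigendecomposes $I - P$ and filters with
$g(\lambda) = 1 - \lambda$.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| cognitive filter | 0.5–20 Hz, order 3 | zero-phase band-pass for cognitive epochs |
| MI filter | 8–30 Hz, order 5 | captures mu + beta rhythms for CSP |
| baseline window | first 0.2 s | pre-stimulus mean subtracted per channel |
| analysis window | 0.2–1.2 s | final 1 s, 19 × 1000 per trial |
| time-feature points | 40 (grid 20/40/60) | block means over 25-sample windows |
| Welch segment | min(256, n) samples, Hann, 50% overlap | band-power estimation |
| PLV aggregation | mean over 4 bands | one adjacency from four per-band PLV matrices |
| clustering threshold | top 30% of off-diagonal weights | binarization before Eq.-style triangle counting |
| GCN sizes | 32, 16 hidden units | fixed branch architecture |
| Chebyshev order | 1 (grid {1, 2}) | spectral approximation order |
| dropout | 0.5 (grid {0.25, 0.5}) | after each GC layer |
| learning rate / epochs | 0.001 / 1000 | Adam, full batch |
| DNN | 4-100-50-10-2, sigmoid, decay 0.05, lr 0.01 | MI left/right decoder |

The default configuration (order 1, 40 time points, dropout 0.5) is
the reference scheme; the alternatives form the supported
hyperparameter grid and are validated by the configuration layer.

## Numerical choices

**Zero-phase filtering.** Causality of the band-pass is not an
intrinsic requirement of the analysis, and ERP-style pipelines
conventionally avoid phase distortion, so filtering is zero-phase.
Rather than running the Butterworth recursion forward and backward, the
package applies the squared magnitude response $|H(\omega)|^2$ of the
`signal::butter` design in the frequency domain after odd-reflection
padding. The two are mathematically the same response; the spectral
form is exactly linear in the input (the direct-form recursion
amplifies rounding error by several orders of magnitude at a 0.5 Hz
edge on 1 kHz data, which breaks superposition at the 1e-8 level) and
vectorizes over channels. Filtering happens on the full 1.2 s epoch
before cropping so that edge effects fall outside the analysis window.

**Band decomposition.** The four analysis bands (1–4, 4–8, 8–13,
13–20 Hz) are obtained by zero-phase band-pass reconstruction at
exactly those edges. A dyadic wavelet decomposition cannot produce the
non-dyadic alpha/beta edges at 1 kHz sampling, so a wavelet backend is
deliberately not offered: fidelity to the stated band edges is treated
as binding, and a second backend that could not match them would only
invite silent inconsistency.

**Phase-locking value.** Instantaneous phases come from the analytic
signal (FFT Hilbert transform) of each band-limited channel — the
conventional choice when the source of phases is not otherwise
specified. One PLV matrix arises per band; the model consumes a single
adjacency, so the four are averaged (the simplest symmetric pooling;
`max` and single-band aggregation are available). PLV is invariant to
channel amplitude scaling by construction.

**Manhattan-distance adjacency.** Raw distances $|s_{h_1} - s_{h_2}|$
between CSP features are min-max normalized over off-diagonal pairs
and converted to similarities $1 - d$ so that, as in the other two
domains, larger edge weights mean stronger connection. Min-max
normalization makes the result invariant to positive affine transforms
of the feature vector. If all features coincide the adjacency
degenerates to all-ones with a warning.

**CSP.** Class covariances are per-trial trace-normalized, averaged,
and jointly diagonalized via whitening + eigendecomposition; filters
are sorted by descending whitened first-class variance, so whitened
class variances sum to one per filter. A ridge proportional to the
largest eigenvalue is added only when the composite covariance is
numerically rank-deficient (with a message). The spatial node feature
is the log share of each component's variance,
$\log(v_i / \sum_j v_j)$: variance share is the quantity CSP orders
components by, and the log compresses its dynamic range. The
cognitive-domain CSP model is fitted strictly on training subjects
within each LOSO fold.

**Output block.** The concatenated 48-dimensional pooled features are
batch-standardized (learned scale/shift, running statistics with
momentum 0.1 for evaluation) and then mapped by a dense 48×2 softmax
layer. Standardizing the concatenation — rather than the 2 logits —
is the only reading under which the layer can do its stated job of
removing amplitude discrepancies between the three branches.

**Training.** Cross-entropy is minimized by full-batch Adam
(lr 0.001). Full batch is used at every training size: the per-fold
LOSO training set (675 trials) fits comfortably in memory, batch
statistics for the standardization layer are then deterministic, and
one pass over a block-sparse stacked operator is faster than
minibatching in this implementation. Class weighting is off by
default (the 25/50 imbalance is part of the design); inverse-frequency
weights are available by flag. Weight initialization is
variance-scaled uniform from the training seed, and dropout masks are
drawn from the same seeded stream, so a config + seed reproduces the
loss trace bit for bit. The numerical core is compiled
(RcppArmadillo); all trials are stacked into one matrix per domain and
the per-trial propagation matrices into one sparse block-diagonal
operator.

**MI decoder.** The 4-100-50-10-2 network uses sigmoid hidden
activations (consistent with its autoencoder-era architecture),
softmax output, decoupled L2 weight decay 0.05 and supervised learning
rate 0.01 (of the two stated rates, the fine-tuning one is operative);
sparse-autoencoder pretraining options whose semantics are not
recoverable are out of scope — the decoder's role here is only to
*rank* actions. Features are z-scaled once per action before
cross-validation; folds are stratified with equal left/right counts.

**Ties and degenerate cases.** Equal per-action accuracies or equal
vote counts resolve to the lowest action index with a warning/flag —
deterministic and visible. Metrics with zero denominators (and F1 when
no positive predictions exist) are NaN and listed in an `undefined`
field, never silently zero. Clustering-coefficient binarization keeps
the top 30% of strictly positive off-diagonal weights, ties at the
cutoff included, so an already-binary graph passes through unchanged;
nodes of degree < 2 contribute 0.

**Network contrast.** The strong-vs-weak difference in mean per-trial
clustering coefficient is tested with a two-sided permutation test that
shuffles condition labels *within subject* (1000 permutations,
seeded), which respects the cohort's subject structure without
distributional assumptions.

## The synthetic cohort

The generator emulates the acquisition design the pipeline expects —
per subject, 3 actions × 25 cognitive trials (19 channels, 1.2 s at
1000 Hz including a 0.2 s silent pre-stimulus baseline) and 3 actions
× 80 MI trials (12 channels, 6 s, 40 left / 40 right) — with exactly
one strong action per subject, assigned by a seeded shuffle of a
balanced action repetition so every action is strong for someone.

Cognitive trials mix three narrow-band oscillatory sources (6, 10,
16 Hz sinusoids with random-walk phase jitter, one per theta/alpha/beta
band) into the channels with weights decaying with 2-D inter-electrode
distance from a per-band centre electrode, on top of AR(1)
($\varphi = 0.95$) plus white background noise — a cheap 1/f-like
spectrum. Strong-action trials use source gain 0.8 against 0.3 for
weak actions, and their alpha/beta source power is raised by 50%.
MI trials superimpose a shared 10 Hz mu rhythm on both sensorimotor
strips whose amplitude fluctuates per trial and hemisphere
(log-normal, $\sigma = 0.4$); the hemisphere contralateral to the cued
hand is attenuated by the action's ERD depth (0.6 strong, 0.2 weak).
The trial-to-trial amplitude variability is what keeps left/right
decoding in the realistic 60–90% range instead of saturating — without
it, decoding accuracy could not rank actions at all. Effect sizes are
not reported per subject by any reference measurement, so these values
are the package's reference conditions, chosen once and exposed in the
configuration.

All randomness flows from one seeded stream per subject (derived from
the master seed and the subject id), so cohorts are bit-reproducible
and subjects can be regenerated independently.

What the generator does **not** emulate: ocular/muscle artifacts (the
preprocessing hook accepts externally ICA-cleaned data instead),
volume-conduction mixing of the noise background, non-stationary
drifts, inter-subject anatomical variability, or resting-state data.
Passing tests on this cohort therefore demonstrate that the pipeline
recovers the statistical structure it assumes — coupled oscillations,
band-power shifts, lateralized ERD — not that it would reach any
particular accuracy on real recordings.

## Problem sizes used in the checks

The package's own validation runs at the reference scale: 10 subjects
for labeling recovery and LOSO decoding (200 training epochs, three
training seeds), with fold-invariant time/frequency graphs cached
across folds. The null-calibration study uses 30 cohorts of 3 subjects
with 20 MI trials per action, 5-fold CV and a shortened decoder —
scales chosen so the null distribution is sampled broadly while the
whole suite stays quick on a laptop. Loss-trace determinism and
configuration hashing are checked at small scale where they are
equally binding.

## Known limitations

* The headline accuracies reported for the original 10-subject
  laboratory cohort are not reproducible here: that dataset is
  private, and the synthetic cohort is deliberately easier to decode
  at the default effect sizes. Numbers produced on synthetic data
  characterize the implementation, not the science of real EEG.
* The labeling DNN reproduces the stated architecture but not the
  unrecoverable sparse-pretraining options; with strongly separable
  CSP features its exact regularization barely matters for ranking.
* `EEGEpochs` holds data densely in memory (~140 MB per subject's MI
  block at the reference scale); cohorts far beyond tens of subjects
  would need an on-disk container.
* EDF export writes plain EDF (16-bit quantized, one sampling rate for
  all signals); EDF+ annotations are not produced, and epoch
  boundaries are carried in a sidecar rather than the file itself.
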