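---
title: "Models and methods behind tracefm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tracefm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

tracefm is a desk-scale re-implementation of a foundation-model workflow for
single-molecule fluorescence time traces: a ground-truth-labeled trace
simulator, a small patch-tokenized self-attention encoder pre-trained on many
quantized analysis tasks at once, frozen-encoder logistic-regression
fine-tuning for downstream analyses, and a set of embedding-space analytics
(label Self-Consistency Score, Local Shannon Entropy, Principal Projection,
and an smFRET Atlas). This vignette records the models, their assumptions,
and every numerical or design choice that was genuinely open.

## The trace simulator

A two-color smFRET trace is generated in four stages.

**Kinetics.** A molecule is a discrete-time Markov chain over `n_states`
emission states (uniform on 1–4). The initial distribution and each row of
the per-frame transition matrix are independent uniform draws normalized to
sum to one. Each state carries a FRET efficiency, uniform on [0, 1] subject
to a minimum pairwise separation of 0.1 so that "distinct states" are
resolvable and Atlas level-binning is unambiguous. States are indexed in
ascending FRET order; this canonicalization makes the per-frame state-index
training label a well-defined function of the trace (otherwise it is an
arbitrary permutation per molecule — pure label noise).

**Noiseless rendering.** With total intensity `I_max` (uniform on 100–1000
arbitrary units; any scale works because SNR is controlled and the encoder
normalizes its input), the acceptor channel reads `I_max * FRET(s(t))` and
the donor the remainder, so the channels sum to `I_max` at every frame.

**Photophysics.** Each channel bleaches at an exponential time whose
expectation is itself uniform on 1–2000 frames. After acceptor bleach the
excitation energy is no longer transferred, so the donor recovers to
`I_max`; after donor bleach both channels drop to background. Donor blinking
alternates emitting/dark segments with exponential durations (expected dark
lifetime uniform on 1–20 frames, emitting lifetime uniform on 200–2000
frames — short dark states typical of carbocyanine donors; both channels are
dark during a blink because the donor absorbs no light). The acceptor is
scaled by a relative brightness uniform on 0.9–1.0. Blinking is applied to
the donor only, and not to one-color traces.

**Noise.** A target SNR is drawn uniform on (1.8, 6) and i.i.d. Gaussian
noise with `sigma = I_max / SNR` — the same sigma in both channels — plus a
constant offset uniform on [0, 0.2] × `I_max` is added. The SNR convention
(`I_max` over sigma, shared across channels) is a package definition; the
source recipe states the range but not the convention.

One-color traces (default 25% of a corpus, stored with the second channel
exactly zero) are intensity-level processes: a single fluorophore follows a
Markov chain over relative intensity levels with one bleach step, while
`n_fluors > 1` gives an equal-step photobleaching staircase with independent
exponential bleach times and no internal kinetics. Camera noise models
(EMCCD gain, shot noise), triplet kinetics and spectral crosstalk are out of
scope.

What a green simulator test establishes: sampling-bound compliance, channel
conservation, causality of the bleach mask, and seeded byte-reproducibility.
What it does not: resemblance to any particular microscope; real data have
correlated noise, baseline drift and crosstalk that this generator
deliberately omits.

## The encoder

Traces enter as `T x 2` tensors (one-color traces zero-filled). Each
50-frame patch (configurable width `W`) is flattened and linearly projected
to a `D`-dimensional token; a learnable trace token is prepended and a
learnable absolute position embedding added, giving a sequence of length
`T/W + 1`. `N` pre-norm multi-head self-attention layers with GELU
feed-forward blocks (hidden width `4D`) map the sequence to embeddings; the
trace-token output `z0` (used raw, no pooling) serves trace-level tasks and
the remaining token outputs are expanded to per-frame embeddings by a linear
unstack operator (`D -> W x D` per token). The reference configuration is
`W = 50, D = 96, N = 4`, 4 heads; desk-scale tests use `D = 32, N = 2`.

Open choices fixed here: pre-norm layer placement plus a final layer norm
(stability at small scale; a zero-layer stack is exactly the identity);
feed-forward ratio 4; truncated-normal initialization (s.d. 0.02, seeded);
traces whose length is not a multiple of `W` are right-truncated with a
warning, never padded (padding would inject fabricated frames into
frame-level labels).

**Input normalization.** Intensities are divided by the 95th percentile of
the summed channels before tokenization, at training and inference alike.
Raw arbitrary-unit intensities (hundreds of counts) would dwarf the
0.02-scale learned position embeddings and trace token; nothing in the
problem fixes the units a recording arrives in, and SNR and kinetics are
scale-free. Measured at desk scale, this choice moves frame-level
idealization from chance to >0.95 accuracy.

## Multitask pre-training

Every training task is quantized into a multi-class classification problem
so that regression and classification targets share one cross-entropy (KL to
a one-hot empirical distribution) loss scale. The roster reconstructs the
printed head count: 10 attribute groups — transition rate, FRET state count,
FRET value, acceptor lifetime, donor lifetime, photobleaching steps and SNR
for two-color traces; rate, photobleaching steps and SNR for single-channel
traces — each with a coarse trace-level head, a fine trace-level head and a
frame-level head, 30 heads total. The exact bin edges are package choices:
10 equal bins for fine heads (FRET on [0,1], rate on [0,0.5] per frame, SNR
on [1,8], lifetimes log-spaced on [1,2000] frames), 3 coarse bins (FRET uses
the Atlas thresholds 0.35/0.65), natural classes for counts. Labels outside
the outer edges clamp to the end bins.

Mini-batches are task-balanced: per-batch task counts differ by at most one,
so no task's gradient dominates an iteration. Optimization is ADAM
(beta1 = 0.9, beta2 = 0.999) with a linear 100-step warmup to a peak rate of
3e-4 by default (a conventional choice for small transformers; desk-scale
test fixtures use 1e-3 to reach useful features inside a CI time budget).
The forward and backward passes through the tokenizer, attention stack,
unstack operator and heads are written in plain R matrix algebra and are
verified against numerical gradients to ~1e-10 relative error.

**Corpus diversity.** Uniform-normalized transition rows imply mean
switching rates of ~0.3–0.7 per frame, so most multi-state traces switch
faster than the patch scale and the state-count attribute is close to
unlearnable at desk scale. `generate_dataset(..., category_fraction)` can
draw a fraction of two-color traces from the Atlas category-conditioned
sampler (well-separated slow/fast kinetics), in the spirit of sampling as
diverse a behavior set as possible; the default of 0 keeps the plain recipe.

## Fine-tuning and downstream analyses

Fine-tuning is frozen-encoder logistic regression: only the new head's
`W`/`b` are fitted (ridge-regularized multinomial regression, penalty
`1/n`, via glmnet), so embeddings before and after fine-tuning are
bit-identical — asserted by fingerprint in the tests.

*Idealization* maps each frame to the argmax FRET bin of a frame-level head
and then to the bin-center FRET value; an optional running-median filter
(default width 5 frames) over class indices removes isolated misclassified
frames, the standard cleanup applied to idealized paths before dwell
analysis. *Dwell analysis* segments idealized sequences into dwells,
excludes the censored first and last dwell of every trace, merges
idealization levels occupying <5% of frames into their nearest major level,
and fits each state's cumulative dwell-time distribution by least squares on
the log survival curve through the origin (a single dwell falls back to the
moment estimate `1/mean`). Rates are reported per frame and per second.
Discretization means the fitted `-slope` estimates `-log(1-k)`, a ~2.5%
upward bias at `k = 0.05` — inside the recovery tolerances and documented
rather than corrected. Window censoring is the dominant bias for slow rates:
at `T = 500` frames the surviving interior dwells of a `k = 0.005` process
are conditioned to fit inside the window, inflating the fitted rate by ~90%
even on ground-truth paths (measured); the recovery suite therefore uses
`T = 2000` for the slowest regime. This is a statement about observation
windows, not about the estimator.

*Photobleaching step counting* reads a trace-level head's class as a step
count. *Kinetic fingerprinting* accepts traces whose posterior for the
positive kinetic class exceeds a threshold (default 0.5, configurable — the
operating point is not fixed by the source) and reports per-field-of-view
counts.

## Embedding metrics

Neighbors are exact brute-force Euclidean on trace-level embeddings
(deterministic tie-break by lower index; self excluded). The label
Self-Consistency Score for label value `l` is
`SCS = (1/(kN)) * sum_i sum_{j in NN(i,k)} d(y_i,l) d(y_i,y_j)` with `k = 1`
by default; the printed normalization divides by all `N` traces, so
per-label scores sum to the overall neighbor-agreement probability and
depend on label prevalence — a prevalence-normalized variant is available
but marked as an extension. Local Shannon Entropy is the natural-log entropy
of the condition composition of the `(1+k)`-multiset {self plus k = 50
neighbors}; it is bounded by `log |C|` and low values flag
condition-specific behavior. The `k = 2*sqrt(N)` rule of thumb is exposed as
`lse_k_heuristic()`; the printed form of that rule is dimensionally
implausible and is treated as a typesetting artifact, not asserted anywhere.

## Principal Projection

Attribute operators come from the SVD of the column-concatenated
(uncentered, as printed) head weight matrices of an attribute group; the
smallest leading set of singular directions whose squared singular values
reach 95% of the total is kept, and embeddings are projected as
`z_tilde = U^T z` before any 2-D reduction. Operator alignment is the
spectral norm `phi = ||U1^T U2||_2` (0 for orthogonal spans, 1 up to a
unitary rotation). "Correlation" between a classifier head and the
attributes is implemented as this same `phi` — the only quantitative
operator comparison defined — and both raw `phi` and fractions normalized to
sum 1 are reported; a head orthogonal to every attribute yields uniform
fractions with a warning.

## The smFRET Atlas

Categories follow the printed grammar "states-SNR-FRETlevels[-rate]" with
states 1–3, SNR clean (>= 4) / noisy, FRET levels high (> 0.65) / medium
(0.35–0.65, inclusive) / low, and rate fast (>= 0.05 per frame) / slow for
2+ states; level letters are written ascending ("mh", the canonical dialect
here). The enumeration closes at 22 categories (6 + 12 + 4), which matches
the printed total and implies rate is inapplicable to 1-state traces. The
"average rate" being thresholded is defined centrally in the simulator as
the stationary-averaged per-frame probability of leaving the current state.

The atlas corpus is sampled per category (FRET values inside the letter
windows, symmetric transition matrices at a rate drawn from the class
range, SNR from the class range; bleaching lifetimes kept >= 500 frames so
the category's kinetic identity dominates). The 2-D reducer is PCA with
whitened scores — the reference implementation's UMAP has no pre-installed R
counterpart, so the fallback sanctioned for that situation is used and
flagged in `reducer$kind`; whitening makes the absolute Gaussian-mixture
contour level `p = 1e-2` meaningful on a scale-free coordinate system. Each
category is annotated by a 4-component full-covariance Gaussian mixture
fitted by EM (k-means initialization, ridge 1e-6, seeded); contours are
polylines at the `1e-2` density level. Projection of new data requires a
matching encoder fingerprint; reference scale is 1,000 traces per category,
desk-scale tests use far fewer.

## Determinism and degenerate inputs

Every stochastic stage takes an explicit seed; identical seeds give
byte-identical datasets, loss curves and atlas contours on one machine.
Predicted probabilities are clipped at 1e-9 before logarithms; non-finite
training losses abort with the step index; degenerate GMM projections
(near-zero variance) and mismatched atlas fingerprints are errors, not
silent fallbacks.

## Known limitations

The desk-scale encoder (D = 32, N = 2, a few thousand traces, a few
thousand optimizer steps) learns first-order attributes (SNR, FRET value,
lifetimes) readily; second-order temporal attributes (state count,
transition rate) emerge slowly and remain the weakest part of the trace
token at this scale — the reference model trains on ~10^6 traces for days on
a GPU. Measured consequences, asserted at their honest level in the test
suite rather than at reference-scale values: exact photobleaching-step
concordance saturates near 0.5–0.6 (off-by-one ~0.88); idealized transition
boundaries jitter by a frame or two, so a "within one bin everywhere" check
holds for ~95% of frames but not literally everywhere, and usable-segment
ends track the true bleach frame within 5 frames for ~95% of traces, not
all; in the PCA atlas only distinctive one-state categories are
argmax-localized — composite categories (e.g. two-state mid/high fast)
overlap in the linear 2-D view. Under the plain transition-matrix recipe
the state-count label is close to information-free (switching faster than
the patch scale, uniform class marginal), which is why desk-scale training
corpora here use the category-mixed generator. Frame-level idealization is
only meaningful when FRET states are separated by at least one quantization
bin. None of the package's tests assert benchmark numbers measured on
experimental datasets; every green test is a statement about the synthetic
world defined above.
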