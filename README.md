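# tracefm

A self-contained R toolkit for analyzing single-molecule fluorescence time
traces (smFRET and single-channel photobleaching data) with a small
multitask transformer encoder — for biophysicists who need trace
selection, segmentation, idealization, step counting and dataset-level
exploration without hand-curating every movie.

Real single-molecule analysis pipelines hinge on scarce expert labels.
tracefm follows the foundation-model route: a simulator generates
unlimited traces with exact ground truth (Markov state kinetics `s(t)`,
photobleaching, donor blinking, Gaussian noise at controlled SNR
`= I_max / sigma`); a patch-tokenized self-attention encoder is pre-trained
on 30 quantized classification tasks at once (cross-entropy / KL loss on
task-balanced batches, ADAM); downstream analyses then fit only a linear
logistic head on the frozen embeddings from ~100–1,000 labeled traces.

Beyond task heads, the package implements four embedding analytics:

- **Label Self-Consistency Score** — `SCS(l) = (1/kN) Σ_i Σ_{j∈NN(i,k)}
  δ(y_i,l) δ(y_i,y_j)`, the k-NN label-agreement probability (k = 1),
  for auditing manual labels;
- **Local Shannon Entropy** — entropy of the experimental-condition
  composition of each trace's {self + 50 nearest neighbors} multiset;
  low-entropy traces mark condition-specific behaviors;
- **Principal Projection** — low-rank operators `Ũ` from the SVD of
  concatenated task-head weights (smallest set of components holding
  ≥ 95% of Σs²), with operator alignment `φ = ‖Ũ₁ᵀŨ₂‖₂ ∈ [0,1]`;
- **smFRET Atlas** — a fixed 2-D reducer over a 22-category synthetic
  corpus ("states-SNR-FRETlevels-rate" nomenclature, e.g. `2-c-mh-f`),
  annotated with 4-component Gaussian-mixture contours at density 1e-2.

## Worked example

```r
library(tracefm)

## 1. simulate a labeled corpus and pre-train a desk-scale encoder
scfg <- sim_config(n_frames = 500L)
ds   <- generate_dataset(2000, scfg, seed = 11, category_fraction = 0.5)
cfg  <- model_config(patch_width = 50L, embed_dim = 32L, n_layers = 2L,
                     n_heads = 4L, max_tokens = 41L)
fit  <- pretrain(ds, cfg, steps = 1000L, lr = 1e-3, seed = 7)
h <- fit$history
h[h$task == ".total" & h$step %in% c(0, 1000), ]
#>   step   task split     loss
#>      0 .total   val 42.59469
#> 4 1000 .total   val 25.16753
```

The summed validation loss over all 30 tasks drops from 42.6 to 25.2 in
this one-minute demonstration run; `history` holds the full per-task
curves (the test suite checks that every per-task loss decreases).

```r
## 2. fine-tune a frame-level FRET head from 80 labeled traces,
##    idealize held-out two-state traces, and fit rate constants
mk <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) simulate_two_color_trace(
    sim_config(n_frames = 500L, snr_range = c(4.5, 5.5),
               tau_bleach_range = c(1e9, 1e9), tau_nonblink_range = c(1e9, 1e9)),
    model = two_state_model(0.02, 0.02, fret = c(0.25, 0.75), i_max = 500)))
}
trn <- mk(80, 1); tst <- mk(100, 2)
embf <- embed_traces(trn, fit$weights, cfg, frames = TRUE)
labs <- lapply(trn, function(tr)
  findInterval(tr$ground_truth$ideal_fret, seq(0, 1, length.out = 11),
               all.inside = TRUE))
ft  <- fit_logistic_head(embf$frames, labs, "frame")
idl <- idealize(tst, ft, fit$weights, cfg, smooth = 5)
dw  <- dwell_times_and_rates(idl, frame_period = 0.1)
round(c(dw$k12, dw$k21), 4)   # per-frame rates, truth 0.02
#> [1] 0.0229 0.0179
dw$fret_state_means           # truth 0.25 / 0.75
#> [1] 0.25 0.75
```

The recovered rate constants are within ~15% of the simulated truth and
the FRET state means are exact (bin centers); the acceptance suite
repeats this recovery across three rate regimes at tighter training
budgets. All numbers above are real output from the exact seeds shown.

```r
## 3. embedding metrics on any labeled set of traces
emb  <- embed_traces(ds, fit$weights, cfg, frames = FALSE)
idx  <- knn_index(emb$z0, k = 50)
scs  <- self_consistency_score(idx, labels, k = 1)    # per-label + aggregate
lse  <- local_shannon_entropy(idx, conditions, k = 50)
keep <- lowest_entropy_subset(lse, 0.1, conditions)   # condition-specific traces
```

## Layout

- `R/` — simulator, encoder + training engine, fine-tuning and kinetic
  analyses, metrics, principal projection, atlas, IO/CLI
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/methods.Rmd` — models, assumptions, numerical choices
- `inst/cli/tracefm` — command-line umbrella (`simulate`, `embed`,
  `metrics scs|lse`, `atlas enumerate`)
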