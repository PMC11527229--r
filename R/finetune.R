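## Frozen-encoder fine-tuning and derived kinetic analyses. Only the new
## head's parameters are fitted (multinomial ridge logistic regression);
## the encoder weights are never touched, so embeddings before and after
## fine-tuning are bit-identical.

#' Fit a logistic-regression head on frozen embeddings
#'
#' Multinomial (or binomial) L2-regularized logistic regression on
#' trace-level embeddings or stacked frame-level embeddings, on the order
#' of 100--1,000 labeled traces. Deterministic given the data; `seed` is
#' recorded in the metadata.
#'
#' @param embeddings N x D matrix (trace level) or list of T x D matrices
#'   (frame level).
#' @param labels length-N vector (trace level) or list of length-T
#'   vectors (frame level).
#' @param level `"trace"` or `"frame"`.
#' @param seed integer seed recorded with the head.
#' @param lambda ridge penalty; default `1 / n` (unit L2 strength).
#' @param task_name name recorded on the head.
#' @return List of class `downstream_head` with `W` (D x n_classes), `b`,
#'   `classes`, `level`, `n_train`, `seed`, `train_accuracy`; usable with
#'   [head_predict()].
#' @export
fit_logistic_head <- function(embeddings, labels, level = c("trace", "frame"),
                              seed = 1L, lambda = NULL, task_name = "downstream") {
  level <- match.arg(level)
  if (level == "frame") {
    stopifnot(is.list(embeddings), is.list(labels))
    X <- do.call(rbind, embeddings)
    y <- unlist(labels)
  } else {
    X <- as.matrix(embeddings)
    y <- labels
  }
  f <- factor(y)
  if (nlevels(f) < 2)
    stop(sprintf("labels contain a single class ('%s'); at least 2 are required",
                 levels(f)[1]), call. = FALSE)
  n <- nrow(X)
  if (is.null(lambda)) lambda <- 1 / n
  fam <- if (nlevels(f) == 2) "binomial" else "multinomial"
  lam_path <- exp(seq(log(lambda * 100), log(lambda), length.out = 8))
  fit <- glmnet::glmnet(X, f, family = fam, alpha = 0, lambda = lam_path,
                        standardize = FALSE)
  D <- ncol(X)
  if (fam == "binomial") {
    beta <- as.numeric(stats::coef(fit, s = lambda))
    W <- cbind(rep(0, D), beta[-1])
    b <- c(0, beta[1])
  } else {
    cf <- stats::coef(fit, s = lambda)
    W <- do.call(cbind, lapply(cf, function(m) as.numeric(m)[-1]))
    b <- vapply(cf, function(m) as.numeric(m)[1], 0)
  }
  colnames(W) <- levels(f)
  head <- list(task_name = task_name, level = level, classes = levels(f),
               n_classes = nlevels(f), W = W, b = unname(b),
               n_train = if (level == "frame") length(embeddings) else n,
               seed = as.integer(seed))
  p <- head_predict(X, head)
  if (is.null(dim(p))) p <- matrix(p, 1)
  head$train_accuracy <- mean(levels(f)[max.col(p, ties.method = "first")] == as.character(f))
  class(head) <- "downstream_head"
  head
}

#' Classify traces and extract usable segments
#'
#' Applies a trace-level accept/reject head and a frame-level usable-mask
#' head; the per-frame mask of accepted traces is converted to maximal
#' half-open intervals `[start, end)` in 0-based frames.
#'
#' @param traces traces to classify.
#' @param trace_head `downstream_head` (or pre-trained head) whose
#'   positive class marks accepted traces.
#' @param frame_head frame-level head whose positive class marks usable
#'   frames.
#' @param weights,cfg encoder weights and [model_config()].
#' @param accept_class,usable_class positive class index (default: last).
#' @param threshold posterior threshold for acceptance (default 0.5).
#' @param min_length minimum usable-interval length in frames; shorter
#'   runs (isolated frame-head misfires) are dropped. Default 1 keeps
#'   every run.
#' @return List per trace: `accepted` (logical), `p_accept`, `intervals`
#'   (m x 2 matrix, columns start/end; empty for rejected traces).
#' @export
classify_and_segment <- function(traces, trace_head, frame_head, weights, cfg,
                                 accept_class = NULL, usable_class = NULL,
                                 threshold = 0.5, min_length = 1L) {
  emb <- embed_traces(traces, weights, cfg, frames = TRUE)
  n <- nrow(emb$z0)
  pa <- head_predict(emb$z0, trace_head)
  if (is.null(dim(pa))) pa <- matrix(pa, 1)
  ac <- accept_class %||% ncol(pa)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    accepted <- pa[i, ac] >= threshold
    intervals <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
    if (accepted) {
      pf <- head_predict(emb$frames[[i]], frame_head)
      if (is.null(dim(pf))) pf <- matrix(pf, 1)
      uc <- usable_class %||% ncol(pf)
      mask <- max.col(pf, ties.method = "first") == uc
      r <- rle(mask)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values & r$lengths >= min_length
      intervals <- cbind(start = starts[keep], end = ends[keep])
    }
    out[[i]] <- list(accepted = accepted, p_accept = pa[i, ac], intervals = intervals)
  }
  out
}

#' Idealize traces with a frame-level FRET head
#'
#' Per-frame argmax FRET class mapped to the bin-center FRET value. An
#' optional running-median filter over class indices (width `smooth`,
#' odd; 1 disables) removes isolated misclassified frames before dwell
#' analysis.
#'
#' @param traces two-color traces.
#' @param frame_fret_head frame-level head over ordered FRET bins (the
#'   pre-trained `fret_value_frame` head or a fine-tuned one).
#' @param weights,cfg encoder weights and [model_config()].
#' @param bin_edges FRET bin edges (default 10 equal bins on [0, 1]).
#' @param smooth odd median-filter width in frames.
#' @return List of class `idealization`: per trace a list with `class`
#'   (integer bins) and `fret` (bin-center values).
#' @export
idealize <- function(traces, frame_fret_head, weights, cfg,
                     bin_edges = seq(0, 1, length.out = 11), smooth = 5L) {
  emb <- embed_traces(traces, weights, cfg, frames = TRUE)
  centers <- (head(bin_edges, -1) + tail(bin_edges, -1)) / 2
  # a fine-tuned head may cover a subset of bins: its `classes` field
  # (factor levels of the training labels) maps back to global bin indices
  class_map <- if (!is.null(frame_fret_head$classes) &&
                   !anyNA(suppressWarnings(as.integer(frame_fret_head$classes))))
    as.integer(frame_fret_head$classes) else NULL
  out <- lapply(emb$frames, function(fm) {
    p <- head_predict(fm, frame_fret_head)
    if (is.null(dim(p))) p <- matrix(p, 1)
    cls <- max.col(p, ties.method = "first")
    if (!is.null(class_map)) cls <- class_map[cls]
    if (smooth > 1L && length(cls) > smooth)
      cls <- as.integer(stats::runmed(cls, k = smooth, endrule = "median"))
    list(class = cls, fret = centers[cls])
  })
  class(out) <- "idealization"
  out
}

# least-squares exponential fit of the dwell-time survival curve:
# log S(t) = -k t (no intercept; S(0) = 1)
fit_exp_rate <- function(dwells) {
  ts <- sort(unique(dwells))
  S <- vapply(ts, function(t) mean(dwells > t), 0)
  keep <- S > 0
  if (sum(keep) < 2) return(1 / mean(dwells))   # degenerate: moment estimate
  t_ <- ts[keep]; ls <- log(S[keep])
  -sum(t_ * ls) / sum(t_ * t_)
}

#' Dwell times and rate constants from idealized sequences
#'
#' Segments each idealized FRET sequence into dwells, excludes the
#' censored first and last dwell of every trace, and fits the cumulative
#' dwell-time distribution of each state with an exponential (least
#' squares on log survival). Idealization levels occupying less than
#' `min_occupancy` of all frames are merged into the nearest major level
#' before segmentation. States are ordered by FRET value ascending, so
#' with two states `k12` is the rate of leaving the low-FRET state and
#' `k21` of leaving the high-FRET state.
#'
#' @param idealized an `idealization` (or list of numeric FRET
#'   sequences).
#' @param frame_period seconds per frame; rates are reported in both
#'   frame^-1 and s^-1.
#' @param min_dwells minimum dwell count for a confident rate fit.
#' @param min_occupancy occupancy fraction below which a level is merged.
#' @return List of class `dwell_summary`: `levels`, `fret_state_means`,
#'   `dwells` (list per state), `rates_per_frame`, `rates_per_s`,
#'   `n_dwells`, `low_confidence`, and for two states `k12`, `k21`.
#' @export
dwell_times_and_rates <- function(idealized, frame_period = 1, min_dwells = 5L,
                                  min_occupancy = 0.05) {
  seqs <- lapply(idealized, function(x) if (is.list(x)) x$fret else as.numeric(x))
  all_vals <- unlist(seqs)
  occ <- table(all_vals) / length(all_vals)
  levels_all <- as.numeric(names(occ))
  major <- levels_all[occ >= min_occupancy]
  if (length(major) < 2)
    stop("fewer than 2 states observed at the requested occupancy", call. = FALSE)
  snap <- function(v) major[vapply(v, function(x) which.min(abs(major - x)), 0L)]
  dwells <- vector("list", length(major))
  fret_sums <- numeric(length(major)); fret_ns <- numeric(length(major))
  for (s_raw in seqs) {
    s <- snap(s_raw)
    st <- match(s, major)
    fret_sums <- fret_sums + vapply(seq_along(major), function(j) sum(s_raw[st == j]), 0)
    fret_ns <- fret_ns + tabulate(st, nbins = length(major))
    r <- rle(st)
    if (length(r$lengths) <= 2) next        # only censored dwells
    keep <- 2:(length(r$lengths) - 1)       # drop first/last (censored)
    for (j in keep) {
      dwells[[r$values[j]]] <- c(dwells[[r$values[j]]], r$lengths[j])
    }
  }
  n_dwells <- vapply(dwells, length, 0L)
  rates <- vapply(seq_along(major), function(j) {
    if (n_dwells[j] == 0) return(NA_real_)
    fit_exp_rate(dwells[[j]])
  }, 0)
  low_conf <- n_dwells < min_dwells
  if (any(low_conf))
    warning(sprintf("state(s) %s have fewer than %d dwells; rates flagged low-confidence",
                    paste(which(low_conf), collapse = ","), min_dwells))
  out <- list(levels = major,
              fret_state_means = ifelse(fret_ns > 0, fret_sums / fret_ns, NA_real_),
              dwells = dwells,
              rates_per_frame = rates,
              rates_per_s = rates / frame_period,
              n_dwells = n_dwells,
              low_confidence = low_conf,
              frame_period = frame_period)
  if (length(major) == 2) {
    out$k12 <- rates[1]
    out$k21 <- rates[2]
  }
  class(out) <- "dwell_summary"
  out
}

#' Count photobleaching steps with a trace-level head
#'
#' The head class is interpreted as a step count via `counts`.
#'
#' @param traces one-color traces.
#' @param pb_head trace-level head over step-count classes.
#' @param weights,cfg encoder weights and [model_config()].
#' @param counts step count of each head class (default `0:(C-1)`).
#' @return Integer vector of per-trace counts with attribute `summary`
#'   (mean and s.d.).
#' @export
count_photobleach_steps <- function(traces, pb_head, weights, cfg, counts = NULL) {
  emb <- embed_traces(traces, weights, cfg, frames = FALSE)
  p <- head_predict(emb$z0, pb_head)
  if (is.null(dim(p))) p <- matrix(p, 1)
  counts <- counts %||% (seq_len(ncol(p)) - 1L)
  est <- counts[max.col(p, ties.method = "first")]
  structure(as.integer(est), summary = c(mean = mean(est), sd = sd(est)))
}

#' Kinetic-fingerprint classification of traces
#'
#' Accept/reject per trace by the posterior of a head fitted on labeled
#' positive/negative kinetics, plus positive counts per field of view.
#'
#' @param traces traces to classify.
#' @param head fitted `downstream_head` with a positive class.
#' @param weights,cfg encoder weights and [model_config()].
#' @param positive_class index of the positive class (default: last).
#' @param threshold posterior acceptance threshold.
#' @param fov optional per-trace field-of-view identifiers.
#' @return Logical acceptance vector; attribute `fov_counts` (table) when
#'   `fov` is given.
#' @export
kinetic_fingerprint_classify <- function(traces, head, weights, cfg,
                                         positive_class = NULL, threshold = 0.5,
                                         fov = NULL) {
  mats <- as_trace_matrices(traces)
  if (length(mats) == 0) {
    out <- logical(0)
    if (!is.null(fov)) attr(out, "fov_counts") <- table(factor(character(0)))
    return(out)
  }
  emb <- embed_traces(traces, weights, cfg, frames = FALSE)
  p <- head_predict(emb$z0, head)
  if (is.null(dim(p))) p <- matrix(p, 1)
  pc <- positive_class %||% ncol(p)
  accepted <- p[, pc] >= threshold
  if (!is.null(fov)) attr(accepted, "fov_counts") <- table(fov[accepted])
  accepted
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores for a binary outcome.
#'
#' @param scores numeric classifier scores, larger = more positive.
#' @param labels logical (or 0/1) outcome vector.
#' @return Scalar AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both outcome classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
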