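## Embedding-space quality metrics: exact k-NN, label Self-Consistency
## Score, and Local Shannon Entropy of experimental-condition labels.

#' Exact k-nearest-neighbor index
#'
#' Brute-force Euclidean neighbors (never approximate), excluding self,
#' with deterministic tie-breaking by lower trace index. Distances are
#' computed in blocks to bound memory.
#'
#' @param embeddings N x D numeric matrix (rows are trace-level
#'   embeddings), or an `embedding_set`.
#' @param k neighbors per point; must satisfy `k < N`.
#' @param block row-block size for the distance computation.
#' @return List of class `neighbor_index` with `idx` (N x k neighbor
#'   indices, nearest first), `dist` (matching distances), `n`, `k`.
#' @export
knn_index <- function(embeddings, k, block = 1024L) {
  if (inherits(embeddings, "embedding_set")) embeddings <- embeddings$z0
  X <- as.matrix(embeddings)
  N <- nrow(X)
  if (k >= N) stop(sprintf("k (%d) must be smaller than the number of points (%d)", k, N),
                   call. = FALSE)
  sq <- rowSums(X * X)
  idx <- matrix(0L, N, k)
  dst <- matrix(0, N, k)
  for (start in seq(1L, N, by = block)) {
    rows <- start:min(N, start + block - 1L)
    D2 <- outer(sq[rows], sq, `+`) - 2 * tcrossprod(X[rows, , drop = FALSE], X)
    D2[D2 < 0] <- 0
    for (j in seq_along(rows)) {
      i <- rows[j]
      d <- D2[j, ]
      d[i] <- Inf                       # self never a neighbor
      ord <- order(d, seq_len(N))[seq_len(k)]
      idx[i, ] <- ord
      dst[i, ] <- sqrt(d[ord])
    }
  }
  structure(list(idx = idx, dist = dst, n = N, k = k), class = "neighbor_index")
}

resolve_index <- function(index, k) {
  stopifnot(inherits(index, "neighbor_index"))
  if (k > index$k) stop("index holds fewer neighbors than requested k", call. = FALSE)
  index$idx[, seq_len(k), drop = FALSE]
}

#' Label Self-Consistency Score
#'
#' For label value `l`:
#' `SCS = (1 / (k N)) * sum_i sum_{j in NN(i,k)} d(y_i, l) d(y_i, y_j)`
#' with Kronecker deltas `d`, i.e. the per-label contribution to the
#' probability that a trace and its nearest neighbors share a label. The
#' normalization is by the full trace count N, so per-label scores sum to
#' the overall k-NN label-agreement probability. A prevalence-normalized
#' variant (dividing by the count of traces labeled `l` instead of N) is
#' available as an extension via `normalize = "prevalence"`.
#'
#' @param index a `neighbor_index` from [knn_index()].
#' @param labels length-N label vector (any atomic type).
#' @param l label value to score; `NULL` scores every observed value.
#' @param k neighbors used (default 1).
#' @param normalize `"printed"` (divide by N) or `"prevalence"`.
#' @return If `l` is given, a scalar in [0, 1]; otherwise a named vector
#'   of per-label scores with attribute `aggregate`, the total k-NN
#'   agreement probability.
#' @export
self_consistency_score <- function(index, labels, l = NULL, k = 1L,
                                   normalize = c("printed", "prevalence")) {
  normalize <- match.arg(normalize)
  nn <- resolve_index(index, k)
  N <- index$n
  if (length(labels) != N) stop("labels must cover every trace", call. = FALSE)
  values <- unique(labels)
  if (!is.null(l) && (length(l) != 1 || is.na(l)))
    stop("label value 'l' must be a single non-missing value", call. = FALSE)
  agree <- matrix(labels[nn] == rep(labels, times = k), N, k)
  per_i <- rowSums(agree)               # matches among the k neighbors
  score_for <- function(val) {
    sel <- labels == val
    denom <- if (normalize == "printed") k * N else k * max(1L, sum(sel))
    sum(per_i[sel]) / denom
  }
  if (!is.null(l)) return(score_for(l))
  out <- vapply(values, score_for, 0)
  names(out) <- as.character(values)
  structure(out, aggregate = sum(per_i) / (k * N))
}

#' Local Shannon Entropy of experimental conditions
#'
#' For each trace, the Shannon entropy (natural log by default) of the
#' condition composition of the multiset formed by the trace itself and
#' its k nearest neighbors:
#' `P(c) = (d(y_i, c) + sum_{j in NN(i)} d(y_j, c)) / (1 + k)`,
#' `S(x_i) = -sum_c P(c) log P(c)`.
#' Bounded by `0 <= S <= log(|C|)`.
#'
#' @param index a `neighbor_index` from [knn_index()].
#' @param conditions length-N categorical condition labels.
#' @param k neighborhood size (default 50).
#' @param base logarithm base (default `exp(1)`, natural log).
#' @return Numeric vector of per-trace entropies.
#' @export
local_shannon_entropy <- function(index, conditions, k = 50L, base = exp(1)) {
  nn <- resolve_index(index, k)
  N <- index$n
  if (length(conditions) != N) stop("conditions must cover every trace", call. = FALSE)
  f <- factor(conditions)
  lev <- as.integer(f)
  ncond <- nlevels(f)
  S <- numeric(N)
  for (i in seq_len(N)) {
    counts <- tabulate(c(lev[i], lev[nn[i, ]]), nbins = ncond)
    p <- counts[counts > 0] / (1 + k)
    S[i] <- -sum(p * log(p, base = base))
  }
  S
}

#' Recommended neighborhood size for entropy calculations
#'
#' Heuristic `k = 2 * sqrt(N)` (rounded), clamped to `[1, N - 1]`. The
#' default used throughout the package remains k = 50.
#'
#' @param n total number of traces.
#' @return Integer k.
#' @export
lse_k_heuristic <- function(n) {
  as.integer(pmin(pmax(round(2 * sqrt(n)), 1), n - 1))
}

#' Lowest-entropy subset of traces
#'
#' Indices of the `floor(fraction * N)` traces with the smallest local
#' entropies, ties broken by lower index; used to isolate
#' condition-specific behaviors.
#'
#' @param entropies per-trace entropies from [local_shannon_entropy()].
#' @param fraction fraction in (0, 1] of traces to keep.
#' @param conditions optional condition labels; when given, the
#'   per-condition composition of the subset is attached.
#' @return Integer index vector, with attribute `composition` (a table)
#'   when `conditions` is supplied.
#' @export
lowest_entropy_subset <- function(entropies, fraction, conditions = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]", call. = FALSE)
  n_keep <- floor(fraction * length(entropies))
  ord <- order(entropies, seq_along(entropies))
  keep <- sort(ord[seq_len(n_keep)])
  if (!is.null(conditions))
    attr(keep, "composition") <- table(conditions[keep])
  keep
}
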