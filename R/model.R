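## Patch-tokenized multi-head self-attention encoder.
## Layout: tokenize (W*C -> D per 50-frame patch), prepend a learnable
## trace token, add a learnable absolute position embedding, N pre-norm
## attention + feed-forward layers, final layer norm. The trace-token
## output z0 serves trace-level tasks; the remaining token outputs are
## expanded back to per-frame embeddings by a linear unstack operator.

trunc_normal <- function(n, sd = 0.02) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv_std <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv_std
  list(y = sweep(xhat, 2, g, `*`) + matrix(b, nrow(x), length(b), byrow = TRUE),
       xhat = xhat, inv_std = inv_std)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, `*`)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv_std
  list(dx = dx, dg = dg, db = db)
}

#' Initialize encoder weights
#'
#' Truncated-normal (s.d. 0.02, resampled beyond 2 s.d.) matrices, zero
#' biases, unit layer-norm gains; deterministic given `seed`.
#'
#' @param cfg a [model_config()].
#' @param heads optional list of task head specs (see [task_roster()]);
#'   each gets a `D x n_classes` weight and a bias vector.
#' @param seed integer seed.
#' @return Nested weight list.
#' @export
init_weights <- function(cfg, heads = list(), seed = 1L) {
  set.seed(seed)
  D <- cfg$embed_dim; W <- cfg$patch_width
  mat <- function(r, c) matrix(trunc_normal(r * c), r, c)
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    list(ln1_g = rep(1, D), ln1_b = rep(0, D),
         Wq = mat(D, D), bq = rep(0, D),
         Wk = mat(D, D), bk = rep(0, D),
         Wv = mat(D, D), bv = rep(0, D),
         Wo = mat(D, D), bo = rep(0, D),
         ln2_g = rep(1, D), ln2_b = rep(0, D),
         W1 = mat(D, cfg$ffn_multiplier * D), b1 = rep(0, cfg$ffn_multiplier * D),
         W2 = mat(cfg$ffn_multiplier * D, D), b2 = rep(0, D))
  })
  head_wts <- lapply(heads, function(h)
    list(W = mat(D, h$n_classes), b = rep(0, h$n_classes)))
  names(head_wts) <- vapply(heads, function(h) h$name, "")
  wts <- list(tok_W = mat(2L * W, D), tok_b = rep(0, D),
              pos = mat(cfg$max_tokens, D), cls = mat(1, D),
              layers = layers,
              lnf_g = rep(1, D), lnf_b = rep(0, D),
              unstack = mat(D, W * D),
              heads = head_wts)
  attr(wts, "config") <- cfg
  wts
}

#' Tokenize a trace into patch tokens
#'
#' Each `W`-frame, 2-channel patch is flattened (frame-major: all donor
#' values of the patch, then all acceptor values) and mapped by
#' `flatten(patch) %*% W_tokenizer + b_tokenizer`.
#'
#' @param trace T x 2 intensity matrix; T must be divisible by the patch
#'   width `nrow(W_tokenizer) / 2`.
#' @param W_tokenizer (2W) x D weight matrix.
#' @param b_tokenizer length-D bias.
#' @return (T/W) x D token matrix.
#' @export
tokenize <- function(trace, W_tokenizer, b_tokenizer) {
  W <- nrow(W_tokenizer) / 2L
  T_ <- nrow(trace)
  if (T_ %% W != 0)
    stop(sprintf("input-shape error: T = %d is not divisible by patch width W = %d; truncate or pad explicitly", T_, W), call. = FALSE)
  n_tok <- T_ %/% W
  # rows of `patches`: [donor frames 1..W, acceptor frames 1..W] per patch
  idx <- matrix(seq_len(T_), nrow = W)
  patches <- cbind(matrix(trace[, 1][idx], n_tok, W, byrow = TRUE),
                   matrix(trace[, 2][idx], n_tok, W, byrow = TRUE))
  patches %*% W_tokenizer + matrix(b_tokenizer, n_tok, length(b_tokenizer), byrow = TRUE)
}

#' Prepend the trace token and add the position embedding
#'
#' @param tokens (T/W) x D token matrix.
#' @param position_embedding at least (T/W + 1) x D.
#' @param class_token 1 x D learnable trace token.
#' @return (T/W + 1) x D input sequence.
#' @export
assemble_input <- function(tokens, position_embedding, class_token) {
  n <- nrow(tokens) + 1L
  if (nrow(position_embedding) < n)
    stop(sprintf("position embedding covers %d positions but %d are required",
                 nrow(position_embedding), n), call. = FALSE)
  rbind(class_token, tokens) + position_embedding[seq_len(n), , drop = FALSE]
}

# Multi-head self-attention + feed-forward stack on a batch of B
# sequences of length S stacked row-wise into an (B*S) x D matrix.
# The final layer norm is applied only when the stack has layers, so a
# zero-layer encoder is exactly the identity.
encoder_forward <- function(H, B, S, wts, cfg, keep_cache = FALSE) {
  D <- cfg$embed_dim; nh <- cfg$n_heads; dh <- D %/% nh
  row_of <- function(b) ((b - 1L) * S + 1L):(b * S)
  caches <- if (keep_cache) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    w <- wts$layers[[l]]
    if (any(!is.finite(w$Wq))) stop("numeric error: non-finite attention weights", call. = FALSE)
    ln1 <- layernorm_fwd(H, w$ln1_g, w$ln1_b)
    A <- ln1$y
    Q <- A %*% w$Wq + matrix(w$bq, nrow(A), D, byrow = TRUE)
    K <- A %*% w$Wk + matrix(w$bk, nrow(A), D, byrow = TRUE)
    V <- A %*% w$Wv + matrix(w$bv, nrow(A), D, byrow = TRUE)
    ctx <- matrix(0, nrow(A), D)
    Plist <- if (keep_cache) vector("list", B * nh) else NULL
    for (b in seq_len(B)) {
      r <- row_of(b)
      for (h in seq_len(nh)) {
        cidx <- ((h - 1L) * dh + 1L):(h * dh)
        Sc <- tcrossprod(Q[r, cidx, drop = FALSE], K[r, cidx, drop = FALSE]) / sqrt(dh)
        P <- softmax_rows(Sc)
        ctx[r, cidx] <- P %*% V[r, cidx, drop = FALSE]
        if (keep_cache) Plist[[(b - 1L) * nh + h]] <- P
      }
    }
    O <- ctx %*% w$Wo + matrix(w$bo, nrow(A), D, byrow = TRUE)
    H_mid <- H + O
    ln2 <- layernorm_fwd(H_mid, w$ln2_g, w$ln2_b)
    Fm <- ln2$y
    U <- Fm %*% w$W1 + matrix(w$b1, nrow(Fm), ncol(w$W1), byrow = TRUE)
    G <- gelu(U)
    O2 <- G %*% w$W2 + matrix(w$b2, nrow(G), D, byrow = TRUE)
    H_new <- H_mid + O2
    if (keep_cache) {
      caches[[l]] <- list(ln1 = ln1[c("xhat", "inv_std")], A = A, Q = Q, K = K,
                          V = V, Plist = Plist, ctx = ctx,
                          ln2 = ln2[c("xhat", "inv_std")], Fm = Fm, U = U, G = G)
    }
    H <- H_new
  }
  if (cfg$n_layers == 0L) return(list(Z = H, lnf = NULL, caches = caches))
  lnf <- layernorm_fwd(H, wts$lnf_g, wts$lnf_b)
  list(Z = lnf$y, lnf = lnf[c("xhat", "inv_std")], caches = caches)
}

#' Encode a token sequence with the attention stack
#'
#' Runs the pre-norm multi-head self-attention + feed-forward layers and
#' the final layer normalization on one sequence. A zero-layer stack is
#' the identity.
#'
#' @param seq T' x D input sequence (from [assemble_input()]).
#' @param weights weight list from [init_weights()].
#' @param cfg a [model_config()].
#' @return T' x D encoded sequence.
#' @export
attention_encode <- function(seq, weights, cfg) {
  encoder_forward(seq, 1L, nrow(seq), weights, cfg)$Z
}

#' Expand a patch embedding to per-frame embeddings
#'
#' The reverse operator of the tokenizer: `z_i %*% W_unstack` reshaped to
#' a W x D block, one embedding row per frame of the patch.
#'
#' @param z_i length-D embedding of one patch token.
#' @param W_unstack D x (W*D) weight matrix; frame w reads columns
#'   `((w-1)D+1):(wD)`.
#' @return W x D matrix of frame embeddings.
#' @export
unstack_frames <- function(z_i, W_unstack) {
  D <- length(z_i)
  W <- ncol(W_unstack) %/% D
  v <- as.numeric(matrix(z_i, 1, D) %*% W_unstack)
  matrix(v, nrow = W, ncol = D, byrow = TRUE)
}

#' Predict class probabilities from an embedding with a linear head
#'
#' @param emb length-D vector or n x D matrix.
#' @param head list with `W` (D x n_classes) and `b`.
#' @return Probability vector (or n x n_classes matrix), rows sum to 1.
#' @export
head_predict <- function(emb, head) {
  if (is.null(dim(emb))) emb <- matrix(emb, 1)
  logits <- emb %*% head$W + matrix(head$b, nrow(emb), length(head$b), byrow = TRUE)
  p <- softmax_rows(logits)
  if (nrow(p) == 1L) as.numeric(p) else p
}

#' Embed traces with the encoder
#'
#' Composition tokenize -> assemble -> attention-encode -> split: the
#' trace-token output is the trace-level embedding `z0`; the remaining
#' token outputs are unstacked to per-frame embeddings. Traces whose
#' length is not a multiple of the patch width are right-truncated with a
#' warning (never padded).
#'
#' @param traces a `trace_set`, list of `sm_trace`, or list of T x 2
#'   matrices.
#' @param weights weight list from [init_weights()].
#' @param cfg a [model_config()].
#' @param frames also compute per-frame embeddings (default TRUE).
#' @return List of class `embedding_set`: `z0` (N x D matrix), `frames`
#'   (list of T x D matrices or NULL), `fingerprint` (hash of weights).
#' @export
embed_traces <- function(traces, weights, cfg, frames = TRUE) {
  mats <- as_trace_matrices(traces)
  W <- cfg$patch_width; D <- cfg$embed_dim
  N <- length(mats)
  lens <- vapply(mats, nrow, 0L)
  if (any(lens %% W != 0)) {
    warning(sprintf("%d trace(s) right-truncated to a multiple of the patch width (W = %d)",
                    sum(lens %% W != 0), W))
    mats <- lapply(mats, function(m) m[seq_len((nrow(m) %/% W) * W), , drop = FALSE])
    lens <- vapply(mats, nrow, 0L)
  }
  if (any(lens < W)) stop("input-shape error: trace shorter than one patch", call. = FALSE)
  z0 <- matrix(0, N, D)
  fr <- if (frames) vector("list", N) else NULL
  for (Tval in unique(lens)) {
    idx <- which(lens == Tval)
    S <- Tval %/% W + 1L
    H <- matrix(0, length(idx) * S, D)
    for (j in seq_along(idx)) {
      tok <- tokenize(normalize_trace_matrix(mats[[idx[j]]]),
                      weights$tok_W, weights$tok_b)
      H[((j - 1L) * S + 1L):(j * S), ] <- assemble_input(tok, weights$pos, weights$cls)
    }
    Z <- encoder_forward(H, length(idx), S, weights, cfg)$Z
    for (j in seq_along(idx)) {
      r <- ((j - 1L) * S + 1L):(j * S)
      z <- Z[r, , drop = FALSE]
      z0[idx[j], ] <- z[1, ]
      if (frames) {
        ztok <- z[-1, , drop = FALSE]
        # rows of (ztok %*% unstack) are patches; each row reshapes
        # row-major to a W x D block of frame embeddings
        fmat <- matrix(as.vector(t(ztok %*% weights$unstack)),
                       nrow = Tval, ncol = D, byrow = TRUE)
        fr[[idx[j]]] <- fmat
      }
    }
  }
  out <- list(z0 = z0, frames = fr, fingerprint = config_hash(weights))
  class(out) <- "embedding_set"
  out
}

as_trace_matrices <- function(traces) {
  if (inherits(traces, "trace_set")) traces <- traces$traces
  if (inherits(traces, "sm_trace")) traces <- list(traces)
  lapply(traces, function(t) if (inherits(t, "sm_trace")) t$intensities else as.matrix(t))
}

# Scale-normalize a trace before tokenization: intensities are divided by
# the 95th percentile of the summed channels, making embeddings invariant
# to the arbitrary intensity units of the recording (SNR and kinetics are
# scale-free). Applied consistently at embedding and training time.
normalize_trace_matrix <- function(m) {
  s <- quantile(m[, 1] + m[, 2], 0.95, names = FALSE)
  if (!is.finite(s) || s < 1e-9) s <- 1
  m / s
}

#' Count trainable parameters of the encoder and heads
#'
#' Closed-form summation over tokenizer, position embedding, trace token,
#' attention layers, final norm, unstack operator and task heads.
#'
#' @param cfg a [model_config()].
#' @param heads list of head specs with `n_classes` fields.
#' @return Integer parameter count.
#' @export
count_parameters <- function(cfg, heads = list()) {
  D <- cfg$embed_dim; W <- cfg$patch_width; Fh <- cfg$ffn_multiplier * D
  per_layer <- 2 * D +                  # ln1
    3 * (D * D + D) +                   # Q, K, V
    (D * D + D) +                       # output projection
    2 * D +                             # ln2
    (D * Fh + Fh) + (Fh * D + D)        # feed-forward
  n <- (2 * W * D + D) +                # tokenizer
    cfg$max_tokens * D + D +            # position embedding + trace token
    cfg$n_layers * per_layer +
    2 * D +                             # final norm
    D * W * D                           # unstack
  for (h in heads) n <- n + D * h$n_classes + h$n_classes
  as.integer(n)
}
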