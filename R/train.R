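## Multitask pre-training: balanced batches, unified cross-entropy
## (KL-to-one-hot) loss, ADAM, and a hand-written backward pass through
## the full encoder (heads, unstack, attention layers, position
## embedding, trace token, tokenizer).

EPS_PROB <- 1e-9

#' Multitask cross-entropy loss
#'
#' Sum over tasks of the per-task mean cross-entropy between empirical
#' label distributions (one-hot by default) and predicted probabilities:
#' for one-hot labels this equals the KL divergence up to constants and
#' is non-negative. Predicted probabilities are clipped at 1e-9 before
#' the logarithm (with a warning when clipping occurs).
#'
#' @param predictions named list, one entry per task: n_i x C probability
#'   matrix (rows sum to 1).
#' @param labels named list matching `predictions`: integer class vectors,
#'   or n_i x C matrices of empirical distributions.
#' @return Scalar total loss, with attribute `per_task` holding the
#'   per-task means.
#' @export
multitask_loss <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  per_task <- vapply(seq_along(predictions), function(j) {
    p <- predictions[[j]]
    if (is.null(dim(p))) p <- matrix(p, 1)
    y <- labels[[j]]
    if (is.matrix(y)) {
      q <- pmax(p, EPS_PROB)
      if (any(p < EPS_PROB & y > 0)) warning("predicted probability clipped at 1e-9")
      mean(-rowSums(y * log(q)))
    } else {
      picked <- p[cbind(seq_len(nrow(p)), as.integer(y))]
      if (any(picked < EPS_PROB)) warning("predicted probability clipped at 1e-9")
      mean(-log(pmax(picked, EPS_PROB)))
    }
  }, 0)
  names(per_task) <- names(predictions)
  structure(sum(per_task), per_task = per_task)
}

#' Task-balanced mini-batch sampler
#'
#' Within every batch the per-task example counts differ by at most one
#' and all tasks are represented. Returns a closure; each call yields one
#' batch as a data.frame with columns `task` (name) and `trace` (index).
#'
#' @param dataset a `trace_set` (or list of `sm_trace`).
#' @param batch_size examples per batch; must be >= the task count.
#' @param tasks task roster (default [task_roster()]).
#' @return Function of no arguments producing one batch per call.
#' @export
build_balanced_minibatches <- function(dataset, batch_size, tasks = task_roster()) {
  traces <- if (inherits(dataset, "trace_set")) dataset$traces else dataset
  nt <- length(tasks)
  if (batch_size < nt)
    stop(sprintf("batch_size (%d) must be at least the task count (%d)", batch_size, nt),
         call. = FALSE)
  eligible <- lapply(tasks, function(task)
    which(vapply(traces, function(tr) task_eligible(task, tr), TRUE)))
  empty <- vapply(eligible, length, 0L) == 0L
  if (any(empty))
    stop("no eligible traces for task(s): ",
         paste(names(tasks)[empty], collapse = ", "), call. = FALSE)
  base <- batch_size %/% nt
  extra <- batch_size %% nt
  task_names <- names(tasks)
  function() {
    counts <- rep(base, nt)
    if (extra > 0) {
      bump <- sample.int(nt, extra)
      counts[bump] <- counts[bump] + 1L
    }
    task_col <- rep(task_names, counts)
    trace_col <- unlist(lapply(seq_len(nt), function(j) {
      pool <- eligible[[j]]
      pool[sample.int(length(pool), counts[j], replace = length(pool) < counts[j])]
    }))
    data.frame(task = task_col, trace = trace_col, stringsAsFactors = FALSE)
  }
}

## ---- parameter flattening for the optimizer -------------------------------

flatten_params <- function(x) {
  out <- list()
  rec <- function(v, prefix) {
    if (is.list(v)) {
      nm <- names(v) %||% as.character(seq_along(v))
      for (i in seq_along(v)) rec(v[[i]], paste0(prefix, ".", nm[i]))
    } else out[[substring(prefix, 2)]] <<- v
  }
  rec(x, "")
  out
}

zero_like <- function(flat) lapply(flat, function(v) v * 0)

unflatten_params <- function(flat, skeleton) {
  i <- 0L
  rec <- function(v) {
    if (is.list(v)) {
      for (j in seq_along(v)) v[[j]] <- rec(v[[j]])
      v
    } else {
      i <<- i + 1L
      flat[[i]]
    }
  }
  rec(skeleton)
}

adam_update <- function(wflat, gflat, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(wflat)) {
    g <- gflat[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    wflat[[k]] <- wflat[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  wflat
}

## ---- encoder backward -----------------------------------------------------

encoder_backward <- function(dZ, fwd, H_rows, wts, cfg, B, S) {
  D <- cfg$embed_dim; nh <- cfg$n_heads; dh <- D %/% nh
  grads <- list(layers = vector("list", cfg$n_layers))
  if (cfg$n_layers == 0L) {
    grads$lnf_g <- rep(0, D); grads$lnf_b <- rep(0, D)
    return(list(dH = dZ, grads = grads))
  }
  bw <- layernorm_bwd(dZ, fwd$lnf, wts$lnf_g)
  grads$lnf_g <- bw$dg; grads$lnf_b <- bw$db
  dH <- bw$dx
  row_of <- function(b) ((b - 1L) * S + 1L):(b * S)
  for (l in rev(seq_len(cfg$n_layers))) {
    w <- wts$layers[[l]]
    c_ <- fwd$caches[[l]]
    ## feed-forward block
    dO2 <- dH
    dG <- dO2 %*% t(w$W2)
    gW2 <- crossprod(c_$G, dO2)
    gb2 <- colSums(dO2)
    dU <- dG * gelu_grad(c_$U)
    dF <- dU %*% t(w$W1)
    gW1 <- crossprod(c_$Fm, dU)
    gb1 <- colSums(dU)
    bw2 <- layernorm_bwd(dF, c_$ln2, w$ln2_g)
    dH <- dH + bw2$dx
    ## attention block
    dO <- dH
    dctx <- dO %*% t(w$Wo)
    gWo <- crossprod(c_$ctx, dO)
    gbo <- colSums(dO)
    dQ <- matrix(0, nrow(dH), D); dK <- dQ; dV <- dQ
    for (b in seq_len(B)) {
      r <- row_of(b)
      for (h in seq_len(nh)) {
        cidx <- ((h - 1L) * dh + 1L):(h * dh)
        P <- c_$Plist[[(b - 1L) * nh + h]]
        dctx_h <- dctx[r, cidx, drop = FALSE]
        Vh <- c_$V[r, cidx, drop = FALSE]
        dP <- tcrossprod(dctx_h, Vh)
        dV[r, cidx] <- crossprod(P, dctx_h)
        dSc <- (dP - rowSums(dP * P)) * P / sqrt(dh)
        dQ[r, cidx] <- dSc %*% c_$K[r, cidx, drop = FALSE]
        dK[r, cidx] <- crossprod(dSc, c_$Q[r, cidx, drop = FALSE])
      }
    }
    gWq <- crossprod(c_$A, dQ); gbq <- colSums(dQ)
    gWk <- crossprod(c_$A, dK); gbk <- colSums(dK)
    gWv <- crossprod(c_$A, dV); gbv <- colSums(dV)
    dA <- dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv)
    bw1 <- layernorm_bwd(dA, c_$ln1, w$ln1_g)
    dH <- dH + bw1$dx
    grads$layers[[l]] <- list(ln1_g = bw1$dg, ln1_b = bw1$db,
                              Wq = gWq, bq = gbq, Wk = gWk, bk = gbk,
                              Wv = gWv, bv = gbv, Wo = gWo, bo = gbo,
                              ln2_g = bw2$dg, ln2_b = bw2$db,
                              W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }
  list(dH = dH, grads = grads)
}

## row-major flatten of a frame-block matrix: (S-1) x (W*D) <-> T x D
frames_to_patch_rows <- function(fmat, W, D) {
  n_tok <- nrow(fmat) %/% W
  matrix(as.vector(t(fmat)), nrow = n_tok, ncol = W * D, byrow = TRUE)
}

patch_rows_to_frames <- function(pmat, W, D) {
  matrix(as.vector(t(pmat)), nrow = nrow(pmat) * W, ncol = D, byrow = TRUE)
}

## one training step on a batch; returns loss and flat gradients
train_step_grads <- function(batch, patches, labels, tasks, wts, cfg) {
  B <- nrow(batch); W <- cfg$patch_width; D <- cfg$embed_dim
  n_tok <- nrow(patches[[batch$trace[1]]])
  S <- n_tok + 1L
  H <- matrix(0, B * S, D)
  Pbig <- matrix(0, B * n_tok, 2L * W)
  pos <- wts$pos[seq_len(S), , drop = FALSE]
  for (j in seq_len(B)) {
    P <- patches[[batch$trace[j]]]
    Pbig[((j - 1L) * n_tok + 1L):(j * n_tok), ] <- P
    tok <- P %*% wts$tok_W + matrix(wts$tok_b, n_tok, D, byrow = TRUE)
    H[((j - 1L) * S + 1L):(j * S), ] <- rbind(wts$cls, tok) + pos
  }
  fwd <- encoder_forward(H, B, S, wts, cfg, keep_cache = TRUE)
  Z <- fwd$Z
  dZ <- matrix(0, B * S, D)
  head_grads <- list()
  g_unstack <- NULL
  loss <- 0
  for (j in seq_len(B)) {
    tname <- batch$task[j]
    task <- tasks[[tname]]
    hw <- wts$heads[[tname]]
    rows <- ((j - 1L) * S + 1L):(j * S)
    if (task$level == "trace") {
      z <- Z[rows[1], , drop = FALSE]
      y <- labels[[tname]][batch$trace[j]]
      p <- softmax_rows(z %*% hw$W + matrix(hw$b, 1, task$n_classes))
      loss <- loss + (-log(max(p[1, y], EPS_PROB))) / B
      dlog <- p
      dlog[1, y] <- dlog[1, y] - 1
      dlog <- dlog / B
      dz <- dlog %*% t(hw$W)
      gW <- crossprod(z, dlog); gb <- as.numeric(dlog)
      dZ[rows[1], ] <- dZ[rows[1], ] + dz
    } else {
      ztok <- Z[rows[-1], , drop = FALSE]
      fmat <- patch_rows_to_frames(ztok %*% wts$unstack, W, D)
      y <- labels[[tname]][[batch$trace[j]]]
      T_ <- nrow(fmat)
      logits <- fmat %*% hw$W + matrix(hw$b, T_, task$n_classes, byrow = TRUE)
      p <- softmax_rows(logits)
      picked <- pmax(p[cbind(seq_len(T_), y)], EPS_PROB)
      loss <- loss + mean(-log(picked)) / B
      dlog <- p
      dlog[cbind(seq_len(T_), y)] <- dlog[cbind(seq_len(T_), y)] - 1
      dlog <- dlog / (T_ * B)
      gW <- crossprod(fmat, dlog); gb <- colSums(dlog)
      dframes <- dlog %*% t(hw$W)
      dpatch <- frames_to_patch_rows(dframes, W, D)
      if (is.null(g_unstack)) g_unstack <- crossprod(ztok, dpatch)
      else g_unstack <- g_unstack + crossprod(ztok, dpatch)
      dZ[rows[-1], ] <- dZ[rows[-1], ] + dpatch %*% t(wts$unstack)
    }
    if (is.null(head_grads[[tname]])) head_grads[[tname]] <- list(W = gW, b = gb)
    else {
      head_grads[[tname]]$W <- head_grads[[tname]]$W + gW
      head_grads[[tname]]$b <- head_grads[[tname]]$b + gb
    }
  }
  bk <- encoder_backward(dZ, fwd, NULL, wts, cfg, B, S)
  dH <- bk$dH
  ## distribute dH into position embedding, trace token and tokens
  g_pos <- matrix(0, nrow(wts$pos), D)
  g_cls <- matrix(0, 1, D)
  dTok <- matrix(0, B * n_tok, D)
  for (j in seq_len(B)) {
    rows <- ((j - 1L) * S + 1L):(j * S)
    dh_j <- dH[rows, , drop = FALSE]
    g_pos[seq_len(S), ] <- g_pos[seq_len(S), ] + dh_j
    g_cls <- g_cls + dh_j[1, , drop = FALSE]
    dTok[((j - 1L) * n_tok + 1L):(j * n_tok), ] <- dh_j[-1, , drop = FALSE]
  }
  g_tokW <- crossprod(Pbig, dTok)
  g_tokb <- colSums(dTok)

  grads <- list(tok_W = g_tokW, tok_b = g_tokb, pos = g_pos, cls = g_cls,
                layers = bk$grads$layers,
                lnf_g = bk$grads$lnf_g, lnf_b = bk$grads$lnf_b,
                unstack = g_unstack %||% (wts$unstack * 0),
                heads = lapply(names(wts$heads), function(nm)
                  head_grads[[nm]] %||% list(W = wts$heads[[nm]]$W * 0,
                                             b = wts$heads[[nm]]$b * 0)))
  names(grads$heads) <- names(wts$heads)
  list(loss = loss, grads = grads)
}

## evaluate per-task losses over a set of traces with current weights
evaluate_task_losses <- function(traces, labels, tasks, wts, cfg, idx = NULL) {
  if (inherits(traces, "trace_set")) traces <- traces$traces
  if (is.null(idx)) idx <- seq_along(traces)
  emb <- embed_traces(traces[idx], wts, cfg, frames = TRUE)
  preds <- list(); labs <- list()
  for (tname in names(tasks)) {
    task <- tasks[[tname]]
    hw <- wts$heads[[tname]]
    if (task$level == "trace") {
      y <- labels[[tname]][idx]
      keep <- which(!is.na(y))
      if (length(keep) == 0) next
      preds[[tname]] <- head_predict(emb$z0[keep, , drop = FALSE], hw)
      labs[[tname]] <- y[keep]
    } else {
      ylist <- labels[[tname]][idx]
      keep <- which(!vapply(ylist, is.null, TRUE))
      if (length(keep) == 0) next
      fall <- do.call(rbind, emb$frames[keep])
      preds[[tname]] <- head_predict(fall, hw)
      labs[[tname]] <- unlist(ylist[keep])
    }
  }
  total <- multitask_loss(preds, labs)
  list(total = as.numeric(total), per_task = attr(total, "per_task"))
}

#' Pre-train the encoder on the multitask roster
#'
#' Task-balanced mini-batches, unified cross-entropy loss, ADAM
#' (beta1 = 0.9, beta2 = 0.999) with linear learning-rate warmup.
#' Deterministic given `seed` on one machine. Validation losses (per task
#' and total) are recorded at step 0, every `eval_every` steps and at the
#' final step, on a held-out split.
#'
#' @param dataset a labeled `trace_set` from [generate_dataset()].
#' @param cfg a [model_config()].
#' @param tasks task roster (default [task_roster()]).
#' @param steps number of optimizer steps.
#' @param batch_size examples per batch (default: one per task).
#' @param lr peak learning rate.
#' @param warmup_steps linear warmup length.
#' @param seed integer seed for initialization and batch sampling.
#' @param val_fraction held-out fraction for validation losses.
#' @param eval_every validation cadence in steps.
#' @param eval_max maximum validation traces used per evaluation.
#' @param init optional initial weights (resume training).
#' @return List of class `pretrain_fit`: `weights`, `history` (data.frame
#'   step/task/split/loss including `.total` rows), `train_loss`
#'   (per-step batch losses), `config`, `tasks`.
#' @export
pretrain <- function(dataset, cfg = model_config(), tasks = task_roster(),
                     steps = 1000L, batch_size = length(tasks), lr = 3e-4,
                     warmup_steps = 100L, seed = 1L, val_fraction = 0.1,
                     eval_every = 250L, eval_max = 200L, init = NULL) {
  traces <- dataset$traces
  set.seed(seed)
  wts <- init %||% init_weights(cfg, tasks, seed = seed)
  n <- length(traces)
  n_val <- max(1L, floor(val_fraction * n))
  val_idx <- sample.int(n, n_val)
  if (length(val_idx) > eval_max) val_idx <- val_idx[seq_len(eval_max)]
  train_idx <- setdiff(seq_len(n), val_idx)
  labels <- compute_task_labels(traces, tasks)
  W <- cfg$patch_width
  patches <- lapply(traces, function(tr) {
    m <- normalize_trace_matrix(tr$intensities)
    T_ <- (nrow(m) %/% W) * W
    if (T_ < nrow(m)) m <- m[seq_len(T_), , drop = FALSE]
    idxm <- matrix(seq_len(T_), nrow = W)
    cbind(matrix(m[, 1][idxm], T_ %/% W, W, byrow = TRUE),
          matrix(m[, 2][idxm], T_ %/% W, W, byrow = TRUE))
  })
  sampler <- build_balanced_minibatches(
    structure(list(traces = traces[train_idx]), class = "trace_set"),
    batch_size, tasks)
  # sampler indexes into train subset; remap to full indices
  remap <- train_idx

  skeleton <- wts
  wflat <- flatten_params(wts)
  state <- new.env()
  state$t <- 0L
  state$m <- zero_like(wflat)
  state$v <- zero_like(wflat)

  history <- list()
  train_loss <- numeric(steps)
  record_eval <- function(step) {
    ev <- evaluate_task_losses(traces, labels, tasks, wts, cfg, idx = val_idx)
    rows <- data.frame(step = step, task = c(names(ev$per_task), ".total"),
                       split = "val", loss = c(ev$per_task, ev$total),
                       stringsAsFactors = FALSE)
    history[[length(history) + 1L]] <<- rows
  }
  record_eval(0L)
  for (s in seq_len(steps)) {
    batch <- sampler()
    batch$trace <- remap[batch$trace]
    res <- train_step_grads(batch, patches, labels, tasks, wts, cfg)
    if (!is.finite(res$loss))
      stop(sprintf("divergence: non-finite loss at step %d", s), call. = FALSE)
    train_loss[s] <- res$loss
    lr_t <- lr * min(1, s / max(1, warmup_steps))
    wflat <- adam_update(wflat, flatten_params(res$grads), state, lr_t)
    wts <- unflatten_params(wflat, skeleton)
    attr(wts, "config") <- cfg
    if (s %% eval_every == 0L || s == steps) record_eval(s)
  }
  out <- list(weights = wts, history = do.call(rbind, history),
              train_loss = train_loss, config = cfg, tasks = tasks,
              seed = seed, val_idx = val_idx)
  class(out) <- "pretrain_fit"
  out
}
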