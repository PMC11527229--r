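test_that("tokenizer shapes and linear algebra", {
  W <- 50L; D <- 16L
  trace <- matrix(rnorm(2000 * 2), 2000, 2)
  Wt <- matrix(rnorm(2 * W * D, sd = 0.1), 2 * W, D)
  bt <- rnorm(D)
  tok <- tokenize(trace, Wt, bt)
  expect_equal(dim(tok), c(40L, D))

  # zero weights: every token equals the bias
  tok0 <- tokenize(trace, Wt * 0, bt)
  expect_equal(tok0, matrix(bt, 40, D, byrow = TRUE))

  # hand-computed oracle for one patch: explicit flatten + product
  patch <- trace[1:W, ]
  flat <- c(patch[, 1], patch[, 2])
  manual <- as.numeric(flat %*% Wt) + bt
  expect_equal(unname(tok[1, ]), manual, tolerance = 1e-12)

  expect_error(tokenize(trace[1:1999, ], Wt, bt), "input-shape")
})

test_that("input assembly prepends the trace token and adds positions", {
  D <- 8L
  tokens <- matrix(rnorm(40 * D), 40, D)
  pos <- matrix(rnorm(41 * D), 41, D)
  cls <- matrix(rnorm(D), 1, D)
  seqv <- assemble_input(tokens, pos, cls)
  expect_equal(nrow(seqv), 41L)           # T' = T/W + 1
  expect_equal(assemble_input(tokens, pos * 0, cls), rbind(cls, tokens))
  one <- assemble_input(tokens[1, , drop = FALSE], pos, cls)
  expect_equal(nrow(one), 2L)             # T = W: length 2
  expect_error(assemble_input(tokens, pos[1:10, ], cls), "position embedding")
})

test_that("attention encoder: identity at zero depth, determinism, oracle", {
  D <- 8L
  cfg0 <- model_config(patch_width = 5L, embed_dim = D, n_layers = 0L,
                       n_heads = 2L, max_tokens = 9L)
  wts0 <- init_weights(cfg0, seed = 1)
  x <- matrix(rnorm(4 * D), 4, D)
  expect_identical(attention_encode(x, wts0, cfg0), x)

  cfg1 <- model_config(patch_width = 5L, embed_dim = D, n_layers = 2L,
                       n_heads = 2L, max_tokens = 9L)
  wts1 <- init_weights(cfg1, seed = 2)
  o1 <- attention_encode(x, wts1, cfg1)
  o2 <- attention_encode(x, wts1, cfg1)
  expect_identical(o1, o2)
  expect_equal(dim(o1), dim(x))

  # single-layer single-head oracle with hand-set Q = K = V = identity,
  # computed independently with explicit softmax attention
  cfgh <- model_config(patch_width = 2L, embed_dim = 4L, n_layers = 1L,
                       n_heads = 1L, max_tokens = 4L)
  wtsh <- init_weights(cfgh, seed = 3)
  L <- wtsh$layers[[1]]
  L$Wq <- diag(4); L$Wk <- diag(4); L$Wv <- diag(4); L$Wo <- diag(4)
  L$bq <- L$bk <- L$bv <- L$bo <- rep(0, 4)
  L$ln1_g <- L$ln2_g <- rep(1, 4); L$ln1_b <- L$ln2_b <- rep(0, 4)
  L$W1 <- matrix(0, 4, 16); L$b1 <- rep(0, 16)
  L$W2 <- matrix(0, 16, 4); L$b2 <- rep(0, 4)
  wtsh$layers[[1]] <- L
  wtsh$lnf_g <- rep(1, 4); wtsh$lnf_b <- rep(0, 4)
  xs <- matrix(c(1, 0, -1, 2, 0.5, 1, -0.5, 0), 2, 4, byrow = TRUE)
  got <- attention_encode(xs, wtsh, cfgh)
  # oracle
  ln <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
  A <- t(apply(xs, 1, ln))
  S <- A %*% t(A) / sqrt(4)
  P <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  H <- xs + P %*% A                      # gelu(0) = 0: FFN contributes nothing
  want <- t(apply(H, 1, ln))
  expect_equal(got, want, tolerance = 1e-6)

  # non-finite weights surface an error
  wbad <- wts1
  wbad$layers[[1]]$Wq[1, 1] <- NaN
  expect_error(attention_encode(x, wbad, cfg1), "numeric error")
})

test_that("attention is permutation-equivariant over non-class positions", {
  D <- 8L
  cfg <- model_config(patch_width = 5L, embed_dim = D, n_layers = 2L,
                      n_heads = 2L, max_tokens = 9L)
  wts <- init_weights(cfg, seed = 4)
  set.seed(5)
  tokens <- matrix(rnorm(6 * D), 6, D)
  pos <- wts$pos[1:7, ]
  x <- rbind(wts$cls + pos[1, ], tokens + pos[-1, ])
  out <- attention_encode(x, wts, cfg)
  perm <- c(3, 1, 2, 6, 5, 4)
  xp <- rbind(wts$cls + pos[1, ], tokens[perm, ] + pos[-1, ][perm, ])
  outp <- attention_encode(xp, wts, cfg)
  expect_equal(outp[1, ], out[1, ], tolerance = 1e-10)
  expect_equal(outp[-1, ], out[-1, ][perm, ], tolerance = 1e-10)
})

test_that("unstack expands patch embeddings per frame", {
  D <- 6L; W <- 4L
  Wu <- matrix(rnorm(D * W * D), D, W * D)
  z <- rnorm(D)
  fr <- unstack_frames(z, Wu)
  expect_equal(dim(fr), c(W, D))
  expect_equal(unstack_frames(rep(0, D), Wu), matrix(0, W, D))
  # W = 1: plain linear map
  Wu1 <- matrix(rnorm(D * D), D, D)
  expect_equal(unstack_frames(z, Wu1), matrix(as.numeric(z %*% Wu1), 1, D))
  # independent oracle: column block w holds frame w
  v <- as.numeric(matrix(z, 1) %*% Wu)
  for (w in seq_len(W))
    expect_equal(unname(fr[w, ]), v[((w - 1) * D + 1):(w * D)])
})

test_that("embed_traces: shape contract, batching, channel asymmetry", {
  cfg <- tiny_model_cfg()
  wts <- init_weights(cfg, seed = 6)
  set.seed(7)
  mats <- lapply(1:3, function(i) matrix(rnorm(20 * 2, 100, 10), 20, 2))
  e3 <- embed_traces(mats, wts, cfg)
  expect_equal(dim(e3$z0), c(3L, cfg$embed_dim))
  expect_equal(dim(e3$frames[[2]]), c(20L, cfg$embed_dim))
  # batch invariance
  e1 <- embed_traces(mats[2], wts, cfg)
  expect_equal(e1$z0[1, ], e3$z0[2, ], tolerance = 1e-12)
  expect_equal(e1$frames[[1]], e3$frames[[2]], tolerance = 1e-12)
  # one-color trace: finite embeddings
  m1 <- cbind(rnorm(20, 100, 10), 0)
  eo <- embed_traces(list(m1), wts, cfg)
  expect_true(all(is.finite(eo$z0)))
  # channels are not symmetric
  sw <- m1[, 2:1]
  es <- embed_traces(list(sw), wts, cfg)
  expect_gt(max(abs(es$z0 - eo$z0)), 1e-6)
  # non-multiple length: explicit truncation with warning
  expect_warning(et <- embed_traces(list(matrix(rnorm(23 * 2), 23, 2)), wts, cfg),
                 "truncated")
  expect_equal(nrow(et$frames[[1]]), 20L)
})

test_that("head_predict is a softmax probability vector", {
  D <- 8L
  h0 <- list(W = matrix(0, D, 4), b = rep(0, 4))
  expect_equal(head_predict(rnorm(D), h0), rep(0.25, 4))
  hb <- list(W = matrix(0, D, 4), b = c(0, 50, 0, 0))
  expect_equal(which.max(head_predict(rnorm(D), hb)), 2L)
  set.seed(8)
  h <- list(W = matrix(rnorm(D * 3), D, 3), b = rnorm(3))
  z <- rnorm(D)
  p <- head_predict(z, h)
  logits <- as.numeric(z %*% h$W) + h$b
  oracle <- exp(logits) / sum(exp(logits))
  expect_equal(p, oracle, tolerance = 1e-6)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("parameter count matches instantiated weight shapes", {
  cfg <- model_config(patch_width = 1L, embed_dim = 4L, n_layers = 0L,
                      n_heads = 1L, max_tokens = 3L)
  # tokenizer (2*1*4 + 4) + pos (3*4) + cls 4 + final norm 8 + unstack 4*1*4
  expect_equal(count_parameters(cfg), 12L + 12L + 4L + 8L + 16L)

  tasks <- task_roster()
  cfg2 <- model_config(patch_width = 10L, embed_dim = 16L, n_layers = 3L,
                       n_heads = 4L, max_tokens = 11L)
  wts <- init_weights(cfg2, tasks, seed = 9)
  walk <- sum(vapply(tracefm:::flatten_params(wts), length, 0L))
  expect_equal(count_parameters(cfg2, tasks), walk)

  # doubling depth adds exactly N * per-layer parameters
  cfg3 <- model_config(patch_width = 10L, embed_dim = 16L, n_layers = 6L,
                       n_heads = 4L, max_tokens = 11L)
  per_layer <- (count_parameters(cfg3) - count_parameters(cfg2)) / 3L
  cfg4 <- model_config(patch_width = 10L, embed_dim = 16L, n_layers = 12L,
                       n_heads = 4L, max_tokens = 11L)
  expect_equal(count_parameters(cfg4) - count_parameters(cfg3), 6L * per_layer)
})
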