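## The smFRET Atlas: systematic category nomenclature over simulation
## parameters, a category-conditioned corpus generator, a fitted global
## 2-D reducer, and per-category Gaussian-mixture contour annotation.

LEVEL_LETTERS <- c("l", "m", "h")

fret_level_letter <- function(v) {
  # high: > 0.65; medium: 0.35 <= v <= 0.65 (inclusive); low: < 0.35
  ifelse(v > 0.65, "h", ifelse(v >= 0.35, "m", "l"))
}

#' Enumerate the Atlas category labels
#'
#' Nomenclature "states-SNR-FRETlevels[-rate]": state count 1--3, SNR
#' class c(lean) / n(oisy), FRET levels a size-`states` set of distinct
#' letters from {l, m, h} written ascending, and a rate class s(low) /
#' f(ast) only for 2+ states. The enumeration closes the grammar at 22
#' categories (6 one-state + 12 two-state + 4 three-state).
#'
#' @return Character vector of category labels in canonical order.
#' @export
enumerate_categories <- function() {
  out <- character(0)
  for (s in 1:3) {
    combos <- combn(LEVEL_LETTERS, s, paste, collapse = "")
    for (snr in c("c", "n")) {
      for (lv in combos) {
        if (s == 1L) {
          out <- c(out, paste(s, snr, lv, sep = "-"))
        } else {
          for (rate in c("s", "f"))
            out <- c(out, paste(s, snr, lv, rate, sep = "-"))
        }
      }
    }
  }
  out
}

#' Categorize a trace from its ground truth
#'
#' Thresholds: SNR >= 4 is "clean"; FRET > 0.65 high, 0.35 <= value
#' <= 0.65 medium, < 0.35 low; average transition rate >= 0.05 frame^-1
#' fast (rate class applies only to 2+ states). FRET level letters are
#' written ascending (the canonical dialect, e.g. "2-c-mh-f").
#'
#' @param ground_truth a `ground_truth` (or `sm_trace`) with fields
#'   `n_states`, `snr`, `state_fret_values`, `mean_transition_rate`.
#' @return Category label string.
#' @export
categorize <- function(ground_truth) {
  gt <- if (inherits(ground_truth, "sm_trace")) ground_truth$ground_truth else ground_truth
  if (!is.null(gt$channels) && gt$channels != 2L)
    stop("Atlas categories apply to two-color traces", call. = FALSE)
  s <- gt$n_states
  if (s > 3L)
    stop(sprintf("%d-state trace is outside the Atlas grammar (1-3 states)", s),
         call. = FALSE)
  letters_ <- fret_level_letter(gt$state_fret_values)
  if (anyDuplicated(letters_))
    stop("two states share a FRET level; trace is outside the Atlas grammar",
         call. = FALSE)
  lv <- paste(LEVEL_LETTERS[sort(match(letters_, LEVEL_LETTERS))], collapse = "")
  snr_class <- if (gt$snr >= 4) "c" else "n"
  if (s == 1L) return(paste(s, snr_class, lv, sep = "-"))
  rate_class <- if (gt$mean_transition_rate >= 0.05) "f" else "s"
  paste(s, snr_class, lv, rate_class, sep = "-")
}

# ranges used when simulating a trace conditioned on a category;
# level/rate/SNR windows sit safely inside the categorization thresholds
CATEGORY_RANGES <- list(
  fret = list(l = c(0.05, 0.30), m = c(0.40, 0.60), h = c(0.70, 0.95)),
  rate = list(s = c(0.005, 0.04), f = c(0.05, 0.30)),
  snr = list(c = c(4, 6), n = c(1.8, 3.9)))

#' Sample a kinetic model conditioned on an Atlas category
#'
#' FRET values are drawn inside the letter's window; the transition
#' matrix is symmetric with a stay probability matching a mean rate drawn
#' from the rate class; SNR is returned as a target range for the noise
#' stage.
#'
#' @param label category label from [enumerate_categories()].
#' @param cfg a [sim_config()] (for the intensity range).
#' @return List with `model` (a [kinetic_model()]) and `snr_range`.
#' @export
sample_category_model <- function(label, cfg = sim_config()) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  s <- as.integer(parts[1])
  letters_ <- strsplit(parts[3], "")[[1]]
  stopifnot(s == length(letters_))
  fret <- vapply(letters_, function(ch) {
    rg <- CATEGORY_RANGES$fret[[ch]]
    runif(1, rg[1], rg[2])
  }, 0)
  i_max <- runif(1, cfg$i_max_range[1], cfg$i_max_range[2])
  if (s == 1L) {
    P <- matrix(1, 1, 1)
    p_init <- 1
  } else {
    rr <- CATEGORY_RANGES$rate[[parts[4]]]
    r <- runif(1, rr[1], rr[2])
    P <- matrix(r / (s - 1), s, s)
    diag(P) <- 1 - r
    p_init <- rep(1 / s, s)
  }
  model <- kinetic_model(p_init, P, fret, i_max)
  list(model = model, snr_range = CATEGORY_RANGES$snr[[parts[2]]])
}

# simulate one trace of a category; photobleaching lifetimes are kept
# long so the category's kinetic identity dominates the trace
simulate_category_trace <- function(label, cfg = sim_config()) {
  cm <- sample_category_model(label, cfg)
  cfg$snr_range <- cm$snr_range
  cfg$tau_bleach_range <- c(max(500, cfg$tau_bleach_range[1]),
                            max(2000, cfg$tau_bleach_range[2]))
  simulate_two_color_trace(cfg, model = cm$model, condition = label)
}

## ---- 2-D Gaussian mixture -------------------------------------------------

gauss2_density <- function(X, mu, sigma) {
  d <- sweep(X, 2, mu)
  inv <- solve(sigma)
  q <- rowSums((d %*% inv) * d)
  exp(-q / 2) / (2 * pi * sqrt(det(sigma)))
}

fit_gmm2d <- function(X, k = 4L, max_iter = 200L, tol = 1e-8, ridge = 1e-6) {
  X <- as.matrix(X)
  if (nrow(X) < 2 * k || min(apply(X, 2, stats::var)) < 1e-12)
    stop("GMM fit error: degenerate projection (near-zero variance)", call. = FALSE)
  km <- kmeans(X, centers = k, nstart = 5, iter.max = 50)
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / nrow(X)
  w <- pmax(w, 1e-6); w <- w / sum(w)
  mu <- km$centers
  sigma <- lapply(seq_len(k), function(j) {
    pts <- X[km$cluster == j, , drop = FALSE]
    if (nrow(pts) > 2) stats::cov(pts) + diag(ridge, 2) else diag(stats::var(as.numeric(X)), 2)
  })
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * gauss2_density(X, mu[j, ], sigma[[j]]),
                   numeric(nrow(X)))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    R <- dens / tot
    nk <- colSums(R)
    w <- nk / nrow(X)
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(R[, j] * X) / nk[j]
      d <- sweep(X, 2, mu[j, ])
      sigma[[j]] <- crossprod(d * sqrt(R[, j] / nk[j]), d * sqrt(R[, j] / nk[j])) +
        diag(ridge, 2)
    }
    if (abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sigma = sigma, loglik = ll)
}

gmm_density <- function(gmm, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) return(numeric(0))
  dens <- numeric(nrow(X))
  for (j in seq_along(gmm$w))
    dens <- dens + gmm$w[j] * gauss2_density(X, gmm$mu[j, ], gmm$sigma[[j]])
  dens
}

gmm_contours <- function(gmm, level = 1e-2, grid_n = 151L, expand = 0.15) {
  rx <- range(gmm$mu[, 1]) + c(-1, 1) * (3 * sqrt(max(vapply(gmm$sigma, function(s) s[1, 1], 0))))
  ry <- range(gmm$mu[, 2]) + c(-1, 1) * (3 * sqrt(max(vapply(gmm$sigma, function(s) s[2, 2], 0))))
  gx <- seq(rx[1], rx[2], length.out = grid_n)
  gy <- seq(ry[1], ry[2], length.out = grid_n)
  Z <- matrix(gmm_density(gmm, as.matrix(expand.grid(gx, gy))), grid_n, grid_n)
  grDevices::contourLines(gx, gy, Z, levels = level)
}

## ---- reducer --------------------------------------------------------------

fit_reducer <- function(z0, kind = "pca") {
  if (kind != "pca")
    stop("only the PCA reducer is available in this build; ",
         "requested kind is recorded as a fallback", call. = FALSE)
  pc <- prcomp(z0, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  sds <- apply(scores, 2, sd)
  sds[sds < 1e-12] <- 1
  list(kind = "pca", requested = kind, center = pc$center,
       rotation = pc$rotation[, 1:2, drop = FALSE], scale = sds)
}

reducer_transform <- function(reducer, z0) {
  if (nrow(z0) == 0) return(matrix(numeric(0), 0, 2))
  sweep(sweep(z0, 2, reducer$center) %*% reducer$rotation, 2, reducer$scale, `/`)
}

## ---- atlas ----------------------------------------------------------------

#' Build the smFRET Atlas
#'
#' Simulates a balanced per-category corpus, embeds it with the encoder,
#' fits an unsupervised 2-D reducer on the (whitened) trace-level
#' embeddings, and annotates each category with a 4-component 2-D
#' Gaussian mixture whose density contour at `contour_level` (default
#' 1e-2) approximates the category boundary. Deterministic given `seed`.
#' The reducer is PCA with whitened axes (a documented fallback for the
#' reference reducer, recorded in `reducer$kind`).
#'
#' @param weights,cfg encoder weights and [model_config()].
#' @param sim_cfg a [sim_config()] for the corpus (its `n_frames` must be
#'   compatible with the encoder).
#' @param n_per_category annotation traces per category (reference scale
#'   1,000; scale down for desk runs).
#' @param seed integer seed.
#' @param contour_level probability density at which contours are drawn.
#' @param categories category subset (default: all 22).
#' @return List of class `smfret_atlas`: `reducer`, `categories`, `gmms`,
#'   `contours`, `coords`, `category_of`, `fingerprint`,
#'   `n_per_category`, `seed`.
#' @export
build_atlas <- function(weights, cfg, sim_cfg = sim_config(),
                        n_per_category = 1000L, seed = 1L,
                        contour_level = 1e-2, categories = enumerate_categories()) {
  set.seed(seed)
  traces <- list(); cat_of <- character(0)
  for (lab in categories) {
    for (i in seq_len(n_per_category)) {
      traces[[length(traces) + 1L]] <- simulate_category_trace(lab, sim_cfg)
      cat_of <- c(cat_of, lab)
    }
  }
  emb <- embed_traces(traces, weights, cfg, frames = FALSE)
  reducer <- fit_reducer(emb$z0, "pca")
  coords <- reducer_transform(reducer, emb$z0)
  gmms <- lapply(categories, function(lab)
    fit_gmm2d(coords[cat_of == lab, , drop = FALSE], k = 4L))
  names(gmms) <- categories
  contours <- lapply(gmms, gmm_contours, level = contour_level)
  atlas <- list(reducer = reducer, categories = categories, gmms = gmms,
                contours = contours, coords = coords, category_of = cat_of,
                fingerprint = emb$fingerprint, n_per_category = n_per_category,
                contour_level = contour_level, seed = as.integer(seed))
  class(atlas) <- "smfret_atlas"
  atlas
}

#' Project new traces into a fitted Atlas
#'
#' Applies the frozen reducer transform to embeddings from the same
#' encoder checkpoint (enforced by fingerprint) and reports the fitted
#' density of every category at each point.
#'
#' @param traces new traces (may be empty).
#' @param atlas an `smfret_atlas`.
#' @param weights,cfg encoder weights and [model_config()]; must match
#'   the checkpoint the atlas was built with.
#' @return List with `coords` (n x 2), `density` (n x categories) and
#'   `nearest_category` (argmax density per point).
#' @export
project_into_atlas <- function(traces, atlas, weights, cfg) {
  if (config_hash(weights) != atlas$fingerprint)
    stop("mismatched encoder fingerprint: embeddings are not comparable with this atlas",
         call. = FALSE)
  mats <- as_trace_matrices(traces)
  if (length(mats) == 0) {
    return(list(coords = matrix(numeric(0), 0, 2),
                density = matrix(numeric(0), 0, length(atlas$categories),
                                 dimnames = list(NULL, atlas$categories)),
                nearest_category = character(0)))
  }
  emb <- embed_traces(traces, weights, cfg, frames = FALSE)
  coords <- reducer_transform(atlas$reducer, emb$z0)
  dens <- vapply(atlas$categories, function(lab) gmm_density(atlas$gmms[[lab]], coords),
                 numeric(nrow(coords)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = 1)
  colnames(dens) <- atlas$categories
  list(coords = coords, density = dens,
       nearest_category = atlas$categories[max.col(dens, ties.method = "first")])
}
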