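#' Kinetic model of a fluorescent molecule
#'
#' A discrete-time Markov model over emission states. For two-color traces
#' `state_fret` holds the FRET efficiency of each state; for one-color
#' traces it is interpreted as a relative intensity level.
#'
#' @param p_init initial state probability vector (sums to 1).
#' @param p_transfer row-stochastic per-frame transition matrix.
#' @param state_fret per-state FRET efficiency (or relative intensity) in
#'   [0, 1], pairwise distinct.
#' @param i_max total emission intensity, arbitrary units.
#' @return A list of class `kinetic_model`.
#' @export
kinetic_model <- function(p_init, p_transfer, state_fret, i_max) {
  n <- length(p_init)
  p_transfer <- as.matrix(p_transfer)
  stopifnot(n >= 1, nrow(p_transfer) == n, ncol(p_transfer) == n,
            length(state_fret) == n, i_max > 0)
  if (abs(sum(p_init) - 1) > 1e-8)
    stop("p_init must sum to 1", call. = FALSE)
  if (any(abs(rowSums(p_transfer) - 1) > 1e-8))
    stop("every row of p_transfer must sum to 1", call. = FALSE)
  if (any(state_fret < 0 | state_fret > 1))
    stop("state_fret values must lie in [0, 1]", call. = FALSE)
  if (n > 1 && min(dist(state_fret)) <= 0)
    stop("state_fret values must be pairwise distinct", call. = FALSE)
  m <- list(n_states = n, p_init = as.numeric(p_init), p_transfer = p_transfer,
            state_fret = as.numeric(state_fret), i_max = i_max)
  class(m) <- "kinetic_model"
  m
}

# FRET values uniform on [0,1] subject to a minimum pairwise separation,
# by rejection; separation 0.1 guarantees acceptance is fast for n <= 4.
sample_separated_fret <- function(n, min_sep) {
  repeat {
    v <- runif(n)
    if (n == 1L || min(dist(v)) >= min_sep) return(v)
  }
}

#' Sample a random kinetic model
#'
#' The state count is uniform on `cfg$n_states_range` (default 1--4); the
#' initial distribution and each transition-matrix row are independent
#' uniform draws normalized to sum 1; total intensity is uniform on
#' `cfg$i_max_range`; state FRET values are uniform on [0, 1] with a
#' minimum pairwise separation.
#'
#' @param cfg a [sim_config()].
#' @return A [kinetic_model()].
#' @export
sample_kinetic_model <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- sample.int(cfg$n_states_range[2] - cfg$n_states_range[1] + 1L, 1L) +
    cfg$n_states_range[1] - 1L
  p_init <- runif(n)
  p_init <- p_init / sum(p_init)
  P <- matrix(runif(n * n), n, n)
  P <- P / rowSums(P)
  fret <- sample_separated_fret(n, cfg$fret_min_separation)
  i_max <- runif(1, cfg$i_max_range[1], cfg$i_max_range[2])
  # canonical state order: ascending FRET, so state indices are a
  # well-defined function of the trace (state 1 = lowest FRET level)
  ord <- order(fret)
  kinetic_model(p_init[ord], P[ord, ord, drop = FALSE], fret[ord], i_max)
}

#' Two-state kinetic model with specified rates
#'
#' Convenience constructor for parameter-recovery studies: state 1 (low
#' FRET) leaves at per-frame probability `k12`, state 2 at `k21`.
#'
#' @param k12,k21 per-frame transition probabilities in (0, 1).
#' @param fret length-2 FRET values, low state first.
#' @param i_max total intensity.
#' @param p_init initial distribution (default stationary).
#' @return A [kinetic_model()].
#' @export
two_state_model <- function(k12, k21, fret = c(0.25, 0.75), i_max = 500,
                            p_init = NULL) {
  stopifnot(k12 > 0, k12 < 1, k21 > 0, k21 < 1, length(fret) == 2)
  P <- matrix(c(1 - k12, k12, k21, 1 - k21), 2, 2, byrow = TRUE)
  if (is.null(p_init)) p_init <- c(k21, k12) / (k12 + k21)
  kinetic_model(p_init, P, fret, i_max)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the row-stochastic matrix for eigenvalue 1,
#' normalized to a probability vector.
#'
#' @param P row-stochastic matrix.
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(P) {
  n <- nrow(P)
  if (n == 1L) return(1)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Mean per-frame transition rate of a kinetic model
#'
#' Expected per-frame probability of leaving the current state, averaged
#' over the stationary distribution of the transition matrix. This is the
#' quantity the Atlas thresholds as "fast" (>= 0.05 per frame) vs "slow".
#'
#' @param model a [kinetic_model()].
#' @return Scalar rate in frame^-1.
#' @export
mean_transition_rate <- function(model) {
  if (model$n_states == 1L) return(0)
  pi_s <- stationary_distribution(model$p_transfer)
  sum(pi_s * (1 - diag(model$p_transfer)))
}

#' Simulate a Markov state path
#'
#' `state_path[1]` is drawn from `p_init`; each subsequent frame from the
#' transition-matrix row of the current state.
#'
#' @param model a [kinetic_model()].
#' @param n_frames number of frames T (>= 1).
#' @return Integer vector of length T with state indices in 1..n_states.
#' @export
simulate_state_path <- function(model, n_frames) {
  stopifnot(inherits(model, "kinetic_model"), n_frames >= 1)
  n <- model$n_states
  if (n == 1L) return(rep(1L, n_frames))
  cum <- t(apply(model$p_transfer, 1, cumsum))
  u <- runif(n_frames)
  path <- integer(n_frames)
  s <- which(u[1] <= cumsum(model$p_init))[1]
  path[1] <- s
  if (n_frames > 1) {
    for (t in 2:n_frames) {
      row <- cum[s, ]
      s <- 1L
      while (u[t] > row[s]) s <- s + 1L
      path[t] <- s
    }
  }
  path
}
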