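#' Render the noiseless two-color trace of a state path
#'
#' The acceptor channel carries `i_max * state_fret[s(t)]` and the donor
#' the remainder, so the two channels sum to `i_max` at every frame.
#'
#' @param model a [kinetic_model()].
#' @param state_path integer state indices (from [simulate_state_path()]).
#' @return T x 2 matrix with columns `donor`, `acceptor`.
#' @export
render_ideal_trace <- function(model, state_path) {
  stopifnot(all(state_path >= 1), all(state_path <= model$n_states))
  acc <- model$i_max * model$state_fret[state_path]
  out <- cbind(donor = model$i_max - acc, acceptor = acc)
  out
}

# Sample alternating on/off (emitting/dark) segments covering [0, t_end].
# Returns a matrix of dark intervals (start, end) in continuous frame time.
sample_blink_intervals <- function(t_end, tau_on, tau_off) {
  if (t_end <= 0) return(matrix(numeric(0), 0, 2))
  starts <- numeric(0); ends <- numeric(0)
  t <- 0
  while (t < t_end) {
    t <- t + rexp(1, 1 / tau_on)
    if (t >= t_end) break
    off <- rexp(1, 1 / tau_off)
    starts <- c(starts, t); ends <- c(ends, min(t + off, t_end))
    t <- t + off
  }
  cbind(starts, ends)
}

#' Apply photophysics to a noiseless two-color trace
#'
#' Photobleaching: each channel's bleach time is exponential with an
#' expected lifetime drawn uniform from `cfg$tau_bleach_range`. After
#' acceptor bleach, emission is redirected to the donor channel (donor
#' reads `i_max`); after donor bleach both channels drop to zero. Donor
#' blinking: alternating emitting/dark segments with exponential durations
#' (expected lifetimes drawn uniform from `cfg$tau_nonblink_range` /
#' `cfg$tau_blink_range`); both channels are dark during a blink. The
#' acceptor channel is scaled by a relative brightness factor drawn
#' uniform from `cfg$acceptor_brightness_range`.
#'
#' @param ideal T x 2 noiseless intensities from [render_ideal_trace()].
#' @param cfg a [sim_config()].
#' @param i_max total emission intensity of the trace.
#' @return List with `intensities` (T x 2) and `photo`, a list recording
#'   bleach frames (first dark frame per channel, `Inf` if none within T),
#'   bleach-step counts, blink-event count, per-frame emitting-channel
#'   count and the dark-frame mask.
#' @export
apply_photophysics <- function(ideal, cfg, i_max) {
  T_ <- nrow(ideal)
  tau_d <- runif(1, cfg$tau_bleach_range[1], cfg$tau_bleach_range[2])
  tau_a <- runif(1, cfg$tau_bleach_range[1], cfg$tau_bleach_range[2])
  t_bleach_d <- rexp(1, 1 / tau_d)
  t_bleach_a <- rexp(1, 1 / tau_a)
  bf_d <- if (t_bleach_d < T_) floor(t_bleach_d) + 1 else Inf
  bf_a <- if (t_bleach_a < T_) floor(t_bleach_a) + 1 else Inf
  brightness <- runif(1, cfg$acceptor_brightness_range[1],
                      cfg$acceptor_brightness_range[2])

  tau_on <- runif(1, cfg$tau_nonblink_range[1], cfg$tau_nonblink_range[2])
  tau_off <- runif(1, cfg$tau_blink_range[1], cfg$tau_blink_range[2])
  dark <- sample_blink_intervals(min(T_, if (is.finite(bf_d)) bf_d - 1 else T_),
                                 tau_on, tau_off)
  mid <- seq_len(T_) - 0.5
  blink_mask <- rep(FALSE, T_)
  blink_events <- 0L
  if (nrow(dark) > 0) {
    for (j in seq_len(nrow(dark))) {
      hit <- mid >= dark[j, 1] & mid < dark[j, 2]
      if (any(hit)) blink_events <- blink_events + 1L
      blink_mask <- blink_mask | hit
    }
  }

  t_idx <- seq_len(T_)
  donor <- ideal[, 1]
  acceptor <- ideal[, 2] * brightness
  after_a <- t_idx >= bf_a
  donor[after_a] <- i_max
  acceptor[after_a] <- 0
  after_d <- t_idx >= bf_d
  donor[after_d] <- 0
  acceptor[after_d] <- 0
  donor[blink_mask] <- 0
  acceptor[blink_mask] <- 0

  emitting <- rep(2L, T_)
  emitting[after_a] <- 1L
  emitting[after_d] <- 0L
  emitting[blink_mask] <- 0L

  list(intensities = cbind(donor = donor, acceptor = acceptor),
       photo = list(bleach_frame = c(donor = bf_d, acceptor = bf_a),
                    n_bleach_steps = c(donor = as.integer(is.finite(bf_d)),
                                       acceptor = as.integer(is.finite(bf_a))),
                    bleach_taus = c(donor = tau_d, acceptor = tau_a),
                    brightness = brightness,
                    blink_events = as.integer(blink_events),
                    blink_mask = blink_mask,
                    emitting_count = emitting))
}

#' Add Gaussian noise and a constant background offset
#'
#' A target SNR is drawn uniform from `cfg$snr_range`; i.i.d. Gaussian
#' noise with `sigma = i_max / SNR` (shared across channels) and a
#' constant offset uniform on `cfg$offset_fraction_range * i_max` are
#' added to every active channel.
#'
#' @param clean T x 2 intensities.
#' @param cfg a [sim_config()].
#' @param i_max total emission intensity.
#' @param channels 1 or 2; with 1 channel the second column stays exactly 0.
#' @return List with `intensities`, `snr`, `sigma`, `offset`.
#' @export
add_noise <- function(clean, cfg, i_max, channels = 2L) {
  if (cfg$snr_range[1] <= 0)
    stop("configuration error: snr_range must exclude 0", call. = FALSE)
  T_ <- nrow(clean)
  snr <- runif(1, cfg$snr_range[1], cfg$snr_range[2])
  sigma <- i_max / snr
  offset <- runif(1, cfg$offset_fraction_range[1],
                  cfg$offset_fraction_range[2]) * i_max
  out <- clean
  out[, 1] <- out[, 1] + rnorm(T_, 0, sigma) + offset
  if (channels == 2L) {
    out[, 2] <- out[, 2] + rnorm(T_, 0, sigma) + offset
  } else {
    out[, 2] <- 0
  }
  list(intensities = out, snr = snr, sigma = sigma, offset = offset)
}

new_ground_truth <- function(...) {
  gt <- list(...)
  class(gt) <- "ground_truth"
  gt
}

new_trace <- function(intensities, channels, frame_period, condition = NA_character_,
                      ground_truth = NULL) {
  tr <- list(intensities = intensities, channels = as.integer(channels),
             frame_period = frame_period, condition = condition,
             ground_truth = ground_truth)
  class(tr) <- "sm_trace"
  tr
}

#' Simulate one two-color trace
#'
#' Full pipeline: kinetic-model sampling (unless `model` is given), Markov
#' state path, noiseless rendering, photophysics, Gaussian noise.
#'
#' @param cfg a [sim_config()].
#' @param model optional fixed [kinetic_model()]; sampled if `NULL`.
#' @param condition optional experiment-condition tag.
#' @return An `sm_trace` with complete ground truth.
#' @export
simulate_two_color_trace <- function(cfg = sim_config(), model = NULL,
                                     condition = NA_character_) {
  if (is.null(model)) model <- sample_kinetic_model(cfg)
  T_ <- cfg$n_frames
  path <- simulate_state_path(model, T_)
  ideal <- render_ideal_trace(model, path)
  ph <- apply_photophysics(ideal, cfg, model$i_max)
  nz <- add_noise(ph$intensities, cfg, model$i_max, channels = 2L)

  first_bleach <- min(ph$photo$bleach_frame)
  active <- seq_len(T_) < first_bleach
  ideal_fret <- model$state_fret[path]
  if (is.finite(first_bleach)) ideal_fret[seq_len(T_) >= first_bleach] <- 0

  gt <- new_ground_truth(
    state_path = path, ideal_fret = ideal_fret, active_mask = active,
    n_states = model$n_states, snr = nz$snr,
    mean_transition_rate = mean_transition_rate(model),
    bleach_frame = ph$photo$bleach_frame,
    n_bleach_steps = ph$photo$n_bleach_steps,
    blink_events = ph$photo$blink_events,
    emitting_count = ph$photo$emitting_count,
    state_fret_values = model$state_fret,
    channels = 2L, n_fluors = 1L,
    i_max = model$i_max, sigma = nz$sigma, offset = nz$offset,
    bleach_taus = ph$photo$bleach_taus)
  new_trace(nz$intensities, 2L, cfg$frame_period, condition, gt)
}

#' Simulate one one-color trace
#'
#' One-color traces are intensity-level processes in a single channel
#' (the second channel is zero-filled). With one fluorophore the intensity
#' follows a Markov chain over relative levels with a photobleaching step;
#' with `n_fluors > 1` the trace is a photobleaching staircase of equal
#' per-fluorophore intensities with independent exponential bleach times.
#'
#' @param cfg a [sim_config()].
#' @param n_fluors fluorophore count; sampled uniform from
#'   `cfg$n_fluor_range` if `NULL`.
#' @param condition optional experiment-condition tag.
#' @return An `sm_trace` with complete ground truth.
#' @export
simulate_one_color_trace <- function(cfg = sim_config(), n_fluors = NULL,
                                     condition = NA_character_) {
  T_ <- cfg$n_frames
  if (is.null(n_fluors)) {
    n_fluors <- sample.int(cfg$n_fluor_range[2] - cfg$n_fluor_range[1] + 1L, 1L) +
      cfg$n_fluor_range[1] - 1L
  }
  tau <- runif(1, cfg$tau_bleach_range[1], cfg$tau_bleach_range[2])
  i_max <- runif(1, cfg$i_max_range[1], cfg$i_max_range[2])
  if (n_fluors == 1L) {
    model <- sample_kinetic_model(cfg)
    model$i_max <- i_max
    path <- simulate_state_path(model, T_)
    clean <- i_max * model$state_fret[path]
    rate <- mean_transition_rate(model)
    n_states <- model$n_states
    fret_vals <- model$state_fret
    bleach_times <- rexp(1, 1 / tau)
  } else {
    path <- rep(1L, T_)
    rate <- 0
    n_states <- 1L
    fret_vals <- 1
    bleach_times <- rexp(n_fluors, 1 / tau)
    clean <- rep(i_max, T_)
  }
  bleach_frames <- ifelse(bleach_times < T_, floor(bleach_times) + 1, Inf)
  t_idx <- seq_len(T_)
  alive <- vapply(t_idx, function(t) sum(t < bleach_frames), 0L)
  if (n_fluors == 1L) {
    dead <- which(alive == 0L)
    if (length(dead) > 0) {
      clean[dead] <- 0
      path[dead] <- if (dead[1] > 1L) path[dead[1] - 1L] else path[1]
    }
  } else {
    clean <- (i_max / n_fluors) * alive
  }
  nz <- add_noise(cbind(donor = clean, acceptor = 0), cfg, i_max, channels = 1L)
  n_steps <- sum(is.finite(bleach_frames))
  first_bleach <- min(bleach_frames)
  gt <- new_ground_truth(
    state_path = path, ideal_fret = rep(0, T_),
    active_mask = t_idx < first_bleach,
    n_states = n_states, snr = nz$snr, mean_transition_rate = rate,
    bleach_frame = c(donor = first_bleach, acceptor = NA_real_),
    n_bleach_steps = c(donor = as.integer(n_steps), acceptor = 0L),
    blink_events = 0L, emitting_count = as.integer(alive),
    state_fret_values = fret_vals, channels = 1L,
    n_fluors = as.integer(n_fluors),
    i_max = i_max, sigma = nz$sigma, offset = nz$offset,
    bleach_taus = c(donor = tau, acceptor = NA_real_))
  new_trace(nz$intensities, 1L, cfg$frame_period, condition, gt)
}

#' Generate a labeled synthetic dataset
#'
#' Deterministic given `seed`. A configurable fraction of traces is
#' one-color (zero-filled second channel); every trace carries complete
#' ground truth for all training tasks.
#'
#' @param n number of traces (>= 1).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param conditions optional per-trace condition tags (recycled).
#' @param category_fraction fraction of two-color traces drawn from the
#'   Atlas category-conditioned sampler (cycling over all categories)
#'   instead of the fully random kinetic-model sampler. The default 0
#'   reproduces the plain recipe; a positive value broadens kinetic
#'   diversity (well-separated slow/fast behaviors) in pre-training
#'   corpora.
#' @return A `trace_set`: list with `traces`, `config`, `seed`.
#' @export
generate_dataset <- function(n, cfg = sim_config(), seed = 1L, conditions = NULL,
                             category_fraction = 0) {
  stopifnot(n >= 1)
  set.seed(seed)
  if (!is.null(conditions)) conditions <- rep_len(conditions, n)
  cats <- enumerate_categories()
  cat_i <- 0L
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    cond <- if (is.null(conditions)) NA_character_ else conditions[i]
    one_color <- runif(1) < cfg$one_color_fraction
    traces[[i]] <- if (one_color) {
      simulate_one_color_trace(cfg, condition = cond)
    } else if (runif(1) < category_fraction) {
      cat_i <- cat_i %% length(cats) + 1L
      tr <- simulate_category_trace(cats[cat_i], cfg)
      tr$condition <- cond
      tr
    } else {
      simulate_two_color_trace(cfg, condition = cond)
    }
  }
  ts <- list(traces = traces, config = cfg, seed = as.integer(seed))
  class(ts) <- "trace_set"
  ts
}

#' @export
print.trace_set <- function(x, ...) {
  n <- length(x$traces)
  nc <- vapply(x$traces, function(t) t$channels, 0L)
  cat(sprintf("trace_set: %d traces (%d two-color, %d one-color), T = %d frames\n",
              n, sum(nc == 2L), sum(nc == 1L), x$config$n_frames))
  invisible(x)
}

#' @export
print.sm_trace <- function(x, ...) {
  cat(sprintf("sm_trace: %d frames, %d channel(s)%s\n", nrow(x$intensities),
              x$channels,
              if (!is.null(x$ground_truth))
                sprintf(", n_states = %d, SNR = %.2f", x$ground_truth$n_states,
                        x$ground_truth$snr) else ""))
  invisible(x)
}
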