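#' @importFrom stats rnorm runif rexp setNames prcomp kmeans dnorm quantile sd
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

check_interval <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
      x[1] > x[2] || x[1] < lower || x[2] > upper) {
    stop(sprintf("configuration error: '%s' must be an ordered interval within [%g, %g]",
                 name, lower, upper), call. = FALSE)
  }
  invisible(x)
}

#' Simulator configuration
#'
#' Collects every range the stochastic trace generator samples from.
#' Defaults follow the stated training-data recipe where one exists
#' (photobleaching lifetime expectation uniform on 1--2000 frames, target
#' SNR uniform on (1.8, 6), relative acceptor brightness uniform on
#' 0.9--1.0, state count uniform on 1--4); the remaining ranges (total
#' intensity, offset, blinking lifetimes) are documented package choices.
#'
#' @param n_frames trace length T in frames; must be a positive multiple of
#'   the encoder patch width when traces are fed to the model.
#' @param frame_period seconds per frame (metadata only).
#' @param n_states_range integer range for the number of emission states.
#' @param i_max_range range of the total emission intensity, arbitrary units.
#' @param fret_min_separation minimum pairwise distance between sampled
#'   state FRET values, keeping "distinct states" resolvable.
#' @param tau_bleach_range range (frames) of the expected photobleaching
#'   lifetime, sampled per channel.
#' @param tau_blink_range range (frames) of the expected dark (blink-off)
#'   lifetime of the donor dye.
#' @param tau_nonblink_range range (frames) of the expected emitting
#'   (blink-on) lifetime of the donor dye.
#' @param acceptor_brightness_range relative acceptor brightness range,
#'   a subset of [0, 1].
#' @param snr_range target signal-to-noise ratio range; SNR is defined as
#'   I_max / sigma_noise with a shared per-channel Gaussian sigma.
#' @param offset_fraction_range constant background offset, expressed as a
#'   fraction of I_max.
#' @param one_color_fraction fraction of generated traces that are
#'   one-color (second channel zero-filled).
#' @param n_fluor_range integer range of fluorophore count for one-color
#'   traces (photobleaching staircases).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_frames = 2000L,
                       frame_period = 0.1,
                       n_states_range = c(1L, 4L),
                       i_max_range = c(100, 1000),
                       fret_min_separation = 0.1,
                       tau_bleach_range = c(1, 2000),
                       tau_blink_range = c(1, 20),
                       tau_nonblink_range = c(200, 2000),
                       acceptor_brightness_range = c(0.9, 1.0),
                       snr_range = c(1.8, 6),
                       offset_fraction_range = c(0, 0.2),
                       one_color_fraction = 0.25,
                       n_fluor_range = c(1L, 4L)) {
  if (n_frames < 1) stop("configuration error: n_frames must be >= 1", call. = FALSE)
  check_interval(n_states_range, "n_states_range", 1, 4)
  check_interval(i_max_range, "i_max_range", lower = 0)
  check_interval(tau_bleach_range, "tau_bleach_range", lower = 0)
  check_interval(tau_blink_range, "tau_blink_range", lower = 0)
  check_interval(tau_nonblink_range, "tau_nonblink_range", lower = 0)
  check_interval(acceptor_brightness_range, "acceptor_brightness_range", 0, 1)
  check_interval(snr_range, "snr_range")
  if (snr_range[1] <= 0) stop("configuration error: snr_range must exclude 0", call. = FALSE)
  check_interval(offset_fraction_range, "offset_fraction_range", lower = 0)
  stopifnot(one_color_fraction >= 0, one_color_fraction <= 1)
  cfg <- list(n_frames = as.integer(n_frames), frame_period = frame_period,
              n_states_range = as.integer(n_states_range),
              i_max_range = i_max_range,
              fret_min_separation = fret_min_separation,
              tau_bleach_range = tau_bleach_range,
              tau_blink_range = tau_blink_range,
              tau_nonblink_range = tau_nonblink_range,
              acceptor_brightness_range = acceptor_brightness_range,
              snr_range = snr_range,
              offset_fraction_range = offset_fraction_range,
              one_color_fraction = one_color_fraction,
              n_fluor_range = as.integer(n_fluor_range))
  class(cfg) <- "sim_config"
  cfg
}

#' Encoder architecture configuration
#'
#' @param patch_width W, frames per token.
#' @param embed_dim D, embedding width; must be divisible by `n_heads`.
#' @param n_layers N, number of attention layers.
#' @param n_heads attention heads per layer.
#' @param ffn_multiplier hidden width of the position-wise feed-forward
#'   network as a multiple of D.
#' @param activation feed-forward activation, currently `"gelu"`.
#' @param max_tokens maximum token-sequence length (including the trace
#'   token) the position embedding is allocated for.
#' @return A list of class `model_config`.
#' @export
model_config <- function(patch_width = 50L, embed_dim = 96L, n_layers = 4L,
                         n_heads = 4L, ffn_multiplier = 4L,
                         activation = "gelu", max_tokens = 41L) {
  if (embed_dim %% n_heads != 0)
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  if (patch_width < 1) stop("patch_width must be >= 1", call. = FALSE)
  if (!identical(activation, "gelu"))
    stop("unsupported activation: ", activation, call. = FALSE)
  cfg <- list(patch_width = as.integer(patch_width),
              embed_dim = as.integer(embed_dim),
              n_layers = as.integer(n_layers),
              n_heads = as.integer(n_heads),
              ffn_multiplier = as.integer(ffn_multiplier),
              activation = activation,
              max_tokens = as.integer(max_tokens))
  class(cfg) <- "model_config"
  cfg
}

#' Run configuration bundling seeds and component configs
#'
#' Every stochastic stage reads its seed from here; the config (and its
#' hash) is serialized alongside artifacts so two runs with equal hashes
#' are byte-reproducible.
#'
#' @param seed_simulator,seed_model,seed_training,seed_reducer integer seeds.
#' @param model a [model_config()].
#' @param simulator a [sim_config()].
#' @param paths named list of output paths.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed_simulator = 1L, seed_model = 2L,
                       seed_training = 3L, seed_reducer = 4L,
                       model = model_config(), simulator = sim_config(),
                       paths = list()) {
  rc <- list(seeds = list(simulator = as.integer(seed_simulator),
                          model = as.integer(seed_model),
                          training = as.integer(seed_training),
                          reducer = as.integer(seed_reducer)),
             model = model, simulator = simulator, paths = paths)
  class(rc) <- "run_config"
  rc
}

#' Stable hash of a configuration or weight set
#'
#' @param x any R object.
#' @return A character scalar hash.
#' @export
config_hash <- function(x) rlang::hash(x)
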