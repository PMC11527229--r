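## Plain-text trace container, per-trace CSV import, checkpoint
## serialization and projector export. The container is a directory of
## TSV matrices plus a JSON manifest; floating-point values are written
## with 17 significant digits so a write/read round trip is bit-exact.

CONTAINER_SCHEMA <- "tracefm-container-1"

fmt_matrix <- function(m) {
  apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
}

parse_matrix <- function(lines) {
  do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
}

#' Write traces to a plain-text container directory
#'
#' Layout: `manifest.json` (schema version, sizes, config hash),
#' `donor.tsv` / `acceptor.tsv` (one trace per row, 17-digit precision),
#' `meta.tsv` (per-trace channels, frame period, condition), optional
#' `labels/<name>.tsv` (one value per trace) and `frame_labels/<name>.tsv`
#' (one row per trace).
#'
#' @param traces a `trace_set` or list of `sm_trace` of equal length.
#' @param path container directory (created).
#' @param labels optional named list of per-trace label vectors.
#' @param frame_labels optional named list of N x T matrices.
#' @return `path`, invisibly.
#' @export
write_trace_container <- function(traces, path, labels = NULL, frame_labels = NULL) {
  ts <- if (inherits(traces, "trace_set")) traces else
    structure(list(traces = traces, config = NULL, seed = NA_integer_), class = "trace_set")
  n <- length(ts$traces)
  T_ <- nrow(ts$traces[[1]]$intensities)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  donor <- t(vapply(ts$traces, function(tr) tr$intensities[, 1], numeric(T_)))
  acceptor <- t(vapply(ts$traces, function(tr) tr$intensities[, 2], numeric(T_)))
  writeLines(fmt_matrix(donor), file.path(path, "donor.tsv"))
  writeLines(fmt_matrix(acceptor), file.path(path, "acceptor.tsv"))
  meta <- data.frame(
    trace_id = seq_len(n) - 1L,
    channels = vapply(ts$traces, function(tr) tr$channels, 0L),
    frame_period = vapply(ts$traces, function(tr) tr$frame_period, 0),
    condition = vapply(ts$traces, function(tr) as.character(tr$condition %||% NA), ""))
  data.table::fwrite(meta, file.path(path, "meta.tsv"), sep = "\t")
  manifest <- list(schema_version = CONTAINER_SCHEMA, n = n, n_frames = T_,
                   seed = ts$seed,
                   config_hash = if (!is.null(ts$config)) config_hash(ts$config) else NA,
                   labels = names(labels) %||% character(0),
                   frame_labels = names(frame_labels) %||% character(0))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(labels)) {
    dir.create(file.path(path, "labels"), showWarnings = FALSE)
    for (nm in names(labels)) {
      stopifnot(length(labels[[nm]]) == n)
      data.table::fwrite(data.frame(trace_id = seq_len(n) - 1L, value = labels[[nm]]),
                         file.path(path, "labels", paste0(nm, ".tsv")), sep = "\t")
    }
  }
  if (!is.null(frame_labels)) {
    dir.create(file.path(path, "frame_labels"), showWarnings = FALSE)
    for (nm in names(frame_labels)) {
      stopifnot(nrow(frame_labels[[nm]]) == n)
      writeLines(fmt_matrix(frame_labels[[nm]]),
                 file.path(path, "frame_labels", paste0(nm, ".tsv")))
    }
  }
  invisible(path)
}

#' Read a plain-text trace container
#'
#' @param path container directory from [write_trace_container()].
#' @return A `trace_set`; any labels are attached as attributes `labels`
#'   and `frame_labels`. One-color traces have the second channel exactly
#'   zero (enforced on read).
#' @export
read_trace_container <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop("not a trace container: missing manifest.json", call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(mf$schema_version, CONTAINER_SCHEMA))
    stop(sprintf("unknown container schema version '%s' (expected '%s')",
                 mf$schema_version, CONTAINER_SCHEMA), call. = FALSE)
  donor <- parse_matrix(readLines(file.path(path, "donor.tsv")))
  acceptor <- parse_matrix(readLines(file.path(path, "acceptor.tsv")))
  meta <- data.table::fread(file.path(path, "meta.tsv"), sep = "\t")
  n <- mf$n
  if (nrow(donor) != n || nrow(acceptor) != n)
    stop("corrupt container: intensity row count does not match manifest", call. = FALSE)
  traces <- lapply(seq_len(n), function(i) {
    ch <- meta$channels[i]
    acc <- if (ch == 1L) rep(0, ncol(acceptor)) else acceptor[i, ]
    new_trace(cbind(donor = donor[i, ], acceptor = acc), ch,
              meta$frame_period[i],
              if (is.na(meta$condition[i])) NA_character_ else meta$condition[i])
  })
  ts <- structure(list(traces = traces, config = NULL,
                       seed = mf$seed %||% NA_integer_), class = "trace_set")
  read_label_file <- function(nm, dir, frame = FALSE) {
    f <- file.path(path, dir, paste0(nm, ".tsv"))
    if (frame) {
      m <- parse_matrix(readLines(f))
      if (nrow(m) != n)
        stop(sprintf("malformed frame label dataset '%s': %d rows for %d traces",
                     nm, nrow(m), n), call. = FALSE)
      m
    } else {
      d <- data.table::fread(f, sep = "\t")
      if (nrow(d) != n)
        stop(sprintf("malformed label dataset '%s': %d values for %d traces",
                     nm, nrow(d), n), call. = FALSE)
      d$value
    }
  }
  if (length(mf$labels))
    attr(ts, "labels") <- setNames(lapply(mf$labels, read_label_file, dir = "labels"),
                                   mf$labels)
  if (length(mf$frame_labels))
    attr(ts, "frame_labels") <- setNames(
      lapply(mf$frame_labels, read_label_file, dir = "frame_labels", frame = TRUE),
      mf$frame_labels)
  ts
}

#' Import traces from per-trace CSV files
#'
#' Each file holds one trace with header `frame,donor[,acceptor]`; the
#' frame column must increase in unit steps. Files are ordered by name; a
#' missing acceptor column yields a one-color trace (zero-filled).
#'
#' @param directory directory containing `.csv` files.
#' @param frame_period seconds per frame recorded on the traces.
#' @return A `trace_set`.
#' @export
import_csv_traces <- function(directory, frame_period = 0.1) {
  files <- sort(list.files(directory, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no .csv files found in ", directory, call. = FALSE)
  traces <- lapply(files, function(f) {
    d <- data.table::fread(f)
    if (!all(c("frame", "donor") %in% names(d)))
      stop(sprintf("%s: header must contain 'frame' and 'donor'", basename(f)), call. = FALSE)
    if (nrow(d) > 1 && any(diff(d$frame) != 1))
      stop(sprintf("%s: frame column must increase in unit steps (gap or non-monotone)",
                   basename(f)), call. = FALSE)
    two <- "acceptor" %in% names(d)
    acc <- if (two) d$acceptor else rep(0, nrow(d))
    new_trace(cbind(donor = d$donor, acceptor = acc), if (two) 2L else 1L, frame_period)
  })
  structure(list(traces = traces, config = NULL, seed = NA_integer_),
            class = "trace_set")
}

## ---- checkpoints ----------------------------------------------------------

#' Save encoder weights to a JSON checkpoint
#'
#' One entry per named weight (flattened values plus dimensions), full
#' numeric precision, with the model configuration embedded.
#'
#' @param weights weight list from [init_weights()] or [pretrain()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(weights, path) {
  cfg <- attr(weights, "config")
  flat <- flatten_params(weights)
  # values are encoded as %.17g strings: exact double round-trip, which
  # JSON number formatting does not guarantee at the last ulp
  entries <- lapply(flat, function(v)
    list(dim = dim(v) %||% length(v), data = sprintf("%.17g", as.numeric(v))))
  obj <- list(format = "tracefm-checkpoint-1",
              config = unclass(cfg),
              fingerprint = config_hash(weights),
              weights = entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load encoder weights from a JSON checkpoint
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @return Weight list with the `model_config` reattached.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tracefm-checkpoint-1"))
    stop("unknown checkpoint format", call. = FALSE)
  wts <- list()
  for (nm in names(obj$weights)) {
    e <- obj$weights[[nm]]
    v <- as.numeric(e$data)
    if (length(e$dim) == 2) v <- matrix(v, e$dim[1], e$dim[2])
    keys <- strsplit(nm, ".", fixed = TRUE)[[1]]
    wts <- assign_nested(wts, keys, v)
  }
  cfgl <- obj$config
  cfg <- model_config(cfgl$patch_width, cfgl$embed_dim, cfgl$n_layers,
                      cfgl$n_heads, cfgl$ffn_multiplier, cfgl$activation,
                      cfgl$max_tokens)
  # restore positional list for layers (stored under numeric keys)
  if (!is.null(wts$layers)) wts$layers <- unname(wts$layers[order(as.integer(names(wts$layers)))])
  attr(wts, "config") <- cfg
  if (config_hash(wts) != obj$fingerprint)
    warning("checkpoint fingerprint mismatch after load")
  wts
}

assign_nested <- function(x, keys, value) {
  if (length(keys) == 1) {
    x[[keys]] <- value
    return(x)
  }
  x[[keys[1]]] <- assign_nested(x[[keys[1]]] %||% list(), keys[-1], value)
  x
}

## ---- projector export -----------------------------------------------------

#' Export a 2-D/3-D projection for external viewers
#'
#' Writes `points.tsv` (coordinates plus metadata columns, row count
#' equal to trace count) and `manifest.json` (encoder fingerprint,
#' reducer settings, seeds).
#'
#' @param points n x 2 or n x 3 coordinate matrix.
#' @param metadata data.frame with n rows (labels, conditions, entropy,
#'   category, ...).
#' @param path output directory.
#' @param fingerprint encoder fingerprint string.
#' @param reducer reducer settings list (kind, parameters).
#' @param seeds named list/vector of seeds used.
#' @return `path`, invisibly.
#' @export
export_projector <- function(points, metadata = NULL, path,
                             fingerprint = NA_character_, reducer = list(),
                             seeds = list()) {
  points <- as.matrix(points)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  colnames(points) <- paste0("dim", seq_len(ncol(points)))
  d <- as.data.frame(points)
  if (!is.null(metadata)) {
    stopifnot(nrow(metadata) == nrow(points))
    d <- cbind(d, metadata)
  }
  out_tsv <- file.path(path, "points.tsv")
  num <- vapply(d, is.double, TRUE)
  d[num] <- lapply(d[num], function(v) sprintf("%.17g", v))
  data.table::fwrite(d, out_tsv, sep = "\t")
  jsonlite::write_json(list(format = "tracefm-projector-1",
                            fingerprint = fingerprint, reducer = reducer,
                            seeds = seeds,
                            n = nrow(points), dims = ncol(points)),
                       file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a projector export
#'
#' @param path directory from [export_projector()].
#' @return List with `points` (numeric matrix), `metadata` (data.frame of
#'   the remaining columns) and `manifest`.
#' @export
read_projector_export <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"), simplifyVector = TRUE)
  d <- data.table::fread(file.path(path, "points.tsv"), sep = "\t", colClasses = "character")
  dims <- mf$dims
  pts <- as.matrix(d[, seq_len(dims), with = FALSE])
  pts <- matrix(as.numeric(pts), nrow(pts), dims,
                dimnames = list(NULL, colnames(pts)))
  meta <- if (ncol(d) > dims) as.data.frame(d[, -seq_len(dims), with = FALSE]) else NULL
  list(points = pts, metadata = meta, manifest = mf)
}
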