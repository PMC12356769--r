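#' Construct a video stack
#'
#' A `video_stack` wraps a 3-D intensity array indexed `(row, col, frame)`
#' together with its acquisition metadata. Intensities are arbitrary
#' nonnegative units; the frame interval is user-supplied metadata (default
#' 15 min, the usual NETosis time-lapse cadence) rather than parsed from TIFF
#' tags, which vary by vendor dialect.
#'
#' @param data Numeric array, dim `c(H, W, T)` with `T >= 2`, finite, `>= 0`.
#'   A `H x W x T` array or a list of `T` matrices is accepted.
#' @param frame_interval Minutes per frame, `> 0`.
#' @param channel_name Free-text channel label (e.g. `"sytox"`, `"dapi"`).
#' @param t0 Acquisition start in minutes (default 0).
#' @return An object of class `video_stack`.
#' @examples
#' vs <- video_stack(array(1, dim = c(4, 4, 3)), frame_interval = 15)
#' n_frames(vs)
#' @export
video_stack <- function(data, frame_interval = 15, channel_name = "", t0 = 0) {
  if (is.list(data)) data <- simplify2array(data)
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3) abort("data must be a (row, col, frame) array")
  if (dim(data)[3] < 2) abort("a video stack needs at least 2 frames")
  if (!all(is.finite(data))) abort("intensities must be finite")
  if (min(data) < 0) abort("intensities must be >= 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    abort("frame_interval must be > 0 minutes")
  }
  structure(
    list(data = data, frame_interval = frame_interval,
         channel_name = channel_name, t0 = t0),
    class = "video_stack"
  )
}

#' @rdname video_stack
#' @param x A `video_stack`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "video_stack"))
  dim(x$data)[3]
}

#' @rdname video_stack
#' @export
frame_times <- function(x) {
  stopifnot(inherits(x, "video_stack"))
  x$t0 + (seq_len(n_frames(x)) - 1) * x$frame_interval
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<video_stack> %dx%d px, %d frames @ %g min%s\n",
              d[1], d[2], d[3], x$frame_interval,
              if (nzchar(x$channel_name)) paste0(" [", x$channel_name, "]") else ""))
  invisible(x)
}

# flatten to a frames x pixels matrix (column p = pixel in column-major order)
.as_tp_matrix <- function(stack) {
  d <- dim(stack$data)
  t(matrix(stack$data, nrow = d[1] * d[2], ncol = d[3]))
}

.from_tp_matrix <- function(m, dims) {
  array(t(m), dim = dims)
}

#' Read a multi-frame TIFF into a video stack
#'
#' Frames are read in file order. Interleaved multi-channel exports (frame1-ch1,
#' frame1-ch2, frame2-ch1, ...) are de-interleaved with `n_channels`; single
#' channel files use the defaults. 8/16-bit files are returned on their native
#' integer scale (0..255 / 0..65535), float files as stored.
#'
#' @param path Path to a multi-frame grayscale TIFF.
#' @param channel 1-based channel index to extract.
#' @param n_channels Number of interleaved channels in the file.
#' @param frame_interval Minutes per frame (metadata, not read from the file).
#' @param channel_name Optional channel label.
#' @return A [video_stack()].
#' @export
read_stack <- function(path, channel = 1, n_channels = 1, frame_interval = 15,
                       channel_name = "") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) f[, , 1] else f  # collapse RGB-as-gray exports
  })
  if (length(frames) %% n_channels != 0) {
    abort(sprintf("%d frames cannot hold %d interleaved channels", length(frames), n_channels))
  }
  if (channel < 1 || channel > n_channels) {
    abort(sprintf(
      "channel out of range: asked for %d of %d (axis layout: %d pages of %dx%d)",
      channel, n_channels, length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  }
  sel <- frames[seq(channel, length(frames), by = n_channels)]
  if (length(sel) < 2) abort("single-frame stack: a video needs >= 2 frames")
  video_stack(simplify2array(sel), frame_interval = frame_interval,
              channel_name = channel_name)
}

#' Write a video stack as a multi-frame TIFF
#'
#' Integer-valued stacks are written as 16-bit (values must lie in 0..65535),
#' giving a bit-exact read/write round trip; other stacks are written as
#' 32-bit float scaled into `[0, 1]` by `scale_max`.
#'
#' @param stack A [video_stack()].
#' @param path Output path.
#' @param bits 16 (integer, exact round trip) or 32 (float).
#' @param scale_max Full-scale intensity for the 32-bit float encoding;
#'   defaults to the stack maximum.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16, scale_max = NULL) {
  stopifnot(inherits(stack, "video_stack"), bits %in% c(16, 32))
  d <- stack$data
  frames <- lapply(seq_len(dim(d)[3]), function(t) d[, , t])
  if (bits == 16) {
    if (max(d) > 65535 || any(d != round(d))) {
      abort("16-bit output needs integer intensities in 0..65535; use bits = 32")
    }
    frames <- lapply(frames, function(f) f / 65535)
  } else {
    if (is.null(scale_max)) scale_max <- max(d)
    if (scale_max <= 0) scale_max <- 1
    frames <- lapply(frames, function(f) pmin(f / scale_max, 1))
  }
  tiff::writeTIFF(frames, path, bits.per.sample = bits)
  invisible(path)
}

#' Read / write a pixel class label map
#'
#' Label maps use 0 = background, 1 = netotic, 2 = necrotic, written as a
#' single-frame 8-bit TIFF.
#'
#' @param labels Integer matrix with values in `{0, 1, 2}`.
#' @param path File path.
#' @return `read_label_map()` returns the integer label matrix;
#'   `write_label_map()` returns `path` invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (!all(labels %in% 0:2)) abort("label values must be in {0, 1, 2}")
  storage.mode(labels) <- "double"
  tiff::writeTIFF(labels / 255, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Write pipeline outputs and a provenance manifest
#'
#' Writes the label map as TIFF, each table as headered CSV, the configuration
#' as YAML, and a JSON manifest recording files, config and seed. Re-running
#' with the same inputs reproduces every file byte-for-byte except the
#' manifest timestamp.
#'
#' @param labels Label matrix (see [write_label_map()]), or `NULL`.
#' @param tables Named list of data frames, written as `<name>.csv`.
#' @param out_dir Output directory (created if missing).
#' @param cfg A [run_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
write_outputs <- function(labels, tables, out_dir, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  if (file.access(out_dir, 2) != 0) abort(paste0("output directory not writable: ", out_dir))
  files <- character(0)
  if (!is.null(labels)) {
    write_label_map(labels, file.path(out_dir, "labels.tif"))
    files <- c(files, "labels.tif")
  }
  for (nm in names(tables)) {
    f <- paste0(nm, ".csv")
    write.csv(tables[[nm]], file.path(out_dir, f), row.names = FALSE)
    files <- c(files, f)
  }
  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  manifest <- list(
    files = c(files, "config.yaml"),
    config = unclass(cfg),
    seed = cfg$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
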