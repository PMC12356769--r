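#' Sample netotic pixel traces
#'
#' Draws up to `n` pixels uniformly without replacement from those classified
#' netotic and collects their raw (unscaled, smoothed) Sytox time series plus
#' their peaking times (earliest maximum of each trace). The rescaled signal
#' is deliberately not used here: kinetics run on the smoothed raw intensities.
#'
#' @param smoothed Smoothed raw Sytox [video_stack()].
#' @param labels A `pixel_class_map` from [classify_stack()].
#' @param n Number of pixels to sample (default from `cfg`-style 1000).
#' @param seed Integer seed for the draw.
#' @return A `trace_set`: list with `traces` (n x T matrix), `pixel_coords`
#'   (tibble row/col), `peak_times` (frame indices), `frame_interval`,
#'   `n_requested`, `exhausted` (TRUE when fewer netotic pixels than `n`
#'   existed, in which case all are taken), `seed`.
#' @export
sample_netotic <- function(smoothed, labels, n = 1000, seed = 1L) {
  stopifnot(inherits(smoothed, "video_stack"), inherits(labels, "pixel_class_map"))
  if (!identical(dim(labels)[1:2], dim(smoothed$data)[1:2])) {
    abort("label map and stack dimensions differ")
  }
  idx <- which(labels == 1L)
  if (length(idx) == 0) abort("no NETs detected: zero pixels classified netotic")
  exhausted <- length(idx) < n
  take <- if (exhausted) idx else .with_seed(seed, sample(idx, n))
  if (exhausted) {
    warn(sprintf("only %d netotic pixels available (requested %d): taking all", length(idx), n))
  }
  d <- dim(smoothed$data)
  m <- matrix(smoothed$data, nrow = d[1] * d[2], ncol = d[3])
  traces <- m[take, , drop = FALSE]
  peaks <- max.col(traces, ties.method = "first")
  structure(
    list(traces = traces,
         pixel_coords = tibble(row = (take - 1L) %% d[1] + 1L,
                               col = (take - 1L) %/% d[1] + 1L),
         peak_times = peaks,
         frame_interval = smoothed$frame_interval,
         n_requested = as.integer(n),
         exhausted = exhausted,
         normalized = FALSE,
         seed = as.integer(seed)),
    class = "trace_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d traces x %d frames @ %g min%s%s\n",
              nrow(x$traces), ncol(x$traces), x$frame_interval,
              if (x$normalized) ", normalized" else "",
              if (x$exhausted) " (exhausted)" else ""))
  invisible(x)
}

#' Long-format view of a trace set
#'
#' @param x A `trace_set`.
#' @param ... Unused.
#' @return Tibble with columns pixel, row, col, frame, time_min,
#'   rel_time_min (relative to the pixel's peak), value.
#' @method tidy trace_set
#' @export
tidy.trace_set <- function(x, ...) {
  nt <- ncol(x$traces)
  np <- nrow(x$traces)
  tibble(
    pixel = rep(seq_len(np), each = nt),
    row = rep(x$pixel_coords$row, each = nt),
    col = rep(x$pixel_coords$col, each = nt),
    frame = rep(seq_len(nt), np),
    time_min = (rep(seq_len(nt), np) - 1) * x$frame_interval,
    rel_time_min = (rep(seq_len(nt), np) - rep(x$peak_times, each = nt)) * x$frame_interval,
    value = as.vector(t(x$traces))
  )
}

#' Normalize traces between pre-peak minimum and peak
#'
#' Maps each trace affinely so its minimum before (and including) the peak
#' becomes 0 and its maximum becomes 1: `y' = (y - min_prepeak) /
#' (max - min_prepeak)`. Post-peak values may legitimately fall below 0 (no
#' clipping). Flat traces (max equal to pre-peak minimum) carry no kinetic
#' information and are dropped with a message.
#'
#' @param ts A `trace_set`.
#' @return The normalized `trace_set` (`normalized = TRUE`).
#' @export
normalize_traces <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  np <- nrow(ts$traces)
  nt <- ncol(ts$traces)
  peak_val <- ts$traces[cbind(seq_len(np), ts$peak_times)]
  min_pre <- vapply(seq_len(np), function(i) min(ts$traces[i, seq_len(ts$peak_times[i])]), 1)
  flat <- peak_val <= min_pre
  if (all(flat)) abort("all traces are flat: nothing to normalize")
  if (any(flat)) {
    inform(sprintf("dropping %d flat trace(s) out of %d", sum(flat), np))
    ts$traces <- ts$traces[!flat, , drop = FALSE]
    ts$pixel_coords <- ts$pixel_coords[!flat, ]
    ts$peak_times <- ts$peak_times[!flat]
    peak_val <- peak_val[!flat]
    min_pre <- min_pre[!flat]
  }
  ts$traces <- (ts$traces - min_pre) / (peak_val - min_pre)
  ts$normalized <- TRUE
  ts
}

#' Peak-align traces and summarize as median and quartile curves
#'
#' Shifts every trace so its peak sits at relative time 0, then computes the
#' pointwise median and the 25%/75% quartiles over all traces covering each
#' relative timepoint. Relative times covered by fewer than `min_coverage` of
#' the traces are trimmed so the quartiles are never computed from a handful
#' of outlier-length traces.
#'
#' @param ts A `trace_set` (raw or normalized).
#' @param min_coverage Minimum fraction of traces that must cover a relative
#'   timepoint for it to be kept (default 0.25).
#' @return A `summary_curves` object: tibble-backed list with `curve`
#'   (columns rel_time_min, median, q1, q3, n_traces), `normalized`,
#'   `frame_interval`.
#' @export
align_and_summarize <- function(ts, min_coverage = 0.25) {
  stopifnot(inherits(ts, "trace_set"))
  np <- nrow(ts$traces)
  if (np == 0) abort("empty trace set")
  nt <- ncol(ts$traces)
  offs <- seq_len(nt)  # frame index
  rel_min <- min(1L - ts$peak_times)
  rel_max <- max(nt - ts$peak_times)
  grid <- rel_min:rel_max
  acc <- matrix(NA_real_, np, length(grid))
  for (i in seq_len(np)) {
    pos <- offs - ts$peak_times[i] - rel_min + 1L
    acc[i, pos] <- ts$traces[i, ]
  }
  cov <- colMeans(!is.na(acc))
  keep <- cov >= min_coverage
  grid <- grid[keep]
  acc <- acc[, keep, drop = FALSE]
  qs <- apply(acc, 2, quantile, probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
  curve <- tibble(
    rel_time_min = grid * ts$frame_interval,
    q1 = qs[1, ], median = qs[2, ], q3 = qs[3, ],
    n_traces = colSums(!is.na(acc))
  )
  structure(list(curve = curve, normalized = ts$normalized,
                 frame_interval = ts$frame_interval, n_traces = np),
            class = "summary_curves")
}

#' @export
print.summary_curves <- function(x, ...) {
  cat(sprintf("<summary_curves>%s %d traces, rel time %g..%g min\n",
              if (x$normalized) " normalized," else "", x$n_traces,
              min(x$curve$rel_time_min), max(x$curve$rel_time_min)))
  invisible(x)
}

#' @method tidy summary_curves
#' @export
tidy.summary_curves <- function(x, ...) x$curve

#' Plot peak-aligned summary curves
#'
#' @param object A `summary_curves`.
#' @param ... Unused.
#' @return A ggplot: median line with a Q1-Q3 ribbon against time from peak.
#' @method autoplot summary_curves
#' @export
autoplot.summary_curves <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$rel_time_min)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::labs(x = "time from peak (min)",
                  y = if (object$normalized) "normalized Sytox signal" else "Sytox signal (a.u.)")
}

#' Time for a normalized curve to decay to a level
#'
#' Measures how long the peak-normalized curve takes to fall from 1 (the
#' peak, at relative time 0) to `level`, using linear interpolation between
#' the two frames bracketing the first crossing. A curve that never reaches
#' the level is censored at its observed span.
#'
#' @param values Normalized curve sampled at the frame interval, starting at
#'   its peak: `values[1]` must be 1 (tolerance 1e-6).
#' @param level Target level in (0, 1): 0.5 gives the 50%-lifetime
#'   (half-life), 0.2 the 80%-lifetime.
#' @param frame_interval Minutes per frame.
#' @return A `lifetime_estimate`: list with `minutes` (NA when censored),
#'   `censored`, `observed_span_min`, `level`.
#' @examples
#' lifetime(c(1, .75, .5, .25, 0), 0.5, 15)$minutes  # 30
#' lifetime(c(1, .75, .5, .25, 0), 0.2, 15)$minutes  # 48
#' @export
lifetime <- function(values, level, frame_interval = 15) {
  if (length(values) < 1) abort("empty curve")
  if (!is.finite(values[1]) || abs(values[1] - 1) > 1e-6) {
    abort("curve must start at its normalized peak (value 1 at relative time 0)")
  }
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  span <- (length(values) - 1) * frame_interval
  hit <- which(values <= level)
  hit <- hit[hit > 1]
  if (length(hit) == 0) {
    return(structure(list(minutes = NA_real_, censored = TRUE,
                          observed_span_min = span, level = level),
                     class = "lifetime_estimate"))
  }
  j <- hit[1]
  v0 <- values[j - 1]; v1 <- values[j]
  t0 <- (j - 2) * frame_interval
  minutes <- if (v1 == v0) t0 + frame_interval else
    t0 + frame_interval * (v0 - level) / (v0 - v1)
  structure(list(minutes = minutes, censored = FALSE,
                 observed_span_min = span, level = level),
            class = "lifetime_estimate")
}

#' @export
print.lifetime_estimate <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<lifetime> level %.2f: censored (observed %g min)\n", x$level, x$observed_span_min))
  } else {
    cat(sprintf("<lifetime> level %.2f: %.1f min\n", x$level, x$minutes))
  }
  invisible(x)
}

#' Lifetimes of the median and quartile curves
#'
#' Applies [lifetime()] at each configured fraction (default 0.5 and 0.2) to
#' the post-peak part of the normalized median, Q1 and Q3 curves. The
#' 50%-lifetime of the median curve is the per-field NET half-life.
#'
#' @param curves Normalized `summary_curves` from [align_and_summarize()].
#' @param cfg A [run_config()] supplying `lifetime_fractions`.
#' @return Tibble: fraction, curve (`median`/`q1`/`q3`), lifetime_min,
#'   censored, observed_span_min.
#' @export
half_life_report <- function(curves, cfg = run_config()) {
  stopifnot(inherits(curves, "summary_curves"))
  if (!curves$normalized) abort("half_life_report needs normalized curves; run normalize_traces() first")
  post <- curves$curve[curves$curve$rel_time_min >= 0, ]
  out <- list()
  for (frac in cfg$lifetime_fractions) {
    for (nm in c("median", "q1", "q3")) {
      vals <- post[[nm]]
      # quartile curves need not start exactly at 1; renormalize to their
      # own value at the peak so the level is relative to that curve
      est <- lifetime(vals / vals[1], level = frac,
                      frame_interval = curves$frame_interval)
      out[[length(out) + 1]] <- tibble(
        fraction = frac, curve = nm, lifetime_min = est$minutes,
        censored = est$censored, observed_span_min = est$observed_span_min)
    }
  }
  dplyr::bind_rows(out)
}

#' Endpoint NET area per connected component
#'
#' Otsu-thresholds a single Sytox frame (typically the one nearest 200 min),
#' labels the above-threshold mask into connected components and returns the
#' component areas in pixels: the per-component NET-area distribution.
#'
#' @param frame Numeric H x W matrix, or a [video_stack()] together with
#'   `at_minute`.
#' @param connectivity 4 or 8.
#' @param at_minute When `frame` is a stack: acquisition minute whose nearest
#'   frame is analysed (default 200).
#' @return Tibble: component, area_px; attribute `threshold` carries the Otsu
#'   cut. Adding a global scalar gain to the frame leaves the areas unchanged.
#' @export
net_area_endpoint <- function(frame, connectivity = 8, at_minute = 200) {
  if (inherits(frame, "video_stack")) {
    t_idx <- which.min(abs(frame_times(frame) - at_minute))
    frame <- frame$data[, , t_idx]
  }
  stopifnot(is.matrix(frame))
  th <- .frame_otsu(frame)
  if (is.na(th)) abort("degenerate frame: zero intensity range or trivial Otsu split")
  mask <- frame > th
  lab <- label_components(mask, connectivity)
  areas <- if (max(lab) == 0) integer(0) else tabulate(lab[lab > 0])
  out <- tibble(component = seq_along(areas), area_px = as.integer(areas))
  attr(out, "threshold") <- th
  out
}
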