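#' Shape features of one rescaled pixel trace
#'
#' Computes the quantities the three-class rule needs from a single
#' background-rescaled time series: extrema and their (earliest) positions,
#' the final value, and the fractions of post-extremum steps on which the
#' discrete derivative is strictly positive (after the minimum) or strictly
#' negative (after the maximum). Zero-derivative steps count in the
#' denominator only, so flat plateaus are neither "increasing" nor
#' "decreasing" time. If an extremum falls on the last frame its fraction is
#' 0 (empty window).
#'
#' @param trace Numeric vector of length >= 2.
#' @return A list of class `trace_features`: `max_val`, `min_val`,
#'   `argmax_t`, `argmin_t` (1-based frame indices), `final_val`,
#'   `frac_increasing_after_min`, `frac_decreasing_after_max`.
#' @examples
#' trace_features(c(1, 10, 8, 5, 3))
#' @export
trace_features <- function(trace) {
  if (length(trace) < 2) abort("a trace needs at least 2 frames")
  nt <- length(trace)
  d <- diff(trace)
  argmax <- which.max(trace)
  argmin <- which.min(trace)
  inc <- if (argmin < nt) sum(d[argmin:(nt - 1)] > 0) / (nt - argmin) else 0
  dec <- if (argmax < nt) sum(d[argmax:(nt - 1)] < 0) / (nt - argmax) else 0
  structure(
    list(max_val = trace[argmax], min_val = trace[argmin],
         argmax_t = argmax, argmin_t = argmin, final_val = trace[nt],
         frac_increasing_after_min = inc, frac_decreasing_after_max = dec),
    class = "trace_features"
  )
}

#' Classify one trace as background / netotic / necrotic
#'
#' Applies the published three-class criteria, all comparisons strict, with
#' the necrotic rule tested first:
#' * necrotic (2): rescaled maximum > 5, more than 50% of post-minimum steps
#'   increasing, final value above 90% of the maximum;
#' * netotic (1): rescaled maximum > 5, more than 50% of post-maximum steps
#'   decreasing, final value below the maximum;
#' * background (0) otherwise.
#'
#' Necrotic precedes netotic because a noisy plateau can satisfy both rules
#' (its final value can sit between 90% and 100% of the maximum).
#'
#' @param f A `trace_features` object.
#' @param cfg A [run_config()] supplying the thresholds.
#' @return Integer label: 0 background, 1 netotic, 2 necrotic.
#' @examples
#' cfg <- run_config()
#' classify_trace(trace_features(c(1, 2, 6, 8, 10)), cfg)  # 2: rise-and-keep
#' classify_trace(trace_features(c(1, 10, 8, 5, 3)), cfg)  # 1: rise-and-decay
#' @export
classify_trace <- function(f, cfg = run_config()) {
  stopifnot(inherits(f, "trace_features"))
  if (f$max_val > cfg$rescaled_max_threshold) {
    if (f$frac_increasing_after_min > cfg$time_fraction_threshold &&
        f$final_val > cfg$final_fraction_threshold * f$max_val) {
      return(2L)
    }
    if (f$frac_decreasing_after_max > cfg$time_fraction_threshold &&
        f$final_val < f$max_val) {
      return(1L)
    }
  }
  0L
}

#' Per-pixel three-class classification of a rescaled stack
#'
#' Vectorized application of [classify_trace()] to every pixel of the
#' background-rescaled video; agrees with the per-pixel reference
#' [oracle_classify()] exactly. Ties in extrema positions break to the
#' earliest frame.
#'
#' @param rescaled A background-rescaled [video_stack()] (see
#'   [rescale_stack()]).
#' @param cfg A [run_config()].
#' @return A `pixel_class_map`: integer H x W matrix in `{0, 1, 2}` with the
#'   configuration attached as attribute `config`.
#' @export
classify_stack <- function(rescaled, cfg = run_config()) {
  stopifnot(inherits(rescaled, "video_stack"))
  d <- dim(rescaled$data)
  nt <- d[3]
  x <- matrix(rescaled$data, nrow = d[1] * d[2], ncol = nt)  # pixels x frames
  np <- nrow(x)

  argmax <- max.col(x, ties.method = "first")
  argmin <- max.col(-x, ties.method = "first")
  max_val <- x[cbind(seq_len(np), argmax)]
  final_val <- x[, nt]

  dd <- x[, 2:nt, drop = FALSE] - x[, 1:(nt - 1), drop = FALSE]
  # suffix counts: S[p, k] = #{t >= k : d[p, t] sign-matches}
  lower <- lower.tri(matrix(0, nt - 1, nt - 1), diag = TRUE) * 1
  suf_pos <- (dd > 0) %*% lower
  suf_neg <- (dd < 0) %*% lower

  n_after_min <- nt - argmin
  n_after_max <- nt - argmax
  inc <- numeric(np)
  dec <- numeric(np)
  has <- argmin < nt
  inc[has] <- suf_pos[cbind(which(has), argmin[has])] / n_after_min[has]
  has <- argmax < nt
  dec[has] <- suf_neg[cbind(which(has), argmax[has])] / n_after_max[has]

  gate <- max_val > cfg$rescaled_max_threshold
  necrotic <- gate & inc > cfg$time_fraction_threshold &
    final_val > cfg$final_fraction_threshold * max_val
  netotic <- !necrotic & gate & dec > cfg$time_fraction_threshold &
    final_val < max_val

  labels <- matrix(0L, d[1], d[2])
  labels[necrotic] <- 2L
  labels[netotic] <- 1L
  structure(labels, class = c("pixel_class_map", "matrix", "array"), config = cfg)
}

#' Reference per-pixel classifier (nested loop)
#'
#' Plain transliteration of the printed criteria, one pixel at a time via
#' [trace_features()] and [classify_trace()]. Used as the independent oracle
#' that the vectorized [classify_stack()] must match pixel-for-pixel; far too
#' slow for production fields.
#'
#' @inheritParams classify_stack
#' @return A `pixel_class_map`.
#' @export
oracle_classify <- function(rescaled, cfg = run_config()) {
  stopifnot(inherits(rescaled, "video_stack"))
  d <- dim(rescaled$data)
  labels <- matrix(0L, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      labels[r, c] <- classify_trace(trace_features(rescaled$data[r, c, ]), cfg)
    }
  }
  structure(labels, class = c("pixel_class_map", "matrix", "array"), config = cfg)
}

#' @export
print.pixel_class_map <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<pixel_class_map> %dx%d: %.1f%% background, %.1f%% netotic, %.1f%% necrotic\n",
              nrow(x), ncol(x), 100 * mean(x == 0), 100 * mean(x == 1), 100 * mean(x == 2)))
  invisible(x)
}

#' Per-class pixel summary of a class map
#'
#' @param x A `pixel_class_map`.
#' @param ... Unused.
#' @return A tibble with one row per class: label, class name, pixel count,
#'   fraction of the field.
#' @method tidy pixel_class_map
#' @export
tidy.pixel_class_map <- function(x, ...) {
  tibble(
    label = 0:2,
    class = c("background", "netotic", "necrotic"),
    n_pixels = vapply(0:2, function(k) sum(x == k), 1L),
    fraction = vapply(0:2, function(k) mean(x == k), 1)
  )
}

#' Classify a raw Sytox stack end to end
#'
#' Runs [preprocess_stack()] then [classify_stack()].
#'
#' @param sytox Raw Sytox [video_stack()].
#' @param cfg A [run_config()].
#' @return List with `labels` (a `pixel_class_map`) plus the `smoothed`,
#'   `background` and `rescaled` intermediates.
#' @export
classify_video <- function(sytox, cfg = run_config()) {
  pp <- preprocess_stack(sytox, cfg)
  c(pp, list(labels = classify_stack(pp$rescaled, cfg)))
}
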