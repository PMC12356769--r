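#' Temporal Gaussian smoothing of a video stack
#'
#' Convolves every pixel's time series with a discretized Gaussian kernel
#' (truncated at 4 sigma, renormalized to sum 1) using symmetric ("reflect")
#' boundary handling. `sigma = 0` is the identity. Spatial content is not
#' touched; nonnegative input stays nonnegative and, away from the
#' boundaries, the per-pixel temporal mean is preserved.
#'
#' @param stack A [video_stack()].
#' @param sigma Kernel standard deviation in frames, `>= 0`.
#' @return A smoothed [video_stack()] with the same metadata.
#' @export
smooth_temporal <- function(stack, sigma) {
  stopifnot(inherits(stack, "video_stack"))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    abort("sigma must be a single number >= 0")
  }
  if (sigma == 0) return(stack)
  nt <- n_frames(stack)
  K <- .gaussian_smoother(nt, sigma)
  m <- K %*% .as_tp_matrix(stack)
  out <- stack
  out$data <- .from_tp_matrix(m, dim(stack$data))
  out
}

# nt x nt smoothing matrix: row t holds the reflected, truncated Gaussian
# weights applied to the raw frames
.gaussian_smoother <- function(nt, sigma) {
  radius <- max(1L, ceiling(4 * sigma))
  offs <- -radius:radius
  w <- dnorm(offs, sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, nt, nt)
  for (t in seq_len(nt)) {
    src <- t + offs
    # symmetric reflection: ... 2 1 | 1 2 ... nt | nt nt-1 ...
    src <- ifelse(src < 1, 1 - src, src)
    src <- ifelse(src > nt, 2 * nt + 1 - src, src)
    # repeat until inside (short stacks with wide kernels)
    while (any(src < 1 | src > nt)) {
      src <- ifelse(src < 1, 1 - src, src)
      src <- ifelse(src > nt, 2 * nt + 1 - src, src)
    }
    for (k in seq_along(src)) K[t, src[k]] <- K[t, src[k]] + w[k]
  }
  K
}

# Otsu threshold of one frame; returns NA for "trivial" frames whose range is
# zero or whose split leaves under min_side_frac of pixels on either side
.frame_otsu <- function(frame, min_side_frac = 0.01) {
  rg <- range(frame)
  if (rg[1] == rg[2]) return(NA_real_)
  th <- EBImage::otsu(frame, range = rg, levels = 256L)
  below <- mean(frame <= th)
  if (below < min_side_frac || below > 1 - min_side_frac) return(NA_real_)
  th
}

#' Estimate the common background of a smoothed video
#'
#' For every non-trivial frame the below-Otsu-threshold region is computed;
#' the common background is the intersection of those regions across frames
#' (pixels never part of a cell or a NET). Averaging the video over the mask
#' at each timepoint gives the mean common-background curve: the time-variable
#' scaling used by [rescale_stack()] to cancel global contrast drift. A frame
#' is trivial when its intensity range is zero or its Otsu split leaves less
#' than 1% of pixels on either side; trivial frames are skipped so degenerate
#' thresholds cannot poison the intersection.
#'
#' @param stack A smoothed [video_stack()].
#' @return A list of class `common_background` with `mask` (H x W logical),
#'   `mean_curve` (per-frame mean over the mask, floored at a small epsilon)
#'   and `n_frames_used`.
#' @export
estimate_common_background <- function(stack) {
  stopifnot(inherits(stack, "video_stack"))
  d <- dim(stack$data)
  nt <- d[3]
  mask <- matrix(TRUE, d[1], d[2])
  used <- 0L
  for (t in seq_len(nt)) {
    fr <- stack$data[, , t]
    th <- .frame_otsu(fr)
    if (is.na(th)) next
    mask <- mask & (fr <= th)
    used <- used + 1L
  }
  if (used == 0L) abort("all frames are trivial (uniform or degenerate Otsu split): cannot estimate a background")
  if (!any(mask)) {
    abort("common background is empty: every pixel crosses the Otsu threshold in some frame; use a larger field of view or fewer cells")
  }
  idx <- which(mask)
  m <- .as_tp_matrix(stack)
  mean_curve <- rowMeans(m[, idx, drop = FALSE])
  eps <- 1e-6 * max(stack$data)
  mean_curve <- pmax(mean_curve, eps)
  structure(list(mask = mask, mean_curve = mean_curve, n_frames_used = used),
            class = "common_background")
}

#' @export
print.common_background <- function(x, ...) {
  cat(sprintf("<common_background> %d px mask (%.1f%% of field), %d frames used\n",
              sum(x$mask), 100 * mean(x$mask), x$n_frames_used))
  invisible(x)
}

#' Background-rescale a smoothed video
#'
#' Divides every frame by the mean common-background intensity at that
#' timepoint, yielding the dimensionless background-rescaled stack on which
#' pixel classification operates. A background pixel's rescaled trace hovers
#' around 1; per-frame multiplicative drift applied to the input cancels
#' exactly. The rescaled stack is used only for classification, never for
#' kinetics.
#'
#' @param stack A smoothed [video_stack()].
#' @param bg A `common_background` from [estimate_common_background()].
#' @return A [video_stack()] of dimensionless rescaled intensities.
#' @export
rescale_stack <- function(stack, bg) {
  stopifnot(inherits(stack, "video_stack"), inherits(bg, "common_background"))
  if (length(bg$mean_curve) != n_frames(stack)) {
    abort("mean_curve length does not match the number of frames")
  }
  out <- stack
  out$data <- sweep(stack$data, 3, bg$mean_curve, `/`)
  out$channel_name <- paste0(stack$channel_name, "_rescaled")
  out
}

#' Smooth, background-estimate and rescale in one call
#'
#' Convenience wrapper running [smooth_temporal()],
#' [estimate_common_background()] and [rescale_stack()] with the sigma from
#' `cfg`.
#'
#' @param stack Raw Sytox [video_stack()].
#' @param cfg A [run_config()].
#' @return List with `smoothed`, `background`, `rescaled`.
#' @export
preprocess_stack <- function(stack, cfg = run_config()) {
  smoothed <- smooth_temporal(stack, cfg$smoothing_sigma)
  bg <- estimate_common_background(smoothed)
  list(smoothed = smoothed, background = bg,
       rescaled = rescale_stack(smoothed, bg))
}
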