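#' Quantify one field of view end to end
#'
#' Full per-video analysis: smooth and background-rescale the Sytox channel,
#' classify every pixel (background / netotic / necrotic), sample netotic
#' traces, build peak-aligned raw and normalized median/quartile curves,
#' measure 50%- and 80%-lifetimes, and compute the cell census and net span
#' from the DAPI channel and the necrotic region.
#'
#' @param dapi DAPI [video_stack()] (membrane-permeable DNA stain).
#' @param sytox Sytox [video_stack()] (membrane-impermeable DNA stain).
#' @param cfg A [run_config()].
#' @return An object of class `net_quant`: list with `labels`, `traces`,
#'   `curves_raw`, `curves_norm`, `lifetimes` (tibble), `census` (tibble),
#'   `net_span` (tibble or NULL when no netotic cells), `config`.
#' @seealso [tidy.net_quant()], [glance.net_quant()], [autoplot.summary_curves()]
#' @export
quantify_video <- function(dapi, sytox, cfg = run_config()) {
  cls <- classify_video(sytox, cfg)
  ts <- sample_netotic(cls$smoothed, cls$labels,
                       n = cfg$n_sample_pixels, seed = cfg$seed)
  curves_raw <- align_and_summarize(ts)
  ts_norm <- normalize_traces(ts)
  curves_norm <- align_and_summarize(ts_norm)
  lifetimes <- half_life_report(curves_norm, cfg)
  census <- cell_census(dapi, cls$labels, cfg)
  span <- if (census$netotic_cells[1] > 0) net_span(cls$labels, census) else NULL
  structure(
    list(labels = cls$labels, background = cls$background,
         traces = ts, curves_raw = curves_raw, curves_norm = curves_norm,
         lifetimes = lifetimes, census = census, net_span = span,
         config = cfg),
    class = "net_quant"
  )
}

#' @export
print.net_quant <- function(x, ...) {
  hl <- x$lifetimes[x$lifetimes$fraction == 0.5 & x$lifetimes$curve == "median", ]
  cat("<net_quant>\n")
  print(x$labels)
  cat(sprintf("  census: %d initial, %d necrotic, %d netotic\n",
              x$census$initial_cells, x$census$necrotic_cells, x$census$netotic_cells))
  if (nrow(hl) && !hl$censored) {
    cat(sprintf("  NET half-life (median curve): %.0f min (%.2f h)\n",
                hl$lifetime_min, hl$lifetime_min / 60))
  } else if (nrow(hl)) {
    cat(sprintf("  NET half-life: censored beyond %g min\n", hl$observed_span_min))
  }
  invisible(x)
}

#' Lifetime table of a quantified video
#'
#' @param x A `net_quant` from [quantify_video()].
#' @param ... Unused.
#' @return The lifetimes tibble: fraction, curve, lifetime_min, censored,
#'   observed_span_min.
#' @method tidy net_quant
#' @export
tidy.net_quant <- function(x, ...) x$lifetimes

#' One-row summary of a quantified video
#'
#' @param x A `net_quant`.
#' @param ... Unused.
#' @return One-row tibble: cell counts, total NET area, span per cell, the
#'   median-curve half-life (50%-lifetime) and 80%-lifetime in minutes, the
#'   number of sampled traces.
#' @method glance net_quant
#' @export
glance.net_quant <- function(x, ...) {
  pick <- function(frac) {
    r <- x$lifetimes[x$lifetimes$fraction == frac & x$lifetimes$curve == "median", ]
    if (nrow(r) == 0 || r$censored) NA_real_ else r$lifetime_min
  }
  tibble(
    initial_cells = x$census$initial_cells,
    necrotic_cells = x$census$necrotic_cells,
    netotic_cells = x$census$netotic_cells,
    total_net_area_px = sum(x$labels == 1L),
    span_px_per_cell = if (is.null(x$net_span)) NA_real_ else x$net_span$span_px_per_cell,
    half_life_min = pick(0.5),
    lifetime80_min = pick(0.2),
    n_traces = nrow(x$traces$traces)
  )
}

#' Plot the pixel class map
#'
#' @param object A `pixel_class_map`.
#' @param ... Unused.
#' @return A ggplot raster of the three classes.
#' @method autoplot pixel_class_map
#' @export
autoplot.pixel_class_map <- function(object, ...) {
  df <- tibble(
    row = rep(seq_len(nrow(object)), ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    class = factor(c("background", "netotic", "necrotic")[as.vector(object) + 1L],
                   levels = c("background", "netotic", "necrotic"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(background = "grey15",
                                          netotic = "#35b779",
                                          necrotic = "#e45756")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}
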