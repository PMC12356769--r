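#' Analysis run configuration
#'
#' Collects every tunable of the classification and kinetics pipeline in one
#' validated object. Defaults follow the published protocol: a rescaled-max
#' gate of 5, post-extremum time fractions above 0.5, a plateau criterion of
#' 90% of the maximum, 1000 sampled netotic pixels, nucleus area gate of
#' 1000-4000 px, necrotic area gate of 5000-10000 px, and lifetimes read at
#' the 0.5 and 0.2 normalized levels.
#'
#' @param smoothing_sigma Temporal Gaussian sigma in frames (>= 0).
#' @param rescaled_max_threshold A pixel is a candidate cell pixel only if the
#'   maximum of its background-rescaled trace exceeds this (strictly).
#' @param time_fraction_threshold Fraction of post-extremum steps that must be
#'   strictly increasing (necrotic) or decreasing (netotic); strict comparison.
#' @param final_fraction_threshold Necrotic pixels must end above this fraction
#'   of their trace maximum (strictly).
#' @param n_sample_pixels Number of netotic pixels sampled for kinetics.
#' @param kernel_area_bounds Inclusive pixel-area interval for a valid nucleus
#'   in the DAPI channel.
#' @param necrotic_area_bounds Inclusive pixel-area interval for a valid
#'   necrotic cell component.
#' @param lifetime_fractions Normalized levels at which lifetimes are measured
#'   (0.5 gives the half-life, 0.2 the 80%-lifetime).
#' @param connectivity Pixel connectivity for component counting, 4 or 8.
#' @param seed Integer seed recorded for provenance and used for sampling.
#'
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config(seed = 1)
#' cfg$rescaled_max_threshold
#' @export
run_config <- function(smoothing_sigma = 1,
                       rescaled_max_threshold = 5,
                       time_fraction_threshold = 0.5,
                       final_fraction_threshold = 0.9,
                       n_sample_pixels = 1000,
                       kernel_area_bounds = c(1000, 4000),
                       necrotic_area_bounds = c(5000, 10000),
                       lifetime_fractions = c(0.5, 0.2),
                       connectivity = 8,
                       seed = 1L) {
  stopifnot(
    is.numeric(smoothing_sigma), length(smoothing_sigma) == 1, smoothing_sigma >= 0,
    is.numeric(rescaled_max_threshold), rescaled_max_threshold > 0,
    time_fraction_threshold > 0, time_fraction_threshold < 1,
    final_fraction_threshold > 0, final_fraction_threshold < 1,
    n_sample_pixels >= 1,
    length(kernel_area_bounds) == 2, kernel_area_bounds[1] < kernel_area_bounds[2],
    kernel_area_bounds[1] >= 0,
    length(necrotic_area_bounds) == 2, necrotic_area_bounds[1] < necrotic_area_bounds[2],
    necrotic_area_bounds[1] >= 0,
    all(lifetime_fractions > 0), all(lifetime_fractions < 1),
    connectivity %in% c(4, 8)
  )
  structure(
    list(
      smoothing_sigma = smoothing_sigma,
      rescaled_max_threshold = rescaled_max_threshold,
      time_fraction_threshold = time_fraction_threshold,
      final_fraction_threshold = final_fraction_threshold,
      n_sample_pixels = as.integer(n_sample_pixels),
      kernel_area_bounds = as.numeric(kernel_area_bounds),
      necrotic_area_bounds = as.numeric(necrotic_area_bounds),
      lifetime_fractions = as.numeric(lifetime_fractions),
      connectivity = as.integer(connectivity),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-25s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Read / write run configuration as YAML
#'
#' The YAML file mirrors the fields of [run_config()]; missing fields fall back
#' to the defaults so partial configs are valid.
#'
#' @param path Path to a YAML file.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param cfg A `run_config` object.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
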