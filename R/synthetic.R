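#' Specify one synthetic cell
#'
#' One row of a scene's cell table. A cell has a nucleus footprint
#' (`kernel_area`, visible in the DAPI channel, target within the 1000-4000 px
#' census gate) and a post-lysis Sytox footprint (`lysed_area`; for necrotic
#' cells target within the 5000-10000 px gate, for netotic cells the spread of
#' the released NET). Kinetics: netotic pixels rise from `onset_time` over
#' `rise_time` to `peak_amplitude` above background and then decay
#' exponentially with `decay_half_life`; necrotic pixels rise to 90% of their
#' amplitude and then climb slowly to their maximum at the final frame, so the
#' trace ends above the 90%-of-max plateau criterion; quiescent cells show no
#' Sytox signal at all.
#'
#' @param kind `"netotic"`, `"necrotic"` or `"quiescent"`.
#' @param center_row,center_col Footprint center in pixels.
#' @param kernel_area Nucleus footprint area in px.
#' @param lysed_area Post-lysis Sytox footprint area in px (ignored for
#'   quiescent cells).
#' @param onset_time Lysis onset in minutes from acquisition start.
#' @param peak_amplitude Sytox amplitude above background at peak.
#' @param decay_half_life Exponential decay half-life in minutes (netotic).
#' @param rise_time Minutes from onset to peak.
#' @return A one-row tibble.
#' @export
cell_spec <- function(kind, center_row, center_col,
                      kernel_area = 2000,
                      lysed_area = if (kind == "necrotic") 7000 else 2500,
                      onset_time = 60,
                      peak_amplitude = 800,
                      decay_half_life = NA_real_,
                      rise_time = 30) {
  kind <- match.arg(kind, c("netotic", "necrotic", "quiescent"))
  if (kind == "netotic" && (is.na(decay_half_life) || decay_half_life <= 0)) {
    abort("netotic cells need decay_half_life > 0 minutes")
  }
  if (kind != "quiescent" && peak_amplitude <= 0) abort("peak_amplitude must be > 0")
  tibble(
    kind = kind, center_row = center_row, center_col = center_col,
    kernel_area = kernel_area, lysed_area = lysed_area,
    onset_time = onset_time, peak_amplitude = peak_amplitude,
    decay_half_life = decay_half_life, rise_time = rise_time
  )
}

#' Define a synthetic imaging scene
#'
#' A scene fixes the field geometry, the cell layout (a table of
#' [cell_spec()] rows), the background model (level + additive Gaussian noise,
#' clipped at zero) and a per-frame multiplicative drift curve emulating
#' global contrast variation. Defaults emulate one field of view of a
#' PMA-stimulated neutrophil time-lapse: 15-min frames over 15 h.
#'
#' @param height,width Field size in pixels.
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval Minutes per frame.
#' @param cells Tibble of cells (rows from [cell_spec()]); may be empty.
#' @param background_level Mean background intensity.
#' @param background_noise_sd Additive Gaussian noise SD.
#' @param drift Per-frame multiplicative scalars (length `n_frames`, all > 0),
#'   e.g. from [drift_profile()]. Default: no drift.
#' @param dapi_background,dapi_amplitude DAPI channel background and nucleus
#'   intensity above background.
#' @param overlap_tol Maximum number of pixels allowed to be claimed by more
#'   than one cell footprint; beyond it, scene construction errors because
#'   ground-truth classes would be ambiguous.
#' @param seed Integer seed; the generated video is a deterministic function
#'   of the scene including this seed.
#' @return A list of class `synthetic_scene`.
#' @seealso [generate_video()], [random_scene()]
#' @export
synthetic_scene <- function(height, width, n_frames,
                            frame_interval = 15,
                            cells = cell_spec("netotic", 1, 1,
                                              decay_half_life = 180)[0, ],
                            background_level = 100,
                            background_noise_sd = 5,
                            drift = rep(1, n_frames),
                            dapi_background = 20,
                            dapi_amplitude = 400,
                            overlap_tol = 0,
                            seed = 1L) {
  stopifnot(height >= 1, width >= 1, n_frames >= 2, frame_interval > 0,
            background_level > 0, background_noise_sd >= 0)
  if (length(drift) != n_frames) abort("drift curve length must equal n_frames")
  if (any(drift <= 0)) abort("all drift scalars must be > 0")
  cells <- as_tibble(cells)
  fp <- .scene_footprints(cells, height, width)
  claimed <- unlist(lapply(fp, function(f) f$sytox_px))
  n_over <- sum(duplicated(claimed))
  if (n_over > overlap_tol) {
    abort(sprintf("cell footprints overlap on %d px (tolerance %d): ground-truth classes would be ambiguous",
                  n_over, overlap_tol))
  }
  structure(
    list(height = height, width = width, n_frames = n_frames,
         frame_interval = frame_interval, cells = cells,
         background_level = background_level,
         background_noise_sd = background_noise_sd,
         drift = drift, dapi_background = dapi_background,
         dapi_amplitude = dapi_amplitude, seed = as.integer(seed),
         footprints = fp),
    class = "synthetic_scene"
  )
}

# linear pixel indices of a rasterized disk of the given area, clipped test:
# the disk must fit inside the frame
.disk_pixels <- function(center_row, center_col, area, height, width) {
  r <- sqrt(area / pi)
  r0 <- max(1, floor(center_row - r)); r1 <- min(height, ceiling(center_row + r))
  c0 <- max(1, floor(center_col - r)); c1 <- min(width, ceiling(center_col + r))
  rows <- r0:r1; cols <- c0:c1
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  inside <- (rr - center_row)^2 + (cc - center_col)^2 <= r^2
  if (center_row - r < 0.5 || center_row + r > height + 0.5 ||
      center_col - r < 0.5 || center_col + r > width + 0.5) {
    abort("cell footprint extends outside the frame")
  }
  (cc[inside] - 1L) * height + rr[inside]
}

.scene_footprints <- function(cells, height, width) {
  lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    kernel <- .disk_pixels(cl$center_row, cl$center_col, cl$kernel_area, height, width)
    sytox <- if (cl$kind == "quiescent") integer(0) else
      .disk_pixels(cl$center_row, cl$center_col, cl$lysed_area, height, width)
    list(kernel_px = kernel, sytox_px = sytox)
  })
}

# deterministic noiseless Sytox shape of one cell at the given frame times
# (minutes), as a fraction of peak_amplitude
.cell_shape <- function(cell, times) {
  onset <- cell$onset_time
  peak_t <- onset + cell$rise_time
  s <- numeric(length(times))
  rising <- times >= onset & times < peak_t
  after <- times >= peak_t
  if (cell$kind == "netotic") {
    s[rising] <- (times[rising] - onset) / cell$rise_time
    s[after] <- 2^(-(times[after] - peak_t) / cell$decay_half_life)
  } else if (cell$kind == "necrotic") {
    s[rising] <- 0.9 * (times[rising] - onset) / cell$rise_time
    t_end <- times[length(times)]
    if (t_end > peak_t) {
      s[after] <- 0.9 + 0.1 * (times[after] - peak_t) / (t_end - peak_t)
    } else {
      s[after] <- 0.9
    }
  }
  s
}

# run expr with a private RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a two-channel synthetic video with ground truth
#'
#' Renders the scene into a DAPI stack (all nuclei visible from frame 0), a
#' Sytox stack (background + cell kinetics + clipped Gaussian noise, each
#' frame multiplied by its drift scalar), and the ground truth: the pixel
#' class map, the cell counts, per-cell half-lives and the set of true netotic
#' pixels. Identical scenes (including seed) give bit-identical output.
#'
#' @param scene A [synthetic_scene()].
#' @return A list with elements `dapi` and `sytox` ([video_stack()]s) and
#'   `truth` (list: `class_map`, `counts`, `cells`, `netotic_px`).
#' @export
generate_video <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  h <- scene$height; w <- scene$width; nt <- scene$n_frames
  np <- h * w
  times <- (seq_len(nt) - 1) * scene$frame_interval
  sy <- matrix(scene$background_level, np, nt)
  da <- matrix(scene$dapi_background, np, nt)
  class_map <- matrix(0L, h, w)
  for (i in seq_len(nrow(scene$cells))) {
    cl <- scene$cells[i, ]
    fp <- scene$footprints[[i]]
    da[fp$kernel_px, ] <- scene$dapi_background + scene$dapi_amplitude
    if (cl$kind != "quiescent") {
      shape <- .cell_shape(cl, times)
      sy[fp$sytox_px, ] <- sy[fp$sytox_px, ] +
        rep(cl$peak_amplitude * shape, each = length(fp$sytox_px))
      class_map[fp$sytox_px] <- if (cl$kind == "netotic") 1L else 2L
    }
  }
  .with_seed(scene$seed, {
    if (scene$background_noise_sd > 0) {
      sy <- sy + rnorm(np * nt, 0, scene$background_noise_sd)
      da <- da + rnorm(np * nt, 0, scene$background_noise_sd)
    }
  })
  sy <- sweep(sy, 2, scene$drift, `*`)
  da <- sweep(da, 2, scene$drift, `*`)
  sy[sy < 0] <- 0
  da[da < 0] <- 0
  kinds <- scene$cells$kind
  counts <- c(initial = nrow(scene$cells),
              netotic = sum(kinds == "netotic"),
              necrotic = sum(kinds == "necrotic"),
              quiescent = sum(kinds == "quiescent"))
  truth <- list(
    class_map = class_map,
    counts = counts,
    cells = dplyr::mutate(scene$cells,
      kernel_px = vapply(scene$footprints, function(f) length(f$kernel_px), 1L),
      sytox_px = vapply(scene$footprints, function(f) length(f$sytox_px), 1L)),
    netotic_px = which(class_map == 1L)
  )
  list(
    dapi = video_stack(array(da, c(h, w, nt)), scene$frame_interval, "dapi"),
    sytox = video_stack(array(sy, c(h, w, nt)), scene$frame_interval, "sytox"),
    truth = truth
  )
}

#' Per-frame multiplicative drift profiles
#'
#' Stress inputs for the background-rescaling stage: global contrast drift
#' that the normalization must cancel.
#'
#' @param kind `"none"` (all ones), `"linear"` (monotone ramp from
#'   `1 - magnitude` to `1 + magnitude`) or `"sinusoid"` (one period within
#'   `1 +/- magnitude`).
#' @param n_frames Number of frames.
#' @param magnitude Relative drift amplitude in `[0, 1)`.
#' @return Numeric vector of length `n_frames`, all values in
#'   `[1 - magnitude, 1 + magnitude]`.
#' @examples
#' drift_profile("linear", 5, 0.2)
#' @export
drift_profile <- function(kind = c("none", "linear", "sinusoid"),
                          n_frames, magnitude = 0) {
  kind <- match.arg(kind)
  if (magnitude < 0 || magnitude >= 1) abort("drift magnitude must be in [0, 1)")
  switch(kind,
    none = rep(1, n_frames),
    linear = seq(1 - magnitude, 1 + magnitude, length.out = n_frames),
    sinusoid = 1 + magnitude * sin(2 * pi * (seq_len(n_frames) - 1) / n_frames)
  )
}

#' Lay out a random non-overlapping scene
#'
#' Places the requested numbers of netotic, necrotic and quiescent cells at
#' random non-overlapping positions (rejection sampling) and returns the
#' scene. Areas are drawn uniformly inside the census gates: nuclei in
#' 1000-4000 px, necrotic lysed footprints in 5000-10000 px. Netotic onset
#' times are drawn from `onset_range`.
#'
#' @param n_netotic,n_necrotic,n_quiescent Cell counts.
#' @param height,width,n_frames,frame_interval Field geometry; see
#'   [synthetic_scene()].
#' @param decay_half_life True NET decay half-life in minutes (all netotic
#'   cells).
#' @param onset_range Min/max lysis onset in minutes.
#' @param netotic_lysed_area Sytox footprint of a netotic cell in px.
#' @param seed Integer seed controlling both layout and rendering noise.
#' @param ... Passed on to [synthetic_scene()] (noise, drift, ...).
#' @return A [synthetic_scene()].
#' @export
random_scene <- function(n_netotic, n_necrotic, n_quiescent = 0,
                         height = 256, width = 256, n_frames = 61,
                         frame_interval = 15,
                         decay_half_life = 360,
                         onset_range = c(30, 90),
                         netotic_lysed_area = 2500,
                         seed = 1L, ...) {
  .with_seed(seed + 1L, {
    # place large (necrotic) footprints first; restart the whole layout if a
    # crowded draw cannot be completed
    kinds <- c(rep("necrotic", n_necrotic), rep("netotic", n_netotic),
               rep("quiescent", n_quiescent))
    cells <- NULL
    for (attempt in 1:25) {
      placed <- list()
      radii <- numeric(0)
      cells <- NULL
      failed <- FALSE
      for (k in kinds) {
        kernel_area <- runif(1, 1200, 3800)
        lysed_area <- switch(k,
          netotic = netotic_lysed_area,
          necrotic = runif(1, 5500, 9500),
          quiescent = NA_real_)
        rad <- sqrt(max(kernel_area, lysed_area, na.rm = TRUE) / pi) + 2
        ok <- FALSE
        for (try in 1:500) {
          cr <- runif(1, rad + 1, height - rad)
          cc <- runif(1, rad + 1, width - rad)
          if (length(placed) == 0 ||
              all(sqrt((cr - vapply(placed, `[`, 0, 1))^2 +
                       (cc - vapply(placed, `[`, 0, 2))^2) > rad + radii + 1)) {
            ok <- TRUE; break
          }
        }
        if (!ok) { failed <- TRUE; break }
        placed[[length(placed) + 1]] <- c(cr, cc)
        radii <- c(radii, rad)
        row <- cell_spec(k, cr, cc, kernel_area = kernel_area,
                         lysed_area = if (is.na(lysed_area)) 2500 else lysed_area,
                         onset_time = runif(1, onset_range[1], onset_range[2]),
                         decay_half_life = if (k == "netotic") decay_half_life else NA_real_)
        cells <- if (is.null(cells)) row else dplyr::bind_rows(cells, row)
      }
      if (!failed) break
      cells <- NULL
    }
    if (is.null(cells) && length(kinds) > 0) {
      abort("could not place all cells without overlap; enlarge the field")
    }
    if (is.null(cells)) cells <- cell_spec("netotic", 1, 1, decay_half_life = 180)[0, ]
    synthetic_scene(height, width, n_frames, frame_interval = frame_interval,
                    cells = cells, seed = seed, ...)
  })
}
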