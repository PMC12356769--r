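#' Label connected components of a binary mask
#'
#' Connected-component labelling with selectable 4- or 8-connectivity, built
#' on [igraph::components()] over the pixel adjacency graph of the foreground.
#'
#' @param mask Logical (or 0/1) H x W matrix.
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal).
#' @return Integer H x W matrix: 0 background, 1..k component ids. Ids are
#'   assigned in first-pixel (column-major) order, but all component
#'   statistics are invariant to id permutation.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  out <- matrix(0L, h, w)
  if (length(fg) == 0) return(out)
  id <- integer(h * w)
  id[fg] <- seq_along(fg)
  edge_pairs <- function(dr, dc) {
    r <- (fg - 1L) %% h + 1L
    c <- (fg - 1L) %/% h + 1L
    r2 <- r + dr; c2 <- c + dc
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    src <- fg[ok]
    keep <- mask[nb]
    cbind(id[src[keep]], id[nb[keep]])
  }
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(shifts, function(s) edge_pairs(s[1], s[2])))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # renumber in first-occurrence (column-major) order for determinism
  out[fg] <- match(comp, unique(comp))
  out
}

#' Count components within an area gate
#'
#' Counts connected components of the mask whose pixel area lies inside the
#' inclusive `[min, max]` bounds. An empty mask counts 0 components (not an
#' error).
#'
#' @param mask Logical H x W matrix.
#' @param area_bounds Length-2 inclusive pixel-area interval.
#' @param connectivity 4 or 8.
#' @return Integer count.
#' @export
count_components <- function(mask, area_bounds, connectivity = 8) {
  stopifnot(length(area_bounds) == 2, area_bounds[1] < area_bounds[2])
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0) return(0L)
  areas <- tabulate(lab[lab > 0])
  sum(areas >= area_bounds[1] & areas <= area_bounds[2])
}

#' Initial cell count from the first DAPI frame
#'
#' Otsu-thresholds frame 0 of the DAPI (membrane-permeable stain) channel and
#' counts foreground components whose area falls inside the nucleus gate
#' (default 1000-4000 px). Counting is invariant to global intensity scaling
#' of the frame.
#'
#' @param dapi DAPI [video_stack()].
#' @param cfg A [run_config()] supplying `kernel_area_bounds` and
#'   `connectivity`.
#' @return Integer count of valid cell kernels.
#' @export
initial_cell_count <- function(dapi, cfg = run_config()) {
  stopifnot(inherits(dapi, "video_stack"))
  fr <- dapi$data[, , 1]
  th <- .frame_otsu(fr)
  if (is.na(th)) abort("degenerate DAPI frame 0: zero range or trivial Otsu split")
  count_components(fr > th, cfg$kernel_area_bounds, cfg$connectivity)
}

#' Necrotic cell count from the classification
#'
#' Counts connected components of the necrotic-labelled region whose area
#' falls inside the necrotic gate (default 5000-10000 px).
#'
#' @param labels A `pixel_class_map`.
#' @param cfg A [run_config()].
#' @return Integer count.
#' @export
necrotic_cell_count <- function(labels, cfg = run_config()) {
  stopifnot(inherits(labels, "pixel_class_map"))
  count_components(labels == 2L, cfg$necrotic_area_bounds, cfg$connectivity)
}

#' Full cell census of one field of view
#'
#' Combines the frame-0 DAPI count with the necrotic count and derives the
#' netotic count under the simplifying assumption that every initial cell
#' resolves to either a NET or a necrotic cell:
#' `netotic = max(initial - necrotic, 0)` (floored at zero with a warning,
#' since noise can push the necrotic count above the initial one).
#'
#' @param dapi DAPI [video_stack()].
#' @param labels A `pixel_class_map`.
#' @param cfg A [run_config()].
#' @return One-row tibble: initial_cells, necrotic_cells, netotic_cells.
#' @export
cell_census <- function(dapi, labels, cfg = run_config()) {
  initial <- initial_cell_count(dapi, cfg)
  necrotic <- necrotic_cell_count(labels, cfg)
  netotic <- initial - necrotic
  if (netotic < 0) {
    warn(sprintf("necrotic count (%d) exceeds initial count (%d): netotic floored at 0",
                 necrotic, initial))
    netotic <- 0L
  }
  tibble(initial_cells = initial, necrotic_cells = necrotic,
         netotic_cells = as.integer(netotic))
}

#' Net span: total NET area per netotic cell
#'
#' Divides the total netotic pixel coverage by the estimated number of
#' netotic cells. Because released NETs often overlap, this value
#' systematically underestimates the true per-cell NET extent; the result
#' carries an `underestimate` flag to keep that caveat attached to the
#' number.
#'
#' @param labels A `pixel_class_map`.
#' @param census One-row tibble from [cell_census()] (or anything with a
#'   `netotic_cells` column).
#' @return One-row tibble: total_net_area_px, netotic_cells,
#'   span_px_per_cell, underestimate (always TRUE).
#' @export
net_span <- function(labels, census) {
  stopifnot(inherits(labels, "pixel_class_map"))
  n_net <- census$netotic_cells[1]
  if (is.na(n_net) || n_net <= 0) {
    abort("net span undefined: zero netotic cells estimated")
  }
  total <- sum(labels == 1L)
  tibble(total_net_area_px = as.integer(total),
         netotic_cells = as.integer(n_net),
         span_px_per_cell = total / n_net,
         underestimate = TRUE)
}
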