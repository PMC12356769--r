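cfg <- run_config()

test_that("area-gated component counting matches the rasterized-disk oracle", {
  m <- matrix(FALSE, 200, 260)
  r1500 <- sqrt(1500 / pi)
  m <- m | disk_mask(200, 260, 40, 40, r1500) | disk_mask(200, 260, 40, 150, r1500) |
    disk_mask(200, 260, 150, 40, r1500) | disk_mask(200, 260, 150, 150, sqrt(500 / pi))
  expect_equal(count_components(m, c(1000, 4000), 8), 3L)

  big <- disk_mask(200, 260, 100, 130, sqrt(12000 / pi))
  expect_equal(count_components(big, c(5000, 10000), 8), 0L)

  expect_equal(count_components(matrix(FALSE, 5, 5), c(1, 10), 8), 0L)
})

test_that("diagonal touching merges under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE
  m[5:7, 5:7] <- TRUE   # touches the first block only at the (4,4)/(5,5) diagonal
  lab8 <- label_components(m, 8)
  lab4 <- label_components(m, 4)
  expect_equal(max(lab8), 1L)
  expect_equal(max(lab4), 2L)
  expect_equal(count_components(m, c(1, 100), 8), 1L)
  expect_equal(count_components(m, c(1, 100), 4), 2L)
})

test_that("4-connectivity labelling agrees with EBImage::bwlabel", {
  withr::with_seed(12, {
    for (i in 1:5) {
      m <- matrix(stats::runif(900) > 0.6, 30, 30)
      ours <- label_components(m, 4)
      ref <- EBImage::bwlabel(m * 1)
      # same partition: component id maps are a relabelling of each other
      expect_equal(max(ours), max(ref))
      key <- paste(ours[m], ref[m])
      expect_equal(length(unique(key)), max(ref))
    }
  })
})

test_that("component counts are invariant to labelling order and isolated pixels work", {
  m <- matrix(FALSE, 8, 8); m[1, 1] <- TRUE; m[8, 8] <- TRUE; m[4, 5] <- TRUE
  expect_equal(max(label_components(m, 4)), 3L)
  expect_equal(count_components(m, c(1, 2), 4), 3L)
  # flipping the mask through transpose permutes component order, not counts
  expect_equal(count_components(t(m), c(1, 2), 4), 3L)
})

test_that("initial census counts gated nuclei from DAPI frame 0", {
  sc <- random_scene(n_netotic = 6, n_necrotic = 4, n_quiescent = 0,
                     height = 400, width = 400, n_frames = 5,
                     decay_half_life = 180, background_noise_sd = 0, seed = 8)
  vid <- generate_video(sc)
  expect_equal(initial_cell_count(vid$dapi, cfg), 10L)

  blank <- video_stack(array(3, c(10, 10, 3)))
  expect_error(initial_cell_count(blank, cfg), "degenerate")

  # an oversized nucleus is logged out of the gate
  sc1 <- synthetic_scene(160, 160, 4,
    cells = cell_spec("necrotic", 80, 80, kernel_area = 6000, lysed_area = 7000),
    background_noise_sd = 0, seed = 2)
  vid1 <- generate_video(sc1)
  expect_equal(initial_cell_count(vid1$dapi, cfg), 0L)

  # Otsu scale covariance: a global gain changes nothing
  scaled <- vid$dapi; scaled$data <- scaled$data * 7.3
  expect_equal(initial_cell_count(scaled, cfg), 10L)
})

test_that("necrotic counts come from gated components of the label map", {
  lab <- matrix(0L, 300, 300)
  d1 <- disk_mask(300, 300, 70, 70, sqrt(7000 / pi))
  d2 <- disk_mask(300, 300, 200, 200, sqrt(7000 / pi))
  lab[d1 | d2] <- 2L
  pcm <- structure(lab, class = c("pixel_class_map", "matrix", "array"))
  expect_equal(necrotic_cell_count(pcm, cfg), 2L)

  small <- matrix(0L, 120, 120)
  small[disk_mask(120, 120, 60, 60, sqrt(4000 / pi))] <- 2L
  pcm2 <- structure(small, class = c("pixel_class_map", "matrix", "array"))
  expect_equal(necrotic_cell_count(pcm2, cfg), 0L)

  none <- structure(matrix(0L, 10, 10), class = c("pixel_class_map", "matrix", "array"))
  expect_equal(necrotic_cell_count(none, cfg), 0L)
})

test_that("net span divides total NET coverage by the netotic count", {
  lab <- matrix(0L, 200, 200)
  lab[1:120, 1:100] <- 1L  # 12000 netotic px
  pcm <- structure(lab, class = c("pixel_class_map", "matrix", "array"))
  census <- tibble::tibble(initial_cells = 6L, necrotic_cells = 2L, netotic_cells = 4L)
  sp <- net_span(pcm, census)
  expect_equal(sp$span_px_per_cell, 3000)
  expect_true(sp$underestimate)

  empty <- structure(matrix(0L, 10, 10), class = c("pixel_class_map", "matrix", "array"))
  sp0 <- net_span(empty, tibble::tibble(netotic_cells = 2L))
  expect_equal(sp0$span_px_per_cell, 0)

  expect_error(net_span(pcm, tibble::tibble(netotic_cells = 0L)), "undefined")
})

test_that("zero-noise scenes yield an exact census and a faithful net span", {
  sc <- random_scene(n_netotic = 5, n_necrotic = 3, height = 420, width = 420,
                     n_frames = 21, decay_half_life = 180,
                     background_noise_sd = 0, seed = 14)
  vid <- generate_video(sc)
  out <- classify_video(vid$sytox, cfg)
  census <- cell_census(vid$dapi, out$labels, cfg)
  expect_equal(census$initial_cells, 8L)
  expect_equal(census$necrotic_cells, 3L)
  expect_equal(census$netotic_cells, 5L)

  sp <- net_span(out$labels, census)
  true_mean_fp <- mean(vid$truth$cells$sytox_px[vid$truth$cells$kind == "netotic"])
  expect_lt(abs(sp$span_px_per_cell - true_mean_fp) / true_mean_fp, 0.15)
})
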