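# shared fixtures: small scenes and stacks built in code

# wrap a pixels-last array or per-pixel trace list into a video_stack
stack_from_traces <- function(traces, frame_interval = 15) {
  # traces: list of numeric vectors (one per pixel) laid out on a 1 x n grid
  nt <- length(traces[[1]])
  arr <- array(0, c(1, length(traces), nt))
  for (i in seq_along(traces)) arr[1, i, ] <- traces[[i]]
  video_stack(arr, frame_interval = frame_interval)
}

# uniform random rescaled-like stack for classifier property tests
random_stack <- function(h, w, nt, max_val = 12, seed = 1) {
  withr::with_seed(seed, {
    video_stack(array(runif(h * w * nt, 0, max_val), c(h, w, nt)),
                frame_interval = 15)
  })
}

# two-cell scene (one netotic, one necrotic) used across modules
demo_scene <- function(noise_sd = 5, n_frames = 41, half_life = 180,
                       drift = rep(1, n_frames), seed = 11) {
  cells <- rbind(
    cell_spec("netotic", 60, 60, kernel_area = 2000, lysed_area = 2500,
              onset_time = 60, decay_half_life = half_life),
    cell_spec("necrotic", 170, 170, kernel_area = 2000, lysed_area = 7000,
              onset_time = 60)
  )
  synthetic_scene(230, 230, n_frames, cells = cells,
                  background_noise_sd = noise_sd, drift = drift, seed = seed)
}

# rasterized disk mask oracle, independent of the generator internals
disk_mask <- function(h, w, cr, cc, radius) {
  rr <- matrix(seq_len(h), h, w)
  cc_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - cr)^2 + (cc_ - cc)^2 <= radius^2
}
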