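# Shared fixtures: everything is generated in code at test time.

quiet_sensor <- function(width = 16, height = 16, dI = 0.1) {
  sensor_model(width = width, height = height, contrast_threshold = dI,
               noise_rate = 0)
}

# a small but complete architecture for orchestration tests
small_config <- function(seed = 1, n_esn = 4, ...) {
  arch_config(n_esn = n_esn, n_neurons = 10,
              sensor = sensor_model(width = 64, height = 64),
              cell_size = 5, rf_half_extent = 5, seed = seed, ...)
}

# random valid event stream on a small sensor
random_stream <- function(n = 200, width = 16, height = 16, t_max = 5e4,
                          seed = 1) {
  set.seed(seed)
  event_stream(data.frame(
    t_us = sort(floor(runif(n, 0, t_max))),
    x = floor(runif(n, 0, width)),
    y = floor(runif(n, 0, height)),
    p = sample(c(-1, 1), n, replace = TRUE)),
    width = width, height = height)
}

# Independent dense-grid oracle for the event-generation model: sequential
# per-pixel threshold crossing on the sampled luminance trace (no
# interpolation refinements, no vectorization shared with the implementation).
oracle_events_1px <- function(lum, dI) {
  ref <- lum[1]
  n_on <- 0L
  n_off <- 0L
  for (v in lum[-1]) {
    while (v - ref >= dI - 1e-12) {
      n_on <- n_on + 1L
      ref <- ref + dI
    }
    while (ref - v >= dI - 1e-12) {
      n_off <- n_off + 1L
      ref <- ref - dI
    }
  }
  c(on = n_on, off = n_off)
}
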