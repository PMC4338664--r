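test_that("constant luminance emits no events", {
  sm <- quiet_sensor(4, 4)
  frames <- array(0.7, dim = c(4, 4, 50))
  ev <- luminance_to_events(frames, seq(0, 0.049, by = 0.001), sm)
  expect_equal(nrow(ev), 0)
})

test_that("a step of exactly two thresholds emits two ON events", {
  sm <- quiet_sensor(2, 1, dI = 0.1)
  frames <- array(0, dim = c(1, 2, 3))
  frames[1, 1, 2:3] <- 0.2
  ev <- luminance_to_events(frames, c(0, 0.001, 0.002), sm)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$p == 1))
  expect_true(all(ev$x == 0 & ev$y == 0))
})

test_that("a linear ramp matches the dense-grid crossing oracle", {
  dI <- 0.1
  sm <- quiet_sensor(1, 1, dI = dI)
  for (k in c(0.35, 0.61, 1.0)) {
    t_grid <- seq(0, 1, by = 1e-4)
    lum <- k * t_grid
    frames <- array(lum, dim = c(1, 1, length(t_grid)))
    ev <- luminance_to_events(frames, t_grid, sm)
    orc <- oracle_events_1px(lum, dI)
    expect_equal(nrow(ev), floor(k * 1 / dI + 1e-9))
    expect_equal(sum(ev$p == 1), unname(orc["on"]))
    # crossings of a constant-slope ramp are equally spaced
    if (nrow(ev) > 2) {
      expect_lt(diff(range(diff(ev$t_us))), 3)  # within us rounding
    }
  }
  # a down ramp gives OFF events
  t_grid <- seq(0, 1, by = 1e-4)
  frames <- array(1 - 0.45 * t_grid, dim = c(1, 1, length(t_grid)))
  ev <- luminance_to_events(frames, t_grid, sm)
  expect_equal(nrow(ev), 4)
  expect_true(all(ev$p == -1))
})

test_that("non-finite luminance is rejected", {
  sm <- quiet_sensor(2, 2)
  frames <- array(0, dim = c(2, 2, 2))
  frames[1, 1, 2] <- NaN
  expect_error(luminance_to_events(frames, c(0, 1e-3), sm), "finite")
})

test_that("event generation is translation-equivariant", {
  sm <- quiet_sensor(10, 10, dI = 0.1)
  set.seed(42)
  core <- array(cumsum(rnorm(4 * 4 * 30, sd = 0.08)), dim = c(4, 4, 30))
  base <- array(0, dim = c(10, 10, 30))
  base[2:5, 2:5, ] <- core
  shifted <- array(0, dim = c(10, 10, 30))
  shifted[4:7, 5:8, ] <- core  # dy = 2, dx = 3
  times <- seq(0, 0.029, by = 1e-3)
  ev0 <- luminance_to_events(base, times, sm)
  ev1 <- luminance_to_events(shifted, times, sm)
  moved <- as.data.frame(ev0)
  moved$x <- moved$x + 3
  moved$y <- moved$y + 2
  expect_equal(as.data.frame(ev1), moved, ignore_attr = TRUE)
})

test_that("a bar sweeping outside the field of view leaves no events", {
  sm <- quiet_sensor(32, 32, dI = 0.14)
  spec <- stimulus_bar(30, speed = 100, duration = 0.5)
  ev <- simulate_moving_bar(spec, sm, sweep_from = 200, sweep_to = 300)
  expect_equal(nrow(ev), 0)
})

test_that("bar events stay inside the swept envelope dilated by one pixel", {
  sm <- quiet_sensor(32, 32, dI = 0.14)
  for (ang in c(0, 45, 110)) {
    spec <- stimulus_bar(ang, speed = 150, duration = 1)
    ev <- simulate_moving_bar(spec, sm, sweep_from = -6, sweep_to = 6)
    expect_gt(nrow(ev), 0)
    th <- ang * pi / 180
    cp <- -(ev$x - 15.5) * sin(th) + (ev$y - 15.5) * cos(th)
    reach <- spec$bar_width / 2 + 0.5
    expect_true(all(cp >= -6 - reach - 1 & cp <= 6 + reach + 1))
  }
})

test_that("doubling the speed over a fixed traversal halves the time span", {
  sm <- quiet_sensor(32, 32, dI = 0.14)
  ev1 <- simulate_moving_bar(stimulus_bar(0, speed = 50, duration = 2), sm,
                             sweep_from = -20, sweep_to = 20)
  ev2 <- simulate_moving_bar(stimulus_bar(0, speed = 100, duration = 2), sm,
                             sweep_from = -20, sweep_to = 20)
  expect_equal(nrow(ev1), nrow(ev2))
  expect_equal(diff(range(ev1$t_us)) / diff(range(ev2$t_us)), 2,
               tolerance = 1e-3)
})

test_that("analytic bar events match the frame-rendered sensor front end", {
  # same geometric luminance profile, rendered at 0.1 ms and passed through
  # luminance_to_events, versus the closed-form crossing times
  sm <- quiet_sensor(16, 16, dI = 0.14)
  spec <- stimulus_bar(30, speed = 100, duration = 0.5)
  sweep <- c(-13, 12)  # start beyond every pixel: no partial coverage at t = 0
  ev_a <- simulate_moving_bar(spec, sm, sweep_from = sweep[1],
                              sweep_to = sweep[2])
  th <- spec$orientation * pi / 180
  xs <- (0:15) - 7.5
  ys <- (0:15) - 7.5
  cp <- outer(ys, xs, function(y, x) -x * sin(th) + y * cos(th))
  hw <- spec$bar_width / 2
  profile <- function(d) pmin(pmax((hw + 0.5 - abs(d)) / 1, 0), 1)
  times <- seq(0, spec$duration, by = 1e-4)
  frames <- vapply(times, function(t) {
    spec$contrast * profile(cp - (sweep[1] + spec$speed * t))
  }, matrix(0, 16, 16))
  ev_f <- luminance_to_events(frames, times, sm)
  key <- function(e) {
    d <- as.data.frame(e)[c("x", "y", "p")]
    d <- d[order(d$x, d$y, d$p), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(nrow(ev_a), nrow(ev_f))
  expect_equal(key(ev_a), key(ev_f))
  # timestamps agree to the frame quantization (compare per-pixel sorted)
  srt <- function(e) {
    d <- as.data.frame(e)
    d[order(d$x, d$y, d$p, d$t_us), "t_us"]
  }
  expect_lt(max(abs(srt(ev_a) - srt(ev_f))), 150)
})

test_that("jitter with zero amplitude emits nothing; equal seeds agree", {
  sm <- sensor_model(width = 64, height = 64, noise_rate = 0)
  bm <- digit_bitmap(3, scale = 3)
  still <- stimulus_bitmap(bm, jitter_amplitude = 0, jitter_rate = 50,
                           duration = 0.3)
  expect_equal(nrow(simulate_jittered_pattern(still, sm, seed = 1)), 0)
  spec <- stimulus_bitmap(bm, jitter_amplitude = 2, jitter_rate = 50,
                          duration = 0.3)
  e1 <- simulate_jittered_pattern(spec, sm, seed = 9)
  e2 <- simulate_jittered_pattern(spec, sm, seed = 9)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_gt(nrow(e1), 0)
})

test_that("jitter events stay within the amplitude-dilated pattern edge", {
  sm <- sensor_model(width = 64, height = 64, noise_rate = 0)
  bm <- digit_bitmap(7, scale = 3)
  amp <- 2
  spec <- stimulus_bitmap(bm, jitter_amplitude = amp, jitter_rate = 50,
                          duration = 0.4)
  ev <- simulate_jittered_pattern(spec, sm, seed = 4)
  # centred pattern foreground, dilated by amp + 1 (edge + max displacement)
  oy <- floor((64 - (nrow(bm) + 2 * amp)) / 2) + amp
  ox <- floor((64 - (ncol(bm) + 2 * amp)) / 2) + amp
  fg <- which(bm == 1, arr.ind = TRUE)
  ok <- vapply(seq_len(nrow(ev)), function(i) {
    any(abs(ev$x[i] - (ox + fg[, 2] - 1)) <= amp + 1 &
          abs(ev$y[i] - (oy + fg[, 1] - 1)) <= amp + 1)
  }, logical(1))
  expect_true(all(ok))
})

test_that("oversized bitmaps are rejected", {
  sm <- sensor_model(width = 16, height = 16, noise_rate = 0)
  bm <- matrix(1L, 20, 20)
  expect_error(simulate_jittered_pattern(
    stimulus_bitmap(bm, duration = 0.1), sm), "larger than sensor")
})

test_that("event CSV round-trips losslessly and rejects malformed files", {
  st <- random_stream(n = 300, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(st, path)
  back <- read_events(path, width = 16, height = 16)
  expect_identical(as.data.frame(back), as.data.frame(st))
  expect_identical(sensor_geometry(back), sensor_geometry(st))

  # decreasing timestamps -> error naming the line
  writeLines(c("t_us,x,y,p", "100,0,0,1", "50,1,1,-1"), path)
  expect_error(read_events(path, 16, 16), "line 3")
  # x == width violates the half-open coordinate contract
  writeLines(c("t_us,x,y,p", "100,16,0,1"), path)
  expect_error(read_events(path, 16, 16), "line 2")
  # invalid polarity
  writeLines(c("t_us,x,y,p", "100,3,3,0"), path)
  expect_error(read_events(path, 16, 16), "polarity")
})

test_that("noise-only event counts are Poisson across windows", {
  sm <- sensor_model(width = 16, height = 16, noise_rate = 2)
  set.seed(2024)
  ev <- simulate_noise(sm, duration = 12)
  win <- floor(ev$t_us / 1e4)                   # 10 ms windows
  counts <- tabulate(win + 1, nbins = 1200)
  mu <- sm$noise_rate * 16 * 16 * 0.01
  kmax <- 12
  obs <- c(vapply(0:(kmax - 1), function(k) sum(counts == k), numeric(1)),
           sum(counts >= kmax))
  prob <- c(dpois(0:(kmax - 1), mu), 1 - ppois(kmax - 1, mu))
  gof <- suppressWarnings(chisq.test(obs, p = prob))
  expect_gt(gof$p.value, 0.01)
  # mean count near the nominal rate
  expect_equal(mean(counts), mu, tolerance = 0.1)
})

test_that("digit bitmaps load and scale", {
  bm <- digit_bitmap(8, scale = 1)
  expect_equal(dim(bm), c(7, 5))
  expect_true(all(bm %in% 0:1))
  big <- digit_bitmap(8, scale = 4)
  expect_equal(dim(big), c(28, 20))
  expect_equal(sum(big), 16 * sum(bm))
})

test_that("event_stream enforces its invariants", {
  expect_error(event_stream(data.frame(t_us = 1, x = -1, y = 0, p = 1),
                            16, 16), "coordinates")
  expect_error(event_stream(data.frame(t_us = 1, x = 0, y = 0, p = 2),
                            16, 16), "polarity")
  expect_error(event_stream(data.frame(t_us = -5, x = 0, y = 0, p = 1),
                            16, 16), "timestamp")
  # unsorted input is sorted on construction
  st <- event_stream(data.frame(t_us = c(30, 10), x = 0:1, y = 0, p = 1),
                     16, 16)
  expect_equal(st$t_us, c(10, 30))
})
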