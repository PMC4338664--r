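#' Convert a log-luminance movie into address events
#'
#' Emulates the pixel front end of a change-based vision sensor. Each pixel
#' keeps the log-luminance level at its last emitted event; whenever the
#' current level differs from that reference by at least the contrast
#' threshold, one event per threshold step is emitted (ON for increases, OFF
#' for decreases), with the crossing time interpolated linearly between frame
#' samples and rounded to the microsecond.
#'
#' @param frames numeric array of dimension `c(height, width, n_frames)`
#'   holding log-luminance samples; all values must be finite.
#' @param times frame sample times in seconds, strictly increasing,
#'   `length(times) == n_frames`.
#' @param sensor a [sensor_model()] (geometry must match `frames`). The
#'   model's `noise_rate` is not applied here; see [simulate_noise()].
#' @return An [event_stream()].
#' @examples
#' sm <- sensor_model(width = 2, height = 1, contrast_threshold = 0.1)
#' frames <- array(c(0, 0, 0.25, 0), dim = c(1, 2, 2))
#' luminance_to_events(frames, c(0, 0.001), sm)  # two ON events at pixel 0,0
#' @export
luminance_to_events <- function(frames, times, sensor) {
  stopifnot(inherits(sensor, "sensor_model"), is.array(frames),
            length(dim(frames)) == 3)
  d <- dim(frames)
  if (d[1] != sensor$height || d[2] != sensor$width) {
    abort("frame geometry does not match sensor")
  }
  if (length(times) != d[3] || any(diff(times) <= 0)) {
    abort("times must be strictly increasing, one per frame")
  }
  if (!all(is.finite(frames))) abort("non-finite log-luminance values")
  dI <- sensor$contrast_threshold
  h <- d[1]
  l_ref <- frames[, , 1]
  out <- vector("list", d[3])
  for (f in seq_len(d[3])[-1]) {
    l_prev <- frames[, , f - 1]
    l_cur <- frames[, , f]
    dev <- l_cur - l_ref
    n_ev <- floor(abs(dev) / dI + 1e-9)
    idx <- which(n_ev > 0)
    if (length(idx)) {
      reps <- n_ev[idx]
      pix <- rep(idx, reps)
      sgn <- rep(sign(dev[idx]), reps)
      j <- sequence(reps)
      lev <- l_ref[pix] + j * dI * sgn
      slope <- l_cur[pix] - l_prev[pix]
      frac <- ifelse(slope == 0, 1, (lev - l_prev[pix]) / slope)
      frac <- pmin(pmax(frac, 0), 1)
      t_ev <- times[f - 1] + frac * (times[f] - times[f - 1])
      out[[f]] <- tibble(
        t_us = round(t_ev * 1e6),
        x = (pix - 1L) %/% h,
        y = (pix - 1L) %% h,
        p = sgn)
      l_ref[idx] <- l_ref[idx] + n_ev[idx] * dI * sign(dev[idx])
    }
  }
  ev <- dplyr::bind_rows(out)
  if (!nrow(ev)) ev <- tibble(t_us = double(), x = double(), y = double(),
                              p = double())
  event_stream(ev, sensor$width, sensor$height)
}

#' Background sensor noise
#'
#' Stationary Poisson background activity: the total event count over the
#' interval is Poisson with mean `noise_rate * duration * width * height`,
#' with uniform times, uniform pixel addresses and fair random polarity.
#'
#' @param sensor a [sensor_model()].
#' @param duration interval length in seconds.
#' @param t0_us timestamp offset in microseconds.
#' @return An [event_stream()]. Uses the current RNG state.
#' @export
simulate_noise <- function(sensor, duration, t0_us = 0) {
  stopifnot(duration >= 0)
  n <- rpois(1, sensor$noise_rate * duration * sensor$width * sensor$height)
  ev <- tibble(
    t_us = round(t0_us + sort(runif(n, 0, duration)) * 1e6),
    x = floor(runif(n, 0, sensor$width)),
    y = floor(runif(n, 0, sensor$height)),
    p = sample(c(-1, 1), n, replace = TRUE))
  event_stream(ev, sensor$width, sensor$height)
}

#' Merge event streams
#'
#' @param ... event streams sharing one sensor geometry.
#' @return A single time-sorted [event_stream()].
#' @export
merge_streams <- function(...) {
  streams <- list(...)
  stopifnot(length(streams) >= 1)
  g <- sensor_geometry(streams[[1]])
  for (s in streams) {
    if (!identical(sensor_geometry(s), g)) abort("sensor geometries differ")
  }
  ev <- dplyr::bind_rows(lapply(streams, as_tibble))
  ev <- ev[order(ev$t_us), , drop = FALSE]
  new_event_stream(ev, g[["width"]], g[["height"]])
}

# Per-pixel signed coordinate along the bar's direction of motion.
bar_perp_coord <- function(spec, sensor) {
  th <- spec$orientation * pi / 180
  nrm <- c(-sin(th), cos(th))
  xs <- seq_len(sensor$width) - 1
  ys <- seq_len(sensor$height) - 1
  cx <- (sensor$width - 1) / 2
  cy <- (sensor$height - 1) / 2
  outer(ys - cy, xs - cx, function(y, x) x * nrm[1] + y * nrm[2])
}

#' Simulate a moving oriented bar
#'
#' The bar is an infinite stripe (spanning the field of view along its axis)
#' of thickness `bar_width` with 1-pixel soft edges, translating along its
#' normal at constant speed. Each pixel therefore sees a trapezoidal
#' log-luminance pulse per pass, and the exact threshold-crossing times are
#' solved in closed form: a pixel emits `floor(contrast / threshold)` ON
#' events while the leading edge crosses it and the same number of OFF events
#' for the trailing edge. Poisson background noise is merged in afterwards.
#'
#' @param spec a [stimulus_bar()].
#' @param sensor a [sensor_model()].
#' @param seed integer seed (drives the noise draw only; the signal is
#'   deterministic).
#' @param sweep_from,sweep_to optional perpendicular start/end offsets of the
#'   bar centre, in pixels relative to the sensor centre. The default sweeps
#'   the whole field of view cyclically (one pass, a blank gap of
#'   `spec$gap_px`, then the next pass) for the full duration.
#' @return An [event_stream()].
#' @export
simulate_moving_bar <- function(spec, sensor, seed = 1,
                                sweep_from = NULL, sweep_to = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"), spec$kind == "bar",
            inherits(sensor, "sensor_model"))
  if (sensor$width < 1 || sensor$height < 1) abort("zero-size sensor")
  dI <- sensor$contrast_threshold
  k_ev <- floor(spec$contrast / dI + 1e-9)
  cp <- as.vector(bar_perp_coord(spec, sensor))
  hw <- spec$bar_width / 2
  reach <- hw + 0.5   # soft edge extends 0.5 px beyond the half-width
  auto <- is.null(sweep_from)
  if (auto) {
    sweep_from <- min(cp) - reach
    sweep_to <- max(cp) + reach
  }
  sig <- tibble(t_us = double(), x = double(), y = double(), p = double())
  if (spec$speed > 0 && spec$duration > 0 && k_ev > 0) {
    s <- spec$speed
    cycle_s <- if (auto) ((sweep_to - sweep_from) + spec$gap_px) / s else 0
    n_pass <- if (auto) max(1, ceiling(spec$duration / cycle_s)) else 1
    h <- sensor$height
    # pixel is crossed only if it lies inside the swept perpendicular band
    hit <- which(cp - reach <= sweep_to & cp + reach >= sweep_from)
    if (length(hit)) {
      ramp <- (seq_len(k_ev) * dI / spec$contrast) / s  # within-edge offsets
      one_edge <- function(t_start, pol) {
        tibble(t_us = rep(t_start, each = k_ev) + ramp,
               pix = rep(hit, each = k_ev),
               p = pol)
      }
      passes <- lapply(seq_len(n_pass) - 1, function(m) {
        # leading edge starts when the bar front reaches the pixel
        t_on <- (cp[hit] - reach - sweep_from) / s + m * cycle_s
        t_off <- (cp[hit] + (hw - 0.5) - sweep_from) / s + m * cycle_s
        dplyr::bind_rows(one_edge(t_on, 1), one_edge(t_off, -1))
      })
      ev <- dplyr::bind_rows(passes)
      ev <- ev[ev$t_us >= 0 & ev$t_us <= spec$duration, , drop = FALSE]
      sig <- tibble(t_us = round(ev$t_us * 1e6),
                    x = (ev$pix - 1L) %/% h,
                    y = (ev$pix - 1L) %% h,
                    p = ev$p)
    }
  }
  signal <- event_stream(sig, sensor$width, sensor$height)
  if (sensor$noise_rate > 0) {
    set.seed(seed)
    merge_streams(signal, simulate_noise(sensor, spec$duration))
  } else {
    signal
  }
}

#' Simulate a jittered static pattern
#'
#' The bitmap is held around the sensor centre and displaced by a random
#' jitter: every `1 / jitter_rate` seconds a new integer offset is drawn
#' uniformly from the square of half-side `jitter_amplitude`. The piecewise-
#' constant log-luminance movie is converted to events with
#' [luminance_to_events()] (each jump is rendered as a 0.1 ms transition),
#' then background noise is merged in. The initial appearance of the pattern
#' sets the per-pixel reference level, so an unjittered pattern emits no
#' signal events.
#'
#' @param spec a [stimulus_bitmap()].
#' @param sensor a [sensor_model()].
#' @param seed integer seed; equal seeds give identical streams.
#' @return An [event_stream()].
#' @export
simulate_jittered_pattern <- function(spec, sensor, seed = 1) {
  stopifnot(inherits(spec, "stimulus_spec"), spec$kind == "bitmap",
            inherits(sensor, "sensor_model"))
  bm <- spec$bitmap
  amp <- ceiling(spec$jitter_amplitude)
  if (nrow(bm) + 2 * amp > sensor$height || ncol(bm) + 2 * amp > sensor$width) {
    abort("bitmap (plus jitter margin) larger than sensor")
  }
  set.seed(seed)
  n_jump <- floor(spec$duration * spec$jitter_rate)
  # working subwindow around the centred pattern
  wh <- nrow(bm) + 2 * amp
  ww <- ncol(bm) + 2 * amp
  oy <- floor((sensor$height - wh) / 2)
  ox <- floor((sensor$width - ww) / 2)
  amp_i <- floor(spec$jitter_amplitude)
  offs <- cbind(dx = c(0, sample(-amp_i:amp_i, n_jump, replace = TRUE)),
                dy = c(0, sample(-amp_i:amp_i, n_jump, replace = TRUE)))
  render <- function(dx, dy) {
    fr <- matrix(0, wh, ww)
    fr[amp + dy + seq_len(nrow(bm)), amp + dx + seq_len(ncol(bm))] <-
      bm * spec$contrast
    fr
  }
  sig <- tibble(t_us = double(), x = double(), y = double(), p = double())
  if (n_jump > 0) {
    eps <- 1e-4  # each jump rendered as a 0.1 ms luminance transition
    t_jump <- seq_len(n_jump) / spec$jitter_rate
    times <- c(0, as.vector(rbind(t_jump - eps, t_jump)))
    frames <- array(0, dim = c(wh, ww, length(times)))
    frames[, , 1] <- render(0, 0)
    for (k in seq_len(n_jump)) {
      frames[, , 2 * k] <- render(offs[k, 1], offs[k, 2])       # pre-jump hold
      frames[, , 2 * k + 1] <- render(offs[k + 1, 1], offs[k + 1, 2])
    }
    sub <- sensor_model(ww, wh, sensor$contrast_threshold, noise_rate = 0)
    ev <- as_tibble(luminance_to_events(frames, times, sub))
    ev$x <- ev$x + ox
    ev$y <- ev$y + oy
    sig <- ev
  }
  signal <- event_stream(sig, sensor$width, sensor$height)
  if (sensor$noise_rate > 0) {
    merge_streams(signal, simulate_noise(sensor, spec$duration))
  } else {
    signal
  }
}
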