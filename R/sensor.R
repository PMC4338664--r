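#' Event-camera sensor model
#'
#' Parameters of the emulated change-based vision sensor. A pixel emits an
#' event whenever its log-luminance has moved by more than the contrast
#' threshold since the level at its last emitted event; ON for increases, OFF
#' for decreases. Background activity is modelled as a stationary Poisson
#' process per pixel with random polarity.
#'
#' @param width,height sensor resolution in pixels (default 128 x 128).
#' @param contrast_threshold log-luminance step per event. The default 0.14 is
#'   ln(1.15), i.e. about 15% relative contrast per event, typical for these
#'   sensors.
#' @param noise_rate background events per pixel per second (default 0.1).
#' @return A list of class `sensor_model`.
#' @export
sensor_model <- function(width = 128, height = 128,
                         contrast_threshold = 0.14, noise_rate = 0.1) {
  stopifnot(width >= 1, height >= 1, contrast_threshold > 0, noise_rate >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 contrast_threshold = contrast_threshold,
                 noise_rate = noise_rate),
            class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf(
    "<sensor_model %dx%d, contrast threshold %.3f, noise %.3g Hz/pixel>\n",
    x$width, x$height, x$contrast_threshold, x$noise_rate))
  invisible(x)
}

#' Moving-bar stimulus
#'
#' A high-contrast bar of fixed orientation translating at constant speed
#' along its normal, sweeping the field of view repeatedly (treadmill-like:
#' when the sweep completes, the next pass starts after a short blank gap).
#' Orientation is the angle of the bar's axis from the x-axis, so a bar at
#' 90 degrees is vertical and moves horizontally.
#'
#' @param orientation bar axis angle in degrees.
#' @param speed translation speed in pixels/second (default 200).
#' @param duration presentation length in seconds.
#' @param bar_width bar thickness in pixels (default 3).
#' @param contrast log-luminance amplitude of the bar. The default, ten
#'   contrast-threshold steps (1.4), makes each edge crossing of a pixel emit
#'   about ten events.
#' @param gap_px blank distance between successive sweeps (default 16).
#' @return A list of class `stimulus_spec` (kind `"bar"`).
#' @export
stimulus_bar <- function(orientation, speed = 200, duration = 1,
                         bar_width = 3, contrast = 1.4, gap_px = 16) {
  stopifnot(speed >= 0, duration >= 0, bar_width > 0, contrast > 0)
  structure(list(kind = "bar", orientation = orientation, speed = speed,
                 duration = duration, bar_width = bar_width,
                 contrast = contrast, gap_px = gap_px),
            class = "stimulus_spec")
}

#' Jittered-bitmap stimulus
#'
#' A static binary pattern held at a central position and displaced by a
#' random jitter (uniform displacements of at most `jitter_amplitude` pixels
#' around the centre, redrawn `jitter_rate` times per second). The jitter
#' emulates microsaccadic eye movements: it is what makes a static shape
#' visible to a change-based sensor.
#'
#' @param bitmap 0/1 matrix (rows = image rows), e.g. from [digit_bitmap()].
#' @param jitter_amplitude maximum displacement from centre, pixels.
#' @param jitter_rate displacements per second.
#' @param duration presentation length in seconds.
#' @param contrast log-luminance amplitude of foreground pixels.
#' @return A list of class `stimulus_spec` (kind `"bitmap"`).
#' @export
stimulus_bitmap <- function(bitmap, jitter_amplitude = 3, jitter_rate = 100,
                            duration = 1, contrast = 1.4) {
  stopifnot(is.matrix(bitmap), all(bitmap %in% 0:1),
            jitter_amplitude >= 0, jitter_rate > 0, duration >= 0,
            contrast > 0)
  structure(list(kind = "bitmap", bitmap = bitmap,
                 jitter_amplitude = jitter_amplitude,
                 jitter_rate = jitter_rate, duration = duration,
                 contrast = contrast),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  if (x$kind == "bar") {
    cat(sprintf("<stimulus: bar, %g deg, %g px/s, %g s>\n",
                x$orientation, x$speed, x$duration))
  } else {
    cat(sprintf("<stimulus: %dx%d bitmap, jitter %g px @ %g/s, %g s>\n",
                nrow(x$bitmap), ncol(x$bitmap), x$jitter_amplitude,
                x$jitter_rate, x$duration))
  }
  invisible(x)
}
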