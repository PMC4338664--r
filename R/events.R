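#' Construct an address-event stream
#'
#' An event stream is the raw output of an event camera: a time-ordered
#' sequence of address events `e(x, y, t)` with polarity `p = +1` (ON, local
#' log-luminance increase) or `p = -1` (OFF, decrease). It is represented as a
#' tibble with columns `t_us` (integer-valued microsecond timestamp), `x`, `y`
#' (0-based pixel coordinates) and `p`, carrying the sensor geometry as
#' attributes.
#'
#' @param events data frame with columns `t_us`, `x`, `y`, `p` (may have zero
#'   rows).
#' @param width,height sensor geometry in pixels; coordinates must satisfy
#'   `0 <= x < width`, `0 <= y < height`.
#' @return A tibble of class `event_stream`, sorted by `t_us`.
#' @examples
#' ev <- event_stream(data.frame(t_us = c(0, 10), x = 1:2, y = 0, p = 1),
#'                    width = 128, height = 128)
#' sensor_geometry(ev)
#' @export
event_stream <- function(events, width, height) {
  stopifnot(is.data.frame(events), width >= 1, height >= 1)
  need <- c("t_us", "x", "y", "p")
  if (!all(need %in% names(events))) {
    abort(paste0("event data must have columns ", paste(need, collapse = ", ")))
  }
  ev <- as_tibble(events)[need]
  validate_events(ev, width, height)
  ev <- ev[order(ev$t_us), , drop = FALSE]
  new_event_stream(ev, width, height)
}

new_event_stream <- function(ev, width, height) {
  attr(ev, "width") <- as.integer(width)
  attr(ev, "height") <- as.integer(height)
  class(ev) <- c("event_stream", class(tibble()))
  ev
}

validate_events <- function(ev, width, height, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) paste0("row ", i) else paste0("line ", lines[i])
  }
  bad <- which(!is.finite(ev$t_us) | ev$t_us < 0 | ev$t_us != floor(ev$t_us))
  if (length(bad)) abort(paste0("invalid timestamp at ", where(bad[1])))
  bad <- which(ev$x < 0 | ev$x >= width | ev$y < 0 | ev$y >= height |
                 ev$x != floor(ev$x) | ev$y != floor(ev$y))
  if (length(bad)) abort(paste0("coordinates outside sensor at ", where(bad[1])))
  bad <- which(abs(ev$p) != 1)
  if (length(bad)) abort(paste0("polarity must be -1 or +1 at ", where(bad[1])))
  invisible(ev)
}

#' Sensor geometry of an event stream
#' @param stream an [event_stream()].
#' @return Named integer vector `c(width, height)`.
#' @export
sensor_geometry <- function(stream) {
  c(width = attr(stream, "width"), height = attr(stream, "height"))
}

#' @export
print.event_stream <- function(x, ...) {
  g <- sensor_geometry(x)
  cat(sprintf("<event_stream: %d events, %dx%d sensor, %.3f s span>\n",
              nrow(x), g[["width"]], g[["height"]],
              if (nrow(x)) diff(range(x$t_us)) / 1e6 else 0))
  NextMethod()
}

#' Read or write the canonical event CSV
#'
#' The on-disk dialect is a UTF-8 CSV with header `t_us,x,y,p`, one event per
#' row, rows sorted by timestamp. `read_events()` rejects malformed files
#' (decreasing timestamps, out-of-range coordinates, polarity outside
#' \{-1, +1\}) with an error naming the offending line.
#'
#' @param path file path.
#' @param width,height sensor geometry the events must lie in (the CSV itself
#'   carries no geometry).
#' @return `read_events()` returns an [event_stream()]; `write_events()`
#'   invisibly returns `path`.
#' @export
read_events <- function(path, width = 128, height = 128) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ev <- read.csv(path, colClasses = "numeric")
  if (!identical(names(ev), c("t_us", "x", "y", "p"))) {
    abort("expected CSV header t_us,x,y,p")
  }
  ev <- as_tibble(ev)
  lines <- seq_len(nrow(ev)) + 1L  # header is line 1
  validate_events(ev, width, height, lines = lines)
  dec <- which(diff(ev$t_us) < 0)
  if (length(dec)) {
    abort(paste0("timestamps decrease at line ", lines[dec[1] + 1L]))
  }
  new_event_stream(ev, width, height)
}

#' @param stream an [event_stream()] to serialize.
#' @rdname read_events
#' @export
write_events <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  df <- as.data.frame(stream)[c("t_us", "x", "y", "p")]
  df[] <- lapply(df, function(col) format(col, scientific = FALSE, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an ASCII PBM (P1) bitmap
#'
#' Minimal reader for the plain portable-bitmap dialect used to ship the digit
#' stimuli: `1` bits are foreground (stimulus), `0` background.
#'
#' @param path path to a `P1` PBM file.
#' @return Integer 0/1 matrix (rows = image rows).
#' @export
read_pbm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (!identical(tok[1], "P1")) abort("not an ASCII PBM (P1) file")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  bits <- as.integer(unlist(strsplit(paste(tok[-(1:3)], collapse = ""), "")))
  if (length(bits) != w * h) abort("PBM pixel count does not match header")
  matrix(bits, nrow = h, ncol = w, byrow = TRUE)
}

#' Digit stimulus bitmaps
#'
#' Returns one of the digit bitmaps (1-9) shipped with the package, optionally
#' magnified by an integer factor for presentation on the sensor.
#'
#' @param digit integer 1-9.
#' @param scale integer magnification factor (default 6, giving a 30x42 pixel
#'   glyph from the 5x7 master).
#' @return 0/1 matrix.
#' @export
digit_bitmap <- function(digit, scale = 6) {
  stopifnot(digit %in% 1:9, scale >= 1, scale == floor(scale))
  path <- system.file("extdata", "digits", sprintf("digit%d.pbm", digit),
                      package = "evsn", mustWork = TRUE)
  m <- read_pbm(path)
  m[rep(seq_len(nrow(m)), each = scale), rep(seq_len(ncol(m)), each = scale)]
}
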