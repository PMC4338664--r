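#' Spatial subsampling grid
#'
#' Tiles the sensor with non-overlapping square cells of `cell_size` x
#' `cell_size` pixels, anchored at `origin` (top-left of the used region);
#' pixels in the cropped remainder are unassigned. Pooling events per cell is
#' what reduces the 16k-pixel sensor to a tractable number of input channels.
#'
#' @param width,height sensor geometry in pixels.
#' @param cell_size cell side in pixels (5 for the single-field experiments,
#'   3 for the tiled ones).
#' @param origin integer `c(x, y)` offset of the tiled region (default
#'   `c(0, 0)`).
#' @return A list of class `cell_grid` with the grid dimensions and cell
#'   centres (row-major order: cell index increases along x first).
#' @export
cell_grid <- function(width, height, cell_size, origin = c(0, 0)) {
  stopifnot(cell_size >= 1, all(origin >= 0))
  n_cx <- (width - origin[1]) %/% cell_size
  n_cy <- (height - origin[2]) %/% cell_size
  if (n_cx < 1 || n_cy < 1) abort("sensor too small for this cell size")
  cx <- rep(seq_len(n_cx) - 1, times = n_cy)
  cy <- rep(seq_len(n_cy) - 1, each = n_cx)
  structure(list(
    width = width, height = height, cell_size = cell_size,
    origin = as.integer(origin), n_cx = n_cx, n_cy = n_cy,
    centers = tibble(cell = seq_len(n_cx * n_cy), cx = cx, cy = cy,
                     xc = origin[1] + cx * cell_size + (cell_size - 1) / 2,
                     yc = origin[2] + cy * cell_size + (cell_size - 1) / 2)),
    class = "cell_grid")
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf("<cell_grid %dx%d cells of %dx%d px, origin (%d,%d)>\n",
              x$n_cx, x$n_cy, x$cell_size, x$cell_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Map events to subsampling cells
#'
#' @param events data frame with `x`, `y` columns (e.g. an [event_stream()]).
#' @param grid a [cell_grid()].
#' @return Integer vector of 1-based cell indices (row-major), `NA` for
#'   events outside the tiled region.
#' @export
map_event_to_cell <- function(events, grid) {
  px <- events$x - grid$origin[1]
  py <- events$y - grid$origin[2]
  cx <- px %/% grid$cell_size
  cy <- py %/% grid$cell_size
  idx <- cy * grid$n_cx + cx + 1
  bad <- px < 0 | py < 0 | cx >= grid$n_cx | cy >= grid$n_cy
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Receptive field over the cell grid
#'
#' A square window of cells feeding one detector bank: the member cells are
#' exactly those within `half_extent` cells of the centre in both directions,
#' kept in a fixed row-major order that defines the component layout of the
#' analog vector.
#'
#' @param grid a [cell_grid()].
#' @param center integer `c(cx, cy)` cell coordinates of the field centre
#'   (0-based; default the grid centre).
#' @param half_extent half-width in cells, so the field spans
#'   `(2 * half_extent + 1)^2` cells.
#' @return A list of class `receptive_field` with member cell indices and the
#'   input dimension `m`.
#' @export
receptive_field <- function(grid, center = NULL, half_extent = 8) {
  if (is.null(center)) {
    center <- c((grid$n_cx - 1) %/% 2, (grid$n_cy - 1) %/% 2)
  }
  cc <- grid$centers
  member <- cc$cell[abs(cc$cx - center[1]) <= half_extent &
                      abs(cc$cy - center[2]) <= half_extent]
  side <- 2 * half_extent + 1
  if (length(member) != side^2) {
    abort("receptive field extends beyond the cell grid")
  }
  comp_of_cell <- rep(NA_integer_, nrow(cc))
  comp_of_cell[member] <- seq_along(member)
  structure(list(grid = grid, center = as.integer(center),
                 half_extent = as.integer(half_extent),
                 cells = member, comp_of_cell = comp_of_cell,
                 m = length(member)),
            class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf("<receptive_field %dx%d cells (m = %d) centred on cell (%d,%d)>\n",
              2 * x$half_extent + 1, 2 * x$half_extent + 1, x$m,
              x$center[1], x$center[2]))
  invisible(x)
}

#' Causal exponential filter state over a receptive field
#'
#' Each member cell keeps one filtered trace: every event adds a unit impulse
#' that decays as `exp(-(t - t_i) / tau)`. The vector of traces, normalized by
#' a running maximum so components lie in `[0, 1]`, is the analog input fed to
#' the predictors.
#'
#' @param rf a [receptive_field()].
#' @param tau filter time constant in seconds (default 0.01).
#' @return A list of class `analog_state` with fields `a` (raw traces),
#'   `t_us` (time of last update) and `running_max`.
#' @export
analog_state <- function(rf, tau = 0.01) {
  stopifnot(inherits(rf, "receptive_field"), tau > 0)
  structure(list(rf = rf, tau = tau, a = numeric(rf$m), t_us = 0,
                 running_max = 1),
            class = "analog_state")
}

#' Advance the filter state to a new sample time
#'
#' Decays every trace by `exp(-(t - t_prev) / tau)` and adds
#' `exp(-(t - t_i) / tau)` for each new event, which is algebraically
#' identical to re-evaluating the filter over the full event history. The
#' running maximum used for normalization is updated at the same time.
#'
#' @param state an [analog_state()].
#' @param events data frame of events with timestamps in `(t_prev, t_us]`
#'   (events outside the receptive field are ignored).
#' @param t_us new sample time in microseconds (`>= state$t_us`).
#' @return The updated `analog_state`.
#' @export
update_analog <- function(state, events, t_us) {
  if (t_us < state$t_us) abort("sample time precedes current state")
  tau_us <- state$tau * 1e6
  a <- state$a * exp(-(t_us - state$t_us) / tau_us)
  if (nrow(events)) {
    keep <- events$t_us > state$t_us & events$t_us <= t_us
    ev <- events[keep, , drop = FALSE]
    comp <- state$rf$comp_of_cell[map_event_to_cell(ev, state$rf$grid)]
    ok <- !is.na(comp)
    if (any(ok)) {
      w <- exp(-(t_us - ev$t_us[ok]) / tau_us)
      add <- rowsum(w, comp[ok])
      a[as.integer(rownames(add))] <- a[as.integer(rownames(add))] + add[, 1]
    }
  }
  state$a <- a
  state$t_us <- t_us
  state$running_max <- max(state$running_max, a)
  state
}

#' Sample the normalized analog vector
#'
#' @param state an [analog_state()].
#' @return Numeric vector of length `state$rf$m` with components in
#'   `[0, 1]` (raw traces divided by the running maximum, which is floored at
#'   1 so silence is not amplified).
#' @export
sample_vector <- function(state) {
  state$a / state$running_max
}

#' Batch evaluation of the exponential filter
#'
#' Direct summation of the filter response over the full event history —
#' the reference the incremental [update_analog()] must agree with.
#'
#' @param events data frame of events.
#' @param rf a [receptive_field()].
#' @param tau time constant in seconds.
#' @param t_us evaluation time in microseconds.
#' @return Raw (unnormalized) trace vector of length `rf$m`.
#' @export
analog_from_events <- function(events, rf, tau, t_us) {
  a <- numeric(rf$m)
  keep <- events$t_us <= t_us
  ev <- events[keep, , drop = FALSE]
  comp <- rf$comp_of_cell[map_event_to_cell(ev, rf$grid)]
  ok <- !is.na(comp)
  if (any(ok)) {
    w <- exp(-(t_us - ev$t_us[ok]) / (tau * 1e6))
    add <- rowsum(w, comp[ok])
    a[as.integer(rownames(add))] <- add[, 1]
  }
  a
}

# Pre-bin an event stream into a sparse injection matrix for the tick engine:
# column k holds the sum of exp(-(k*dt - t_i)/tau) over events in tick k, so
# a[, k] = a[, k-1] * exp(-dt/tau) + inject[, k] reproduces update_analog().
event_injection <- function(events, rf, tau, dt_us, n_ticks) {
  comp <- rf$comp_of_cell[map_event_to_cell(events, rf$grid)]
  ok <- !is.na(comp) & events$t_us <= n_ticks * dt_us
  t_ev <- events$t_us[ok]
  comp <- comp[ok]
  tick <- pmax(1, ceiling(t_ev / dt_us))
  w <- exp(-(tick * dt_us - t_ev) / (tau * 1e6))
  sparseMatrix(i = comp, j = tick, x = w, dims = c(rf$m, n_ticks))
}
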