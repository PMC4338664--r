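#' Architecture configuration
#'
#' Bundles every parameter of the full system: sensor emulation, subsampling
#' geometry, the predictor bank, the selection layer and the processing tick.
#'
#' @param n_esn number of competing predictor ESNs.
#' @param n_neurons reservoir size per ESN (default 15).
#' @param sensor a [sensor_model()].
#' @param cell_size subsampling cell side in pixels (default 5).
#' @param grid_origin integer `c(x, y)` anchor of the cell grid.
#' @param rf_center cell coordinates of the receptive-field centre (`NULL` =
#'   grid centre).
#' @param rf_half_extent receptive-field half-width in cells (default 8,
#'   i.e. 17 x 17 cells).
#' @param tau exponential filter time constant in seconds (default 0.01).
#' @param dt_s processing tick in seconds (default 1e-3).
#' @param spectral_radius,w_in_range,w_back_range,w_out_range ESN
#'   initialization parameters (see [esn_params()]).
#' @param forgetting,delta RLS parameters (see [rls_state()]).
#' @param wta a [wta_params()].
#' @param pm_neurons reservoir size of the predictability-minimization
#'   estimators (default 15).
#' @param pm_forgetting RLS forgetting factor of the estimator readouts
#'   (default 1; see [pm_bank()] for why the estimators use infinite
#'   memory while the predictor readouts forget).
#' @param seed master seed; weight draws and noise use fixed offsets from it.
#' @return A list of class `arch_config`.
#' @export
arch_config <- function(n_esn = 8, n_neurons = 15, sensor = sensor_model(),
                        cell_size = 5, grid_origin = c(0, 0),
                        rf_center = NULL, rf_half_extent = 8, tau = 0.01,
                        dt_s = 1e-3, spectral_radius = 0.7,
                        w_in_range = 0.4, w_back_range = 0.02,
                        w_out_range = 0.01, forgetting = 0.999, delta = 0.01,
                        wta = wta_params(), pm_neurons = 15,
                        pm_forgetting = 1, seed = 1) {
  stopifnot(n_esn >= 1, n_neurons >= 1, dt_s > 0, tau > 0,
            inherits(sensor, "sensor_model"), inherits(wta, "wta_params"))
  structure(list(n_esn = as.integer(n_esn), n_neurons = as.integer(n_neurons),
                 sensor = sensor, cell_size = cell_size,
                 grid_origin = grid_origin, rf_center = rf_center,
                 rf_half_extent = rf_half_extent, tau = tau, dt_s = dt_s,
                 spectral_radius = spectral_radius, w_in_range = w_in_range,
                 w_back_range = w_back_range, w_out_range = w_out_range,
                 forgetting = forgetting, delta = delta, wta = wta,
                 pm_neurons = as.integer(pm_neurons),
                 pm_forgetting = pm_forgetting, seed = as.integer(seed)),
            class = "arch_config")
}

#' Build a runnable system from a configuration
#'
#' Draws all random weights (reproducibly from `config$seed`), sets up the
#' preprocessing pipeline and zero-initializes all state.
#'
#' @param config an [arch_config()].
#' @return A list of class `evsn_system`.
#' @export
build_system <- function(config) {
  stopifnot(inherits(config, "arch_config"))
  grid <- cell_grid(config$sensor$width, config$sensor$height,
                    config$cell_size, config$grid_origin)
  rf <- receptive_field(grid, config$rf_center, config$rf_half_extent)
  par <- esn_params(input_dim = rf$m, n_neurons = config$n_neurons,
                    spectral_radius = config$spectral_radius,
                    w_in_range = config$w_in_range,
                    w_back_range = config$w_back_range,
                    w_out_range = config$w_out_range)
  bank <- lapply(seq_len(config$n_esn),
                 function(k) init_esn(par, seed = config$seed + k))
  if (config$n_esn >= 2) {
    pm <- pm_bank(config$n_esn, config$pm_neurons,
                  seed = config$seed + 1000L,
                  forgetting = config$pm_forgetting, delta = config$delta)
  } else {
    pm <- NULL
  }
  structure(list(
    config = config, grid = grid, rf = rf, bank = bank,
    rls = replicate(config$n_esn,
                    rls_state(config$n_neurons, config$forgetting,
                              config$delta),
                    simplify = FALSE),
    pm = pm,
    states = matrix(0, config$n_neurons, config$n_esn),
    outputs = matrix(0, rf$m, config$n_esn),
    a_raw = numeric(rf$m), running_max = 1, x0 = 0.5,
    counts = integer(config$n_esn), t_us = 0),
    class = "evsn_system")
}

#' @export
print.evsn_system <- function(x, ...) {
  cat(sprintf(
    "<evsn_system: %d ESNs x %d neurons, rf %dx%d cells (m = %d), t = %.3f s>\n",
    x$config$n_esn, x$config$n_neurons, 2 * x$rf$half_extent + 1,
    2 * x$rf$half_extent + 1, x$rf$m, x$t_us / 1e6))
  invisible(x)
}

# --- tick engine -----------------------------------------------------------

sys_to_env <- function(sys) {
  env <- list2env(sys, parent = emptyenv())
  cfg <- sys$config
  n <- cfg$n_neurons
  env$dt_us <- cfg$dt_s * 1e6
  env$decay <- exp(-cfg$dt_s / cfg$tau)
  env$Wr_big <- matrix(0, n * cfg$n_esn, n * cfg$n_esn)
  env$Win_big <- matrix(0, n * cfg$n_esn, sys$rf$m)
  for (k in seq_len(cfg$n_esn)) {
    rows <- (k - 1) * n + seq_len(n)
    env$Wr_big[rows, rows] <- sys$bank[[k]]$W_r
    env$Win_big[rows, ] <- sys$bank[[k]]$W_in
  }
  env$svec <- as.vector(sys$states)
  # stacked fast path for the predictability-minimization estimators;
  # estimator k's input column for its own similarity is structurally zero,
  # so the stacked step equals esn_step() on similarities[-k]
  if (!is.null(sys$pm)) {
    pm <- sys$pm
    pn <- nrow(pm$states)
    nc <- pm$n
    env$pm_n <- pn
    env$PMWr_big <- matrix(0, pn * nc, pn * nc)
    env$PMWin_big <- matrix(0, pn * nc, nc)
    env$PMWback <- vector("list", nc)
    env$PMWout <- vector("list", nc)
    env$PMP <- vector("list", nc)
    for (k in seq_len(nc)) {
      rows <- (k - 1) * pn + seq_len(pn)
      env$PMWr_big[rows, rows] <- pm$weights[[k]]$W_r
      env$PMWin_big[rows, -k] <- pm$weights[[k]]$W_in
      env$PMWback[[k]] <- pm$weights[[k]]$W_back
      env$PMWout[[k]] <- pm$weights[[k]]$W_out
      env$PMP[[k]] <- pm$rls[[k]]$P
    }
    env$pm_svec <- as.vector(pm$states)
    env$pm_out <- pm$outputs
    env$pm_inhibit <- pm$inhibit_until_us
    env$pm_lambda <- pm$rls[[1]]$forgetting
  }
  env
}

env_to_sys <- function(env) {
  pm <- env$pm
  if (!is.null(pm)) {
    pn <- env$pm_n
    pm$states <- matrix(env$pm_svec, pn, pm$n)
    pm$outputs <- env$pm_out
    pm$inhibit_until_us <- env$pm_inhibit
    for (k in seq_len(pm$n)) {
      pm$weights[[k]]$W_out <- env$PMWout[[k]]
      pm$rls[[k]]$P <- env$PMP[[k]]
    }
  }
  structure(list(config = env$config, grid = env$grid, rf = env$rf,
                 bank = env$bank, rls = env$rls, pm = pm,
                 states = env$states, outputs = env$outputs,
                 a_raw = env$a_raw, running_max = env$running_max,
                 x0 = env$x0, counts = env$counts, t_us = env$t_us),
            class = "evsn_system")
}

# Stacked in-place equivalent of pm_step() used by the tick engine
# (verified against pm_step in the test suite).
pm_tick <- function(env, S, winner, learn) {
  pn <- env$pm_n
  nc <- env$config$n_esn
  t_inh_us <- env$config$wta$t_inh_s * 1e6
  fb <- numeric(pn * nc)
  for (k in seq_len(nc)) {
    fb[(k - 1) * pn + seq_len(pn)] <- env$PMWback[[k]] %*% env$pm_out[, k]
  }
  snew <- plogis(env$PMWr_big %*% env$pm_svec + env$PMWin_big %*% S + fb)[, 1]
  env$pm_svec <- snew
  onehot <- numeric(nc)
  onehot[winner] <- 1
  lam <- env$pm_lambda
  for (k in seq_len(nc)) {
    s_k <- snew[(k - 1) * pn + seq_len(pn)]
    out_k <- (env$PMWout[[k]] %*% s_k)[, 1]
    env$pm_out[, k] <- out_k
    if (which.max(out_k) == winner && winner == k) {
      env$pm_inhibit[k] <- env$t_us + t_inh_us
    }
    if (learn) {
      Ps <- env$PMP[[k]] %*% s_k
      gain <- Ps / (lam + sum(s_k * Ps))[1]
      env$PMWout[[k]] <- env$PMWout[[k]] + tcrossprod(onehot - out_k, gain[, 1])
      P <- (env$PMP[[k]] - tcrossprod(gain[, 1], Ps[, 1])) / lam
      P <- (P + t(P)) / 2
      if (any(!is.finite(P)) || any(diag(P) <= 0)) {
        warning("RLS inverse-correlation matrix degenerated; reinitializing")
        P <- diag(1 / env$pm$rls[[k]]$delta, pn)
      }
      env$PMP[[k]] <- P
    }
  }
  invisible(env)
}

# One processing tick. `inj` is the injection column for this tick (summed
# decayed impulses of the tick's events); mutates `env` and returns the tick
# record.
tick_core <- function(env, inj, learn) {
  cfg <- env$config
  wta <- cfg$wta
  n <- cfg$n_neurons
  n_esn <- cfg$n_esn
  env$t_us <- env$t_us + env$dt_us
  a <- env$a_raw * env$decay + inj
  env$a_raw <- a
  mx <- max(a)
  if (mx > env$running_max) env$running_max <- mx
  A <- a / env$running_max
  OUT <- env$outputs
  err <- sqrt(colSums((OUT - A)^2))
  sum_a <- sum(A)
  sum_hat <- colSums(abs(OUT))
  S <- numeric(n_esn)
  nz <- sum_a > 0 & sum_hat > 0
  if (any(nz)) {
    S[nz] <- colSums(abs(OUT * A))[nz] / (sum_a * sum_hat[nz])
  }
  gated <- mean(A) > wta$gate_threshold
  winner <- NA_integer_
  s_w <- NA_real_
  min_ok <- NA
  if (gated) {
    inhib <- if (is.null(env$pm)) rep(FALSE, n_esn)
             else env$pm_inhibit > env$t_us
    currents <- encode_current(S, wta, env$x0)
    sel <- select_winner(currents, inhib, cfg$dt_s, wta, similarities = S)
    w <- sel$winner
    if (!is.na(w)) {
      winner <- w
      s_w <- S[w]
      min_ok <- err[w] <= min(err[!inhib]) + 1e-12
      if (!is.null(env$pm)) pm_tick(env, S, w, learn)
      if (learn) {
        upd <- rls_update(env$rls[[w]], env$states[, w], A,
                          env$bank[[w]]$W_out)
        env$rls[[w]] <- upd$rls
        env$bank[[w]]$W_out <- upd$W_out
        env$counts[w] <- env$counts[w] + 1L
      }
      # two 0.5 ms controller sub-steps within the tick
      n_sub <- max(1L, round(cfg$dt_s / wta$controller_period_s))
      for (i in seq_len(n_sub)) env$x0 <- update_offset(env$x0, s_w, wta)
    }
  }
  # advance every reservoir on the new input, free-running feedback
  fb <- numeric(n * n_esn)
  for (k in seq_len(n_esn)) {
    fb[(k - 1) * n + seq_len(n)] <- env$bank[[k]]$W_back %*% OUT[, k]
  }
  snew <- plogis(env$Wr_big %*% env$svec + env$Win_big %*% A + fb)[, 1]
  env$svec <- snew
  env$states <- matrix(snew, n, n_esn)
  for (k in seq_len(n_esn)) {
    env$outputs[, k] <- env$bank[[k]]$W_out %*% env$states[, k]
  }
  list(winner = winner, gated = gated, s_winner = s_w, min_err = min_ok,
       errors = err, similarities = S)
}

#' Advance the system by one tick
#'
#' Runs one full processing step on the events of a single tick window:
#' analog update and sampling, prediction scoring of every ESN against the
#' prediction it issued last tick, gated winner-take-all selection,
#' predictability minimization, selective RLS training of the winner, and
#' the reservoir update that issues the next predictions.
#'
#' @param system an [build_system()] result.
#' @param events data frame of events with timestamps inside
#'   `(system$t_us, system$t_us + dt]`.
#' @param learn logical; apply RLS updates this tick?
#' @return `list(system, record)` where `record` holds the tick's winner,
#'   gate flag, per-ESN errors and similarities.
#' @export
train_step <- function(system, events, learn = TRUE) {
  stopifnot(inherits(system, "evsn_system"))
  env <- sys_to_env(system)
  dt_us <- env$dt_us
  t_next <- system$t_us + dt_us
  tau_us <- system$config$tau * 1e6
  inj <- numeric(system$rf$m)
  if (nrow(events)) {
    keep <- events$t_us > system$t_us & events$t_us <= t_next
    ev <- events[keep, , drop = FALSE]
    comp <- system$rf$comp_of_cell[map_event_to_cell(ev, system$grid)]
    ok <- !is.na(comp)
    if (any(ok)) {
      w <- exp(-(t_next - ev$t_us[ok]) / tau_us)
      add <- rowsum(w, comp[ok])
      inj[as.integer(rownames(add))] <- add[, 1]
    }
  }
  rec <- tick_core(env, inj, learn)
  list(system = env_to_sys(env), record = rec)
}

# Run the engine over a pre-binned injection matrix. learn_vec is a logical
# per tick. Returns list(system, winners tibble, errors matrix). Dispatches
# to the compiled engine; `engine_run_r` is the plain-R reference path the
# compiled engine is tested against.
engine_run <- function(system, inject, learn_vec, record_errors = TRUE,
                       use_compiled = TRUE) {
  if (!use_compiled) {
    return(engine_run_r(system, inject, learn_vec, record_errors))
  }
  n_ticks <- ncol(inject)
  stopifnot(length(learn_vec) == n_ticks)
  cfg <- system$config
  wta <- cfg$wta
  inject <- methods::as(inject, "CsparseMatrix")
  has_pm <- !is.null(system$pm)
  weights <- list(
    W_r = lapply(system$bank, `[[`, "W_r"),
    W_in = lapply(system$bank, `[[`, "W_in"),
    W_back = lapply(system$bank, `[[`, "W_back"),
    W_out = lapply(system$bank, `[[`, "W_out"),
    P = lapply(system$rls, `[[`, "P"))
  pm_weights <- if (has_pm) {
    list(W_r = lapply(system$pm$weights, `[[`, "W_r"),
         W_in = lapply(system$pm$weights, `[[`, "W_in"),
         W_back = lapply(system$pm$weights, `[[`, "W_back"),
         W_out = lapply(system$pm$weights, `[[`, "W_out"),
         P = lapply(system$pm$rls, `[[`, "P"))
  } else list()
  state0 <- list(states = system$states, outputs = system$outputs,
                 a_raw = system$a_raw, running_max = system$running_max,
                 x0 = system$x0, t_us = system$t_us,
                 counts = as.integer(system$counts))
  if (has_pm) {
    state0$pm_states <- system$pm$states
    state0$pm_outputs <- system$pm$outputs
    state0$pm_inhibit <- as.numeric(system$pm$inhibit_until_us)
  }
  pars <- list(
    n_esn = cfg$n_esn, n_neurons = cfg$n_neurons, m = system$rf$m,
    dt_us = cfg$dt_s * 1e6, dt_s = cfg$dt_s,
    decay = exp(-cfg$dt_s / cfg$tau),
    gate_threshold = wta$gate_threshold, g_min = wta$g_min,
    g_max = wta$g_max, lambda = wta$lambda, kp = wta$kp, theta = wta$theta,
    t_inh_us = wta$t_inh_s * 1e6,
    n_sub = max(1L, round(cfg$dt_s / wta$controller_period_s)),
    forgetting = cfg$forgetting, delta = cfg$delta, has_pm = has_pm,
    pm_neurons = if (has_pm) nrow(system$pm$states) else 0L,
    pm_forgetting = if (has_pm) system$pm$rls[[1]]$forgetting else 1,
    pm_delta = if (has_pm) system$pm$rls[[1]]$delta else 0.01)
  res <- .engine_cpp(inject@p, inject@i, inject@x, n_ticks,
                     as.logical(learn_vec), record_errors, weights,
                     pm_weights, state0, pars)
  if (res$warn_pd > 0) {
    warning("RLS inverse-correlation matrix degenerated; reinitialized (",
            res$warn_pd, "x)")
  }
  sys <- system
  for (k in seq_len(cfg$n_esn)) {
    sys$bank[[k]]$W_out <- res$W_out[[k]]
    sys$rls[[k]]$P <- res$P[[k]]
  }
  if (has_pm) {
    for (k in seq_len(cfg$n_esn)) {
      sys$pm$weights[[k]]$W_out <- res$pm_W_out[[k]]
      sys$pm$rls[[k]]$P <- res$pm_P[[k]]
    }
    sys$pm$states <- res$pm_states
    sys$pm$outputs <- res$pm_outputs
    sys$pm$inhibit_until_us <- as.numeric(res$pm_inhibit)
  }
  sys$states <- res$states
  sys$outputs <- res$outputs
  sys$a_raw <- as.numeric(res$a_raw)
  sys$running_max <- res$running_max
  sys$x0 <- res$x0
  sys$counts <- as.integer(res$counts)
  t0 <- system$t_us
  dt_us <- cfg$dt_s * 1e6
  sys$t_us <- t0 + n_ticks * dt_us
  winners <- tibble(
    tick = seq_len(n_ticks),
    t_us = t0 + seq_len(n_ticks) * dt_us,
    winner = as.integer(res$winner), gated = as.logical(res$gated),
    s_winner = as.numeric(res$s_winner),
    winner_min_err = as.logical(res$min_ok))
  list(system = sys, winners = winners, errors = res$errors)
}

engine_run_r <- function(system, inject, learn_vec, record_errors = TRUE) {
  n_ticks <- ncol(inject)
  stopifnot(length(learn_vec) == n_ticks)
  env <- sys_to_env(system)
  winner <- integer(n_ticks)
  gated <- logical(n_ticks)
  s_w <- numeric(n_ticks)
  min_ok <- rep(NA, n_ticks)
  errs <- if (record_errors) {
    matrix(NA_real_, n_ticks, system$config$n_esn)
  } else NULL
  t0 <- system$t_us
  dt_us <- env$dt_us
  m <- system$rf$m
  inject <- methods::as(inject, "CsparseMatrix")
  colptr <- inject@p
  rowidx <- inject@i
  vals <- inject@x
  for (k in seq_len(n_ticks)) {
    inj <- numeric(m)
    if (colptr[k + 1] > colptr[k]) {
      ii <- (colptr[k] + 1):colptr[k + 1]
      inj[rowidx[ii] + 1] <- vals[ii]
    }
    rec <- tick_core(env, inj, learn_vec[k])
    winner[k] <- rec$winner
    gated[k] <- rec$gated
    s_w[k] <- if (is.na(rec$s_winner)) NA_real_ else rec$s_winner
    min_ok[k] <- rec$min_err
    if (record_errors) errs[k, ] <- rec$errors
  }
  winners <- tibble(
    tick = seq_len(n_ticks),
    t_us = t0 + seq_len(n_ticks) * dt_us,
    winner = winner, gated = gated, s_winner = s_w,
    winner_min_err = min_ok)
  list(system = env_to_sys(env), winners = winners, errors = errs)
}

# --- experiment schedules --------------------------------------------------

#' Moving-bar presentation schedule
#'
#' One presentation per orientation, repeated `reps` times (block order:
#' all orientations, then the next repetition), each followed by a blank
#' pause in which only sensor noise is present.
#'
#' @param orientations bar angles in degrees (default the nine orientations
#'   0, 20, ..., 160).
#' @param reps number of repetitions of the full set (default 3).
#' @param duration_s presentation length in seconds (default 1).
#' @param pause_s blank pause after each presentation (default 0.6).
#' @param speed bar speed in pixels/second (default 200).
#' @param phase `"learn"` or `"test"` for every row.
#' @return A schedule tibble with columns `phase`, `label`, `stimulus`
#'   (list-column of [stimulus_bar()]), `pause_s`, `rep`.
#' @export
bar_schedule <- function(orientations = seq(0, 160, by = 20), reps = 3,
                         duration_s = 1, pause_s = 0.6, speed = 200,
                         phase = "learn") {
  tibble(
    phase = phase,
    label = rep(paste0("bar", orientations), times = reps),
    stimulus = rep(lapply(orientations, function(o) {
      stimulus_bar(o, speed = speed, duration = duration_s)
    }), times = reps),
    pause_s = pause_s,
    rep = rep(seq_len(reps), each = length(orientations)))
}

#' Jittered-digit presentation schedule
#'
#' @param digits digit labels, in presentation order.
#' @param duration_s presentation length in seconds (default 5).
#' @param pause_s blank pause after each digit (default 3; use 0 for
#'   back-to-back presentation).
#' @param scale integer magnification of the 5x7 digit masters.
#' @param jitter_amplitude,jitter_rate jitter parameters
#'   (see [stimulus_bitmap()]).
#' @param phase `"learn"` or `"test"`.
#' @return A schedule tibble (see [bar_schedule()]).
#' @export
digit_schedule <- function(digits = 1:9, duration_s = 5, pause_s = 3,
                           scale = 6, jitter_amplitude = 3,
                           jitter_rate = 100, phase = "learn") {
  tibble(
    phase = phase,
    label = paste0("digit", digits),
    stimulus = lapply(digits, function(d) {
      stimulus_bitmap(digit_bitmap(d, scale),
                      jitter_amplitude = jitter_amplitude,
                      jitter_rate = jitter_rate, duration = duration_s)
    }),
    pause_s = pause_s,
    rep = 1L)
}

# Simulate all schedule rows into one event stream plus ground truth.
# Signal events are deterministic per stimulus and cached; noise is drawn
# once for the whole run from the current RNG state.
schedule_events <- function(schedule, sensor) {
  quiet <- sensor_model(sensor$width, sensor$height,
                        sensor$contrast_threshold, noise_rate = 0)
  cache <- new.env(parent = emptyenv())
  segs <- vector("list", nrow(schedule))
  t_off <- 0
  truth <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    spec <- schedule$stimulus[[i]]
    key <- rlang::hash(spec)
    sig <- if (!is.null(cache[[key]])) cache[[key]] else {
      s <- if (spec$kind == "bar") {
        simulate_moving_bar(spec, quiet)
      } else {
        simulate_jittered_pattern(spec, quiet,
                                  seed = sample.int(2^30, 1))
      }
      cache[[key]] <- s
      s
    }
    seg <- as_tibble(sig)
    seg$t_us <- seg$t_us + t_off
    segs[[i]] <- seg
    truth[[i]] <- tibble(label = schedule$label[i],
                         phase = schedule$phase[i],
                         rep = schedule$rep[i],
                         onset_us = t_off,
                         offset_us = t_off + spec$duration * 1e6,
                         end_us = t_off +
                           (spec$duration + schedule$pause_s[i]) * 1e6)
    t_off <- t_off + (spec$duration + schedule$pause_s[i]) * 1e6
  }
  signal <- dplyr::bind_rows(segs)
  noise <- as_tibble(simulate_noise(sensor, t_off / 1e6))
  ev <- dplyr::bind_rows(signal, noise)
  ev <- ev[order(ev$t_us), , drop = FALSE]
  list(events = new_event_stream(ev, sensor$width, sensor$height),
       truth = dplyr::bind_rows(truth), duration_us = t_off)
}

#' Run a full unsupervised learning experiment
#'
#' Simulates the event stream for the given presentation schedule (stimuli
#' plus background noise), then runs the complete architecture tick by tick.
#' RLS learning (of winners and estimators) is enabled during rows with
#' `phase == "learn"` and frozen during `"test"` rows. Deterministic for a
#' fixed config seed.
#'
#' @param config an [arch_config()].
#' @param schedule a schedule tibble from [bar_schedule()] /
#'   [digit_schedule()] (rows are presented in order; `rbind` learn and test
#'   schedules to combine phases).
#' @param record_errors keep the full per-tick, per-ESN prediction-error
#'   traces in the report (default `TRUE`).
#' @return An `evsn_report` (see [tidy.evsn_report()], [glance.evsn_report()],
#'   [recruitment_report()], [autoplot.evsn_report()]).
#' @export
run_experiment <- function(config, schedule, record_errors = TRUE) {
  stopifnot(inherits(config, "arch_config"), nrow(schedule) >= 1)
  system <- build_system(config)
  set.seed(config$seed + 90001L)
  sim <- schedule_events(schedule, config$sensor)
  dt_us <- config$dt_s * 1e6
  n_ticks <- ceiling(sim$duration_us / dt_us)
  inject <- event_injection(sim$events, system$rf, config$tau, dt_us, n_ticks)
  t_tick <- seq_len(n_ticks) * dt_us
  row_of_tick <- findInterval(t_tick - 1e-9, c(0, sim$truth$end_us),
                              rightmost.closed = FALSE)
  row_of_tick <- pmin(pmax(row_of_tick, 1L), nrow(sim$truth))
  learn_vec <- sim$truth$phase[row_of_tick] == "learn"
  run <- engine_run(system, inject, learn_vec, record_errors)
  new_report(run, sim$truth, config)
}

new_report <- function(run, truth, config, rf_id = 1L) {
  winners <- run$winners
  winners$rf_id <- rf_id
  structure(list(winners = winners, errors = run$errors, truth = truth,
                 counts = run$system$counts, system = run$system,
                 config = config),
            class = "evsn_report")
}

#' Recruitment summary
#'
#' Counts, per ESN, the ticks in which its readout was trained (it won the
#' gated competition during a learning phase). An ESN is *recruited* if its
#' training-sample count exceeds 1% of all gated training ticks — the
#' operational reading of "shows increased activation".
#'
#' @param report an `evsn_report` from [run_experiment()].
#' @return A tibble with columns `esn`, `samples`, `share`, `recruited`.
#' @export
recruitment_report <- function(report) {
  stopifnot(inherits(report, "evsn_report"))
  counts <- report$counts
  total <- sum(counts)
  tibble(esn = seq_along(counts), samples = as.integer(counts),
         share = if (total > 0) counts / total else rep(0, length(counts)),
         recruited = total > 0 & counts > 0.01 * total)
}

# --- multi-receptive-field tiling ------------------------------------------

#' Tile a trained bank over multiple receptive fields
#'
#' Copies the trained weights (predictors and estimators) into one
#' independent detector bank per receptive field. All banks share identical
#' weights but keep independent reservoir states and analog pipelines, so
#' they act as translated copies of the same feature detectors.
#'
#' @param system a trained `evsn_system`.
#' @param centers list of cell-coordinate centres `c(cx, cy)`, one per
#'   receptive field; every field must fit the grid with the trained field's
#'   half-extent.
#' @return A list of class `evsn_tiled`.
#' @export
tile_receptive_fields <- function(system, centers) {
  stopifnot(inherits(system, "evsn_system"), length(centers) >= 1)
  rfs <- lapply(centers, function(ct) {
    receptive_field(system$grid, ct, system$rf$half_extent)
  })
  pm0 <- system$pm
  if (!is.null(pm0)) {
    pm0$states[] <- 0
    pm0$outputs[] <- 0
    pm0$inhibit_until_us[] <- -Inf
  }
  banks <- lapply(seq_along(rfs), function(i) {
    s <- system
    s$rf <- rfs[[i]]
    s$states[] <- 0
    s$outputs[] <- 0
    s$a_raw <- numeric(rfs[[i]]$m)
    s$running_max <- 1
    s$x0 <- 0.5
    s$counts[] <- 0L
    s$t_us <- 0
    s$pm <- pm0
    s
  })
  structure(list(banks = banks, centers = centers, config = system$config),
            class = "evsn_tiled")
}

#' Run a tiled system on an event stream (inference only)
#'
#' Every receptive field processes the same stream independently with frozen
#' weights; each emits its own gated winner timeline.
#'
#' @param tiled an [tile_receptive_fields()] result.
#' @param events an [event_stream()].
#' @param duration_s stream length to process, seconds.
#' @return An `evsn_report` whose `winners` tibble has one timeline per
#'   `rf_id`.
#' @export
run_tiled <- function(tiled, events, duration_s) {
  stopifnot(inherits(tiled, "evsn_tiled"))
  cfg <- tiled$config
  dt_us <- cfg$dt_s * 1e6
  n_ticks <- ceiling(duration_s * 1e6 / dt_us)
  runs <- lapply(seq_along(tiled$banks), function(i) {
    sys <- tiled$banks[[i]]
    inject <- event_injection(events, sys$rf, cfg$tau, dt_us, n_ticks)
    run <- engine_run(sys, inject, rep(FALSE, n_ticks),
                      record_errors = FALSE)
    w <- run$winners
    w$rf_id <- i
    w
  })
  structure(list(winners = dplyr::bind_rows(runs), errors = NULL,
                 truth = NULL, counts = NULL, system = NULL, config = cfg),
            class = "evsn_report")
}

#' Lag between two receptive fields' winner timelines
#'
#' Cross-correlates the gated winner timelines of two receptive fields
#' (counting ticks on which both fields report the same winner at the given
#' shift) and returns the lag with the highest count. For a stimulus
#' translating across the tiling, the expected lag is the field pitch divided
#' by the stimulus speed.
#'
#' @param report an `evsn_report` from [run_tiled()].
#' @param rf_a,rf_b receptive-field ids to compare (`rf_b` is expected to
#'   lag `rf_a`).
#' @param max_lag_s largest lag searched, seconds (default 0.5).
#' @return A tibble with the best `lag_s` and its match count.
#' @export
timeline_lag <- function(report, rf_a, rf_b, max_lag_s = 0.5) {
  w <- report$winners
  dt_s <- report$config$dt_s
  wa <- w$winner[w$rf_id == rf_a]
  wb <- w$winner[w$rf_id == rf_b]
  wa[!w$gated[w$rf_id == rf_a]] <- NA
  wb[!w$gated[w$rf_id == rf_b]] <- NA
  n <- length(wa)
  lags <- seq(-floor(max_lag_s / dt_s), floor(max_lag_s / dt_s))
  score <- vapply(lags, function(l) {
    ia <- seq_len(n)
    ib <- ia + l
    ok <- ib >= 1 & ib <= n
    sum(wa[ia[ok]] == wb[ib[ok]], na.rm = TRUE)
  }, numeric(1))
  best <- which(score == max(score))
  best <- best[which.min(abs(lags[best]))]
  tibble(lag_s = lags[best] * dt_s, matches = score[best])
}
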