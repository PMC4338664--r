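#' Winner-take-all parameters
#'
#' The similarity of each predictor is mapped through a sigmoid onto an input
#' current for a non-leaky integrate-and-fire neuron. With threshold
#' `theta = 1` the firing rate in Hz equals the current, so the defaults span
#' rates of 5-15 kHz across the similarity range. The sigmoid midpoint `x0`
#' is adaptive: a proportional controller (period 0.5 ms) pulls it toward the
#' winner's similarity so the sigmoid is always centred where selectivity is
#' needed.
#'
#' @param g_min,g_max current range in Hz-equivalents (defaults 5000, 15000).
#' @param lambda sigmoid selectivity (default `5e-5`).
#' @param kp proportional gain of the offset controller (default 0.1).
#' @param controller_period_s controller update period in seconds
#'   (default 5e-4).
#' @param theta integrate-and-fire threshold (default 1).
#' @param t_inh_s duration of predictability-minimization inhibition in
#'   seconds (default 0.01).
#' @param gate_threshold minimum mean analog activity for the circuit to emit
#'   output at all (default 0.01).
#' @return A list of class `wta_params`.
#' @export
wta_params <- function(g_min = 5000, g_max = 15000, lambda = 5e-5, kp = 0.1,
                       controller_period_s = 5e-4, theta = 1,
                       t_inh_s = 0.01, gate_threshold = 0.01) {
  stopifnot(g_min < g_max, lambda > 0, kp > 0, kp <= 1, theta > 0,
            controller_period_s > 0, t_inh_s >= 0, gate_threshold >= 0)
  structure(list(g_min = g_min, g_max = g_max, lambda = lambda, kp = kp,
                 controller_period_s = controller_period_s, theta = theta,
                 t_inh_s = t_inh_s, gate_threshold = gate_threshold),
            class = "wta_params")
}

#' Sigmoid current encoding of a similarity value
#'
#' `g(S) = g_min + (g_max - g_min) / (1 + exp(-(S - x0) / lambda))`.
#'
#' @param s similarity value(s) in `[0, 1]` (vectorized).
#' @param params a [wta_params()].
#' @param x0 adaptive sigmoid offset.
#' @return Current(s) in `[g_min, g_max]`.
#' @export
encode_current <- function(s, params, x0) {
  params$g_min + (params$g_max - params$g_min) *
    plogis((s - x0) / params$lambda)
}

#' Proportional update of the sigmoid offset
#'
#' One controller step: `x0' = x0 + kp * (s_winner - x0)`, clamped to
#' `[0, 1]`, so the offset tracks the winning predictor's similarity.
#'
#' @param x0 current offset.
#' @param s_winner similarity of the currently selected predictor.
#' @param params a [wta_params()].
#' @return Updated offset.
#' @export
update_offset <- function(x0, s_winner, params) {
  min(1, max(0, x0 + params$kp * (s_winner - x0)))
}

#' Spiking winner selection over one decision window
#'
#' Simulates the inhibitory winner-take-all circuit of non-leaky
#' integrate-and-fire neurons over the window: all non-inhibited channels
#' integrate their (constant) currents from zero, the first to reach the
#' threshold spikes and globally resets the population, and the race repeats.
#' With constant currents the same channel — the one with the largest current
#' — wins every race, spiking at regular intervals `theta / current`; ties
#' break toward the lowest channel index.
#'
#' @param currents non-negative finite current per channel.
#' @param inhibited logical vector, `TRUE` for channels currently silenced by
#'   predictability minimization.
#' @param window_s decision window length in seconds.
#' @param params a [wta_params()].
#' @param similarities optional similarity values behind the currents, used
#'   to resolve saturation ties: the sigmoid encoder is strictly increasing,
#'   but a similarity more than a few tens of `lambda` above the offset
#'   saturates to `g_max` at double precision, so equal currents are a
#'   floating-point artifact and are ranked by the underlying similarity.
#'   Exact ties break toward the lowest channel index.
#' @return `list(winner, spike_times)`: the winning channel index (`NA` if
#'   every channel is inhibited or no spike occurs in the window) and its
#'   spike times in seconds from window start.
#' @export
select_winner <- function(currents, inhibited = NULL, window_s = 1e-3,
                          params = wta_params(), similarities = NULL) {
  n <- length(currents)
  if (is.null(inhibited)) inhibited <- rep(FALSE, n)
  stopifnot(length(inhibited) == n, all(is.finite(currents)),
            all(currents >= 0))
  eligible <- which(!inhibited)
  if (!length(eligible)) return(list(winner = NA_integer_,
                                     spike_times = numeric()))
  w <- eligible[which.max(currents[eligible])]
  if (!is.null(similarities)) {
    tied <- eligible[currents[eligible] == currents[w]]
    w <- tied[which.max(similarities[tied])]
  }
  isi <- params$theta / currents[w]
  n_spk <- if (is.finite(isi)) floor(window_s / isi + 1e-9) else 0
  if (n_spk < 1) return(list(winner = NA_integer_, spike_times = numeric()))
  list(winner = w, spike_times = seq_len(n_spk) * isi)
}

#' Activity gate
#'
#' The selection layer only emits output while there is enough input: the
#' gate is open iff the mean component of the normalized analog vector
#' strictly exceeds the threshold.
#'
#' @param a normalized analog vector.
#' @param params a [wta_params()] (uses `gate_threshold`).
#' @return Logical flag.
#' @export
activity_gate <- function(a, params = wta_params()) {
  mean(a) > params$gate_threshold
}

#' Predictability-minimization estimator bank
#'
#' One estimator ESN per channel. Estimator `k` sees only the similarities of
#' the *other* channels and is trained online to reproduce the winner-take-all
#' output (as a one-hot vector). When estimator `k` correctly names the winner
#' and that winner is channel `k` itself, channel `k`'s win was redundant —
#' predictable from its peers — and the channel is inhibited for a while,
#' handing the feature to a competitor.
#'
#' @param n_channels number of WTA channels.
#' @param n_neurons estimator reservoir size (default 15).
#' @param seed integer seed.
#' @param forgetting,delta RLS parameters for the estimator readouts. The
#'   default forgetting factor is 1 (infinite memory): redundancy must be
#'   judged against the whole stimulus history, because an estimator with a
#'   short memory can "predict" any persistent winner from recency alone,
#'   which would inhibit every stable specialist and collapse the
#'   competition into a round-robin rotation.
#' @return A list of class `pm_bank` with per-estimator weights, states and
#'   RLS accumulators, plus per-channel inhibition expiry times (us).
#' @export
pm_bank <- function(n_channels, n_neurons = 15, seed = 1,
                    forgetting = 1, delta = 0.01) {
  stopifnot(n_channels >= 2)
  par <- esn_params(input_dim = n_channels - 1, output_dim = n_channels,
                    n_neurons = n_neurons)
  bank <- lapply(seq_len(n_channels),
                 function(k) init_esn(par, seed = seed + k))
  structure(list(
    n = n_channels,
    weights = bank,
    states = matrix(0, n_neurons, n_channels),
    outputs = matrix(0, n_channels, n_channels),
    rls = replicate(n_channels, rls_state(n_neurons, forgetting, delta),
                    simplify = FALSE),
    inhibit_until_us = rep(-Inf, n_channels)),
    class = "pm_bank")
}

#' One predictability-minimization step
#'
#' Steps every estimator on the current similarities of its peers, compares
#' its winner estimate with the actual winner, applies the inhibition rule,
#' and (if `learn`) RLS-trains each estimator toward the one-hot encoding of
#' the winner.
#'
#' @param pm a [pm_bank()].
#' @param similarities similarity vector of all channels at this tick.
#' @param winner index of the channel selected by the WTA this tick.
#' @param t_us current time in microseconds.
#' @param params a [wta_params()] (uses `t_inh_s`).
#' @param learn logical; train the estimator readouts this tick?
#' @return The updated `pm_bank` (with `inhibit_until_us` refreshed).
#' @export
pm_step <- function(pm, similarities, winner, t_us, params = wta_params(),
                    learn = TRUE) {
  stopifnot(length(similarities) == pm$n, length(winner) == 1,
            !is.na(winner), winner >= 1, winner <= pm$n)
  onehot <- numeric(pm$n)
  onehot[winner] <- 1
  for (k in seq_len(pm$n)) {
    stepped <- esn_step(pm$weights[[k]], pm$states[, k],
                        similarities[-k], pm$outputs[, k])
    pm$states[, k] <- stepped$state
    pm$outputs[, k] <- stepped$output
    agrees <- which.max(stepped$output) == winner
    if (agrees && winner == k) {
      pm$inhibit_until_us[k] <- t_us + params$t_inh_s * 1e6
    }
    if (learn) {
      upd <- rls_update(pm$rls[[k]], stepped$state, onehot,
                        pm$weights[[k]]$W_out)
      pm$rls[[k]] <- upd$rls
      pm$weights[[k]]$W_out <- upd$W_out
    }
  }
  pm
}

#' Channels currently inhibited
#'
#' @param pm a [pm_bank()].
#' @param t_us current time in microseconds.
#' @return Logical vector over channels.
#' @export
pm_inhibited <- function(pm, t_us) {
  pm$inhibit_until_us > t_us
}
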