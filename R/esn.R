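#' Echo-state network parameters
#'
#' @param input_dim dimension of the analog input vector.
#' @param output_dim dimension of the predicted vector (defaults to
#'   `input_dim`; the readout predicts the next input sample).
#' @param n_neurons reservoir size (default 15).
#' @param spectral_radius target spectral radius of the recurrent matrix
#'   (default 0.7, below 1 so the echo state property holds).
#' @param w_in_range,w_back_range,w_out_range half-widths of the symmetric
#'   uniform distributions for the input, feedback and initial readout
#'   weights (defaults 0.4, 0.02 and 0.01).
#' @return A list of class `esn_params`.
#' @export
esn_params <- function(input_dim, output_dim = input_dim, n_neurons = 15,
                       spectral_radius = 0.7, w_in_range = 0.4,
                       w_back_range = 0.02, w_out_range = 0.01) {
  stopifnot(input_dim >= 1, output_dim >= 1, n_neurons >= 1,
            spectral_radius > 0, spectral_radius < 1,
            w_in_range > 0, w_back_range > 0, w_out_range > 0)
  structure(list(input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 n_neurons = as.integer(n_neurons),
                 spectral_radius = spectral_radius,
                 w_in_range = w_in_range, w_back_range = w_back_range,
                 w_out_range = w_out_range),
            class = "esn_params")
}

#' Initialize ESN weights
#'
#' All matrices are drawn from symmetric uniform distributions; the recurrent
#' matrix is drawn on `[-1, 1]` and rescaled so its spectral radius equals
#' `spectral_radius` exactly. Only the readout is ever trained — the
#' recurrent, input and feedback weights stay at their random values.
#'
#' @param params an [esn_params()].
#' @param seed integer seed; identical seeds give identical weights.
#' @return A list of class `esn_weights` with matrices `W_r` (n x n), `W_in`
#'   (n x input_dim), `W_back` (n x output_dim) and `W_out` (output_dim x n).
#' @export
init_esn <- function(params, seed = 1) {
  stopifnot(inherits(params, "esn_params"))
  n <- params$n_neurons
  set.seed(seed)
  w_r <- matrix(runif(n * n, -1, 1), n, n)
  rho <- max(abs(eigen(w_r, only.values = TRUE)$values))
  w_r <- w_r * (params$spectral_radius / rho)
  r_in <- params$w_in_range
  r_bk <- params$w_back_range
  r_out <- params$w_out_range
  structure(list(
    W_r = w_r,
    W_in = matrix(runif(n * params$input_dim, -r_in, r_in), n),
    W_back = matrix(runif(n * params$output_dim, -r_bk, r_bk), n),
    W_out = matrix(runif(params$output_dim * n, -r_out, r_out),
                   params$output_dim),
    params = params, seed = as.integer(seed)),
    class = "esn_weights")
}

#' One reservoir update
#'
#' Advances the internal state with the logistic nonlinearity and reads out
#' the next prediction linearly:
#' `s' = logistic(W_r s + W_in a + W_back out_prev)`, `out = W_out s'`.
#' The output at tick `t_n` is the prediction of the input at `t_n + dt`.
#'
#' @param weights an [init_esn()] result.
#' @param state numeric reservoir state vector (length `n_neurons`).
#' @param input analog input vector at the current tick.
#' @param prev_output the network's own previous output (free-running
#'   feedback).
#' @return `list(state, output)`.
#' @export
esn_step <- function(weights, state, input, prev_output) {
  if (length(state) != nrow(weights$W_r) ||
      length(input) != ncol(weights$W_in) ||
      length(prev_output) != ncol(weights$W_back)) {
    abort("dimension mismatch in esn_step")
  }
  s <- plogis(weights$W_r %*% state + weights$W_in %*% input +
                weights$W_back %*% prev_output)[, 1]
  list(state = s, output = (weights$W_out %*% s)[, 1])
}

#' Recursive-least-squares readout state
#'
#' @param n_neurons reservoir size (regressor dimension).
#' @param forgetting exponential forgetting factor in `(0, 1]`
#'   (default 0.999).
#' @param delta regularization scale: the inverse-correlation matrix is
#'   initialized to `diag(1 / delta)` (default 0.01).
#' @return A list of class `rls_state` with fields `P`, `forgetting`,
#'   `delta`.
#' @export
rls_state <- function(n_neurons, forgetting = 0.999, delta = 0.01) {
  stopifnot(n_neurons >= 1, forgetting > 0, forgetting <= 1, delta > 0)
  structure(list(P = diag(1 / delta, n_neurons), forgetting = forgetting,
                 delta = delta),
            class = "rls_state")
}

#' One RLS update of the readout
#'
#' Standard exponentially-weighted recursive least squares, with a single
#' inverse-correlation matrix shared by all output dimensions (they share the
#' regressor). The update pairs the reservoir state that issued a prediction
#' with the subsequently observed input. If `P` degenerates (non-finite or
#' non-positive diagonal) it is reinitialized with a warning.
#'
#' @param rls an [rls_state()].
#' @param regressor reservoir state vector that produced the pending
#'   prediction.
#' @param target the observed vector the prediction should have matched.
#' @param W_out current readout matrix (`output_dim x n_neurons`).
#' @return `list(rls, W_out)` with both updated.
#' @export
rls_update <- function(rls, regressor, target, W_out) {
  lam <- rls$forgetting
  s <- regressor
  Ps <- rls$P %*% s
  k <- Ps / (lam + sum(s * Ps))[1]
  err <- target - (W_out %*% s)[, 1]
  W_out <- W_out + tcrossprod(err, k[, 1])
  P <- (rls$P - tcrossprod(k[, 1], Ps[, 1])) / lam
  P <- (P + t(P)) / 2
  if (any(!is.finite(P)) || any(diag(P) <= 0)) {
    warning("RLS inverse-correlation matrix degenerated; reinitializing")
    P <- diag(1 / rls$delta, length(s))
  }
  rls$P <- P
  list(rls = rls, W_out = W_out)
}

#' Prediction error
#'
#' Euclidean norm of the difference between the predicted and observed
#' analog vectors.
#'
#' @param a observed vector.
#' @param a_hat predicted vector (same length).
#' @return Non-negative scalar.
#' @export
prediction_error <- function(a, a_hat) {
  stopifnot(length(a) == length(a_hat))
  sqrt(sum((a_hat - a)^2))
}

#' Similarity between observation and prediction
#'
#' `S = sum_i |a_i * a_hat_i| / (sum_i |a_i| * sum_i |a_hat_i|)`, the overlap
#' statistic each predictor reports to the selection layer; it lies in
#' `[0, 1]` and is defined as 0 when either vector is all-zero.
#'
#' @inheritParams prediction_error
#' @return Scalar in `[0, 1]`.
#' @export
similarity <- function(a, a_hat) {
  stopifnot(length(a) == length(a_hat))
  da <- sum(abs(a))
  dh <- sum(abs(a_hat))
  if (da == 0 || dh == 0) return(0)
  sum(abs(a * a_hat)) / (da * dh)
}

#' Archive ESN weights as JSON
#'
#' Writes a bank of ESN weight sets (and, optionally, their RLS states) to a
#' single JSON file, one entry per network with its seed and parameters, and
#' reads them back losslessly at full double precision.
#'
#' @param bank list of [init_esn()] results.
#' @param path file path.
#' @param rls optional list of [rls_state()] objects, same length as `bank`.
#' @return `write_weights()` invisibly returns `path`; `read_weights()`
#'   returns `list(bank, rls)`.
#' @export
write_weights <- function(bank, path, rls = NULL) {
  enc <- lapply(seq_along(bank), function(k) {
    w <- bank[[k]]
    out <- list(seed = w$seed, params = unclass(w$params),
                W_r = w$W_r, W_in = w$W_in, W_back = w$W_back,
                W_out = w$W_out)
    if (!is.null(rls)) {
      out$P <- rls[[k]]$P
      out$forgetting <- rls[[k]]$forgetting
      out$delta <- rls[[k]]$delta
    }
    out
  })
  jsonlite::write_json(enc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- length(raw)
  bank <- vector("list", n)
  rls <- vector("list", n)
  has_rls <- FALSE
  for (k in seq_len(n)) {
    e <- raw[[k]]
    p <- do.call(esn_params, lapply(e$params[c("input_dim", "output_dim",
                                               "n_neurons", "spectral_radius",
                                               "w_in_range", "w_back_range",
                                               "w_out_range")], unlist))
    bank[[k]] <- structure(list(W_r = as_mat(e$W_r), W_in = as_mat(e$W_in),
                                W_back = as_mat(e$W_back),
                                W_out = as_mat(e$W_out),
                                params = p,
                                seed = as.integer(unlist(e$seed))),
                           class = "esn_weights")
    if (!is.null(e$P)) {
      has_rls <- TRUE
      r <- rls_state(p$n_neurons, unlist(e$forgetting), unlist(e$delta))
      r$P <- as_mat(e$P)
      rls[[k]] <- r
    }
  }
  list(bank = bank, rls = if (has_rls) rls else NULL)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else do.call(rbind, lapply(x, unlist))
}
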