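#' @export
print.evsn_report <- function(x, ...) {
  n_rf <- length(unique(x$winners$rf_id))
  cat(sprintf("<evsn_report: %d ticks, %d receptive field(s)%s>\n",
              max(x$winners$tick), n_rf,
              if (!is.null(x$counts)) {
                sprintf(", %d/%d ESNs recruited",
                        sum(recruitment_report(x)$recruited),
                        length(x$counts))
              } else ""))
  invisible(x)
}

#' Tidy the per-tick winner timeline
#'
#' @param x an `evsn_report`.
#' @param ... unused.
#' @return A tibble with one row per tick and receptive field: `t_us`,
#'   `rf_id`, `winner`, `gated`, `s_winner`, and (when ground truth is
#'   available) the stimulus `label`, `phase` and `rep` active at that tick.
#' @method tidy evsn_report
#' @export
tidy.evsn_report <- function(x, ...) {
  w <- x$winners
  if (!is.null(x$truth)) {
    row <- findInterval(w$t_us - 1e-9, c(0, x$truth$end_us))
    row <- pmin(pmax(row, 1L), nrow(x$truth))
    w$label <- x$truth$label[row]
    w$phase <- x$truth$phase[row]
    w$rep <- x$truth$rep[row]
    w$stimulated <- w$t_us <= x$truth$offset_us[row]
  }
  w
}

#' One-row experiment summary
#'
#' @param x an `evsn_report`.
#' @param ... unused.
#' @return A tibble with tick counts, gate duty cycle, the number of
#'   training samples delivered and the number of recruited ESNs.
#' @method glance evsn_report
#' @export
glance.evsn_report <- function(x, ...) {
  rec <- if (!is.null(x$counts)) recruitment_report(x) else NULL
  tibble(
    n_ticks = max(x$winners$tick),
    n_rf = length(unique(x$winners$rf_id)),
    gated_frac = mean(x$winners$gated),
    training_samples = if (is.null(rec)) NA_integer_ else sum(rec$samples),
    n_esn = if (is.null(x$counts)) NA_integer_ else length(x$counts),
    n_recruited = if (is.null(rec)) NA_integer_ else sum(rec$recruited))
}

#' Modal winner per stimulus presentation
#'
#' For every presentation in the ground-truth schedule, the winner that took
#' the most gated ticks while the stimulus was on. Presentations with no
#' gated winner are dropped.
#'
#' @param report an `evsn_report` with ground truth.
#' @return A tibble with `label`, `phase`, `rep`, `modal_winner`, `n_gated`.
#' @export
modal_winners <- function(report) {
  stopifnot(!is.null(report$truth))
  td <- tidy(report)
  td <- td[td$gated & !is.na(td$winner) & td$stimulated, , drop = FALSE]
  td |>
    dplyr::count(.data$label, .data$phase, .data$rep, .data$winner) |>
    dplyr::group_by(.data$label, .data$phase, .data$rep) |>
    dplyr::summarise(
      modal_winner = .data$winner[which.max(.data$n)],
      n_gated = sum(.data$n), .groups = "drop")
}

#' Prediction-error quiescence summary
#'
#' Compares each ESN's prediction error during stimulation with its error
#' during the blank gaps between presentations. Because the analog input
#' decays with the filter time constant, the first `settle_s` seconds of each
#' gap are attributed to the preceding stimulus and excluded.
#'
#' @param report an `evsn_report` with recorded error traces.
#' @param settle_s offset-transient margin excluded from gaps (default 0.1).
#' @return A tibble per ESN: median error while stimulated (`stim_median`),
#'   maximum error in gaps (`gap_max`) and their ratio.
#' @export
error_quiescence <- function(report, settle_s = 0.1) {
  stopifnot(!is.null(report$errors), !is.null(report$truth))
  t_us <- report$winners$t_us
  tr <- report$truth
  row <- pmin(pmax(findInterval(t_us - 1e-9, c(0, tr$end_us)), 1L), nrow(tr))
  stim <- t_us <= tr$offset_us[row]
  gap <- t_us > tr$offset_us[row] + settle_s * 1e6 & t_us <= tr$end_us[row]
  err <- report$errors
  tibble(
    esn = seq_len(ncol(err)),
    stim_median = apply(err[stim, , drop = FALSE], 2, median),
    gap_max = if (any(gap)) {
      apply(err[gap, , drop = FALSE], 2, max)
    } else NA_real_
  ) |>
    dplyr::mutate(ratio = .data$gap_max / .data$stim_median)
}

#' Plot a winner timeline
#'
#' Raster of the gated winner per tick (one panel per receptive field), with
#' stimulus presentation windows shaded when ground truth is available.
#'
#' @param object an `evsn_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot evsn_report
#' @export
autoplot.evsn_report <- function(object, ...) {
  w <- object$winners
  w <- w[w$gated & !is.na(w$winner), , drop = FALSE]
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$t_us / 1e6,
                                       y = factor(.data$winner)))
  if (!is.null(object$truth)) {
    p <- p + ggplot2::geom_rect(
      data = object$truth,
      ggplot2::aes(xmin = .data$onset_us / 1e6, xmax = .data$offset_us / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  }
  p <- p + ggplot2::geom_point(shape = "|", size = 2)
  if (length(unique(w$rf_id)) > 1) {
    p <- p + ggplot2::facet_wrap(~rf_id, ncol = 1,
                                 labeller = ggplot2::label_both)
  }
  p + ggplot2::labs(x = "time [s]", y = "selected ESN",
                    title = "Winner-take-all selection timeline")
}

#' Plot per-ESN training-sample counts
#'
#' @param report an `evsn_report` from [run_experiment()].
#' @return A ggplot bar chart; recruited ESNs are highlighted.
#' @export
plot_recruitment <- function(report) {
  rec <- recruitment_report(report)
  ggplot2::ggplot(rec, ggplot2::aes(x = factor(.data$esn), y = .data$samples,
                                    fill = .data$recruited)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "ESN", y = "training samples",
                  title = "Learning samples per reservoir")
}

#' Plot prediction-error traces
#'
#' @param report an `evsn_report` with recorded error traces.
#' @param esns which ESNs to show (default all).
#' @return A ggplot object, one panel per ESN.
#' @export
plot_errors <- function(report, esns = NULL) {
  stopifnot(!is.null(report$errors))
  err <- report$errors
  if (is.null(esns)) esns <- seq_len(ncol(err))
  df <- tidyr::pivot_longer(
    tibble(t_s = report$winners$t_us / 1e6,
           as.data.frame(err[, esns, drop = FALSE]) |>
             setNames(paste0("esn", esns))),
    -"t_s", names_to = "esn", values_to = "error")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$error)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~esn, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "time [s]", y = "prediction error",
                  title = "Per-ESN prediction error")
}
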