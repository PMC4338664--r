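# a burst of events dense enough to open the activity gate in one tick
gate_burst <- function(sys, t_lo, t_hi, n = 3000, seed = 1) {
  set.seed(seed)
  g <- sys$grid
  px <- g$cell_size * (2 * sys$rf$half_extent + 1)
  x0 <- g$origin[1] + (sys$rf$center[1] - sys$rf$half_extent) * g$cell_size
  y0 <- g$origin[2] + (sys$rf$center[2] - sys$rf$half_extent) * g$cell_size
  data.frame(t_us = sort(floor(runif(n, t_lo, t_hi))),
             x = x0 + floor(runif(n, 0, px)),
             y = y0 + floor(runif(n, 0, px)),
             p = sample(c(-1, 1), n, replace = TRUE))
}

test_that("a gated tick trains exactly one predictor; an empty tick none", {
  sys <- build_system(small_config(seed = 2))
  empty <- data.frame(t_us = numeric(), x = numeric(), y = numeric(),
                      p = numeric())
  st <- train_step(sys, empty)
  expect_false(st$record$gated)
  expect_true(is.na(st$record$winner))
  expect_equal(sum(st$system$counts), 0)

  st2 <- train_step(sys, gate_burst(sys, 0, 1000))
  expect_true(st2$record$gated)
  w <- st2$record$winner
  expect_false(is.na(w))
  expect_equal(sum(st2$system$counts), 1)
  expect_equal(st2$system$counts[w], 1L)
  # no learning when frozen
  st3 <- train_step(sys, gate_burst(sys, 0, 1000), learn = FALSE)
  expect_equal(sum(st3$system$counts), 0)
  expect_equal(st3$system$bank[[st3$record$winner]]$W_out,
               sys$bank[[st3$record$winner]]$W_out)
})

test_that("an inhibited winner hands training to the next-best channel", {
  sys <- build_system(small_config(seed = 2))
  ev <- gate_burst(sys, 0, 1000)
  w1 <- train_step(sys, ev)$record$winner
  sys2 <- sys
  sys2$pm$inhibit_until_us[w1] <- 1e9
  st <- train_step(sys2, ev)
  expect_false(st$record$winner == w1)
  expect_equal(st$system$counts[st$record$winner], 1L)
  expect_equal(st$system$counts[w1], 0L)
})

test_that("the compiled engine reproduces the plain-R reference path", {
  cfg <- small_config(seed = 7)
  sys <- build_system(cfg)
  ev <- gate_burst(sys, 0, 150 * 1000, n = 20000, seed = 3)
  dt_us <- cfg$dt_s * 1e6
  inj <- evsn:::event_injection(ev, sys$rf, cfg$tau, dt_us, 150)
  lv <- rep(c(TRUE, FALSE), length.out = 150)
  a <- evsn:::engine_run(sys, inj, lv, TRUE, use_compiled = TRUE)
  b <- evsn:::engine_run(sys, inj, lv, TRUE, use_compiled = FALSE)
  expect_identical(a$winners$winner, b$winners$winner)
  expect_identical(a$winners$gated, b$winners$gated)
  expect_identical(a$system$counts, b$system$counts)
  expect_lt(max(abs(a$errors - b$errors)), 1e-10)
  for (k in seq_len(cfg$n_esn)) {
    expect_lt(max(abs(a$system$bank[[k]]$W_out - b$system$bank[[k]]$W_out)),
              1e-10)
    expect_lt(max(abs(a$system$pm$weights[[k]]$W_out -
                        b$system$pm$weights[[k]]$W_out)), 1e-10)
  }
  expect_equal(a$system$x0, b$system$x0, tolerance = 1e-12)
  expect_equal(a$system$pm$inhibit_until_us, b$system$pm$inhibit_until_us)
})

test_that("the engine matches tick-by-tick composition of train_step", {
  cfg <- small_config(seed = 4)
  sys <- build_system(cfg)
  ev <- gate_burst(sys, 0, 40 * 1000, n = 6000, seed = 5)
  dt_us <- cfg$dt_s * 1e6
  inj <- evsn:::event_injection(ev, sys$rf, cfg$tau, dt_us, 40)
  run <- evsn:::engine_run(sys, inj, rep(TRUE, 40))
  sys_r <- sys
  winners <- integer(40)
  for (k in 1:40) {
    st <- train_step(sys_r, ev[ev$t_us > (k - 1) * dt_us &
                                 ev$t_us <= k * dt_us, ])
    sys_r <- st$system
    winners[k] <- st$record$winner
  }
  expect_identical(run$winners$winner, winners)
  expect_identical(run$system$counts, sys_r$counts)
  expect_equal(run$system$a_raw, sys_r$a_raw, tolerance = 1e-12)
  for (k in seq_len(cfg$n_esn)) {
    expect_equal(run$system$bank[[k]]$W_out, sys_r$bank[[k]]$W_out,
                 tolerance = 1e-10)
  }
})

test_that("experiments are deterministic per seed", {
  cfg <- small_config(seed = 9)
  sched <- bar_schedule(orientations = c(0, 90), reps = 1, duration_s = 0.4,
                        pause_s = 0.2)
  r1 <- run_experiment(cfg, sched)
  r2 <- run_experiment(cfg, sched)
  expect_identical(r1$winners, r2$winners)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$errors, r2$errors)
  r3 <- run_experiment(small_config(seed = 10), sched)
  expect_false(identical(r1$winners$winner, r3$winners$winner))
})

test_that("recruitment follows the 1%-of-training-ticks rule", {
  # fabricated counts: the rule itself
  fake <- structure(list(counts = c(500L, 300L, 3L, 0L)),
                    class = "evsn_report")
  rec <- recruitment_report(fake)
  expect_equal(rec$recruited, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rec$share, c(500, 300, 3, 0) / 803)
  # counts are non-negative and bounded by the tick budget
  cfg <- small_config(seed = 3)
  sched <- bar_schedule(orientations = 40, reps = 1, duration_s = 0.5,
                        pause_s = 0.2)
  rep1 <- run_experiment(cfg, sched)
  expect_true(all(rep1$counts >= 0))
  expect_lte(sum(rep1$counts), nrow(rep1$winners))
  expect_equal(sum(rep1$counts),
               sum(rep1$winners$gated & !is.na(rep1$winners$winner)))
  # an idle run (stationary stimulus, so no events at all) recruits nobody
  cfg0 <- arch_config(n_esn = 4, n_neurons = 10,
                      sensor = sensor_model(width = 64, height = 64,
                                            noise_rate = 0),
                      cell_size = 5, rf_half_extent = 5, seed = 3)
  idle <- run_experiment(cfg0, bar_schedule(orientations = 0, reps = 1,
                                            duration_s = 0.5, pause_s = 0.2,
                                            speed = 0))
  expect_equal(sum(idle$winners$gated), 0)
  expect_equal(sum(recruitment_report(idle)$recruited), 0)
})

test_that("tiled receptive fields share weights but evolve independently", {
  cfg <- arch_config(n_esn = 3, n_neurons = 10,
                     sensor = sensor_model(width = 64, height = 64),
                     cell_size = 5, rf_center = c(6, 6), rf_half_extent = 2,
                     seed = 6)
  sched <- bar_schedule(orientations = 90, reps = 1, duration_s = 0.5,
                        pause_s = 0.1)
  trained <- run_experiment(cfg, sched)$system
  centers <- list(c(2, 2), c(8, 2), c(2, 8), c(8, 8))
  expect_error(tile_receptive_fields(trained, list(c(0, 0))), "beyond")
  tiled <- tile_receptive_fields(trained, centers)
  for (b in tiled$banks) {
    for (k in seq_len(cfg$n_esn)) {
      expect_identical(b$bank[[k]]$W_out, trained$bank[[k]]$W_out)
      expect_identical(b$bank[[k]]$W_r, trained$bank[[k]]$W_r)
    }
    expect_equal(b$counts, rep(0L, cfg$n_esn))
    expect_equal(b$a_raw, numeric(b$rf$m))
  }
  # drive only the first field's pixels: it gates, a distant one does not
  sens <- cfg$sensor
  g <- trained$grid
  px0 <- g$origin[1] + (2 - 2) * g$cell_size
  set.seed(8)
  burst <- event_stream(data.frame(
    t_us = sort(floor(runif(4000, 0, 3e5))),
    x = px0 + floor(runif(4000, 0, 5 * g$cell_size)),
    y = px0 + floor(runif(4000, 0, 5 * g$cell_size)),
    p = sample(c(-1, 1), 4000, replace = TRUE)), 64, 64)
  out <- run_tiled(tiled, burst, 0.3)
  gated_by_rf <- tapply(out$winners$gated, out$winners$rf_id, sum)
  expect_gt(gated_by_rf[["1"]], 0)
  expect_equal(unname(gated_by_rf[["4"]]), 0)
})

test_that("timeline lag recovers a known shift between winner timelines", {
  n <- 600
  set.seed(15)
  w1 <- sample(1:4, n, replace = TRUE)
  lag <- 50
  w2 <- c(rep(NA, lag), w1[1:(n - lag)])
  fake <- structure(list(
    winners = tibble::tibble(
      rf_id = rep(1:2, each = n),
      tick = rep(seq_len(n), 2),
      t_us = rep(seq_len(n) * 1000, 2),
      winner = c(w1, w2),
      gated = !is.na(c(w1, w2))),
    config = list(dt_s = 1e-3)), class = "evsn_report")
  est <- timeline_lag(fake, 1, 2, max_lag_s = 0.2)
  expect_equal(est$lag_s, 0.05)
})

test_that("reports tidy, glance and plot", {
  cfg <- small_config(seed = 5)
  sched <- rbind(bar_schedule(orientations = c(0, 90), reps = 1,
                              duration_s = 0.4, pause_s = 0.2),
                 bar_schedule(orientations = c(0, 90), reps = 1,
                              duration_s = 0.4, pause_s = 0.2,
                              phase = "test"))
  rep1 <- run_experiment(cfg, sched)
  td <- tidy(rep1)
  expect_true(all(c("label", "phase", "rep", "stimulated") %in% names(td)))
  expect_equal(nrow(td), nrow(rep1$winners))
  expect_setequal(unique(td$phase), c("learn", "test"))
  gl <- glance(rep1)
  expect_equal(gl$n_esn, 4L)
  expect_equal(gl$training_samples, sum(rep1$counts))
  # learning is frozen in the test phase
  expect_equal(sum(rep1$counts),
               sum(td$gated & !is.na(td$winner) & td$phase == "learn"))
  mw <- modal_winners(rep1)
  expect_true(all(mw$modal_winner %in% 1:4))
  q <- error_quiescence(rep1)
  expect_equal(nrow(q), 4)
  expect_true(all(q$stim_median > 0))
  expect_s3_class(autoplot(rep1), "ggplot")
  expect_s3_class(plot_recruitment(rep1), "ggplot")
  expect_s3_class(plot_errors(rep1, esns = 1:2), "ggplot")
})
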