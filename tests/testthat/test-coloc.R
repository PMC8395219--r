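mk_chan <- function(df, dt = 0.0305) {
  df$cell_id <- 1
  trajectory_set(df[c("cell_id", "particle_id", "frame", "x_um", "y_um", "state")],
                 dt = dt)
}

test_that("colocalization gates on distance and diffusion state", {
  base <- data.frame(particle_id = 1, frame = 1:3, x_um = 1, y_um = 1, state = 2)
  near_same <- data.frame(particle_id = 9, frame = 1:3, x_um = 1.15, y_um = 1, state = 2)
  far_same <- data.frame(particle_id = 9, frame = 1:3, x_um = 1.25, y_um = 1, state = 2)
  near_other <- data.frame(particle_id = 9, frame = 1:3, x_um = 1.15, y_um = 1, state = 1)

  ev1 <- detect_colocalization(mk_chan(base), mk_chan(near_same))
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$start_frame, 1L)
  expect_equal(ev1$end_frame, 3L)
  expect_equal(ev1$duration, 3 * 0.0305)
  expect_equal(ev1$mean_separation, 0.15)
  expect_true(ev1$censored)

  expect_equal(nrow(detect_colocalization(mk_chan(base), mk_chan(far_same))), 0L)
  expect_equal(nrow(detect_colocalization(mk_chan(base), mk_chan(near_other))), 0L)
  ## state gate can be lifted
  ev2 <- detect_colocalization(mk_chan(base), mk_chan(near_other),
                               require_same_state = FALSE)
  expect_equal(nrow(ev2), 1L)
  ## mismatched clocks rejected
  expect_error(detect_colocalization(mk_chan(base), mk_chan(near_same, dt = 0.05)),
               "frame intervals")
})

test_that("a one-frame gap splits events at the default merge tolerance", {
  a <- data.frame(particle_id = 1, frame = 1:7, x_um = 1, y_um = 1, state = 1)
  b <- data.frame(particle_id = 2, frame = 1:7,
                  x_um = c(1.1, 1.1, 1.1, 5, 1.1, 1.1, 5), y_um = 1, state = 1)
  ev <- detect_colocalization(mk_chan(a), mk_chan(b))
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$start_frame, c(1L, 5L))
  expect_equal(ev$end_frame, c(3L, 6L))
  expect_false(any(ev$censored))
  ## with max_gap = 1 the two segments merge
  ev2 <- detect_colocalization(mk_chan(a), mk_chan(b), max_gap = 1)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$end_frame, 6L)
})

test_that("detection equals exhaustive pair enumeration on a busy movie", {
  p <- sim_params(n_particles = 40, n_frames = 25, cell_area = 100, seed = 77)
  sim <- simulate_oligomer_intensities(simulate_trajectories(p), p)
  ch <- two_color_sets(sim, p)
  ev <- detect_colocalization(ch$ch1, ch$ch2)
  oracle <- brute_force_coloc(ch$ch1, ch$ch2)
  expect_equal(nrow(ev), nrow(oracle))
  expect_equal(ev$id_ch1, oracle$id1)
  expect_equal(ev$id_ch2, oracle$id2)
  expect_equal(ev$start_frame, oracle$start)
  expect_equal(ev$end_frame, oracle$end)
  ## channel symmetry: swapping channels permutes the id fields only
  ev_sw <- detect_colocalization(ch$ch2, ch$ch1)
  expect_equal(nrow(ev_sw), nrow(ev))
  expect_equal(sort(paste(ev_sw$id_ch2, ev_sw$id_ch1, ev_sw$start_frame)),
               sort(paste(ev$id_ch1, ev$id_ch2, ev$start_frame)))
})

test_that("colocalized fraction counts participating particles", {
  ch1 <- mk_chan(data.frame(particle_id = rep(1:5, each = 2), frame = rep(1:2, 5),
                            x_um = rep(seq(1, 9, by = 2), each = 2), y_um = 1,
                            state = 1))
  ## only particle 1 of ch2 sits near particle 1 of ch1
  ch2 <- mk_chan(data.frame(particle_id = rep(1:5, each = 2), frame = rep(1:2, 5),
                            x_um = rep(c(1.05, 20, 30, 40, 50), each = 2),
                            y_um = 1, state = 1))
  ev <- detect_colocalization(ch1, ch2)
  fr <- colocalized_fraction(ev, ch1, ch2)
  expect_equal(fr$overall, 2 / 10)
  expect_equal(fr$per_state$fraction, 0.2)
  ## no events -> 0
  fr0 <- colocalized_fraction(ev[0, ], ch1, ch2)
  expect_equal(fr0$overall, 0)
})

test_that("on-rate arithmetic matches its definition exactly", {
  ## 10 association events within the first second of a 3 s movie, 100 um^2
  ev <- data.frame(id_ch1 = 1:10, id_ch2 = 1:10, start_frame = 2:11,
                   end_frame = 12, duration = 0.1, state = 1,
                   mean_separation = 0.1, censored = FALSE)
  ev <- structure(ev, dt = 0.1, radius = 0.2, n_frames = 30,
                  class = c("coloc_events", "data.frame"))
  est <- on_rate(ev, area = 100, density_ch1 = 0.5, density_ch2 = 0.4)
  expect_equal(est$V0, 0.1, tolerance = 1e-9)
  expect_equal(est$k_on, est$V0 / (0.5 * 0.4), tolerance = 1e-12)
  expect_equal(est$k_on, 0.5, tolerance = 1e-9)
  ## no events -> zero rate; bad densities rejected
  expect_equal(on_rate(ev[0, ], 100, 0.5, 0.4)$k_on, 0)
  expect_error(on_rate(ev, 100, 0, 0.4), "positive")
})

test_that("k_on is invariant to doubling both channel densities", {
  run_kon <- function(n, seed) {
    p <- single_state_params(D = 0.25, loc_sigma = 0, n_particles = n,
                             n_frames = 50, cell_area = 100, seed = seed,
                             label_probs = c(0.5, 0.5, 0))
    sim <- simulate_oligomer_intensities(simulate_trajectories(p), p)
    ch <- two_color_sets(sim, p)
    ev <- detect_colocalization(ch$ch1, ch$ch2, require_same_state = TRUE)
    d1 <- nrow(ch$ch1$data) / 50 / 100
    d2 <- nrow(ch$ch2$data) / 50 / 100
    on_rate(ev, 100, d1, d2)$k_on
  }
  k1 <- mean(vapply(1:3, function(s) run_kon(60, s), 1))
  k2 <- mean(vapply(1:3, function(s) run_kon(120, s + 10), 1))
  expect_gt(k1, 0); expect_gt(k2, 0)
  expect_lt(abs(log(k2 / k1)), log(2))  # within 2-fold despite 4x encounter rate
})

test_that("on-time survival handles steps, censoring, and exponential data", {
  mk_ev <- function(dur, cens) {
    structure(data.frame(id_ch1 = seq_along(dur), id_ch2 = seq_along(dur),
                         start_frame = 1, end_frame = 2, duration = dur,
                         state = 1, mean_separation = 0.1, censored = cens),
              dt = 0.0305, radius = 0.2, n_frames = 100,
              class = c("coloc_events", "data.frame"))
  }
  ## all durations 5 frames, uncensored: survival steps to 0 at 5 dt
  dur <- rep(5 * 0.0305, 12)
  ot <- on_time_survival(mk_ev(dur, rep(FALSE, 12)))
  expect_equal(ot$mean_on_time, 5 * 0.0305)
  sf <- summary(ot$survfit)
  expect_equal(sf$time, 5 * 0.0305)
  expect_equal(min(ot$survfit$surv), 0)

  ## exponential durations, mean 0.3 s, ~20% censored
  set.seed(3)
  d <- stats::rexp(400, 1 / 0.3)
  cens <- stats::runif(400) < 0.2
  d[cens] <- d[cens] * stats::runif(sum(cens))
  ot2 <- on_time_survival(mk_ev(d, cens))
  expect_lt(abs(ot2$mean_on_time - 0.3) / 0.3, 0.1)

  ## all censored: flagged, no fit
  expect_warning(ot3 <- on_time_survival(mk_ev(rep(1, 15), rep(TRUE, 15))),
                 "censored")
  expect_true(is.na(ot3$mean_on_time))
  expect_error(on_time_survival(mk_ev(rep(1, 5), rep(FALSE, 5))), ">= 10")
})
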