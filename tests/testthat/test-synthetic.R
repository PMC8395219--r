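test_that("degenerate diffusion (D = 0, no noise) produces static tracks", {
  p <- single_state_params(D = 0, loc_sigma = 0, n_particles = 10,
                           n_frames = 20, seed = 1)
  sim <- simulate_trajectories(p)
  st <- pooled_steps(sim$traj)
  expect_equal(max(st$r2), 0)
  m <- compute_msd(sim$traj, max_lag = 5)
  expect_equal(m$msd, rep(0, nrow(m)))
})

test_that("free-diffusion step statistics match 2 D dt per axis (+ noise term)", {
  cases <- list(list(D = 0.25, sig = 0), list(D = 0.05, sig = 0.02))
  for (cs in cases) {
    p <- single_state_params(D = cs$D, loc_sigma = cs$sig, n_particles = 300,
                             n_frames = 41, seed = 101)
    sim <- simulate_trajectories(p)
    st <- pooled_steps(sim$traj)
    expect_gt(nrow(st), 1e4)
    target <- 2 * cs$D * p$dt + 2 * cs$sig^2
    for (ax in c("dx", "dy")) {
      v <- st[[ax]]^2
      se <- stats::sd(v) / sqrt(length(v))
      expect_lt(abs(mean(v) - target), 3 * se)
    }
  }
})

test_that("confined state has stationary variance L^2/12 and MSD plateau L^2/3", {
  L <- 0.15
  ## long tracks: the per-track variance estimator is downward-biased by the
  ## position autocorrelation time (~1.5 frames), negligible at 400 frames
  p <- single_state_params(D = 0.05, loc_sigma = 0, n_particles = 100,
                           n_frames = 400, confinement_side = L, seed = 7)
  sim <- simulate_trajectories(p)
  g <- sim$truth$positions
  v <- c(tapply(g$x_true, g$particle_id, stats::var),
         tapply(g$y_true, g$particle_id, stats::var))
  se <- stats::sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - L^2 / 12), 3 * se)
  m <- compute_msd(sim$traj, max_lag = 40)
  plateau <- mean(m$msd[m$lag > 20 * p$dt])
  expect_lt(abs(plateau - L^2 / 3), 0.1 * L^2 / 3)
})

test_that("state dwell times match the inverse exit rates", {
  k12 <- 2; k21 <- 1
  p <- sim_params(n_states = 2, D = c(0.01, 0.3),
                  rate_matrix = rbind(c(-k12, k12), c(k21, -k21)),
                  confinement_side = c(NA, NA), loc_sigma = 0,
                  n_particles = 200, n_frames = 200, track_lifetime_mean = Inf,
                  oligomer_dist = matrix(rep(c(1, rep(0, 7)), 2), 2, byrow = TRUE),
                  seed = 3)
  sim <- simulate_trajectories(p)
  d <- sim$traj$data
  P <- as.matrix(Matrix::expm(p$rate_matrix * p$dt))
  ## per-frame exit probability is a window-unbiased Bernoulli estimator of
  ## 1 - P_ss (unlike averaging interior run lengths, which is length-biased
  ## against long sojourns in a finite movie)
  for (cs in list(list(s = 1, rate = k12), list(s = 2, rate = k21))) {
    stay <- 0L; leave <- 0L
    for (tr in split(d$state_true, d$particle_id)) {
      here <- tr[-length(tr)] == cs$s
      stay <- stay + sum(here & tr[-1] == cs$s)
      leave <- leave + sum(here & tr[-1] != cs$s)
    }
    n <- stay + leave
    p_exit <- leave / n
    se_p <- sqrt(p_exit * (1 - p_exit) / n)
    ## exact per-frame exit probability from the matrix exponential
    expect_lt(abs(p_exit - (1 - P[cs$s, cs$s])), 3 * se_p)
    ## derived mean dwell agrees with 1/exit-rate (delta-method SE; the
    ## discrete-frame observation adds a few percent, inside the band)
    dwell <- p$dt / p_exit
    se_dwell <- p$dt * se_p / p_exit^2
    expect_lt(abs(dwell - 1 / cs$rate), 3 * se_dwell + 0.05 / cs$rate)
  }
})

test_that("oligomer intensities follow composition and labeling arithmetic", {
  ## monomers fully labeled with dye1: channel-1 mean equals the monomer mean
  p <- single_state_params(n_particles = 400, n_frames = 10, seed = 11,
                           label_probs = c(1, 0, 0))
  sim <- simulate_oligomer_intensities(simulate_trajectories(p), p)
  i1 <- sim$traj$data$intensity_ch1
  se <- stats::sd(i1) / sqrt(length(i1))
  expect_lt(abs(mean(i1) - 890), 3 * se)
  expect_true(all(sim$traj$data$intensity_ch2 == 0))

  ## pure dimers fully labeled: mean doubles
  p2 <- single_state_params(n_particles = 400, n_frames = 10, seed = 12,
                            label_probs = c(1, 0, 0))
  p2$oligomer_dist <- matrix(c(0, 1, rep(0, 6)), 1)
  sim2 <- simulate_oligomer_intensities(simulate_trajectories(p2), p2)
  i2 <- sim2$traj$data$intensity_ch1
  se2 <- stats::sd(i2) / sqrt(length(i2))
  expect_lt(abs(mean(i2) - 2 * 890), 3 * se2)

  ## tetramers at (0.4, 0.4, 0.2): dye1 visibility = 1 - 0.6^4
  p4 <- single_state_params(n_particles = 4000, n_frames = 1, seed = 13,
                            label_probs = c(0.4, 0.4, 0.2))
  p4$oligomer_dist <- matrix(c(0, 0, 0, 1, rep(0, 4)), 1)
  sim4 <- simulate_oligomer_intensities(simulate_trajectories(p4), p4)
  vis <- mean(sim4$truth$particles$n_dye1 > 0)
  p_vis <- 1 - 0.6^4
  se4 <- sqrt(p_vis * (1 - p_vis) / 4000)
  expect_lt(abs(vis - p_vis), 3 * se4)
  invisible_rows <- sim4$traj$data$intensity_ch1[
    sim4$truth$particles$n_dye1[sim4$traj$data$particle_id] == 0]
  expect_true(all(invisible_rows == 0))
})

test_that("time-lapse removal follows expectation arithmetic on counts", {
  p <- sim_params(n_particles = 2000, n_frames = 4, track_lifetime_mean = Inf,
                  seed = 5)
  ## no removal: pools constant
  s0 <- simulate_timelapse(p, matrix(0, 3, 3), time_points = c(0, 5, 10))
  pools <- attr(s0, "pool_counts")
  expect_true(all(pools == rep(pools[1, ], each = 3)))

  ## immobile removal 0.5 at the second time point only
  rr <- matrix(0, 3, 3); rr[2, 1] <- 0.5
  p$seed <- 6
  s1 <- simulate_timelapse(p, rr, time_points = c(0, 5, 10))
  pools1 <- attr(s1, "pool_counts")
  n0 <- pools1[1, 1]
  se <- sqrt(n0 * 0.5 * 0.5)
  expect_lt(abs(pools1[2, 1] - 0.5 * n0), 3 * se)
  expect_equal(pools1[2, 2:3], pools1[1, 2:3])
  frac_fast <- pools1[, 3] / rowSums(pools1)
  expect_gt(frac_fast[2], frac_fast[1])

  ## presets: TRPV4-like decline starts one time point before TRPV1-like
  t4 <- timelapse_preset("TRPV4"); t1 <- timelapse_preset("TRPV1")
  first_removal <- function(m) min(which(rowSums(m) > 0))
  expect_equal(first_removal(t1) - first_removal(t4), 1)
  expect_true(all(timelapse_preset("vehicle") == 0))
})

test_that("dose-response generator obeys Hill midpoint and asymptote", {
  conc <- c(1, 5, 10, 20, 1e6)
  d <- simulate_dose_response(10, 1.5, 2, 8, conc, noise_sd = 0, n_reps = 1)
  expect_equal(d$response[d$concentration == 10], (2 + 8) / 2)
  expect_equal(d$response[d$concentration == 1e6], 8, tolerance = 1e-6)
  d3 <- simulate_dose_response(10, 1, 0, 1, conc, noise_sd = 0.1, n_reps = 3,
                               seed = 1)
  expect_equal(nrow(d3), 15)
})

test_that("fixed seed makes every generator bit-reproducible", {
  p <- sim_params(n_particles = 30, n_frames = 15, seed = 99)
  a <- simulate_oligomer_intensities(simulate_trajectories(p), p)
  b <- simulate_oligomer_intensities(simulate_trajectories(p), p)
  expect_identical(a$traj$data, b$traj$data)
  expect_identical(a$truth$particles, b$truth$particles)
  r1 <- simulate_dose_response(26, 1, 1, 6, c(1, 10, 100, 1000),
                               noise_sd = 0.1, n_reps = 2, seed = 4)
  r2 <- simulate_dose_response(26, 1, 1, 6, c(1, 10, 100, 1000),
                               noise_sd = 0.1, n_reps = 2, seed = 4)
  expect_identical(r1, r2)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(dt = 0), "dt")
  expect_error(sim_params(rate_matrix = rbind(c(-1, -0.5, 1.5), c(1, -2, 1),
                                              c(0.5, 1, -1.5))),
               "negative off-diagonal")
  expect_error(sim_params(label_probs = c(0.5, 0.5, 0.5)), "probability")
  bad <- default_oligomer_dist(3); bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(sim_params(oligomer_dist = bad), "sum to 1")
})
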