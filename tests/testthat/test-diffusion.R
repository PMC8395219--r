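test_that("MSD over all time origins matches the hand-computed example", {
  d <- data.frame(cell_id = 1, particle_id = 1, frame = 1:3,
                  x_um = c(0, 1, 1), y_um = c(0, 0, 1))
  traj <- trajectory_set(d, dt = 0.0305)
  m <- compute_msd(traj, max_lag = 2)
  ## lag 1: mean(1, 1) = 1; lag 2: |(1,1)-(0,0)|^2 = 2
  expect_equal(m$msd[m$lag > 0], c(1, 2))
  expect_equal(m$msd[m$lag == 0], 0)
  expect_equal(m$n_pairs[m$lag > 0], c(2, 1))
})

test_that("MSD of simulated Brownian motion is unbiased at every lag", {
  p <- single_state_params(D = 0.25, n_particles = 300, n_frames = 30, seed = 17)
  sim <- simulate_trajectories(p)
  m <- compute_msd(sim$traj, max_lag = 4)
  for (i in which(m$lag > 0)) {
    D_hat <- m$msd[i] / (4 * m$lag[i])
    expect_lt(abs(D_hat - 0.25) / 0.25, 0.05)
  }
  lin <- fit_msd_linear(m)
  expect_lt(abs(lin$D - 0.25) / 0.25, 0.05)
})

test_that("linear fit recovers slope and localization-noise offset", {
  lag <- (1:6) * 0.0305
  exact <- data.frame(lag = c(0, lag), msd = c(0, 4 * 0.1 * lag),
                      sem = NA, n_pairs = NA)
  class(exact) <- c("msd_curve", "data.frame")
  fit <- fit_msd_linear(exact)
  expect_equal(fit$D, 0.1, tolerance = 1e-12)
  expect_equal(fit$offset, 0, tolerance = 1e-12)

  sig <- 0.02
  p <- single_state_params(D = 0.05, loc_sigma = sig, n_particles = 600,
                           n_frames = 40, seed = 23)
  sim <- simulate_trajectories(p)
  m <- compute_msd(sim$traj, max_lag = 4)
  fit2 <- fit_msd_linear(m)
  ## offset estimates 4 sigma^2 (0.0016 um^2)
  expect_lt(abs(fit2$offset - 4 * sig^2), 6e-4)
  expect_lt(abs(fit2$D - 0.05) / 0.05, 0.1)
})

test_that("confined fit recovers the domain side from plateau arithmetic", {
  ## exact saturating curve: plateau 0.0075 -> L = 0.15 um
  lag <- (1:15) * 0.0305
  tau <- 0.04
  curve <- data.frame(lag = c(0, lag),
                      msd = c(0, 0.0075 * (1 - exp(-lag / tau))),
                      sem = NA, n_pairs = NA)
  class(curve) <- c("msd_curve", "data.frame")
  fit <- fit_msd_confined(curve)
  expect_equal(fit$L, sqrt(3 * 0.0075), tolerance = 1e-4)
  expect_equal(fit$L, 0.15, tolerance = 1e-3)
  expect_equal(fit$offset, 0, tolerance = 1e-5)

  ## simulated confined immobile state, paper-scale sampling
  p <- single_state_params(D = 0.05, loc_sigma = 0.02, n_particles = 500,
                           n_frames = 100, confinement_side = 0.15, seed = 2)
  sim <- simulate_trajectories(p)
  m <- compute_msd(sim$traj, max_lag = 15)
  fit2 <- fit_msd_confined(m)
  expect_lt(abs(fit2$L - 0.15) / 0.15, 0.1)
  expect_false(fit2$censored)

  ## unconfined linear data: tau runs past the data range and is flagged
  lin <- data.frame(lag = c(0, lag), msd = c(0, 4 * 0.2 * lag),
                    sem = NA, n_pairs = NA)
  class(lin) <- c("msd_curve", "data.frame")
  expect_warning(fitl <- fit_msd_confined(lin), "censored")
  expect_true(fitl$censored)
})

test_that("step histograms agree with the Rayleigh-type overlay", {
  p <- single_state_params(D = 0.1, n_particles = 300, n_frames = 30, seed = 5)
  sim <- simulate_trajectories(p)
  f <- fit_vbhmm(sim$traj, K = 1, n_restarts = 1)
  labeled <- assign_states(sim$traj, f)
  sh <- step_histogram(labeled, state = 1, D = f$D_est)
  expect_gt(sh$n_steps, 5000)
  ## chi-square goodness of fit against the theoretical overlay
  h <- sh$hist
  widths <- diff(h$breaks)
  pexp <- sh$density(h$mids) * widths
  pexp <- pexp / sum(pexp)
  keep <- pexp * sh$n_steps >= 5
  gof <- suppressWarnings(stats::chisq.test(h$counts[keep], p = pexp[keep],
                                            rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)

  ## D = 0: all mass in the first bin
  p0 <- single_state_params(D = 0, n_particles = 20, n_frames = 10, seed = 1)
  sim0 <- simulate_trajectories(p0)
  sh0 <- step_histogram(sim0$traj, state = NULL, D = 1e-6,
                        breaks = seq(0, 1, by = 0.05))
  expect_equal(sh0$hist$counts[1], sh0$n_steps)
})

test_that("density time courses count labeled particles per area", {
  mk <- function(n, state) {
    d <- expand.grid(particle_id = seq_len(n), frame = 1:5)
    d$cell_id <- 1; d$x_um <- 0; d$y_um <- 0; d$state <- state
    trajectory_set(d[c("cell_id", "particle_id", "frame", "x_um", "y_um", "state")],
                   dt = 0.0305, cell_area = 100)
  }
  ## 100 particles always visible in 100 um^2 -> density 1
  tc <- density_timecourse(list(mk(100, 1)), time_points = 0, n_states = 1)
  expect_equal(tc$density, 1)
  expect_equal(tc$fraction, 1)

  ## uniform halving: densities halve, fractions unchanged
  two <- function(n1, n2) {
    a <- mk(n1, 1)$data; b <- mk(n2, 2)$data
    b$particle_id <- b$particle_id + n1
    trajectory_set(rbind(a, b), dt = 0.0305, cell_area = 100)
  }
  tc2 <- density_timecourse(list(two(60, 40), two(30, 20)),
                            time_points = c(0, 5), n_states = 2)
  d0 <- tc2[tc2$time == 0, ]; d1 <- tc2[tc2$time == 5, ]
  expect_equal(d1$density, d0$density / 2)
  expect_equal(d1$fraction, d0$fraction)
  expect_equal(sum(d0$fraction), 1, tolerance = 1e-9)
  expect_equal(d0$fraction, c(0.6, 0.4))
})

test_that("density-MSD correlation matches the textbook formula", {
  tc <- data.frame(time = rep(1:5, each = 1), state = 1,
                   density = c(5, 4, 3, 2, 1))
  expect_equal(correlate_density_msd(tc, c(1, 2, 3, 4, 5)), -1)
  msd <- c(0.3, 0.8, 0.2, 0.9, 0.5)
  expect_equal(correlate_density_msd(tc, msd),
               stats::cor(c(5, 4, 3, 2, 1), msd))
  expect_warning(r <- correlate_density_msd(
    data.frame(time = 1:3, state = 1, density = c(1, 1, 1)), c(1, 2, 3)),
    "constant")
  expect_true(is.na(r))
})
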