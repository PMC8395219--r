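px <- 0.067

one_spot_set <- function(x_px, y_px, frames = 1, intensity = NULL) {
  d <- data.frame(cell_id = 1, particle_id = 1, frame = frames,
                  x_um = x_px * px, y_um = y_px * px)
  if (!is.null(intensity)) d$intensity <- intensity
  trajectory_set(d, dt = 0.0305, pixel_size = px)
}

test_that("renderer obeys Poisson statistics and photon budget", {
  empty <- trajectory_set(data.frame(cell_id = integer(0), particle_id = integer(0),
                                     frame = integer(0), x_um = numeric(0),
                                     y_um = numeric(0)),
                          dt = 0.0305, pixel_size = px)
  set.seed(1)
  stk <- render_movie(empty, img_size = 32, background = 100)
  expect_equal(mean(stk), 100, tolerance = 0.02)
  expect_equal(stats::var(as.numeric(stk)), 100, tolerance = 0.1)

  set.seed(2)
  stk1 <- render_movie(one_spot_set(16.2, 15.7), img_size = 32, background = 0,
                       photon_scale = 4000)
  expect_lt(abs(sum(stk1) - 4000), 3 * sqrt(4000))
})

test_that("rendered centroid sits at the requested subpixel position", {
  stk <- render_movie(one_spot_set(20.3, 41.7), img_size = 64, background = 0,
                      photon_scale = 1000, noise = FALSE)
  img <- stk[, , 1]
  tot <- sum(img)
  cx <- sum(img %*% (seq_len(64) - 0.5)) / tot       # columns = x
  cy <- sum((seq_len(64) - 0.5) %*% img) / tot       # rows = y
  expect_lt(abs(cx - 20.3), 0.05)
  expect_lt(abs(cy - 41.7), 0.05)
})

test_that("preprocessing removes flat background and preserves static spots", {
  flat <- array(500, c(40, 40, 3))
  pp <- preprocess_stack(flat, rolling_ball_radius = 10, frame_average = FALSE)
  expect_equal(max(abs(pp)), 0)

  stk <- render_movie(one_spot_set(20.5, 20.5, frames = 1:2), img_size = 40,
                      background = 0, photon_scale = 2000, noise = FALSE)
  pp2 <- preprocess_stack(stk, rolling_ball_radius = 0, frame_average = TRUE)
  expect_equal(dim(pp2)[3], 1L)
  expect_equal(sum(pp2), sum(stk[, , 1]), tolerance = 0.05)

  expect_error(preprocess_stack(array(1, c(5, 5, 1)), frame_average = TRUE),
               "2 frames")
})

test_that("spot detection is subpixel-accurate and resolves nearby spots", {
  expect_equal(nrow(detect_spots(matrix(10, 30, 30))), 0L)

  stk <- render_movie(one_spot_set(20.3, 41.7), img_size = 64, background = 0,
                      photon_scale = 5000, noise = FALSE)
  sp <- detect_spots(stk[, , 1], snr_threshold = 5)
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$x - 20.3), 0.1)
  expect_lt(abs(sp$y - 41.7), 0.1)
  expect_equal(sp$intensity, 5000, tolerance = 0.05)

  d2 <- data.frame(cell_id = 1, particle_id = 1:2, frame = 1,
                   x_um = c(20.3, 30.3) * px, y_um = c(41.7, 41.7) * px)
  set.seed(3)
  stk2 <- render_movie(trajectory_set(d2, dt = 0.0305, pixel_size = px),
                       img_size = 64, background = 50, photon_scale = 3000)
  sp2 <- detect_spots(stk2[, , 1], snr_threshold = 5)
  expect_equal(nrow(sp2), 2L)
})

test_that("linking follows nearest-neighbour rules and the max_disp veto", {
  mk <- function(frame, x, y) data.frame(frame = frame, x = x, y = y,
                                         intensity = 1, fit_quality = 0,
                                         method = "gaussian")
  ## one particle over 2 frames
  sp <- rbind(mk(1, 10, 10), mk(2, 10.5, 10))
  tr <- link_spots(sp, max_disp = 0.45, pixel_size = px)
  expect_equal(length(unique(tr$data$particle_id)), 1L)
  expect_equal(nrow(tr$data), 2L)

  ## two well-separated static particles over 10 frames: no identity swap
  sp2 <- do.call(rbind, lapply(1:10, function(f)
    rbind(mk(f, 10, 10), mk(f, 40, 40))))
  tr2 <- link_spots(sp2, max_disp = 0.45, pixel_size = px)
  expect_equal(length(unique(tr2$data$particle_id)), 2L)
  lens <- table(tr2$data$particle_id)
  expect_true(all(lens == 10))
  xr <- tapply(tr2$data$x_um, tr2$data$particle_id, function(v) diff(range(v)))
  expect_true(all(xr == 0))

  ## displacement beyond max_disp: two single-frame tracks
  sp3 <- rbind(mk(1, 10, 10), mk(2, 30, 10))
  tr3 <- link_spots(sp3, max_disp = 0.45, pixel_size = px)
  expect_equal(length(unique(tr3$data$particle_id)), 2L)

  ## gap closing with interpolation
  sp4 <- rbind(mk(1, 10, 10), mk(3, 12, 10))
  tr4 <- link_spots(sp4, max_disp = 0.45, max_gap = 1, pixel_size = px)
  expect_equal(length(unique(tr4$data$particle_id)), 1L)
  mid <- tr4$data[tr4$data$frame == 2, ]
  expect_true(mid$inferred)
  expect_equal(mid$x_um, 11 * px)

  ## determinism
  expect_identical(link_spots(sp2, max_disp = 0.45, pixel_size = px)$data,
                   tr2$data)
})

test_that("tracker recovers >= 90% of ground-truth step identities", {
  p <- single_state_params(D = 0.05, loc_sigma = 0, n_particles = 6,
                           n_frames = 12, seed = 31,
                           cell_area = (64 * px)^2)
  sim <- simulate_trajectories(p)
  sim$traj$pixel_size <- px
  set.seed(8)
  stack <- render_movie(sim$traj, img_size = 64, psf_sigma = 1.3,
                        background = 100, photon_scale = 800)
  tr <- track_movie(stack, snr_threshold = 5)
  d <- tr$data; g <- sim$truth$positions
  d$true_id <- NA_integer_
  for (i in seq_len(nrow(d))) {
    gg <- g[g$frame == d$frame[i], ]
    dd <- sqrt((gg$x_true - d$x_um[i])^2 + (gg$y_true - d$y_um[i])^2)
    if (length(dd) && min(dd) < 0.15) d$true_id[i] <- gg$particle_id[which.min(dd)]
  }
  ok <- 0; tot <- 0
  for (s in split(d, d$particle_id)) {
    if (nrow(s) < 2) next
    for (j in 2:nrow(s)) {
      tot <- tot + 1
      if (!is.na(s$true_id[j]) && !is.na(s$true_id[j - 1]) &&
          s$true_id[j] == s$true_id[j - 1]) ok <- ok + 1
    }
  }
  expect_gt(tot, 20)
  expect_gte(ok / tot, 0.9)
})
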