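#' Simulation parameters for switching-diffusion trajectories
#'
#' Bundles and validates everything the trajectory generator needs. The
#' defaults are a three-state preset modelled on TRPV-channel dynamics in the
#' basal membrane of HEK293 cells: immobile / medium / fast states with
#' diffusion coefficients near 0.008, 0.05 and 0.25 um^2/s, the immobile
#' state confined to ~150 nm membrane domains, subsecond state dwell times,
#' a 30.5 ms frame interval, 20 nm localization noise, oligomer sizes 1-8
#' whose mix shifts toward higher orders in slower states, and two-dye
#' stochastic labeling at 40% + 40% per subunit (80% of subunits carry a
#' dye in total).
#'
#' @param n_states Number of diffusion states.
#' @param D Per-state diffusion coefficient, um^2/s (ascending).
#' @param rate_matrix `n_states x n_states` transition rate matrix Q in 1/s:
#'   non-negative off-diagonals, rows summing to zero.
#' @param confinement_side Per-state side length (um) of a square reflecting
#'   domain; `NA` for unconfined states.
#' @param dt Frame interval, seconds.
#' @param n_frames Frames per movie.
#' @param n_particles Particles per cell.
#' @param n_cells Number of cells (independent replicates).
#' @param loc_sigma Localization noise SD per axis, um.
#' @param track_lifetime_mean Mean track lifetime in frames (exponential,
#'   truncated at `n_frames`); `Inf` for no disappearance.
#' @param oligomer_dist Matrix `n_states x n_max`: per-state probability
#'   vector over oligomer sizes 1..n_max (rows sum to 1). A particle's size
#'   is drawn once, conditional on its initial state, and is fixed for its
#'   lifetime.
#' @param label_probs Length-3 probability vector `(p_dye1, p_dye2,
#'   p_unlabeled)` per subunit.
#' @param monomer_mean Per-dye mean single-fluorophore intensity, a.u.
#' @param monomer_cv Coefficient of variation of the (lognormal) monomer
#'   intensity distribution.
#' @param cell_area Cell footprint, um^2 (square field assumed).
#' @param seed Optional integer seed.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_states = 3,
                       D = c(0.008, 0.05, 0.25),
                       rate_matrix = rbind(c(-1.5,  1.0, 0.5),
                                           c( 1.0, -2.0, 1.0),
                                           c( 0.5,  1.0, -1.5)),
                       confinement_side = c(0.15, NA, NA),
                       dt = 0.0305,
                       n_frames = 100,
                       n_particles = 200,
                       n_cells = 1,
                       loc_sigma = 0.02,
                       track_lifetime_mean = 30,
                       oligomer_dist = default_oligomer_dist(n_states),
                       label_probs = c(0.4, 0.4, 0.2),
                       monomer_mean = c(ch1 = 890, ch2 = 720),
                       monomer_cv = 0.35,
                       cell_area = 400,
                       seed = NULL) {
  stopifnot(length(D) == n_states, length(confinement_side) == n_states)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (any(D < 0)) stop("diffusion coefficients must be >= 0", call. = FALSE)
  if (loc_sigma < 0) stop("loc_sigma must be >= 0", call. = FALSE)
  check_rate_matrix(rate_matrix)
  if (!is.matrix(oligomer_dist)) oligomer_dist <- matrix(oligomer_dist, nrow = n_states,
                                                         ncol = length(oligomer_dist), byrow = TRUE)
  if (nrow(oligomer_dist) != n_states)
    stop("oligomer_dist needs one row per state", call. = FALSE)
  if (any(abs(rowSums(oligomer_dist) - 1) > 1e-12))
    stop("oligomer_dist rows must sum to 1", call. = FALSE)
  if (abs(sum(label_probs) - 1) > 1e-12 || any(label_probs < 0))
    stop("label_probs must be a probability vector", call. = FALSE)
  structure(list(n_states = n_states, D = D, rate_matrix = rate_matrix,
                 confinement_side = confinement_side, dt = dt,
                 n_frames = as.integer(n_frames),
                 n_particles = as.integer(n_particles),
                 n_cells = as.integer(n_cells),
                 loc_sigma = loc_sigma,
                 track_lifetime_mean = track_lifetime_mean,
                 oligomer_dist = oligomer_dist, label_probs = label_probs,
                 monomer_mean = monomer_mean, monomer_cv = monomer_cv,
                 cell_area = cell_area, seed = seed),
            class = "sim_params")
}

#' Default state-dependent oligomer-size mix
#'
#' Slower states carry more higher-order oligomers: the fast state peaks at
#' apparent dimers, the medium state at trimers, the immobile state at
#' tetramers and above, mirroring intensity histograms whose per-state peaks
#' sit near 2x, 3x and 4x the single-fluorophore intensity.
#'
#' @param n_states Number of states (rows); sizes run 1..8.
#' @return `n_states x 8` row-stochastic matrix.
#' @export
default_oligomer_dist <- function(n_states = 3) {
  base <- rbind(
    immobile = c(0.02, 0.13, 0.20, 0.35, 0.15, 0.10, 0.03, 0.02),
    medium   = c(0.05, 0.30, 0.30, 0.25, 0.10, 0.00, 0.00, 0.00),
    fast     = c(0.15, 0.55, 0.20, 0.10, 0.00, 0.00, 0.00, 0.00))
  if (n_states == 3) return(base)
  if (n_states == 1) return(base[2, , drop = FALSE])
  m <- base[rep_len(seq_len(3), n_states), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ", x$n_states, " states, D = ",
      paste(signif(x$D, 3), collapse = "/"), " um^2/s, dt = ", x$dt, " s\n",
      "  ", x$n_cells, " cell(s) x ", x$n_particles, " particles x ",
      x$n_frames, " frames; sigma_loc = ", x$loc_sigma, " um\n", sep = "")
  invisible(x)
}

#' Simulate switching-diffusion trajectories
#'
#' Generates 2-D single-particle tracks from a continuous-time Markov chain
#' over diffusion states observed at the frame interval: the per-frame
#' transition matrix is the exact matrix exponential `expm(Q * dt)`.
#' Displacements per frame per axis are zero-mean Gaussian with variance
#' `2 * D_state * dt`. States with a finite `confinement_side` evolve inside
#' a square domain with reflecting boundaries; the domain is centred on the
#' particle's position when it enters the state (particles starting confined
#' begin at a uniformly drawn position inside their domain, so the confined
#' position distribution is stationary). Reported positions add isotropic
#' Gaussian localization noise. Track lifetimes are exponential with mean
#' `track_lifetime_mean` frames, truncated to the movie length.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `traj` (a [trajectory_set()], including a
#'   `state_true` column) and `truth` (noise-free positions, per-particle
#'   oligomer sizes and dye-label counts, per-step states).
#' @export
simulate_trajectories <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  K <- params$n_states
  dtv <- params$dt
  P <- as.matrix(Matrix::expm(params$rate_matrix * dtv))
  P <- pmax(P, 0); P <- P / rowSums(P)
  pi0 <- stationary_dist_Q(params$rate_matrix)
  side <- sqrt(params$cell_area)
  sd_step <- sqrt(2 * params$D * dtv)

  rows <- vector("list", params$n_cells)
  truth_rows <- vector("list", params$n_cells)
  olig <- vector("list", params$n_cells)
  for (cell in seq_len(params$n_cells)) {
    n <- params$n_particles
    nf <- params$n_frames
    len <- if (is.finite(params$track_lifetime_mean))
      pmin(pmax(1L, as.integer(ceiling(stats::rexp(n, 1 / params$track_lifetime_mean)))), nf)
    else rep(nf, n)

    s0 <- sample.int(K, n, replace = TRUE, prob = pi0)
    states <- matrix(NA_integer_, n, nf)
    states[, 1] <- s0
    for (t in seq_len(nf - 1L)) {
      u <- stats::runif(n)
      cp <- P[states[, t], , drop = FALSE]
      cp <- t(apply(cp, 1, cumsum))
      states[, t + 1L] <- max.col(u < cp, ties.method = "first")
    }

    x <- matrix(NA_real_, n, nf); y <- matrix(NA_real_, n, nf)
    cx <- stats::runif(n, 0, side); cy <- stats::runif(n, 0, side)
    conf0 <- !is.na(params$confinement_side[s0])
    L0 <- params$confinement_side[s0]
    x[, 1] <- ifelse(conf0, cx + stats::runif(n, -0.5, 0.5) * L0, cx)
    y[, 1] <- ifelse(conf0, cy + stats::runif(n, -0.5, 0.5) * L0, cy)
    dom_x <- cx; dom_y <- cy  # domain centres for confined motion
    for (t in seq_len(nf - 1L)) {
      st <- states[, t + 1L]
      dx <- stats::rnorm(n, 0, sd_step[st])
      dy <- stats::rnorm(n, 0, sd_step[st])
      nx <- x[, t] + dx; ny <- y[, t] + dy
      Lst <- params$confinement_side[st]
      confined <- !is.na(Lst)
      entered <- confined & (is.na(params$confinement_side[states[, t]]))
      dom_x[entered] <- x[entered, t]
      dom_y[entered] <- y[entered, t]
      if (any(confined)) {
        nx[confined] <- reflect_into(nx[confined], dom_x[confined] - Lst[confined] / 2,
                                     dom_x[confined] + Lst[confined] / 2)
        ny[confined] <- reflect_into(ny[confined], dom_y[confined] - Lst[confined] / 2,
                                     dom_y[confined] + Lst[confined] / 2)
      }
      x[, t + 1L] <- nx; y[, t + 1L] <- ny
    }

    osize <- integer(n)
    for (k in seq_len(K)) {
      idx <- which(s0 == k)
      if (length(idx))
        osize[idx] <- sample.int(ncol(params$oligomer_dist), length(idx),
                                 replace = TRUE, prob = params$oligomer_dist[k, ])
    }
    lab <- t(vapply(osize, function(m)
      as.integer(stats::rmultinom(1, m, params$label_probs)[, 1]), integer(3)))

    keep <- lapply(seq_len(n), function(i) seq_len(len[i]))
    nr <- sum(len)
    obs_x <- unlist(lapply(seq_len(n), function(i) x[i, keep[[i]]]))
    obs_y <- unlist(lapply(seq_len(n), function(i) y[i, keep[[i]]]))
    st_v <- unlist(lapply(seq_len(n), function(i) states[i, keep[[i]]]))
    fr_v <- unlist(keep)
    id_v <- rep(seq_len(n), len)
    noise_x <- stats::rnorm(nr, 0, params$loc_sigma)
    noise_y <- stats::rnorm(nr, 0, params$loc_sigma)
    rows[[cell]] <- data.frame(
      cell_id = cell, particle_id = id_v, frame = fr_v,
      x_um = obs_x + noise_x, y_um = obs_y + noise_y,
      state_true = st_v)
    truth_rows[[cell]] <- data.frame(
      cell_id = cell, particle_id = id_v, frame = fr_v,
      x_true = obs_x, y_true = obs_y, state_true = st_v)
    olig[[cell]] <- data.frame(cell_id = cell, particle_id = seq_len(n),
                               oligomer_size = osize,
                               n_dye1 = lab[, 1], n_dye2 = lab[, 2],
                               lifetime = len)
  }
  data <- do.call(rbind, rows)
  traj <- trajectory_set(data, dt = dtv, cell_area = params$cell_area)
  truth <- list(positions = do.call(rbind, truth_rows),
                particles = do.call(rbind, olig),
                params = params)
  class(truth) <- "sim_truth"
  list(traj = traj, truth = truth)
}

#' Attach oligomer fluorescence intensities to simulated trajectories
#'
#' Each particle's per-channel intensity in a frame is the sum of
#' independent lognormal single-fluorophore draws, one per labeled subunit
#' (one draw per subunit per frame); unlabeled subunits contribute nothing.
#' Particles with no labeled subunit in a channel have intensity 0 there —
#' they are invisible in that channel.
#'
#' @param sim Result of [simulate_trajectories()] (list with `traj`, `truth`).
#' @param params The [sim_params()] used for the simulation.
#' @return The input list with `traj$data` gaining `intensity_ch1` and
#'   `intensity_ch2` columns.
#' @export
simulate_oligomer_intensities <- function(sim, params) {
  stopifnot(inherits(params, "sim_params"))
  d <- sim$traj$data
  pt <- sim$truth$particles
  if (any(pt$oligomer_size > ncol(params$oligomer_dist)))
    stop("oligomer size exceeds n_max", call. = FALSE)
  key <- paste(d$cell_id, d$particle_id)
  pkey <- paste(pt$cell_id, pt$particle_id)
  idx <- match(key, pkey)
  for (ch in 1:2) {
    nlab <- pt[[paste0("n_dye", ch)]][idx]
    pars <- lnorm_from_mean_cv(params$monomer_mean[ch], params$monomer_cv)
    total <- sum(nlab)
    draws <- numeric(nrow(d))
    pos <- nlab > 0
    if (any(pos)) {
      all_draws <- stats::rlnorm(sum(nlab[pos]), pars["meanlog"], pars["sdlog"])
      grp <- rep(seq_len(sum(pos)), nlab[pos])
      draws[pos] <- as.numeric(tapply(all_draws, grp, sum))
    }
    d[[paste0("intensity_ch", ch)]] <- draws
  }
  sim$traj$data <- d
  sim
}

#' Split a labeled simulation into two detection channels
#'
#' Emulates dual-camera two-colour imaging: a particle appears in channel c
#' only if it carries at least one dye-c label, and each channel re-localizes
#' the particle with its own independent Gaussian noise (the cameras are
#' independent). Channel intensities are carried over.
#'
#' @param sim Result of [simulate_oligomer_intensities()].
#' @param params The [sim_params()] used.
#' @return List with `trajectory_set`s `ch1` and `ch2`.
#' @export
two_color_sets <- function(sim, params) {
  pt <- sim$truth$particles
  pos <- sim$truth$positions
  out <- list()
  for (ch in 1:2) {
    vis <- pt[pt[[paste0("n_dye", ch)]] > 0, c("cell_id", "particle_id")]
    key <- paste(pos$cell_id, pos$particle_id)
    keep <- key %in% paste(vis$cell_id, vis$particle_id)
    p <- pos[keep, ]
    n <- nrow(p)
    d <- data.frame(cell_id = p$cell_id, particle_id = p$particle_id,
                    frame = p$frame,
                    x_um = p$x_true + stats::rnorm(n, 0, params$loc_sigma),
                    y_um = p$y_true + stats::rnorm(n, 0, params$loc_sigma),
                    state_true = p$state_true)
    ik <- paste(sim$traj$data$cell_id, sim$traj$data$particle_id, sim$traj$data$frame)
    dk <- paste(d$cell_id, d$particle_id, d$frame)
    icol <- paste0("intensity_ch", ch)
    if (!is.null(sim$traj$data[[icol]]))
      d$intensity <- sim$traj$data[[icol]][match(dk, ik)]
    out[[paste0("ch", ch)]] <- trajectory_set(d, dt = params$dt,
                                              cell_area = params$cell_area)
  }
  out
}

#' Simulate a 5-minute-interval time-lapse with state-selective removal
#'
#' Independent movies are generated at each time point from a particle pool
#' whose per-state counts decay by the given removal probabilities between
#' consecutive time points (endocytosis acts on whole particles between
#' movies, never mid-movie). Within each movie a particle keeps the
#' diffusion state it was assigned from the stationary distribution at the
#' first time point: between-state switching is subsecond, far faster than
#' the 5-minute sampling, so the state label here plays the role of a
#' persistent membrane-domain association rather than an instantaneous
#' kinetic state.
#'
#' @param params A [sim_params()].
#' @param removal_rates Matrix `length(time_points) x n_states` of removal
#'   probabilities in `[0, 1]` applied before each time point (first row is
#'   usually 0 — nothing is removed before the basal movie).
#' @param time_points Numeric vector of time points (minutes), ordered.
#' @return List of simulation results (as from [simulate_trajectories()]),
#'   one per time point, with the per-state pool counts in
#'   `attr(, "pool_counts")`.
#' @export
simulate_timelapse <- function(params, removal_rates, time_points = c(0, 5, 10, 15, 20)) {
  stopifnot(inherits(params, "sim_params"))
  if (is.unsorted(time_points)) stop("time_points must be ordered", call. = FALSE)
  removal_rates <- as.matrix(removal_rates)
  if (any(removal_rates < 0 | removal_rates > 1))
    stop("removal probabilities must lie in [0, 1]", call. = FALSE)
  if (nrow(removal_rates) != length(time_points) ||
      ncol(removal_rates) != params$n_states)
    stop("removal_rates must be length(time_points) x n_states", call. = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)
  K <- params$n_states
  pi0 <- stationary_dist_Q(params$rate_matrix)
  counts <- as.integer(stats::rmultinom(1, params$n_particles, pi0)[, 1])
  ## frozen-state params: zero rate matrix, state fixed per particle
  out <- vector("list", length(time_points))
  pools <- matrix(NA_integer_, length(time_points), K)
  for (i in seq_along(time_points)) {
    counts <- vapply(seq_len(K), function(k)
      stats::rbinom(1, counts[k], 1 - removal_rates[i, k]), integer(1))
    pools[i, ] <- counts
    sims <- lapply(seq_len(K), function(k) {
      if (counts[k] == 0L) return(NULL)
      pk <- params
      pk$seed <- NULL
      pk$n_particles <- counts[k]
      Q0 <- matrix(0, K, K)
      pk$rate_matrix <- Q0
      sim_k <- simulate_trajectories_fixed_state(pk, state = k)
      sim_k
    })
    sims <- sims[!vapply(sims, is.null, TRUE)]
    merged <- merge_sims(sims, params)
    merged <- simulate_oligomer_intensities(merged, params)
    out[[i]] <- merged
  }
  attr(out, "time_points") <- time_points
  attr(out, "pool_counts") <- pools
  out
}

## simulate with every particle pinned to one state (used by the time-lapse)
simulate_trajectories_fixed_state <- function(params, state) {
  p2 <- params
  p2$rate_matrix <- matrix(0, params$n_states, params$n_states)
  simulate_trajectories_init(p2, rep.int(state, p2$n_particles))
}

## as simulate_trajectories but with prescribed initial states
simulate_trajectories_init <- function(params, s0) {
  ps <- params
  ps$seed <- NULL
  ## reuse the main generator by temporarily overriding the initial draw:
  ## implemented by rebuilding the chain here (zero-rate case is the only use)
  stopifnot(all(rowSums(abs(ps$rate_matrix)) == 0))
  K <- ps$n_states; nf <- ps$n_frames; n <- ps$n_particles
  dtv <- ps$dt
  sd_step <- sqrt(2 * ps$D * dtv)
  side <- sqrt(ps$cell_area)
  len <- if (is.finite(ps$track_lifetime_mean))
    pmin(pmax(1L, as.integer(ceiling(stats::rexp(n, 1 / ps$track_lifetime_mean)))), nf)
  else rep(nf, n)
  states <- matrix(rep(s0, nf), n, nf)
  x <- matrix(NA_real_, n, nf); y <- matrix(NA_real_, n, nf)
  cx <- stats::runif(n, 0, side); cy <- stats::runif(n, 0, side)
  Ls <- ps$confinement_side[s0]
  conf <- !is.na(Ls)
  x[, 1] <- ifelse(conf, cx + stats::runif(n, -0.5, 0.5) * Ls, cx)
  y[, 1] <- ifelse(conf, cy + stats::runif(n, -0.5, 0.5) * Ls, cy)
  for (t in seq_len(nf - 1L)) {
    dx <- stats::rnorm(n, 0, sd_step[s0]); dy <- stats::rnorm(n, 0, sd_step[s0])
    nx <- x[, t] + dx; ny <- y[, t] + dy
    if (any(conf)) {
      nx[conf] <- reflect_into(nx[conf], cx[conf] - Ls[conf] / 2, cx[conf] + Ls[conf] / 2)
      ny[conf] <- reflect_into(ny[conf], cy[conf] - Ls[conf] / 2, cy[conf] + Ls[conf] / 2)
    }
    x[, t + 1L] <- nx; y[, t + 1L] <- ny
  }
  osize <- integer(n)
  for (k in seq_len(K)) {
    idx <- which(s0 == k)
    if (length(idx))
      osize[idx] <- sample.int(ncol(ps$oligomer_dist), length(idx),
                               replace = TRUE, prob = ps$oligomer_dist[k, ])
  }
  lab <- t(vapply(osize, function(m)
    as.integer(stats::rmultinom(1, m, ps$label_probs)[, 1]), integer(3)))
  keep <- lapply(seq_len(n), function(i) seq_len(len[i]))
  obs_x <- unlist(lapply(seq_len(n), function(i) x[i, keep[[i]]]))
  obs_y <- unlist(lapply(seq_len(n), function(i) y[i, keep[[i]]]))
  st_v <- unlist(lapply(seq_len(n), function(i) states[i, keep[[i]]]))
  fr_v <- unlist(keep); id_v <- rep(seq_len(n), len)
  nr <- length(fr_v)
  data <- data.frame(cell_id = 1L, particle_id = id_v, frame = fr_v,
                     x_um = obs_x + stats::rnorm(nr, 0, ps$loc_sigma),
                     y_um = obs_y + stats::rnorm(nr, 0, ps$loc_sigma),
                     state_true = st_v)
  truth <- list(positions = data.frame(cell_id = 1L, particle_id = id_v, frame = fr_v,
                                       x_true = obs_x, y_true = obs_y, state_true = st_v),
                particles = data.frame(cell_id = 1L, particle_id = seq_len(n),
                                       oligomer_size = osize, n_dye1 = lab[, 1],
                                       n_dye2 = lab[, 2], lifetime = len),
                params = ps)
  class(truth) <- "sim_truth"
  list(traj = trajectory_set(data, dt = dtv, cell_area = ps$cell_area), truth = truth)
}

## concatenate simulations into one trajectory set with unique particle ids
merge_sims <- function(sims, params) {
  off <- 0L
  data <- list(); pos <- list(); part <- list()
  for (s in sims) {
    d <- s$traj$data; p <- s$truth$positions; q <- s$truth$particles
    d$particle_id <- d$particle_id + off
    p$particle_id <- p$particle_id + off
    q$particle_id <- q$particle_id + off
    off <- off + max(q$particle_id - off)
    data[[length(data) + 1L]] <- d
    pos[[length(pos) + 1L]] <- p
    part[[length(part) + 1L]] <- q
  }
  truth <- list(positions = do.call(rbind, pos), particles = do.call(rbind, part),
                params = params)
  class(truth) <- "sim_truth"
  list(traj = trajectory_set(do.call(rbind, data), dt = params$dt,
                             cell_area = params$cell_area),
       truth = truth)
}

#' Time-lapse removal presets
#'
#' Two endocytosis schedules over time points 0/5/10/15/20 min:
#' `"TRPV4"` removes immobile- and medium-state particles beginning at the
#' 5-min point (rapid internalization), `"TRPV1"` begins removal at the
#' 10-min point (delayed internalization after entrapment in immobile
#' domains), and `"vehicle"` removes nothing.
#'
#' @param type One of `"TRPV1"`, `"TRPV4"`, `"vehicle"`.
#' @param rate Per-interval removal probability for the targeted states.
#' @return Removal-rate matrix for [simulate_timelapse()].
#' @export
timelapse_preset <- function(type = c("TRPV4", "TRPV1", "vehicle"), rate = 0.35) {
  type <- match.arg(type)
  m <- matrix(0, 5, 3, dimnames = list(paste0("t", c(0, 5, 10, 15, 20)),
                                       c("immobile", "medium", "fast")))
  if (type == "TRPV4") m[2:5, 1:2] <- rate
  if (type == "TRPV1") m[3:5, 1:2] <- rate
  m
}

#' Simulate a Hill dose-response table
#'
#' Evaluates the Hill equation
#' `f(x) = bottom + (top - bottom) / (1 + (ec50 / x)^n)` at each
#' concentration and adds Gaussian noise, replicated.
#'
#' @param ec50 Half-maximal concentration (same units as `concentrations`).
#' @param hill_n Hill coefficient.
#' @param bottom,top Lower and upper response asymptotes.
#' @param concentrations Positive concentrations.
#' @param noise_sd Gaussian noise SD (response units).
#' @param n_reps Replicates per concentration.
#' @param seed Optional seed.
#' @return Data frame `concentration`, `response`, `replicate`.
#' @export
simulate_dose_response <- function(ec50, hill_n = 1, bottom = 0, top = 1,
                                   concentrations, noise_sd = 0, n_reps = 1,
                                   seed = NULL) {
  if (any(concentrations <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  f <- bottom + (top - bottom) / (1 + (ec50 / concentrations)^hill_n)
  d <- expand.grid(replicate = seq_len(n_reps), concentration = concentrations)
  d$response <- rep(f, each = n_reps) + stats::rnorm(nrow(d), 0, noise_sd)
  d[c("concentration", "response", "replicate")]
}
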