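#' Time- and ensemble-averaged mean squared displacement
#'
#' MSD at lag `n * dt` is the average of `|r(t + n dt) - r(t)|^2` over all
#' tracks and all (overlapping) time origins. When states are labeled and
#' `state` is given, a displacement pair contributes only if every step it
#' spans carries that label — the per-state MSD is computed within state
#' dwells, so it reflects that state's motion rather than subsequent
#' switches. The uncertainty is the SEM across cells when more than one
#' cell is present (mirroring per-cell averaging in live-cell studies),
#' otherwise across tracks.
#'
#' @param traj A [trajectory_set()].
#' @param max_lag Maximum lag in frames.
#' @param state Optional diffusion-state label to restrict to.
#' @return Object of class `msd_curve`: data frame `lag` (s), `msd` (um^2),
#'   `sem`, `n_pairs`, with lag 0 fixed at 0 by convention, plus the frame
#'   interval in `attr(, "dt")`.
#' @export
compute_msd <- function(traj, max_lag = 15, state = NULL) {
  stopifnot(inherits(traj, "trajectory_set"))
  tracks <- split_tracks(traj)
  tracks <- tracks[vapply(tracks, nrow, 1L) >= 2L]
  if (!length(tracks)) stop("need at least one track with >= 2 points", call. = FALSE)
  longest <- max(vapply(tracks, nrow, 1L)) - 1L
  if (max_lag > longest) {
    warning("max_lag exceeds the longest track; truncating to ", longest)
    max_lag <- longest
  }
  per_unit <- lapply(tracks, function(d) {
    ## accumulate sums per lag for one track (contiguous frames only)
    out <- matrix(0, max_lag, 2)  # sum, n
    nfr <- nrow(d)
    in_state <- if (!is.null(state) && !is.null(d$state)) {
      ## step i (rows i -> i+1) carries the label of its starting row
      cumsum(c(0, as.numeric(!is.na(d$state[-nfr]) & d$state[-nfr] == state)))
    } else NULL
    for (n in seq_len(min(max_lag, nfr - 1L))) {
      i0 <- seq_len(nfr - n)
      ok <- d$frame[i0 + n] - d$frame[i0] == n
      if (!is.null(in_state))  # all n spanned steps labeled `state`
        ok <- ok & (in_state[i0 + n] - in_state[i0] == n)
      if (!any(ok)) next
      sq <- (d$x_um[i0 + n][ok] - d$x_um[i0][ok])^2 +
            (d$y_um[i0 + n][ok] - d$y_um[i0][ok])^2
      out[n, ] <- c(sum(sq), sum(ok))
    }
    cbind(out, cell = d$cell_id[1])
  })
  cells <- vapply(per_unit, function(m) m[1, 3], 1)
  groups <- if (length(unique(cells)) > 1) cells else seq_along(per_unit)
  ug <- unique(groups)
  ## per-group (cell or track) MSD, then mean and SEM across groups
  msd_g <- matrix(NA_real_, length(ug), max_lag)
  for (gi in seq_along(ug)) {
    ms <- Reduce(`+`, lapply(per_unit[groups == ug[gi]], function(m) m[, 1:2, drop = FALSE]))
    msd_g[gi, ] <- ifelse(ms[, 2] > 0, ms[, 1] / ms[, 2], NA_real_)
  }
  n_pairs <- colSums(do.call(rbind, lapply(per_unit, function(m) m[, 2])))
  msd <- colMeans(msd_g, na.rm = TRUE)
  ngrp <- colSums(!is.na(msd_g))
  sem <- apply(msd_g, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(ngrp, 1))
  dt <- traj$dt
  out <- data.frame(lag = c(0, seq_len(max_lag) * dt),
                    msd = c(0, msd), sem = c(0, sem),
                    n_pairs = c(NA, n_pairs))
  out <- out[!is.na(out$msd) | out$lag == 0, , drop = FALSE]
  structure(out, dt = dt, class = c("msd_curve", "data.frame"))
}

#' Linear MSD fit
#'
#' Weighted least squares of `msd = 4 D lag + offset` over the first
#' `n_fit_points` nonzero lags (weights `1/sem^2` where SEMs are available).
#' The intercept estimates `4 sigma_loc^2`, four times the squared
#' localization noise.
#'
#' @param curve An `msd_curve`.
#' @param n_fit_points Number of lags fitted (default 4).
#' @return List with `D` (um^2/s), `offset` (um^2) and the `lm` fit.
#' @export
fit_msd_linear <- function(curve, n_fit_points = 4) {
  d <- curve[curve$lag > 0, , drop = FALSE]
  if (nrow(d) < 2) stop("need >= 2 nonzero lags", call. = FALSE)
  d <- d[seq_len(min(n_fit_points, nrow(d))), , drop = FALSE]
  w <- if (all(is.finite(d$sem)) && all(d$sem > 0)) 1 / d$sem^2 else rep(1, nrow(d))
  fit <- stats::lm(msd ~ lag, data = d, weights = w)
  D <- unname(stats::coef(fit)[2] / 4)
  if (D < 0) warning("fitted D is negative (small-sample noise); reported as-is")
  list(D = D, offset = unname(stats::coef(fit)[1]), fit = fit)
}

#' Confined-diffusion MSD fit
#'
#' Least-squares fit of the saturating model
#' `MSD(t) = (L^2 / 3) (1 - exp(-t / tau)) + offset`,
#' the 2-D mean squared displacement in a square domain of side `L` with
#' reflecting walls, whose plateau is `L^2 / 3` above the offset (the offset
#' absorbs localization noise, `4 sigma_loc^2`). The short-time diffusion
#' coefficient is reported through the convention `tau = L^2 / (12 D_micro)`
#' (the initial slope of the model equals `4 D_micro`). If the fitted `tau`
#' exceeds the largest lag in the data the curve is effectively unconfined
#' over the observation window and the fit is flagged `censored`.
#'
#' @param curve An `msd_curve` with at least 6 nonzero lags.
#' @param n_lags Number of lags used (default 15).
#' @return Object of class `confined_fit`: `L` (um), `tau` (s), `D_micro`
#'   (um^2/s), `offset`, `plateau`, `censored`, `converged` and the `nls`
#'   fit.
#' @export
fit_msd_confined <- function(curve, n_lags = 15) {
  d <- curve[curve$lag > 0, , drop = FALSE]
  if (nrow(d) < 6) stop("confined fit needs >= 6 nonzero lags", call. = FALSE)
  d <- d[seq_len(min(n_lags, nrow(d))), , drop = FALSE]
  plateau0 <- max(d$msd)
  off0 <- max(min(d$msd) / 2, 1e-6)
  L0 <- sqrt(3 * max(plateau0 - off0, 1e-6))
  half <- off0 + (plateau0 - off0) / 2
  tau0 <- d$lag[which.min(abs(d$msd - half))]
  fit <- try(minpack.lm::nlsLM(
    msd ~ (L^2 / 3) * (1 - exp(-lag / tau)) + offset,
    data = d,
    start = list(L = L0, tau = max(tau0, d$lag[1] / 2), offset = off0),
    lower = c(1e-4, 1e-6, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("confined MSD fit did not converge (starts: L=", signif(L0, 3),
         ", tau=", signif(tau0, 3), ", offset=", signif(off0, 3), ")",
         call. = FALSE)
  cf <- stats::coef(fit)
  L <- unname(cf["L"]); tau <- unname(cf["tau"]); offset <- unname(cf["offset"])
  censored <- tau > max(d$lag)
  if (censored)
    warning("fitted tau exceeds the observed lag range; L is unreliable (censored)")
  structure(list(L = L, tau = tau, D_micro = L^2 / (12 * tau),
                 offset = offset, plateau = L^2 / 3 + offset,
                 censored = censored, converged = TRUE, fit = fit),
            class = "confined_fit")
}

#' @export
print.confined_fit <- function(x, ...) {
  cat("<confined_fit> L = ", signif(x$L, 4), " um (", signif(x$L * 1000, 4),
      " nm), tau = ", signif(x$tau, 4), " s, D_micro = ",
      signif(x$D_micro, 4), " um^2/s\n", sep = "")
  cat("  plateau = ", signif(x$plateau, 4), " um^2, offset = ",
      signif(x$offset, 4), " um^2",
      if (x$censored) "  [censored: tau beyond data range]", "\n", sep = "")
  invisible(x)
}

#' Step-length histogram with its theoretical overlay
#'
#' Histograms the step lengths of one diffusion state and overlays the
#' single-state prediction `p(r) = (r / (2 D dt)) exp(-r^2 / (4 D dt))`
#' (the 2-D displacement-length density for diffusion coefficient `D`).
#'
#' @param traj A state-labeled [trajectory_set()] (see [assign_states()]);
#'   pass `state = NULL` to pool all steps.
#' @param state State label to select.
#' @param D Diffusion coefficient for the overlay (um^2/s); e.g. the
#'   corresponding `D_est` from the fit.
#' @param breaks Histogram breaks (um) or a number of bins.
#' @return List with the `hist` object (probability-density scaled), the
#'   overlay function `density(r)`, and `n_steps`.
#' @export
step_histogram <- function(traj, state = NULL, D, breaks = 50) {
  steps <- do.call(rbind, track_steps(traj, min_steps = 1L))
  if (!is.null(state)) {
    if (is.null(traj$data$state)) stop("state labels missing; run assign_states()", call. = FALSE)
    ## step label = label of the row the step starts at
    key_d <- paste(traj$data$cell_id, traj$data$particle_id, traj$data$frame)
    lab <- traj$data$state[match(paste(steps$cell_id, steps$particle_id, steps$frame), key_d)]
    steps <- steps[!is.na(lab) & lab == state, , drop = FALSE]
  }
  r <- sqrt(steps$r2)
  if (!length(r))
    return(list(hist = NULL, density = NULL, n_steps = 0L))
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  dt <- traj$dt
  dens <- function(x) (x / (2 * D * dt)) * exp(-x^2 / (4 * D * dt))
  list(hist = h, density = dens, n_steps = length(r))
}

#' Per-state density and fraction time courses
#'
#' For each time point, the density of state k is the mean number of
#' particles labeled k per frame divided by the cell area; fractions are
#' normalized per time point.
#'
#' @param traj_list List of state-labeled [trajectory_set()]s, one per time
#'   point.
#' @param time_points Time points (minutes).
#' @param cell_area Cell area, um^2 (defaults to each set's own).
#' @param n_states Number of states (inferred from labels if missing).
#' @return Object of class `state_timecourse`: data frame with `time`,
#'   `state`, `density` (um^-2), `fraction`.
#' @export
density_timecourse <- function(traj_list, time_points = seq_along(traj_list),
                               cell_area = NULL, n_states = NULL) {
  stopifnot(length(traj_list) == length(time_points))
  if (is.null(n_states))
    n_states <- max(unlist(lapply(traj_list, function(tr) tr$data$state)), na.rm = TRUE)
  rows <- list()
  for (i in seq_along(traj_list)) {
    tr <- traj_list[[i]]
    area <- cell_area %||% tr$cell_area
    if (is.null(area) || is.na(area) || area <= 0)
      stop("cell_area must be positive", call. = FALSE)
    d <- tr$data
    if (is.null(d$state)) stop("state labels missing; run assign_states()", call. = FALSE)
    nf <- length(unique(d$frame))
    cnt <- vapply(seq_len(n_states), function(k)
      sum(d$state == k, na.rm = TRUE) / nf, 1)
    dens <- cnt / area
    tot <- sum(dens)
    frac <- if (tot > 0) dens / tot else rep(NA_real_, n_states)
    if (tot == 0) warning("no labeled particles at time point ", time_points[i])
    rows[[i]] <- data.frame(time = time_points[i], state = seq_len(n_states),
                            density = dens, fraction = frac)
  }
  structure(do.call(rbind, rows), class = c("state_timecourse", "data.frame"))
}

#' Correlate total particle density with time-averaged MSD
#'
#' Pearson correlation across time points between total density and a
#' scalar MSD summary per time point — the readout that links endocytosis
#' kinetics to diffusion changes.
#'
#' @param timecourse A `state_timecourse` (or data frame with `time` and
#'   `density`).
#' @param msd_per_timepoint Numeric vector, one MSD summary per time point.
#' @return Pearson correlation coefficient.
#' @export
correlate_density_msd <- function(timecourse, msd_per_timepoint) {
  dens <- tapply(timecourse$density, timecourse$time, sum)
  dens <- as.numeric(dens[order(as.numeric(names(dens)))])
  if (length(dens) != length(msd_per_timepoint))
    stop("one MSD value per time point required", call. = FALSE)
  if (length(dens) < 3) stop("need >= 3 time points", call. = FALSE)
  if (stats::sd(dens) == 0 || stats::sd(msd_per_timepoint) == 0) {
    warning("constant input; correlation undefined")
    return(NA_real_)
  }
  stats::cor(dens, msd_per_timepoint, method = "pearson")
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lag, x$msd, type = "b", pch = 16,
                 xlab = "lag (s)", ylab = expression(MSD ~ (mu * m^2)), ...)
  ok <- is.finite(x$sem) & x$sem > 0
  graphics::arrows(x$lag[ok], x$msd[ok] - x$sem[ok], x$lag[ok], x$msd[ok] + x$sem[ok],
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
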