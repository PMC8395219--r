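#' Preprocess a raw movie before spot detection
#'
#' Two steps, both individually toggleable: (1) background subtraction by
#' grayscale morphological opening with a disc structuring element of the
#' given radius (the classic rolling-ball background estimate), and (2) a
#' running two-frame average (frame i becomes the mean of frames i and
#' i + 1), which halves shot noise at the cost of one frame; the output then
#' has n - 1 frames. Defaults follow common single-molecule practice: a
#' 25-pixel radius and averaging on.
#'
#' @param stack Numeric array `h x w x n_frames`.
#' @param rolling_ball_radius Structuring-element radius in pixels; `0`
#'   disables background subtraction.
#' @param frame_average Apply the two-frame running average.
#' @return Numeric array; `n - 1` frames if averaging was applied. Metadata
#'   attributes are preserved.
#' @export
preprocess_stack <- function(stack, rolling_ball_radius = 25, frame_average = TRUE) {
  dims <- dim(stack)
  if (length(dims) != 3L) stop("stack must be h x w x frames", call. = FALSE)
  if (frame_average && dims[3] < 2L)
    stop("two-frame averaging needs at least 2 frames", call. = FALSE)
  out <- array(as.numeric(stack), dims)
  if (rolling_ball_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(rolling_ball_radius) + 1L, shape = "disc")
    top <- max(out, 1)
    for (t in seq_len(dims[3])) {
      bg <- EBImage::opening(out[, , t] / top, brush) * top
      out[, , t] <- out[, , t] - bg
    }
  }
  if (frame_average) {
    out <- (out[, , -dims[3], drop = FALSE] + out[, , -1, drop = FALSE]) / 2
  }
  attr(out, "pixel_size") <- attr(stack, "pixel_size")
  attr(out, "dt") <- attr(stack, "dt")
  out
}

#' Detect fluorescent spots in one frame
#'
#' Local maxima above `median + snr_threshold * robust-SD` are refined by a
#' 2-D Gaussian least-squares fit in a window around the maximum; if the fit
#' diverges (or drifts out of the window) the intensity-weighted centroid of
#' the window is used instead and flagged in `fit_quality`. The integrated
#' (background-subtracted) intensity `2 * pi * sigma^2 * amplitude` is
#' reported for fitted spots, the window sum above background for centroid
#' fallbacks.
#'
#' @param frame Numeric matrix (a preprocessed frame).
#' @param snr_threshold Detection threshold in robust-SD units.
#' @param window Half-width of the fit window, pixels.
#' @param min_sep Minimum separation between maxima, pixels.
#' @return Data frame `x, y, intensity, fit_quality, method` with positions
#'   in pixel units (image convention: x = column, y = row, continuous
#'   coordinates where pixel (i, j) spans x in [j-1, j], y in [i-1, i]).
#' @export
detect_spots <- function(frame, snr_threshold = 5, window = 3L, min_sep = 2) {
  med <- stats::median(frame)
  sdr <- stats::mad(frame)
  if (sdr == 0) sdr <- stats::sd(frame)
  if (is.na(sdr) || sdr == 0) return(empty_spots())
  thr <- med + snr_threshold * sdr
  h <- nrow(frame); w <- ncol(frame)
  cand <- which(frame > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_spots())
  ## keep strict local maxima in a 3x3 neighbourhood
  is_max <- vapply(seq_len(nrow(cand)), function(s) {
    i <- cand[s, 1]; j <- cand[s, 2]
    ii <- max(1, i - 1):min(h, i + 1); jj <- max(1, j - 1):min(w, j + 1)
    frame[i, j] >= max(frame[ii, jj])
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand)) return(empty_spots())
  ## suppress multiple maxima closer than min_sep (keep the brighter)
  o <- order(frame[cand], decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (s in seq_len(nrow(cand))) {
    if (!keep[s]) next
    if (s < nrow(cand)) {
      later <- (s + 1):nrow(cand)
      dd <- sqrt((cand[later, 1] - cand[s, 1])^2 + (cand[later, 2] - cand[s, 2])^2)
      keep[later][dd < min_sep] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  res <- lapply(seq_len(nrow(cand)), function(s) {
    i <- cand[s, 1]; j <- cand[s, 2]
    ii <- max(1, i - window):min(h, i + window)
    jj <- max(1, j - window):min(w, j + window)
    patch <- frame[ii, jj]
    fit_gaussian_patch(patch, ii, jj)
  })
  out <- do.call(rbind, res)
  out[out$intensity > 0, , drop = FALSE]
}

empty_spots <- function() {
  data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0),
             fit_quality = numeric(0), method = character(0))
}

## least-squares 2-D Gaussian on a patch; centroid fallback
fit_gaussian_patch <- function(patch, ii, jj) {
  ## pixel-centre coordinates in the continuous convention
  yc <- ii - 0.5; xc <- jj - 0.5
  b0 <- min(patch)
  a0 <- max(patch) - b0
  wsum <- sum(patch - b0)
  cx0 <- sum(outer(rep(1, length(yc)), xc) * (patch - b0)) / wsum
  cy0 <- sum(outer(yc, rep(1, length(xc))) * (patch - b0)) / wsum
  obj <- function(p) {
    a <- exp(p[1]); sx <- exp(p[4]); b <- p[5]
    mu <- a * exp(-((outer(yc, rep(1, length(xc))) - p[3])^2 +
                    (outer(rep(1, length(yc)), xc) - p[2])^2) / (2 * sx^2)) + b
    sum((mu - patch)^2)
  }
  p0 <- c(log(max(a0, 1e-6)), cx0, cy0, log(1.3), b0)
  fit <- try(stats::optim(p0, obj, method = "BFGS",
                          control = list(maxit = 200)), silent = TRUE)
  ok <- !inherits(fit, "try-error") && is.finite(fit$value) &&
    fit$par[2] >= min(xc) - 1 && fit$par[2] <= max(xc) + 1 &&
    fit$par[3] >= min(yc) - 1 && fit$par[3] <= max(yc) + 1
  if (ok) {
    a <- exp(fit$par[1]); sx <- exp(fit$par[4])
    data.frame(x = fit$par[2], y = fit$par[3],
               intensity = 2 * pi * sx^2 * a,
               fit_quality = sqrt(fit$value / length(patch)),
               method = "gaussian")
  } else {
    data.frame(x = cx0, y = cy0, intensity = max(wsum, 0),
               fit_quality = NA_real_, method = "centroid")
  }
}

#' Link detected spots into trajectories
#'
#' Greedy globally-nearest-neighbour assignment between track ends and the
#' spots of each new frame: all candidate (track, spot) pairs closer than
#' `max_disp` are sorted by distance and accepted one-to-one in ascending
#' order, ties broken by smallest track id then smallest spot index (the
#' procedure is deterministic). Unassigned spots start new tracks. A track
#' missing from up to `max_gap` consecutive frames may still be linked; the
#' skipped frames are filled by linear interpolation and flagged in the
#' `inferred` column.
#'
#' @param spots Data frame of detections with columns `frame, x, y,
#'   intensity` (pixel units, as produced by [detect_spots()] over frames).
#' @param max_disp Maximum displacement per frame, um.
#' @param max_gap Maximum number of missed frames bridged.
#' @param pixel_size Pixel size, um.
#' @param dt Frame interval, s.
#' @param cell_area Optional cell area, um^2.
#' @return A [trajectory_set()] (coordinates converted to um); the
#'   `intensity_ch1` column carries the spot intensities.
#' @export
link_spots <- function(spots, max_disp = 0.45, max_gap = 0,
                       pixel_size = 0.067, dt = 0.0305, cell_area = NA_real_) {
  if (!nrow(spots)) {
    return(trajectory_set(data.frame(cell_id = integer(0), particle_id = integer(0),
                                     frame = integer(0), x_um = numeric(0),
                                     y_um = numeric(0), intensity_ch1 = numeric(0),
                                     inferred = logical(0)),
                          dt = dt, pixel_size = pixel_size, cell_area = cell_area))
  }
  spots <- spots[order(spots$frame), , drop = FALSE]
  spots$x_um <- spots$x * pixel_size
  spots$y_um <- spots$y * pixel_size
  frames <- sort(unique(spots$frame))
  next_id <- 0L
  ## active tracks: id, last frame, last position
  act <- data.frame(id = integer(0), last_frame = integer(0),
                    x = numeric(0), y = numeric(0))
  rows <- vector("list", length(frames) * 2L)
  nrows <- 0L
  add_row <- function(df) {
    nrows <<- nrows + 1L
    rows[[nrows]] <<- df
  }
  for (f in frames) {
    sp <- spots[spots$frame == f, , drop = FALSE]
    act <- act[act$last_frame >= f - 1L - max_gap, , drop = FALSE]
    assigned_sp <- rep(FALSE, nrow(sp))
    if (nrow(act) && nrow(sp)) {
      dmat <- outer(act$x, sp$x_um, "-")^2 + outer(act$y, sp$y_um, "-")^2
      gap <- f - act$last_frame  # >= 1
      lim <- (max_disp * gap)^2
      cand <- which(dmat <= lim, arr.ind = TRUE)
      if (nrow(cand)) {
        o <- order(dmat[cand], act$id[cand[, 1]], cand[, 2])
        cand <- cand[o, , drop = FALSE]
        used_tr <- rep(FALSE, nrow(act))
        for (s in seq_len(nrow(cand))) {
          a <- cand[s, 1]; b <- cand[s, 2]
          if (used_tr[a] || assigned_sp[b]) next
          used_tr[a] <- TRUE; assigned_sp[b] <- TRUE
          gfr <- act$last_frame[a]
          if (f - gfr > 1L) {  # bridge the gap by interpolation
            for (g in (gfr + 1L):(f - 1L)) {
              w <- (g - gfr) / (f - gfr)
              add_row(data.frame(cell_id = 1L, particle_id = act$id[a], frame = g,
                                 x_um = act$x[a] + w * (sp$x_um[b] - act$x[a]),
                                 y_um = act$y[a] + w * (sp$y_um[b] - act$y[a]),
                                 intensity_ch1 = NA_real_, inferred = TRUE))
            }
          }
          add_row(data.frame(cell_id = 1L, particle_id = act$id[a], frame = f,
                             x_um = sp$x_um[b], y_um = sp$y_um[b],
                             intensity_ch1 = sp$intensity[b], inferred = FALSE))
          act$last_frame[a] <- f; act$x[a] <- sp$x_um[b]; act$y[a] <- sp$y_um[b]
        }
      }
    }
    if (any(!assigned_sp)) {
      for (b in which(!assigned_sp)) {
        next_id <- next_id + 1L
        add_row(data.frame(cell_id = 1L, particle_id = next_id, frame = f,
                           x_um = sp$x_um[b], y_um = sp$y_um[b],
                           intensity_ch1 = sp$intensity[b], inferred = FALSE))
        act <- rbind(act, data.frame(id = next_id, last_frame = f,
                                     x = sp$x_um[b], y = sp$y_um[b]))
      }
    }
  }
  trajectory_set(do.call(rbind, rows[seq_len(nrows)]), dt = dt,
                 pixel_size = pixel_size, cell_area = cell_area)
}

#' Track a movie end-to-end
#'
#' Convenience wrapper: [preprocess_stack()] then [detect_spots()] per frame
#' then [link_spots()].
#'
#' @param stack Raw movie array with `pixel_size` / `dt` attributes (or pass
#'   them explicitly).
#' @inheritParams preprocess_stack
#' @inheritParams detect_spots
#' @inheritParams link_spots
#' @return A [trajectory_set()].
#' @export
track_movie <- function(stack, rolling_ball_radius = 25, frame_average = TRUE,
                        snr_threshold = 5, max_disp = 0.45, max_gap = 0,
                        pixel_size = attr(stack, "pixel_size") %||% 0.067,
                        dt = attr(stack, "dt") %||% 0.0305,
                        cell_area = NA_real_) {
  pp <- preprocess_stack(stack, rolling_ball_radius, frame_average)
  nf <- dim(pp)[3]
  sp <- lapply(seq_len(nf), function(t) {
    s <- detect_spots(pp[, , t], snr_threshold = snr_threshold)
    if (nrow(s)) s$frame <- t
    s
  })
  sp <- do.call(rbind, sp[vapply(sp, nrow, 1L) > 0])
  if (is.null(sp)) sp <- cbind(empty_spots(), frame = integer(0))
  link_spots(sp, max_disp = max_disp, max_gap = max_gap,
             pixel_size = pixel_size, dt = dt, cell_area = cell_area)
}
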