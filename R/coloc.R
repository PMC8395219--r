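#' Detect two-colour colocalization events
#'
#' Within each frame, particles from the two channels closer than `radius`
#' AND carrying the same diffusion-state label are candidate pairs; pairs
#' are resolved one-to-one greedily by ascending separation (ties broken by
#' smallest particle id, so detection is deterministic). Pairs of the same
#' two particles in consecutive frames are merged into events; a gap of
#' more than `max_gap` frames (default 0) splits an event. An event is
#' right-censored when its last frame coincides with the end of either
#' member's track or the movie — its dissociation was not observed.
#'
#' @param ch1,ch2 State-labeled [trajectory_set()]s sharing the frame clock
#'   and coordinate system.
#' @param radius Colocalization distance threshold, um (200 nm default).
#' @param max_gap Frames of tolerated interruption within one event.
#' @param require_same_state Gate pairs on equal state labels (default
#'   TRUE; set FALSE if no labels are available).
#' @return Object of class `coloc_events`: data frame `id_ch1, id_ch2,
#'   start_frame, end_frame, duration` (s), `state`, `mean_separation`
#'   (um), `censored`; attributes `dt`, `radius`, `n_frames`.
#' @export
detect_colocalization <- function(ch1, ch2, radius = 0.2, max_gap = 0,
                                  require_same_state = TRUE) {
  stopifnot(inherits(ch1, "trajectory_set"), inherits(ch2, "trajectory_set"))
  if (abs(ch1$dt - ch2$dt) > 1e-12)
    stop("channels have different frame intervals", call. = FALSE)
  d1 <- ch1$data; d2 <- ch2$data
  scol <- function(d) if (!is.null(d$state)) d$state else
    if (!is.null(d$state_true)) d$state_true else rep(NA_integer_, nrow(d))
  s1 <- scol(d1); s2 <- scol(d2)
  frames <- sort(intersect(unique(d1$frame), unique(d2$frame)))
  pairs <- list()
  for (f in frames) {
    i1 <- which(d1$frame == f); i2 <- which(d2$frame == f)
    if (!length(i1) || !length(i2)) next
    dm <- sqrt(outer(d1$x_um[i1], d2$x_um[i2], "-")^2 +
               outer(d1$y_um[i1], d2$y_um[i2], "-")^2)
    ok <- dm < radius
    if (require_same_state)
      ok <- ok & outer(s1[i1], s2[i2], function(a, b) !is.na(a) & !is.na(b) & a == b)
    cand <- which(ok, arr.ind = TRUE)
    if (!nrow(cand)) next
    o <- order(dm[cand], d1$particle_id[i1][cand[, 1]], d2$particle_id[i2][cand[, 2]])
    cand <- cand[o, , drop = FALSE]
    used1 <- logical(length(i1)); used2 <- logical(length(i2))
    for (s in seq_len(nrow(cand))) {
      a <- cand[s, 1]; b <- cand[s, 2]
      if (used1[a] || used2[b]) next
      used1[a] <- TRUE; used2[b] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        frame = f, id_ch1 = d1$particle_id[i1][a], id_ch2 = d2$particle_id[i2][b],
        sep = dm[a, b], state = s1[i1][a])
    }
  }
  dt <- ch1$dt
  last_frame <- max(c(d1$frame, d2$frame))
  end1 <- tapply(d1$frame, d1$particle_id, max)
  end2 <- tapply(d2$frame, d2$particle_id, max)
  if (!length(pairs)) {
    ev <- data.frame(id_ch1 = integer(0), id_ch2 = integer(0),
                     start_frame = integer(0), end_frame = integer(0),
                     duration = numeric(0), state = integer(0),
                     mean_separation = numeric(0), censored = logical(0))
  } else {
    pp <- do.call(rbind, pairs)
    pp <- pp[order(pp$id_ch1, pp$id_ch2, pp$frame), , drop = FALSE]
    key <- paste(pp$id_ch1, pp$id_ch2)
    ev <- list()
    for (k in unique(key)) {
      sub <- pp[key == k, , drop = FALSE]
      brk <- c(0L, which(diff(sub$frame) > max_gap + 1L), nrow(sub))
      for (j in seq_len(length(brk) - 1L)) {
        seg <- sub[(brk[j] + 1L):brk[j + 1L], , drop = FALSE]
        endf <- seg$frame[nrow(seg)]
        cens <- endf >= last_frame ||
          endf >= end1[as.character(seg$id_ch1[1])] ||
          endf >= end2[as.character(seg$id_ch2[1])]
        ev[[length(ev) + 1L]] <- data.frame(
          id_ch1 = seg$id_ch1[1], id_ch2 = seg$id_ch2[1],
          start_frame = seg$frame[1], end_frame = endf,
          duration = (endf - seg$frame[1] + 1L) * dt,
          state = seg$state[1], mean_separation = mean(seg$sep),
          censored = isTRUE(cens))
      }
    }
    ev <- do.call(rbind, ev)
    ev <- ev[order(ev$start_frame, ev$id_ch1, ev$id_ch2), , drop = FALSE]
    rownames(ev) <- NULL
  }
  structure(ev, dt = dt, radius = radius, n_frames = last_frame,
            class = c("coloc_events", "data.frame"))
}

#' Fraction of particles engaged in colocalization
#'
#' A particle counts as colocalized if it participates in at least one
#' event anywhere in the movie; the fraction is colocalized particles over
#' total detected particles, pooled over both channels, reported overall
#' and per diffusion state (a particle's state is the state of its events,
#' or for totals the majority label of its steps).
#'
#' @param events A `coloc_events` object.
#' @param ch1,ch2 The trajectory sets the events came from.
#' @return List with `overall` fraction and `per_state` data frame.
#' @export
colocalized_fraction <- function(events, ch1, ch2) {
  n1 <- length(unique(ch1$data$particle_id))
  n2 <- length(unique(ch2$data$particle_id))
  if (n1 + n2 == 0) {
    warning("no particles; fraction undefined")
    return(list(overall = NA_real_, per_state = NULL))
  }
  c1 <- length(unique(events$id_ch1))
  c2 <- length(unique(events$id_ch2))
  overall <- (c1 + c2) / (n1 + n2)
  per_state <- NULL
  scol <- function(d) if (!is.null(d$state)) d$state else d$state_true
  s1 <- scol(ch1$data); s2 <- scol(ch2$data)
  if (!is.null(s1) && !is.null(s2)) {
    maj <- function(d, s) {
      sp <- split(s, d$particle_id)
      vapply(sp, function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) return(NA_integer_)
        as.integer(names(which.max(table(v))))
      }, integer(1))
    }
    m1 <- maj(ch1$data, s1); m2 <- maj(ch2$data, s2)
    states <- sort(unique(stats::na.omit(c(m1, m2))))
    per_state <- do.call(rbind, lapply(states, function(k) {
      tot <- sum(m1 == k, na.rm = TRUE) + sum(m2 == k, na.rm = TRUE)
      ev_k <- events[!is.na(events$state) & events$state == k, , drop = FALSE]
      col <- length(unique(ev_k$id_ch1)) + length(unique(ev_k$id_ch2))
      data.frame(state = k, n_particles = tot, n_colocalized = col,
                 fraction = if (tot > 0) col / tot else NA_real_)
    }))
  }
  list(overall = overall, per_state = per_state)
}

#' Association on-rate constant from colocalization events
#'
#' Counts cumulative association-event starts per unit area over time; the
#' initial rate `V0` is the least-squares slope over the early window
#' (default the first third of the movie), and the second-order on-rate
#' constant is `k_on = V0 / (density_ch1 * density_ch2)`. Events already in
#' progress at the movie's first frame are left-censored associations and
#' are excluded from the cumulative count.
#'
#' @param events A `coloc_events` object.
#' @param area Imaged area, um^2.
#' @param density_ch1,density_ch2 Mean particle densities per channel,
#'   um^-2.
#' @param window Fraction of the movie over which the initial slope is
#'   fitted.
#' @return Object of class `on_rate`: `V0` (events um^-2 s^-1), `k_on`
#'   (um^2 s^-1), densities, the cumulative curve.
#' @export
on_rate <- function(events, area, density_ch1, density_ch2, window = 1/3) {
  if (density_ch1 <= 0 || density_ch2 <= 0)
    stop("densities must be positive", call. = FALSE)
  dt <- attr(events, "dt") %||% 1
  nf <- attr(events, "n_frames") %||% 1L
  tgrid <- seq_len(nf) * dt
  ## pairs already together in the movie's first frame are not observed
  ## associations (left-censored); they do not count toward the initial rate
  starts <- events$start_frame[events$start_frame > 1L]
  cum <- vapply(seq_len(nf), function(f) sum(starts <= f), 1) / area
  if (!nrow(events)) {
    return(structure(list(V0 = 0, k_on = 0, density_ch1 = density_ch1,
                          density_ch2 = density_ch2,
                          curve = data.frame(time = tgrid, cum_events = cum)),
                     class = "on_rate"))
  }
  nwin <- max(2L, ceiling(window * nf))
  fit <- stats::lm(y ~ t, data = data.frame(t = tgrid[seq_len(nwin)],
                                            y = cum[seq_len(nwin)]))
  V0 <- max(unname(stats::coef(fit)[2]), 0)
  structure(list(V0 = V0, k_on = V0 / (density_ch1 * density_ch2),
                 density_ch1 = density_ch1, density_ch2 = density_ch2,
                 curve = data.frame(time = tgrid, cum_events = cum)),
            class = "on_rate")
}

#' @export
print.on_rate <- function(x, ...) {
  cat("<on_rate> V0 =", signif(x$V0, 4), "events um^-2 s^-1, k_on =",
      signif(x$k_on, 4), "um^2 s^-1\n")
  invisible(x)
}

#' On-time survival of colocalization events
#'
#' Kaplan-Meier survival of event durations with right-censoring at track
#' end, plus the censoring-aware exponential maximum-likelihood mean
#' on-time (total observed time over the number of observed dissociations).
#'
#' @param events A `coloc_events` object with at least 10 events.
#' @return Object of class `on_time_fit`: `survfit` (from the survival
#'   package), `mean_on_time` (s; `NA` with a warning if every event is
#'   censored), `n_events`, `n_censored`.
#' @export
on_time_survival <- function(events) {
  if (nrow(events) < 10) stop("need >= 10 events", call. = FALSE)
  cens <- if (!is.null(events$censored)) events$censored else rep(FALSE, nrow(events))
  sf <- survival::survfit(survival::Surv(events$duration, !cens) ~ 1)
  n_unc <- sum(!cens)
  if (n_unc == 0) {
    warning("all events censored; exponential fit skipped")
    mean_on <- NA_real_
  } else {
    mean_on <- sum(events$duration) / n_unc
  }
  structure(list(survfit = sf, mean_on_time = mean_on,
                 n_events = nrow(events), n_censored = sum(cens)),
            class = "on_time_fit")
}

#' @export
print.on_time_fit <- function(x, ...) {
  cat("<on_time_fit>", x$n_events, "events (", x$n_censored, "censored ), mean on-time =",
      signif(x$mean_on_time, 4), "s\n")
  invisible(x)
}
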