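#' Trajectory sets
#'
#' A `trajectory_set` is the common currency of all analysis stages: a table
#' of localized particles over frames, one row per particle per frame, plus
#' the acquisition metadata needed to interpret it (frame interval, pixel
#' size, cell area).
#'
#' Conventions used throughout the package: coordinates are in micrometres
#' with the origin at the image top-left corner and y increasing downward
#' (image convention); frames are integer indices starting at 1; a track's
#' displacement steps are the first differences of its positions, so a track
#' of L points has L - 1 steps.
#'
#' @param data A data frame with at least columns `cell_id`, `particle_id`,
#'   `frame`, `x_um`, `y_um`. Optional columns: `intensity_ch1`,
#'   `intensity_ch2`, `state`, `state_true`, `inferred`.
#' @param dt Frame interval in seconds.
#' @param pixel_size Pixel size in micrometres (0.067 by default).
#' @param cell_area Cell footprint area in square micrometres, used to turn
#'   particle counts into densities.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(data, dt, pixel_size = 0.067, cell_area = NA_real_) {
  need <- c("cell_id", "particle_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("trajectory data lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  data <- data[order(data$cell_id, data$particle_id, data$frame), , drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, dt = dt, pixel_size = pixel_size,
                 cell_area = cell_area),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  d <- x$data
  nt <- nrow(unique(d[c("cell_id", "particle_id")]))
  cat("<trajectory_set> ", nt, " tracks, ", nrow(d), " localizations, ",
      length(unique(d$cell_id)), " cell(s)\n", sep = "")
  cat("  dt = ", x$dt, " s, pixel = ", x$pixel_size, " um, cell area = ",
      x$cell_area, " um^2\n", sep = "")
  if (!is.null(d$state)) {
    tab <- table(d$state)
    cat("  state labels: ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.trajectory_set <- function(object, ...) {
  d <- object$data
  len <- tapply(d$frame, interaction(d$cell_id, d$particle_id, drop = TRUE), length)
  out <- list(n_tracks = length(len), n_localizations = nrow(d),
              n_cells = length(unique(d$cell_id)),
              track_length = summary(as.numeric(len)),
              dt = object$dt, cell_area = object$cell_area)
  class(out) <- "summary.trajectory_set"
  out
}

#' @export
print.summary.trajectory_set <- function(x, ...) {
  cat("trajectory_set:", x$n_tracks, "tracks /", x$n_localizations,
      "localizations /", x$n_cells, "cell(s), dt =", x$dt, "s\n")
  cat("track length (frames):\n"); print(x$track_length)
  invisible(x)
}

## split into per-track data frames (ordered by frame)
split_tracks <- function(traj) {
  d <- traj$data
  split(d, interaction(d$cell_id, d$particle_id, drop = TRUE, lex.order = TRUE))
}

## per-track step table: squared step length and per-axis displacements
track_steps <- function(traj, min_steps = 1L) {
  tr <- split_tracks(traj)
  tr <- tr[vapply(tr, nrow, 1L) >= min_steps + 1L]
  lapply(tr, function(d) {
    dx <- diff(d$x_um); dy <- diff(d$y_um)
    data.frame(cell_id = d$cell_id[-1], particle_id = d$particle_id[-1],
               frame = d$frame[-nrow(d)], dx = dx, dy = dy, r2 = dx^2 + dy^2)
  })
}

#' Write / read trajectory tables as CSV
#'
#' The CSV schema is shared between the simulator and the tracker:
#' `cell_id, particle_id, frame, x_um, y_um` plus whatever optional columns
#' are present (`intensity_ch1`, `intensity_ch2`, `state`, `state_true`).
#' Metadata (dt, pixel size, cell area) is stored in commented header lines
#' so the file round-trips losslessly through [read_trajectories()].
#'
#' @param traj A [trajectory_set()].
#' @param path File path.
#' @return `write_trajectories` returns `path` invisibly; `read_trajectories`
#'   returns a [trajectory_set()].
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%.17g pixel_size=%.17g cell_area=%.17g",
                     traj$dt, traj$pixel_size, traj$cell_area), con)
  utils::write.csv(traj$data, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- c(dt = NA_real_, pixel_size = 0.067, cell_area = NA_real_)
  if (startsWith(hdr, "#")) {
    kv <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.eE+naNA]+", hdr))[[1]]
    for (p in kv) {
      parts <- strsplit(p, "=", fixed = TRUE)[[1]]
      meta[parts[1]] <- as.numeric(parts[2])
    }
  }
  d <- utils::read.csv(path, comment.char = "#")
  trajectory_set(d, dt = meta[["dt"]], pixel_size = meta[["pixel_size"]],
                 cell_area = meta[["cell_area"]])
}
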