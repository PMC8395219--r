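#' Render a trajectory set into a synthetic TIRF movie
#'
#' Each particle visible in a frame is drawn as an integrated 2-D Gaussian
#' point-spread function centred at its subpixel position: the counts in a
#' pixel are the Gaussian mass falling inside the pixel (difference of
#' normal CDFs along each axis), scaled so the particle's total expected
#' counts equal `photon_scale * intensity`. A constant background is added
#' and Poisson shot noise applied; counts above 65535 are clipped with a
#' warning.
#'
#' Geometry: pixel `(i, j)` (row i, column j, 1-based) covers
#' `[(j-1)*px, j*px] x [(i-1)*px, i*px]` in micrometres, so a coordinate in
#' um maps to pixel units by dividing by the pixel size.
#'
#' @param traj A [trajectory_set()]; if an `intensity` (or `intensity_ch1`)
#'   column is present it scales each particle's photon budget, otherwise
#'   unit intensity is used.
#' @param img_size Image side, pixels.
#' @param psf_sigma PSF standard deviation, pixels.
#' @param background Mean background level, counts.
#' @param photon_scale Expected total counts per unit intensity.
#' @param noise Add Poisson noise (`TRUE`) or return the noise-free
#'   expectation (`FALSE`).
#' @return Integer array `img_size x img_size x n_frames` with attributes
#'   `pixel_size` (um) and `dt` (s).
#' @export
render_movie <- function(traj, img_size = 64, psf_sigma = 1.3,
                         background = 100, photon_scale = 1, noise = TRUE) {
  stopifnot(inherits(traj, "trajectory_set"))
  px <- traj$pixel_size
  d <- traj$data
  icol <- if (!is.null(d$intensity)) d$intensity
          else if (!is.null(d$intensity_ch1)) d$intensity_ch1
          else rep(1, nrow(d))
  xpix <- d$x_um / px; ypix <- d$y_um / px
  if (nrow(d) && (any(xpix < 0 | xpix > img_size) || any(ypix < 0 | ypix > img_size)))
    stop("positions fall outside the field after um -> pixel conversion", call. = FALSE)
  frames <- sort(unique(d$frame))
  nf <- if (length(frames)) max(frames) else 1L
  stack <- array(0, c(img_size, img_size, nf))
  half <- ceiling(4 * psf_sigma)
  edges <- 0:img_size
  for (t in seq_len(nf)) {
    img <- matrix(background, img_size, img_size)
    sel <- which(d$frame == t)
    for (s in sel) {
      amp <- photon_scale * icol[s]
      cx <- xpix[s]; cy <- ypix[s]
      jr <- max(1, floor(cx - half)):min(img_size, ceiling(cx + half))
      ir <- max(1, floor(cy - half)):min(img_size, ceiling(cy + half))
      wx <- diff(stats::pnorm(edges[c(jr, jr[length(jr)] + 1L)], cx, psf_sigma))
      wy <- diff(stats::pnorm(edges[c(ir, ir[length(ir)] + 1L)], cy, psf_sigma))
      img[ir, jr] <- img[ir, jr] + amp * (wy %o% wx)
    }
    if (noise) img[] <- stats::rpois(length(img), img)
    stack[, , t] <- img
  }
  if (any(stack > 65535)) {
    warning("saturated pixels clipped at 65535")
    stack[stack > 65535] <- 65535
  }
  storage.mode(stack) <- "integer"
  attr(stack, "pixel_size") <- px
  attr(stack, "dt") <- traj$dt
  stack
}

#' Write / read a movie as 16-bit multi-page TIFF
#'
#' Acquisition metadata (pixel size in um, frame interval in s) is stored in
#' a JSON sidecar file (`<path>.meta.json`) and restored on read, so the
#' pair round-trips losslessly.
#'
#' @param stack Integer array `h x w x n_frames` (counts in 0..65535), with
#'   optional `pixel_size` / `dt` attributes.
#' @param path TIFF file path.
#' @param pixel_size,dt Metadata overrides; defaults come from the stack's
#'   attributes.
#' @return `write_movie` returns `path` invisibly; `read_movie` returns the
#'   stack with metadata attributes set.
#' @export
write_movie <- function(stack, path, pixel_size = attr(stack, "pixel_size"),
                        dt = attr(stack, "dt")) {
  nf <- dim(stack)[3]
  pages <- lapply(seq_len(nf), function(t) stack[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(list(pixel_size = pixel_size, dt = dt),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) stack[, , t] <- as.integer(round(pages[[t]] * 65535))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    attr(stack, "pixel_size") <- meta$pixel_size
    attr(stack, "dt") <- meta$dt
  }
  stack
}
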