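#' Calibrate the single-fluorophore intensity from a monomer control
#'
#' Fits a parametric intensity distribution to single-molecule intensities
#' of a monomeric membrane-protein control (the CD86 strategy) by maximum
#' likelihood. The fitted arithmetic mean is the calibration value used to
#' interpret oligomer intensity histograms.
#'
#' @param intensities Positive intensity samples (a.u.), at least 200.
#' @param family `"lognormal"` (closed-form MLE) or `"gamma"`.
#' @param dye Optional dye identifier carried through reports.
#' @return Object of class `monomer_cal`: `mean_intensity`, `family`,
#'   `params`, `dye`, `n`.
#' @export
calibrate_monomer <- function(intensities, family = c("lognormal", "gamma"),
                              dye = NA_character_) {
  family <- match.arg(family)
  if (any(!is.finite(intensities) | intensities <= 0))
    stop("intensities must be positive and finite", call. = FALSE)
  if (length(intensities) < 200)
    stop("need >= 200 intensity samples for calibration", call. = FALSE)
  if (family == "lognormal") {
    ml <- mean(log(intensities))
    sl <- stats::sd(log(intensities)) * sqrt((length(intensities) - 1) / length(intensities))
    params <- c(meanlog = ml, sdlog = sl)
    m <- exp(ml + sl^2 / 2)
  } else {
    fd <- MASS::fitdistr(intensities, "gamma")
    params <- fd$estimate
    m <- unname(params["shape"] / params["rate"])
  }
  structure(list(dye = dye, family = family, params = params,
                 mean_intensity = unname(m), n = length(intensities)),
            class = "monomer_cal")
}

#' @export
print.monomer_cal <- function(x, ...) {
  cat("<monomer_cal> ", if (!is.na(x$dye)) paste0(x$dye, ": "), "mean = ",
      signif(x$mean_intensity, 5), " a.u. (", x$family, ", n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

## intensity grid shared by the oligomer basis: 0 .. n_max * monomer mean
intensity_grid <- function(cal, n_max = 8, n_bins = 256) {
  upper <- n_max * cal$mean_intensity
  breaks <- seq(0, upper, length.out = n_bins + 1)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       width = breaks[2] - breaks[1])
}

## per-bin probability mass of the monomer distribution
monomer_bin_mass <- function(cal, breaks) {
  p <- switch(cal$family,
              lognormal = stats::plnorm(breaks, cal$params["meanlog"], cal$params["sdlog"]),
              gamma = stats::pgamma(breaks, cal$params["shape"], cal$params["rate"]))
  diff(p)
}

## n-fold discrete self-convolution, full support (length grows)
convolve_n <- function(p1, n) {
  out <- p1
  if (n > 1) for (i in 2:n) out <- stats::convolve(out, rev(p1), type = "open")
  pmax(out, 0)
}

## m-fold monomer convolution computed on an oversampled grid and aggregated
## back to n_bins; oversampling suppresses the half-bin smearing that direct
## coarse-grid convolution accumulates over repeated convolutions
mconv_on_grid <- function(cal, m_values, n_max, n_bins, oversample = 8) {
  nf <- n_bins * oversample
  breaks_f <- seq(0, n_max * cal$mean_intensity, length.out = nf + 1)
  p1f <- monomer_bin_mass(cal, breaks_f)
  lapply(m_values, function(m) {
    cm <- convolve_n(p1f, m)[seq_len(nf)]
    colSums(matrix(cm, oversample))
  })
}

#' Model intensity distribution of an n-mer
#'
#' The intensity of an n-mer with n labeled subunits is the n-fold
#' convolution of the single-fluorophore distribution; it is computed
#' numerically on a fixed intensity grid (default 0 to `n_max` times the
#' monomer mean, 256 bins). Mass convolved beyond the grid is truncated,
#' not renormalized, so bases remain comparable when observed histograms
#' are clipped at the same upper bound.
#'
#' @param cal A [calibrate_monomer()] result.
#' @param n Oligomer size (number of labeled subunits).
#' @param n_max Grid upper bound in monomer-mean units (default 8).
#' @param n_bins Grid bins.
#' @param oversample Internal grid refinement factor for the convolution.
#' @return List: `mids` (bin centres, a.u.), `breaks`, `mass` (per-bin
#'   probability, truncated at the grid).
#' @export
nmer_model <- function(cal, n, n_max = 8, n_bins = 256, oversample = 8) {
  stopifnot(inherits(cal, "monomer_cal"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (n > n_max) stop("n exceeds n_max", call. = FALSE)
  g <- intensity_grid(cal, n_max, n_bins)
  mass <- mconv_on_grid(cal, n, n_max, n_bins, oversample)[[1]]
  list(mids = g$mids, breaks = g$breaks, mass = mass)
}

## visible-intensity basis of a k-mer under per-subunit labeling probability p:
## binomial mixture over the number of labeled subunits, conditioned on >= 1
kmer_visible_mass <- function(mconvs, k, p_label) {
  if (p_label <= 0 || p_label > 1) stop("labeling probability must be in (0, 1]")
  w <- stats::dbinom(seq_len(k), k, p_label)
  w <- w / sum(w)  # condition on visibility (>= 1 label)
  out <- numeric(length(mconvs[[1]]))
  for (m in seq_len(k)) out <- out + w[m] * mconvs[[m]]
  out
}

#' Decompose an intensity histogram into oligomer-size weights
#'
#' Non-negative least squares of the observed per-state intensity histogram
#' against model bases for k-mers, k = 1..n_max. With partial labeling
#' (probability `labeling` per subunit), each k-mer basis is the binomial
#' mixture over the number of labeled subunits conditional on at least one
#' label — unlabeled particles are never detected, so the visible intensity
#' of, say, a tetramer at 50% labeling peaks well below four monomer units.
#' The NNLS solution estimates the mix of *visible* particles; because a
#' k-mer is visible with probability `1 - (1 - labeling)^k`, the reported
#' composition weights divide out that detection probability (small k-mers
#' are under-represented among detections) and renormalize. NNLS is convex,
#' so the decomposition is deterministic.
#'
#' @param intensities Observed particle intensities (a.u.), or a precomputed
#'   histogram as a list with `counts` on the package grid.
#' @param cal A [calibrate_monomer()] result (same intensity units).
#' @param n_max Largest oligomer size considered.
#' @param labeling Per-subunit labeling probability for this dye.
#' @param n_bins Grid bins.
#' @param oversample Internal grid refinement for basis convolutions.
#' @return Object of class `oligomer_decomp`: `weights` (composition
#'   probability vector over sizes 1..n_max), `visible_weights` (mix of
#'   detected particles), `residual` (relative L2 residual of the NNLS
#'   fit), `basis`, `observed`, `mids`.
#' @export
decompose_histogram <- function(intensities, cal, n_max = 8, labeling = 1,
                                n_bins = 256, oversample = 8) {
  stopifnot(inherits(cal, "monomer_cal"))
  g <- intensity_grid(cal, n_max, n_bins)
  if (is.list(intensities) && !is.null(intensities$counts)) {
    obs <- intensities$counts
    if (length(obs) != n_bins) stop("histogram does not match the grid", call. = FALSE)
  } else {
    x <- intensities[is.finite(intensities) & intensities > 0]
    x <- x[x <= max(g$breaks)]
    obs <- graphics::hist(x, breaks = g$breaks, plot = FALSE)$counts
  }
  if (sum(obs) == 0) stop("all-zero histogram", call. = FALSE)
  obs <- obs / sum(obs)
  mconvs <- mconv_on_grid(cal, seq_len(n_max), n_max, n_bins, oversample)
  basis <- vapply(seq_len(n_max), function(k)
    kmer_visible_mass(mconvs, k, labeling), numeric(n_bins))
  sol <- pracma::lsqnonneg(basis, obs)
  w <- sol$x
  if (sum(w) == 0) stop("NNLS returned the zero solution", call. = FALSE)
  visible_weights <- w / sum(w)
  p_vis <- 1 - (1 - labeling)^seq_len(n_max)
  comp <- visible_weights / p_vis
  structure(list(weights = comp / sum(comp),
                 visible_weights = visible_weights,
                 n_max = n_max, labeling = labeling,
                 residual = sqrt(sum((basis %*% w - obs)^2)) / sqrt(sum(obs^2)),
                 basis = basis, observed = obs, mids = g$mids),
            class = "oligomer_decomp")
}

#' @export
print.oligomer_decomp <- function(x, ...) {
  cat("<oligomer_decomp> n_max =", x$n_max, " labeling =", x$labeling,
      " residual =", signif(x$residual, 3), "\n")
  w <- round(x$weights, 3)
  names(w) <- paste0(seq_along(w), "-mer")
  print(w)
  invisible(x)
}

#' Density-normalized difference of two intensity histograms
#'
#' Per-bin `after - before`, with each histogram scaled to its particle
#' density so that net removal of particles (endocytosis) appears as
#' negative mass and a compositional shift as paired positive/negative
#' lobes.
#'
#' @param hist_before,hist_after Histograms as lists with `counts` and
#'   `breaks` (identical binning) — e.g. from [graphics::hist()].
#' @param density_before,density_after Particle densities (um^-2) used to
#'   scale each histogram; defaults of 1 compare raw count fractions.
#' @return Data frame `mid`, `before`, `after`, `difference` (density
#'   units per bin).
#' @export
difference_histogram <- function(hist_before, hist_after,
                                 density_before = 1, density_after = 1) {
  if (length(hist_before$breaks) != length(hist_after$breaks) ||
      any(hist_before$breaks != hist_after$breaks))
    stop("histogram binning mismatch", call. = FALSE)
  nb <- sum(hist_before$counts); na <- sum(hist_after$counts)
  if (nb == 0 || na == 0) stop("empty histogram", call. = FALSE)
  b <- hist_before$counts / nb * density_before
  a <- hist_after$counts / na * density_after
  mids <- (hist_before$breaks[-1] + hist_before$breaks[-length(hist_before$breaks)]) / 2
  data.frame(mid = mids, before = b, after = a, difference = a - b)
}
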