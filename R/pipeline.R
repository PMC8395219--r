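#' Pipeline configuration
#'
#' Collects every stage's parameters with namespaced defaults. Any entry
#' can be overridden; the fully resolved configuration is written next to
#' the outputs of [run_pipeline()] for reproducibility.
#'
#' @param seed Root seed; per-stage seeds are derived from it with
#'   [derive_seeds()].
#' @param out_dir Output directory, or `NULL` to keep results in memory
#'   only.
#' @param preset Time-lapse endocytosis preset (see [timelapse_preset()]).
#' @param ... Overrides for any default entry (e.g. `hmm_K`, `msd_max_lag`,
#'   `coloc_radius`, or a full `sim` [sim_params()] object).
#' @return A named list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL,
                            preset = c("vehicle", "TRPV1", "TRPV4"), ...) {
  preset <- match.arg(preset)
  cfg <- list(seed = seed, out_dir = out_dir, preset = preset,
              sim = sim_params(),
              timelapse = TRUE,
              time_points = c(0, 5, 10, 15, 20),
              hmm_K = 3, hmm_restarts = 3, hmm_min_steps = 5,
              msd_max_lag = 10, msd_fit_points = 4,
              oligomer_n_max = 8, oligomer_n_bins = 256,
              monomer_n = 3000,
              coloc_radius = 0.2, coloc_window = 1/3)
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds flat key-value entries matching [pipeline_config()]
#' arguments; a nested `sim:` block is passed on to [sim_params()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_over <- y$sim
  y$sim <- NULL
  cfg <- do.call(pipeline_config, y)
  if (!is.null(sim_over)) {
    if (!is.null(sim_over$rate_matrix))
      sim_over$rate_matrix <- matrix(unlist(sim_over$rate_matrix),
                                     nrow = length(sim_over$rate_matrix), byrow = TRUE)
    cfg$sim <- do.call(sim_params, sim_over)
  }
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' Reproduces the analysis graph end-to-end on simulated data: simulate a
#' two-colour time-lapse with the chosen endocytosis preset, fit the
#' diffusion-state HMM on the basal movie, label every step, compute
#' per-state MSD curves with linear and confined fits, per-state density
#' and fraction time courses, the monomer calibration and per-state
#' oligomer decomposition, and two-colour colocalization kinetics (fraction,
#' on-rate, on-time survival) per time point. Returns a machine-readable
#' summary and optionally writes JSON/CSV outputs plus the resolved
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements `hmm`, `rates`,
#'   `msd`, `timecourse`, `oligomer`, `coloc`, `summary` (plain list, JSON
#'   serializable).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 6)
  sim_p <- config$sim
  preset_rates <- if (config$preset == "vehicle")
    matrix(0, length(config$time_points), sim_p$n_states)
  else timelapse_preset(config$preset)[seq_along(config$time_points), , drop = FALSE]

  ## --- simulate the time-lapse ------------------------------------------
  sim_p$seed <- seeds[1]
  series <- simulate_timelapse(sim_p, preset_rates, config$time_points)

  ## --- diffusion-state HMM on the basal movie ---------------------------
  basal <- series[[1]]
  fit <- fit_vbhmm(basal$traj, K = config$hmm_K, seed = seeds[2],
                   n_restarts = config$hmm_restarts,
                   min_steps = config$hmm_min_steps)
  rates <- transition_rates(fit)
  labeled <- lapply(series, function(s) assign_states(s$traj, fit))

  ## --- MSD per state on the basal movie ---------------------------------
  msd_total <- compute_msd(labeled[[1]], max_lag = config$msd_max_lag)
  lin <- fit_msd_linear(msd_total, config$msd_fit_points)
  msd_states <- lapply(seq_len(fit$K), function(k)
    compute_msd(labeled[[1]], max_lag = config$msd_max_lag, state = k))
  conf <- tryCatch(fit_msd_confined(msd_states[[1]]), error = function(e) NULL,
                   warning = function(w) suppressWarnings(fit_msd_confined(msd_states[[1]])))
  msd_tp <- vapply(labeled, function(tr) {
    m <- compute_msd(tr, max_lag = config$msd_max_lag)
    mean(m$msd[m$lag > 0])
  }, 1)

  ## --- densities / fractions over time ----------------------------------
  tc <- density_timecourse(labeled, config$time_points,
                           cell_area = sim_p$cell_area, n_states = fit$K)
  dens_cor <- if (length(config$time_points) >= 3)
    correlate_density_msd(tc, msd_tp) else NA_real_

  ## --- oligomer analysis -------------------------------------------------
  set.seed(seeds[3])
  mono_pars <- lnorm_from_mean_cv(sim_p$monomer_mean[1], sim_p$monomer_cv)
  mono <- stats::rlnorm(config$monomer_n, mono_pars["meanlog"], mono_pars["sdlog"])
  cal <- calibrate_monomer(mono, dye = "ch1")
  p_visible <- sim_p$label_probs[1]
  olig <- lapply(seq_len(fit$K), function(k) {
    d <- labeled[[1]]$data
    ints <- d$intensity_ch1[!is.na(d$state) & d$state == k & d$intensity_ch1 > 0]
    if (length(ints) < 30) return(NULL)
    decompose_histogram(ints, cal, n_max = config$oligomer_n_max,
                        labeling = p_visible, n_bins = config$oligomer_n_bins)
  })

  ## --- two-colour colocalization per time point --------------------------
  set.seed(seeds[4])
  coloc <- lapply(seq_along(series), function(i) {
    chans <- two_color_sets(series[[i]], sim_p)
    ch1 <- assign_states(chans$ch1, fit)
    ch2 <- assign_states(chans$ch2, fit)
    ev <- detect_colocalization(ch1, ch2, radius = config$coloc_radius)
    nf <- max(ch1$data$frame)
    dens1 <- nrow(ch1$data) / nf / sim_p$cell_area
    dens2 <- nrow(ch2$data) / nf / sim_p$cell_area
    frac <- colocalized_fraction(ev, ch1, ch2)
    onr <- on_rate(ev, sim_p$cell_area, dens1, dens2, window = config$coloc_window)
    ont <- if (nrow(ev) >= 10) on_time_survival(ev) else NULL
    list(events = ev, fraction = frac, on_rate = onr, on_time = ont)
  })

  summary <- list(
    seed = config$seed, preset = config$preset,
    K = fit$K, D_est = fit$D_est, A = fit$A,
    state_fractions = fit$state_fractions,
    lower_bound = fit$lower_bound,
    rates_per_s = rates$rates, dwell_times_s = rates$dwell_times,
    D_linear_total = lin$D, msd_offset = lin$offset,
    confinement_L_um = if (!is.null(conf)) conf$L else NA,
    density_timecourse = as.data.frame(tc),
    density_msd_correlation = dens_cor,
    monomer_mean = cal$mean_intensity,
    oligomer_weights = lapply(olig, function(o) if (is.null(o)) NULL else o$weights),
    colocalized_fraction = vapply(coloc, function(c) c$fraction$overall, 1),
    k_on = vapply(coloc, function(c) c$on_rate$k_on, 1),
    mean_on_time = vapply(coloc, function(c)
      if (is.null(c$on_time)) NA_real_ else c$on_time$mean_on_time, 1))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    cfg_out <- config; cfg_out$sim <- unclass(cfg_out$sim)
    cfg_out$sim$rate_matrix <- apply(cfg_out$sim$rate_matrix, 1, identity, simplify = FALSE)
    yaml::write_yaml(lapply(unclass(cfg_out), function(z) if (is.matrix(z))
      apply(z, 1, identity, simplify = FALSE) else z),
      file.path(config$out_dir, "config_resolved.yaml"))
    for (i in seq_along(labeled))
      write_trajectories(labeled[[i]],
                         file.path(config$out_dir,
                                   sprintf("trajectories_t%02d.csv", i)))
  }
  structure(list(hmm = fit, rates = rates,
                 msd = list(total = msd_total, linear = lin,
                            per_state = msd_states, confined = conf),
                 timecourse = tc, oligomer = list(calibration = cal, decomp = olig),
                 coloc = coloc, summary = summary),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result> preset =", s$preset, ", seed =", s$seed, "\n")
  cat("  K =", s$K, " D =", paste(signif(s$D_est, 3), collapse = "/"), "um^2/s\n")
  cat("  fractions:", paste(signif(s$state_fractions, 3), collapse = "/"), "\n")
  cat("  colocalized fraction (per time point):",
      paste(signif(s$colocalized_fraction, 3), collapse = ", "), "\n")
  invisible(x)
}
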