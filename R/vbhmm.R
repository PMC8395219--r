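#' Variational-Bayes HMM over diffusion states
#'
#' Clusters trajectory steps into K diffusive states. Each 2-D displacement
#' step is emitted from one of K zero-mean Gaussian states with per-axis
#' variance `2 * D_k * dt` (localization noise is absorbed into the apparent
#' D by default; see [subtract_loc_noise()]), and states switch between
#' steps as a first-order Markov chain. Inference is conjugate variational
#' Bayes: Dirichlet priors on the initial distribution and the transition
#' matrix rows, Gamma priors on the per-state displacement precisions, a
#' forward-backward E-step run with expected log-parameters, and closed-form
#' hyperparameter updates in the M-step. Iteration stops when the relative
#' change of the evidence lower bound (ELBO) falls below `tol`; the bound is
#' non-decreasing at every iteration. The best of `n_restarts` runs (first
#' run initialized by a quantile split of the step lengths, later runs
#' randomly) is returned, with states canonically ordered by ascending
#' diffusion coefficient (state 1 = immobile).
#'
#' @param traj A [trajectory_set()].
#' @param K Number of diffusion states.
#' @param priors Optional list overriding `alpha_pi`, `alpha_A` (Dirichlet
#'   concentrations, default 1) and `a0`, `b0` (Gamma shape/rate on the
#'   per-state precision; defaults: shape 2 and rate `2 * dt * D_prior`
#'   with `D_prior` the overall mean squared step over `4 dt` — weakly
#'   informative and scale-aware).
#' @param seed Integer seed controlling the random restarts.
#' @param n_restarts Number of restarts.
#' @param min_steps Tracks with fewer displacement steps are excluded from
#'   fitting (they can still be labeled afterwards by [assign_states()]).
#' @param tol Relative ELBO change declaring convergence.
#' @param max_iter Iteration cap per restart.
#' @return Object of class `vbhmm`: `D_est` (ascending, um^2/s), `A`
#'   (posterior-mean per-frame transition matrix), `pi`, `state_fractions`
#'   (stationary occupancy of `A`), `lower_bound`, `elbo_trace`,
#'   `responsibilities` (per-step posterior state probabilities with track
#'   keys), `viterbi` (per-step MAP labels), `converged`, `n_iter`, `dt`.
#' @export
fit_vbhmm <- function(traj, K, priors = NULL, seed = NULL, n_restarts = 5,
                      min_steps = 5, tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(traj, "trajectory_set"), K >= 1)
  prep <- vbhmm_prep(traj, min_steps)
  n_steps <- sum(prep$L)
  if (n_steps == 0) stop("no usable tracks (all shorter than min_steps)", call. = FALSE)
  if (K > n_steps) stop("K exceeds the number of displacement steps", call. = FALSE)
  r2all <- prep$R2[!is.na(prep$R2)]
  if (stats::var(r2all) == 0 && K > 1)
    stop("degenerate data: all squared steps identical", call. = FALSE)
  dt <- traj$dt
  D_prior <- mean(r2all) / (4 * dt)
  pr <- list(alpha_pi = 1, alpha_A = 1, a0 = 2, b0 = 2 * dt * D_prior)
  pr[names(priors)] <- priors

  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    gamma0 <- vbhmm_init(prep, K, random = rs > 1)
    fit <- vbhmm_run(prep, K, pr, gamma0, dt, tol, max_iter)
    if (is.null(best) || fit$lower_bound > best$lower_bound) best <- fit
  }
  best$call_priors <- pr
  best$n_restarts <- n_restarts
  best
}

## ---- internal machinery -------------------------------------------------

## pack tracks into padded step matrices
vbhmm_prep <- function(traj, min_steps) {
  steps <- track_steps(traj, min_steps = max(1L, min_steps))
  if (!length(steps))
    return(list(R2 = matrix(NA_real_, 0, 0), L = integer(0), keys = NULL))
  L <- vapply(steps, nrow, 1L)
  Tmax <- max(L)
  n <- length(steps)
  R2 <- matrix(NA_real_, n, Tmax)
  for (i in seq_len(n)) R2[i, seq_len(L[i])] <- steps[[i]]$r2
  keys <- lapply(steps, function(d) d[c("cell_id", "particle_id", "frame")])
  list(R2 = R2, L = L, keys = keys)
}

## initial responsibilities: quantile split of step lengths, or random
vbhmm_init <- function(prep, K, random = FALSE) {
  n <- nrow(prep$R2); Tmax <- ncol(prep$R2)
  gamma <- array(0, c(n, K, Tmax))
  if (K == 1L) {
    for (t in seq_len(Tmax)) gamma[, 1, t] <- as.numeric(prep$L >= t)
    return(gamma)
  }
  if (random) {
    for (t in seq_len(Tmax)) {
      g <- matrix(stats::rexp(n * K), n, K)
      g <- g / rowSums(g)
      g[prep$L < t, ] <- 0
      gamma[, , t] <- g
    }
    return(gamma)
  }
  r <- sqrt(prep$R2)
  qs <- stats::quantile(r[!is.na(r)], probs = seq(0, 1, length.out = K + 1),
                        names = FALSE)
  qs[1] <- -Inf; qs[K + 1] <- Inf
  qs <- cummax(qs + seq(0, K) * 1e-12)  # guard against tied quantiles
  lab <- matrix(findInterval(r, qs, rightmost.closed = TRUE), nrow(r), ncol(r))
  lab[lab < 1] <- 1; lab[lab > K] <- K
  for (t in seq_len(Tmax)) {
    act <- which(prep$L >= t)
    gamma[cbind(act, lab[act, t], t)] <- 1
  }
  gamma
}

## sufficient statistics from responsibilities (used only at initialization)
vbhmm_stats_from_gamma <- function(gamma, prep) {
  n <- dim(gamma)[1]; K <- dim(gamma)[2]; Tmax <- dim(gamma)[3]
  Ng <- numeric(K); Sr <- numeric(K); Npi <- numeric(K); Nxi <- matrix(0, K, K)
  for (t in seq_len(Tmax)) {
    g <- gamma[, , t, drop = FALSE][, , 1, drop = TRUE]
    if (K == 1) g <- matrix(g, n, 1)
    act <- prep$L >= t
    r2 <- prep$R2[, t]
    Ng <- Ng + colSums(g[act, , drop = FALSE])
    Sr <- Sr + colSums(g[act, , drop = FALSE] * r2[act])
    if (t == 1) Npi <- colSums(g[act, , drop = FALSE])
    if (t > 1) {
      act2 <- prep$L >= t
      gp <- gamma[, , t - 1, drop = FALSE][, , 1, drop = TRUE]
      if (K == 1) gp <- matrix(gp, n, 1)
      Nxi <- Nxi + t(gp[act2, , drop = FALSE]) %*% g[act2, , drop = FALSE]
    }
  }
  list(Ngamma = Ng, Sr2 = Sr, Npi = Npi, Nxi = Nxi)
}

## one full VB run from initial responsibilities
vbhmm_run <- function(prep, K, pr, gamma0, dt, tol, max_iter) {
  n <- nrow(prep$R2); Tmax <- ncol(prep$R2); L <- prep$L
  stats <- vbhmm_stats_from_gamma(gamma0, prep)
  elbo_trace <- numeric(0)
  elbo_old <- -Inf
  converged <- FALSE
  hyper <- NULL; E <- NULL
  for (it in seq_len(max_iter)) {
    ## M-step: posterior hyperparameters
    hyper <- list(alpha_pi = pr$alpha_pi + stats$Npi,
                  alpha_A = pr$alpha_A + stats$Nxi,
                  a = pr$a0 + stats$Ngamma,
                  b = pr$b0 + stats$Sr2 / 2)
    ## E-step with expected log-parameters
    E <- vbhmm_estep(prep, hyper)
    stats <- E$stats
    elbo <- E$loglik_tilde - vbhmm_kl(hyper, pr, K)
    elbo_trace <- c(elbo_trace, elbo)
    if (is.finite(elbo_old) &&
        abs(elbo - elbo_old) < tol * (abs(elbo_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    elbo_old <- elbo
  }
  ## reporting: point estimates from the final responsibilities
  hyper <- list(alpha_pi = pr$alpha_pi + stats$Npi,
                alpha_A = pr$alpha_A + stats$Nxi,
                a = pr$a0 + stats$Ngamma,
                b = pr$b0 + stats$Sr2 / 2)
  D_est <- stats$Sr2 / (4 * dt * pmax(stats$Ngamma, .Machine$double.eps))
  A <- hyper$alpha_A / rowSums(hyper$alpha_A)
  pi_hat <- hyper$alpha_pi / sum(hyper$alpha_pi)
  ord <- order(D_est)
  D_est <- D_est[ord]; A <- A[ord, ord, drop = FALSE]; pi_hat <- pi_hat[ord]
  gamma <- E$gamma[, ord, , drop = FALSE]
  fractions <- if (K == 1) 1 else stationary_dist(A)
  vit <- vbhmm_viterbi(prep, pi_hat, A, D_est, dt)
  resp <- vbhmm_resp_frame(prep, gamma, vit)
  structure(list(K = K, D_est = unname(D_est), A = unname(A),
                 pi = unname(pi_hat), state_fractions = unname(fractions),
                 lower_bound = elbo_trace[length(elbo_trace)],
                 elbo_trace = elbo_trace,
                 responsibilities = resp,
                 converged = converged, n_iter = length(elbo_trace),
                 dt = dt, hyper = hyper, n_tracks = n, n_steps = sum(L)),
            class = "vbhmm")
}

## forward-backward over all tracks simultaneously (tracks are rows)
vbhmm_estep <- function(prep, hyper) {
  R2 <- prep$R2; L <- prep$L
  n <- nrow(R2); Tmax <- ncol(R2)
  K <- length(hyper$a)
  Elam <- hyper$a / hyper$b
  Eloglam <- digamma(hyper$a) - log(hyper$b)
  lpi <- digamma(hyper$alpha_pi) - digamma(sum(hyper$alpha_pi))
  lA <- digamma(hyper$alpha_A) - digamma(rowSums(hyper$alpha_A))
  piT <- exp(lpi); AT <- exp(lA)

  ## emission subprobabilities; padded steps get 1
  B <- array(1, c(n, K, Tmax))
  for (t in seq_len(Tmax)) {
    act <- L >= t
    if (!any(act)) next
    lb <- outer(R2[act, t], -Elam / 2) +
      matrix(Eloglam - log(2 * pi), sum(act), K, byrow = TRUE)
    B[act, , t] <- exp(lb)
  }

  alpha <- array(0, c(n, K, Tmax))
  cmat <- matrix(1, n, Tmax)
  a1 <- sweep(B[, , 1, drop = FALSE][, , 1, drop = FALSE], 2, piT, "*")
  a1 <- matrix(a1, n, K)
  c1 <- rowSums(a1); c1[c1 <= 0 | !is.finite(c1)] <- .Machine$double.xmin
  alpha[, , 1] <- a1 / c1
  cmat[, 1] <- ifelse(L >= 1, c1, 1)
  if (Tmax > 1) for (t in 2:Tmax) {
    prev <- matrix(alpha[, , t - 1], n, K)
    at <- (prev %*% AT) * matrix(B[, , t], n, K)
    ct <- rowSums(at); ct[ct <= 0 | !is.finite(ct)] <- .Machine$double.xmin
    at <- at / ct
    act <- L >= t
    at[!act, ] <- prev[!act, ]
    ct[!act] <- 1
    alpha[, , t] <- at
    cmat[, t] <- ct
  }
  loglik_tilde <- sum(log(cmat))

  ## backward pass with xi/gamma accumulation
  gamma <- array(0, c(n, K, Tmax))
  beta <- matrix(1, n, K)
  Nxi <- matrix(0, K, K)
  if (Tmax > 1) for (t in Tmax:2) {
    act <- L >= t
    g <- matrix(alpha[, , t], n, K) * beta
    g <- g / pmax(rowSums(g), .Machine$double.xmin)
    g[!act, ] <- 0
    gamma[, , t] <- g
    if (any(act)) {
      Bb <- matrix(B[, , t], n, K) * beta / cmat[, t]
      Nxi <- Nxi + AT * (t(matrix(alpha[, , t - 1], n, K)[act, , drop = FALSE]) %*%
                           Bb[act, , drop = FALSE])
      beta_new <- Bb %*% t(AT)
      beta[act, ] <- beta_new[act, , drop = FALSE]
    }
  }
  g1 <- matrix(alpha[, , 1], n, K) * beta
  g1 <- g1 / pmax(rowSums(g1), .Machine$double.xmin)
  g1[L < 1, ] <- 0
  gamma[, , 1] <- g1

  Ng <- numeric(K); Sr <- numeric(K)
  for (t in seq_len(Tmax)) {
    act <- L >= t
    g <- matrix(gamma[, , t], n, K)
    Ng <- Ng + colSums(g[act, , drop = FALSE])
    Sr <- Sr + colSums(g[act, , drop = FALSE] * R2[act, t])
  }
  list(stats = list(Ngamma = Ng, Sr2 = Sr, Npi = colSums(g1), Nxi = Nxi),
       gamma = gamma, loglik_tilde = loglik_tilde)
}

## KL divergences of the variational posteriors from the priors
vbhmm_kl <- function(hyper, pr, K) {
  kl_dir <- function(alpha, alpha0) {
    a0 <- rep_len(alpha0, length(alpha))
    lgamma(sum(alpha)) - sum(lgamma(alpha)) -
      lgamma(sum(a0)) + sum(lgamma(a0)) +
      sum((alpha - a0) * (digamma(alpha) - digamma(sum(alpha))))
  }
  kl_gamma <- function(a, b, a0, b0) {
    (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
      a0 * (log(b) - log(b0)) + a * (b0 - b) / b
  }
  kl <- kl_dir(hyper$alpha_pi, pr$alpha_pi)
  for (i in seq_len(K))
    kl <- kl + kl_dir(hyper$alpha_A[i, ], pr$alpha_A)
  kl + sum(kl_gamma(hyper$a, hyper$b, pr$a0, pr$b0))
}

## MAP state path per track with posterior-mean parameters
vbhmm_viterbi <- function(prep, pi_hat, A, D_est, dt) {
  K <- length(D_est)
  s2 <- pmax(2 * D_est * dt, .Machine$double.xmin)  # per-axis variance
  lA <- log(pmax(A, .Machine$double.xmin))
  lpi <- log(pmax(pi_hat, .Machine$double.xmin))
  lapply(seq_len(nrow(prep$R2)), function(i) {
    Li <- prep$L[i]
    r2 <- prep$R2[i, seq_len(Li)]
    le <- outer(r2, 1 / (2 * s2), "*") * (-1) -
      matrix(log(2 * pi * s2), Li, K, byrow = TRUE)
    V <- matrix(-Inf, Li, K); ptr <- matrix(0L, Li, K)
    V[1, ] <- lpi + le[1, ]
    if (Li > 1) for (t in 2:Li) {
      cand <- V[t - 1, ] + lA   # K x K
      ptr[t, ] <- max.col(t(cand), ties.method = "first")
      V[t, ] <- cand[cbind(ptr[t, ], seq_len(K))] + le[t, ]
    }
    path <- integer(Li)
    path[Li] <- which.max(V[Li, ])
    if (Li > 1) for (t in (Li - 1):1) path[t] <- ptr[t + 1, path[t + 1]]
    path
  })
}

## long-format responsibilities with track keys
vbhmm_resp_frame <- function(prep, gamma, vit) {
  K <- dim(gamma)[2]
  out <- lapply(seq_along(prep$keys), function(i) {
    Li <- prep$L[i]
    g <- t(matrix(gamma[i, , seq_len(Li)], K, Li))
    colnames(g) <- paste0("state", seq_len(K))
    cbind(prep$keys[[i]], as.data.frame(g), viterbi = vit[[i]])
  })
  do.call(rbind, out)
}

## ---- user-facing companions ---------------------------------------------

#' Fit VB-HMMs over a range of state counts and select by lower bound
#'
#' Fits each `K` in `K_range` and returns the model with the highest
#' evidence lower bound, together with the full per-K table for reporting.
#'
#' @inheritParams fit_vbhmm
#' @param K_range Candidate state counts.
#' @return Object of class `vbhmm_selection`: `best_K`, `best` (the winning
#'   [fit_vbhmm()] object), `fits` (all fits), and `table` (K, lower bound,
#'   convergence).
#' @export
select_model <- function(traj, K_range = 1:5, priors = NULL, seed = NULL,
                         n_restarts = 5, min_steps = 5, tol = 1e-6,
                         max_iter = 500) {
  if (!length(K_range)) stop("K_range must be non-empty", call. = FALSE)
  seeds <- if (is.null(seed)) rep(list(NULL), length(K_range))
           else as.list(derive_seeds(seed, length(K_range)))
  fits <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    fits[[i]] <- fit_vbhmm(traj, K_range[i], priors = priors,
                           seed = seeds[[i]], n_restarts = n_restarts,
                           min_steps = min_steps, tol = tol, max_iter = max_iter)
  }
  lbs <- vapply(fits, function(f) f$lower_bound, 1)
  tab <- data.frame(K = K_range, lower_bound = lbs,
                    converged = vapply(fits, function(f) f$converged, TRUE))
  best <- which.max(lbs)
  structure(list(best_K = K_range[best], best = fits[[best]], fits = fits,
                 table = tab),
            class = "vbhmm_selection")
}

#' Transition rate constants from a fitted HMM
#'
#' Converts the per-frame transition probability matrix to first-order rate
#' constants: `k_ij = A_ij / dt` off the diagonal, diagonal entries minus
#' the row sums, and mean state dwell times `1 / |k_ii|`.
#'
#' @param fit A `vbhmm` object.
#' @param dt Frame interval, s (defaults to the fit's).
#' @return List with `rates` (K x K, 1/s) and `dwell_times` (s).
#' @export
transition_rates <- function(fit, dt = fit$dt) {
  stopifnot(inherits(fit, "vbhmm"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  K <- fit$K
  rates <- fit$A / dt
  diag(rates) <- 0
  diag(rates) <- -rowSums(rates)
  dwell <- ifelse(diag(rates) == 0, Inf, 1 / abs(diag(rates)))
  list(rates = rates, dwell_times = dwell)
}

#' Label every trajectory step with its MAP diffusion state
#'
#' Viterbi-decodes all tracks (including those too short to have entered the
#' fit) with the fitted posterior-mean parameters and writes a `state`
#' column into the trajectory table. Step t's label is attached to the row
#' at which the step starts; the final row of a track inherits the last
#' step's label, so labels propagate to whole particles.
#'
#' @param traj A [trajectory_set()].
#' @param fit A `vbhmm` object.
#' @return The trajectory set with a `state` column.
#' @export
assign_states <- function(traj, fit) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(fit, "vbhmm"))
  prep <- vbhmm_prep(traj, min_steps = 1L)
  if (!length(prep$L)) stop("trajectory set has no track with >= 2 points", call. = FALSE)
  vit <- vbhmm_viterbi(prep, fit$pi, fit$A, fit$D_est, fit$dt)
  d <- traj$data
  d$state <- NA_integer_
  key_d <- paste(d$cell_id, d$particle_id, d$frame)
  for (i in seq_along(vit)) {
    k <- prep$keys[[i]]
    idx <- match(paste(k$cell_id, k$particle_id, k$frame), key_d)
    d$state[idx] <- vit[[i]]
    last <- match(paste(k$cell_id[nrow(k)], k$particle_id[nrow(k)],
                        k$frame[nrow(k)] + 1L), key_d)
    if (!is.na(last)) d$state[last] <- vit[[i]][length(vit[[i]])]
  }
  traj$data <- d
  traj
}

#' Subtract localization noise from apparent diffusion coefficients
#'
#' The fitted per-state variance of a displacement step is
#' `2 D dt + 2 sigma_loc^2` per axis, so the apparent coefficient exceeds
#' the true one by `sigma_loc^2 / dt`. This helper removes that term
#' analytically (floored at zero).
#'
#' @param D Apparent diffusion coefficients, um^2/s.
#' @param loc_sigma Localization SD per axis, um.
#' @param dt Frame interval, s.
#' @return Corrected diffusion coefficients.
#' @export
subtract_loc_noise <- function(D, loc_sigma, dt) {
  pmax(D - loc_sigma^2 / dt, 0)
}

#' @export
print.vbhmm <- function(x, ...) {
  cat("<vbhmm> K = ", x$K, ", ", x$n_tracks, " tracks / ", x$n_steps,
      " steps, ELBO = ", format(x$lower_bound, digits = 8),
      if (x$converged) " (converged, " else " (NOT converged, ",
      x$n_iter, " iter)\n", sep = "")
  cat("  D (um^2/s): ", paste(signif(x$D_est, 3), collapse = ", "), "\n", sep = "")
  cat("  state fractions: ", paste(signif(x$state_fractions, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.vbhmm <- function(object, ...) {
  tr <- transition_rates(object)
  out <- list(K = object$K, D_est = object$D_est, A = object$A,
              pi = object$pi, state_fractions = object$state_fractions,
              rates = tr$rates, dwell_times = tr$dwell_times,
              lower_bound = object$lower_bound, converged = object$converged,
              n_iter = object$n_iter)
  class(out) <- "summary.vbhmm"
  out
}

#' @export
print.summary.vbhmm <- function(x, ...) {
  cat("VB-HMM with", x$K, "diffusion states (ascending D)\n")
  cat("D (um^2/s):", paste(signif(x$D_est, 4), collapse = ", "), "\n")
  cat("stationary fractions:", paste(signif(x$state_fractions, 3), collapse = ", "), "\n")
  cat("per-frame transition matrix A:\n"); print(signif(x$A, 4))
  cat("rates (1/s):\n"); print(signif(x$rates, 4))
  cat("dwell times (s):", paste(signif(x$dwell_times, 3), collapse = ", "), "\n")
  cat("ELBO:", format(x$lower_bound, digits = 8),
      if (x$converged) "(converged," else "(not converged,", x$n_iter, "iterations)\n")
  invisible(x)
}

#' @export
coef.vbhmm <- function(object, ...) {
  list(D = object$D_est, A = object$A, pi = object$pi)
}

#' @export
logLik.vbhmm <- function(object, ...) {
  structure(object$lower_bound, df = NA_integer_, class = "logLik")
}

#' @export
print.vbhmm_selection <- function(x, ...) {
  cat("<vbhmm_selection> best K =", x$best_K, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
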