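# Shared fixture builders and independent oracles.

## single-state simulation parameters with monomeric particles
single_state_params <- function(D = 0.25, loc_sigma = 0, n_particles = 50,
                                n_frames = 41, confinement_side = NA,
                                track_lifetime_mean = Inf, dt = 0.0305,
                                seed = NULL, ...) {
  sim_params(n_states = 1, D = D, rate_matrix = matrix(0, 1, 1),
             confinement_side = confinement_side, dt = dt,
             loc_sigma = loc_sigma, n_particles = n_particles,
             n_frames = n_frames, track_lifetime_mean = track_lifetime_mean,
             oligomer_dist = matrix(c(1, rep(0, 7)), 1), seed = seed, ...)
}

two_state_params <- function(D = c(0.01, 0.3), k = 1, n_particles = 400,
                             n_frames = 30, loc_sigma = 0,
                             track_lifetime_mean = 20, seed = NULL) {
  sim_params(n_states = 2, D = D, rate_matrix = rbind(c(-k, k), c(k, -k)),
             confinement_side = c(NA, NA), loc_sigma = loc_sigma,
             n_particles = n_particles, n_frames = n_frames,
             track_lifetime_mean = track_lifetime_mean,
             oligomer_dist = matrix(rep(c(1, rep(0, 7)), 2), 2, byrow = TRUE),
             seed = seed)
}

## pooled squared steps of a simulation
pooled_steps <- function(traj) do.call(rbind, smdyn:::track_steps(traj))

## brute-force HMM posterior by enumerating all state sequences of one track,
## using the same expected-log ("tilde") parameters as the VB E-step
brute_force_fb <- function(r2, hyper) {
  K <- length(hyper$a)
  Elam <- hyper$a / hyper$b
  Eloglam <- digamma(hyper$a) - log(hyper$b)
  lpi <- digamma(hyper$alpha_pi) - digamma(sum(hyper$alpha_pi))
  lA <- digamma(hyper$alpha_A) - digamma(rowSums(hyper$alpha_A))
  Tn <- length(r2)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  logw <- apply(seqs, 1, function(s) {
    lw <- lpi[s[1]]
    if (Tn > 1) for (t in 2:Tn) lw <- lw + lA[s[t - 1], s[t]]
    lw + sum(Eloglam[s] - log(2 * pi) - Elam[s] * r2 / 2)
  })
  w <- exp(logw - max(logw))
  Z <- sum(w)
  gamma <- matrix(0, Tn, K)
  for (t in seq_len(Tn)) for (k in seq_len(K))
    gamma[t, k] <- sum(w[seqs[, t] == k]) / Z
  list(logZ = log(Z) + max(logw), gamma = gamma)
}

## exhaustive colocalization oracle: all-pairs enumeration per frame with
## the same greedy one-to-one resolution and consecutive-frame merge rule,
## written independently of the package internals
brute_force_coloc <- function(ch1, ch2, radius = 0.2) {
  d1 <- ch1$data; d2 <- ch2$data
  s1 <- if (!is.null(d1$state)) d1$state else d1$state_true
  s2 <- if (!is.null(d2$state)) d2$state else d2$state_true
  recs <- list()
  for (f in sort(intersect(d1$frame, d2$frame))) {
    a <- d1[d1$frame == f, ]; b <- d2[d2$frame == f, ]
    sa <- s1[d1$frame == f]; sb <- s2[d2$frame == f]
    cand <- list()
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      dd <- sqrt((a$x_um[i] - b$x_um[j])^2 + (a$y_um[i] - b$y_um[j])^2)
      if (dd < radius && !is.na(sa[i]) && !is.na(sb[j]) && sa[i] == sb[j])
        cand[[length(cand) + 1L]] <- c(i, j, dd)
    }
    if (!length(cand)) next
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, 3], a$particle_id[cm[, 1]], b$particle_id[cm[, 2]]), ,
             drop = FALSE]
    u1 <- c(); u2 <- c()
    for (r in seq_len(nrow(cm))) {
      if (cm[r, 1] %in% u1 || cm[r, 2] %in% u2) next
      u1 <- c(u1, cm[r, 1]); u2 <- c(u2, cm[r, 2])
      recs[[length(recs) + 1L]] <- data.frame(
        frame = f, id1 = a$particle_id[cm[r, 1]], id2 = b$particle_id[cm[r, 2]])
    }
  }
  if (!length(recs)) return(data.frame(id1 = integer(0), id2 = integer(0),
                                       start = integer(0), end = integer(0)))
  pp <- do.call(rbind, recs)
  pp <- pp[order(pp$id1, pp$id2, pp$frame), ]
  out <- list()
  key <- paste(pp$id1, pp$id2)
  for (k in unique(key)) {
    sub <- pp[key == k, ]
    brk <- c(0, which(diff(sub$frame) > 1), nrow(sub))
    for (j in seq_len(length(brk) - 1)) {
      seg <- sub[(brk[j] + 1):brk[j + 1], ]
      out[[length(out) + 1L]] <- data.frame(id1 = seg$id1[1], id2 = seg$id2[1],
                                            start = min(seg$frame), end = max(seg$frame))
    }
  }
  out <- do.call(rbind, out)
  out[order(out$start, out$id1, out$id2), ]
}
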