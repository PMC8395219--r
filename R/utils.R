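# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive reproducible child seeds from one root seed
#'
#' All randomness in a multi-stage run flows from a single root seed; each
#' stage draws its own child seed so that changing one stage's sample size
#' does not perturb the random stream of another.
#'
#' @param seed Integer root seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

## reflect a coordinate into [lo, hi] (specular boundaries)
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  y + lo
}

## stationary distribution of a transition-probability matrix (rows sum to 1)
stationary_dist <- function(A) {
  K <- nrow(A)
  ev <- eigen(t(A))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

## stationary distribution of a rate matrix Q (rows sum to 0)
stationary_dist_Q <- function(Q) {
  K <- nrow(Q)
  ## solve pi Q = 0, sum(pi) = 1
  M <- rbind(t(Q), rep(1, K))
  b <- c(rep(0, K), 1)
  qr.solve(M, b)
}

check_rate_matrix <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop("rate matrix must be square", call. = FALSE)
  off <- Q; diag(off) <- 0
  if (any(off < 0))
    stop("rate matrix has negative off-diagonal entries", call. = FALSE)
  if (any(abs(rowSums(Q)) > 1e-8))
    stop("rate matrix rows must sum to 0", call. = FALSE)
  invisible(Q)
}

## lognormal (meanlog, sdlog) from arithmetic mean and CV
lnorm_from_mean_cv <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(unname(mean)) - sdlog^2 / 2
  c(meanlog = meanlog, sdlog = unname(sdlog))
}
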