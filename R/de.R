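#' Bounded differential evolution (rand/1/bin)
#'
#' Global minimizer used to optimize interpolated synthetic likelihoods over
#' the neighbourhood box. Classic DE: population `15 * K`, mutation
#' `F = 0.8`, crossover `CR = 0.9`, up to 200 generations, stopping early
#' when the population objective spread falls below `tol`. The objective is
#' evaluated on whole populations at once (`fn` takes a matrix of candidate
#' rows and returns a vector), which keeps surrogate-based objectives cheap.
#'
#' @param fn vectorized objective: matrix (rows = candidates) -> numeric.
#' @param lower,upper bounds (finite, `lower < upper` allowed to be equal in
#'   degenerate dimensions).
#' @param control list: `pop`, `F`, `CR`, `generations`, `tol`, and
#'   optionally `init`, a matrix of candidate rows used to seed part of the
#'   initial population (clipped to the bounds).
#' @return list with `par`, `value`, `converged`, `generations`.
#' @export
de_optimize <- function(fn, lower, upper,
                        control = list()) {
  K <- length(lower)
  stopifnot(length(upper) == K, all(upper >= lower))
  ctl <- utils::modifyList(
    list(pop = 15 * K, F = 0.8, CR = 0.9, generations = 200, tol = 1e-8),
    control)
  np <- max(ctl$pop, 5)
  rng <- upper - lower
  X <- matrix(stats::runif(np * K), np, K)
  X <- sweep(sweep(X, 2, rng, `*`), 2, lower, `+`)
  if (!is.null(ctl$init)) {
    ini <- as.matrix(ctl$init)
    ni <- min(nrow(ini), ceiling(np / 2))
    for (j in seq_len(K))
      ini[, j] <- pmin(pmax(ini[, j], lower[j]), upper[j])
    X[seq_len(ni), ] <- ini[seq_len(ni), , drop = FALSE]
  }
  f <- fn(X)
  conv <- FALSE
  g <- 0
  while (g < ctl$generations) {
    g <- g + 1
    r1 <- sample.int(np)
    r2 <- sample.int(np)
    r3 <- sample.int(np)
    V <- X[r1, , drop = FALSE] +
      ctl$F * (X[r2, , drop = FALSE] - X[r3, , drop = FALSE])
    # binomial crossover with one guaranteed mutant coordinate
    Cr <- matrix(stats::runif(np * K) < ctl$CR, np, K)
    Cr[cbind(seq_len(np), sample.int(K, np, replace = TRUE))] <- TRUE
    U <- X
    U[Cr] <- V[Cr]
    # reflect into the box
    for (j in seq_len(K)) {
      U[, j] <- pmin(pmax(U[, j], lower[j]), upper[j])
    }
    fu <- fn(U)
    better <- fu < f
    X[better, ] <- U[better, , drop = FALSE]
    f[better] <- fu[better]
    if (max(f) - min(f) < ctl$tol) {
      conv <- TRUE
      break
    }
  }
  i <- which.min(f)
  list(par = X[i, ], value = f[i], converged = conv || g < ctl$generations,
       generations = g)
}
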