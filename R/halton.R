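#' Quasi-random Halton points in a parameter box
#'
#' Deterministic low-discrepancy points: dimension `j` uses the radical
#' inverse in the `j`-th prime base (2, 3, 5, ...), affinely mapped to the
#' working-scale box of `space`. Unlike pseudo-random draws from the uniform
#' prior, Halton points avoid large empty gaps, which directly bounds the
#' worst-case distance between any true parameter and its nearest grid row.
#'
#' @param omega number of points (the sequence is used from index 1).
#' @param space a [parameter_space()]; alternatively `NULL` with `dim` given,
#'   for points in the unit cube.
#' @param dim dimension when `space` is `NULL`.
#' @return an `omega x K` matrix (working scale, columns named by parameter).
#' @examples
#' halton_points(3, dim = 1) # 0.5, 0.25, 0.75
#' @export
halton_points <- function(omega, space = NULL, dim = NULL) {
  stopifnot(omega >= 1)
  k <- if (is.null(space)) dim else space_dim(space)
  stopifnot(!is.null(k), k >= 1)
  bases <- .first_primes(k)
  u <- vapply(bases, function(b) .radical_inverse(seq_len(omega), b),
              numeric(omega))
  u <- matrix(u, nrow = omega, ncol = k)
  if (is.null(space)) return(u)
  out <- sweep(sweep(u, 2, space$upper - space$lower, `*`), 2,
               space$lower, `+`)
  colnames(out) <- space$names
  out
}

.radical_inverse <- function(idx, base) {
  r <- numeric(length(idx))
  f <- 1 / base
  while (any(idx > 0)) {
    r <- r + f * (idx %% base)
    idx <- idx %/% base
    f <- f / base
  }
  r
}

.first_primes <- function(k) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47)
  stopifnot(k <= length(primes))
  primes[seq_len(k)]
}

#' Crude star-discrepancy estimate of a point set in the unit cube
#'
#' Brute-force estimate: the maximum over `n_probe` random anchor boxes
#' `[0, a)` of `|empirical mass - volume|`. Used to verify that Halton point
#' sets cover a box more evenly than pseudo-random ones; not a tight bound.
#'
#' @param u points in `[0,1]^K` (rows).
#' @param n_probe number of probe boxes.
#' @param seed RNG seed for the probe anchors.
#' @return a single number, the estimated discrepancy.
#' @export
star_discrepancy <- function(u, n_probe = 2000, seed = 1) {
  u <- as.matrix(u)
  with_seed(seed, {
    k <- ncol(u)
    a <- matrix(stats::runif(n_probe * k), n_probe, k)
    worst <- 0
    for (i in seq_len(n_probe)) {
      inside <- colSums(t(u) < a[i, ]) == k
      worst <- max(worst, abs(mean(inside) - prod(a[i, ])))
    }
    worst
  })
}
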