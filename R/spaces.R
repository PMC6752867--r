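#' Bounded parameter space with working scales and a prior
#'
#' All estimation in this package happens on a bounded box, on a *working*
#' scale: parameters flagged `"log"` are handled (bounded, gridded, optimized)
#' as natural logarithms and only exponentiated when estimates are reported.
#' `lower`/`upper` are the box bounds **on the working scale** — i.e. exactly
#' as priors such as log(I) ~ U(3, 5) state them.
#'
#' @param names character vector of parameter labels.
#' @param lower,upper finite numeric bounds on the working scale,
#'   `lower < upper` elementwise.
#' @param scale per-parameter flag, `"linear"` or `"log"` (natural log).
#' @param prior optional prior object (see [uniform_prior()]); defaults to
#'   uniform on the working-scale box.
#' @return an object of class `parameter_space`.
#' @examples
#' ricker_space()
#' @export
parameter_space <- function(names, lower, upper, scale = "linear",
                            prior = NULL) {
  k <- length(names)
  scale <- rep_len(scale, k)
  stopifnot(length(lower) == k, length(upper) == k,
            all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper), all(scale %in% c("linear", "log")))
  sp <- structure(
    list(names = names, lower = as.numeric(lower), upper = as.numeric(upper),
         scale = scale, prior = NULL),
    class = "parameter_space")
  sp$prior <- prior %||% uniform_prior(sp)
  sp
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("parameter_space with", length(x$names), "parameters\n")
  for (i in seq_along(x$names))
    cat(sprintf("  %-8s [%g, %g] (%s)\n", x$names[i], x$lower[i],
                x$upper[i], x$scale[i]))
  cat("  prior:", x$prior$kind, "\n")
  invisible(x)
}

space_dim <- function(space) length(space$names)

#' Convert parameters between working and natural scale
#'
#' @param space a [parameter_space()].
#' @param theta numeric vector or matrix (rows = parameter vectors) on the
#'   working scale (`to_natural`) or natural scale (`to_working`).
#' @return vector/matrix of the same shape on the other scale.
#' @export
to_natural <- function(space, theta) {
  .scale_map(space, theta, exp)
}

#' @rdname to_natural
#' @export
to_working <- function(space, theta) {
  .scale_map(space, theta, log)
}

.scale_map <- function(space, theta, f) {
  vec <- is.null(dim(theta))
  m <- if (vec) matrix(theta, nrow = 1) else as.matrix(theta)
  stopifnot(ncol(m) == space_dim(space))
  for (j in which(space$scale == "log")) m[, j] <- f(m[, j])
  colnames(m) <- space$names
  if (vec) stats::setNames(drop(m), space$names) else m
}

space_contains <- function(space, theta, tol = 1e-9) {
  m <- if (is.null(dim(theta))) matrix(theta, nrow = 1) else as.matrix(theta)
  rng <- space$upper - space$lower
  apply(m, 1, function(r)
    all(r >= space$lower - tol * rng & r <= space$upper + tol * rng))
}

#' Expected grid gap of an evenly spaced grid
#'
#' For a box with `K` dimensions covered by `omega` evenly spaced points, the
#' per-dimension spacing is `(upper - lower) / omega^(1/K)`. A quasi-random
#' (Halton) grid of the same size has expected gaps close to these values;
#' they set the accuracy floor of pure nearest-neighbour estimation.
#'
#' @param space a [parameter_space()].
#' @param omega number of grid points.
#' @return named numeric vector of per-parameter gaps (working scale).
#' @export
expected_grid_gap <- function(space, omega) {
  stopifnot(omega >= 1)
  stats::setNames((space$upper - space$lower) / omega^(1 / space_dim(space)),
                  space$names)
}

#' Priors over a parameter space
#'
#' Priors act on the working scale. `uniform_prior` is flat on the box;
#' `beta_box_prior` maps each coordinate affinely to `[0, 1]` and applies an
#' independent Beta(alpha, beta) density, which is how informative
#' generating/estimating priors (e.g. Beta(10, 10) or Beta(2, 10) per axis)
#' are expressed on a bounded space.
#'
#' @param space a [parameter_space()].
#' @param alpha,beta per-parameter Beta shape vectors (recycled).
#' @return a prior object: list with `kind`, `logpdf(theta)` (matrix in,
#'   vector out) and `sample(n)` (working-scale matrix out).
#' @export
uniform_prior <- function(space) {
  lv <- -sum(log(space$upper - space$lower))
  list(
    kind = "uniform",
    logpdf = function(theta) {
      m <- if (is.null(dim(theta))) matrix(theta, nrow = 1) else as.matrix(theta)
      ifelse(space_contains(space, m), lv, -Inf)
    },
    sample = function(n) {
      k <- space_dim(space)
      m <- matrix(stats::runif(n * k), n, k)
      sweep(sweep(m, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
    })
}

#' @rdname uniform_prior
#' @export
beta_box_prior <- function(space, alpha, beta) {
  k <- space_dim(space)
  alpha <- rep_len(alpha, k)
  beta <- rep_len(beta, k)
  rng <- space$upper - space$lower
  list(
    kind = sprintf("beta(%s;%s)", paste(alpha, collapse = ","),
                   paste(beta, collapse = ",")),
    logpdf = function(theta) {
      m <- if (is.null(dim(theta))) matrix(theta, nrow = 1) else as.matrix(theta)
      u <- sweep(sweep(m, 2, space$lower, `-`), 2, rng, `/`)
      lp <- numeric(nrow(m))
      for (j in seq_len(k))
        lp <- lp + stats::dbeta(u[, j], alpha[j], beta[j], log = TRUE) -
          log(rng[j])
      lp[!space_contains(space, m)] <- -Inf
      lp
    },
    sample = function(n) {
      m <- matrix(NA_real_, n, k)
      for (j in seq_len(k))
        m[, j] <- space$lower[j] + rng[j] * stats::rbeta(n, alpha[j], beta[j])
      m
    })
}

#' Point-mass check helper used for numerically validating built-in priors
#' @noRd
prior_integrates <- function(space, n = 2e5, seed = 1) {
  # plain Monte-Carlo integral of exp(logpdf) over the box
  with_seed(seed, {
    k <- space_dim(space)
    u <- matrix(stats::runif(n * k), n, k)
    m <- sweep(sweep(u, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
    vol <- prod(space$upper - space$lower)
    mean(exp(space$prior$logpdf(m))) * vol
  })
}
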