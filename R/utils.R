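`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed and an index
#'
#' Grid builds, test-set generation and per-cell study seeds all derive their
#' streams from a single master seed so that results are independent of
#' execution order and partial reruns are reproducible. The mixing is a small
#' multiplicative-congruential scramble carried out in double precision
#' (products stay below 2^53), reduced mod 2^31 - 1 so the result is always a
#' valid 32-bit seed for [set.seed()].
#'
#' @param master integer master seed.
#' @param index nonnegative integer index (e.g. grid row).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index = 0L) {
  m <- 2147483647 # 2^31 - 1
  x <- (abs(as.double(master)) + 1) %% m
  i <- (abs(as.double(index)) + 1) %% m
  # two rounds of x <- (a*x + b + c*i) mod m with distinct multipliers
  x <- (69069 * x + 1234567 + 2654435 * i) %% m
  x <- (3467255 * x + 362437 + 9576890 * i) %% m
  as.integer(x)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Weighted sample quantiles
#'
#' Quantiles of a weighted sample, continuous (type-7-like) rule: with equal
#' weights this reproduces `stats::quantile(x, probs, type = 7)` exactly.
#' Draw `i` (in increasing order of `x`) sits at its cumulative-mass midpoint
#' `m_i = C_{i-1} + w_i / 2`, rescaled so the extreme draws map to 0 and 1;
#' quantiles interpolate linearly between adjacent positions. Mass
#' concentrated on one draw collapses the quantiles onto that draw.
#'
#' @param x numeric values.
#' @param w nonnegative weights (normalized internally).
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of quantiles, named like [stats::quantile()].
#' @export
weighted_quantile <- function(x, w = NULL, probs = c(0.025, 0.975)) {
  stopifnot(length(x) >= 1, all(probs >= 0 & probs <= 1))
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  n <- length(x)
  if (n == 1L) {
    out <- rep(x, length(probs))
  } else {
    m <- cumsum(w) - w / 2
    denom <- m[n] - m[1]
    pos <- if (denom > 0) (m - m[1]) / denom else seq(0, 1, length.out = n)
    out <- stats::approx(pos, x, xout = probs, rule = 2, ties = "ordered")$y
  }
  names(out) <- paste0(format(100 * probs, trim = TRUE), "%")
  out
}

skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
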