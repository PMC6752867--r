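# Least-squares support vector machine regression (RBF kernel) and the local
# interpolator built from it. An LS-SVM solves the linear system
#   [ 0   1'        ] [b]   [0]
#   [ 1   K + I/gam ] [a] = [y]
# where K_ij = exp(-||x_i - x_j||^2 / (2 bw^2)); predictions are
# f(x) = sum_i a_i K(x, x_i) + b. Both the regularization gamma and the
# bandwidth are tuned by exact leave-one-out error on a 5x5 log grid
# (LOO residual e_i = a_i / (Ainv)_{i+1,i+1}).

.rbf_kernel <- function(X, Y, bw) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  exp(-pmax(d2, 0) / (2 * bw^2))
}

lssvm_fit1 <- function(X, y, gammas = 10^seq(-1, 7, length.out = 5),
                       bws = NULL) {
  n <- nrow(X)
  if (is.null(bws)) {
    # bandwidth candidates around the median pairwise distance
    d2 <- stats::dist(X)
    med <- stats::median(d2)
    if (!is.finite(med) || med <= 0) med <- 1
    bws <- med * 2^seq(-2, 2, length.out = 5)
  }
  best <- NULL
  for (bw in bws) {
    K <- .rbf_kernel(X, X, bw)
    for (gam in gammas) {
      A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(1 / gam, n)))
      Ainv <- tryCatch(solve(A), error = function(e) NULL)
      if (is.null(Ainv)) next
      sol <- Ainv %*% c(0, y)
      alpha <- sol[-1]
      loo <- alpha / diag(Ainv)[-1]
      err <- mean(loo^2)
      if (is.null(best) || err < best$loo) {
        best <- list(alpha = alpha, b = sol[1], bw = bw, gamma = gam,
                     loo = err)
      }
    }
  }
  if (is.null(best)) stop("LS-SVM fit failed: singular kernel system")
  best
}

lssvm_predict1 <- function(fit, X, Xnew) {
  drop(.rbf_kernel(Xnew, X, fit$bw) %*% fit$alpha) + fit$b
}

#' Fit a local surrogate mapping parameters to summary statistics
#'
#' Trains, per statistic, either a tuned RBF LS-SVM (`kind = "lssvm"`) or an
#' ordinary least squares linear model (`kind = "linear"`) on the
#' neighbourhood of a query point, on standardized working-scale parameters.
#' Predictions are clamped to the statistics' admissible ranges, and the
#' training box (per-parameter min/max of the neighbours) is recorded as the
#' region where the surrogate can be trusted.
#'
#' @param theta_nn `N x K` working-scale parameters of the neighbours.
#' @param stats_nn `N x R` matrix of their summary statistics.
#' @param kind `"lssvm"` or `"linear"`.
#' @param clamp `2 x R` matrix of admissible statistic ranges (rows min,max).
#' @return a `local_interpolator` with elements `predict(theta)` (matrix in,
#'   matrix out, clamped), `training_box`, `kind`.
#' @export
fit_local_interpolator <- function(theta_nn, stats_nn,
                                   kind = c("lssvm", "linear"),
                                   clamp = NULL) {
  kind <- match.arg(kind)
  theta_nn <- as.matrix(theta_nn)
  stats_nn <- as.matrix(stats_nn)
  N <- nrow(theta_nn)
  K <- ncol(theta_nn)
  R <- ncol(stats_nn)
  stopifnot(nrow(stats_nn) == N, N >= K + 2)
  if (is.null(clamp)) clamp <- rbind(rep(-Inf, R), rep(Inf, R))
  ctr <- colMeans(theta_nn)
  sdv <- apply(theta_nn, 2, stats::sd)
  sdv[sdv <= 0] <- 1
  Z <- sweep(sweep(theta_nn, 2, ctr), 2, sdv, `/`)
  ysc <- apply(stats_nn, 2, stats::sd)
  ysc[ysc <= 0 | !is.finite(ysc)] <- 1
  yc <- colMeans(stats_nn)
  fits <- vector("list", R)
  if (kind == "lssvm") {
    for (r in seq_len(R))
      fits[[r]] <- lssvm_fit1(Z, (stats_nn[, r] - yc[r]) / ysc[r])
  } else {
    X <- cbind(1, Z)
    qrX <- qr(X)
    if (qrX$rank < K + 1)
      stop("rank-deficient design for linear interpolator")
    coef <- qr.coef(qrX, sweep(sweep(stats_nn, 2, yc), 2, ysc, `/`))
    for (r in seq_len(R)) fits[[r]] <- coef[, r]
  }
  obj <- list(
    kind = kind, center = ctr, scale = sdv, y_center = yc, y_scale = ysc,
    Z = Z, fits = fits, clamp = clamp,
    training_box = apply(theta_nn, 2, range))
  obj$predict <- function(theta) {
    m <- if (is.null(dim(theta))) matrix(theta, nrow = 1) else as.matrix(theta)
    Znew <- sweep(sweep(m, 2, ctr), 2, sdv, `/`)
    out <- matrix(NA_real_, nrow(m), R)
    for (r in seq_len(R)) {
      p <- if (kind == "lssvm") lssvm_predict1(fits[[r]], Z, Znew)
           else drop(cbind(1, Znew) %*% fits[[r]])
      out[, r] <- p * ysc[r] + yc[r]
    }
    colnames(out) <- colnames(stats_nn)
    clamp_stats(out, clamp)
  }
  class(obj) <- "local_interpolator"
  obj
}

#' @export
print.local_interpolator <- function(x, ...) {
  cat("local_interpolator:", x$kind, "-", length(x$fits), "statistics,",
      nrow(x$Z), "training points\n")
  invisible(x)
}
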