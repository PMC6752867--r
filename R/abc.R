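#' Grid posterior mean under the prepaid synthetic likelihood (SLPMGrid)
#'
#' The grid was laid out under the uniform prior, so normalized synthetic
#' likelihoods over grid rows approximate the posterior; a non-uniform prior
#' multiplies the weights by the prior ratio. The point estimate is the
#' weighted posterior mean on the working scale, exported on the natural
#' scale. Log-weights are recentred by their maximum before exponentiating,
#' so finite inputs never underflow to an all-zero weight vector.
#'
#' @inheritParams estimate_slml_grid
#' @param prior optional prior object (weights multiplied by its density).
#' @return list: `estimate` (a `prepaid_estimate`, method `"SLPMGrid"`) and
#'   `posterior` (a `posterior_sample` over all grid rows).
#' @export
posterior_mean_grid <- function(grid, s_obs, t_obs, prior = NULL) {
  lw <- grid_loglik(grid, s_obs, t_obs)
  if (!is.null(prior)) lw <- lw + prior$logpdf(grid$theta)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  theta_hat_w <- colSums(grid$theta * w)
  post <- posterior_sample(grid$theta, w, method = "SLPMGrid",
                           source = seq_len(nrow(grid$theta)))
  est <- .new_estimate(grid$meta$spec$space, theta_hat_w, "SLPMGrid",
                       max(lw), neighbors = which.max(lw))
  list(estimate = est, posterior = post)
}

#' Weighted posterior sample container
#'
#' @param draws `n x K` working-scale parameter draws.
#' @param weights nonnegative weights (normalized internally).
#' @param method method tag.
#' @param source per-draw provenance (grid row or cluster id).
#' @return a `posterior_sample`.
#' @export
posterior_sample <- function(draws, weights = NULL, method = "",
                             source = NULL) {
  draws <- as.matrix(draws)
  if (is.null(weights)) weights <- rep(1, nrow(draws))
  stopifnot(length(weights) == nrow(draws), all(weights >= 0),
            sum(weights) > 0)
  structure(list(draws = draws, weights = weights / sum(weights),
                 method = method, source = source),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("posterior_sample (%s): %d draws x %d parameters\n",
              x$method, nrow(x$draws), ncol(x$draws)))
  invisible(x)
}

#' Smallest grid subset with 99.9% posterior coverage
#'
#' Sorts log-weights in decreasing order and accumulates normalized mass,
#' stopping at the first index where the cumulative mass reaches 0.999. The
#' result is the smallest set whose mass is at least the target (always at
#' least one element).
#'
#' @param log_weights finite log posterior weights over grid rows.
#' @param mass target cumulative mass.
#' @return list: `indices` (grid rows, decreasing weight) and `Q` (size).
#' @export
select_coverage_set <- function(log_weights, mass = 0.999) {
  stopifnot(length(log_weights) >= 1)
  w <- exp(log_weights - max(log_weights))
  w <- w / sum(w)
  o <- order(-w, seq_along(w))
  cum <- cumsum(w[o])
  Q <- which(cum >= mass)[1]
  if (is.na(Q)) Q <- length(w)
  list(indices = o[seq_len(Q)], Q = Q)
}

#' Grid-bank approximate Bayesian computation (ABCPMGrid)
#'
#' ABC over the prepaid sample bank: restrict to the 99.9% coverage set `S`
#' of grid rows ([select_coverage_set()] on the synthetic likelihoods), pool
#' the covariance `W_Q` of all banked statistics of `S`, and keep the
#' `n_keep` bank samples with the smallest Mahalanobis distance
#' `(s - s_obs)' W_Q^{-1} (s - s_obs)`. Their source parameters with equal
#' weights form the posterior; the estimate is the posterior mean. When
#' `t_obs` is not a stored bank length, the bank nearest in log scale is
#' used and the parameter draws are rescaled about their mean so the
#' posterior covariance gains the factor `t_prepaid / t_obs`.
#'
#' @inheritParams estimate_slml_grid
#' @param n_keep posterior sample size.
#' @return list: `estimate` (method `"ABCPMGrid"`), `posterior`, and
#'   `details` (coverage set, bank length, kept sample index).
#' @export
abc_posterior_grid <- function(grid, s_obs, t_obs, n_keep = 1000) {
  lens <- as.numeric(names(grid$bank))
  lens <- lens[!vapply(grid$bank, is.null, logical(1))]
  if (length(lens) == 0) stop("grid has no sample bank")
  tb <- lens[which.min(abs(log10(lens) - log10(t_obs)))]
  lw <- grid_loglik(grid, s_obs, t_obs)
  cov_set <- select_coverage_set(lw)
  S <- cov_set$indices
  bank <- grid$bank[[as.character(tb)]]
  M <- dim(bank)[2]
  R <- dim(bank)[3]
  # Q*M x R matrix of pooled bank statistics for the coverage set
  X <- matrix(aperm(bank[S, , , drop = FALSE], c(2, 1, 3)),
              nrow = length(S) * M, ncol = R)
  src <- rep(S, each = M)
  WQ <- stats::cov(X)
  WQ <- WQ + diag(1e-8 * mean(diag(WQ)) + 1e-300, R)
  ch <- chol(WQ)
  z <- backsolve(ch, t(X) - as.numeric(s_obs), transpose = TRUE)
  eps <- colSums(z^2)
  if (length(eps) < n_keep) {
    warning("coverage set bank smaller than n_keep; keeping all samples")
    keep <- order(eps, seq_along(eps))
  } else {
    keep <- order(eps, seq_along(eps))[seq_len(n_keep)]
  }
  draws <- grid$theta[src[keep], , drop = FALSE]
  # affine rescale about the mean for T mismatch (mean preserved exactly)
  if (tb != t_obs) {
    ctr <- colMeans(draws)
    draws <- sweep(sweep(draws, 2, ctr), 1, sqrt(tb / t_obs), `*`)
    draws <- sweep(draws, 2, ctr, `+`)
  }
  post <- posterior_sample(draws, method = "ABCPMGrid", source = src[keep])
  theta_hat_w <- colMeans(draws)
  est <- .new_estimate(grid$meta$spec$space, theta_hat_w, "ABCPMGrid",
                       max(lw), neighbors = S[seq_len(min(5, length(S)))])
  list(estimate = est, posterior = post,
       details = list(coverage = cov_set, t_bank = tb, kept_eps = eps[keep],
                      kept_source = src[keep], WQ = WQ))
}

# ---------------------------------------------------------------------------
# Minimum-volume enclosing ellipsoid (Khachiyan's algorithm) with a bounding
# box fallback for degenerate point sets. Region objects support uniform
# sampling, volume, and a shape matrix.
# ---------------------------------------------------------------------------

#' Minimum-volume enclosing ellipsoid of a point set
#'
#' Khachiyan's barycentric coordinate-ascent algorithm (tolerance `tol`):
#' returns the ellipse `{x : (x - c)' A (x - c) <= 1}` enclosing all rows of
#' `P`. Degenerate sets (rank-deficient, too few points) fall back to the
#' axis-aligned bounding box, reported with `kind = "box"`.
#'
#' @param P `n x K` point matrix.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return a region object: list with `kind` (`"ellipse"`/`"box"`),
#'   `center`, `shape` (`A`, ellipse only), `lower`/`upper` (box only),
#'   `volume`, and `sample(n)`.
#' @export
mvee <- function(P, tol = 1e-5, max_iter = 1000) {
  P <- as.matrix(P)
  n <- nrow(P)
  K <- ncol(P)
  box <- function() {
    lo <- apply(P, 2, min)
    hi <- apply(P, 2, max)
    wid <- pmax(hi - lo, 1e-12)
    list(kind = "box", center = (lo + hi) / 2, lower = lo, upper = hi,
         volume = prod(wid),
         sample = function(m) {
           u <- matrix(stats::runif(m * K), m, K)
           sweep(sweep(u, 2, wid, `*`), 2, lo, `+`)
         })
  }
  if (n <= K || qr(sweep(P, 2, colMeans(P)))$rank < K) return(box())
  Q <- t(cbind(P, 1)) # (K+1) x n
  u <- rep(1 / n, n)
  err <- 1
  it <- 0
  while (err > tol && it < max_iter) {
    it <- it + 1
    X <- Q %*% (u * t(Q))
    Xi <- tryCatch(solve(X), error = function(e) NULL)
    if (is.null(Xi)) return(box())
    Md <- colSums(Q * (Xi %*% Q))
    j <- which.max(Md)
    step <- (Md[j] - K - 1) / ((K + 1) * (Md[j] - 1))
    nu <- (1 - step) * u
    nu[j] <- nu[j] + step
    err <- sqrt(sum((nu - u)^2))
    u <- nu
  }
  ctr <- drop(crossprod(P, u))
  Cov <- crossprod(P, u * P) - tcrossprod(ctr)
  A <- tryCatch(solve(Cov) / K, error = function(e) NULL)
  if (is.null(A)) return(box())
  A <- (A + t(A)) / 2
  # inflate marginally so every defining point is inside despite the
  # finite-tolerance stop of the iteration
  D <- sweep(P, 2, ctr)
  maxq <- max(rowSums((D %*% A) * D))
  if (is.finite(maxq) && maxq > 0) A <- A / (maxq * (1 + 1e-9))
  E <- tryCatch(chol(solve(A)), error = function(e) NULL)
  if (is.null(E)) return(box())
  unit_ball <- pi^(K / 2) / gamma(K / 2 + 1)
  vol <- unit_ball / sqrt(det(A))
  list(kind = "ellipse", center = ctr, shape = A, volume = vol,
       sample = function(m) {
         z <- matrix(stats::rnorm(m * K), m, K)
         z <- z / sqrt(rowSums(z^2))
         r <- stats::runif(m)^(1 / K)
         sweep((r * z) %*% E, 2, ctr, `+`)
       })
}

region_contains <- function(reg, x) {
  if (reg$kind == "box") {
    all(x >= reg$lower - 1e-12) && all(x <= reg$upper + 1e-12)
  } else {
    d <- x - reg$center
    drop(t(d) %*% reg$shape %*% d) <= 1 + 1e-6
  }
}

# cut a Ward dendrogram at the shallowest level where every cluster has at
# most max_size members
.cluster_max_size <- function(theta, max_size = 50) {
  n <- nrow(theta)
  if (n <= max_size) return(rep(1L, n))
  hc <- stats::hclust(stats::dist(theta), method = "ward.D2")
  for (k in 2:n) {
    cl <- stats::cutree(hc, k = k)
    if (max(tabulate(cl)) <= max_size) return(cl)
  }
  seq_len(n)
}

#' Surrogate-refined grid ABC (ABCPMSVM)
#'
#' Refines [abc_posterior_grid()] by interpolating between grid rows:
#' (a) take the `n_neighbors` grid rows contributing the most kept bank
#' samples (padded by smallest per-row minimum distance); (b) Ward-cluster
#' them (working scale) until every cluster has at most 50 rows, padding
#' small clusters to at least 20 rows with the nearest grid rows; (c) per
#' cluster, fit an LS-SVM surrogate `theta -> mu` and the minimum-volume
#' enclosing ellipse; (d) iteratively sample 1000 parameters uniformly in
#' the ellipse, predict their statistics, translate the nearest originating
#' row's bank by the predicted shift, score the Mahalanobis distances, keep
#' the 5000 best parameter draws and refit the ellipse, until the worst kept
#' distance stops decreasing (relative improvement below `stop_tol`, cap
#' `max_iter`); (e) pool clusters, keep the global `n_keep` best samples,
#' weight each draw by its originating cluster's ellipse volume (the uniform
#' prior over each sampled region), and report the weighted posterior mean.
#'
#' @inheritParams abc_posterior_grid
#' @param n_neighbors rows retained for surrogate training.
#' @param n_sample parameters sampled per ellipse per iteration.
#' @param n_trim parameter draws kept per cluster per iteration.
#' @param stop_tol relative-improvement stopping threshold for the worst
#'   kept distance.
#' @param max_iter iteration cap per cluster.
#' @return list: `estimate` (method `"ABCPMSVM"`), `posterior` (volume-
#'   weighted draws), `details` (clusters, ellipse volumes, iterations).
#' @export
abc_posterior_svm <- function(grid, s_obs, t_obs, n_neighbors = 100,
                              n_keep = 1000, n_sample = 1000, n_trim = 5000,
                              stop_tol = 1e-3, max_iter = 50) {
  base <- abc_posterior_grid(grid, s_obs, t_obs, n_keep = n_keep)
  tb <- base$details$t_bank
  bank <- grid$bank[[as.character(tb)]]
  M <- dim(bank)[2]
  R <- dim(bank)[3]
  WQ <- base$details$WQ
  ch <- chol(WQ)
  s_obs_n <- as.numeric(s_obs)
  space <- grid$meta$spec$space
  # (a) rows by kept-sample count, padded by per-row minimum distance
  cnt <- table(base$details$kept_source)
  rows <- as.integer(names(sort(cnt, decreasing = TRUE)))
  if (length(rows) < n_neighbors) {
    S <- base$details$coverage$indices
    others <- setdiff(S, rows)
    if (length(others) > 0) {
      mineps <- vapply(others, function(p) {
        z <- backsolve(ch, t(matrix(bank[p, , ], M, R)) - s_obs_n,
                       transpose = TRUE)
        min(colSums(z^2))
      }, numeric(1))
      rows <- c(rows, others[order(mineps)])
    }
  }
  rows <- rows[seq_len(min(n_neighbors, length(rows)))]
  # (b) clustering and padding
  cl <- .cluster_max_size(grid$theta[rows, , drop = FALSE], max_size = 50)
  clusters <- split(rows, cl)
  rngs <- pmax(apply(grid$theta, 2, function(v) diff(range(v))), 1e-12)
  Zall <- sweep(grid$theta, 2, rngs, `/`)
  clusters <- lapply(clusters, function(idx) {
    if (length(idx) >= 20) return(idx)
    ctr <- colMeans(Zall[idx, , drop = FALSE])
    d2 <- rowSums(sweep(Zall, 2, ctr)^2)
    d2[idx] <- Inf
    c(idx, order(d2)[seq_len(20 - length(idx))])
  })
  # (c)-(d) per-cluster refinement
  all_draws <- NULL
  all_eps <- NULL
  all_clid <- NULL
  volumes <- numeric(length(clusters))
  iters <- integer(length(clusters))
  worst_trace <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    idx <- clusters[[ci]]
    interp <- fit_local_interpolator(grid$theta[idx, , drop = FALSE],
                                     grid$mu[idx, , drop = FALSE],
                                     kind = "lssvm",
                                     clamp = grid$meta$stat_range)
    reg <- mvee(grid$theta[idx, , drop = FALSE])
    kept_theta <- NULL # one row per kept (parameter, bank-sample) pair
    kept_eps <- NULL
    worst_prev <- Inf
    it <- 0
    repeat {
      it <- it + 1
      th <- reg$sample(n_sample)
      # keep proposals inside the parameter box
      inside <- space_contains(space, th)
      if (!any(inside)) break
      th <- th[inside, , drop = FALSE]
      pred <- interp$predict(th)
      # nearest originating row per proposal (working-scale distance)
      Zc <- sweep(grid$theta[idx, , drop = FALSE], 2, rngs, `/`)
      Zt <- sweep(th, 2, rngs, `/`)
      d2 <- outer(rowSums(Zt^2), rowSums(Zc^2), `+`) - 2 * tcrossprod(Zt, Zc)
      nearest <- idx[max.col(-d2, ties.method = "first")]
      # translate the nearest row's bank by the predicted statistic shift;
      # every translated sample is one candidate (parameter, sample) pair
      eps_mat <- matrix(NA_real_, nrow(th), M)
      for (j in seq_len(nrow(th))) {
        p <- nearest[j]
        d <- pred[j, ] - grid$mu[p, ]
        Xs <- sweep(matrix(bank[p, , ], M, R), 2, d, `+`)
        z <- backsolve(ch, t(Xs) - s_obs_n, transpose = TRUE)
        eps_mat[j, ] <- colSums(z^2)
      }
      kept_theta <- rbind(kept_theta, th[rep(seq_len(nrow(th)), times = M),
                                         , drop = FALSE])
      kept_eps <- c(kept_eps, as.numeric(eps_mat))
      o <- order(kept_eps, seq_along(kept_eps))
      o <- o[seq_len(min(n_trim, length(o)))]
      kept_theta <- kept_theta[o, , drop = FALSE]
      kept_eps <- kept_eps[o]
      # pool always contains the previous kept pairs, so the worst kept
      # distance is non-increasing across iterations by construction
      worst <- max(kept_eps)
      worst_trace[[ci]] <- c(worst_trace[[ci]], worst)
      reg <- mvee(unique(kept_theta))
      if (it >= max_iter ||
          (is.finite(worst_prev) &&
           (worst_prev - worst) < stop_tol * abs(worst_prev))) break
      worst_prev <- worst
    }
    iters[ci] <- it
    volumes[ci] <- reg$volume
    if (!is.null(kept_theta)) {
      all_draws <- rbind(all_draws, kept_theta)
      all_eps <- c(all_eps, kept_eps)
      all_clid <- c(all_clid, rep(ci, nrow(kept_theta)))
    }
  }
  if (is.null(all_draws)) return(base) # every cluster degenerate: fall back
  o <- order(all_eps, seq_along(all_eps))
  o <- o[seq_len(min(n_keep, length(o)))]
  draws <- all_draws[o, , drop = FALSE]
  clid <- all_clid[o]
  w <- volumes[clid]
  if (all(w <= 0)) w <- rep(1, length(w))
  post <- posterior_sample(draws, w, method = "ABCPMSVM", source = clid)
  theta_hat_w <- colSums(draws * post$weights)
  est <- .new_estimate(space, theta_hat_w, "ABCPMSVM",
                       -min(all_eps), neighbors = rows)
  list(estimate = est, posterior = post,
       details = list(clusters = clusters, volumes = volumes,
                      iterations = iters, worst_trace = worst_trace,
                      t_bank = tb))
}

#' Posterior credible intervals from a weighted sample
#'
#' Weighted quantiles at `(1 - level)/2` and `1 - (1 - level)/2` per
#' parameter (see [weighted_quantile()]), on the working scale of the
#' draws.
#'
#' @param sample a [posterior_sample()].
#' @param level credible level.
#' @return `K x 2` matrix with columns `lower`, `upper`.
#' @export
posterior_interval <- function(sample, level = 0.95) {
  stopifnot(inherits(sample, "posterior_sample"), nrow(sample$draws) >= 1)
  alpha <- (1 - level) / 2
  out <- t(apply(sample$draws, 2, function(v)
    weighted_quantile(v, sample$weights, probs = c(alpha, 1 - alpha))))
  colnames(out) <- c("lower", "upper")
  out
}
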