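#' Synthetic log-likelihood
#'
#' Gaussian likelihood on summary statistics:
#' `l_s = -(1/2) (s - mu)' Sigma^{-1} (s - mu) - (1/2) log|Sigma|`,
#' without the `-(R/2) log(2*pi)` constant (it cancels in every comparison
#' the package makes). The covariance is ridged with `eps * mean(diag)`
#' before inversion because near-singular statistic sets occur at extreme
#' parameters.
#'
#' @param s_obs observed statistics (length `R`).
#' @param mu simulated statistic mean (length `R`).
#' @param sigma `R x R` statistic covariance.
#' @param eps relative diagonal regularization.
#' @return a single number.
#' @export
synthetic_loglik <- function(s_obs, mu, sigma, eps = 1e-8) {
  s_obs <- as.numeric(s_obs)
  mu <- as.numeric(mu)
  sigma <- as.matrix(sigma)
  if (length(s_obs) != length(mu) || any(dim(sigma) != length(mu)))
    stop("dimension mismatch between statistics and covariance")
  sigma <- sigma + diag(eps * mean(diag(sigma)) + 1e-300, nrow(sigma))
  ch <- chol(sigma)
  z <- backsolve(ch, s_obs - mu, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(ch)))
}

.new_estimate <- function(space, theta_working, method, objective,
                          neighbors = integer(), ci = NULL,
                          diagnostics = list()) {
  structure(list(theta_hat = to_natural(space, theta_working),
                 theta_working = stats::setNames(as.numeric(theta_working),
                                                 space$names),
                 method = method, objective_value = objective,
                 neighbor_indices = neighbors, ci = ci,
                 diagnostics = diagnostics),
            class = "prepaid_estimate")
}

#' @export
print.prepaid_estimate <- function(x, ...) {
  cat(sprintf("prepaid_estimate (%s)\n", x$method))
  print(signif(x$theta_hat, 5))
  cat("  objective:", format(x$objective_value), "\n")
  if (!is.null(x$ci)) {
    cat(sprintf("  %g%% CI:\n", 100 * x$ci$level))
    print(signif(x$ci$interval, 5))
  }
  invisible(x)
}

#' Nearest-neighbour synthetic-likelihood estimate (SLMLGrid)
#'
#' Evaluates the prepaid synthetic log-likelihood at every grid row (stored
#' covariance nearest to `t_obs` in log scale, rescaled by
#' [scale_covariance()]) and returns the arg-max row. Ties break to the
#' lowest row index. The accuracy floor of this estimator is the grid gap
#' (see [expected_grid_gap()]); for short series the sampling error dwarfs
#' the gap and nearest neighbour is already adequate.
#'
#' @param grid a `prepaid_grid`.
#' @param s_obs observed [summary_vector()].
#' @param t_obs observed series length.
#' @param prior optional prior object; when supplied, the arg-max is over
#'   log-prior + log-likelihood (the MAP variant).
#' @return a `prepaid_estimate`.
#' @export
estimate_slml_grid <- function(grid, s_obs, t_obs, prior = NULL) {
  if (nrow(grid$theta) == 0) stop("empty grid")
  ll <- grid_loglik(grid, s_obs, t_obs)
  obj <- ll
  method <- "SLMLGrid"
  if (!is.null(prior)) {
    lp <- prior$logpdf(grid$theta)
    if (all(!is.finite(lp))) stop("prior is zero at every grid row")
    obj <- ll + lp
    method <- "SLMAPGrid"
  }
  j <- which.max(obj) # first maximum = lowest index on ties
  .new_estimate(grid$meta$spec$space, grid$theta[j, ], method, obj[j],
                neighbors = j)
}

#' Maximum a posteriori over the grid (SLMAPGrid)
#'
#' [estimate_slml_grid()] with a prior: arg-max of log-prior plus synthetic
#' log-likelihood over grid rows. With a uniform prior this reduces exactly
#' to the maximum-likelihood grid estimate.
#'
#' @inheritParams estimate_slml_grid
#' @param prior a prior object (e.g. [beta_box_prior()]).
#' @return a `prepaid_estimate`.
#' @export
estimate_map <- function(grid, s_obs, t_obs, prior) {
  estimate_slml_grid(grid, s_obs, t_obs, prior = prior)
}

#' Select the nearest grid neighbours of an observed statistic vector
#'
#' Indices of the `n` grid rows with the largest synthetic log-likelihood,
#' in descending order (ties by row index).
#'
#' @inheritParams estimate_slml_grid
#' @param n neighbourhood size (default 100).
#' @return integer vector of length `n`.
#' @export
select_neighbors <- function(grid, s_obs, t_obs, n = 100) {
  om <- nrow(grid$theta)
  stopifnot(n >= 1, n <= om)
  ll <- grid_loglik(grid, s_obs, t_obs)
  order(-ll, seq_len(om))[seq_len(n)]
}

#' Interpolated synthetic-likelihood estimate (SLMLSVM / SLMLLin)
#'
#' Fits a local surrogate `f: theta -> s` on the `n_neighbors` nearest grid
#' rows (per-statistic LS-SVM, or linear regression for the `"linear"`
#' kind), then maximizes the interpolated synthetic log-likelihood
#' `-(1/2)(s_obs - f(theta))' Sigma^{-1} (s_obs - f(theta)) - (1/2)log|Sigma|`
#' with differential evolution, bounded by the neighbours' per-parameter
#' min/max. `Sigma` is the nearest neighbour's stored covariance rescaled to
#' `t_obs`. Interpolation pays off when `t_obs` is large and the grid gap -
#' not sampling noise - limits accuracy.
#'
#' @inheritParams estimate_slml_grid
#' @param kind surrogate kind: `"lssvm"` (default) or `"linear"`.
#' @param n_neighbors neighbourhood size.
#' @param de_control control list passed to [de_optimize()].
#' @return a `prepaid_estimate`; `diagnostics$converged` flags optimizer
#'   convergence.
#' @export
estimate_slml_svm <- function(grid, s_obs, t_obs, kind = c("lssvm", "linear"),
                              n_neighbors = 100, de_control = list()) {
  kind <- match.arg(kind)
  nn <- select_neighbors(grid, s_obs, t_obs, n = min(n_neighbors,
                                                     nrow(grid$theta)))
  interp <- fit_local_interpolator(grid$theta[nn, , drop = FALSE],
                                   grid$mu[nn, , drop = FALSE],
                                   kind = kind,
                                   clamp = grid$meta$stat_range)
  tp <- nearest_t_prepaid(grid, t_obs)
  R <- ncol(grid$mu)
  sig <- scale_covariance(matrix(grid$sigma[[as.character(tp)]][nn[1], , ],
                                 R, R), tp, t_obs)
  sig <- sig + diag(1e-8 * mean(diag(sig)) + 1e-300, R)
  ch <- chol(sig)
  logdet <- 2 * sum(log(diag(ch)))
  s_obs_n <- as.numeric(s_obs)
  negll <- function(theta) {
    pred <- interp$predict(theta)
    d <- sweep(pred, 2, s_obs_n)
    z <- backsolve(ch, t(d), transpose = TRUE)
    0.5 * colSums(z^2) + 0.5 * logdet
  }
  lo <- interp$training_box[1, ]
  hi <- interp$training_box[2, ]
  # seed part of the population with the best neighbours: the returned
  # objective can then never fall below the best grid row's
  de_control$init <- de_control$init %||% grid$theta[nn, , drop = FALSE]
  opt <- de_optimize(negll, lo, hi, control = de_control)
  if (!opt$converged)
    warning("differential evolution did not converge; returning best found")
  .new_estimate(grid$meta$spec$space, opt$par,
                if (kind == "lssvm") "SLMLSVM" else "SLMLLin",
                -opt$value, neighbors = nn,
                diagnostics = list(converged = opt$converged,
                                   interpolator = interp,
                                   generations = opt$generations))
}

#' Cross-condition constraint specification
#'
#' @param shared names of parameters constrained to be equal across
#'   conditions.
#' @param sigma_prior width of the product-normal equality penalty on the
#'   working scale (smaller = stiffer; see [tune_sigma_prior()]).
#' @param pool_size per-condition candidate pool (top grid rows by synthetic
#'   likelihood).
#' @param n_conditions expected number of conditions (optional; validated
#'   against the data lists when estimating).
#' @return a `constraint_spec` list.
#' @export
constraint_spec <- function(shared, sigma_prior, pool_size = 200,
                            n_conditions = NULL) {
  stopifnot(length(shared) >= 1, sigma_prior > 0, pool_size >= 1,
            is.null(n_conditions) || n_conditions >= 2)
  structure(list(shared = shared, sigma_prior = sigma_prior,
                 pool_size = as.integer(pool_size),
                 n_conditions = n_conditions),
            class = "constraint_spec")
}

.constraint_logpenalty <- function(theta_list, shared_idx, sigma_prior) {
  # product over shared parameters and conditions of N((theta_c - mean)/sp),
  # unnormalized (argmax-invariant), on the working scale
  lp <- 0
  for (j in shared_idx) {
    v <- vapply(theta_list, function(th) th[j], numeric(1))
    lp <- lp - 0.5 * sum(((v - mean(v)) / sigma_prior)^2)
  }
  lp
}

#' Constrained estimation across experimental conditions
#'
#' For `C` independent conditions sharing some parameters (e.g. equal growth
#' rate and process noise, condition-specific scaling), the experiment
#' likelihood is the product of per-condition synthetic likelihoods, and the
#' equality constraint enters as a product-normal prior of width
#' `sigma_prior` on the working scale. Three steps: (1) per-condition
#' candidate pools of the top `pool_size` grid rows; (2) maximize the
#' penalized joint objective over pool combinations (exhaustive for two
#' conditions, coordinate ascent otherwise); (3) replace every shared
#' parameter by its cross-condition mean so the constraint holds exactly.
#'
#' @param grid a `prepaid_grid`.
#' @param s_obs_list list of per-condition observed [summary_vector()]s.
#' @param t_obs_list per-condition observed lengths (recycled).
#' @param constraint a [constraint_spec()].
#' @return list of per-condition `prepaid_estimate`s (method
#'   `"constrained"`); attribute `"joint_objective"` holds the attained
#'   penalized objective.
#' @export
estimate_constrained <- function(grid, s_obs_list, t_obs_list, constraint) {
  C <- length(s_obs_list)
  stopifnot(C >= 2, inherits(constraint, "constraint_spec"))
  if (!is.null(constraint$n_conditions) && constraint$n_conditions != C)
    stop("constraint expects ", constraint$n_conditions,
         " conditions, got ", C)
  t_obs_list <- rep_len(t_obs_list, C)
  space <- grid$meta$spec$space
  shared_idx <- match(constraint$shared, space$names)
  if (anyNA(shared_idx)) stop("unknown shared parameter name")
  np <- min(constraint$pool_size, nrow(grid$theta))
  ll <- pools <- vector("list", C)
  for (cc in seq_len(C)) {
    l <- grid_loglik(grid, s_obs_list[[cc]], t_obs_list[[cc]])
    pools[[cc]] <- order(-l, seq_along(l))[seq_len(np)]
    if (length(pools[[cc]]) == 0) stop("empty candidate pool")
    ll[[cc]] <- l[pools[[cc]]]
  }
  sp <- constraint$sigma_prior
  if (C == 2) {
    th1 <- grid$theta[pools[[1]], , drop = FALSE]
    th2 <- grid$theta[pools[[2]], , drop = FALSE]
    pen <- matrix(0, np, np)
    for (j in shared_idx) {
      d <- outer(th1[, j], th2[, j], `-`)
      pen <- pen - 0.25 * (d / sp)^2 # (x1-m)^2+(x2-m)^2 = (x1-x2)^2/2
    }
    tot <- outer(ll[[1]], ll[[2]], `+`) + pen
    ij <- arrayInd(which.max(tot), dim(tot))
    pick <- c(pools[[1]][ij[1]], pools[[2]][ij[2]])
    best_obj <- tot[ij]
  } else {
    pick <- vapply(seq_len(C), function(cc)
      pools[[cc]][which.max(ll[[cc]])], integer(1))
    repeat {
      changed <- FALSE
      for (cc in seq_len(C)) {
        others <- lapply(setdiff(seq_len(C), cc), function(o)
          grid$theta[pick[o], ])
        cand <- pools[[cc]]
        sc <- vapply(seq_along(cand), function(i) {
          ths <- c(others, list(grid$theta[cand[i], ]))
          ll[[cc]][i] + .constraint_logpenalty(ths, shared_idx, sp)
        }, numeric(1))
        new <- cand[which.max(sc)]
        if (new != pick[cc]) {
          pick[cc] <- new
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    best_obj <- sum(vapply(seq_len(C), function(cc)
      grid_loglik(grid, s_obs_list[[cc]], t_obs_list[[cc]])[pick[cc]],
      numeric(1))) +
      .constraint_logpenalty(lapply(pick, function(p) grid$theta[p, ]),
                             shared_idx, sp)
  }
  th <- grid$theta[pick, , drop = FALSE]
  for (j in shared_idx) th[, j] <- mean(th[, j]) # exact equality
  out <- lapply(seq_len(C), function(cc)
    .new_estimate(space, th[cc, ], "constrained", best_obj,
                  neighbors = pick[cc],
                  diagnostics = list(sigma_prior = sp)))
  attr(out, "joint_objective") <- best_obj
  out
}

#' Tune the constraint penalty width by simulated recovery
#'
#' Simulates `n_sim` constraint-satisfying multi-condition test sets from the
#' grid's space, estimates each with [estimate_constrained()] under every
#' candidate `sigma_prior`, and returns the candidate minimizing the summed
#' range-standardized RMSE (working scale). A near-zero width collapses all
#' conditions onto a single grid row (so even unconstrained parameters are
#' forced equal); candidates whose fits collapse in more than half of the
#' simulations are discarded before the minimum is taken.
#'
#' @param grid a `prepaid_grid`.
#' @param model the matching `prepaid_model`.
#' @param constraint a [constraint_spec()] (its `sigma_prior` is ignored).
#' @param candidates numeric vector of candidate widths (`>= 2` values
#'   unless there is only one, which is returned unchanged).
#' @param n_sim simulated test sets.
#' @param t_obs observed length per condition.
#' @param n_conditions number of conditions.
#' @param seed master seed (deterministic selection).
#' @return the selected width; attribute `"scores"` holds per-candidate
#'   summed standardized RMSE.
#' @export
tune_sigma_prior <- function(grid, model, constraint, candidates,
                             n_sim = 20, t_obs = 100, n_conditions = 2,
                             seed = 1) {
  if (length(candidates) == 1) return(candidates)
  space <- grid$meta$spec$space
  K <- space_dim(space)
  shared_idx <- match(constraint$shared, space$names)
  rng <- space$upper - space$lower
  # simulate constraint-satisfying truths and their observed statistics
  truths <- vector("list", n_sim)
  stats <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    th <- with_seed(derive_seed(seed, i), {
      m <- space$prior$sample(n_conditions)
      for (j in shared_idx) m[, j] <- m[1, j]
      m
    })
    truths[[i]] <- th
    stats[[i]] <- lapply(seq_len(n_conditions), function(cc) {
      nat <- to_natural(space, th[cc, ])
      with_seed(derive_seed(seed, i * 1000L + cc),
                model$summarize(model$simulate_data(nat, t_obs)))
    })
  }
  scores <- collapsed <- numeric(length(candidates))
  for (k in seq_along(candidates)) {
    cs <- constraint_spec(constraint$shared, candidates[k],
                          constraint$pool_size)
    err2 <- matrix(0, n_sim, K)
    ncol_collapse <- 0
    for (i in seq_len(n_sim)) {
      est <- estimate_constrained(grid, stats[[i]], t_obs, cs)
      th_hat <- t(vapply(est, function(e) e$theta_working, numeric(K)))
      err2[i, ] <- colMeans((th_hat - truths[[i]])^2)
      free_idx <- setdiff(seq_len(K), shared_idx)
      if (length(free_idx) > 0 &&
          all(apply(th_hat[, free_idx, drop = FALSE], 2,
                    function(v) max(v) - min(v)) == 0))
        ncol_collapse <- ncol_collapse + 1
    }
    rmse <- sqrt(colMeans(err2)) / rng
    scores[k] <- sum(rmse)
    collapsed[k] <- ncol_collapse / n_sim
  }
  ok <- collapsed <= 0.5
  if (!any(ok)) ok <- rep(TRUE, length(candidates))
  pick <- which(ok)[which.min(scores[ok])]
  structure(candidates[pick], scores = scores, collapsed = collapsed)
}

#' Parametric-bootstrap confidence intervals
#'
#' Simulates `B` data sets of length `t_obs` at `theta_hat`, re-estimates
#' each with the nearest-neighbour grid method, and reports percentile
#' intervals (natural scale). When the first 100 bootstrap estimates hit
#' fewer than 50 unique grid rows the grid is too coarse for the bootstrap
#' distribution (expected for large `t_obs`); every bootstrap replicate is
#' then re-estimated by differential evolution on the surrogate built from
#' the original observation's 100 nearest neighbours.
#'
#' @param grid a `prepaid_grid`.
#' @param model the matching `prepaid_model`.
#' @param theta_hat point estimate on the natural scale (named).
#' @param t_obs observed length.
#' @param B bootstrap replicates.
#' @param level confidence level.
#' @param s_obs optional original observed statistics, required for the
#'   surrogate fallback.
#' @param seed master seed.
#' @param de_control control list for the fallback optimizer.
#' @return list: `interval` (`K x 2` matrix, natural scale), `level`,
#'   `theta_boot` (`B x K` natural-scale estimates), `fallback` (logical).
#' @export
parametric_bootstrap_ci <- function(grid, model, theta_hat, t_obs, B = 1000,
                                    level = 0.95, s_obs = NULL, seed = 1,
                                    de_control = list()) {
  space <- grid$meta$spec$space
  K <- space_dim(space)
  stopifnot(all(space_contains(space, to_working(space, theta_hat))))
  stats_b <- vector("list", B)
  for (b in seq_len(B))
    stats_b[[b]] <- with_seed(derive_seed(seed, b),
      model$summarize(model$simulate_data(unlist(theta_hat), t_obs)))
  rows <- integer(B)
  theta_b <- matrix(NA_real_, B, K)
  for (b in seq_len(B)) {
    e <- estimate_slml_grid(grid, stats_b[[b]], t_obs)
    rows[b] <- e$neighbor_indices
    theta_b[b, ] <- e$theta_working
  }
  nprobe <- min(100L, B)
  fallback <- length(unique(rows[seq_len(nprobe)])) < nprobe / 2
  if (fallback && is.null(s_obs)) {
    warning("grid saturated (few unique bootstrap rows) but s_obs not ",
            "supplied; keeping grid bootstrap estimates")
    fallback <- FALSE
  }
  if (fallback) {
    nn <- select_neighbors(grid, s_obs, t_obs,
                           n = min(100, nrow(grid$theta)))
    interp <- fit_local_interpolator(grid$theta[nn, , drop = FALSE],
                                     grid$mu[nn, , drop = FALSE],
                                     kind = "lssvm",
                                     clamp = grid$meta$stat_range)
    tp <- nearest_t_prepaid(grid, t_obs)
    R <- ncol(grid$mu)
    sig <- scale_covariance(matrix(grid$sigma[[as.character(tp)]][nn[1], , ],
                                   R, R), tp, t_obs)
    sig <- sig + diag(1e-8 * mean(diag(sig)) + 1e-300, R)
    ch <- chol(sig)
    lo <- interp$training_box[1, ]
    hi <- interp$training_box[2, ]
    for (b in seq_len(B)) {
      sb <- as.numeric(stats_b[[b]])
      negll <- function(theta) {
        d <- sweep(interp$predict(theta), 2, sb)
        z <- backsolve(ch, t(d), transpose = TRUE)
        0.5 * colSums(z^2)
      }
      opt <- with_seed(derive_seed(seed, 500000L + b),
                       de_optimize(negll, lo, hi, control = de_control))
      theta_b[b, ] <- opt$par
    }
  }
  nat <- to_natural(space, theta_b)
  if (is.null(dim(nat))) nat <- matrix(nat, ncol = K)
  alpha <- (1 - level) / 2
  interval <- t(apply(nat, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                      names = FALSE))
  dimnames(interval) <- list(space$names, c("lower", "upper"))
  list(interval = interval, level = level, theta_boot = nat,
       fallback = fallback)
}
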