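#' Draw a test set of true parameters
#'
#' Samples parameter vectors from a generating prior (default: the space's
#' own prior) and discards draws lying within `trim` of the box range of any
#' bound, which removes boundary artefacts from recovery studies. Draws are
#' on the working scale.
#'
#' @param space a [parameter_space()].
#' @param n_test test-set size after trimming.
#' @param generator_prior optional prior object used for generation (e.g. a
#'   [beta_box_prior()], or a narrower uniform for selected parameters).
#' @param trim relative trimming margin (0 disables).
#' @param seed RNG seed.
#' @return `n_test x K` working-scale matrix.
#' @export
make_test_set <- function(space, n_test, generator_prior = NULL,
                          trim = 0.01, seed = 1) {
  stopifnot(n_test >= 1, trim >= 0, trim < 0.5)
  pr <- generator_prior %||% space$prior
  rng <- space$upper - space$lower
  with_seed(seed, {
    out <- NULL
    tries <- 0
    while (is.null(out) || nrow(out) < n_test) {
      tries <- tries + 1
      if (tries > 1000) stop("test-set trimming rejected too many draws")
      m <- pr$sample(2 * n_test)
      keep <- rep(TRUE, nrow(m))
      if (trim > 0)
        for (j in seq_len(space_dim(space)))
          keep <- keep & m[, j] > space$lower[j] + trim * rng[j] &
            m[, j] < space$upper[j] - trim * rng[j]
      out <- rbind(out, m[keep, , drop = FALSE])
    }
    out <- out[seq_len(n_test), , drop = FALSE]
    colnames(out) <- space$names
    out
  })
}

#' Generating prior for trait-model test sets
#'
#' Identical to the estimation prior except that the optimal trait `h` is
#' drawn from `U(0, 100)` - the physically meaningful range of community
#' optima - rather than the padded estimation box `U(-25, 125)`.
#'
#' @param space the [trait_space()].
#' @return a prior object suitable for [make_test_set()].
#' @export
trait_test_prior <- function(space = trait_space()) {
  base <- uniform_prior(space)
  hj <- match("h", space$names)
  list(kind = "trait-test", logpdf = base$logpdf,
       sample = function(n) {
         m <- base$sample(n)
         m[, hj] <- stats::runif(n, 0, 100)
         m
       })
}

.estimate_once <- function(grid, model, method, s_obs, t_obs, seed) {
  if (is.function(method))
    return(with_seed(seed, method(grid, model, s_obs, t_obs)))
  switch(method,
    SLMLGrid = estimate_slml_grid(grid, s_obs, t_obs)$theta_working,
    SLMLSVM = with_seed(seed,
      estimate_slml_svm(grid, s_obs, t_obs, kind = "lssvm"))$theta_working,
    SLMLLin = with_seed(seed,
      estimate_slml_svm(grid, s_obs, t_obs, kind = "linear"))$theta_working,
    SLPMGrid = posterior_mean_grid(grid, s_obs, t_obs)$estimate$theta_working,
    ABCPMGrid = abc_posterior_grid(grid, s_obs, t_obs)$estimate$theta_working,
    ABCPMSVM = with_seed(seed,
      abc_posterior_svm(grid, s_obs, t_obs))$estimate$theta_working,
    stop("unknown method: ", method))
}

#' Parameter-recovery study
#'
#' For every test parameter and observed length, simulates one data set,
#' estimates it with each method, and aggregates per-parameter RMSE and MAE
#' (median absolute error) on the working scale - i.e. errors of log-scaled
#' parameters are errors in log units, matching how such parameters are
#' reported. Per-cell seeds derive from `(seed, test index, t_obs)` so
#' partial reruns reproduce exactly.
#'
#' @param grid a `prepaid_grid`.
#' @param model the matching `prepaid_model`.
#' @param methods character vector of method tags (`"SLMLGrid"`,
#'   `"SLMLSVM"`, `"SLMLLin"`, `"SLPMGrid"`, `"ABCPMGrid"`, `"ABCPMSVM"`),
#'   or a named list mixing tags with custom estimator functions
#'   `function(grid, model, s_obs, t_obs)` returning a working-scale vector.
#' @param test_set working-scale matrix from [make_test_set()].
#' @param t_obs_list observed lengths to scan.
#' @param seed master seed.
#' @return data frame: `parameter`, `t_obs`, `method`, `rmse`, `mae`,
#'   `n_test`, `n_fail`.
#' @export
run_recovery_study <- function(grid, model, methods, test_set, t_obs_list,
                               seed = 1) {
  space <- grid$meta$spec$space
  K <- space_dim(space)
  out <- NULL
  for (t_obs in t_obs_list) {
    stats_list <- vector("list", nrow(test_set))
    for (i in seq_len(nrow(test_set))) {
      nat <- to_natural(space, test_set[i, ])
      stats_list[[i]] <- with_seed(
        derive_seed(seed, i * 131L + as.integer(log10(t_obs) * 7)),
        model$summarize(model$simulate_data(nat, t_obs)))
    }
    method_names <- names(methods) %||% as.character(methods)
    if (is.null(names(methods)) && is.list(methods))
      stop("a list of methods must be named")
    for (mi in seq_along(methods)) {
      method <- if (is.list(methods)) methods[[mi]] else methods[mi]
      err <- matrix(NA_real_, nrow(test_set), K)
      for (i in seq_len(nrow(test_set))) {
        th <- tryCatch(
          .estimate_once(grid, model, method, stats_list[[i]], t_obs,
                         seed = derive_seed(seed, 7777L + i)),
          error = function(e) rep(NA_real_, K))
        err[i, ] <- th - test_set[i, ]
      }
      for (j in seq_len(K)) {
        e <- err[, j]
        out <- rbind(out, data.frame(
          parameter = space$names[j], t_obs = t_obs,
          method = method_names[mi],
          rmse = sqrt(mean(e^2, na.rm = TRUE)),
          mae = stats::median(abs(e), na.rm = TRUE),
          coverage = NA_real_, # filled by the recover CLI on request
          n_test = nrow(test_set), n_fail = sum(is.na(e))))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Coverage study of nominal-level intervals
#'
#' Fraction of test parameters whose interval contains the truth. For the
#' bootstrap methods the interval is a [parametric_bootstrap_ci()]; for the
#' posterior methods it is a [posterior_interval()]. Intervals for log-scale
#' parameters are checked on the working scale.
#'
#' @inheritParams run_recovery_study
#' @param method one of `"SLMLGrid"`, `"SLMLSVM"` (bootstrap intervals) or
#'   `"SLPMGrid"`, `"ABCPMGrid"`, `"ABCPMSVM"` (posterior intervals).
#' @param t_obs observed length.
#' @param B bootstrap replicates (bootstrap methods only).
#' @param level nominal level.
#' @return named numeric: per-parameter empirical coverage.
#' @export
run_coverage_study <- function(grid, model, method, test_set, t_obs,
                               B = 200, level = 0.95, seed = 1) {
  space <- grid$meta$spec$space
  K <- space_dim(space)
  hits <- matrix(NA, nrow(test_set), K)
  for (i in seq_len(nrow(test_set))) {
    nat <- to_natural(space, test_set[i, ])
    s_obs <- with_seed(derive_seed(seed, i),
                       model$summarize(model$simulate_data(nat, t_obs)))
    if (is.function(method)) {
      iv <- method(grid, model, s_obs, t_obs)
      lo <- iv[, 1]
      hi <- iv[, 2]
    } else if (method %in% c("SLMLGrid", "SLMLSVM")) {
      est <- if (method == "SLMLGrid")
        estimate_slml_grid(grid, s_obs, t_obs)
      else with_seed(derive_seed(seed, 31L + i),
                     estimate_slml_svm(grid, s_obs, t_obs))
      ci <- parametric_bootstrap_ci(grid, model, est$theta_hat, t_obs,
                                    B = B, level = level, s_obs = s_obs,
                                    seed = derive_seed(seed, 9000L + i))
      lo <- to_working(space, stats::setNames(ci$interval[, 1], space$names))
      hi <- to_working(space, stats::setNames(ci$interval[, 2], space$names))
    } else {
      post <- switch(method,
        SLPMGrid = posterior_mean_grid(grid, s_obs, t_obs)$posterior,
        ABCPMGrid = abc_posterior_grid(grid, s_obs, t_obs)$posterior,
        ABCPMSVM = with_seed(derive_seed(seed, 31L + i),
                             abc_posterior_svm(grid, s_obs, t_obs))$posterior,
        stop("unknown method: ", method))
      iv <- posterior_interval(post, level = level)
      lo <- iv[, 1]
      hi <- iv[, 2]
    }
    hits[i, ] <- test_set[i, ] >= lo & test_set[i, ] <= hi
  }
  stats::setNames(colMeans(hits), space$names)
}
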