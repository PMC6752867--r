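# Analytic toy study: prepaid estimation of the mean of a normal with known
# SD, where every step of the pipeline (evenly spaced grid, nearest
# neighbours in statistic space, linear inversion) has a closed form to test
# against.

#' Toy-normal prepaid estimate of the mean
#'
#' Given an observed sample mean and a prepaid grid of
#' `(mu_j, simulated-statistic)` pairs, selects the `N` pairs whose simulated
#' statistic is nearest the observed one, regresses statistic on `mu`
#' (ordinary least squares) and inverts the line:
#' `mu_hat = (y_bar - b0) / b1`.
#'
#' @param y_bar observed statistic (sample mean, or its square in
#'   situation 2).
#' @param grid_mu grid parameter values `mu_j`.
#' @param grid_stat simulated statistics paired with `grid_mu`.
#' @param N neighbours used for the local regression.
#' @return `mu_hat`, with attributes `M_mu` (mean of selected `mu`s) and
#'   `selected` (their indices).
#' @export
toy_estimate_mu <- function(y_bar, grid_mu, grid_stat, N) {
  stopifnot(length(grid_mu) == length(grid_stat), N >= 2,
            N <= length(grid_mu))
  sel <- order(abs(grid_stat - y_bar), seq_along(grid_stat))[seq_len(N)]
  x <- grid_mu[sel]
  y <- grid_stat[sel]
  mx <- mean(x)
  vx <- sum((x - mx)^2)
  if (vx <= 0) stop("non-identifiable slope: selected mu values identical")
  b1 <- sum((x - mx) * (y - mean(y))) / vx
  if (b1 == 0) stop("non-identifiable slope: regression slope is zero")
  b0 <- mean(y) - b1 * mx
  structure((y_bar - b0) / b1, M_mu = mx, selected = sel)
}

#' Idealized moments of the selected neighbour parameters
#'
#' For `N` exactly consecutive grid values with spacing `delta`, the selected
#' `mu`s have variance `V = delta^2 (N - 1)(N + 1) / 12` (exact), standard
#' deviation `sqrt(V)`, and the commonly quoted large-`N` approximation
#' `delta^2 N^2 / 12`. The mean offset from the smallest selected value is
#' `delta (N - 1) / 2`.
#'
#' @param delta grid gap.
#' @param N neighbours.
#' @return list: `M_offset`, `V_mu`, `S_mu`, `V_approx`.
#' @export
toy_neighbor_moments <- function(delta, N) {
  stopifnot(delta > 0, N >= 1)
  V <- delta^2 * (N - 1) * (N + 1) / 12
  list(M_offset = delta * (N - 1) / 2, V_mu = V, S_mu = sqrt(V),
       V_approx = delta^2 * N^2 / 12)
}

#' Closed-form bias and variance of the toy prepaid estimator
#'
#' Situation 1 (statistic = sample mean). The estimator bias is
#' `-alpha * 12 s^2 / (T_sim delta^2 N^3)` where `alpha` is the systematic
#' offset `E(M_mu) - mu` of the selected neighbourhood centre. The marginal
#' variance is
#' `s^2/T_obs + s^2/(T_sim N) + 12 s^2 E((mu - M_mu)^2)/(T_sim delta^2 N^3)
#'  + 24 s^4/(T_obs T_sim delta^2 N^3) + 144 s^6/(T_obs T_sim^2 delta^4 N^6)`.
#' The leading term is the classical `s^2/T_obs`; all others shrink with
#' `T_sim`, but blow up when `delta` shrinks at fixed `N` (the local
#' regression then sits on too small a lever arm).
#'
#' @param alpha systematic neighbourhood offset `E(M_mu) - mu`.
#' @param s known SD.
#' @param t_obs,t_sim observed / prepaid simulation lengths.
#' @param delta grid gap.
#' @param N neighbours.
#' @param e_dev2 `E((mu - M_mu)^2)` (defaults to `alpha^2`, the pure-offset
#'   case; pass the empirical value in simulation checks).
#' @return `toy_analytic_bias`: the bias; `toy_analytic_variance`: the
#'   variance.
#' @export
toy_analytic_bias <- function(alpha, s, t_sim, delta, N) {
  -alpha * 12 * s^2 / (t_sim * delta^2 * N^3)
}

#' @rdname toy_analytic_bias
#' @export
toy_analytic_variance <- function(s, t_obs, t_sim, delta, N,
                                  e_dev2 = NULL, alpha = 0) {
  if (is.null(e_dev2)) e_dev2 <- alpha^2
  s^2 / t_obs + s^2 / (t_sim * N) +
    12 * s^2 * e_dev2 / (t_sim * delta^2 * N^3) +
    24 * s^4 / (t_obs * t_sim * delta^2 * N^3) +
    144 * s^6 / (t_obs * t_sim^2 * delta^4 * N^6)
}

#' Toy-study configuration and replicate runs
#'
#' `toy_config()` collects the study settings; `toy_replicates()` runs the
#' full prepaid pipeline (fresh evenly spaced grid of `N_r` simulated means
#' per replicate, neighbour selection in statistic space, linear inversion)
#' and compares the empirical moments of `mu_hat` with the closed forms.
#' The grid is centred on the true `mu` with spacing `delta`.
#'
#' @param mu true mean.
#' @param s known SD.
#' @param t_obs,t_sim observed / prepaid lengths.
#' @param delta grid gap.
#' @param N neighbours.
#' @param n_r grid size.
#' @param situation 1 (`ybar`) or 2 (`ybar^2`).
#' @param replicates Monte-Carlo replicates.
#' @param seed master seed.
#' @return `toy_config`: a config list. `toy_replicates`: list with
#'   `mu_hat`, `M_mu` (per replicate), empirical `bias`, `variance`, `rmse`,
#'   `alpha`, `e_dev2`, and the matching `analytic_bias`,
#'   `analytic_variance`.
#' @export
toy_config <- function(mu = 0, s = 1, t_obs = 100, t_sim = 1000,
                       delta = 0.1, N = 20, n_r = 501, situation = 1,
                       replicates = 1000, seed = 1) {
  stopifnot(delta > 0, N >= 2, n_r > N, situation %in% c(1, 2),
            replicates >= 1)
  list(mu = mu, s = s, t_obs = t_obs, t_sim = t_sim, delta = delta, N = N,
       n_r = n_r, situation = situation, replicates = replicates,
       seed = seed)
}

#' @param config a [toy_config()].
#' @rdname toy_config
#' @export
toy_replicates <- function(config) {
  cf <- config
  grid_mu <- cf$mu + cf$delta * (seq_len(cf$n_r) - (cf$n_r + 1) / 2)
  # the squared-mean statistic only identifies mu up to sign: situation 2
  # works on the nonnegative half-line, so clip the grid there
  if (cf$situation == 2) grid_mu <- grid_mu[grid_mu >= 0]
  if (length(grid_mu) <= cf$N)
    stop("grid too small for N neighbours after clipping")
  mu_hat <- M_mu <- numeric(cf$replicates)
  for (r in seq_len(cf$replicates)) {
    res <- with_seed(derive_seed(cf$seed, r), {
      sim_mean <- stats::rnorm(length(grid_mu), grid_mu,
                             cf$s / sqrt(cf$t_sim))
      obs_mean <- stats::rnorm(1, cf$mu, cf$s / sqrt(cf$t_obs))
      if (cf$situation == 1)
        toy_estimate_mu(obs_mean, grid_mu, sim_mean, cf$N)
      else
        toy_estimate_mu(obs_mean^2, grid_mu, sim_mean^2, cf$N)
    })
    mu_hat[r] <- as.numeric(res)
    M_mu[r] <- attr(res, "M_mu")
  }
  bias <- mean(mu_hat) - cf$mu
  variance <- stats::var(mu_hat)
  alpha <- mean(M_mu) - cf$mu
  e_dev2 <- mean((M_mu - cf$mu)^2)
  list(config = cf, mu_hat = mu_hat, M_mu = M_mu, bias = bias,
       variance = variance, rmse = sqrt(mean((mu_hat - cf$mu)^2)),
       alpha = alpha, e_dev2 = e_dev2,
       analytic_bias = toy_analytic_bias(alpha, cf$s, cf$t_sim, cf$delta,
                                         cf$N),
       analytic_variance = toy_analytic_variance(cf$s, cf$t_obs, cf$t_sim,
                                                 cf$delta, cf$N,
                                                 e_dev2 = e_dev2))
}

#' RMSE surface of the toy estimator over (gap, neighbours)
#'
#' Runs [toy_replicates()] on every `(delta, N)` combination. In situation 1
#' the RMSE deteriorates as `delta` shrinks below the prepaid noise scale at
#' fixed `N`; in situation 2 (quadratic statistic) an interior optimum in
#' `delta` appears because large gaps add linear-approximation error.
#'
#' @param deltas grid gaps to scan.
#' @param ns neighbourhood sizes to scan.
#' @param situation 1 or 2.
#' @param replicates Monte-Carlo replicates per cell.
#' @param config base [toy_config()] supplying the remaining settings.
#' @return data frame with columns `delta`, `N`, `rmse`, `bias`, `variance`.
#' @export
toy_rmse_surface <- function(deltas, ns, situation = 1, replicates = 200,
                             config = toy_config()) {
  out <- expand.grid(delta = deltas, N = ns)
  out$rmse <- out$bias <- out$variance <- NA_real_
  for (i in seq_len(nrow(out))) {
    cf <- config
    cf$delta <- out$delta[i]
    cf$N <- out$N[i]
    cf$situation <- situation
    cf$replicates <- replicates
    cf$n_r <- max(cf$n_r, 4 * cf$N + 50)
    cf$seed <- derive_seed(config$seed, i)
    rep <- toy_replicates(cf)
    out$rmse[i] <- rep$rmse
    out$bias[i] <- rep$bias
    out$variance[i] <- rep$variance
  }
  out[, c("delta", "N", "rmse", "bias", "variance")]
}
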