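#' Ricker population model
#'
#' Discrete-time population dynamics with Poisson observation:
#' `y_t ~ Pois(phi * N_t)`, `N_{t+1} = r * N_t * exp(-N_t + e_t)`,
#' `e_t ~ N(0, sigma^2)`. `r` is the growth rate, `sigma` the process-noise
#' SD and `phi` the Poisson scaling; `N_t` and `e_t` are hidden states. The
#' map is near-chaotic for large `r` and the likelihood is intractable, which
#' makes the model a standard test bed for synthetic-likelihood inference.
#'
#' `ricker_space()` is the default bounded box: `r~U(1,90)`,
#' `sigma ~ U(0.05, 0.7)`, `phi ~ U(0, 20)` on the linear scale;
#' `wide = TRUE` gives the larger log-scaled box
#' `log(r) ~ U(log 1, log 200)`, `sigma ~ U(0.05, 0.7)`, `log(phi) ~ U(-2, 7)`
#' used for data sets with growth rates or scalings outside the default box.
#'
#' @param wide use the wide log-scaled box.
#' @return a [parameter_space()].
#' @export
ricker_space <- function(wide = FALSE) {
  if (!wide)
    parameter_space(c("r", "sigma", "phi"),
                    lower = c(1, 0.05, 0), upper = c(90, 0.7, 20))
  else
    parameter_space(c("r", "sigma", "phi"),
                    lower = c(log(1), 0.05, -2),
                    upper = c(log(200), 0.7, 7),
                    scale = c("log", "linear", "log"))
}

#' Simulate a Ricker count series
#'
#' The hidden state starts at `n0 = 1` and `burnin` steps are discarded so
#' that the emitted counts come from the stationary regime of the map.
#'
#' @param params named vector/list with `r`, `sigma`, `phi` (natural scale,
#'   all positive; `sigma = 0` gives the deterministic map).
#' @param T series length (`>= 1`).
#' @param seed optional integer seed; identical seed gives identical output.
#' @param burnin discarded initial steps.
#' @param n0 initial hidden state.
#' @return integer vector of `T` counts.
#' @examples
#' y <- simulate_ricker(c(r = exp(1), sigma = 0.3, phi = 10), 100, seed = 1)
#' @export
simulate_ricker <- function(params, T, seed = NULL, burnin = 50, n0 = 1) {
  params <- unlist(params)[c("r", "sigma", "phi")]
  stopifnot(T >= 1, all(is.finite(params)), params[["r"]] > 0,
            params[["sigma"]] >= 0, params[["phi"]] > 0)
  with_seed(seed,
    ricker_sim_cpp(params[["r"]], params[["sigma"]], params[["phi"]],
                   as.integer(T), as.integer(burnin), n0))
}

.ricker_stat_names <- c("mean", "prop_zero", paste0("acov", 1:5),
                        paste0("ar", 0:2))

.ricker_stat_range <- function() {
  rng <- rbind(rep(-Inf, 10), rep(Inf, 10))
  colnames(rng) <- .ricker_stat_names
  rng[, "mean"] <- c(0, Inf)
  rng[, "prop_zero"] <- c(0, 1)
  rng
}

#' Summarize a Ricker count series
#'
#' Compresses a count series into 10 statistics: the mean, the proportion of
#' zeros (a percentage-type statistic, so it is comparable across series
#' lengths), the autocovariances at lags 1 to 5, and the three coefficients
#' of the ordinary least squares regression of `x_t = y_t^0.3` on
#' `{1, x_{t-1}, x_{t-1}^2}`. A constant series makes the autoregression
#' singular; its coefficients then degrade to `(mean(x), 0, 0)`.
#'
#' @param series integer count series, length `>= 7` (lag-5 autocovariance).
#' @return a [summary_vector()] of length 10.
#' @export
summarize_ricker <- function(series) {
  series <- as.integer(series)
  if (length(series) < 7) stop("series too short: need length >= 7")
  if (any(series < 0)) stop("counts must be nonnegative")
  summary_vector(ricker_summary_cpp(series), .ricker_stat_names,
                 .ricker_stat_range())
}

#' Prepaid model objects
#'
#' A `prepaid_model` bundles everything [build_grid()] and the study harness
#' need: the bounded [parameter_space()], statistic names and admissible
#' ranges, a long-run simulator that returns the grid-point statistic mean
#' plus split statistics at the stored lengths, and observed-data helpers.
#'
#' @param wide use the wide Ricker box (see [ricker_space()]).
#' @return a list of class `prepaid_model`.
#' @export
ricker_model <- function(wide = FALSE) {
  space <- ricker_space(wide)
  rng <- .ricker_stat_range()
  model <- list(
    name = "ricker",
    space = space,
    stat_names = .ricker_stat_names,
    stat_range = rng,
    min_T = 7,
    # one long chain per grid point, split contiguously for the covariances
    sim_stats = function(theta_nat, t_sim, t_prepaid, m_bank) {
      y <- ricker_sim_cpp(theta_nat[["r"]], theta_nat[["sigma"]],
                          theta_nat[["phi"]], as.integer(t_sim), 50L, 1)
      mu <- ricker_summary_cpp(y)
      splits <- lapply(t_prepaid, function(tp)
        ricker_split_summaries_cpp(y, as.integer(tp), -1L))
      names(splits) <- as.character(t_prepaid)
      list(mu = mu, splits = splits)
    },
    simulate_data = function(theta_nat, t_obs)
      ricker_sim_cpp(theta_nat[["r"]], theta_nat[["sigma"]],
                     theta_nat[["phi"]], as.integer(t_obs), 50L, 1),
    summarize = function(data) summarize_ricker(data))
  class(model) <- "prepaid_model"
  model
}

#' @export
print.prepaid_model <- function(x, ...) {
  cat("prepaid_model:", x$name, "-", length(x$stat_names), "statistics\n")
  print(x$space)
  invisible(x)
}
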