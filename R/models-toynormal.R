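#' Toy-normal model
#'
#' Analytically tractable test bed: `y_i ~ N(mu, s^2)` with `s` known and
#' only the mean `mu` estimated (`K = 1`). Situation 1 uses the sample mean
#' as the single summary statistic (sufficient, linear in `mu`); situation 2
#' uses the squared sample mean (nonlinear), which exposes the trade-off
#' between grid gap and neighbourhood size of the prepaid estimator.
#'
#' @param lower,upper bounds of the `mu` box.
#' @return a [parameter_space()].
#' @export
toynormal_space <- function(lower = 0, upper = 10) {
  parameter_space("mu", lower = lower, upper = upper)
}

#' @param s known standard deviation.
#' @param situation 1 (statistic `mean(y)`) or 2 (statistic `mean(y)^2`).
#' @param space optional [parameter_space()] for `mu`.
#' @rdname ricker_model
#' @export
toynormal_model <- function(s = 1, situation = 1,
                            space = toynormal_space()) {
  stopifnot(s > 0, situation %in% c(1, 2))
  stat_name <- if (situation == 1) "ybar" else "ybar_sq"
  rng <- rbind(if (situation == 1) -Inf else 0, Inf)
  colnames(rng) <- stat_name
  stat_of_mean <- function(m) if (situation == 1) m else m^2
  model <- list(
    name = "toynormal",
    space = space,
    s = s,
    situation = situation,
    stat_names = stat_name,
    stat_range = rng,
    min_T = 1,
    # chunk means are exact: a split of length L has ybar ~ N(mu, s^2/L)
    sim_stats = function(theta_nat, t_sim, t_prepaid, m_bank) {
      y <- stats::rnorm(t_sim, theta_nat[["mu"]], s)
      mu <- stat_of_mean(mean(y))
      splits <- lapply(t_prepaid, function(tp) {
        ns <- length(y) %/% tp
        grp <- rep(seq_len(ns), each = tp)
        m <- rowsum(y[seq_len(ns * tp)], grp) / tp
        matrix(stat_of_mean(m), ncol = 1)
      })
      names(splits) <- as.character(t_prepaid)
      list(mu = mu, splits = splits)
    },
    simulate_data = function(theta_nat, t_obs)
      stats::rnorm(t_obs, theta_nat[["mu"]], s),
    summarize = function(data)
      summary_vector(stat_of_mean(mean(data)), stat_name, rng))
  class(model) <- "prepaid_model"
  model
}
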