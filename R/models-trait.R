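#' Trait-based stochastic community model
#'
#' A local community of `J` individuals assembled from a regional pool of `S`
#' species evenly spaced on the trait axis `[0, 100]`. At each step one local
#' individual dies uniformly at random; with probability `I / (I + J + 1)` it
#' is replaced by an immigrant species drawn uniformly from the pool,
#' otherwise by the offspring of a local individual chosen proportionally to
#' its competitiveness `F(u) = 1 + A * exp(-(u - h)^2 / (2 * sigma_f^2))`.
#' `I` controls immigration, `A` the maximal competitive advantage, `h` the
#' locally optimal trait and `sigma_f` the width of the environmental filter.
#'
#' `trait_space()` is the standard estimation box, uniform on
#' `log(I) ~ U(3, 5)`, `log(A) ~ U(log 0.1, log 5)`, `h ~ U(-25, 125)`,
#' `log(sigma_f) ~ U(log 0.5, log 25)` (natural logs).
#'
#' @return a [parameter_space()].
#' @export
trait_space <- function() {
  parameter_space(c("I", "A", "h", "sigma_f"),
                  lower = c(3, log(0.1), -25, log(0.5)),
                  upper = c(5, log(5), 125, log(25)),
                  scale = c("log", "log", "linear", "log"))
}

#' @param S regional pool size (species evenly spaced on `[0, 100]`).
#' @param J local community size.
#' @param thinning community deaths between recorded snapshots.
#' @rdname trait_space
#' @export
trait_config <- function(S = 1000, J = 500, thinning = 500) {
  stopifnot(S >= 2, J >= 2, thinning >= 1)
  list(S = as.integer(S), J = as.integer(J), thinning = as.integer(thinning))
}

#' Trait filtering (competitiveness) function
#'
#' @param u trait value(s).
#' @param params named vector/list with `A`, `h`, `sigma_f` (natural scale).
#' @return `1 + A * exp(-(u - h)^2 / (2 * sigma_f^2))`.
#' @export
filtering_value <- function(u, params) {
  p <- unlist(params)
  stopifnot(p[["sigma_f"]] > 0)
  1 + p[["A"]] * exp(-(u - p[["h"]])^2 / (2 * p[["sigma_f"]]^2))
}

trait_axis <- function(S) seq(0, 100, length.out = S)

#' Simulate community snapshots from the trait model
#'
#' The community is initialized by sampling `J` individuals uniformly from
#' the regional pool and run through a discarded transient of `burnin` deaths
#' (default `10 * J`) before the first snapshot; one snapshot of species
#' abundances is recorded every `thinning` deaths.
#'
#' @param params named vector/list with `I`, `A`, `h`, `sigma_f` (natural
#'   scale, positive except `h`).
#' @param config a [trait_config()].
#' @param n_snapshots number of recorded snapshots (`>= 1`).
#' @param seed optional integer seed.
#' @param burnin discarded initial deaths.
#' @return list of class `community_series`: `abundance` (`n_snapshots x S`
#'   integer matrix, rows sum to `J`) and `trait` (length-`S` trait values).
#' @export
simulate_trait <- function(params, config, n_snapshots, seed = NULL,
                           burnin = 10 * config$J) {
  p <- unlist(params)[c("I", "A", "h", "sigma_f")]
  stopifnot(n_snapshots >= 1, p[["I"]] > 0, p[["A"]] >= 0, p[["sigma_f"]] > 0)
  ab <- with_seed(seed,
    trait_sim_states_cpp(p[["I"]], p[["A"]], p[["h"]], p[["sigma_f"]],
                         config$S, config$J, config$thinning,
                         as.integer(n_snapshots), as.integer(burnin)))
  structure(list(abundance = ab, trait = trait_axis(config$S)),
            class = "community_series")
}

.trait_stat_names <- c("richness", "shannon", "trait_mean", "trait_skew")

.trait_stat_range <- function(config) {
  rng <- rbind(c(1, 0, 0, -Inf),
               c(min(config$S, config$J), log(min(config$S, config$J)),
                 100, Inf))
  colnames(rng) <- .trait_stat_names
  rng
}

#' Summarize a community state
#'
#' Statistics of one abundance snapshot: species richness, Shannon entropy of
#' the relative abundances, and the mean and skewness of the (individual-
#' weighted) community trait distribution. For a series of snapshots
#' (`T_obs > 1`) the data summary is the average of the per-snapshot
#' statistics.
#'
#' @param state a `community_series`, or a list with `abundance` (vector or
#'   matrix) and `trait`.
#' @return a [summary_vector()] of length 4 (averaged over snapshots when
#'   several are supplied).
#' @export
summarize_trait <- function(state) {
  ab <- state$abundance
  if (is.null(dim(ab))) ab <- matrix(ab, nrow = 1)
  u <- state$trait
  stopifnot(ncol(ab) == length(u))
  per <- t(apply(ab, 1, function(n) {
    J <- sum(n)
    stopifnot(J > 0)
    p <- n[n > 0] / J
    uu <- u[n > 0]
    m1 <- sum(p * uu)
    v <- sum(p * (uu - m1)^2)
    m3 <- sum(p * (uu - m1)^3)
    c(sum(n > 0), -sum(p * log(p)), m1, if (v > 0) m3 / v^1.5 else 0)
  }))
  rng <- rbind(c(1, 0, 0, -Inf), c(length(u), log(length(u)), 100, Inf))
  summary_vector(colMeans(per), .trait_stat_names, rng)
}

#' @param config a [trait_config()].
#' @param burnin discarded initial deaths per simulation (default `10 * J`).
#' @rdname ricker_model
#' @export
trait_model <- function(config = trait_config(), burnin = 10 * config$J) {
  space <- trait_space()
  rng <- .trait_stat_range(config)
  model <- list(
    name = "trait",
    space = space,
    config = config,
    stat_names = .trait_stat_names,
    stat_range = rng,
    min_T = 1,
    # one long run of snapshot statistics; split contiguously by averaging
    sim_stats = function(theta_nat, t_sim, t_prepaid, m_bank) {
      st <- trait_sim_stats_cpp(theta_nat[["I"]], theta_nat[["A"]],
                                theta_nat[["h"]], theta_nat[["sigma_f"]],
                                config$S, config$J, config$thinning,
                                as.integer(t_sim), as.integer(burnin))
      mu <- colMeans(st)
      splits <- lapply(t_prepaid, function(tp) {
        ns <- nrow(st) %/% tp
        if (tp == 1) st[seq_len(ns), , drop = FALSE]
        else {
          grp <- rep(seq_len(ns), each = tp)
          rowsum(st[seq_len(ns * tp), , drop = FALSE], grp) / tp
        }
      })
      names(splits) <- as.character(t_prepaid)
      list(mu = mu, splits = splits)
    },
    simulate_data = function(theta_nat, t_obs) {
      ab <- trait_sim_states_cpp(theta_nat[["I"]], theta_nat[["A"]],
                                 theta_nat[["h"]], theta_nat[["sigma_f"]],
                                 config$S, config$J, config$thinning,
                                 as.integer(t_obs), as.integer(burnin))
      structure(list(abundance = ab, trait = trait_axis(config$S)),
                class = "community_series")
    },
    summarize = function(data) summarize_trait(data))
  class(model) <- "prepaid_model"
  model
}
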