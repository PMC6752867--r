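#' Specification of a prepaid grid
#'
#' @param space a [parameter_space()].
#' @param omega number of grid points.
#' @param t_sim long-run simulation length per point (units of the model's
#'   observation: time steps for counts, snapshots for communities, draws for
#'   the toy model).
#' @param t_prepaid lengths at which split covariances and sample banks are
#'   stored; every value must divide into `t_sim` at least `R + 1` times so
#'   the covariance of the `R` statistics has positive degrees of freedom.
#' @param m maximum number of raw split-statistic samples banked per
#'   (point, length); `0` disables the bank.
#' @param seed master seed; per-point streams are derived with
#'   [derive_seed()] so the build is order-independent.
#' @param model_name model identifier recorded in the metadata.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(space, omega, t_sim, t_prepaid, m = 1000, seed = 1,
                      model_name = "") {
  stopifnot(omega >= 1, t_sim >= 1, all(t_prepaid >= 1),
            all(t_prepaid <= t_sim), m >= 0)
  structure(list(space = space, omega = as.integer(omega),
                 t_sim = as.integer(t_sim),
                 t_prepaid = sort(as.integer(t_prepaid)),
                 m = as.integer(m), seed = as.integer(seed),
                 model_name = model_name),
            class = "grid_spec")
}

#' Build a prepaid grid
#'
#' Charts the parameter box once: `omega` Halton points on the working scale;
#' at each point one long simulation of length `t_sim` whose full-run summary
#' statistics become the grid mean `mu`, whose contiguous non-overlapping
#' splits of each stored length give the per-length statistic covariance, and
#' whose first `m` split statistics are banked for grid-based ABC. This is
#' the expensive, once-only step - everything else in the package queries the
#' result.
#'
#' @param model a `prepaid_model` (e.g. [ricker_model()]).
#' @param spec a [grid_spec()]; its `model_name` is filled from `model`.
#' @return a `prepaid_grid`: list with `theta` (`omega x K`, working scale),
#'   `mu` (`omega x R`), `sigma` (per stored length, `omega x R x R` array),
#'   `bank` (per stored length, `omega x m_len x R` array) and `meta`.
#' @export
build_grid <- function(model, spec) {
  stopifnot(inherits(model, "prepaid_model"), inherits(spec, "grid_spec"))
  R <- length(model$stat_names)
  nsplit <- spec$t_sim %/% spec$t_prepaid
  if (any(nsplit < R + 1))
    stop(sprintf(
      "insufficient splits: t_sim/t_prepaid = %s but need >= R+1 = %d",
      paste(nsplit, collapse = ","), R + 1))
  theta <- halton_points(spec$omega, spec$space)
  theta_nat <- to_natural(spec$space, theta)
  if (is.null(dim(theta_nat))) theta_nat <- matrix(theta_nat, nrow = 1)
  mlen <- pmin(spec$m, nsplit)
  mu <- matrix(NA_real_, spec$omega, R, dimnames = list(NULL, model$stat_names))
  sigma <- lapply(seq_along(spec$t_prepaid), function(i)
    array(NA_real_, c(spec$omega, R, R)))
  bank <- lapply(seq_along(spec$t_prepaid), function(i)
    if (mlen[i] > 0) array(NA_real_, c(spec$omega, mlen[i], R)) else NULL)
  names(sigma) <- names(bank) <- as.character(spec$t_prepaid)
  for (p in seq_len(spec$omega)) {
    res <- with_seed(derive_seed(spec$seed, p),
      model$sim_stats(theta_nat[p, ], spec$t_sim, spec$t_prepaid, spec$m))
    mu[p, ] <- res$mu
    for (i in seq_along(spec$t_prepaid)) {
      sp <- res$splits[[as.character(spec$t_prepaid[i])]]
      cv <- stats::cov(sp)
      sigma[[i]][p, , ] <- (cv + t(cv)) / 2
      if (mlen[i] > 0)
        bank[[i]][p, , ] <- sp[seq_len(mlen[i]), , drop = FALSE]
    }
  }
  spec$model_name <- model$name
  grid <- structure(
    list(theta = theta, mu = mu, sigma = sigma, bank = bank,
         meta = list(spec = spec, stat_names = model$stat_names,
                     stat_range = model$stat_range,
                     model_args = model[intersect(
                       c("config", "s", "situation"), names(model))],
                     version = .grid_version,
                     built = "prepaid build_grid")),
    class = "prepaid_grid")
  attr(grid, "cache") <- new.env(parent = emptyenv())
  grid
}

.grid_version <- 1L

#' @export
print.prepaid_grid <- function(x, ...) {
  cat(sprintf("prepaid_grid: model %s, %d points x %d parameters, %d stats\n",
              x$meta$spec$model_name, nrow(x$theta), ncol(x$theta),
              ncol(x$mu)))
  cat("  stored lengths:", paste(names(x$sigma), collapse = ", "), "\n")
  invisible(x)
}

#' Rescale a stored covariance matrix to the observed length
#'
#' Summary statistics here are averages, so their covariance shrinks like
#' `1/T`: the covariance stored for series length `t_prepaid` maps to an
#' observed length `t_obs` as `(t_prepaid / t_obs) * sigma`. Callers pick the
#' stored length nearest to `t_obs` on the log scale (see
#' [nearest_t_prepaid()]).
#'
#' @param sigma `R x R` covariance at length `t_prepaid`.
#' @param t_prepaid stored length.
#' @param t_obs observed length.
#' @return rescaled `R x R` covariance.
#' @export
scale_covariance <- function(sigma, t_prepaid, t_obs) {
  stopifnot(t_prepaid >= 1, t_obs >= 1)
  (t_prepaid / t_obs) * sigma
}

#' @param grid a `prepaid_grid` (or numeric vector of stored lengths).
#' @rdname scale_covariance
#' @export
nearest_t_prepaid <- function(grid, t_obs) {
  lens <- if (inherits(grid, "prepaid_grid"))
    as.numeric(names(grid$sigma)) else as.numeric(grid)
  lens[which.min(abs(log10(lens) - log10(t_obs)))]
}

# Cached per-row inverse covariances and log-determinants for one stored
# length, regularized with eps * mean(diag) on the diagonal. Stored as an
# omega x R^2 matrix so that all omega quadratic forms reduce to one matrix-
# vector product.
.grid_cache <- function(grid, t_prepaid, eps = 1e-8) {
  key <- paste0("T", t_prepaid)
  cache <- attr(grid, "cache")
  if (is.null(cache)) {
    # attached environment survives by reference within one session
    cache <- new.env(parent = emptyenv())
    attr(grid, "cache") <- cache
  }
  if (!is.null(cache[[key]])) return(cache[[key]])
  sig <- grid$sigma[[as.character(t_prepaid)]]
  om <- dim(sig)[1]
  R <- dim(sig)[2]
  SI <- matrix(NA_real_, om, R * R)
  logdet <- numeric(om)
  for (p in seq_len(om)) {
    s <- matrix(sig[p, , ], R, R)
    s <- s + diag(eps * mean(diag(s)) + 1e-300, R)
    ch <- tryCatch(chol(s), error = function(e) NULL)
    if (is.null(ch)) {
      # last-resort heavier ridge for pathological rows
      s <- s + diag(1e-4 * mean(diag(s)) + 1e-12, R)
      ch <- chol(s)
    }
    SI[p, ] <- as.numeric(chol2inv(ch))
    logdet[p] <- 2 * sum(log(diag(ch)))
  }
  out <- list(SI = SI, logdet = logdet, R = R, t_prepaid = t_prepaid)
  cache[[key]] <- out
  out
}

#' Synthetic log-likelihood of every grid row
#'
#' Evaluates `-(1/2) (s - mu_p)' Sigma_p^{-1} (s - mu_p) - (1/2) log|Sigma_p|`
#' for all grid rows `p`, with `Sigma_p` the stored covariance at the length
#' nearest `t_obs` (log scale) rescaled by [scale_covariance()].
#'
#' @param grid a `prepaid_grid`.
#' @param s_obs observed [summary_vector()] (or plain numeric of length `R`).
#' @param t_obs observed data length.
#' @return numeric vector of length `omega`.
#' @export
grid_loglik <- function(grid, s_obs, t_obs) {
  tp <- nearest_t_prepaid(grid, t_obs)
  cc <- .grid_cache(grid, tp)
  scale <- tp / t_obs
  d <- sweep(grid$mu, 2, as.numeric(s_obs))
  # quad_p = sum_jk SIp[j,k] d_j d_k ; row-wise via element product
  DD <- d[, rep(seq_len(cc$R), times = cc$R), drop = FALSE] *
    d[, rep(seq_len(cc$R), each = cc$R), drop = FALSE]
  quad <- rowSums(cc$SI * DD)
  -0.5 * quad / scale - 0.5 * (cc$logdet + cc$R * log(scale))
}

#' Save / load a prepaid grid
#'
#' A versioned single-file container: named arrays (`theta`, `mu`, per-length
#' `sigma` and `bank`) plus a JSON-encoded metadata block (statistic names,
#' spec, seed). The round trip is lossless.
#'
#' @param grid a `prepaid_grid`.
#' @param path file path.
#' @return `load_grid` returns the `prepaid_grid`; `save_grid` returns
#'   `path` invisibly.
#' @export
save_grid <- function(grid, path) {
  stopifnot(inherits(grid, "prepaid_grid"))
  meta <- grid$meta
  payload <- list(
    container = "prepaid_grid",
    version = .grid_version,
    theta = grid$theta, mu = grid$mu, sigma = grid$sigma, bank = grid$bank,
    meta_json = jsonlite::toJSON(list(
      model_name = meta$spec$model_name,
      stat_names = meta$stat_names,
      omega = meta$spec$omega, t_sim = meta$spec$t_sim,
      t_prepaid = meta$spec$t_prepaid, m = meta$spec$m,
      seed = meta$spec$seed,
      space = list(names = meta$spec$space$names,
                   lower = meta$spec$space$lower,
                   upper = meta$spec$space$upper,
                   scale = meta$spec$space$scale),
      stat_range = meta$stat_range), digits = NA),
    meta = meta)
  attr(payload, "cache") <- NULL
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_grid
#' @export
load_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("truncated or unreadable grid container: ", path))
  if (!identical(payload$container, "prepaid_grid"))
    stop("not a prepaid_grid container: ", path)
  if (!identical(payload$version, .grid_version))
    stop(sprintf("grid container version mismatch: file %s, package %s",
                 payload$version, .grid_version))
  grid <- structure(list(theta = payload$theta, mu = payload$mu,
                         sigma = payload$sigma, bank = payload$bank,
                         meta = payload$meta),
                    class = "prepaid_grid")
  attr(grid, "cache") <- new.env(parent = emptyenv())
  grid
}
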