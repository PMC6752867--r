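# Shared small fixtures, built once per test run and cached in an
# environment. Everything is generated in code; nothing is read from disk.

.fix <- new.env(parent = emptyenv())

# small Ricker grid for estimator unit tests (seconds to build)
unit_ricker_grid <- function() {
  if (is.null(.fix$rg)) {
    m <- ricker_model()
    .fix$rg <- build_grid(m, grid_spec(m$space, omega = 300, t_sim = 2e4,
                                       t_prepaid = c(100, 1000), m = 0,
                                       seed = 42))
    .fix$rm <- m
  }
  list(grid = .fix$rg, model = .fix$rm)
}

# small toy-normal grid with a sample bank, for ABC unit tests
unit_toy_grid <- function() {
  if (is.null(.fix$tg)) {
    m <- toynormal_model(s = 1, situation = 1,
                         space = toynormal_space(0, 10))
    .fix$tg <- build_grid(m, grid_spec(m$space, omega = 400, t_sim = 5000,
                                       t_prepaid = c(10, 50), m = 100,
                                       seed = 7))
    .fix$tm <- m
  }
  list(grid = .fix$tg, model = .fix$tm)
}

# hand-built grid container with fully controlled mu/sigma, for exactness
# tests of the estimators (1 statistic version: mu equals theta)
fake_grid <- function(theta, mu, sigma_shared, t_prepaid = 100,
                      space = NULL, bank = NULL,
                      stat_names = paste0("s", seq_len(ncol(mu)))) {
  theta <- as.matrix(theta)
  mu <- as.matrix(mu)
  K <- ncol(theta)
  R <- ncol(mu)
  if (is.null(space))
    space <- parameter_space(paste0("p", seq_len(K)),
                             lower = apply(theta, 2, min) - 1,
                             upper = apply(theta, 2, max) + 1)
  om <- nrow(theta)
  sig <- array(NA_real_, c(om, R, R))
  for (p in seq_len(om)) sig[p, , ] <- sigma_shared
  spec <- grid_spec(space, om, t_sim = 10 * t_prepaid,
                    t_prepaid = t_prepaid, m = 0, seed = 1,
                    model_name = "fake")
  g <- structure(
    list(theta = theta, mu = mu,
         sigma = stats::setNames(list(sig), as.character(t_prepaid)),
         bank = stats::setNames(list(bank), as.character(t_prepaid)),
         meta = list(spec = spec, stat_names = stat_names,
                     stat_range = rbind(rep(-Inf, R), rep(Inf, R)),
                     version = 1L)),
    class = "prepaid_grid")
  attr(g, "cache") <- new.env(parent = emptyenv())
  g
}

# dense multivariate-normal log-density computed by an independent route
# (explicit solve + log-determinant), used as the oracle for the synthetic
# log-likelihood
mvn_logpdf_oracle <- function(x, mu, sigma) {
  d <- x - mu
  R <- length(x)
  -0.5 * drop(t(d) %*% solve(sigma) %*% d) -
    0.5 * as.numeric(determinant(sigma, logarithm = TRUE)$modulus) -
    (R / 2) * log(2 * pi)
}

expect_same_bytes <- function(path1, path2) {
  expect_identical(readBin(path1, "raw", file.size(path1)),
                   readBin(path2, "raw", file.size(path2)))
}
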