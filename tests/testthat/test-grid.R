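test_that("grid build is reproducible, finite and PSD", {
  m <- toynormal_model()
  spec <- grid_spec(m$space, omega = 8, t_sim = 1e4, t_prepaid = 100,
                    m = 10, seed = 5)
  g1 <- build_grid(m, spec)
  g2 <- build_grid(m, spec)
  expect_identical(g1$theta, g2$theta)
  expect_identical(g1$mu, g2$mu)
  expect_identical(g1$sigma, g2$sigma)
  expect_identical(g1$bank, g2$bank)
  expect_true(all(is.finite(g1$mu)))
  for (p in 1:8) {
    s <- matrix(g1$sigma[["100"]][p, , ], 1, 1)
    expect_true(all(eigen(s, symmetric = TRUE)$values >= -1e-12))
  }
})

test_that("a multi-statistic grid has symmetric PSD covariances", {
  fix <- unit_ricker_grid()
  g <- fix$grid
  for (p in c(1, 57, 300)) {
    s <- matrix(g$sigma[["1000"]][p, , ], 10, 10)
    expect_equal(s, t(s))
    expect_true(min(eigen(s, symmetric = TRUE,
                          only.values = TRUE)$values) >= -1e-8 * mean(diag(s)))
  }
})

test_that("insufficient splits are refused", {
  m <- ricker_model() # R = 10 statistics
  expect_error(build_grid(m, grid_spec(m$space, omega = 2, t_sim = 1000,
                                       t_prepaid = 100, seed = 1)),
               "insufficient splits")
})

test_that("covariance rescaling is the exact affine map", {
  s <- matrix(c(2, 0.3, 0.3, 1), 2, 2)
  expect_identical(scale_covariance(s, 1000, 1000), s)
  expect_equal(scale_covariance(s, 1000, 2000), s / 2)
  expect_equal(scale_covariance(s, 100, 10), s * 10)
  # nearest stored length on the log scale
  expect_equal(nearest_t_prepaid(c(100, 1000), 300), 100)
  expect_equal(nearest_t_prepaid(c(100, 1000), 320), 1000)
})

test_that("grid log-likelihood equals the direct per-row computation", {
  fix <- unit_toy_grid()
  g <- fix$grid
  s_obs <- 4.2
  for (t_obs in c(10, 200)) {
    tp <- nearest_t_prepaid(g, t_obs)
    ll <- grid_loglik(g, s_obs, t_obs)
    direct <- vapply(seq_len(nrow(g$theta)), function(p)
      synthetic_loglik(s_obs, g$mu[p, ],
                       scale_covariance(matrix(g$sigma[[as.character(tp)]][p, , ], 1, 1),
                                        tp, t_obs)),
      numeric(1))
    expect_equal(ll, direct, tolerance = 1e-10)
  }
})

test_that("toy-normal grid matches closed forms: mu and sigma scaling", {
  fix <- unit_toy_grid()
  g <- fix$grid
  tsim <- g$meta$spec$t_sim
  # long-run mean within 4 s/sqrt(T_sim) of the true mean
  expect_true(all(abs(g$mu[, 1] - g$theta[, 1]) < 4 / sqrt(tsim)))
  # Sigma_T * T approximately constant = s^2 across stored lengths
  v10 <- g$sigma[["10"]][, 1, 1] * 10
  v50 <- g$sigma[["50"]][, 1, 1] * 50
  expect_lt(abs(mean(v10) - 1), 0.05)
  expect_lt(abs(mean(v50) - 1), 0.1)
  expect_lt(abs(mean(v10 / v50) - 1), 0.25)
})

test_that("grid containers round-trip losslessly and fail loudly", {
  m <- toynormal_model()
  g <- build_grid(m, grid_spec(m$space, omega = 6, t_sim = 2000,
                               t_prepaid = c(10, 100), m = 5, seed = 2))
  path <- tempfile(fileext = ".rds")
  save_grid(g, path)
  g2 <- load_grid(path)
  expect_identical(g$theta, g2$theta)
  expect_identical(g$mu, g2$mu)
  expect_identical(g$sigma, g2$sigma)
  expect_identical(g$bank, g2$bank)
  expect_identical(g2$meta$stat_names, m$stat_names)
  expect_identical(g2$meta$spec$seed, 2L)
  expect_error(load_grid(tempfile()), "not found")
  # version mismatch
  payload <- readRDS(path)
  payload$version <- 999L
  bad <- tempfile(fileext = ".rds")
  saveRDS(payload, bad)
  expect_error(load_grid(bad), "version mismatch")
  # wrong container
  notgrid <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), notgrid)
  expect_error(load_grid(notgrid), "not a prepaid_grid")
})

test_that("per-point seeds make builds independent of evaluation order", {
  # build a grid, then recompute a single point's statistics in isolation
  m <- toynormal_model()
  spec <- grid_spec(m$space, omega = 5, t_sim = 1000, t_prepaid = 10,
                    m = 3, seed = 11)
  g <- build_grid(m, spec)
  p <- 4
  nat <- to_natural(m$space, g$theta[p, , drop = FALSE])
  res <- prepaid:::with_seed(derive_seed(11, p),
    m$sim_stats(nat[1, ], 1000, 10, 3))
  expect_equal(unname(g$mu[p, ]), unname(res$mu))
})
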