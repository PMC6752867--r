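test_that("grid posterior means average rows by likelihood weight", {
  theta <- matrix(c(0, 1), ncol = 1)
  # equal likelihoods -> mean 0.5
  g <- fake_grid(theta, matrix(c(2, 2), ncol = 1), matrix(1))
  r <- posterior_mean_grid(g, 2, 100)
  expect_equal(unname(r$estimate$theta_hat), 0.5)
  expect_equal(r$posterior$weights, c(0.5, 0.5))
  # one dominant row
  g2 <- fake_grid(theta, matrix(c(2, 50), ncol = 1), matrix(1))
  r2 <- posterior_mean_grid(g2, 2, 100)
  expect_lt(abs(unname(r2$estimate$theta_hat) - 0), 1e-6)
  # extreme log-likelihoods must not underflow
  g3 <- fake_grid(theta, matrix(c(2, 5000), ncol = 1), matrix(1e-6))
  r3 <- posterior_mean_grid(g3, 2, 100)
  expect_true(all(is.finite(r3$posterior$weights)))
  expect_equal(sum(r3$posterior$weights), 1)
})

test_that("coverage sets are minimal and cover the target mass", {
  expect_equal(select_coverage_set(log(1))$Q, 1)
  r <- select_coverage_set(log(c(0.9995, 0.0005)))
  expect_equal(r$Q, 1)
  expect_equal(r$indices, 1L)
  expect_equal(select_coverage_set(rep(0, 1000))$Q, ceiling(0.999 * 1000))
  set.seed(9)
  for (i in 1:20) {
    lw <- rnorm(200, sd = 3)
    r <- select_coverage_set(lw)
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    expect_gte(sum(w[r$indices]), 0.999)
    if (r$Q > 1)
      expect_lt(sum(w[r$indices[-r$Q]]), 0.999)
  }
})

test_that("bank ABC keeps the Mahalanobis-nearest samples", {
  set.seed(10)
  om <- 30; M <- 20
  theta <- matrix(seq(0, 1, length.out = om), ncol = 1)
  mu <- cbind(theta[, 1], theta[, 1]^2)
  bank <- array(NA_real_, c(om, M, 2))
  for (p in 1:om)
    bank[p, , ] <- cbind(rnorm(M, mu[p, 1], 0.1), rnorm(M, mu[p, 2], 0.1))
  g <- fake_grid(theta, mu, diag(2) * 0.01, t_prepaid = 100, bank = bank)
  s_obs <- c(0.5, 0.25)
  r <- abc_posterior_grid(g, s_obs, 100, n_keep = 50)
  # dual route: recompute distances and the kept set directly
  lw <- grid_loglik(g, s_obs, 100)
  S <- select_coverage_set(lw)$indices
  X <- matrix(aperm(bank[S, , , drop = FALSE], c(2, 1, 3)),
              nrow = length(S) * M, ncol = 2)
  WQ <- cov(X) + diag(1e-8 * mean(diag(cov(X))), 2)
  eps <- mahalanobis(X, s_obs, WQ)
  expect_equal(sort(r$details$kept_eps), sort(sort(eps)[1:50]),
               tolerance = 1e-6)
  # posterior mean lies in the convex hull of the coverage-set rows
  expect_gte(unname(r$estimate$theta_hat), min(theta[S, 1]))
  expect_lte(unname(r$estimate$theta_hat), max(theta[S, 1]))
  # a bank sample equal to s_obs is always kept
  bank2 <- bank
  bank2[17, 3, ] <- s_obs
  g2 <- fake_grid(theta, mu, diag(2) * 0.01, t_prepaid = 100, bank = bank2)
  r2 <- abc_posterior_grid(g2, s_obs, 100, n_keep = 50)
  expect_lt(min(r2$details$kept_eps), 1e-20)
  expect_true(17L %in% r2$details$kept_source)
})

test_that("posterior draws are rescaled exactly for length mismatch", {
  set.seed(11)
  om <- 25; M <- 40
  theta <- matrix(seq(0, 1, length.out = om), ncol = 1)
  mu <- cbind(theta[, 1])
  bank <- array(rnorm(om * M, rep(mu[, 1], M), 0.2), c(om, M, 1))
  g <- fake_grid(theta, mu, matrix(0.04), t_prepaid = 100, bank = bank)
  r <- abc_posterior_grid(g, 0.5, 1000, n_keep = 100) # bank length is 100
  unscaled <- g$theta[r$details$kept_source, 1]
  draws <- r$posterior$draws[, 1]
  expect_equal(mean(draws), mean(unscaled), tolerance = 1e-12)
  expect_equal(var(draws) / var(unscaled), 100 / 1000, tolerance = 1e-9)
})

test_that("undersized banks degrade with a warning, keeping everything", {
  om <- 4; M <- 3
  theta <- matrix(seq(0, 1, length.out = om), ncol = 1)
  bank <- array(rnorm(om * M), c(om, M, 1))
  g <- fake_grid(theta, cbind(theta[, 1]), matrix(1), t_prepaid = 100,
                 bank = bank)
  expect_warning(r <- abc_posterior_grid(g, 0.5, 100, n_keep = 1000),
                 "keeping all")
  expect_lte(nrow(r$posterior$draws), om * M)
})

test_that("minimum-volume ellipses contain their points; degenerate sets box", {
  set.seed(12)
  for (i in 1:10) {
    K <- sample(2:4, 1)
    P <- matrix(rnorm(40 * K), ncol = K)
    e <- mvee(P)
    expect_equal(e$kind, "ellipse")
    q <- apply(P, 1, function(p) {
      d <- p - e$center
      drop(t(d) %*% e$shape %*% d)
    })
    expect_true(all(q <= 1 + 1e-9))
    # volume consistent with the shape determinant
    K_ <- ncol(P)
    expect_equal(e$volume,
                 pi^(K_ / 2) / gamma(K_ / 2 + 1) / sqrt(det(e$shape)),
                 tolerance = 1e-8)
    # sampled points stay inside
    s <- e$sample(500)
    qs <- apply(s, 1, function(p) {
      d <- p - e$center
      drop(t(d) %*% e$shape %*% d)
    })
    expect_true(all(qs <= 1 + 1e-9))
  }
  # collinear points fall back to a box
  P <- cbind(1:10, 2 * (1:10))
  expect_equal(mvee(P)$kind, "box")
})

test_that("posterior intervals follow the weighted quantile rule", {
  s <- posterior_sample(matrix(rep(3, 10), ncol = 1))
  expect_equal(unname(posterior_interval(s)[1, ]), c(3, 3))
  s2 <- posterior_sample(matrix(1:1000, ncol = 1))
  expect_equal(unname(posterior_interval(s2, 0.95)[1, ]),
               unname(quantile(1:1000, c(0.025, 0.975), type = 7)))
  w <- c(rep(1e-9, 999), 1)
  s3 <- posterior_sample(matrix(1:1000, ncol = 1), weights = w)
  iv <- posterior_interval(s3, 0.95)
  expect_lt(abs(iv[1, 1] - 1000), 1.01)
  expect_lt(abs(iv[1, 2] - 1000), 1.01)
})

test_that("surrogate ABC refines the grid posterior on the toy model", {
  fix <- unit_toy_grid()
  g <- fix$grid
  m <- fix$model
  s_obs <- m$summarize(prepaid:::with_seed(13,
                                           m$simulate_data(c(mu = 4.3), 50)))
  set.seed(13)
  r <- abc_posterior_svm(g, s_obs, 50, n_neighbors = 40, n_keep = 200,
                         n_sample = 200, n_trim = 1000, max_iter = 10)
  expect_s3_class(r$posterior, "posterior_sample")
  # worst kept distance never increases after the kept set saturates
  for (tr in r$details$worst_trace)
    if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-9))
  # draw weights are proportional to originating ellipse volumes
  vols <- r$details$volumes
  w <- r$posterior$weights
  src <- r$posterior$source
  if (length(unique(src)) > 1) {
    w1 <- w[src == unique(src)[1]][1]
    w2 <- w[src == unique(src)[2]][1]
    expect_equal(w1 / w2, vols[unique(src)[1]] / vols[unique(src)[2]],
                 tolerance = 1e-9)
  }
  # ABC posterior mean approaches the sufficient statistic
  expect_lt(abs(unname(r$estimate$theta_hat) - as.numeric(s_obs)), 0.5)
  rg <- abc_posterior_grid(g, s_obs, 50, n_keep = 200)
  expect_lt(abs(unname(rg$estimate$theta_hat) - as.numeric(s_obs)), 0.5)
})
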