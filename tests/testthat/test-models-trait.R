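test_that("filtering function has the stated limits", {
  p <- c(A = 3, h = 50, sigma_f = 5)
  expect_equal(filtering_value(50, p), 4) # u = h -> 1 + A
  expect_equal(filtering_value(-1e6, p), 1)
  expect_equal(filtering_value(123, c(A = 0, h = 50, sigma_f = 5)), 1)
  expect_error(filtering_value(1, c(A = 1, h = 0, sigma_f = 0)))
})

test_that("community size is conserved at every snapshot", {
  cfg <- trait_config(S = 60, J = 37, thinning = 5)
  for (seed in 1:3) {
    th <- c(I = exp(runif(1, 3, 5)), A = runif(1, 0.1, 5),
            h = runif(1, 0, 100), sigma_f = runif(1, 0.5, 25))
    cs <- simulate_trait(th, cfg, 20, seed = seed)
    expect_true(all(rowSums(cs$abundance) == 37))
    expect_true(all(cs$abundance >= 0))
  }
})

test_that("trait summaries match their definitions", {
  trait <- seq(0, 100, length.out = 11)
  # single species
  ab <- rep(0L, 11); ab[4] <- 20L
  s <- summarize_trait(list(abundance = ab, trait = trait))
  expect_equal(unname(s[c("richness", "shannon")]), c(1, 0))
  expect_equal(unname(s["trait_mean"]), trait[4])
  # n equally abundant species -> Shannon = log(n)
  ab <- rep(0L, 11); ab[c(1, 4, 6, 9)] <- 5L
  s <- summarize_trait(list(abundance = ab, trait = trait))
  expect_equal(unname(s["shannon"]), log(4))
  expect_equal(unname(s["richness"]), 4)
  # symmetric trait distribution -> zero skewness
  ab <- rep(0L, 11); ab[c(3, 6, 9)] <- c(4L, 7L, 4L)
  s <- summarize_trait(list(abundance = ab, trait = trait))
  expect_equal(unname(s["trait_skew"]), 0)
  expect_equal(unname(s["trait_mean"]), 50)
})

test_that("summaries are invariant to species relabeling that keeps traits", {
  set.seed(3)
  trait <- seq(0, 100, length.out = 40)
  ab <- rmultinom(1, 60, rep(1 / 40, 40))[, 1]
  s1 <- summarize_trait(list(abundance = ab, trait = trait))
  perm <- sample(40)
  s2 <- summarize_trait(list(abundance = ab[perm], trait = trait[perm]))
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-12)
})

test_that("multi-snapshot summaries average the per-snapshot statistics", {
  cfg <- trait_config(S = 30, J = 20, thinning = 3)
  cs <- simulate_trait(c(I = 60, A = 1, h = 50, sigma_f = 5), cfg, 6,
                       seed = 8)
  per <- vapply(1:6, function(k)
    as.numeric(summarize_trait(list(abundance = cs$abundance[k, ],
                                    trait = cs$trait))), numeric(4))
  expect_equal(as.numeric(summarize_trait(cs)), rowMeans(per),
               tolerance = 1e-12)
})

test_that("snapshot statistics from the C++ path match the R summarizer", {
  cfg <- trait_config(S = 40, J = 25, thinning = 4)
  th <- c(I = 100, A = 2, h = 30, sigma_f = 3)
  states <- simulate_trait(th, cfg, 10, seed = 21)
  stats <- prepaid:::with_seed(21,
    prepaid:::trait_sim_stats_cpp(th[["I"]], th[["A"]], th[["h"]],
                                  th[["sigma_f"]], cfg$S, cfg$J,
                                  cfg$thinning, 10L, 10L * cfg$J))
  for (k in 1:10)
    expect_equal(as.numeric(summarize_trait(
      list(abundance = states$abundance[k, ], trait = states$trait))),
      unname(stats[k, ]), tolerance = 1e-10)
})

test_that("strong environmental filtering reduces stationary richness", {
  cfg <- trait_config(S = 200, J = 100, thinning = 100)
  rich <- function(A, sf, seed) {
    cs <- simulate_trait(c(I = 100, A = A, h = 50, sigma_f = sf), cfg,
                         n_snapshots = 20, seed = seed, burnin = 1e4)
    mean(rowSums(cs$abundance > 0))
  }
  strong <- mean(vapply(1:3, function(s) rich(5, 0.5, s), numeric(1)))
  weak <- mean(vapply(1:3, function(s) rich(1e-6, 0.5, s), numeric(1)))
  expect_lt(strong, weak)
})

test_that("immigration probability has the stated closed form", {
  # I = J + 1 makes immigration and local replacement equally likely; with
  # A = 0 every immigrant is a uniform pool species, so the long-run
  # richness under I = 501, J = 500 is far higher than under tiny I
  cfg <- trait_config(S = 100, J = 50, thinning = 50)
  rich <- function(I, seed) {
    cs <- simulate_trait(c(I = I, A = 1e-9, h = 50, sigma_f = 5), cfg,
                         n_snapshots = 10, seed = seed, burnin = 5000)
    mean(rowSums(cs$abundance > 0))
  }
  expect_gt(rich(51, 1), rich(0.5, 1))
})
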