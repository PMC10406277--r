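# Sampler correctness: initialization, conjugate full conditionals,
# multiple-try Metropolis stationarity, latent updates, chain management.

test_that("initialization follows the quantile threshold and support rule", {
  tab <- link_stats_table(t_f = 1:100, t_s = runif(100))
  init <- blfdr_initialize(tab, blfdr_config(pi0_init = 0.94))
  # 94th percentile of 1..100 (linear interpolation) is 94.06
  expect_equal(init$lambda0, 94.06)
  expect_equal(sum(init$w), 6L)
  expect_equal(which(init$w == 1), 95:100)
  expect_equal(init$alpha, c(0, 0))
  expect_equal(init$beta, 0.1)
  expect_equal(init$sigma0_sq, 1.0)
  # pi0_init = 1 puts the threshold at the maximum: a single member
  init1 <- suppressWarnings(blfdr_initialize(tab, blfdr_config(pi0_init = 1.0)))
  expect_equal(sum(init1$w), 1L)
  expect_equal(which(init1$w == 1), 100L)
  # statistics all below mu1 are never initialized alternative
  tab2 <- link_stats_table(t_f = seq(0.01, 0.6, length.out = 50),
                           t_s = runif(50))
  expect_warning(init2 <- blfdr_initialize(tab2, blfdr_config()))
  expect_equal(sum(init2$w), 0L)
})

test_that("gamma-rate full conditional matches its analytic distribution", {
  tab <- link_stats_table(t_f = c(1.2, 2.0, 3.5), t_s = c(0.5, 1.0, 2.0))
  h <- blfdr_hyper()
  alpha <- c(0.3, 0.2)
  w <- c(1L, 1L, 1L)
  sh_true <- h$a_beta + sum(gamma_shape(tab$t_s, alpha))
  rt_true <- h$b_beta + sum(tab$t_f - h$mu1)
  set.seed(100)
  draws <- run_partial_chain(tab, chain_init(tab, w = w, alpha = alpha),
                             n_iter = 1e5,
                             update = list(w = FALSE, alpha = FALSE,
                                           gamma = FALSE, sigma = FALSE))
  b <- draws$draws[, "beta"]
  ks <- suppressWarnings(stats::ks.test(b, stats::pgamma, shape = sh_true,
                                        rate = rt_true))
  expect_lt(unname(ks$statistic), 0.02)
  expect_equal(mean(b), sh_true / rt_true, tolerance = 0.02)
  # empty alternative set reduces to the prior
  set.seed(101)
  d0 <- run_partial_chain(tab, chain_init(tab), n_iter = 2e4,
                          update = list(w = FALSE, alpha = FALSE,
                                        gamma = FALSE, sigma = FALSE))
  ks0 <- suppressWarnings(stats::ks.test(d0$draws[, "beta"], stats::pgamma,
                                         shape = 1, rate = 1))
  expect_lt(unname(ks0$statistic), 0.02)
})

test_that("null-scale full conditional matches its inverse-gamma law", {
  tab <- link_stats_table(t_f = c(0.5, 1.1, 1.6, 2.1), t_s = rep(0.3, 4))
  h <- blfdr_hyper()
  shp <- h$a_sigma + 4 / 2
  scl <- h$b_sigma + 0.5 * sum(tab$t_f^2)
  set.seed(102)
  draws <- run_partial_chain(tab, chain_init(tab), n_iter = 1e5,
                             update = list(w = FALSE, alpha = FALSE,
                                           gamma = FALSE, beta = FALSE))
  s2 <- draws$draws[, "sigma0_sq"]
  # P(sigma^2 <= x) = P(G >= scl / x) for G ~ Gamma(shp, rate = scl-free)
  pinvgamma <- function(x, shape, scale)
    stats::pgamma(scale / x, shape = shape, lower.tail = FALSE)
  ks <- suppressWarnings(stats::ks.test(s2, pinvgamma, shape = shp,
                                        scale = scl))
  expect_lt(unname(ks$statistic), 0.02)
  expect_equal(mean(s2), scl / (shp - 1), tolerance = 0.02)
})

test_that("the inverse-gamma prior on the null scale has mean and
           variance one", {
  dens <- function(x) 2^3 / gamma(3) * x^(-4) * exp(-2 / x)
  expect_equal(integrate(dens, 0, Inf)$value, 1, tolerance = 1e-7)
  m1 <- integrate(function(x) x * dens(x), 0, Inf)$value
  m2 <- integrate(function(x) x^2 * dens(x), 0, Inf)$value
  expect_equal(m1, 1, tolerance = 1e-6)
  expect_equal(m2 - m1^2, 1, tolerance = 1e-5)
})

test_that("gamma-block MTM matches 2-D grid integration of its target", {
  tab <- link_stats_table(t_f = c(0.8, 1.4, 2.6, 3.2, 0.4),
                          t_s = c(0.3, 1.8, 0.7, 2.5, 1.1))
  w <- c(0L, 1L, 0L, 1L, 0L)
  ref <- gamma_grid_moments(tab$t_s, w)
  set.seed(103)
  draws <- run_partial_chain(tab, chain_init(tab, w = w), n_iter = 4e4,
                             update = list(w = FALSE, alpha = FALSE,
                                           beta = FALSE, sigma = FALSE))
  g <- draws$draws[, c("gamma0", "gamma1")]
  expect_lt(max(abs(colMeans(g) - ref$mean)), 0.1)
  expect_lt(max(abs(apply(g, 2, var) - ref$var) / ref$var), 0.25)
  expect_gt(draws$accept_gamma, 0.05)
  expect_lt(draws$accept_gamma, 0.95)
})

test_that("with no members the gamma-block posterior pushes the intercept
           negative", {
  set.seed(104)
  tab <- link_stats_table(t_f = runif(30, 0.8, 3), t_s = runif(30, 0, 2))
  draws <- run_partial_chain(tab, chain_init(tab), n_iter = 2e4,
                             update = list(w = FALSE, alpha = FALSE,
                                           beta = FALSE, sigma = FALSE))
  expect_lt(mean(draws$draws[, "gamma0"]), 0)
})

test_that("alpha-block MTM samples its prior when no links are
           alternative", {
  tab <- link_stats_table(t_f = c(1, 2), t_s = c(0.5, 1))
  set.seed(105)
  draws <- run_partial_chain(tab, chain_init(tab), n_iter = 5e4,
                             update = list(w = FALSE, gamma = FALSE,
                                           beta = FALSE, sigma = FALSE),
                             mtm_scale = 1.5)
  a <- draws$draws[, c("alpha0", "alpha1")]
  expect_lt(max(abs(colMeans(a))), 0.12)
  expect_lt(max(abs(apply(a, 2, var) - 1)), 0.2)
})

test_that("single-try and multiple-try Metropolis share a stationary
           distribution", {
  tab <- link_stats_table(t_f = c(0.8, 1.4, 2.6, 3.2, 0.4),
                          t_s = c(0.3, 1.8, 0.7, 2.5, 1.1))
  w <- c(0L, 1L, 0L, 1L, 0L)
  set.seed(106)
  d1 <- run_partial_chain(tab, chain_init(tab, w = w), n_iter = 4e4,
                          update = list(w = FALSE, alpha = FALSE,
                                        beta = FALSE, sigma = FALSE),
                          mtm_tries = 1L)
  set.seed(107)
  d5 <- run_partial_chain(tab, chain_init(tab, w = w), n_iter = 4e4,
                          update = list(w = FALSE, alpha = FALSE,
                                        beta = FALSE, sigma = FALSE),
                          mtm_tries = 5L)
  expect_lt(max(abs(colMeans(d1$draws[, c("gamma0", "gamma1")]) -
                    colMeans(d5$draws[, c("gamma0", "gamma1")]))), 0.12)
})

test_that("latent membership probabilities complement the posterior null
           probability and respect the support", {
  tab <- tiny_table()
  p <- ref_params()
  init <- chain_init(tab, alpha = p$alpha, gamma = p$gamma, beta = p$beta,
                     sigma0_sq = p$sigma0_sq)
  set.seed(108)
  out <- run_partial_chain(tab, init, n_iter = 1L,
                           update = list(alpha = FALSE, gamma = FALSE,
                                         beta = FALSE, sigma = FALSE))
  expect_equal(out$p_mean, 1 - blfdr_posterior(tab$t_f, tab$t_s, p),
               tolerance = 1e-12)
  # statistics below mu1 never become members
  expect_true(all(out$w_final[tab$t_f <= 0.674] == 0L))
  # pi1 -> 0 limit zeroes every membership probability
  init0 <- chain_init(tab, gamma = c(-500, 0), beta = p$beta,
                      sigma0_sq = p$sigma0_sq)
  out0 <- run_partial_chain(tab, init0, n_iter = 1L,
                            update = list(alpha = FALSE, gamma = FALSE,
                                          beta = FALSE, sigma = FALSE))
  expect_equal(out0$p_mean, rep(0, 5))
})

test_that("full fits are reproducible and correctly shaped", {
  set.seed(109)
  sim <- simulate_from_model(400, ref_params())
  cfg <- blfdr_config(n_chains = 2L, n_iter = 1500L, burn_in = 500L,
                      thin = 5L, seed = 42L)
  f1 <- suppressWarnings(blfdr_fit(sim$table, cfg))
  f2 <- suppressWarnings(blfdr_fit(sim$table, cfg))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$summary, f2$summary)
  expect_equal(f1$n_retained, 2 * floor((1500 - 500) / 5))
  expect_equal(nrow(f1$summary), 6L)
  expect_true(all(f1$summary$ci_lower <= f1$summary$median))
  expect_true(all(f1$summary$median <= f1$summary$ci_upper))
  expect_true(all(is.finite(f1$summary$rhat)))
  expect_true(all(f1$blfdr >= 0 & f1$blfdr <= 1))
  expect_equal(f1$blfdr, blfdr_from_fit(sim$table, f1))
  # the full estimation protocol retains 9,000 draws across three chains
  full <- blfdr_config("full")
  expect_equal(full$n_chains *
                 floor((full$n_iter - full$burn_in) / full$thin), 9000)
})

test_that("retained draws export as delimited text", {
  set.seed(110)
  sim <- simulate_from_model(200, ref_params())
  cfg <- blfdr_config(n_chains = 1L, n_iter = 600L, burn_in = 100L,
                      thin = 10L, seed = 1L)
  fit <- suppressWarnings(blfdr_fit(sim$table, cfg))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read.csv(path)
  expect_equal(nrow(back), fit$n_retained)
  expect_true(all(c("chain", "iter", "alpha0", "sigma0_sq") %in%
                    names(back)))
})
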