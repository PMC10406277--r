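# Shared fixtures: small deterministic instances and reference values.

# posterior medians reported for the motivating study; used as a realistic
# parameter point for oracles and recovery checks
ref_params <- function() {
  blfdr_params(alpha = c(1.120, -0.018), gamma = c(-2.313, -0.692),
               beta = 2.214, sigma0_sq = 1.100)
}

tiny_table <- function() {
  link_stats_table(t_f = c(0.3, 0.9, 1.7, 2.8, 0.5),
                   t_s = c(0.2, 1.1, 0.4, 2.0, 0.8))
}

# independent straight-arithmetic evaluation of the posterior null
# probability (no log-space tricks); the oracle for blfdr_posterior
blfdr_arith <- function(t_f, t_s, params, hyper = blfdr_hyper()) {
  pi1 <- exp(params$gamma[1] + params$gamma[2] * t_s)
  pi1 <- pi1 / (1 + pi1)
  pi0 <- 1 - pi1
  f0 <- 2 / sqrt(2 * pi * params$sigma0_sq) *
    exp(-t_f^2 / (2 * params$sigma0_sq))
  sh <- exp(params$alpha[1] + params$alpha[2] * t_s)
  f1 <- ifelse(t_f > hyper$mu1,
               params$beta^sh / gamma(sh) * (t_f - hyper$mu1)^(sh - 1) *
                 exp(-params$beta * (t_f - hyper$mu1)),
               0)
  pi0 * f0 / (pi0 * f0 + pi1 * f1)
}

# run the compiled sampler with a subset of updates enabled, returning the
# matrix of retained draws (used by the conjugacy / MTM distribution tests)
run_partial_chain <- function(table, init, n_iter, update,
                              hyper = blfdr_hyper(), thin = 1L,
                              burn_in = 0L, mtm_tries = 5L,
                              mtm_scale = 0.5, adapt = FALSE) {
  cfg <- blfdr_config(n_chains = 1L, n_iter = n_iter, burn_in = burn_in,
                      thin = thin, mtm_tries = mtm_tries,
                      mtm_scale_alpha = mtm_scale, mtm_scale_gamma = mtm_scale,
                      adapt = adapt)
  blfdr:::run_single_chain(table, init, cfg, hyper, update = update)
}

chain_init <- function(table, w = NULL, alpha = c(0, 0), gamma = c(0, 0),
                       beta = 1, sigma0_sq = 1) {
  if (is.null(w)) w <- integer(nrow(table))
  list(alpha = alpha, gamma = gamma, beta = beta, sigma0_sq = sigma0_sq,
       w = as.integer(w))
}

# largest rejection set with mean score <= q, by exhaustive search over all
# subsets; the brute-force oracle for the compound decision rule
brute_force_reject <- function(scores, q) {
  m <- length(scores)
  best <- 0L
  for (mask in seq_len(2^m) - 1L) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    k <- sum(sel)
    if (k > best && mean(scores[sel]) <= q) best <- k
  }
  best
}

# 2-D grid integration of the gamma-block posterior (prior x logistic
# likelihood given w); independent of the sampler
gamma_grid_moments <- function(t_s, w, lim = 8, n_grid = 241) {
  g0 <- seq(-lim, lim, length.out = n_grid)
  g1 <- seq(-lim, lim, length.out = n_grid)
  lp <- outer(g0, g1, function(a, b) {
    vapply(seq_along(a), function(i) {
      eta <- a[i] + b[i] * t_s
      -0.5 * (a[i]^2 + b[i]^2) + sum(w * eta - log1p(exp(eta)))
    }, numeric(1))
  })
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  m0 <- sum(p * outer(g0, g1, function(a, b) a))
  m1 <- sum(p * outer(g0, g1, function(a, b) b))
  v0 <- sum(p * outer(g0, g1, function(a, b) (a - m0)^2))
  v1 <- sum(p * outer(g0, g1, function(a, b) (b - m1)^2))
  list(mean = c(m0, m1), var = c(v0, v1))
}
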