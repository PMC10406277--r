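# Chain management for the Gibbs sampler: configuration presets,
# initialization, multi-chain runs, posterior summaries and diagnostics.

#' Sampler configuration
#'
#' The `"full"` preset is the complete estimation protocol (3 chains of 325,000
#' iterations, 25,000 burn-in, thinning 100: 3 x 3,000 = 9,000 retained
#' draws). The `"desk"` preset (3 chains of 20,000 iterations, 5,000
#' burn-in, thinning 10) is a desk-scale profile for interactive work and
#' tests.
#'
#' @param preset `"desk"` or `"full"`; individual arguments override the
#'   preset.
#' @param n_chains Number of independent chains.
#' @param n_iter Iterations per chain.
#' @param burn_in Burn-in iterations discarded per chain (< `n_iter`).
#' @param thin Thinning interval; retained draws per chain =
#'   `floor((n_iter - burn_in) / thin)`.
#' @param pi0_init Initial null proportion; sets the initial membership
#'   threshold at the corresponding upper quantile of `t_f`.
#' @param beta_init,sigma0_sq_init Initial values of beta and sigma0^2.
#' @param mtm_tries Number of candidates per multiple-try Metropolis step.
#' @param mtm_scale_alpha,mtm_scale_gamma Initial proposal scales for the
#'   two coefficient blocks (adapted during burn-in, frozen afterwards).
#' @param adapt Adapt proposal scales during burn-in?
#' @param seed Integer seed; chains use distinct sub-seeds derived from it.
#' @return An object of class `blfdr_config`.
#' @export
blfdr_config <- function(preset = c("desk", "full"), n_chains = NULL,
                         n_iter = NULL, burn_in = NULL, thin = NULL,
                         pi0_init = 0.94, beta_init = 0.1,
                         sigma0_sq_init = 1.0, mtm_tries = 5L,
                         mtm_scale_alpha = 0.1, mtm_scale_gamma = 0.1,
                         adapt = TRUE, seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    desk = list(n_chains = 3L, n_iter = 20000L, burn_in = 5000L, thin = 10L),
    full = list(n_chains = 3L, n_iter = 325000L, burn_in = 25000L,
                thin = 100L))
  cfg <- list(preset = preset,
              n_chains = as.integer(n_chains %||% def$n_chains),
              n_iter = as.integer(n_iter %||% def$n_iter),
              burn_in = as.integer(burn_in %||% def$burn_in),
              thin = as.integer(thin %||% def$thin),
              pi0_init = pi0_init, beta_init = beta_init,
              sigma0_sq_init = sigma0_sq_init,
              mtm_tries = as.integer(mtm_tries),
              mtm_scale_alpha = mtm_scale_alpha,
              mtm_scale_gamma = mtm_scale_gamma,
              adapt = isTRUE(adapt), seed = as.integer(seed))
  stopifnot(cfg$n_chains >= 1L, cfg$burn_in >= 0L, cfg$burn_in < cfg$n_iter,
            cfg$thin >= 1L, cfg$mtm_tries >= 1L,
            pi0_init > 0, pi0_init <= 1, beta_init > 0, sigma0_sq_init > 0)
  structure(cfg, class = "blfdr_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize a chain state
#'
#' Sets alpha = (0, 0), beta, sigma0^2 and pi0 to their configured starting
#' values; the membership threshold lambda is the empirical `pi0_init`
#' quantile of `t_f` (linear interpolation), and `w = 1` for links with
#' `t_f >= lambda` that also exceed `mu1` (the alternative support bound).
#' The initial gamma is the maximum-likelihood logistic regression of `w`
#' on `t_s`; if `w` is degenerate (all 0 or all 1) or the fit fails, gamma
#' falls back to `(qlogis(clipped mean(w)), 0)` with a warning.
#'
#' @param table A [link_stats_table()].
#' @param config A [blfdr_config()].
#' @param hyper A [blfdr_hyper()].
#' @return A list with elements `alpha`, `gamma`, `beta`, `sigma0_sq`, `w`,
#'   `lambda0`.
#' @export
blfdr_initialize <- function(table, config = blfdr_config(),
                             hyper = blfdr_hyper()) {
  t_f <- table$t_f
  lambda0 <- unname(quantile(t_f, probs = config$pi0_init, type = 7))
  w0 <- as.integer(t_f >= lambda0 & t_f > hyper$mu1)
  gamma0 <- tryCatch({
    if (length(unique(w0)) < 2L) stop("degenerate w")
    fit <- suppressWarnings(glm(w0 ~ table$t_s, family = binomial()))
    if (!fit$converged) stop("logistic regression did not converge")
    unname(coef(fit))
  }, error = function(e) {
    pbar <- min(max(mean(w0), 0.01), 0.99)
    warning("initial logistic regression unavailable (", conditionMessage(e),
            "); falling back to intercept-only gamma(0)", call. = FALSE)
    c(qlogis(pbar), 0)
  })
  list(alpha = c(0, 0), gamma = gamma0, beta = config$beta_init,
       sigma0_sq = config$sigma0_sq_init, w = w0, lambda0 = lambda0)
}

# low-level single-chain runner around the compiled sweep
run_single_chain <- function(table, init, config, hyper,
                             update = list()) {
  up <- modifyList(list(w = TRUE, alpha = TRUE, gamma = TRUE, beta = TRUE,
                        sigma = TRUE), update)
  hyp <- list(mu1 = hyper$mu1, a_beta = hyper$a_beta, b_beta = hyper$b_beta,
              a_sigma = hyper$a_sigma, b_sigma = hyper$b_sigma,
              P_alpha = solve(hyper$Sigma_alpha),
              P_gamma = solve(hyper$Sigma_gamma), nu = hyper$nu)
  ctrl <- list(n_iter = config$n_iter, burn_in = config$burn_in,
               thin = config$thin, mtm_tries = config$mtm_tries,
               mtm_scale_alpha = config$mtm_scale_alpha,
               mtm_scale_gamma = config$mtm_scale_gamma,
               adapt = config$adapt,
               update_w = up$w, update_alpha = up$alpha,
               update_gamma = up$gamma, update_beta = up$beta,
               update_sigma = up$sigma)
  .gibbs_chain_cpp(table$t_f, table$t_s, hyp, init, ctrl)
}

#' Fit the BLfdr mixture model by MCMC
#'
#' Runs `n_chains` independent Gibbs chains (each sweeping latent
#' membership, the alpha and gamma blocks by multiple-try Metropolis, and
#' the conjugate beta and sigma0^2 draws), pools retained draws, and
#' summarises them by posterior medians with 95% credible intervals,
#' split-chain R-hat, effective sample sizes and MTM acceptance rates.
#' Per-link BLfdr values are the plug-in posterior-null probabilities at
#' the posterior medians.
#'
#' @param table A [link_stats_table()].
#' @param config A [blfdr_config()].
#' @param hyper A [blfdr_hyper()].
#' @return An object of class `blfdr_fit`: list with `draws` (data.frame of
#'   retained draws with `chain` and `iter` columns), `summary` (per
#'   parameter: median, CI bounds, rhat, ess), `params` (posterior-median
#'   [blfdr_params()]), `blfdr` (per-link values), `accept` (block
#'   acceptance rates), `p_mean` (posterior-mean membership probability per
#'   link), plus the inputs' metadata.
#' @export
blfdr_fit <- function(table, config = blfdr_config(), hyper = blfdr_hyper()) {
  stopifnot(inherits(table, "link_stats_table"))
  par_names <- c("alpha0", "alpha1", "gamma0", "gamma1", "beta", "sigma0_sq")
  chains <- vector("list", config$n_chains)
  sub_seeds <- derive_seeds(config$seed, config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(sub_seeds[ch])
    init <- blfdr_initialize(table, config, hyper)
    chains[[ch]] <- run_single_chain(table, init, config, hyper)
  }
  draw_list <- lapply(chains, `[[`, "draws")
  pooled <- do.call(rbind, draw_list)
  n_ret <- nrow(draw_list[[1]])
  draws <- data.frame(chain = rep(seq_len(config$n_chains), each = n_ret),
                      iter = rep(seq_len(n_ret), config$n_chains), pooled)

  summ <- data.frame(
    parameter = par_names,
    median = apply(pooled, 2, median),
    ci_lower = apply(pooled, 2, quantile, 0.025),
    ci_upper = apply(pooled, 2, quantile, 0.975),
    rhat = vapply(par_names, function(p)
      split_rhat(lapply(draw_list, function(d) d[, p])), numeric(1)),
    ess = vapply(par_names, function(p)
      ess_multi(lapply(draw_list, function(d) d[, p])), numeric(1)),
    row.names = NULL)
  if (any(is.finite(summ$rhat) & summ$rhat > 1.1))
    warning("split R-hat exceeds 1.1 for: ",
            paste(summ$parameter[is.finite(summ$rhat) & summ$rhat > 1.1],
                  collapse = ", "),
            "; chains may not have converged", call. = FALSE)

  med <- setNames(summ$median, summ$parameter)
  params <- blfdr_params(alpha = med[c("alpha0", "alpha1")],
                         gamma = med[c("gamma0", "gamma1")],
                         beta = med[["beta"]],
                         sigma0_sq = med[["sigma0_sq"]])
  p_mean <- Reduce(`+`, lapply(chains, `[[`, "p_mean")) / config$n_chains
  structure(list(
    draws = draws, summary = summ, params = params,
    blfdr = blfdr_posterior(table$t_f, table$t_s, params, hyper),
    accept = list(
      alpha = mean(vapply(chains, `[[`, numeric(1), "accept_alpha")),
      gamma = mean(vapply(chains, `[[`, numeric(1), "accept_gamma"))),
    p_mean = p_mean, n_retained = nrow(pooled),
    config = config, hyper = hyper, m = nrow(table)),
    class = "blfdr_fit")
}

# deterministic sub-seeds below 2^31 from a master seed
derive_seeds <- function(seed, n) {
  (as.double(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629 + 1
}

#' Plug-in BLfdr values from a fitted model
#'
#' Evaluates the posterior-null probability of each link at the posterior
#' medians of a [blfdr_fit()] (possibly for a new table of statistics).
#'
#' @param table A [link_stats_table()].
#' @param fit A `blfdr_fit` object.
#' @return Numeric vector of BLfdr values in \[0, 1\].
#' @export
blfdr_from_fit <- function(table, fit) {
  stopifnot(inherits(fit, "blfdr_fit"))
  blfdr_posterior(table$t_f, table$t_s, fit$params, fit$hyper)
}

#' @export
print.blfdr_fit <- function(x, ...) {
  cat(sprintf(
    "BLfdr mixture model fit: %d links, %d chains, %d retained draws\n",
    x$m, x$config$n_chains, x$n_retained))
  cat(sprintf("MTM acceptance: alpha %.2f, gamma %.2f\n",
              x$accept$alpha, x$accept$gamma))
  print(transform(x$summary, median = signif(median, 4),
                  ci_lower = signif(ci_lower, 4),
                  ci_upper = signif(ci_upper, 4),
                  rhat = round(rhat, 3), ess = round(ess)))
  invisible(x)
}

#' Export retained draws as delimited text
#'
#' One row per retained draw; columns are the chain id, the within-chain
#' retained-draw index and the six model parameters.
#'
#' @param fit A `blfdr_fit`.
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path, sep = ",") {
  stopifnot(inherits(fit, "blfdr_fit"))
  write.table(fit$draws, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- convergence diagnostics ------------------------------------------

# split-chain potential scale reduction factor
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via Geyer's initial monotone positive sequence,
# pooled across chains
ess_multi <- function(chain_list) {
  sum(vapply(chain_list, ess_single, numeric(1)))
}

ess_single <- function(x) {
  n <- length(x)
  if (n < 10L || var(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
             demean = TRUE)$acf[-1]
  # sum consecutive pairs while positive and monotone non-increasing
  s <- 0; prev <- Inf
  for (k in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[k] + rho[k + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    s <- s + pair
    prev <- pair
  }
  max(1, n / (1 + 2 * s))
}
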