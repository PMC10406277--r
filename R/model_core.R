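# Two-group mixture for absolute FC statistics: folded-normal null,
# shifted-gamma alternative with SC-modulated shape, logistic prior.

#' Hyperparameters of the BLfdr mixture model
#'
#' Fixed constants of the model: the alternative location `mu1` (the median
#' of the standard folded normal, below which a link is treated as null a
#' priori), the weakly informative Gamma/Inverse-Gamma priors on the rate
#' `beta` and the null scale `sigma0_sq`, the bivariate-normal prior
#' covariances for the `alpha` (gamma-shape) and `gamma` (logistic)
#' coefficient blocks, and the degrees of freedom `nu` of the multivariate-t
#' Metropolis proposal. The null location is always 0 (half-normal null) and
#' is not user-settable.
#'
#' Defaults: `mu1 = 0.674`; Gamma(1, 1) on beta and Inverse-Gamma(3, 2) on
#' sigma0^2, both with mean 1 and variance 1; identity prior covariances;
#' `nu = 4`.
#'
#' @param mu1 Positive location of the shifted-gamma alternative.
#' @param a_beta,b_beta Shape and rate of the Gamma prior on `beta`.
#' @param a_sigma,b_sigma Shape and scale of the Inverse-Gamma prior on
#'   `sigma0_sq`.
#' @param Sigma_alpha,Sigma_gamma 2x2 symmetric positive-definite prior
#'   covariance matrices.
#' @param nu Positive degrees of freedom of the t proposal.
#' @return An object of class `blfdr_hyper`.
#' @export
blfdr_hyper <- function(mu1 = 0.674, a_beta = 1, b_beta = 1,
                        a_sigma = 3, b_sigma = 2,
                        Sigma_alpha = diag(2), Sigma_gamma = diag(2),
                        nu = 4) {
  stopifnot(is.numeric(mu1), length(mu1) == 1L, mu1 > 0)
  for (v in list(a_beta, b_beta, a_sigma, b_sigma, nu))
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("hyperparameters must be positive scalars")
  check_spd <- function(S, name) {
    if (!is.matrix(S) || !all(dim(S) == 2L) ||
        max(abs(S - t(S))) > 1e-10 || any(eigen(S, TRUE)$values <= 0))
      stop(sprintf("%s must be a 2x2 symmetric positive-definite matrix", name))
  }
  check_spd(Sigma_alpha, "Sigma_alpha")
  check_spd(Sigma_gamma, "Sigma_gamma")
  structure(list(mu0 = 0, mu1 = mu1, a_beta = a_beta, b_beta = b_beta,
                 a_sigma = a_sigma, b_sigma = b_sigma,
                 Sigma_alpha = Sigma_alpha, Sigma_gamma = Sigma_gamma,
                 nu = as.integer(nu)),
            class = "blfdr_hyper")
}

#' Model parameters of the BLfdr mixture
#'
#' @param alpha Numeric pair (alpha0, alpha1): log-linear coefficients of the
#'   gamma shape in the SC statistic.
#' @param gamma Numeric pair (gamma0, gamma1): logistic coefficients of the
#'   prior alternative probability in the SC statistic.
#' @param beta Positive gamma rate of the alternative density.
#' @param sigma0_sq Positive scale of the folded-normal null.
#' @return An object of class `blfdr_params`.
#' @export
blfdr_params <- function(alpha, gamma, beta, sigma0_sq) {
  stopifnot(length(alpha) == 2L, length(gamma) == 2L,
            is.finite(alpha), is.finite(gamma))
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("beta must be a positive scalar")
  if (!is.numeric(sigma0_sq) || length(sigma0_sq) != 1L || sigma0_sq <= 0)
    stop("sigma0_sq must be a positive scalar")
  structure(list(alpha = as.numeric(alpha), gamma = as.numeric(gamma),
                 beta = beta, sigma0_sq = sigma0_sq),
            class = "blfdr_params")
}

#' Folded-normal null density (zero location)
#'
#' Density of |X| for X ~ Normal(0, sigma0_sq): the half-normal
#' 2 (2 pi sigma0^2)^{-1/2} exp(-t^2 / (2 sigma0^2)) on t >= 0. With zero
#' location the two reflected terms of the folded normal coincide, so the
#' density is the single half-normal term doubled.
#'
#' @param t Numeric vector of non-negative statistics (values below 0 give 0).
#' @param sigma0_sq Positive scale.
#' @param log Return the log density?
#' @return Density values (or log densities; -Inf where the density is 0).
#' @export
folded_normal_pdf <- function(t, sigma0_sq, log = FALSE) {
  if (!is.numeric(sigma0_sq) || length(sigma0_sq) != 1L || sigma0_sq <= 0)
    stop("sigma0_sq must be a positive scalar")
  lg <- log(2) + dnorm(t, 0, sqrt(sigma0_sq), log = TRUE)
  lg[t < 0] <- -Inf
  if (log) lg else exp(lg)
}

#' Gamma shape as a log-linear function of the SC statistic
#'
#' shape(t_S) = exp(alpha0 + alpha1 * t_S).
#'
#' @param t_S Numeric vector of non-negative SC statistics.
#' @param alpha Coefficient pair (alpha0, alpha1).
#' @param log Return log shape (the linear predictor)?
#' @return Strictly positive shapes (or the linear predictor).
#' @export
gamma_shape <- function(t_S, alpha, log = FALSE) {
  stopifnot(length(alpha) == 2L)
  eta <- alpha[1] + alpha[2] * t_S
  if (log) eta else exp(eta)
}

#' Shifted-gamma alternative density
#'
#' Gamma density with given shape and rate, translated to the support
#' (mu1, Inf); exactly 0 at and below mu1.
#'
#' @param t Numeric vector.
#' @param shape,rate Positive gamma parameters (`shape` may be a vector
#'   matching `t`).
#' @param mu1 Location (lower support endpoint).
#' @param log Return the log density?
#' @return Density values (0 / -Inf outside the support).
#' @export
shifted_gamma_pdf <- function(t, shape, rate, mu1, log = FALSE) {
  if (any(shape <= 0) || !is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("shape and rate must be positive")
  lg <- rep(-Inf, length(t))
  ok <- t > mu1
  if (any(ok)) {
    sh <- if (length(shape) == 1L) shape else shape[ok]
    lg[ok] <- stats::dgamma(t[ok] - mu1, shape = sh, rate = rate, log = TRUE)
  }
  if (log) lg else exp(lg)
}

#' Prior probability that a link is alternative, given its SC statistic
#'
#' Logistic in t_S: plogis(gamma0 + gamma1 * t_S). The complementary null
#' probability is returned by [prior_prob_null()]; the two sum to one
#' exactly.
#'
#' @param t_S Numeric vector of SC statistics.
#' @param gamma Coefficient pair (gamma0, gamma1).
#' @param log Return log probability?
#' @return Probabilities in (0, 1).
#' @export
prior_prob_alt <- function(t_S, gamma, log = FALSE) {
  stopifnot(length(gamma) == 2L)
  eta <- gamma[1] + gamma[2] * t_S
  plogis(eta, log.p = log)
}

#' @rdname prior_prob_alt
#' @export
prior_prob_null <- function(t_S, gamma, log = FALSE) {
  stopifnot(length(gamma) == 2L)
  eta <- gamma[1] + gamma[2] * t_S
  plogis(eta, lower.tail = FALSE, log.p = log)
}

# log of the two weighted mixture components, as an n x 2 matrix
# (column 1: null, column 2: alternative); the building block shared by
# mixture_density, blfdr_posterior and the likelihood.
mixture_log_terms <- function(t_F, t_S, params, hyper) {
  shape <- gamma_shape(t_S, params$alpha)
  cbind(prior_prob_null(t_S, params$gamma, log = TRUE) +
          folded_normal_pdf(t_F, params$sigma0_sq, log = TRUE),
        prior_prob_alt(t_S, params$gamma, log = TRUE) +
          shifted_gamma_pdf(t_F, shape, params$beta, hyper$mu1, log = TRUE))
}

#' Mixture density of an absolute FC statistic given its SC statistic
#'
#' pi0(t_S) f0(t_F) + pi1(t_S) f1(t_F | t_S): the marginal density of the
#' two-group model after integrating out the latent membership.
#'
#' @param t_F,t_S Numeric vectors (recycled to a common length).
#' @param params A [blfdr_params()] object.
#' @param hyper A [blfdr_hyper()] object.
#' @param log Return the log density?
#' @return Non-negative densities.
#' @export
mixture_density <- function(t_F, t_S, params, hyper = blfdr_hyper(),
                            log = FALSE) {
  n <- max(length(t_F), length(t_S))
  lt <- mixture_log_terms(rep_len(t_F, n), rep_len(t_S, n), params, hyper)
  lg <- log_sum_exp_rows(lt)
  if (log) lg else exp(lg)
}

#' Complete-data log likelihood of the mixture model
#'
#' Log of the product over links of the latent-membership-selected weighted
#' component: links with w = 0 contribute pi0 f0, links with w = 1
#' contribute pi1 f1.
#'
#' @param table A [link_stats_table()].
#' @param w Binary membership vector (1 = alternative); must be 0 wherever
#'   t_F <= mu1 (the alternative density has no support there).
#' @param params,hyper Model parameters and hyperparameters.
#' @return A finite scalar log likelihood.
#' @export
complete_data_loglik <- function(table, w, params, hyper = blfdr_hyper()) {
  stopifnot(length(w) == nrow(table), all(w %in% c(0, 1)))
  if (any(w == 1 & table$t_f <= hyper$mu1))
    stop("w = 1 for a link with t_F <= mu1: zero-density configuration")
  lt <- mixture_log_terms(table$t_f, table$t_s, params, hyper)
  sum(lt[cbind(seq_len(nrow(lt)), w + 1L)])
}

#' Posterior null probability (BLfdr) of each link
#'
#' Bayes' rule on the two-group mixture:
#' pi0 f0 / (pi0 f0 + pi1 f1), computed in log space with a stable
#' log-sum-exp. Statistics at or below `mu1` are outside the alternative
#' support and get BLfdr exactly 1.
#'
#' @inheritParams mixture_density
#' @return Probabilities in \[0, 1\].
#' @export
blfdr_posterior <- function(t_F, t_S, params, hyper = blfdr_hyper()) {
  n <- max(length(t_F), length(t_S))
  t_F <- rep_len(t_F, n); t_S <- rep_len(t_S, n)
  lt <- mixture_log_terms(t_F, t_S, params, hyper)
  if (any(!is.finite(lt[, 1])))
    stop("null component density vanished at a finite statistic")
  # 1 / (1 + exp(l1 - l0)), exact 1 when l1 = -Inf
  plogis(lt[, 1] - lt[, 2])
}

log_sum_exp_rows <- function(lt) {
  mx <- pmax(lt[, 1], lt[, 2])
  out <- mx + log(exp(lt[, 1] - mx) + exp(lt[, 2] - mx))
  out[!is.finite(mx)] <- mx[!is.finite(mx)]
  out
}
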