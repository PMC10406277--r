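# Covariate-free local fdr baseline: Lindsey's Poisson-regression density
# estimate of the mixture of signed statistics and a central-matching
# empirical null.

#' Estimate the mixture density of signed statistics by Lindsey's method
#'
#' Bins the statistics into `n_bins` equal-width bins and models the counts
#' as Poisson with log-mean a degree-`degree` polynomial in the bin
#' midpoints; the fitted means, rescaled by m x binwidth, give a smooth
#' density estimate. On non-convergence the degree is reduced and the fit
#' retried; degrees below 2 are an error.
#'
#' @param t Numeric vector of signed statistics (m >= 200 recommended).
#' @param n_bins Number of histogram bins (>= 20).
#' @param degree Polynomial degree of the log-density.
#' @return List with `mid` (bin midpoints), `counts`, `density` (estimate
#'   at midpoints), `binwidth`, `degree_used`, `m` and `fhat`, a function
#'   evaluating the estimate at arbitrary points.
#' @export
fit_mixture_density <- function(t, n_bins = 120, degree = 7) {
  stopifnot(length(t) >= 20L, n_bins >= 20L, degree >= 2L)
  rng <- range(t)
  pad <- 1e-8 * max(1, diff(rng))
  breaks <- seq(rng[1] - pad, rng[2] + pad, length.out = n_bins + 1L)
  mid <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  counts <- tabulate(findInterval(t, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  binwidth <- diff(breaks)[1]
  m <- length(t)
  for (deg in seq(degree, 2L)) {
    basis <- poly(mid, deg)
    fit <- tryCatch(
      suppressWarnings(glm(counts ~ basis, family = poisson())),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged && all(is.finite(coef(fit)))) {
      co <- coef(fit)
      fhat <- function(x) {
        bx <- predict(basis, pmin(pmax(x, rng[1]), rng[2]))
        as.numeric(exp(co[1] + bx %*% co[-1]) / (m * binwidth))
      }
      return(list(mid = mid, counts = counts,
                  density = fhat(mid), binwidth = binwidth,
                  degree_used = deg, m = m, fhat = fhat))
    }
  }
  stop("Poisson density fit failed to converge at all degrees >= 2")
}

#' Empirical null by central matching
#'
#' Fits a quadratic to the log of the estimated mixture density over the
#' central window (by default the central 50% of the data mass) and reads
#' off the null center, null sd and null proportion from the vertex and
#' curvature: under the zero assumption the center of the statistic
#' distribution is dominated by p0 x Normal(delta0, sigma0^2), whose log is
#' exactly quadratic.
#'
#' @param dens A [fit_mixture_density()] result.
#' @param t The statistics the density was fitted to (to locate the central
#'   mass window).
#' @param central_mass Fraction of central data mass used for the fit.
#' @return List with `delta0_hat`, `sigma0_hat`, `p0_hat` (capped at 1).
#' @export
central_matching_null <- function(dens, t, central_mass = 0.5) {
  stopifnot(central_mass > 0, central_mass < 1)
  lo <- quantile(t, (1 - central_mass) / 2)
  hi <- quantile(t, 1 - (1 - central_mass) / 2)
  sel <- dens$mid >= lo & dens$mid <= hi & dens$density > 0
  if (sum(sel) < 5L) stop("too few bins in the central window")
  x <- dens$mid[sel]
  y <- log(dens$density[sel])
  qf <- lm(y ~ x + I(x^2))
  cf <- coef(qf)
  a <- cf[[1]]; b <- cf[[2]]; cc <- cf[[3]]
  if (!is.finite(cc) || cc >= 0)
    stop("central log-density is not concave: no empirical null")
  sigma0_sq <- -1 / (2 * cc)
  delta0 <- -b / (2 * cc)
  log_p0 <- a - b^2 / (4 * cc) + 0.5 * log(2 * pi * sigma0_sq)
  list(delta0_hat = unname(delta0), sigma0_hat = unname(sqrt(sigma0_sq)),
       p0_hat = min(1, unname(exp(log_p0))))
}

#' Fit the covariate-free local fdr (Efron's Lfdr)
#'
#' Combines the Lindsey mixture-density estimate with the central-matching
#' empirical null and returns per-observation local fdr values
#' p0 f0(t) / f(t), capped at 1.
#'
#' @param t Numeric vector of signed statistics.
#' @param n_bins,degree Passed to [fit_mixture_density()].
#' @param central_mass Passed to [central_matching_null()].
#' @return An object of class `lfdr_fit`: list with the null estimates
#'   (`delta0_hat`, `sigma0_hat`, `p0_hat`), the density fit (`density`),
#'   and `lfdr`, the per-observation values aligned with `t`.
#' @export
fit_lfdr <- function(t, n_bins = 120, degree = 7, central_mass = 0.5) {
  dens <- fit_mixture_density(t, n_bins = n_bins, degree = degree)
  null_est <- central_matching_null(dens, t, central_mass = central_mass)
  structure(c(null_est,
              list(density = dens,
                   lfdr = lfdr_values(t, dens, null_est))),
            class = "lfdr_fit")
}

#' Evaluate local fdr values from a density fit and null estimate
#'
#' @param t Numeric vector of statistics.
#' @param dens A [fit_mixture_density()] result.
#' @param null_est A [central_matching_null()] result.
#' @return Values p0 f0(t) / f(t) in \[0, 1\] (1 where f-hat vanishes).
#' @export
lfdr_values <- function(t, dens, null_est) {
  f <- dens$fhat(t)
  f0 <- dnorm(t, null_est$delta0_hat, null_est$sigma0_hat)
  out <- ifelse(f > 0, null_est$p0_hat * f0 / f, 1)
  pmin(out, 1)
}

#' @export
print.lfdr_fit <- function(x, ...) {
  cat(sprintf(
    "Efron Lfdr fit: empirical null Normal(%.3f, %.3f^2), p0 = %.3f\n",
    x$delta0_hat, x$sigma0_hat, x$p0_hat))
  cat(sprintf("  density: %d bins, polynomial degree %d, m = %d\n",
              length(x$density$mid), x$density$degree_used, x$density$m))
  invisible(x)
}
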