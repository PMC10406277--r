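# Synthetic two-group bimodal connectivity studies: sparse alternatives
# split across modalities, uniform-drawn effect sizes, correlated
# heteroscedastic errors, signed-tail trimming, and an FDR experiment
# harness.

#' Design of a simulated two-group connectivity study
#'
#' Defaults emulate a small late-life-depression-style study: m = 3741
#' links (87 regions), 1% of links alternative in both modalities, 1% in
#' FC only, 1% in SC only; per-replicate effect sizes drawn uniformly,
#' delta_F ~ U(0.055, 0.095) and delta_S ~ U(0.15, 0.35); FC-SC
#' correlation rho nested within subject (bivariate subject random
#' intercepts); skewed gamma observation errors with link-specific
#' heteroscedastic scales and a larger mean scale in the disease group;
#' 10% upper and lower signed-statistic tails trimmed before model
#' fitting.
#'
#' Baseline levels (`mu_fc_*`, `mu_sc_*`) are on the transformed scales
#' (Fisher-Z for FC, cube-root for SC) on which the model operates.
#'
#' @param m Number of links.
#' @param n_per_group Subjects per group.
#' @param frac_alt_both,frac_alt_fc_only,frac_alt_sc_only Fractions of
#'   links alternative in both / FC only / SC only.
#' @param delta_fc_range,delta_sc_range Uniform ranges of the group mean
#'   differences for alternative links.
#' @param rho Correlation of the FC and SC subject random intercepts
#'   (the two modalities are nested within subject) in \[0, 1\].
#' @param trim_fraction Fraction trimmed from each signed-FC-statistic tail.
#' @param mu_fc_mean,mu_fc_sd Distribution of baseline FC link levels.
#' @param mu_sc_mean,mu_sc_sd Distribution of baseline SC link levels.
#' @param subj_sd Subject random-intercept sd (shared across links and
#'   modalities).
#' @param scale_shape Gamma shape of the link-specific error-scale draws
#'   (heterogeneity across links; smaller = more heterogeneous).
#' @param error_shape Gamma shape of the error distribution itself
#'   (skewness 2 / sqrt(error_shape); errors are centered scaled gamma
#'   draws, so small-sample test statistics are skew and heavy-tailed,
#'   normalising as n grows).
#' @param sd_fc,sd_sc Mean error sd per modality in the control group.
#' @param disease_scale_mult Multiplicative error-scale inflation in the
#'   disease group.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(m = 3741, n_per_group = 15,
                       frac_alt_both = 0.01, frac_alt_fc_only = 0.01,
                       frac_alt_sc_only = 0.01,
                       delta_fc_range = c(0.055, 0.095),
                       delta_sc_range = c(0.15, 0.35),
                       rho = 0.4, trim_fraction = 0.10,
                       mu_fc_mean = 0.3, mu_fc_sd = 0.1,
                       mu_sc_mean = 1.5, mu_sc_sd = 0.5,
                       subj_sd = 0.05, scale_shape = 4, error_shape = 8,
                       sd_fc = 0.05, sd_sc = 0.08,
                       disease_scale_mult = 1.2) {
  stopifnot(m >= 10, n_per_group >= 2,
            frac_alt_both >= 0, frac_alt_fc_only >= 0, frac_alt_sc_only >= 0,
            frac_alt_both + frac_alt_fc_only + frac_alt_sc_only <= 1,
            diff(delta_fc_range) >= 0, diff(delta_sc_range) >= 0,
            rho >= 0, rho <= 1, trim_fraction >= 0, trim_fraction < 0.5,
            scale_shape > 0, error_shape > 0, sd_fc > 0, sd_sc > 0,
            disease_scale_mult > 0)
  structure(as.list(environment()), class = "sim_design")
}

#' Assign link truth categories
#'
#' floor(frac x m) links per alternative category (both, FC-only,
#' SC-only), the remainder null in both modalities; membership by random
#' permutation under the current RNG state.
#'
#' @param design A [sim_design()].
#' @return List with binary vectors `truth_fc` and `truth_sc` of length m.
#' @export
assign_truth <- function(design) {
  m <- design$m
  n_both <- floor(design$frac_alt_both * m)
  n_fc <- floor(design$frac_alt_fc_only * m)
  n_sc <- floor(design$frac_alt_sc_only * m)
  perm <- sample.int(m)
  truth_fc <- truth_sc <- integer(m)
  truth_fc[perm[seq_len(n_both + n_fc)]] <- 1L
  truth_sc[perm[c(seq_len(n_both),
                  n_both + n_fc + seq_len(n_sc))]] <- 1L
  list(truth_fc = truth_fc, truth_sc = truth_sc)
}

#' Simulate one two-group connectivity study
#'
#' Per-subject per-link (FC, SC) observations on the transformed scales:
#' baseline link level + subject random intercept (the FC and SC
#' intercepts of a subject are correlated with correlation `rho`) + group
#' shift (the modality's delta on its alternative links in the disease
#' group) + skewed gamma error with link- and group-specific scales.
#' delta_F and delta_S are drawn once per study from their uniform ranges.
#' Link statistics are absolute Welch t statistics per modality after
#' subject-mean centering (the random-intercept adjustment); signed FC
#' statistics are retained for trimming and for the covariate-free
#' baseline.
#'
#' @param design A [sim_design()].
#' @return An object of class `sim_study`: list with `table`
#'   ([link_stats_table()]), `signed_t_f`, `truth_fc`, `truth_sc`,
#'   `delta_f`, `delta_s` and `design`.
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  m <- design$m; n <- design$n_per_group
  truth <- assign_truth(design)
  delta_f <- runif(1, design$delta_fc_range[1], design$delta_fc_range[2])
  delta_s <- runif(1, design$delta_sc_range[1], design$delta_sc_range[2])

  mu_fc <- rnorm(m, design$mu_fc_mean, design$mu_fc_sd)
  mu_sc <- rnorm(m, design$mu_sc_mean, design$mu_sc_sd)

  # FC and SC are nested within subject: the modality pair of subject
  # random intercepts (b_F, b_S) is bivariate normal with correlation rho.
  # Observation errors are centered scaled Gamma(error_shape) draws
  # (skewness 2 / sqrt(error_shape)), independent across modalities, with
  # link-specific heteroscedastic scales.
  gen_group <- function(group) {
    mult <- if (group == "disease") design$disease_scale_mult else 1
    k <- design$error_shape
    rho <- design$rho
    sh <- design$scale_shape
    sd_fc_i <- rgamma(m, sh, rate = sh / (design$sd_fc * mult))
    sd_sc_i <- rgamma(m, sh, rate = sh / (design$sd_sc * mult))
    b_fc <- rnorm(n, 0, design$subj_sd)
    b_sc <- design$subj_sd *
      (rho * b_fc / design$subj_sd + sqrt(1 - rho^2) * rnorm(n))
    rg <- function() matrix((rgamma(m * n, k, 1) - k) / sqrt(k), m, n)
    e_fc <- sd_fc_i * rg()
    e_sc <- sd_sc_i * rg()
    shift_fc <- if (group == "disease") delta_f * truth$truth_fc else 0
    shift_sc <- if (group == "disease") delta_s * truth$truth_sc else 0
    list(fc = mu_fc + shift_fc + rep(b_fc, each = m) + e_fc,
         sc = mu_sc + shift_sc + rep(b_sc, each = m) + e_sc)
  }
  dis <- gen_group("disease")
  ctl <- gen_group("control")
  # subject-mean centering: the random-intercept stand-in used when link
  # statistics are computed from subject-level data
  center <- function(x) sweep(x, 2, colMeans(x))
  signed_t_f <- welch_t_links(center(dis$fc), center(ctl$fc))
  signed_t_s <- welch_t_links(center(dis$sc), center(ctl$sc))
  structure(list(
    table = link_stats_table(abs(signed_t_f), abs(signed_t_s)),
    signed_t_f = signed_t_f,
    truth_fc = truth$truth_fc, truth_sc = truth$truth_sc,
    delta_f = delta_f, delta_s = delta_s, design = design),
    class = "sim_study")
}

#' Trim the tails of the signed FC statistics
#'
#' Removes the `trim_fraction` upper and lower tails of the signed FC
#' statistics (before absolute values are taken), keeping truth labels
#' aligned with the retained links.
#'
#' @param study A [simulate_study()] result.
#' @param trim_fraction Fraction removed from each tail (defaults to the
#'   study design's value).
#' @return A trimmed `sim_study`.
#' @export
trim_statistics <- function(study, trim_fraction = study$design$trim_fraction) {
  stopifnot(inherits(study, "sim_study"),
            trim_fraction >= 0, trim_fraction < 0.5)
  if (trim_fraction == 0) return(study)
  m <- length(study$signed_t_f)
  n_cut <- floor(trim_fraction * m)
  ord <- order(study$signed_t_f)
  drop <- c(head(ord, n_cut), utils::tail(ord, n_cut))
  keep <- setdiff(seq_len(m), drop)
  out <- study
  out$table <- link_stats_table(study$table$t_f[keep],
                                study$table$t_s[keep],
                                study$table$roi_a[keep],
                                study$table$roi_b[keep])
  out$signed_t_f <- study$signed_t_f[keep]
  out$truth_fc <- study$truth_fc[keep]
  out$truth_sc <- study$truth_sc[keep]
  out$kept_index <- keep
  out
}

#' Procedures for the FDR experiment harness
#'
#' Each procedure is a function of a fitting study and an evaluation study
#' (both `sim_study` objects sharing the same replicate): it learns its
#' model from the fitting study's statistics and returns per-link
#' null-probability scores for every link of the evaluation study,
#' consumed by [oracle_reject()]. In the experiment harness the fitting
#' study is the trimmed central 80% and the evaluation study is the full
#' link set. `blfdr_procedure()` fits the covariate-modulated mixture
#' model by MCMC on the absolute statistics; `lfdr_procedure()` fits the
#' covariate-free baseline on the signed FC statistics.
#'
#' @param config A [blfdr_config()] used for every fit (chain seeds are
#'   managed by the experiment harness).
#' @param hyper A [blfdr_hyper()].
#' @return A scoring function `function(fit_study, eval_study) -> numeric`.
#' @export
blfdr_procedure <- function(config = blfdr_config(n_chains = 1L,
                                                  n_iter = 2000L,
                                                  burn_in = 500L, thin = 5L),
                            hyper = blfdr_hyper()) {
  force(config); force(hyper)
  function(fit_study, eval_study = fit_study) {
    cfg <- config
    cfg$seed <- sample.int(2147483600L, 1L)
    fit <- blfdr_fit(fit_study$table, cfg, hyper)
    blfdr_from_fit(eval_study$table, fit)
  }
}

#' @rdname blfdr_procedure
#' @param n_bins,degree,central_mass Passed to [fit_lfdr()].
#' @export
lfdr_procedure <- function(n_bins = 120, degree = 7, central_mass = 0.5) {
  function(fit_study, eval_study = fit_study) {
    fit <- fit_lfdr(fit_study$signed_t_f, n_bins = n_bins, degree = degree,
                    central_mass = central_mass)
    lfdr_values(eval_study$signed_t_f, fit$density,
                fit[c("delta0_hat", "sigma0_hat", "p0_hat")])
  }
}

#' Run a replicated FDR experiment
#'
#' For each replicate: simulate a study from `design`, fit every
#' procedure, apply the oracle rule at each q over all m links and score
#' against the FC truth. With `trim_fit = TRUE` the procedures are fitted
#' on the statistics that survive signed-tail trimming
#' ([trim_statistics()]) while decisions still cover every link; by
#' default they are fitted on the full statistic set. Replicates whose
#' fits fail are skipped with a warning and counted.
#'
#' @param design A [sim_design()].
#' @param procedures Named list of scoring functions (see
#'   [blfdr_procedure()]).
#' @param q_levels Numeric vector of target FDR levels in (0, 1).
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed for the whole experiment.
#' @param trim_fit Fit procedures on the trimmed statistics?
#' @return A data.frame with one row per (procedure, q): columns
#'   `procedure`, `q`, `n_per_group`, `rho`, `fdr` (mean FDP), `se`
#'   (Monte-Carlo standard error), `sensitivity`, `n_reps_used`.
#' @export
run_fdr_experiment <- function(design, procedures, q_levels = c(0.2, 0.3),
                               n_reps = 100, seed = 1L, trim_fit = FALSE) {
  stopifnot(inherits(design, "sim_design"), n_reps >= 1,
            length(procedures) >= 1, all(q_levels > 0 & q_levels < 1))
  if (is.null(names(procedures)))
    names(procedures) <- paste0("proc", seq_along(procedures))
  set.seed(seed)
  rep_seeds <- sample.int(2147483600L, n_reps)
  grid <- expand.grid(procedure = names(procedures), q = q_levels,
                      stringsAsFactors = FALSE)
  fdp <- sens <- matrix(NA_real_, n_reps, nrow(grid))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    study <- simulate_study(design)
    fit_study <- if (trim_fit) trim_statistics(study) else study
    scores <- lapply(procedures, function(p)
      tryCatch(p(fit_study, study), error = function(e) e))
    for (g in seq_len(nrow(grid))) {
      sc <- scores[[grid$procedure[g]]]
      if (inherits(sc, "error")) next
      dec <- oracle_reject(pmin(pmax(sc, 0), 1), grid$q[g])
      s <- score_decisions(dec$rejected, study$truth_fc)
      fdp[r, g] <- s$fdp
      sens[r, g] <- s$sensitivity
    }
    failed <- vapply(scores, inherits, logical(1), "error")
    if (any(failed)) {
      n_failed <- n_failed + 1L
      warning(sprintf("replicate %d: fit failed for %s", r,
                      paste(names(scores)[failed], collapse = ", ")),
              call. = FALSE)
    }
  }
  res <- cbind(grid,
               n_per_group = design$n_per_group, rho = design$rho,
               fdr = colMeans(fdp, na.rm = TRUE),
               se = apply(fdp, 2, function(x)
                 sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))),
               sensitivity = colMeans(sens, na.rm = TRUE),
               n_reps_used = colSums(!is.na(fdp)))
  attr(res, "n_failed") <- n_failed
  res
}

#' Simulate statistics directly from the mixture model
#'
#' Draws m SC statistics (absolute values of a normal), latent membership
#' from the logistic prior, and FC statistics from the folded-normal null
#' or the shifted-gamma alternative at the given parameters. Used for
#' parameter-recovery checks, where the fitted model is exactly the
#' generating model.
#'
#' @param m Number of links.
#' @param params A [blfdr_params()].
#' @param hyper A [blfdr_hyper()].
#' @param t_s_sd Scale of the folded-normal SC statistic distribution.
#' @return List with `table`, `w` (true membership) and the inputs.
#' @export
simulate_from_model <- function(m, params, hyper = blfdr_hyper(),
                                t_s_sd = 1.2) {
  stopifnot(inherits(params, "blfdr_params"), m >= 2)
  t_s <- abs(rnorm(m, 0, t_s_sd))
  w <- rbinom(m, 1, prior_prob_alt(t_s, params$gamma))
  t_f <- abs(rnorm(m, 0, sqrt(params$sigma0_sq)))
  n1 <- sum(w == 1)
  if (n1 > 0) {
    sh <- gamma_shape(t_s[w == 1], params$alpha)
    t_f[w == 1] <- hyper$mu1 + rgamma(n1, shape = sh, rate = params$beta)
  }
  # statistics at or below mu1 are null by construction of the model
  w[t_f <= hyper$mu1] <- 0L
  list(table = link_stats_table(t_f, t_s), w = w, params = params,
       hyper = hyper)
}
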