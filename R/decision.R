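# Rejection decisions: the oracle procedure on local fdr values, the
# Storey null-proportion estimate, and scoring against known truth.

#' Oracle rejection rule on local fdr values
#'
#' Sorts the per-link null probabilities ascending (ties broken by original
#' index) and rejects the k smallest, where k is the largest i such that
#' the running mean of the i smallest values is at most q. This compound
#' decision rule controls the marginal FDR at q while minimising the false
#' non-discovery rate.
#'
#' @param blfdr Numeric vector of local fdr values in \[0, 1\].
#' @param q Target FDR level in (0, 1).
#' @return An object of class `blfdr_decision`: list with `blfdr`,
#'   `rejected` (binary vector), `q`, `k_rejections` and
#'   `mean_blfdr_rejected` (NA when nothing is rejected).
#' @export
oracle_reject <- function(blfdr, q) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("q must lie strictly between 0 and 1")
  if (anyNA(blfdr) || any(blfdr < 0 | blfdr > 1))
    stop("blfdr values must lie in [0, 1]")
  m <- length(blfdr)
  ord <- order(blfdr, seq_len(m))          # stable: ties by original index
  cm <- cumsum(blfdr[ord]) / seq_len(m)
  ok <- which(cm <= q)
  k <- if (length(ok)) max(ok) else 0L
  rejected <- integer(m)
  if (k > 0L) rejected[ord[seq_len(k)]] <- 1L
  structure(list(blfdr = blfdr, rejected = rejected, q = q,
                 k_rejections = k,
                 mean_blfdr_rejected = if (k > 0L) cm[k] else NA_real_),
            class = "blfdr_decision")
}

#' @export
print.blfdr_decision <- function(x, ...) {
  cat(sprintf("Oracle procedure at q = %g: %d of %d links rejected", x$q,
              x$k_rejections, length(x$blfdr)))
  if (x$k_rejections > 0)
    cat(sprintf(" (mean blfdr over rejections = %.4f)", x$mean_blfdr_rejected))
  cat("\n")
  invisible(x)
}

#' Storey estimate of the null proportion
#'
#' pi0-hat = #\{p_i > lambda\} / (m (1 - lambda)), capped at 1. With the
#' tuning value lambda = 0.025 used for absolute-statistic p-values this is
#' a conservative estimate of the proportion of null links.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param lambda Tuning threshold in (0, 1).
#' @return The capped estimate, a scalar in (0, 1\].
#' @export
storey_pi0 <- function(p_values, lambda = 0.025) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  min(1, sum(p_values > lambda) / (length(p_values) * (1 - lambda)))
}

#' Score a rejection set against known truth
#'
#' @param rejected Binary rejection indicator vector.
#' @param truth Binary truth vector (1 = alternative), same length.
#' @return List with `fdp` (false rejections / rejections, 0 when nothing
#'   is rejected), `sensitivity` (true rejections / alternatives) and
#'   `specificity` (true non-rejections / nulls).
#' @export
score_decisions <- function(rejected, truth) {
  stopifnot(length(rejected) == length(truth),
            all(rejected %in% c(0, 1)), all(truth %in% c(0, 1)))
  r <- sum(rejected)
  list(fdp = sum(rejected == 1 & truth == 0) / max(r, 1),
       sensitivity = sum(rejected == 1 & truth == 1) / max(sum(truth), 1),
       specificity = sum(rejected == 0 & truth == 0) /
         max(sum(truth == 0), 1))
}

#' Write a decision table as delimited text
#'
#' Columns: `roi_a, roi_b, t_f, t_s, blfdr, rejected`.
#'
#' @param table The [link_stats_table()] the decision was made on.
#' @param decision A [oracle_reject()] result aligned with `table`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(table, decision, path, sep = ",") {
  stopifnot(inherits(decision, "blfdr_decision"),
            nrow(table) == length(decision$blfdr))
  out <- cbind(as.data.frame(table), blfdr = decision$blfdr,
               rejected = decision$rejected)
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
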