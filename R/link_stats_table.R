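# Link-level statistics table: the package's central data container.

#' Table of absolute link-level test statistics
#'
#' One row per connectivity link, holding the absolute FC test statistic
#' `t_f`, the absolute SC test statistic `t_s`, and optional ROI-pair
#' labels. This is the input to the mixture model and to the baseline.
#'
#' @param t_f,t_s Non-negative numeric vectors of equal length m >= 2,
#'   without missing values.
#' @param roi_a,roi_b Optional character vectors of ROI labels.
#' @return A `data.frame` with classes `c("link_stats_table", "data.frame")`
#'   and columns `roi_a`, `roi_b`, `t_f`, `t_s`.
#' @export
link_stats_table <- function(t_f, t_s, roi_a = NULL, roi_b = NULL) {
  m <- length(t_f)
  if (m < 2L || length(t_s) != m)
    stop("t_f and t_s must have equal length m >= 2")
  if (anyNA(t_f) || anyNA(t_s))
    stop("missing values in link statistics are not allowed")
  if (any(t_f < 0) || any(t_s < 0))
    stop("link statistics must be absolute (non-negative) values")
  if (is.null(roi_a)) roi_a <- rep(NA_character_, m)
  if (is.null(roi_b)) roi_b <- rep(NA_character_, m)
  stopifnot(length(roi_a) == m, length(roi_b) == m)
  structure(data.frame(roi_a = as.character(roi_a),
                       roi_b = as.character(roi_b),
                       t_f = as.numeric(t_f), t_s = as.numeric(t_s),
                       stringsAsFactors = FALSE),
            class = c("link_stats_table", "data.frame"))
}

#' Read / write a link-statistics table as delimited text
#'
#' The on-disk format is a delimited file with header columns
#' `roi_a, roi_b, t_f, t_s`. The reader validates non-negativity and
#' rejects rows with missing statistics.
#'
#' @param path File path.
#' @param sep Field separator (`","` for CSV, `"\t"` for TSV).
#' @return `read_link_stats()` returns a [link_stats_table()];
#'   `write_link_stats()` returns `path` invisibly.
#' @export
read_link_stats <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("roi_a", "roi_b", "t_f", "t_s")
  if (!all(need %in% names(df)))
    stop("link stats file must have columns roi_a, roi_b, t_f, t_s")
  link_stats_table(df$t_f, df$t_s, df$roi_a, df$roi_b)
}

#' @rdname read_link_stats
#' @param table A [link_stats_table()].
#' @export
write_link_stats <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "link_stats_table"))
  write.table(as.data.frame(table), path, sep = sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @export
print.link_stats_table <- function(x, ...) {
  cat(sprintf("Link statistics table: %d links\n", nrow(x)))
  cat(sprintf("  |t_F|: median %.3f, max %.3f;  |t_S|: median %.3f, max %.3f\n",
              median(x$t_f), max(x$t_f), median(x$t_s), max(x$t_s)))
  NextMethod()
}
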