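# Link-level statistics from subject-level connectivity matrices:
# variance-stabilising transforms, vectorisation of symmetric adjacency
# matrices, and per-link heteroscedastic two-group tests.

#' Fisher's Z transformation
#'
#' atanh(r) = 0.5 log((1 + r) / (1 - r)), the variance-stabilising
#' transform for Pearson correlations. Values with |r| >= 1 are clipped to
#' +/-(1 - 1e-7) with a warning.
#'
#' @param r Numeric vector of correlations.
#' @return Transformed values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("correlations with |r| >= 1 clipped to +/-(1 - 1e-7)",
            call. = FALSE)
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  }
  atanh(r)
}

#' Cube-root transformation
#'
#' Normalising transform for non-negative count data such as fiber counts;
#' zeros map to zero (no pseudo-count is added).
#'
#' @param x Non-negative numeric vector.
#' @return x^(1/3).
#' @export
cube_root <- function(x) {
  stopifnot(all(x >= 0, na.rm = TRUE))
  x^(1 / 3)
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Returns the R(R-1)/2 off-diagonal upper-triangle entries in row-major
#' order ((1,2), (1,3), ..., (1,R), (2,3), ...), the stable link-index
#' convention used throughout the package. [link_pairs()] returns the
#' matching (row, column) index pairs.
#'
#' @param mat Symmetric R x R matrix (symmetry checked to `tol`).
#' @param tol Symmetry tolerance.
#' @return Numeric vector of length R(R-1)/2.
#' @export
vectorize_links <- function(mat, tol = 1e-8) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat), nrow(mat) >= 2L)
  if (max(abs(mat - t(mat))) > tol)
    stop("matrix is not symmetric within tolerance")
  idx <- link_pairs(nrow(mat))
  mat[as.matrix(idx)]
}

#' @rdname vectorize_links
#' @param R Number of regions.
#' @export
link_pairs <- function(R) {
  stopifnot(R >= 2L)
  idx <- which(upper.tri(diag(R)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(row = idx[, 1], col = idx[, 2])
}

#' Restore a symmetric matrix from its link vector
#'
#' Inverse of [vectorize_links()] on the off-diagonals; the diagonal is
#' filled with `diag_value`.
#'
#' @param v Link vector of length R(R-1)/2.
#' @param diag_value Value for the diagonal.
#' @return Symmetric R x R matrix.
#' @export
unvectorize_links <- function(v, diag_value = 0) {
  R <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(R - round(R)) > 1e-9)
    stop("length of v is not R(R-1)/2 for integer R")
  R <- as.integer(round(R))
  mat <- matrix(diag_value, R, R)
  idx <- as.matrix(link_pairs(R))
  mat[idx] <- v
  mat[idx[, 2:1]] <- v
  mat
}

#' Welch two-sample t statistic, vectorized over links
#'
#' Heteroscedastic (unequal-variance) two-sample t statistic per row of two
#' matrices whose rows are links and columns are subjects. The sign is
#' group 1 minus group 2; degenerate links (both groups constant) give 0
#' when means agree and are capped at +/-`cap` with a warning otherwise.
#'
#' @param x1,x2 Numeric matrices (links x subjects), >= 2 columns each.
#' @return Numeric vector of signed statistics, one per link.
#' @export
welch_t_links <- function(x1, x2) {
  stopifnot(is.matrix(x1), is.matrix(x2), nrow(x1) == nrow(x2),
            ncol(x1) >= 2L, ncol(x2) >= 2L)
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- (m1 - m2) / se
  bad <- se == 0
  if (any(bad)) {
    t[bad & m1 == m2] <- 0
    if (any(bad & m1 != m2)) {
      warning("zero within-group variance with unequal means; ",
              "statistic capped", call. = FALSE)
      cap <- 1e6
      t[bad & m1 != m2] <- sign(m1 - m2)[bad & m1 != m2] * cap
    }
  }
  t
}

#' Welch t statistic for two sample vectors
#'
#' Scalar convenience wrapper around [welch_t_links()].
#'
#' @param values_g1,values_g2 Numeric vectors with >= 2 finite values each.
#' @return Signed t statistic.
#' @export
link_group_stat <- function(values_g1, values_g2) {
  stopifnot(length(values_g1) >= 2L, length(values_g2) >= 2L,
            all(is.finite(values_g1)), all(is.finite(values_g2)))
  welch_t_links(matrix(values_g1, nrow = 1), matrix(values_g2, nrow = 1))
}

#' A subject's connectivity matrices
#'
#' @param subject_id Identifier string.
#' @param group `"disease"` or `"control"`.
#' @param fc Symmetric R x R Pearson-correlation matrix with unit diagonal.
#' @param sc Symmetric R x R non-negative fiber-count matrix.
#' @return An object of class `subject_connectivity`.
#' @export
subject_connectivity <- function(subject_id, group, fc, sc) {
  group <- match.arg(group, c("disease", "control"))
  stopifnot(is.matrix(fc), is.matrix(sc), all(dim(fc) == dim(sc)),
            nrow(fc) >= 2L)
  if (max(abs(fc - t(fc))) > 1e-8 || max(abs(sc - t(sc))) > 1e-8)
    stop("connectivity matrices must be symmetric")
  if (any(abs(fc) > 1)) stop("FC entries must be correlations in [-1, 1]")
  if (any(sc < 0)) stop("SC entries must be non-negative counts")
  structure(list(subject_id = as.character(subject_id), group = group,
                 fc = fc, sc = sc),
            class = "subject_connectivity")
}

#' Build link statistics from subject-level connectivity
#'
#' Applies Fisher's Z to FC entries and the cube root to SC entries,
#' vectorizes each subject's matrices into links, optionally centers each
#' subject by its across-link mean (a stand-in for a random subject
#' intercept), and computes the absolute Welch t statistic per link and
#' modality between the disease and control groups.
#'
#' @param subjects List of [subject_connectivity()] objects covering both
#'   groups (>= 2 subjects per group).
#' @param center_subjects Subtract each subject's across-link mean before
#'   testing?
#' @return A [link_stats_table()] with ROI-pair labels `"Ri"`.
#' @export
build_link_stats <- function(subjects, center_subjects = FALSE) {
  stopifnot(length(subjects) >= 4L,
            all(vapply(subjects, inherits, logical(1),
                       "subject_connectivity")))
  groups <- vapply(subjects, `[[`, character(1), "group")
  if (sum(groups == "disease") < 2L || sum(groups == "control") < 2L)
    stop("need at least 2 subjects in each group")
  links_of <- function(s) {
    cbind(fc = fisher_z(vectorize_links(s$fc)),
          sc = cube_root(vectorize_links(s$sc)))
  }
  per_subj <- lapply(subjects, links_of)
  stack <- function(mod) {
    x <- vapply(per_subj, function(p) p[, mod],
                numeric(nrow(per_subj[[1]])))
    if (center_subjects) x <- sweep(x, 2, colMeans(x))
    x
  }
  fc_mat <- stack("fc"); sc_mat <- stack("sc")
  dis <- groups == "disease"
  t_f <- abs(welch_t_links(fc_mat[, dis, drop = FALSE],
                           fc_mat[, !dis, drop = FALSE]))
  t_s <- abs(welch_t_links(sc_mat[, dis, drop = FALSE],
                           sc_mat[, !dis, drop = FALSE]))
  R <- nrow(subjects[[1]]$fc)
  pairs <- link_pairs(R)
  link_stats_table(t_f, t_s, roi_a = paste0("R", pairs$row),
                   roi_b = paste0("R", pairs$col))
}

#' Read subject connectivity from a manifest of matrix files
#'
#' The manifest is a delimited file with columns
#' `subject_id, group, fc_path, sc_path`; each referenced file holds one
#' square matrix as delimited text (no header). Relative paths are resolved
#' against the manifest's directory.
#'
#' @param manifest_path Path to the manifest file.
#' @param sep Field separator used in the manifest and the matrix files.
#' @return A list of [subject_connectivity()] objects.
#' @export
read_subjects <- function(manifest_path, sep = ",") {
  man <- read.csv(manifest_path, sep = sep, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "fc_path", "sc_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns subject_id, group, fc_path, sc_path")
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  read_mat <- function(p)
    as.matrix(read.table(p, sep = sep, header = FALSE))
  lapply(seq_len(nrow(man)), function(i)
    subject_connectivity(man$subject_id[i], man$group[i],
                         read_mat(resolve(man$fc_path[i])),
                         read_mat(resolve(man$sc_path[i]))))
}
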