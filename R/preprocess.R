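#' Drop miRNAs with excessive per-group missingness
#'
#' Modified listwise deletion: a miRNA is eliminated when its fraction of
#' missing entries exceeds \code{threshold} (strictly) in the tumour group
#' OR in the normal group, each fraction computed over that group's sample
#' count. A miRNA missing exactly half of each group is retained. Surviving
#' rows are unchanged.
#'
#' @param matrix A \code{\link{cohort_matrix}} with both classes present.
#' @param threshold Per-group missing fraction above which a miRNA is
#'   dropped; in (0, 1], default 0.5.
#' @return List with elements \code{matrix} (filtered
#'   \code{cohort_matrix}) and \code{report} (a \code{preprocess_report}).
#' @seealso \code{\link{remove_outliers}}
#' @export
filter_missing <- function(matrix, threshold = 0.5) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("'threshold' must be a single value in (0, 1]")
  tum <- matrix$sample_labels == "tumour"
  nor <- matrix$sample_labels == "normal"
  frac_t <- rowMeans(is.na(matrix$values[, tum, drop = FALSE]))
  frac_n <- rowMeans(is.na(matrix$values[, nor, drop = FALSE]))
  drop <- frac_t > threshold | frac_n > threshold
  dropped <- data.frame(mirna = rownames(matrix$values)[drop],
                        frac_missing_tumour = unname(frac_t[drop]),
                        frac_missing_normal = unname(frac_n[drop]),
                        reason = rep("missingness", sum(drop)),
                        stringsAsFactors = FALSE)
  if (all(drop)) stop("missingness filter removed every miRNA")
  out <- matrix
  out$values <- matrix$values[!drop, , drop = FALSE]
  out$mirna_ids <- rownames(out$values)
  report <- new_preprocess_report(
    step = "filter_missing",
    dropped_mirnas = dropped,
    removed_entries = empty_removed_entries(),
    n_before = nrow(matrix$values), n_after = nrow(out$values))
  list(matrix = out, report = report)
}

#' Mask boxplot outliers per miRNA and class group
#'
#' Tukey's boxplot rule, applied once (no iterated re-fencing): within each
#' miRNA and each class group separately, values strictly outside
#' [Q1 - k*IQR, Q3 + k*IQR] are set to missing. Quartiles use linear
#' interpolation between order statistics (\code{quantile} type 7) on the
#' non-missing values; the fences themselves are inclusive, so a degenerate
#' group of identical values loses nothing. Groups with fewer than 4
#' non-missing values are skipped with a warning (quartiles unstable).
#'
#' @param matrix A \code{\link{cohort_matrix}}, normally already passed
#'   through \code{\link{filter_missing}}.
#' @param fence_k Fence multiplier; default 1.5.
#' @return List with \code{matrix} (entries masked to \code{NA}) and
#'   \code{report} (removed entries with their group and value).
#' @export
remove_outliers <- function(matrix, fence_k = 1.5) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  if (!is.numeric(fence_k) || length(fence_k) != 1 || fence_k < 0)
    stop("'fence_k' must be a single non-negative value")
  v <- matrix$values
  removed <- list()
  skipped <- character(0)
  for (cls in c("tumour", "normal")) {
    idx <- which(matrix$sample_labels == cls)
    sub <- v[, idx, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      x <- sub[i, ]
      ok <- !is.na(x)
      if (sum(ok) < 4L) {
        if (sum(ok) > 0L)
          skipped <- c(skipped, paste0(rownames(v)[i], "/", cls))
        next
      }
      q <- stats::quantile(x[ok], c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      lo <- q[1] - fence_k * iqr
      hi <- q[2] + fence_k * iqr
      out <- ok & (x < lo | x > hi)
      if (any(out)) {
        removed[[length(removed) + 1L]] <- data.frame(
          mirna = rownames(v)[i],
          sample = colnames(sub)[out],
          value = unname(x[out]),
          group = cls,
          stringsAsFactors = FALSE)
        v[i, idx[out]] <- NA_real_
      }
    }
  }
  if (length(skipped))
    warning("outlier fencing skipped for ", length(skipped),
            " miRNA/group combination(s) with < 4 non-missing values")
  out_mat <- matrix
  out_mat$values <- v
  removed_df <- if (length(removed)) do.call(rbind, removed)
                else empty_removed_entries()
  report <- new_preprocess_report(
    step = "remove_outliers",
    dropped_mirnas = data.frame(mirna = character(0),
                                frac_missing_tumour = numeric(0),
                                frac_missing_normal = numeric(0),
                                reason = character(0)),
    removed_entries = removed_df,
    n_before = nrow(matrix$values), n_after = nrow(v))
  list(matrix = out_mat, report = report)
}

#' Run both preprocessing steps in the reference order
#'
#' Missingness filtering first, then single-pass outlier masking.
#'
#' @param matrix A \code{\link{cohort_matrix}}.
#' @param threshold Missingness threshold (see \code{\link{filter_missing}}).
#' @param fence_k Tukey fence multiplier (see \code{\link{remove_outliers}}).
#' @return List with \code{matrix} and \code{reports} (one per step).
#' @export
preprocess_cohort <- function(matrix, threshold = 0.5, fence_k = 1.5) {
  s1 <- filter_missing(matrix, threshold)
  s2 <- remove_outliers(s1$matrix, fence_k)
  list(matrix = s2$matrix,
       reports = list(filter_missing = s1$report,
                      remove_outliers = s2$report))
}

empty_removed_entries <- function() {
  data.frame(mirna = character(0), sample = character(0),
             value = numeric(0), group = character(0),
             stringsAsFactors = FALSE)
}

new_preprocess_report <- function(step, dropped_mirnas, removed_entries,
                                  n_before, n_after) {
  structure(list(step = step,
                 dropped_mirnas = dropped_mirnas,
                 removed_entries = removed_entries,
                 n_before = n_before,
                 n_after = n_after),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("preprocess_report [%s]: %d -> %d miRNAs, %d dropped, %d entries masked\n",
              x$step, x$n_before, x$n_after,
              nrow(x$dropped_mirnas), nrow(x$removed_entries)))
  invisible(x)
}
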