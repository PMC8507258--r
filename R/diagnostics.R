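#' Rank-based AUC for a single marker
#'
#' The raw AUC is the Mann-Whitney U statistic divided by
#' n_tumour * n_normal, with tumour as the positive class on ascending
#' score and ties contributing 1/2 — i.e. the probability that a random
#' tumour sample scores above a random normal sample. Because a
#' downregulated marker separates the classes with raw AUC near 0, the
#' reported \code{auc} is orientation-resolved as max(raw, 1 - raw), with
#' the orientation recorded; the raw oriented value is retained for audit.
#'
#' @param scores Numeric marker values (one per sample); samples with a
#'   missing score are dropped.
#' @param labels Class per sample (\code{"tumour"}/\code{"normal"}, or any
#'   spelling \code{\link{cohort_matrix}} accepts).
#' @return One-row data frame: \code{raw_auc}, \code{auc},
#'   \code{orientation} (\code{high_in_tumour}/\code{low_in_tumour}),
#'   \code{n_tumour}, \code{n_normal}, \code{accuracy_class}.
#' @examples
#' compute_auc(c(1, 2, 5, 6), c("tumour", "tumour", "normal", "normal"))
#' @export
compute_auc <- function(scores, labels) {
  labels <- normalize_class_labels(labels)
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == "tumour"); n0 <- sum(labels == "normal")
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present with non-missing scores")
  r <- rank(scores)                      # midranks: ties contribute 1/2
  u <- sum(r[labels == "tumour"]) - n1 * (n1 + 1) / 2
  raw <- u / (n1 * n0)
  data.frame(raw_auc = raw,
             auc = max(raw, 1 - raw),
             orientation = if (raw >= 0.5) "high_in_tumour" else
               "low_in_tumour",
             n_tumour = n1, n_normal = n0,
             accuracy_class = classify_auc(max(raw, 1 - raw)),
             stringsAsFactors = FALSE)
}

#' Greiner accuracy classification of an AUC
#'
#' Diagnostic-accuracy bins: AUC = 1 perfect; 0.9 < AUC < 1 highly
#' accurate; 0.7 < AUC <= 0.9 moderately accurate; 0.5 < AUC <= 0.7 less
#' accurate; AUC <= 0.5 uninformative. Note the boundary: an AUC of
#' exactly 0.9 is moderately accurate.
#'
#' @param auc Numeric in [0, 1].
#' @return One of \code{"perfect"}, \code{"high"}, \code{"moderate"},
#'   \code{"less"}, \code{"uninformative"}.
#' @export
classify_auc <- function(auc) {
  if (is.na(auc) || auc < 0 || auc > 1) stop("AUC must lie in [0, 1]")
  if (auc == 1) "perfect"
  else if (auc > 0.9) "high"
  else if (auc > 0.7) "moderate"
  else if (auc > 0.5) "less"
  else "uninformative"
}

#' Per-miRNA ROC evaluation of a cohort
#'
#' Runs \code{\link{compute_auc}} for every requested miRNA of a cohort,
#' skipping miRNAs absent from the matrix (reported in the
#' \code{"absent"} attribute) — absent markers are "not evaluable", not
#' failures.
#'
#' @param matrix A \code{\link{cohort_matrix}}.
#' @param mirnas miRNAs to evaluate; default all rows.
#' @return Data frame: \code{mirna}, \code{cohort_id} plus the
#'   \code{compute_auc} columns, sorted by decreasing \code{auc}.
#' @export
roc_table <- function(matrix, mirnas = rownames(matrix$values)) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  present <- intersect(mirnas, rownames(matrix$values))
  rows <- lapply(present, function(m) {
    cbind(data.frame(mirna = m, cohort_id = matrix$cohort_id,
                     stringsAsFactors = FALSE),
          compute_auc(matrix$values[m, ], matrix$sample_labels))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(0), cohort_id = character(0),
               raw_auc = numeric(0), auc = numeric(0),
               orientation = character(0), n_tumour = integer(0),
               n_normal = integer(0), accuracy_class = character(0))
  out <- out[order(-out$auc, out$mirna), ]
  rownames(out) <- NULL
  attr(out, "absent") <- setdiff(mirnas, present)
  out
}

#' ROC curve coordinates for a single marker
#'
#' False-positive and true-positive rates at every distinct threshold,
#' oriented so that higher score predicts tumour (flip the scores for a
#' downregulated marker).
#'
#' @param scores,labels As in \code{\link{compute_auc}}.
#' @return Data frame \code{threshold}, \code{fpr}, \code{tpr}, starting
#'   at (0, 0) and ending at (1, 1).
#' @export
roc_coordinates <- function(scores, labels) {
  labels <- normalize_class_labels(labels)
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- labels == "tumour"
  out <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, vapply(thr, function(t)
                      mean(scores[!pos] >= t), numeric(1))),
                    tpr = c(0, vapply(thr, function(t)
                      mean(scores[pos] >= t), numeric(1))))
  out
}
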