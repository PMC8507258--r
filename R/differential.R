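#' Two-group differential test with normality-driven test selection
#'
#' For one miRNA, tests tumour vs normal expression. Shapiro-Wilk is run on
#' each group; the pair is declared normal only when both groups have
#' Shapiro p > \code{alpha_normality}. Under the default
#' \code{policy = "conventional"}, a normal pair goes to Levene's test
#' (center = mean) for the equal-variance decision, then Student's t
#' (Levene p > 0.05) or Welch's t (otherwise); a non-normal pair goes to a
#' two-sided Wilcoxon-Mann-Whitney test (exact for small tie-free samples,
#' normal approximation with tie correction otherwise).
#' \code{policy = "paper_literal"} swaps the two branches: a normal pair is
#' sent to Mann-Whitney and a non-normal pair to Levene plus t-test. Both
#' policies are provided because published pipelines state either reading;
#' every intermediate p-value and the test actually used are recorded.
#'
#' @param tumour_values,normal_values Numeric vectors (NAs dropped); each
#'   group needs >= 3 non-missing values.
#' @param policy \code{"conventional"} (default) or \code{"paper_literal"}.
#' @param alpha_normality Shapiro-Wilk significance level, default 0.05.
#' @param mirna Optional name used in error messages.
#' @return One-row data frame: \code{shapiro_p_tumour},
#'   \code{shapiro_p_normal}, \code{variance_test_p} (NA when Levene was not
#'   run), \code{test_used} (student_t / welch_t / mann_whitney),
#'   \code{p_value}, \code{n_tumour}, \code{n_normal}.
#' @export
test_differential <- function(tumour_values, normal_values,
                              policy = c("conventional", "paper_literal"),
                              alpha_normality = 0.05, mirna = NULL) {
  policy <- match.arg(policy)
  a <- tumour_values[!is.na(tumour_values)]
  b <- normal_values[!is.na(normal_values)]
  if (length(a) < 3L || length(b) < 3L)
    stop("group too small for differential testing",
         if (!is.null(mirna)) paste0(" (", mirna, ")"),
         ": need >= 3 non-missing values per group")
  sw_a <- safe_shapiro_p(a)
  sw_b <- safe_shapiro_p(b)
  frag <- function(test_used, p, lev = NA_real_) {
    data.frame(shapiro_p_tumour = sw_a, shapiro_p_normal = sw_b,
               variance_test_p = lev, test_used = test_used,
               p_value = p, n_tumour = length(a), n_normal = length(b),
               stringsAsFactors = FALSE)
  }
  # degenerate case: no variation anywhere
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(frag("mann_whitney", 1))
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    return(frag("mann_whitney", p))
  }
  normal_pair <- !is.na(sw_a) && !is.na(sw_b) &&
    sw_a > alpha_normality && sw_b > alpha_normality
  use_parametric <- if (policy == "conventional") normal_pair else !normal_pair
  if (use_parametric) {
    lev <- levene_p(a, b)
    equal_var <- !is.na(lev) && lev > 0.05
    tt <- stats::t.test(a, b, var.equal = equal_var)
    frag(if (equal_var) "student_t" else "welch_t", tt$p.value, lev)
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                             correct = TRUE)$p.value)
    frag("mann_whitney", p)
  }
}

# Shapiro-Wilk p, or NA when the test is undefined (n outside 3..5000 or a
# constant sample). NA counts as "not normal" in the branch decision.
safe_shapiro_p <- function(x) {
  if (length(x) < 3L || length(x) > 5000L || stats::sd(x) == 0)
    return(NA_real_)
  stats::shapiro.test(x)$p.value
}

# classic Levene: center = mean
levene_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) return(NA_real_)
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  res <- car::leveneTest(y, g, center = mean)
  res[["Pr(>F)"]][1]
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment; the adjustment batch is all miRNAs tested within
#' one cohort.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Vector of BH-adjusted q-values (capped at 1), same order as the
#'   input; empty input gives an empty vector.
#' @export
adjust_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Log2 fold change between tumour and normal expression
#'
#' Inputs are on the log2 scale. The default mode takes the difference of
#' log2 group means (tumour minus normal, so negative = downregulated in
#' tumour). The alternative computes the ratio of linear-scale group means
#' first and then takes log2 — the two differ whenever within-group spread
#' differs, and both are exposed because fold-change pipelines are written
#' either way.
#'
#' @param tumour_values,normal_values Numeric log2-scale vectors; NAs
#'   dropped; both groups must retain at least one value.
#' @param mode \code{"diff_of_log_means"} (default) or
#'   \code{"log_of_linear_mean_ratio"}.
#' @return Single numeric log2 fold change.
#' @export
compute_log2fc <- function(tumour_values, normal_values,
                           mode = c("diff_of_log_means",
                                    "log_of_linear_mean_ratio")) {
  mode <- match.arg(mode)
  a <- tumour_values[!is.na(tumour_values)]
  b <- normal_values[!is.na(normal_values)]
  if (!length(a) || !length(b))
    stop("cannot compute log2FC: a group is entirely missing")
  if (mode == "diff_of_log_means") mean(a) - mean(b)
  else log2(mean(2^a) / mean(2^b))
}

#' Per-cohort differential expression table
#'
#' Applies \code{\link{test_differential}} and \code{\link{compute_log2fc}}
#' to every miRNA of a cohort with at least \code{min_n} non-missing values
#' per group, then BH-adjusts the p-values across the cohort's tested
#' miRNAs. miRNAs failing the group-size requirement are omitted (reported
#' in the \code{"untested"} attribute) rather than aborting the cohort.
#'
#' @param matrix A preprocessed \code{\link{cohort_matrix}}.
#' @param policy,alpha_normality Passed to \code{\link{test_differential}}.
#' @param fc_mode Passed to \code{\link{compute_log2fc}}.
#' @param min_n Minimum per-group non-missing count to test a miRNA;
#'   default 3.
#' @return Data frame with one row per tested miRNA: \code{mirna},
#'   \code{cohort_id}, the \code{test_differential} columns, \code{q_value}
#'   and \code{log2fc}; attribute \code{"untested"} lists skipped miRNAs.
#' @export
run_differential <- function(matrix, policy = c("conventional",
                                                "paper_literal"),
                             fc_mode = c("diff_of_log_means",
                                         "log_of_linear_mean_ratio"),
                             alpha_normality = 0.05, min_n = 3L) {
  policy <- match.arg(policy)
  fc_mode <- match.arg(fc_mode)
  stopifnot(inherits(matrix, "cohort_matrix"))
  tum <- class_values(matrix, "tumour")
  nor <- class_values(matrix, "normal")
  testable <- rowSums(!is.na(tum)) >= min_n & rowSums(!is.na(nor)) >= min_n
  rows <- lapply(which(testable), function(i) {
    fr <- test_differential(tum[i, ], nor[i, ], policy = policy,
                            alpha_normality = alpha_normality,
                            mirna = rownames(tum)[i])
    fr$log2fc <- compute_log2fc(tum[i, ], nor[i, ], mode = fc_mode)
    fr
  })
  if (!length(rows))
    stop("no miRNA has enough non-missing values in both groups")
  res <- do.call(rbind, rows)
  res <- cbind(data.frame(mirna = rownames(tum)[testable],
                          cohort_id = matrix$cohort_id,
                          stringsAsFactors = FALSE),
               res)
  res$q_value <- adjust_fdr(res$p_value)
  rownames(res) <- NULL
  attr(res, "untested") <- rownames(tum)[!testable]
  res
}

#' Cross-cohort consensus selection of differentially expressed miRNAs
#'
#' A miRNA is "significant in a cohort" when its q-value is at or below
#' \code{q_threshold} there. The consensus rule selects miRNAs significant
#' in the designated reference cohort AND in at least \code{min_support}
#' non-reference cohorts (with the defaults: the reference plus 2 of the
#' supporting cohorts, i.e. at least 3 cohorts in total). Regulation
#' direction per cohort is the sign of the log2 fold change, recorded in
#' every cohort where the miRNA is significant.
#'
#' @param results Named list of per-cohort data frames from
#'   \code{\link{run_differential}} (names = cohort ids), or an unnamed list
#'   (cohort ids taken from the tables).
#' @param reference_cohort Id of the reference cohort; must be present.
#' @param min_support Minimum number of significant non-reference cohorts;
#'   default 2.
#' @param q_threshold FDR threshold; default 0.05.
#' @return Data frame (class \code{consensus_table}) with one row per miRNA
#'   observed anywhere: \code{mirna}, \code{in_reference},
#'   \code{n_geo_support} (significant non-reference cohorts),
#'   \code{cohorts_significant} (";"-joined), \code{directions}
#'   (";"-joined \code{cohort:up|down} among significant cohorts),
#'   \code{direction_consistent}, \code{selected}. Rows sorted by miRNA so
#'   the result is invariant to cohort input order.
#' @export
consensus_select <- function(results, reference_cohort, min_support = 2L,
                             q_threshold = 0.05) {
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- vapply(results, function(r) r$cohort_id[1], character(1))
  if (!reference_cohort %in% names(results))
    stop("reference cohort ", shQuote(reference_cohort),
         " not among the supplied cohorts")
  sig <- lapply(results, function(r) r[r$q_value <= q_threshold, , drop = FALSE])
  all_mirnas <- sort(unique(unlist(lapply(results, `[[`, "mirna"))))
  other <- setdiff(names(results), reference_cohort)
  rows <- lapply(all_mirnas, function(m) {
    sig_in <- names(sig)[vapply(sig, function(s) m %in% s$mirna, logical(1))]
    dirs <- vapply(sig_in, function(cid) {
      fc <- sig[[cid]]$log2fc[sig[[cid]]$mirna == m][1]
      if (fc >= 0) "up" else "down"
    }, character(1))
    data.frame(
      mirna = m,
      in_reference = reference_cohort %in% sig_in,
      n_geo_support = sum(sig_in %in% other),
      cohorts_significant = paste(sort(sig_in), collapse = ";"),
      directions = paste(paste0(sort(sig_in), ":",
                                dirs[order(sig_in)]), collapse = ";"),
      direction_consistent = length(unique(dirs)) <= 1L,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$selected <- tab$in_reference & tab$n_geo_support >= min_support
  attr(tab, "reference_cohort") <- reference_cohort
  attr(tab, "min_support") <- min_support
  attr(tab, "q_threshold") <- q_threshold
  class(tab) <- c("consensus_table", "data.frame")
  tab
}

#' Restrict a consensus table to direction-consistent selections
#'
#' Keeps selected miRNAs whose recorded regulation direction is identical in
#' every cohort where they are significant; miRNAs with opposite directions
#' in at least one cohort are dropped from the final list (they remain in
#' the input table, flagged \code{direction_consistent = FALSE}).
#'
#' @param consensus A \code{consensus_table} from
#'   \code{\link{consensus_select}}.
#' @return The subset of rows with \code{selected} and
#'   \code{direction_consistent} both TRUE, with a \code{direction} column
#'   (\code{"up"} or \code{"down"}).
#' @export
direction_filter <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_table"))
  keep <- consensus[consensus$selected & consensus$direction_consistent, ,
                    drop = FALSE]
  keep$direction <- vapply(strsplit(keep$directions, ";"), function(d) {
    sub("^.*:", "", d[1])
  }, character(1))
  rownames(keep) <- NULL
  keep
}
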