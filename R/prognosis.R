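#' Median split of patients on one marker
#'
#' Patients strictly above the median expression form the higher-expression
#' group; patients at or below it form the lower-expression group (equality
#' is not "above", so ties go to the lower group).
#'
#' @param values Named numeric vector of tumour expression, names =
#'   patient ids; NAs dropped.
#' @param patients Optional subset of patient ids to analyze.
#' @return A \code{survival_groups} object (see
#'   \code{\link{panel_groups}}) with an empty excluded set.
#' @export
median_split <- function(values, patients = names(values)) {
  values <- values[patients]
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2L)
    stop("median split impossible: all expression values identical")
  med <- stats::median(values)
  new_survival_groups(panel = NA_character_,
                      higher_ids = names(values)[values > med],
                      lower_ids = names(values)[values <= med],
                      excluded_ids = character(0),
                      medians = med)
}

new_survival_groups <- function(panel, higher_ids, lower_ids, excluded_ids,
                                medians, rejected = FALSE) {
  structure(list(panel = panel, higher_ids = higher_ids,
                 lower_ids = lower_ids, excluded_ids = excluded_ids,
                 medians = medians, rejected = rejected),
            class = "survival_groups")
}

#' @export
print.survival_groups <- function(x, ...) {
  cat(sprintf("survival_groups [%s]: %d higher, %d lower, %d excluded%s\n",
              paste(x$panel, collapse = "+"),
              length(x$higher_ids), length(x$lower_ids),
              length(x$excluded_ids),
              if (x$rejected) " (REJECTED: group below minimum)" else ""))
  invisible(x)
}

#' Concordant-median grouping for a miRNA panel
#'
#' Multi-marker extension of the median split: a patient joins the
#' higher-expression group only when above the median for EVERY panel
#' miRNA, and the lower-expression group only when at-or-below for every
#' one; patients discordant across panel members are excluded. Because the
#' conjunction can only shrink groups as the panel grows, large panels run
#' out of patients — the reason panel size is capped in practice. Medians
#' are computed on the analyzed patients (those with no missing value for
#' any panel miRNA). A \code{"meanscore"} mode is provided for sensitivity
#' analysis: patients are median-split on the mean of the panel miRNAs'
#' standardized expressions, which preserves group sizes.
#'
#' @param matrix Tumour \code{\link{cohort_matrix}} (columns = patients),
#'   possibly already restricted to one disease stage.
#' @param panel Character vector of panel miRNA names (size >= 1).
#' @param patients Patients to analyze; default all columns.
#' @param min_group Minimum size of each group for the panel to be tested;
#'   default 30. Smaller panels are returned with \code{rejected = TRUE}.
#' @param grouping \code{"concordant"} (default) or \code{"meanscore"}.
#' @return A \code{survival_groups} object.
#' @export
panel_groups <- function(matrix, panel, patients = colnames(matrix$values),
                         min_group = 30L,
                         grouping = c("concordant", "meanscore")) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(matrix, "cohort_matrix"))
  missing_mirnas <- setdiff(panel, rownames(matrix$values))
  if (length(missing_mirnas))
    stop("panel miRNA(s) not in matrix: ",
         paste(missing_mirnas, collapse = ", "))
  expr <- matrix$values[panel, patients, drop = FALSE]
  complete <- colSums(is.na(expr)) == 0L
  expr <- expr[, complete, drop = FALSE]
  if (ncol(expr) < 2L) stop("fewer than 2 patients with complete panel values")
  if (grouping == "meanscore") {
    z <- t(scale(t(expr)))
    score <- colMeans(z)
    if (length(unique(score)) < 2L)
      stop("median split impossible: constant panel score")
    med <- stats::median(score)
    grp <- new_survival_groups(panel, names(score)[score > med],
                               names(score)[score <= med], character(0),
                               medians = med)
  } else {
    meds <- apply(expr, 1, stats::median)
    above <- expr > meds              # matrix recycling over columns
    all_above <- colSums(above) == length(panel)
    all_below <- colSums(!above) == length(panel)
    grp <- new_survival_groups(
      panel,
      higher_ids = colnames(expr)[all_above],
      lower_ids = colnames(expr)[all_below],
      excluded_ids = colnames(expr)[!(all_above | all_below)],
      medians = meds)
  }
  grp$rejected <- min(length(grp$higher_ids), length(grp$lower_ids)) <
    min_group
  grp
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two right-censored survival samples:
#' at each distinct event time the observed events in group A are compared
#' with their hypergeometric expectation, chi2 = (sum O - E)^2 / sum V on
#' one degree of freedom.
#'
#' @param times_a,events_a Times (>= 0) and 0/1 event flags for group A.
#' @param times_b,events_b Same for group B.
#' @return List \code{chi2}, \code{p}. With no events in either group the
#'   test is undefined and p = 1 is returned with a warning.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) == length(events_a),
            length(times_b) == length(events_b),
            length(times_a) > 0, length(times_b) > 0)
  if (any(c(times_a, times_b) < 0)) stop("negative survival times")
  if (!all(c(events_a, events_b) %in% c(0, 1))) stop("event flags must be 0/1")
  if (sum(events_a) + sum(events_b) == 0) {
    warning("no events in either group; log-rank undefined, returning p = 1")
    return(list(chi2 = 0, p = 1))
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  chi2 <- unname(sd_fit$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Hazard ratio of the higher- vs lower-expression group
#'
#' Single-covariate Cox proportional-hazards fit (Efron tie handling) of a
#' binary group indicator; the hazard ratio is exp(coefficient) for the
#' higher group relative to the lower group, with a 95% Wald confidence
#' interval. Complete separation of the event processes makes the partial
#' likelihood monotone; such fits are flagged \code{converged = FALSE}
#' instead of crashing.
#'
#' @param group_indicator 0 (lower) / 1 (higher) per patient.
#' @param times,events Survival times and 0/1 event flags.
#' @return List \code{hr}, \code{ci} (length-2), \code{wald_p},
#'   \code{converged}.
#' @export
cox_hr <- function(group_indicator, times, events) {
  stopifnot(length(group_indicator) == length(times),
            length(times) == length(events))
  if (length(unique(group_indicator)) < 2L)
    stop("both group levels must be present")
  g <- as.numeric(group_indicator)
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ g, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  converged <- !diverged && is.finite(beta) && is.finite(se) &&
    abs(beta) < 15
  list(hr = exp(beta),
       ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       wald_p = 2 * stats::pnorm(-abs(beta / se)),
       converged = converged)
}

#' Enumerate candidate miRNA panels
#'
#' All unordered combinations of sizes \code{k_min..k_max} in deterministic
#' lexicographic order (by the input ordering of \code{mirnas}).
#'
#' @param mirnas Candidate miRNA names.
#' @param k_min,k_max Panel size range; defaults 2 and 5.
#' @return List of character vectors with attribute \code{"count"} =
#'   sum over k of choose(n, k).
#' @examples
#' length(enumerate_panels(letters[1:3], 2, 3))  # 4
#' @export
enumerate_panels <- function(mirnas, k_min = 2L, k_max = 5L) {
  if (k_min > k_max) stop("k_min must not exceed k_max")
  if (k_max > length(mirnas)) stop("k_max exceeds the number of miRNAs")
  panels <- list()
  for (k in seq(k_min, k_max)) {
    combos <- utils::combn(mirnas, k, simplify = FALSE)
    panels <- c(panels, combos)
  }
  attr(panels, "count") <- sum(choose(length(mirnas), k_min:k_max))
  panels
}

#' Exhaustive prognostic panel screen
#'
#' For one disease stage and endpoint, enumerates every panel of
#' \code{k_min..k_max} candidate miRNAs, groups patients by the
#' concordant-median rule, and tests higher- vs lower-expression survival
#' with the log-rank test and a Cox hazard ratio. Panels whose smaller
#' group falls below \code{min_group} are rejected without testing. A
#' panel "passes" at nominal log-rank p < \code{alpha}; no multiplicity
#' correction is applied across panels by default, but BH-adjusted
#' q-values over the tested panels are emitted as an extra column.
#'
#' @param matrix Tumour \code{\link{cohort_matrix}} (columns = patients;
#'   ids must match \code{clinical$patient_id}).
#' @param clinical Clinical data frame (see
#'   \code{\link{read_clinical_table}}).
#' @param stage Disease stage to analyze (\code{"I".."IV"}), or NULL for
#'   all stages pooled.
#' @param endpoint \code{"OS"} or \code{"RFS"}.
#' @param k_min,k_max Panel sizes; defaults 2 and 5 (single markers via
#'   \code{k_min = 1}).
#' @param min_group Minimum per-group patient count; default 30.
#' @param alpha Nominal log-rank significance level; default 0.05.
#' @param grouping Passed to \code{\link{panel_groups}}.
#' @param mirnas Candidate miRNAs; default all rows of \code{matrix}.
#' @return Data frame of tested panels sorted by log-rank p: \code{panel}
#'   ("+"-joined), \code{size}, \code{stage}, \code{endpoint},
#'   \code{n_higher}, \code{n_lower}, \code{n_excluded},
#'   \code{logrank_chi2}, \code{logrank_p}, \code{logrank_q}, \code{hr},
#'   \code{hr_lower}, \code{hr_upper}, \code{cox_converged},
#'   \code{passes}. Attribute \code{"counts"}: per-size enumerated /
#'   tested / rejected / passing. Attribute \code{"skipped"} is TRUE when
#'   the stage had too few patients to analyze at all (< 2 * min_group).
#' @export
screen_panels <- function(matrix, clinical, stage = NULL,
                          endpoint = c("OS", "RFS"), k_min = 2L, k_max = 5L,
                          min_group = 30L, alpha = 0.05,
                          grouping = c("concordant", "meanscore"),
                          mirnas = rownames(matrix$values)) {
  endpoint <- match.arg(endpoint)
  grouping <- match.arg(grouping)
  clinical <- validate_clinical(clinical)
  tcol <- if (endpoint == "OS") "os_time" else "rfs_time"
  ecol <- if (endpoint == "OS") "os_event" else "rfs_event"
  if (!all(c(tcol, ecol) %in% names(clinical)))
    stop("clinical table lacks ", endpoint, " columns (", tcol, ", ", ecol,
         ")")
  cl <- clinical[!is.na(clinical[[tcol]]) & !is.na(clinical[[ecol]]), ]
  if (!is.null(stage)) cl <- cl[cl$stage == stage, ]
  cl <- cl[cl$patient_id %in% colnames(matrix$values), ]
  empty <- panel_result_frame()
  if (nrow(cl) < 2 * min_group) {
    attr(empty, "counts") <- NULL
    attr(empty, "skipped") <- TRUE
    attr(empty, "n_patients") <- nrow(cl)
    return(empty)
  }
  patients <- cl$patient_id
  times <- stats::setNames(cl[[tcol]], patients)
  events <- stats::setNames(cl[[ecol]], patients)
  panels <- enumerate_panels(mirnas, k_min, k_max)
  rows <- vector("list", length(panels))
  n_rejected <- integer(0)
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    grp <- panel_groups(matrix, p, patients = patients,
                        min_group = min_group, grouping = grouping)
    if (grp$rejected) {
      n_rejected <- c(n_rejected, length(p))
      next
    }
    lr <- suppressWarnings(
      logrank_test(times[grp$higher_ids], events[grp$higher_ids],
                   times[grp$lower_ids], events[grp$lower_ids]))
    ids <- c(grp$higher_ids, grp$lower_ids)
    cx <- cox_hr(rep(c(1, 0), c(length(grp$higher_ids),
                                length(grp$lower_ids))),
                 times[ids], events[ids])
    rows[[i]] <- data.frame(
      panel = paste(p, collapse = "+"), size = length(p),
      stage = if (is.null(stage)) "all" else stage, endpoint = endpoint,
      n_higher = length(grp$higher_ids), n_lower = length(grp$lower_ids),
      n_excluded = length(grp$excluded_ids),
      logrank_chi2 = lr$chi2, logrank_p = lr$p,
      hr = cx$hr, hr_lower = cx$ci[1], hr_upper = cx$ci[2],
      cox_converged = cx$converged,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out)) {
    out$logrank_q <- adjust_fdr(out$logrank_p)
    out$passes <- out$logrank_p < alpha &
      pmin(out$n_higher, out$n_lower) >= min_group
    out <- out[order(out$logrank_p, out$panel), ]
    rownames(out) <- NULL
  }
  sizes <- seq(k_min, k_max)
  counts <- data.frame(
    size = sizes,
    enumerated = choose(length(mirnas), sizes),
    tested = vapply(sizes, function(k) sum(out$size == k), numeric(1)),
    rejected = vapply(sizes, function(k) sum(n_rejected == k), numeric(1)),
    passing = vapply(sizes, function(k)
      sum(out$size == k & out$passes), numeric(1)))
  attr(out, "counts") <- counts
  attr(out, "skipped") <- FALSE
  attr(out, "n_patients") <- nrow(cl)
  out
}

panel_result_frame <- function() {
  data.frame(panel = character(0), size = integer(0), stage = character(0),
             endpoint = character(0), n_higher = integer(0),
             n_lower = integer(0), n_excluded = integer(0),
             logrank_chi2 = numeric(0), logrank_p = numeric(0),
             hr = numeric(0), hr_lower = numeric(0), hr_upper = numeric(0),
             cox_converged = logical(0), logrank_q = numeric(0),
             passes = logical(0), stringsAsFactors = FALSE)
}
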