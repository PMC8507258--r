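#' Assemble a pipeline configuration
#'
#' Collects every tunable threshold of the discovery workflow with its
#' reference default: 0.5 missingness cut, 1.5 Tukey fence, 0.05
#' normality/correlation/log-rank alpha, 5% FDR, consensus support of 2
#' non-reference cohorts, 30-patient minimum groups and panels of up to 5
#' miRNAs.
#'
#' @param missing_threshold Per-group missingness cut; default 0.5.
#' @param fence_k Tukey fence multiplier; default 1.5.
#' @param alpha Significance level for normality, correlation and
#'   log-rank tests; default 0.05.
#' @param q_threshold FDR threshold for per-cohort significance; default
#'   0.05.
#' @param min_support Non-reference cohorts required by the consensus
#'   rule; default 2.
#' @param min_group Minimum survival group size; default 30.
#' @param k_min,k_max Panel size range; defaults 2 and 5.
#' @param policy Differential test-selection policy; see
#'   \code{\link{test_differential}}.
#' @param fc_mode Fold-change mode; see \code{\link{compute_log2fc}}.
#' @param grouping Panel grouping rule; see \code{\link{panel_groups}}.
#' @param tumour_only_correlation Correlate on tumour samples only;
#'   default TRUE.
#' @param seed Integer seed recorded in the run manifest.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(missing_threshold = 0.5, fence_k = 1.5,
                            alpha = 0.05, q_threshold = 0.05,
                            min_support = 2L, min_group = 30L,
                            k_min = 2L, k_max = 5L,
                            policy = c("conventional", "paper_literal"),
                            fc_mode = c("diff_of_log_means",
                                        "log_of_linear_mean_ratio"),
                            grouping = c("concordant", "meanscore"),
                            tumour_only_correlation = TRUE, seed = 1L) {
  cfg <- list(missing_threshold = missing_threshold, fence_k = fence_k,
              alpha = alpha, q_threshold = q_threshold,
              min_support = as.integer(min_support),
              min_group = as.integer(min_group),
              k_min = as.integer(k_min), k_max = as.integer(k_max),
              policy = match.arg(policy), fc_mode = match.arg(fc_mode),
              grouping = match.arg(grouping),
              tumour_only_correlation = tumour_only_correlation,
              seed = as.integer(seed))
  stopifnot(cfg$missing_threshold > 0, cfg$missing_threshold <= 1,
            cfg$fence_k >= 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$q_threshold > 0, cfg$q_threshold <= 1,
            cfg$min_support >= 0, cfg$min_group >= 1,
            cfg$k_min >= 1, cfg$k_min <= cfg$k_max)
  structure(cfg, class = "pipeline_config")
}

#' Run the full discovery workflow
#'
#' Executes, in order: per-cohort preprocessing (missingness filter, then
#' boxplot outlier masking), per-cohort differential testing with BH
#' adjustment, cross-cohort consensus selection, direction-consistency
#' filtering, target-network analysis (MTI filtering, disease-gene
#' crossing, expression correlation, pathway enrichment, miRNA-pathway
#' incidence), per-cohort ROC evaluation of the final miRNAs, and the
#' prognostic panel screen on the reference cohort's clinical data. The
#' target-network and prognosis stages run only when their inputs are
#' supplied. A summary of per-stage miRNA counts (initial / after
#' missingness filter / tested / consensus / direction-consistent) is
#' attached, mirroring the usual attrition flowchart of such studies.
#'
#' @param cohorts Named list of \code{\link{cohort_matrix}} objects.
#' @param reference_cohort Name of the reference cohort; default the
#'   first.
#' @param clinical Optional clinical data frame for the reference
#'   cohort's tumour patients.
#' @param mti Optional MTI edge table.
#' @param disease_genes Optional disease gene list.
#' @param gene_sets Optional \code{\link{gene_set_collection}}.
#' @param gene_matrix Optional gene-expression \code{cohort_matrix} for
#'   correlation analysis.
#' @param config A \code{\link{pipeline_config}}.
#' @param stages Stages to screen for prognosis; default II and III (the
#'   stages with enough patients in typical cohorts).
#' @param endpoints Endpoints to screen; default OS and RFS.
#' @param outdir Optional directory: every intermediate table is written
#'   as TSV plus a JSON-ish run manifest.
#' @return A list bundle: \code{preprocessed}, \code{reports},
#'   \code{differential}, \code{consensus}, \code{final_mirnas},
#'   \code{network}, \code{roc}, \code{panels}, \code{summary},
#'   \code{manifest}.
#' @export
run_discovery <- function(cohorts, reference_cohort = names(cohorts)[1],
                          clinical = NULL, mti = NULL,
                          disease_genes = NULL, gene_sets = NULL,
                          gene_matrix = NULL,
                          config = pipeline_config(),
                          stages = c("II", "III"),
                          endpoints = c("OS", "RFS"), outdir = NULL) {
  stopifnot(length(cohorts) >= 1,
            all(vapply(cohorts, inherits, logical(1), "cohort_matrix")))
  if (is.null(names(cohorts)))
    names(cohorts) <- vapply(cohorts, `[[`, "", "cohort_id")
  if (!reference_cohort %in% names(cohorts))
    stop("reference cohort ", shQuote(reference_cohort), " not supplied")

  pre <- lapply(cohorts, preprocess_cohort,
                threshold = config$missing_threshold,
                fence_k = config$fence_k)
  matrices <- lapply(pre, `[[`, "matrix")
  reports <- lapply(pre, `[[`, "reports")

  de <- lapply(matrices, run_differential, policy = config$policy,
               fc_mode = config$fc_mode, alpha_normality = config$alpha)
  consensus <- consensus_select(de, reference_cohort,
                                min_support = config$min_support,
                                q_threshold = config$q_threshold)
  final <- direction_filter(consensus)
  final_mirnas <- final$mirna

  network <- NULL
  if (!is.null(mti)) {
    edges <- filter_mti(mti)
    edges <- edges[edges$mirna %in% final_mirnas, , drop = FALSE]
    network <- list(edges = edges)
    if (!is.null(disease_genes)) {
      crossed <- cross_disease_genes(edges, disease_genes)
      network$disease_edges <- crossed$edges
      network$degrees <- crossed$degrees
    }
    if (!is.null(gene_matrix)) {
      use_edges <- if (!is.null(network$disease_edges))
        network$disease_edges else edges
      network$correlations <- correlate_targets(
        use_edges, matrices[[reference_cohort]], gene_matrix,
        tumour_only = config$tumour_only_correlation,
        alpha_normality = config$alpha)
    }
    if (!is.null(gene_sets)) {
      target_genes <- unique(
        if (!is.null(network$disease_edges)) network$disease_edges$gene
        else edges$gene)
      network$enrichment <- suppressWarnings(
        enrich_genesets(target_genes, gene_sets))
      network$pathway_matrix <- mirna_pathway_matrix(
        if (!is.null(network$disease_edges)) network$disease_edges
        else edges,
        gene_sets)
    }
  }

  roc <- lapply(matrices, roc_table, mirnas = final_mirnas)

  panels <- NULL
  if (!is.null(clinical) && length(final_mirnas) >= config$k_min) {
    # clinical carries tumour patients only, so the screen's patient-id
    # intersection restricts the matrix to tumour samples by itself
    ref_tum <- matrices[[reference_cohort]]
    panels <- list()
    for (st in stages) for (ep in endpoints) {
      key <- paste(st, ep, sep = "_")
      panels[[key]] <- tryCatch(
        screen_panels(ref_tum, clinical, stage = st, endpoint = ep,
                      k_min = config$k_min,
                      k_max = min(config$k_max, length(final_mirnas)),
                      min_group = config$min_group, alpha = config$alpha,
                      grouping = config$grouping, mirnas = final_mirnas),
        error = function(e) {
          out <- panel_result_frame()
          attr(out, "skipped") <- TRUE
          attr(out, "error") <- conditionMessage(e)
          out
        })
    }
  }

  summary <- data.frame(
    cohort = names(cohorts),
    n_initial = vapply(cohorts, function(x) nrow(x$values), numeric(1)),
    n_after_missing_filter = vapply(reports, function(r)
      r$filter_missing$n_after, numeric(1)),
    n_tested = vapply(de, nrow, numeric(1)),
    stringsAsFactors = FALSE)
  attr(summary, "n_consensus") <- sum(consensus$selected)
  attr(summary, "n_direction_consistent") <- length(final_mirnas)

  bundle <- list(preprocessed = matrices, reports = reports,
                 differential = de, consensus = consensus,
                 final_mirnas = final_mirnas, final_table = final,
                 network = network, roc = roc, panels = panels,
                 summary = summary,
                 manifest = list(config = unclass(config),
                                 reference_cohort = reference_cohort,
                                 cohorts = names(cohorts),
                                 package_version =
                                   as.character(utils::packageVersion("mircons")),
                                 timestamp = NA))
  if (!is.null(outdir)) write_discovery_bundle(bundle, outdir)
  bundle
}

write_discovery_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  for (nm in names(bundle$differential))
    wt(bundle$differential[[nm]], paste0("de_", nm, ".tsv"))
  wt(bundle$consensus, "consensus.tsv")
  wt(bundle$final_table, "final_mirnas.tsv")
  for (nm in names(bundle$roc))
    wt(bundle$roc[[nm]], paste0("roc_", nm, ".tsv"))
  if (!is.null(bundle$network)) {
    if (!is.null(bundle$network$correlations))
      wt(bundle$network$correlations, "correlations.tsv")
    if (!is.null(bundle$network$enrichment))
      wt(bundle$network$enrichment, "enrichment.tsv")
    if (!is.null(bundle$network$degrees))
      wt(bundle$network$degrees, "mirna_degrees.tsv")
  }
  if (!is.null(bundle$panels))
    for (nm in names(bundle$panels))
      if (nrow(bundle$panels[[nm]]))
        wt(bundle$panels[[nm]], paste0("panels_", nm, ".tsv"))
  wt(bundle$summary, "summary.tsv")
  manifest <- bundle$manifest
  dput(manifest, file.path(outdir, "manifest.R"))
  invisible(NULL)
}

#' Re-evaluate a frozen miRNA list on held-out validation cohorts
#'
#' For each validation cohort and each frozen miRNA: log2 fold change and
#' regulation direction, orientation-resolved AUC and its accuracy class.
#' miRNAs absent from a cohort get status \code{"absent"} and do not count
#' against concordance. The concordance table lists, per miRNA, the number
#' of cohorts where it was evaluable and the number where it was
#' downregulated (resp. upregulated), flagging miRNAs with the same
#' direction in every evaluable cohort.
#'
#' @param frozen_mirnas Non-empty character vector of miRNA names fixed by
#'   the discovery phase.
#' @param validation_cohorts Named list of \code{\link{cohort_matrix}}
#'   objects (already preprocessed or raw).
#' @param config A \code{\link{pipeline_config}} (fold-change mode and
#'   preprocessing thresholds are honoured).
#' @param preprocess Run the standard preprocessing first; default TRUE.
#' @return List: \code{per_cohort} (data frame mirna x cohort:
#'   \code{status}, \code{log2fc}, \code{direction}, \code{auc},
#'   \code{accuracy_class}) and \code{concordance} (per-miRNA summary with
#'   \code{down_in_all}/\code{up_in_all} flags).
#' @export
run_validation <- function(frozen_mirnas, validation_cohorts,
                           config = pipeline_config(), preprocess = TRUE) {
  if (!length(frozen_mirnas)) stop("frozen miRNA list is empty")
  stopifnot(length(validation_cohorts) >= 1)
  if (is.null(names(validation_cohorts)))
    names(validation_cohorts) <- vapply(validation_cohorts, `[[`, "",
                                        "cohort_id")
  rows <- list()
  for (nm in names(validation_cohorts)) {
    cm <- validation_cohorts[[nm]]
    if (preprocess)
      cm <- preprocess_cohort(cm, threshold = config$missing_threshold,
                              fence_k = config$fence_k)$matrix
    tum <- class_values(cm, "tumour")
    nor <- class_values(cm, "normal")
    for (m in frozen_mirnas) {
      if (!m %in% rownames(cm$values) ||
          sum(!is.na(tum[m, ])) == 0 || sum(!is.na(nor[m, ])) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = m, cohort_id = nm, status = "absent",
          log2fc = NA_real_, direction = NA_character_, auc = NA_real_,
          accuracy_class = NA_character_, stringsAsFactors = FALSE)
        next
      }
      fc <- compute_log2fc(tum[m, ], nor[m, ], mode = config$fc_mode)
      auc <- compute_auc(cm$values[m, ], cm$sample_labels)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = m, cohort_id = nm, status = "evaluated",
        log2fc = fc, direction = if (fc >= 0) "up" else "down",
        auc = auc$auc, accuracy_class = auc$accuracy_class,
        stringsAsFactors = FALSE)
    }
  }
  per_cohort <- do.call(rbind, rows)
  conc <- lapply(frozen_mirnas, function(m) {
    sub <- per_cohort[per_cohort$mirna == m &
                        per_cohort$status == "evaluated", ]
    data.frame(mirna = m,
               n_evaluable = nrow(sub),
               n_down = sum(sub$direction == "down"),
               n_up = sum(sub$direction == "up"),
               down_in_all = nrow(sub) > 0 && all(sub$direction == "down"),
               up_in_all = nrow(sub) > 0 && all(sub$direction == "up"),
               stringsAsFactors = FALSE)
  })
  list(per_cohort = per_cohort, concordance = do.call(rbind, conc))
}
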