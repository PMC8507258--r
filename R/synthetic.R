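#' Configuration for the synthetic multi-cohort simulator
#'
#' Defines the generative model used to exercise the whole discovery
#' pipeline without any external download. Expression is simulated on the
#' log2 scale: each miRNA draws a baseline mean from Uniform(4, 12) log2
#' units and samples are Normal(mean, \code{noise_sd}); a planted subset of
#' \code{n_true_de} miRNAs has its tumour mean shifted by \code{de_shift}
#' (negative = downregulated in tumour) in every cohort carrying it.
#' Cohorts share a core of \code{round(mirna_overlap_fraction * n_mirnas)}
#' miRNAs (the planted miRNAs live in the core); the remaining inventory
#' enters each cohort independently with probability 1/2. Missing entries
#' are injected completely at random at \code{missing_rate}; spike
#' outliers add +/- \code{outlier_magnitude} to a random
#' \code{outlier_rate} fraction of observed entries. Survival times for
#' the reference cohort's tumour patients follow an exponential hazard
#' log-linear in the planted panel score (mean of the panel miRNAs'
#' standardized expressions), with independent exponential censoring
#' calibrated so the expected censored fraction is \code{censor_rate}.
#'
#' @param n_cohorts Number of cohorts (>= 2); default 4 (one reference
#'   plus three supporting cohorts).
#' @param n_tumour,n_normal Per-cohort group sizes; recycled across
#'   cohorts. Defaults 50 tumour / 25 normal.
#' @param n_mirnas miRNA inventory size; default 300.
#' @param mirna_overlap_fraction Fraction of the inventory shared by all
#'   cohorts; default 0.8.
#' @param n_true_de Number of planted differentially expressed miRNAs;
#'   default 25.
#' @param de_shift Planted tumour-minus-normal mean difference (log2);
#'   default -2 (downregulated in tumour).
#' @param noise_sd Within-group standard deviation (log2); default 0.5.
#' @param missing_rate Entry-level missingness; default 0.05.
#' @param outlier_rate Spike-outlier fraction; default 0.01.
#' @param outlier_magnitude Spike size (log2); default 6.
#' @param n_genes Gene inventory for the target layer; default 200.
#' @param n_true_correlated_pairs Planted miRNA-gene correlated pairs;
#'   default 20.
#' @param target_corr Planted correlation (sign included); default -0.7.
#' @param disease_gene_fraction Fraction of targeted genes placed on the
#'   disease list; default 0.5.
#' @param baseline_hazard Baseline event rate per year; default 0.1.
#' @param panel_size Number of planted prognostic miRNAs (taken from the
#'   planted DE set); default 3.
#' @param panel_log_hr Log hazard-ratio per unit of panel score; default
#'   log(4).
#' @param censor_rate Expected censored fraction; default 0.3.
#' @param stage_probs Probabilities of stages I-IV; default
#'   c(0.15, 0.35, 0.35, 0.15).
#' @param seed Integer RNG seed.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_cohorts = 4L, n_tumour = 50L, n_normal = 25L,
                       n_mirnas = 300L, mirna_overlap_fraction = 0.8,
                       n_true_de = 25L, de_shift = -2, noise_sd = 0.5,
                       missing_rate = 0.05, outlier_rate = 0.01,
                       outlier_magnitude = 6, n_genes = 200L,
                       n_true_correlated_pairs = 20L, target_corr = -0.7,
                       disease_gene_fraction = 0.5,
                       baseline_hazard = 0.1, panel_size = 3L,
                       panel_log_hr = log(4), censor_rate = 0.3,
                       stage_probs = c(I = 0.15, II = 0.35, III = 0.35,
                                       IV = 0.15),
                       seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_tumour = as.integer(n_tumour),
              n_normal = as.integer(n_normal),
              n_mirnas = as.integer(n_mirnas),
              mirna_overlap_fraction = mirna_overlap_fraction,
              n_true_de = as.integer(n_true_de), de_shift = de_shift,
              noise_sd = noise_sd, missing_rate = missing_rate,
              outlier_rate = outlier_rate,
              outlier_magnitude = outlier_magnitude,
              n_genes = as.integer(n_genes),
              n_true_correlated_pairs = as.integer(n_true_correlated_pairs),
              target_corr = target_corr,
              disease_gene_fraction = disease_gene_fraction,
              baseline_hazard = baseline_hazard,
              panel_size = as.integer(panel_size),
              panel_log_hr = panel_log_hr, censor_rate = censor_rate,
              stage_probs = stage_probs, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_cohorts < 2L) stop("need at least 2 cohorts")
    if (any(c(n_tumour, n_normal, n_mirnas, n_genes) < 1L))
      stop("counts must be positive")
    if (n_true_de < 0L || n_true_de > n_mirnas)
      stop("n_true_de must lie in [0, n_mirnas]")
    if (n_true_correlated_pairs > n_genes)
      stop("n_true_correlated_pairs must not exceed n_genes")
    probs <- c(mirna_overlap_fraction, missing_rate, outlier_rate,
               censor_rate, disease_gene_fraction)
    if (any(probs < 0 | probs > 1)) stop("rates must lie in [0, 1]")
    if (abs(target_corr) > 1) stop("target_corr must lie in [-1, 1]")
    if (noise_sd < 0 || baseline_hazard <= 0)
      stop("noise_sd must be >= 0 and baseline_hazard > 0")
    if (length(stage_probs) != 4L || any(stage_probs < 0) ||
        abs(sum(stage_probs) - 1) > 1e-8)
      stop("stage_probs must be 4 probabilities summing to 1")
    if (panel_size > n_true_de && panel_log_hr != 0)
      stop("panel_size exceeds the planted DE set")
  })
  invisible(cfg)
}

#' Simulate multi-cohort miRNA expression with planted truth
#'
#' See \code{\link{sim_config}} for the generative model. Fully
#' reproducible: the same config (same seed) gives identical output.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{cohorts} (named list of
#'   \code{\link{cohort_matrix}}; the first, \code{"cohort1"}, is the
#'   reference) and \code{truth}: \code{true_de} (data frame mirna,
#'   direction), \code{prognostic_panel}, \code{panel_direction},
#'   \code{de_means} (per-miRNA baseline means, reused by the companion
#'   generators).
#' @export
simulate_cohorts <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_tum <- rep_len(config$n_tumour, config$n_cohorts)
  n_nor <- rep_len(config$n_normal, config$n_cohorts)
  mirnas <- sprintf("sim-miR-%04d", seq_len(config$n_mirnas))
  n_core <- round(config$mirna_overlap_fraction * config$n_mirnas)
  core <- mirnas[seq_len(n_core)]
  periph <- setdiff(mirnas, core)
  if (config$n_true_de > n_core)
    stop("planted DE miRNAs must fit in the shared core; raise the overlap")
  true_de <- sample(core, config$n_true_de)
  base_mean <- stats::setNames(stats::runif(config$n_mirnas, 4, 12), mirnas)
  cohorts <- vector("list", config$n_cohorts)
  names(cohorts) <- paste0("cohort", seq_len(config$n_cohorts))
  for (c_i in seq_len(config$n_cohorts)) {
    extra <- periph[stats::runif(length(periph)) < 0.5]
    inv <- c(core, extra)
    n_s <- n_tum[c_i] + n_nor[c_i]
    labels <- rep(c("tumour", "normal"), c(n_tum[c_i], n_nor[c_i]))
    v <- matrix(stats::rnorm(length(inv) * n_s,
                             mean = rep(base_mean[inv], n_s),
                             sd = config$noise_sd),
                nrow = length(inv), ncol = n_s,
                dimnames = list(inv,
                                sprintf("%s-p%03d", names(cohorts)[c_i],
                                        seq_len(n_s))))
    de_rows <- intersect(inv, true_de)
    v[de_rows, labels == "tumour"] <-
      v[de_rows, labels == "tumour"] + config$de_shift
    if (config$outlier_rate > 0) {
      spike <- stats::runif(length(v)) < config$outlier_rate
      v[spike] <- v[spike] + sample(c(-1, 1), sum(spike), replace = TRUE) *
        config$outlier_magnitude
    }
    if (config$missing_rate > 0)
      v[stats::runif(length(v)) < config$missing_rate] <- NA_real_
    cohorts[[c_i]] <- cohort_matrix(v, labels, names(cohorts)[c_i])
  }
  panel <- if (config$panel_size > 0 && config$n_true_de > 0)
    sort(sample(true_de, min(config$panel_size, length(true_de))))
    else character(0)
  truth <- list(
    true_de = data.frame(mirna = sort(true_de),
                         direction = rep(if (config$de_shift >= 0) "up"
                                         else "down", length(true_de)),
                         stringsAsFactors = FALSE),
    prognostic_panel = panel,
    panel_log_hr = config$panel_log_hr,
    de_means = base_mean)
  list(cohorts = cohorts, truth = truth)
}

#' Simulate clinical survival data for the reference cohort
#'
#' Event times are exponential with subject hazard
#' baseline_hazard * exp(panel_log_hr * panel_score), where panel_score is
#' the mean of the planted panel miRNAs' standardized tumour expressions
#' (missing entries mean-imputed for scoring only). Censoring times are
#' exponential with rate chosen so that, at the average subject hazard,
#' the expected censored fraction equals \code{censor_rate};
#' \code{censor_rate = 0} means no censoring at all. Stages are i.i.d.
#' from \code{stage_probs}. Recurrence-free survival is generated from the
#' same linear predictor with a 1.5x baseline hazard.
#'
#' @param config A \code{\link{sim_config}}.
#' @param tumour_matrix The reference cohort's \code{cohort_matrix} (only
#'   tumour columns are used).
#' @param truth Ground-truth list from \code{\link{simulate_cohorts}}.
#' @return A clinical data frame (see \code{\link{read_clinical_table}}).
#' @export
simulate_clinical <- function(config, tumour_matrix, truth) {
  validate_sim_config(config)
  panel <- truth$prognostic_panel
  if (!length(panel) && config$panel_log_hr != 0)
    stop("empty prognostic panel with nonzero panel_log_hr")
  if (length(panel) && !all(panel %in% rownames(tumour_matrix$values)))
    stop("panel miRNAs missing from the tumour matrix")
  set.seed(config$seed + 1L)
  tum <- class_values(tumour_matrix, "tumour")
  patients <- colnames(tum)
  score <- if (length(panel)) {
    expr <- tum[panel, , drop = FALSE]
    for (i in seq_len(nrow(expr)))   # impute for scoring only
      expr[i, is.na(expr[i, ])] <- mean(expr[i, ], na.rm = TRUE)
    colMeans(t(scale(t(expr))))
  } else rep(0, length(patients))
  lam <- config$baseline_hazard * exp(config$panel_log_hr * score)
  draw <- function(rates) {
    t_event <- stats::rexp(length(rates), rates)
    if (config$censor_rate > 0) {
      # one shared censoring rate mu solving mean_i mu/(lambda_i + mu) =
      # censor_rate, so the expected censored fraction is calibrated even
      # when the panel effect spreads the subject hazards
      f <- function(mu) mean(mu / (rates + mu)) - config$censor_rate
      mu <- stats::uniroot(f, lower = 1e-10,
                           upper = max(rates) * 1e6)$root
      t_cens <- stats::rexp(length(rates), mu)
      list(time = pmin(t_event, t_cens),
           event = as.numeric(t_event <= t_cens))
    } else list(time = t_event, event = rep(1, length(rates)))
  }
  os <- draw(lam)
  rfs <- draw(1.5 * lam)
  data.frame(patient_id = patients,
             stage = sample(names(config$stage_probs), length(patients),
                            replace = TRUE, prob = config$stage_probs),
             os_time = os$time, os_event = os$event,
             rfs_time = rfs$time, rfs_event = rfs$event,
             stringsAsFactors = FALSE)
}

#' Simulate the miRNA-target layer with planted correlations
#'
#' Builds a gene expression matrix over the same samples as the supplied
#' cohort, a validated-interaction table, a disease gene list and a
#' gene-set collection. Each planted pair's gene expression is
#' sign(target_corr) * |target_corr| times the (standardized) miRNA
#' expression plus Gaussian noise scaled so the population correlation is
#' \code{target_corr}; remaining genes are independent noise. The MTI
#' table holds every true pair plus decoy pairs (independent genes), a
#' few weak-evidence rows and one non-human row so the filtering step has
#' something to remove. The disease list covers
#' \code{disease_gene_fraction} of the targeted genes plus background
#' genes; gene sets partition a slice of the inventory into six
#' "pathways".
#'
#' @param config A \code{\link{sim_config}}.
#' @param tumour_matrix A \code{\link{cohort_matrix}} (the reference
#'   cohort); gene expression is generated for all of its samples.
#' @param truth Ground truth from \code{\link{simulate_cohorts}}; the
#'   planted pairs' miRNAs are drawn from the planted DE set when
#'   available.
#' @return List: \code{gene_matrix} (\code{cohort_matrix}),
#'   \code{mti_edges}, \code{disease_genes}, \code{gene_sets},
#'   \code{true_pairs} (data frame mirna, gene, sign).
#' @export
simulate_target_layer <- function(config, tumour_matrix, truth) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  samples <- colnames(tumour_matrix$values)
  n_s <- length(samples)
  gmean <- stats::runif(config$n_genes, 4, 12)
  gv <- matrix(stats::rnorm(config$n_genes * n_s,
                            mean = rep(gmean, n_s), sd = config$noise_sd),
               nrow = config$n_genes, dimnames = list(genes, samples))
  pool <- intersect(truth$true_de$mirna, rownames(tumour_matrix$values))
  if (!length(pool)) pool <- rownames(tumour_matrix$values)
  pair_mirnas <- sample(pool, config$n_true_correlated_pairs, replace = TRUE)
  pair_genes <- sample(genes, config$n_true_correlated_pairs)
  rho <- config$target_corr
  cls <- tumour_matrix$sample_labels
  for (i in seq_len(config$n_true_correlated_pairs)) {
    x <- tumour_matrix$values[pair_mirnas[i], ]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    # standardize within each class so the planted correlation holds both
    # overall and inside the tumour-only subset used downstream
    z <- numeric(n_s)
    for (cl in levels(cls)) {
      idx <- cls == cl
      z[idx] <- if (stats::sd(x[idx]) > 0) as.numeric(scale(x[idx])) else 0
    }
    g <- gmean[match(pair_genes[i], genes)] +
      config$noise_sd * (rho * z + sqrt(1 - rho^2) * stats::rnorm(n_s))
    gv[pair_genes[i], ] <- g
  }
  true_pairs <- data.frame(mirna = pair_mirnas, gene = pair_genes,
                           sign = sign(rho), stringsAsFactors = FALSE)
  n_decoys <- max(3L * config$n_true_correlated_pairs, 10L)
  decoy_pool <- setdiff(genes, pair_genes)
  if (!length(decoy_pool)) decoy_pool <- genes
  decoys <- data.frame(
    mirna = sample(rownames(tumour_matrix$values), n_decoys, replace = TRUE),
    gene = sample(decoy_pool, n_decoys, replace = TRUE),
    stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(mirna = true_pairs$mirna, gene = true_pairs$gene,
               species = "Homo sapiens", support_type = "Functional MTI",
               stringsAsFactors = FALSE),
    data.frame(mirna = decoys$mirna, gene = decoys$gene,
               species = "Homo sapiens", support_type = "Functional MTI",
               stringsAsFactors = FALSE))
  # chaff for the filter: weak evidence + wrong species
  chaff_genes <- sample(genes, 4)
  edges <- rbind(edges,
    data.frame(mirna = sample(rownames(tumour_matrix$values), 4),
               gene = chaff_genes,
               species = c("Homo sapiens", "Homo sapiens",
                           "Mus musculus", "Mus musculus"),
               support_type = c("Functional MTI (Weak)",
                                "Functional MTI (Weak)",
                                "Functional MTI", "Functional MTI"),
               stringsAsFactors = FALSE))
  edges <- edges[!duplicated(edges[, c("mirna", "gene", "species",
                                       "support_type")]), ]
  targeted <- unique(edges$gene[edges$species == "Homo sapiens" &
                                  edges$support_type == "Functional MTI"])
  n_dis <- round(config$disease_gene_fraction * length(targeted))
  disease_genes <- character(0)
  if (n_dis > 0)
    disease_genes <- sample(targeted, n_dis)
  disease_genes <- unique(c(disease_genes,
                            sample(setdiff(genes, targeted),
                                   min(10L, length(setdiff(genes,
                                                           targeted))))))
  if (config$disease_gene_fraction == 0)
    disease_genes <- setdiff(disease_genes, targeted)
  n_path_genes <- min(config$n_genes, 120L)
  path_slice <- genes[seq_len(n_path_genes)]
  sets <- split(path_slice,
                rep_len(paste0("PATHWAY_", 1:6), n_path_genes))
  gene_sets <- gene_set_collection(sets, extra_universe = genes)
  list(gene_matrix = cohort_matrix(gv,
                                   tumour_matrix$sample_labels,
                                   paste0(tumour_matrix$cohort_id,
                                          "-genes")),
       mti_edges = edges,
       disease_genes = disease_genes,
       gene_sets = gene_sets,
       true_pairs = true_pairs)
}

#' Simulate a complete study and optionally write it to disk
#'
#' Convenience wrapper running all three generators off one configuration;
#' with \code{outdir} set, writes the TSV/GMT files that
#' \code{\link{read_expression_matrix}} and friends read back.
#'
#' @param config A \code{\link{sim_config}}.
#' @param outdir Optional output directory.
#' @return List: \code{cohorts}, \code{clinical}, \code{target_layer},
#'   \code{truth}.
#' @export
simulate_study <- function(config, outdir = NULL) {
  sim <- simulate_cohorts(config)
  reference <- sim$cohorts[[1]]
  clinical <- simulate_clinical(config, reference, sim$truth)
  target <- simulate_target_layer(config, reference, sim$truth)
  out <- list(cohorts = sim$cohorts, clinical = clinical,
              target_layer = target, truth = sim$truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (cm in sim$cohorts)
      write_expression_matrix(cm,
        file.path(outdir, paste0(cm$cohort_id, "_expr.tsv")),
        file.path(outdir, paste0(cm$cohort_id, "_labels.tsv")))
    utils::write.table(clinical, file.path(outdir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(target$mti_edges, file.path(outdir, "mti.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(target$disease_genes,
               file.path(outdir, "disease_genes.txt"))
    gmt <- vapply(names(target$gene_sets), function(nm)
      paste(c(nm, "simulated", target$gene_sets[[nm]]), collapse = "\t"),
      character(1))
    writeLines(gmt, file.path(outdir, "gene_sets.gmt"))
    write_expression_matrix(target$gene_matrix,
      file.path(outdir, "gene_expr.tsv"),
      file.path(outdir, "gene_labels.tsv"))
  }
  out
}
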