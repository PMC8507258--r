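test_that("simulation config validates its invariants before generating", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_cohorts = 1), "2 cohorts")
  expect_error(sim_config(n_true_de = 500, n_mirnas = 100), "n_true_de")
  expect_error(sim_config(missing_rate = 1.5), "rates")
  expect_error(sim_config(target_corr = -2), "target_corr")
  expect_error(sim_config(stage_probs = c(0.5, 0.5, 0, 0.1)), "stage_probs")
  expect_error(sim_config(panel_size = 10, n_true_de = 3), "panel_size")
})

test_that("the generator is deterministic in the seed and plants the configured truth", {
  cfg <- sim_config(seed = 91, n_cohorts = 3, n_tumour = 25, n_normal = 15,
                    n_mirnas = 80, n_true_de = 10)
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohorts(sim_config(seed = 92, n_cohorts = 3,
                                    n_tumour = 25, n_normal = 15,
                                    n_mirnas = 80, n_true_de = 10))
  expect_false(identical(a$cohorts[[1]]$values, c2$cohorts[[1]]$values))
  # planted truth is drawn from the shared core, so every cohort carries it
  expect_length(a$truth$true_de$mirna, 10)
  for (cm in a$cohorts)
    expect_true(all(a$truth$true_de$mirna %in% rownames(cm$values)))
  expect_true(all(a$truth$prognostic_panel %in% a$truth$true_de$mirna))
  # group sizes and labels as configured
  for (cm in a$cohorts) {
    expect_equal(sum(cm$sample_labels == "tumour"), 25)
    expect_equal(sum(cm$sample_labels == "normal"), 15)
  }
})

test_that("planted shifts yield the expected per-cohort test power", {
  cfg <- sim_config(seed = 93, n_cohorts = 2, n_tumour = 50, n_normal = 50,
                    n_mirnas = 60, n_true_de = 8, de_shift = -2,
                    noise_sd = 0.5, missing_rate = 0, outlier_rate = 0)
  sim <- simulate_cohorts(cfg)
  for (cm in sim$cohorts) {
    tum <- class_values(cm, "tumour"); nor <- class_values(cm, "normal")
    for (m in sim$truth$true_de$mirna) {
      p <- test_differential(tum[m, ], nor[m, ])$p_value
      expect_lt(p, 1e-6)
    }
  }
})

test_that("missingness and outliers are injected at the configured rates", {
  cfg <- sim_config(seed = 94, n_cohorts = 2, n_tumour = 100,
                    n_normal = 100, n_mirnas = 150, n_true_de = 0,
                    de_shift = 0, missing_rate = 0.1, outlier_rate = 0.02,
                    outlier_magnitude = 8, panel_size = 0, panel_log_hr = 0)
  sim <- simulate_cohorts(cfg)
  cm <- sim$cohorts[[1]]
  expect_lt(abs(mean(is.na(cm$values)) - 0.1), 0.02)
  base <- sim$truth$de_means[rownames(cm$values)]
  spike_rate <- mean(abs(cm$values - base) > 4, na.rm = TRUE)
  expect_lt(abs(spike_rate - 0.02), 0.01)
})

test_that("clinical simulation honours censoring, stages and the null panel", {
  cfg0 <- sim_config(seed = 95, censor_rate = 0, n_tumour = 80)
  sim0 <- simulate_cohorts(cfg0)
  clin0 <- simulate_clinical(cfg0, sim0$cohorts[[1]], sim0$truth)
  expect_true(all(clin0$os_event == 1))          # censor_rate 0: all events
  expect_true(all(clin0$os_time >= 0))
  expect_true(all(clin0$stage %in% c("I", "II", "III", "IV")))
  expect_setequal(clin0$patient_id,
                  colnames(class_values(sim0$cohorts[[1]], "tumour")))
  cfg <- sim_config(seed = 96, censor_rate = 0.4, n_tumour = 400)
  sim <- simulate_cohorts(cfg)
  clin <- simulate_clinical(cfg, sim$cohorts[[1]], sim$truth)
  expect_equal(mean(clin$os_event == 0), 0.4, tolerance = 0.08)
  # an empty panel is only valid with a null hazard effect
  truth0 <- sim$truth; truth0$prognostic_panel <- character(0)
  expect_error(simulate_clinical(cfg, sim$cohorts[[1]], truth0),
               "empty prognostic panel")
})

test_that("a null panel effect leaves the Cox CI covering 1 at the nominal rate", {
  hits <- 0
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = 3000 + s, n_cohorts = 2, n_tumour = 120,
                      n_normal = 10, n_mirnas = 30, n_true_de = 3,
                      noise_sd = 0.5, missing_rate = 0, outlier_rate = 0,
                      panel_size = 3, panel_log_hr = 0, censor_rate = 0.2)
    sim <- simulate_cohorts(cfg)
    clin <- simulate_clinical(cfg, sim$cohorts[[1]], sim$truth)
    g <- panel_groups(sim$cohorts[[1]], sim$truth$prognostic_panel,
                      patients = clin$patient_id, min_group = 1)
    ids <- c(g$higher_ids, g$lower_ids)
    clin_i <- clin[match(ids, clin$patient_id), ]
    fit <- cox_hr(rep(c(1, 0), c(length(g$higher_ids),
                                 length(g$lower_ids))),
                  clin_i$os_time, clin_i$os_event)
    if (fit$ci[1] <= 1 && 1 <= fit$ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("the target layer writes coherent interaction, disease and pathway inputs", {
  cfg <- sim_config(seed = 97, n_tumour = 60, n_normal = 20,
                    missing_rate = 0, outlier_rate = 0)
  sim <- simulate_cohorts(cfg)
  tl <- simulate_target_layer(cfg, sim$cohorts[[1]], sim$truth)
  expect_identical(colnames(tl$gene_matrix$values),
                   colnames(sim$cohorts[[1]]$values))
  # every true pair appears in the MTI table as human functional evidence
  key <- paste(tl$mti_edges$mirna, tl$mti_edges$gene)
  expect_true(all(paste(tl$true_pairs$mirna, tl$true_pairs$gene) %in%
                    key[tl$mti_edges$species == "Homo sapiens" &
                          tl$mti_edges$support_type == "Functional MTI"]))
  # the filter has chaff to remove
  expect_gt(nrow(tl$mti_edges), nrow(filter_mti(tl$mti_edges)))
  expect_s3_class(tl$gene_sets, "gene_set_collection")
  expect_true(all(tl$disease_genes %in% rownames(tl$gene_matrix$values)))
  # a zero disease fraction disconnects the functional network downstream
  cfg0 <- sim_config(seed = 98, disease_gene_fraction = 0)
  sim0 <- simulate_cohorts(cfg0)
  tl0 <- simulate_target_layer(cfg0, sim0$cohorts[[1]], sim0$truth)
  crossed <- cross_disease_genes(filter_mti(tl0$mti_edges),
                                 tl0$disease_genes)
  expect_equal(nrow(crossed$edges), 0)
})

test_that("a written study round-trips through the readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 99, n_cohorts = 2, n_tumour = 15, n_normal = 10,
                    n_mirnas = 30, n_true_de = 5, panel_size = 2,
                    n_genes = 40, n_true_correlated_pairs = 5)
  study <- simulate_study(cfg, outdir = dir)
  cm <- read_expression_matrix(file.path(dir, "cohort1_expr.tsv"),
                               file.path(dir, "cohort1_labels.tsv"),
                               cohort_id = "cohort1")
  expect_equal(cm$values, study$cohorts[[1]]$values)
  expect_identical(cm$sample_labels, study$cohorts[[1]]$sample_labels)
  clin <- read_clinical_table(file.path(dir, "clinical.tsv"))
  expect_equal(clin$os_time, study$clinical$os_time)
  mti <- read_mti_table(file.path(dir, "mti.tsv"))
  expect_equal(nrow(mti), nrow(study$target_layer$mti_edges))
  gs <- read_gene_sets(file.path(dir, "gene_sets.gmt"))
  expect_setequal(names(gs), names(study$target_layer$gene_sets))
})
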