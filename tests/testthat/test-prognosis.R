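tumour_only_matrix <- function(expr) {
  # panel/KM analyses index patients by column name; class labels are not
  # used by the grouping, but the container requires both classes
  cohort_matrix(expr, setNames(rep(c("tumour", "normal"),
                                   c(ncol(expr) - 1, 1)),
                               colnames(expr)), "surv")
}

test_that("median split sends ties to the lower-expression group", {
  v <- setNames(c(1, 2, 3, 4), paste0("p", 1:4))
  g <- median_split(v)
  expect_setequal(g$higher_ids, c("p3", "p4"))
  expect_setequal(g$lower_ids, c("p1", "p2"))
  v3 <- setNames(c(1, 2, 3), paste0("p", 1:3))
  g3 <- median_split(v3)
  expect_identical(g3$higher_ids, "p3")       # the median itself goes lower
  expect_setequal(g3$lower_ids, c("p1", "p2"))
  expect_equal(length(g3$higher_ids) + length(g3$lower_ids), 3)
  expect_error(median_split(setNames(rep(2, 5), paste0("p", 1:5))),
               "identical")
})

test_that("concordant panel grouping excludes discordant patients and shrinks monotonically", {
  set.seed(61)
  expr <- matrix(rnorm(5 * 101, 8), 5, 101,
                 dimnames = list(paste0("miR-", 1:5), paste0("p", 1:101)))
  cm <- tumour_only_matrix(expr)
  pats <- paste0("p", 1:100)
  g2 <- panel_groups(cm, c("miR-1", "miR-2"), patients = pats,
                     min_group = 1)
  # partition property
  expect_equal(sort(c(g2$higher_ids, g2$lower_ids, g2$excluded_ids)),
               sort(pats))
  # each higher patient is above the median of every panel miRNA
  for (p in g2$higher_ids)
    expect_true(all(expr[c("miR-1", "miR-2"), p] > g2$medians))
  for (p in g2$lower_ids)
    expect_true(all(expr[c("miR-1", "miR-2"), p] <= g2$medians))
  # nested panels can only shrink the concordant groups
  g3 <- panel_groups(cm, c("miR-1", "miR-2", "miR-3"), patients = pats,
                     min_group = 1)
  expect_true(all(g3$higher_ids %in% g2$higher_ids))
  expect_true(all(g3$lower_ids %in% g2$lower_ids))
  # singleton panels exclude nobody
  g1 <- panel_groups(cm, "miR-1", patients = pats, min_group = 1)
  expect_length(g1$excluded_ids, 0)
  # a 5-miRNA panel of independent markers keeps ~ 2^-5 per side: rejected
  g5 <- panel_groups(cm, paste0("miR-", 1:5), patients = pats,
                     min_group = 30)
  expect_true(g5$rejected)
  expect_lt(length(g5$higher_ids), 15)
  expect_error(panel_groups(cm, "miR-404"), "not in matrix")
})

test_that("meanscore grouping preserves group sizes", {
  set.seed(67)
  expr <- matrix(rnorm(3 * 41, 8), 3, 41,
                 dimnames = list(paste0("miR-", 1:3), paste0("p", 1:41)))
  cm <- tumour_only_matrix(expr)
  g <- panel_groups(cm, paste0("miR-", 1:3), patients = paste0("p", 1:40),
                    min_group = 1, grouping = "meanscore")
  expect_length(g$excluded_ids, 0)
  expect_equal(length(g$higher_ids), 20)
})

test_that("log-rank agrees with the hand-computed O/E/V table", {
  # fully observed, clearly separated event times
  lr <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  orc <- logrank_oracle(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(lr$chi2, orc$chi2, tolerance = 1e-10)
  expect_equal(lr$p, orc$p, tolerance = 1e-10)
  set.seed(71)
  for (i in 1:10) {
    na <- sample(4:8, 1); nb <- sample(4:8, 1)
    ta <- sample(1:10, na, replace = TRUE)
    tb <- sample(1:10, nb, replace = TRUE)
    ea <- rbinom(na, 1, 0.7); eb <- rbinom(nb, 1, 0.7)
    if (sum(ea) + sum(eb) == 0) next
    lr <- logrank_test(ta, ea, tb, eb)
    orc <- logrank_oracle(ta, ea, tb, eb)
    expect_equal(lr$chi2, orc$chi2, tolerance = 1e-8)
  }
  # identical groups carry no signal
  lr_same <- logrank_test(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(lr_same$chi2, 0, tolerance = 1e-12)
  expect_equal(lr_same$p, 1)
  # replicating both groups strengthens the evidence
  small <- logrank_test(c(1, 2, 5), c(1, 1, 1), c(4, 6, 7), c(1, 1, 1))
  big <- logrank_test(rep(c(1, 2, 5), 2), rep(1, 6),
                      rep(c(4, 6, 7), 2), rep(1, 6))
  expect_gt(big$chi2, small$chi2)
  expect_lt(big$p, small$p)
  expect_warning(out <- logrank_test(1:3, rep(0, 3), 4:6, rep(0, 3)),
                 "no events")
  expect_equal(out$p, 1)
})

test_that("Cox hazard ratio recovers a planted rate ratio and inverts on label swap", {
  set.seed(73)
  n <- 150
  t1 <- rexp(n, 0.4); t0 <- rexp(n, 0.1)  # true HR 4 for group 1
  grp <- rep(c(1, 0), each = n)
  fit <- cox_hr(grp, c(t1, t0), rep(1, 2 * n))
  se <- (log(fit$ci[2]) - log(fit$hr)) / qnorm(0.975)
  expect_lt(abs(log(fit$hr) - log(4)), 3 * se)
  expect_true(fit$converged)
  swapped <- cox_hr(1 - grp, c(t1, t0), rep(1, 2 * n))
  expect_equal(swapped$hr, 1 / fit$hr, tolerance = 1e-6)
  # identical event processes give HR near 1 at large n
  set.seed(74)
  tt <- rexp(2 * n, 0.2)
  null_fit <- cox_hr(rep(c(0, 1), n), tt, rep(1, 2 * n))
  expect_gt(null_fit$hr, 0.8); expect_lt(null_fit$hr, 1.25)
  # complete separation flags non-convergence instead of crashing
  sep <- cox_hr(rep(c(1, 0), each = 4), c(1, 2, 3, 4, 50, 60, 70, 80),
                rep(1, 8))
  expect_false(sep$converged)
  expect_error(cox_hr(rep(1, 5), rexp(5), rep(1, 5)), "both group")
})

test_that("panel enumeration is exhaustive, ordered and correctly counted", {
  p <- enumerate_panels(c("A", "B", "C"), 2, 3)
  expect_equal(attr(p, "count"), 4)
  expect_identical(lapply(p, paste, collapse = ""),
                   list("AB", "AC", "BC", "ABC"))
  expect_equal(attr(enumerate_panels(letters[1:8], 2, 3), "count"), 84)
  expect_equal(attr(enumerate_panels(paste0("m", 1:25), 2, 5), "count"),
               68380)
  expect_error(enumerate_panels(letters[1:3], 3, 2), "k_min")
  expect_error(enumerate_panels(letters[1:3], 2, 4), "exceeds")
})

test_that("panel screen tests feasible panels, rejects small groups and ranks by log-rank p", {
  cfg <- sim_config(seed = 81, n_cohorts = 2, n_tumour = 260, n_normal = 20,
                    n_mirnas = 40, n_true_de = 6, de_shift = -2,
                    noise_sd = 0.5, missing_rate = 0, outlier_rate = 0,
                    panel_size = 2, panel_log_hr = log(4),
                    stage_probs = c(I = 0, II = 1, III = 0, IV = 0))
  sim <- simulate_cohorts(cfg)
  clin <- simulate_clinical(cfg, sim$cohorts[[1]], sim$truth)
  cand <- c(sim$truth$prognostic_panel,
            setdiff(sim$truth$true_de$mirna,
                    sim$truth$prognostic_panel)[1:2])
  res <- screen_panels(sim$cohorts[[1]], clin, stage = "II",
                       endpoint = "OS", k_min = 2, k_max = 2,
                       min_group = 30, mirnas = cand)
  counts <- attr(res, "counts")
  expect_equal(counts$enumerated, choose(4, 2))
  expect_equal(counts$tested + counts$rejected, counts$enumerated)
  expect_true(all(diff(res$logrank_p) >= 0))
  expect_true(all(pmin(res$n_higher, res$n_lower)[res$passes] >= 30))
  true_key <- paste(sim$truth$prognostic_panel, collapse = "+")
  expect_true(true_key %in% res$panel[res$passes])
  # an infeasible minimum group tests nothing
  res_inf <- screen_panels(sim$cohorts[[1]], clin, stage = "II",
                           endpoint = "OS", k_min = 2, k_max = 2,
                           min_group = 500, mirnas = cand)
  expect_true(isTRUE(attr(res_inf, "skipped")) || nrow(res_inf) == 0)
  # a stage without patients is skipped with a report, not an error
  res_iv <- screen_panels(sim$cohorts[[1]], clin, stage = "IV",
                          endpoint = "OS", k_min = 2, k_max = 2,
                          min_group = 30, mirnas = cand)
  expect_true(attr(res_iv, "skipped"))
  expect_error(screen_panels(sim$cohorts[[1]], clin[, 1:4], stage = "II",
                             endpoint = "RFS", mirnas = cand),
               "RFS")
})

test_that("median-based grouping depends only on expression ranks", {
  set.seed(83)
  expr <- matrix(rnorm(2 * 61, 8), 2, 61,
                 dimnames = list(c("miR-1", "miR-2"), paste0("p", 1:61)))
  cm <- tumour_only_matrix(expr)
  cm2 <- tumour_only_matrix(2^expr)   # strictly monotone transform
  pats <- paste0("p", 1:60)
  g <- panel_groups(cm, c("miR-1", "miR-2"), patients = pats, min_group = 1)
  g2 <- panel_groups(cm2, c("miR-1", "miR-2"), patients = pats,
                     min_group = 1)
  expect_setequal(g$higher_ids, g2$higher_ids)
  expect_setequal(g$lower_ids, g2$lower_ids)
})
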