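mti_fixture <- function() {
  data.frame(
    mirna = c("miR-1", "miR-1", "miR-2", "miR-2", "miR-3", "miR-1"),
    gene = c("GENE1", "GENE2", "GENE1", "GENE3", "GENE4", "GENE1"),
    species = c("Homo sapiens", "Homo sapiens", "Homo sapiens",
                "Mus musculus", "Homo sapiens", "Homo sapiens"),
    support_type = c("Functional MTI", "Functional MTI", "Functional MTI",
                     "Functional MTI", "Functional MTI (Weak)",
                     "Functional MTI"),
    stringsAsFactors = FALSE)
}

test_that("MTI filtering keeps human functional edges and deduplicates", {
  edges <- filter_mti(mti_fixture())
  # mouse row and weak row dropped; duplicate (miR-1, GENE1) collapsed
  expect_equal(nrow(edges), 3)
  expect_false(any(edges$species != "Homo sapiens"))
  expect_false(any(grepl("weak", edges$support_type, ignore.case = TRUE)))
  expect_equal(sum(edges$mirna == "miR-1" & edges$gene == "GENE1"), 1)
  # weak evidence retained when functional_only is off
  expect_equal(nrow(filter_mti(mti_fixture(), functional_only = FALSE)), 4)
})

test_that("disease-gene crossing restricts edges and ranks miRNA degrees", {
  edges <- filter_mti(mti_fixture())
  res <- cross_disease_genes(edges, c("gene1"))   # case-insensitive
  expect_equal(nrow(res$edges), 2)
  expect_setequal(res$edges$mirna, c("miR-1", "miR-2"))
  # a miRNA with no disease target keeps degree 0 instead of vanishing
  res2 <- cross_disease_genes(edges, "GENE2")
  deg <- setNames(res2$degrees$degree, res2$degrees$mirna)
  expect_equal(unname(deg["miR-2"]), 0)
  # full universe is the identity on edges
  res3 <- cross_disease_genes(edges, unique(edges$gene))
  expect_equal(nrow(res3$edges), nrow(edges))
  expect_error(cross_disease_genes(edges, character(0)), "empty")
})

test_that("pair correlation selects the method by normality and classifies by Mukaka bins", {
  set.seed(3)
  x <- rnorm(50, 8)
  perfect <- correlate_pair(x, 2 * x)
  expect_equal(perfect$coefficient, 1)
  expect_lt(perfect$p_value, 1e-10)
  expect_identical(perfect$strength_class, "very_high positive")
  # monotone but non-normal: Spearman is selected and sees rho = 1
  y <- x^3 + exp(rnorm(50, 0, 0.001))
  skewed <- exp(rnorm(50, 0, 2))
  res <- correlate_pair(skewed, skewed^3)
  expect_identical(res$method, "spearman")
  expect_equal(res$coefficient, 1)
  # hand rank computations: y=(2,1,4,3,5) has d=(-1,1,-1,1,0), sum d^2=4,
  # rho = 1 - 6*4/(5*24) = 0.8; y=(3,1,2,4,5) has sum d^2 = 6, rho = 0.7
  expect_equal(correlate_pair(1:5, c(2, 1, 4, 3, 5),
                              method = "spearman")$coefficient, 0.8)
  expect_equal(correlate_pair(1:5, c(3, 1, 2, 4, 5),
                              method = "spearman")$coefficient, 0.7)
  # constant vector: undefined coefficient flagged with p = 1
  flat <- correlate_pair(rep(1, 10), rnorm(10))
  expect_true(flat$degenerate)
  expect_equal(flat$p_value, 1)
  expect_error(correlate_pair(1:3, 1:3), ">= 4")
})

test_that("Pearson on ranks equals Spearman in the tie-free case", {
  set.seed(9)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30)
  sp <- correlate_pair(x, y, method = "spearman")$coefficient
  pe <- correlate_pair(rank(x), rank(y), method = "pearson")$coefficient
  expect_equal(sp, pe, tolerance = 1e-12)
})

test_that("Mukaka bins map coefficients to strength classes", {
  expect_identical(classify_correlation(-0.478), "low negative")
  expect_identical(classify_correlation(0), "negligible")
  expect_identical(classify_correlation(1), "very_high positive")
  expect_identical(classify_correlation(-0.9), "very_high negative")
  expect_identical(classify_correlation(0.5), "moderate positive")
  expect_identical(classify_correlation(0.299), "negligible positive")
  expect_error(classify_correlation(1.2), "\\[-1, 1\\]")
})

test_that("hypergeometric enrichment matches the exact tail sum and enumeration", {
  # N=20, K=5, n=5, k=3: C(5,3)C(15,2)+C(5,4)C(15,1)+C(5,5) over C(20,5)
  coll <- gene_set_collection(list(SET = paste0("G", 1:5)),
                              extra_universe = paste0("G", 1:20))
  res <- enrich_genesets(paste0("G", c(1, 2, 3, 10, 11)), coll)
  expect_equal(res$p_value, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$k_overlap, 3)
  # zero overlap and set == universe are both certainty
  res0 <- enrich_genesets(paste0("G", 10:14), coll)
  expect_equal(res0$p_value, 1)
  coll2 <- gene_set_collection(list(ALL = paste0("G", 1:20)))
  expect_equal(enrich_genesets(paste0("G", 1:4), coll2)$p_value, 1)
  # enumeration oracle over all draws for small universes
  set.seed(17)
  for (i in 1:10) {
    N <- sample(6:12, 1); K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    uni <- paste0("g", seq_len(N))
    cl <- gene_set_collection(list(S = uni[seq_len(K)]),
                              extra_universe = uni)
    gl <- sample(uni, n)
    k <- sum(gl %in% uni[seq_len(K)])
    p_pkg <- enrich_genesets(gl, cl)$p_value
    expect_equal(p_pkg, hyper_enum_oracle(N, K, n, k), tolerance = 1e-10)
  }
  # genes outside the universe are dropped with a warning
  expect_warning(enrich_genesets(c("G1", "NOPE"), coll), "outside")
  expect_error(enrich_genesets("G1", list(S = "G1"), universe = character(0)),
               "universe")
})

test_that("miRNA-by-pathway incidence marks any-target membership", {
  coll <- gene_set_collection(list(P1 = c("GENE1"), P2 = c("GENE2"),
                                   P3 = c("GENE9")))
  edges <- data.frame(mirna = c("miR-1", "miR-1", "miR-2"),
                      gene = c("GENE1", "GENE2", "GENE7"),
                      stringsAsFactors = FALSE)
  m <- mirna_pathway_matrix(edges, coll)
  expect_equal(attr(m, "row_sums")[["miR-1"]], 2)
  expect_equal(attr(m, "row_sums")[["miR-2"]], 0)  # no pathway target
  expect_equal(unname(m["miR-1", ]), c(1L, 1L, 0L))
  empty <- mirna_pathway_matrix(edges[0, ], coll)
  expect_equal(nrow(empty), 0)
  expect_error(mirna_pathway_matrix(edges, coll, "P9"), "unknown")
})

test_that("planted correlations are recovered and decoys stay near the null rate", {
  cfg <- sim_config(seed = 41, n_tumour = 100, n_normal = 30,
                    missing_rate = 0, outlier_rate = 0,
                    target_corr = 0.9, n_true_correlated_pairs = 15)
  sim <- simulate_cohorts(cfg)
  tl <- simulate_target_layer(cfg, sim$cohorts[[1]], sim$truth)
  tum_m <- class_values(sim$cohorts[[1]], "tumour")
  tum_g <- class_values(tl$gene_matrix, "tumour")
  est <- vapply(seq_len(nrow(tl$true_pairs)), function(i)
    correlate_pair(tum_m[tl$true_pairs$mirna[i], ],
                   tum_g[tl$true_pairs$gene[i], ])$coefficient,
    numeric(1))
  expect_true(all(abs(est - 0.9) <= 0.15))
  # decoy edges (independent genes) reach significance at about alpha
  decoy <- tl$mti_edges[!paste(tl$mti_edges$mirna, tl$mti_edges$gene) %in%
                          paste(tl$true_pairs$mirna, tl$true_pairs$gene), ]
  decoy <- decoy[decoy$gene %in% rownames(tum_g) &
                   decoy$mirna %in% rownames(tum_m), ]
  pvals <- vapply(seq_len(nrow(decoy)), function(i)
    correlate_pair(tum_m[decoy$mirna[i], ],
                   tum_g[decoy$gene[i], ])$p_value, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.15)
})
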