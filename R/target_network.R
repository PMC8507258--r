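#' Filter a miRNA-target interaction table
#'
#' Restricts validated miRNA-target interactions (MTIs) to one species and,
#' optionally, to functionally supported evidence (support tags containing
#' "weak", case-insensitively, are treated as non-functional). Duplicate
#' (mirna, gene) pairs arising from multiple evidence rows collapse to one
#' edge.
#'
#' @param edges Data frame with columns \code{mirna}, \code{gene},
#'   \code{species}, \code{support_type}.
#' @param species Species to retain; default \code{"Homo sapiens"}.
#' @param functional_only Drop weak-evidence rows; default TRUE.
#' @return Deduplicated edge data frame.
#' @export
filter_mti <- function(edges, species = "Homo sapiens",
                       functional_only = TRUE) {
  stopifnot(all(c("mirna", "gene", "species", "support_type") %in%
                  names(edges)))
  keep <- edges$species == species
  if (functional_only)
    keep <- keep & !grepl("weak", edges$support_type, ignore.case = TRUE)
  out <- edges[keep, , drop = FALSE]
  out <- out[!duplicated(out[, c("mirna", "gene")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross MTI edges with a disease gene list
#'
#' Restricts the interaction network to targets previously associated with
#' the disease (case-insensitive symbol match) and ranks miRNAs by their
#' number of disease-gene interactions. miRNAs present in the input edge
#' list but targeting no disease gene appear with degree 0, so that they
#' can be reported as disconnected from the disease network.
#'
#' @param edges Filtered MTI data frame (see \code{\link{filter_mti}}).
#' @param disease_genes Non-empty character vector of gene symbols.
#' @return List with \code{edges} (restricted bipartite edge list) and
#'   \code{degrees} (data frame \code{mirna}, \code{degree}, sorted by
#'   decreasing degree then name).
#' @export
cross_disease_genes <- function(edges, disease_genes) {
  if (!length(disease_genes))
    stop("disease gene list is empty (parsing failure?)")
  hit <- toupper(edges$gene) %in% toupper(disease_genes)
  kept <- edges[hit, , drop = FALSE]
  rownames(kept) <- NULL
  deg <- table(factor(kept$mirna, levels = sort(unique(edges$mirna))))
  degrees <- data.frame(mirna = names(deg), degree = as.integer(deg),
                        stringsAsFactors = FALSE)
  degrees <- degrees[order(-degrees$degree, degrees$mirna), ]
  rownames(degrees) <- NULL
  list(edges = kept, degrees = degrees)
}

#' Correlate one miRNA-gene expression pair
#'
#' Pearson's coefficient when both vectors pass Shapiro-Wilk normality
#' (p > \code{alpha_normality} each), Spearman's rank correlation
#' (tie-corrected) otherwise; two-sided p-value; strength classified on the
#' Mukaka scale by \code{\link{classify_correlation}}. A constant vector
#' leaves the coefficient undefined: the result is flagged degenerate with
#' p = 1.
#'
#' @param mirna_values,gene_values Paired numeric vectors (same matched
#'   samples, same order); pairs with any NA are dropped; needs >= 4
#'   complete pairs.
#' @param alpha_normality Shapiro threshold, default 0.05.
#' @param method Force \code{"pearson"} or \code{"spearman"} instead of the
#'   normality-driven choice; default NULL (automatic).
#' @return One-row data frame: \code{method}, \code{coefficient},
#'   \code{p_value}, \code{n}, \code{strength_class}, \code{degenerate}.
#' @export
correlate_pair <- function(mirna_values, gene_values, alpha_normality = 0.05,
                           method = NULL) {
  ok <- !is.na(mirna_values) & !is.na(gene_values)
  x <- mirna_values[ok]; y <- gene_values[ok]
  if (length(x) < 4L) stop("need >= 4 complete pairs for correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(method = NA_character_, coefficient = NA_real_,
                      p_value = 1, n = length(x),
                      strength_class = NA_character_, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  if (is.null(method)) {
    swx <- safe_shapiro_p(x); swy <- safe_shapiro_p(y)
    method <- if (!is.na(swx) && !is.na(swy) &&
                  swx > alpha_normality && swy > alpha_normality)
      "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided",
                                         exact = FALSE))
  r <- unname(ct$estimate)
  data.frame(method = method, coefficient = r, p_value = ct$p.value,
             n = length(x),
             strength_class = classify_correlation(r),
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Mukaka strength classification of a correlation coefficient
#'
#' Bins on the absolute coefficient: [0, 0.30) negligible, [0.30, 0.50)
#' low, [0.50, 0.70) moderate, [0.70, 0.90) high, [0.90, 1] very high. The
#' sign is carried separately in the returned string for nonzero
#' coefficients (e.g. \code{"low negative"}).
#'
#' @param coefficient Numeric in [-1, 1].
#' @return Strength class string.
#' @examples
#' classify_correlation(-0.478)  # "low negative"
#' @export
classify_correlation <- function(coefficient) {
  if (is.na(coefficient) || abs(coefficient) > 1)
    stop("correlation coefficient must lie in [-1, 1]")
  a <- abs(coefficient)
  cls <- if (a < 0.30) "negligible"
         else if (a < 0.50) "low"
         else if (a < 0.70) "moderate"
         else if (a < 0.90) "high"
         else "very_high"
  if (cls == "negligible" && coefficient == 0) return(cls)
  paste(cls, if (coefficient >= 0) "positive" else "negative")
}

#' Correlate every miRNA-target edge across matched samples
#'
#' For each interaction edge whose miRNA is a row of \code{mirna_matrix}
#' and whose gene is a row of \code{gene_matrix}, pairs the two expression
#' profiles over matched samples and calls \code{\link{correlate_pair}}.
#' By default only tumour samples of the miRNA cohort enter the
#' correlation.
#'
#' @param edges Bipartite edge data frame (\code{mirna}, \code{gene}).
#' @param mirna_matrix,gene_matrix \code{\link{cohort_matrix}} objects
#'   sharing sample ids (after \code{key_transform}, if given).
#' @param tumour_only Restrict to tumour samples of \code{mirna_matrix};
#'   default TRUE.
#' @param key_transform Optional id transform for sample matching.
#' @param alpha_normality Passed to \code{\link{correlate_pair}}.
#' @return Data frame with one row per evaluable edge: \code{mirna},
#'   \code{gene} plus the \code{correlate_pair} columns; edges with a
#'   missing feature are listed in the \code{"unevaluable"} attribute.
#' @export
correlate_targets <- function(edges, mirna_matrix, gene_matrix,
                              tumour_only = TRUE, key_transform = NULL,
                              alpha_normality = 0.05) {
  stopifnot(inherits(mirna_matrix, "cohort_matrix"),
            inherits(gene_matrix, "cohort_matrix"))
  ids_a <- colnames(mirna_matrix$values)
  if (tumour_only) ids_a <- ids_a[mirna_matrix$sample_labels == "tumour"]
  matched <- match_samples(ids_a, colnames(gene_matrix$values),
                           key_transform = key_transform)
  sa <- attr(matched, "map_a"); sb <- attr(matched, "map_b")
  have <- edges$mirna %in% rownames(mirna_matrix$values) &
          toupper(edges$gene) %in% toupper(rownames(gene_matrix$values))
  gene_rows <- rownames(gene_matrix$values)
  rows <- lapply(which(have), function(i) {
    g <- gene_rows[match(toupper(edges$gene[i]), toupper(gene_rows))]
    cbind(data.frame(mirna = edges$mirna[i], gene = edges$gene[i],
                     stringsAsFactors = FALSE),
          correlate_pair(mirna_matrix$values[edges$mirna[i], sa],
                         gene_matrix$values[g, sb],
                         alpha_normality = alpha_normality))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(0), gene = character(0),
               method = character(0), coefficient = numeric(0),
               p_value = numeric(0), n = integer(0),
               strength_class = character(0), degenerate = logical(0))
  rownames(out) <- NULL
  attr(out, "unevaluable") <- edges[!have, c("mirna", "gene"), drop = FALSE]
  attr(out, "n_matched_samples") <- length(matched)
  out
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, the one-sided upper-tail hypergeometric probability of
#' drawing at least the observed overlap:
#' p = sum_{j >= k} C(K, j) C(N-K, n-j) / C(N, n) with N the universe
#' size, K the set size within the universe, n the query list size and k
#' the overlap. Query genes outside the universe are dropped with a
#' warning. BH q-values are computed across the collection's sets. The
#' EASE-style variant (overlap decremented by one before the tail) is
#' available behind \code{ease}.
#'
#' @param gene_list Character vector of query gene symbols.
#' @param collection A \code{\link{gene_set_collection}} (or named list of
#'   character vectors).
#' @param universe Background gene symbols; defaults to the collection's
#'   universe attribute (all genes in the collection).
#' @param ease Apply the EASE k-1 correction; default FALSE.
#' @return Data frame sorted by p-value: \code{set_name},
#'   \code{k_overlap}, \code{set_size}, \code{list_size},
#'   \code{universe_size}, \code{p_value}, \code{q_value}.
#' @export
enrich_genesets <- function(gene_list, collection, universe = NULL,
                            ease = FALSE) {
  if (is.null(universe)) universe <- attr(collection, "universe")
  if (is.null(universe) || !length(universe)) stop("empty gene universe")
  universe <- unique(toupper(universe))
  gl <- unique(toupper(gene_list))
  outside <- setdiff(gl, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    gl <- intersect(gl, universe)
  }
  N <- length(universe); n <- length(gl)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(toupper(collection[[nm]])), universe)
    K <- length(set)
    k <- length(intersect(gl, set))
    keff <- if (ease) max(k - 1L, 0L) else k
    p <- if (keff == 0L) 1 else
      stats::phyper(keff - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k_overlap = k, set_size = K, list_size = n,
               universe_size = N, p_value = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- adjust_fdr(out$p_value)
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out
}

#' Binary miRNA-by-pathway incidence matrix
#'
#' Cell (m, P) is 1 when some target gene of miRNA m (in the supplied
#' bipartite edge list) belongs to pathway P. Row sums count the pathways a
#' miRNA touches; a row of zeros identifies a miRNA disconnected from the
#' chosen pathways.
#'
#' @param bipartite_edges Edge data frame (\code{mirna}, \code{gene}).
#' @param collection Gene-set collection.
#' @param pathway_subset Names of the pathways to include; default all.
#' @return Integer 0/1 matrix, miRNAs x pathways, with attributes
#'   \code{"row_sums"} and \code{"col_sums"}.
#' @export
mirna_pathway_matrix <- function(bipartite_edges, collection,
                                 pathway_subset = names(collection)) {
  bad <- setdiff(pathway_subset, names(collection))
  if (length(bad))
    stop("unknown pathway(s): ", paste(bad, collapse = ", "))
  mirnas <- sort(unique(bipartite_edges$mirna))
  m <- matrix(0L, nrow = length(mirnas), ncol = length(pathway_subset),
              dimnames = list(mirnas, pathway_subset))
  for (p in pathway_subset) {
    genes <- toupper(collection[[p]])
    hit <- bipartite_edges$mirna[toupper(bipartite_edges$gene) %in% genes]
    m[unique(hit), p] <- 1L
  }
  attr(m, "row_sums") <- rowSums(m)
  attr(m, "col_sums") <- colSums(m)
  m
}
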