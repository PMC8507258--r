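#' Construct a cohort expression matrix
#'
#' A \code{cohort_matrix} bundles one cohort's log2-scale miRNA expression
#' values (miRNA rows, sample columns; \code{NA} = missing measurement) with
#' a tumour/normal class label per sample. Zeros are valid measurements and
#' are never treated as missing.
#'
#' @param values Numeric matrix, miRNAs in rows (rownames = miRNA ids),
#'   samples in columns (colnames = sample ids). Entries may be \code{NA}.
#' @param sample_labels Character/factor vector of length \code{ncol(values)}
#'   with values \code{"tumour"} or \code{"normal"}, or a named vector keyed
#'   by sample id.
#' @param cohort_id Single string identifying the cohort.
#' @return An object of class \code{cohort_matrix}: a list with elements
#'   \code{cohort_id}, \code{values}, \code{sample_labels} (factor with
#'   levels tumour/normal), \code{mirna_ids}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("miR-", 1:3), paste0("s", 1:4)))
#' cm <- cohort_matrix(m, c("tumour", "tumour", "normal", "normal"), "demo")
#' n_samples(cm)
#' @export
cohort_matrix <- function(values, sample_labels, cohort_id = "cohort") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty expression matrix")
  if (is.null(rownames(values)))
    stop("'values' must have miRNA ids as rownames")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate miRNA ids after canonicalization: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (!is.null(names(sample_labels)))
    sample_labels <- sample_labels[colnames(values)]
  if (length(sample_labels) != ncol(values))
    stop("'sample_labels' must supply exactly one class per sample")
  if (anyNA(sample_labels))
    stop("every sample needs a class label")
  sample_labels <- normalize_class_labels(sample_labels)
  if (!any(sample_labels == "tumour") || !any(sample_labels == "normal"))
    stop("cohort must contain at least one tumour and one normal sample")
  structure(
    list(cohort_id = as.character(cohort_id)[1],
         values = values,
         sample_labels = sample_labels,
         mirna_ids = rownames(values)),
    class = "cohort_matrix")
}

# Accept common spellings (T/N, Tumor, case differences) once, at the door.
normalize_class_labels <- function(x) {
  x <- tolower(as.character(x))
  x[x %in% c("t", "tumor", "tumour", "cancer", "case")] <- "tumour"
  x[x %in% c("n", "normal", "control", "healthy")] <- "normal"
  bad <- setdiff(unique(x), c("tumour", "normal"))
  if (length(bad))
    stop("unrecognized sample class label(s): ", paste(bad, collapse = ", "))
  factor(x, levels = c("tumour", "normal"))
}

#' @export
print.cohort_matrix <- function(x, ...) {
  tab <- table(x$sample_labels)
  cat(sprintf("cohort_matrix '%s': %d miRNAs x %d samples (%d tumour, %d normal), %.1f%% missing\n",
              x$cohort_id, nrow(x$values), ncol(x$values),
              tab[["tumour"]], tab[["normal"]],
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @rdname cohort_matrix
#' @param x A \code{cohort_matrix}.
#' @export
n_samples <- function(x) ncol(x$values)

#' Subset the samples of a cohort matrix
#'
#' @param x A \code{cohort_matrix}.
#' @param samples Character vector of sample ids (or logical/integer index).
#' @return A \code{cohort_matrix} restricted to those samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "cohort_matrix"))
  v <- x$values[, samples, drop = FALSE]
  cohort_matrix(v, x$sample_labels[match(colnames(v), colnames(x$values))],
                x$cohort_id)
}

#' Extract the tumour-sample submatrix
#'
#' @param x A \code{cohort_matrix}.
#' @param class Which class to extract, \code{"tumour"} or \code{"normal"}.
#' @return Numeric matrix (miRNA x sample) for the requested class.
#' @export
class_values <- function(x, class = c("tumour", "normal")) {
  class <- match.arg(class)
  x$values[, x$sample_labels == class, drop = FALSE]
}

#' Read a delimited expression matrix into a cohort_matrix
#'
#' Reads a tab-separated matrix with one header row and feature ids in the
#' first column, together with a two-column sidecar label table
#' (\code{sample_id}, \code{class}). Non-numeric cells (including \code{"NA"}
#' and empty cells) become missing entries. GEO-style linear-scale inputs can
#' be converted with \code{log2_transform = TRUE}, which applies
#' \code{log2(x + log2_offset)}.
#'
#' @param path Path to the expression TSV.
#' @param labels Either the path to a two-column TSV (sample_id, class) with
#'   header, or a named character vector of classes keyed by sample id.
#' @param cohort_id Cohort identifier; defaults to the file name sans
#'   extension.
#' @param orientation \code{"features_in_rows"} (default) or
#'   \code{"features_in_columns"} for transposed files.
#' @param log2_transform If \code{TRUE}, apply \code{log2(x + log2_offset)}
#'   to every entry (for linear-scale inputs).
#' @param log2_offset Offset added before the log; default 1.
#' @return A \code{cohort_matrix}.
#' @export
read_expression_matrix <- function(path, labels, cohort_id = NULL,
                                   orientation = c("features_in_rows",
                                                   "features_in_columns"),
                                   log2_transform = FALSE, log2_offset = 1) {
  orientation <- match.arg(orientation)
  if (is.null(cohort_id))
    cohort_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", ""))
  if (ncol(raw) < 2L || nrow(raw) < 1L) stop("empty expression matrix: ", path)
  ids <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")  # non-numeric text -> NA
  rownames(m) <- ids
  if (orientation == "features_in_columns") m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample IDs in ", path)
  if (log2_transform) m <- log2(m + log2_offset)
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels))) {
    lab <- utils::read.delim(labels, header = TRUE, colClasses = "character")
    labels <- stats::setNames(lab[[2]], lab[[1]])
  }
  cohort_matrix(m, labels, cohort_id)
}

#' Write a cohort_matrix back to TSV
#'
#' Inverse of \code{\link{read_expression_matrix}}: writes the expression
#' table (first column \code{mirna}) and the sidecar label table. A
#' write/read round trip is value-identical, missing entries included.
#'
#' @param x A \code{cohort_matrix}.
#' @param path Output path for the expression TSV.
#' @param labels_path Output path for the two-column label TSV.
#' @return Invisibly, \code{x}.
#' @export
write_expression_matrix <- function(x, path, labels_path) {
  stopifnot(inherits(x, "cohort_matrix"))
  df <- data.frame(mirna = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  lab <- data.frame(sample_id = colnames(x$values),
                    class = as.character(x$sample_labels))
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a clinical annotation table
#'
#' Expects a TSV with named columns \code{patient_id}, \code{stage},
#' \code{os_time}, \code{os_event} and optionally \code{rfs_time},
#' \code{rfs_event}. Times are in years; event flags are 0/1 (1 = event
#' observed). Stage values outside I--IV become \code{"unknown"}.
#'
#' @param path Path to the clinical TSV.
#' @return A \code{data.frame} with validated columns.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' Validate a clinical table
#'
#' @param df Data frame with at least \code{patient_id}, \code{stage},
#'   \code{os_time}, \code{os_event}.
#' @return The validated data frame (stage coerced to factor
#'   I/II/III/IV/unknown).
#' @export
validate_clinical <- function(df) {
  need <- c("patient_id", "stage", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in clinical table")
  df$stage <- as.character(df$stage)
  df$stage[!df$stage %in% c("I", "II", "III", "IV")] <- "unknown"
  df$stage <- factor(df$stage, levels = c("I", "II", "III", "IV", "unknown"))
  for (col in intersect(c("os_time", "rfs_time"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(df[[col]] < 0, na.rm = TRUE)) stop("negative times in ", col)
  }
  for (col in intersect(c("os_event", "rfs_event"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
    if (!all(df[[col]] %in% c(0, 1) | is.na(df[[col]])))
      stop("event flags in ", col, " must be 0/1")
  }
  df
}

#' Read a miRNA-target interaction table
#'
#' TSV with columns \code{mirna}, \code{gene}, \code{species},
#' \code{support_type}.
#'
#' @param path Path to the interaction TSV.
#' @return Data frame of interaction edges (not yet deduplicated; see
#'   \code{\link{filter_mti}}).
#' @export
read_mti_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("mirna", "gene", "species", "support_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("MTI table missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path Path to the GMT file.
#' @param extra_universe Optional character vector of background genes to add
#'   to the collection's universe.
#' @return A named list of character vectors with attribute
#'   \code{"universe"} = union of all member genes plus
#'   \code{extra_universe}.
#' @export
read_gene_sets <- function(path, extra_universe = character()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (any(!lengths(sets))) stop("GMT contains an empty gene set")
  gene_set_collection(sets, extra_universe)
}

#' Build a gene-set collection from a list
#'
#' @param sets Named list of non-empty character vectors of gene symbols.
#' @param extra_universe Optional extra background genes.
#' @return The list with class \code{gene_set_collection} and a
#'   \code{"universe"} attribute.
#' @export
gene_set_collection <- function(sets, extra_universe = character()) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  if (any(!lengths(sets))) stop("gene sets must be non-empty")
  structure(sets,
            universe = unique(c(unlist(sets, use.names = FALSE),
                                extra_universe)),
            class = "gene_set_collection")
}

#' Canonicalize miRNA names
#'
#' Maps each input name through an alias table (old name -> canonical name,
#' e.g. the current miRBase accepted names) and strips the species prefix
#' \code{"hsa-"}, so downstream reporting uses the bare mature-miRNA name
#' (e.g. \code{miR-129-5p}). Names absent from the alias table pass through
#' unchanged and are recorded in the \code{"unknown"} attribute. The mapping
#' is idempotent.
#'
#' @param names Character vector of miRNA names.
#' @param alias_table Optional two-column data frame (\code{old},
#'   \code{canonical}) or named character vector (names = old). Rows must be
#'   unique on the old name.
#' @param strip_species_prefix Strip a leading \code{"hsa-"}; default TRUE.
#' @return Named character vector: canonical names, named by the inputs,
#'   with attribute \code{"unknown"} listing inputs not found in the alias
#'   table. Two distinct inputs mapping to one canonical name is an error.
#' @examples
#' canonicalize_mirna_names(c("hsa-miR-129-5p", "miR-320"),
#'                          alias_table = c("miR-320" = "miR-320a"))
#' @export
canonicalize_mirna_names <- function(names, alias_table = NULL,
                                     strip_species_prefix = TRUE) {
  stopifnot(is.character(names))
  map <- character(0)
  if (!is.null(alias_table)) {
    if (is.data.frame(alias_table)) {
      map <- stats::setNames(as.character(alias_table[[2]]),
                             as.character(alias_table[[1]]))
    } else map <- alias_table
    if (anyDuplicated(names(map)))
      stop("alias table not unique on old name")
  }
  strip <- function(x) if (strip_species_prefix) sub("^hsa-", "", x) else x
  # look the name up both as given and prefix-stripped, then strip the result
  out <- vapply(names, function(nm) {
    hit <- if (nm %in% names(map)) map[[nm]]
           else if (strip(nm) %in% names(map)) map[[strip(nm)]]
           else nm
    strip(hit)
  }, character(1))
  unknown <- names[!(names %in% names(map) | strip(names) %in% names(map))]
  dup <- duplicated(out)
  if (any(dup)) {
    clash <- out[dup][1]
    stop("canonicalization collision: inputs ",
         paste(shQuote(names[out == clash]), collapse = " and "),
         " both map to ", shQuote(clash))
  }
  structure(out, unknown = unknown)
}

#' Match sample identifiers between two datasets
#'
#' Intersects two id vectors after an optional deterministic key transform
#' (e.g. truncation to a barcode prefix), returning the matched keys in
#' stable sorted order. Used to pair miRNA and gene expression profiles from
#' the same patients: only matched samples enter correlation analysis.
#'
#' @param ids_a,ids_b Character vectors of sample ids.
#' @param key_transform Optional function applied to both sides before
#'   intersection.
#' @return Character vector of matched (transformed) keys, sorted, with
#'   attributes \code{"unmatched_a"} and \code{"unmatched_b"} (counts) and
#'   \code{"map_a"}/\code{"map_b"} giving, per matched key, the first
#'   original id on each side.
#' @export
match_samples <- function(ids_a, ids_b, key_transform = NULL) {
  ka <- if (is.null(key_transform)) ids_a else vapply(ids_a, key_transform,
                                                      character(1))
  kb <- if (is.null(key_transform)) ids_b else vapply(ids_b, key_transform,
                                                      character(1))
  common <- sort(intersect(ka, kb))
  if (!length(common)) stop("no samples match between the two datasets")
  structure(common,
            unmatched_a = sum(!ka %in% common),
            unmatched_b = sum(!kb %in% common),
            map_a = stats::setNames(ids_a[match(common, ka)], common),
            map_b = stats::setNames(ids_b[match(common, kb)], common))
}
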