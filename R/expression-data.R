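#' Construct an expression dataset
#'
#' Bundles a genes x samples matrix of log-scale expression values with
#' two-class sample labels. All downstream operations (gene scoring, module
#' discovery, classifier fitting) take this container.
#'
#' The two class names are mapped onto the internal groups "A" and "B": by
#' default the lexicographically first class name becomes group "A", because
#' the MLDA decision rule (assign to A when the linear predictor is at least
#' `log(n_B/n_A)`) is asymmetric in the two groups, so the mapping must be
#' explicit and stable. Override with `class_a`.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique row names (gene identifiers) and column names (sample
#'   identifiers). All entries must be finite; missing values are rejected,
#'   not imputed.
#' @param labels Character or factor of length `ncol(values)` giving each
#'   sample's class; exactly two distinct classes are required.
#' @param class_a Optional class name to map to group "A". Default: the
#'   lexicographically first class name.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (the matrix), `labels` (factor whose first level is the class
#'   mapped to "A"), and `class_a`/`class_b` (the original class names).
#' @seealso [read_expression()] to load from delimited text files.
#' @examples
#' x <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' d <- expression_dataset(x, c("tumor", "normal", "tumor", "normal", "tumor"))
#' d$class_a  # "normal": lexicographically first
#' @export
expression_dataset <- function(values, labels, class_a = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix (genes x samples).")
  }
  if (nrow(values) < 1L || ncol(values) < 2L) {
    stopf("Need at least 1 gene and 2 samples; got %d x %d.",
          nrow(values), ncol(values))
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stopf("`values` must have row names (gene IDs) and column names (sample IDs).")
  }
  if (anyDuplicated(gene_ids)) {
    stopf("Duplicate gene IDs: %s.",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stopf("Duplicate sample IDs: %s.",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("Non-finite expression value for gene '%s', sample '%s'.",
          gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]])
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    stopf("`labels` has length %d but there are %d samples.",
          length(labels), ncol(values))
  }
  if (anyNA(labels)) stopf("`labels` contains missing values.")
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stopf("Exactly two classes required; found: %s.",
          paste(classes, collapse = ", "))
  }
  if (is.null(class_a)) {
    class_a <- classes[1L]
  } else if (!class_a %in% classes) {
    stopf("`class_a` = '%s' is not one of the label classes (%s).",
          class_a, paste(classes, collapse = ", "))
  }
  class_b <- setdiff(classes, class_a)
  structure(
    list(
      values = values,
      labels = factor(labels, levels = c(class_a, class_b)),
      class_a = class_a,
      class_b = class_b
    ),
    class = "expression_dataset"
  )
}

#' Read an expression matrix and sample labels from delimited text
#'
#' The expression file is a TSV/CSV with gene IDs in the first column and a
#' header row of sample IDs (the usual genes x samples orientation; set
#' `transpose = TRUE` for samples x genes input). The label file has two
#' columns, sample ID and class name, with or without a header.
#'
#' @param matrix_path Path to the expression matrix file.
#' @param labels_path Path to the two-column label file.
#' @param sep Field separator; default tab. Use `","` for CSV.
#' @param class_a Optional class name to map to group "A"
#'   (see [expression_dataset()]).
#' @param transpose If `TRUE`, the matrix file is samples x genes and is
#'   transposed after reading.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, labels_path, sep = "\t",
                            class_a = NULL, transpose = FALSE) {
  if (!file.exists(matrix_path)) stopf("Expression file not found: %s", matrix_path)
  if (!file.exists(labels_path)) stopf("Label file not found: %s", labels_path)
  raw <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           row.names = 1L, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(raw) < 1L) stopf("Expression file '%s' has no sample columns.", matrix_path)
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw),
           dimnames = dimnames(raw))
  )
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("Non-numeric or missing cell for gene '%s', sample '%s' in '%s'.",
          rownames(raw)[bad[1L, 1L]], colnames(raw)[bad[1L, 2L]], matrix_path)
  }
  if (transpose) vals <- t(vals)

  lab <- utils::read.table(labels_path, header = FALSE, sep = sep,
                           colClasses = "character", comment.char = "")
  if (ncol(lab) < 2L) stopf("Label file '%s' must have two columns.", labels_path)
  # tolerate a header row: drop it if its first field is not a known sample
  if (!lab[[1L]][1L] %in% colnames(vals) && nrow(lab) == ncol(vals) + 1L) {
    lab <- lab[-1L, , drop = FALSE]
  }
  if (anyDuplicated(lab[[1L]])) {
    stopf("Duplicate sample ID in label file: %s.",
          paste(unique(lab[[1L]][duplicated(lab[[1L]])]), collapse = ", "))
  }
  missing <- setdiff(colnames(vals), lab[[1L]])
  if (length(missing) > 0L) {
    stopf("Sample(s) missing from label file: %s.",
          paste(missing, collapse = ", "))
  }
  labels <- setNames(lab[[2L]], lab[[1L]])[colnames(vals)]
  expression_dataset(vals, labels, class_a = class_a)
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "<expression_dataset> %d genes x %d samples (%s: %d [A], %s: %d [B])\n",
    nrow(x$values), ncol(x$values),
    x$class_a, tab[[1L]], x$class_b, tab[[2L]]
  ))
  invisible(x)
}

# internal accessors --------------------------------------------------------

# logical index of group-A samples
is_group_a <- function(data) data$labels == levels(data$labels)[1L]

class_counts <- function(data) {
  tab <- table(data$labels)
  c(n_a = unname(tab[1L]), n_b = unname(tab[2L]))
}

check_fittable <- function(data, min_per_class = 2L) {
  nk <- class_counts(data)
  if (any(nk < min_per_class)) {
    stopf("Each class needs at least %d samples for fitting (got %s: %d, %s: %d).",
          min_per_class, data$class_a, nk[["n_a"]], data$class_b, nk[["n_b"]])
  }
  invisible(nk)
}

# subset samples, keeping the A/B mapping stable
subset_samples <- function(data, idx) {
  expression_dataset(data$values[, idx, drop = FALSE],
                     as.character(data$labels[idx]),
                     class_a = data$class_a)
}
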