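#' Expression matrix for one study
#'
#' Light container for a genes-by-samples expression matrix from a single
#' study, with gene identifiers as opaque strings and optional per-sample
#' categorical labels. Gene identifiers must be unique; values must be finite.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of gene identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids Character vector of sample identifiers (defaults to
#'   `colnames(values)`, or `sample1..M` when absent).
#' @param labels Optional factor/character of length `ncol(values)` giving a
#'   categorical class per sample.
#' @return An object of class `expression_matrix` with fields `values`,
#'   `gene_ids`, `sample_ids`, `labels`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values), labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) stop("gene_ids are required (or set rownames)")
  gene_ids <- as.character(gene_ids)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match row count")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match column count")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 3), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (length(labels) != ncol(values))
      stop("labels length does not match sample count")
  }
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, labels = labels),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(" (%d label classes)", nlevels(x$labels))))
  invisible(x)
}

#' Expression tensor for one multi-condition study
#'
#' Container for a study measured over several crossed experimental
#' conditions (e.g. drug x dose x replicate): a real array with genes on the
#' first mode and one mode per condition.
#'
#' @param values Numeric array; first dimension indexes genes.
#' @param gene_ids Character vector of gene identifiers.
#' @param mode_labels Optional list of per-mode annotations (one entry per
#'   non-gene mode; each a character/factor of that mode's length).
#' @return An object of class `expression_tensor` with fields `values`,
#'   `gene_ids`, `mode_sizes` (non-gene mode lengths), `mode_labels`.
#' @export
expression_tensor <- function(values, gene_ids = dimnames(values)[[1]],
                              mode_labels = NULL) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  d <- dim(values)
  if (length(d) < 2) stop("an expression tensor needs at least one sample mode")
  if (is.null(gene_ids)) stop("gene_ids are required (or set dimnames)")
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != d[1]) stop("gene_ids length does not match mode 1")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (!is.null(mode_labels)) {
    if (length(mode_labels) != length(d) - 1L)
      stop("mode_labels must have one entry per non-gene mode")
    for (s in seq_along(mode_labels)) {
      if (!is.null(mode_labels[[s]]) && length(mode_labels[[s]]) != d[s + 1L])
        stop("mode_labels entry ", s, " has wrong length")
    }
  }
  dn <- dimnames(values)
  if (is.null(dn)) dn <- vector("list", length(d))
  dn[[1]] <- gene_ids
  dimnames(values) <- dn
  structure(list(values = values, gene_ids = gene_ids,
                 mode_sizes = d[-1], mode_labels = mode_labels),
            class = "expression_tensor")
}

#' @export
print.expression_tensor <- function(x, ...) {
  cat(sprintf("<expression_tensor> %d genes x (%s)\n",
              length(x$gene_ids), paste(x$mode_sizes, collapse = " x ")))
  invisible(x)
}

#' Sparse single-cell RNA-seq bundle
#'
#' One scRNA-seq measurement: a sparse non-negative genes-by-cells count
#' matrix plus identifiers and an optional group label for the whole
#' measurement (e.g. disease status x brain region).
#'
#' @param counts Sparse (or dense) non-negative genes-by-cells matrix.
#' @param gene_ids,cell_ids Identifier vectors.
#' @param measurement_id Identifier of this measurement within a collection.
#' @param group Optional single categorical label for the measurement.
#' @return Object of class `scrna_bundle`.
#' @export
scrna_bundle <- function(counts, gene_ids = rownames(counts),
                         cell_ids = colnames(counts),
                         measurement_id = NULL, group = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids)) stop("gene_ids are required")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts)) stop("gene_ids length mismatch")
  if (length(cell_ids) != ncol(counts)) stop("cell_ids length mismatch")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_ids
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 measurement_id = measurement_id, group = group),
            class = "scrna_bundle")
}

#' @export
print.scrna_bundle <- function(x, ...) {
  cat(sprintf("<scrna_bundle> %d genes x %d cells, %d stored entries%s\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x),
              if (is.null(x$group)) "" else paste0(", group=", x$group)))
  invisible(x)
}

n_genes <- function(x) {
  if (inherits(x, "expression_matrix") || inherits(x, "expression_tensor"))
    length(x$gene_ids)
  else if (inherits(x, "scrna_bundle")) nrow(x$counts)
  else stop("unsupported type")
}
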