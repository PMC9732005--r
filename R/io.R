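#' Read a dense expression matrix from delimited text
#'
#' Reads a TSV/CSV file with one header row and one identifier column into an
#' [expression_matrix()], oriented genes x samples regardless of the on-disk
#' orientation. The delimiter is auto-detected from the extension
#' (`.tsv`/`.txt` = tab, `.csv` = comma) unless `sep` is given.
#'
#' @param path File path.
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_columns"`.
#' @param sep Optional field separator overriding extension-based detection.
#' @param labels Optional per-sample labels passed through.
#' @return An [expression_matrix()].
#' @export
read_dense_matrix <- function(path,
                              orientation = c("genes_in_rows", "genes_in_columns"),
                              sep = NULL, labels = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  if (nrow(dt) == 0 || ncol(dt) < 2)
    stop("no data rows/columns in ", path)
  ids <- as.character(dt[[1]])
  vals <- dt[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      bad <- which(is.na(num) & !is.na(vals[[j]]))
      if (length(bad))
        stop(sprintf("non-numeric value at row %d, column '%s' in %s",
                     bad[1], names(vals)[j], path))
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "genes_in_columns") m <- t(m)
  expression_matrix(m, labels = labels)
}

detect_sep <- function(path) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "csv") "," else "\t"
}

#' Write a dense expression matrix to delimited text
#'
#' Writes genes in rows, one header row of sample identifiers, and the gene
#' identifier as the first column (`gene_id`). Delimiter follows the
#' extension as in [read_dense_matrix()].
#'
#' @param x An [expression_matrix()] or numeric matrix with rownames.
#' @param path Output path.
#' @param sep Optional field separator.
#' @export
write_dense_matrix <- function(x, path, sep = NULL) {
  if (inherits(x, "expression_matrix")) x <- x$values
  if (is.null(sep)) sep <- detect_sep(path)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

find_member <- function(dir, stems) {
  for (stem in stems) {
    for (suffix in c("", ".gz")) {
      p <- file.path(dir, paste0(stem, suffix))
      if (file.exists(p)) return(p)
    }
  }
  NULL
}

read_id_column <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Read a MatrixMarket scRNA-seq bundle
#'
#' Reads a 10x-style directory holding `matrix.mtx`, `features.tsv` (or
#' `genes.tsv`) and `barcodes.tsv`, each optionally gzip-compressed, into an
#' [scrna_bundle()]. Only the first column of the feature/barcode files is
#' used as identifier.
#'
#' @param directory Directory containing the three members.
#' @param measurement_id,group Passed through to [scrna_bundle()].
#' @return An [scrna_bundle()] preserving sparsity.
#' @export
read_mtx_bundle <- function(directory, measurement_id = NULL, group = NULL) {
  if (!dir.exists(directory)) stop("directory not found: ", directory)
  mtx <- find_member(directory, "matrix.mtx")
  feat <- find_member(directory, c("features.tsv", "genes.tsv"))
  bars <- find_member(directory, "barcodes.tsv")
  if (is.null(mtx) || is.null(feat) || is.null(bars))
    stop("bundle must contain matrix.mtx, features.tsv (or genes.tsv) and barcodes.tsv")
  counts <- if (grepl("\\.gz$", mtx)) {
    con <- gzfile(mtx, "r"); on.exit(close(con), add = TRUE)
    Matrix::readMM(con)
  } else Matrix::readMM(mtx)
  gene_ids <- read_id_column(feat)
  cell_ids <- read_id_column(bars)
  if (nrow(counts) != length(gene_ids))
    stop(sprintf("matrix has %d rows but %d feature identifiers",
                 nrow(counts), length(gene_ids)))
  if (ncol(counts) != length(cell_ids))
    stop(sprintf("matrix has %d columns but %d barcodes",
                 ncol(counts), length(cell_ids)))
  scrna_bundle(counts, gene_ids, cell_ids,
               measurement_id = measurement_id, group = group)
}

#' Write a MatrixMarket scRNA-seq bundle
#'
#' Inverse of [read_mtx_bundle()]; writes uncompressed members.
#'
#' @param bundle An [scrna_bundle()].
#' @param directory Output directory (created if missing).
#' @export
write_mtx_bundle <- function(bundle, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(bundle$counts, file.path(directory, "matrix.mtx"))
  writeLines(bundle$gene_ids, file.path(directory, "features.tsv"))
  writeLines(bundle$cell_ids, file.path(directory, "barcodes.tsv"))
  invisible(directory)
}

#' Write a gene-selection table
#'
#' Writes a TSV with columns `gene_id`, `statistic`, `P`, `adjP`, `selected`,
#' ordered by adjusted P then gene identifier (a deterministic tie-break).
#'
#' @param selection A `gene_selection` object (see [gene_pvalues()]).
#' @param path Output path.
#' @export
write_gene_table <- function(selection, path) {
  df <- as.data.frame(selection)
  ord <- order(df$adjP, df$gene_id)
  data.table::fwrite(df[ord, , drop = FALSE], path, sep = "\t")
  invisible(path)
}

#' Read back a gene-selection table written by [write_gene_table()]
#'
#' @param path Path to the TSV.
#' @return A data.frame with the written columns.
#' @export
read_gene_table <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE,
                    colClasses = list(character = "gene_id"))
}
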