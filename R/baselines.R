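# Comparison baselines computable from scratch: SVD of the column-wise
# concatenation of all studies, and per-study PCA top-gene overlap.

#' SVD of the column-concatenated studies
#'
#' Concatenates the aligned, normalized studies column-wise into one
#' genes x (sum M_k) matrix and applies a single SVD. The joint sample
#' factors are partitioned back to the studies by contiguous column ranges
#' in input order. Gene-factor signs follow the deterministic convention
#' (paired sample factors flipped together).
#'
#' @param studies List of aligned, normalized [expression_matrix()]s sharing
#'   the gene universe.
#' @return Object of class `concat_result`: `gene_factors` (genes x R),
#'   `sample_factors` ((sum M_k) x R), `singular_values`, `ranges` (list of
#'   per-study column index vectors), `gene_ids`, `labels` (per-study label
#'   vectors, when present).
#' @export
concat_svd <- function(studies) {
  stopifnot(length(studies) >= 1)
  gene_ids <- studies[[1]]$gene_ids
  for (s in studies)
    if (!identical(s$gene_ids, gene_ids))
      stop("studies must share the gene universe")
  X <- do.call(cbind, lapply(studies, function(s) s$values))
  sv <- svd(X)
  for (l in seq_len(ncol(sv$u))) {
    i <- which.max(abs(sv$u[, l]))
    if (sv$u[i, l] < 0) {
      sv$u[, l] <- -sv$u[, l]
      sv$v[, l] <- -sv$v[, l]
    }
  }
  sizes <- vapply(studies, function(s) ncol(s$values), integer(1))
  ends <- cumsum(sizes)
  ranges <- lapply(seq_along(sizes), function(k)
    seq.int(ends[k] - sizes[k] + 1L, ends[k]))
  rownames(sv$u) <- gene_ids
  structure(list(gene_factors = sv$u, sample_factors = sv$v,
                 singular_values = sv$d, ranges = ranges, gene_ids = gene_ids,
                 labels = lapply(studies, function(s) s$labels)),
            class = "concat_result")
}

#' @export
print.concat_result <- function(x, ...) {
  cat(sprintf("<concat_result> %d genes, %d joint samples over %d studies\n",
              nrow(x$gene_factors), nrow(x$sample_factors), length(x$ranges)))
  invisible(x)
}

#' Gene selection from concatenation-SVD gene factors
#'
#' Reuses the chi-squared / BH machinery of [gene_pvalues()] with the chosen
#' concatenation gene factors standing in for the integrated ones.
#'
#' @param result A `concat_result`.
#' @param factor_indices Which gene factors enter the statistic (non-empty).
#' @param threshold Adjusted-P cutoff (default 0.01).
#' @return A `gene_selection` with adjusted P-values and selection flags.
#' @export
concat_select <- function(result, factor_indices, threshold = 0.01) {
  stopifnot(inherits(result, "concat_result"))
  if (length(factor_indices) == 0) stop("factor_indices must be non-empty")
  sel <- gene_pvalues(result$gene_factors, factor_indices)
  bh_adjust_selection(sel, threshold)
}

#' Per-study PCA top-gene overlap
#'
#' Applies SVD to each study separately (gene-side loadings = unit-norm left
#' singular vectors), takes the `top_n` genes with largest absolute loading
#' per component, and reports pairwise overlap counts between studies per
#' component, plus (optionally) the correlation of each study's loadings
#' with reference gene factors (e.g. the integrated ones) and the overlap of
#' each top set with a reference gene list.
#'
#' @param studies List of aligned, normalized [expression_matrix()]s.
#' @param top_n Top-gene count per component (default 100).
#' @param n_components Components per study to analyse (default 5, capped at
#'   each study's sample count).
#' @param reference_factors Optional genes x factors matrix for loading
#'   correlations.
#' @param reference_selection Optional character vector of gene ids (e.g.
#'   the integrated selection) to intersect with each top set.
#' @return Object of class `pca_overlap`: `top_sets` (study x component list
#'   of gene id vectors), `overlap` (array component x study x study),
#'   `loading_cor` (list per study, components x reference factors),
#'   `reference_overlap` (matrix study x component).
#' @export
pca_overlap <- function(studies, top_n = 100L, n_components = 5L,
                        reference_factors = NULL, reference_selection = NULL) {
  stopifnot(length(studies) >= 2)
  gene_ids <- studies[[1]]$gene_ids
  K <- length(studies)
  if (top_n > length(gene_ids)) stop("top_n exceeds the gene count")
  n_components <- min(n_components,
                      min(vapply(studies, function(s) ncol(s$values), integer(1))))
  loadings <- lapply(studies, function(s) {
    if (!identical(s$gene_ids, gene_ids))
      stop("studies must share the gene universe")
    sv <- svd(s$values, nu = n_components, nv = 0)
    fix_column_signs(sv$u[, seq_len(n_components), drop = FALSE])
  })
  top_sets <- lapply(loadings, function(u)
    lapply(seq_len(n_components), function(l)
      gene_ids[order(abs(u[, l]), decreasing = TRUE)[seq_len(top_n)]]))
  overlap <- array(NA_integer_, c(n_components, K, K))
  for (l in seq_len(n_components))
    for (a in seq_len(K))
      for (b in seq_len(K))
        overlap[l, a, b] <- length(intersect(top_sets[[a]][[l]],
                                             top_sets[[b]][[l]]))
  loading_cor <- NULL
  if (!is.null(reference_factors))
    loading_cor <- lapply(loadings, function(u)
      stats::cor(u, as.matrix(reference_factors)))
  reference_overlap <- NULL
  if (!is.null(reference_selection)) {
    reference_overlap <- matrix(NA_integer_, K, n_components)
    for (a in seq_len(K))
      for (l in seq_len(n_components))
        reference_overlap[a, l] <-
          length(intersect(top_sets[[a]][[l]], reference_selection))
  }
  structure(list(top_sets = top_sets, overlap = overlap,
                 loading_cor = loading_cor,
                 reference_overlap = reference_overlap,
                 top_n = top_n, n_components = n_components),
            class = "pca_overlap")
}

#' @export
print.pca_overlap <- function(x, ...) {
  cat(sprintf("<pca_overlap> %d studies, top %d genes x %d components\n",
              dim(x$overlap)[2], x$top_n, x$n_components))
  invisible(x)
}
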