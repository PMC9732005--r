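# scRNA-seq compression path.
#
# One scRNA-seq measurement may hold ~10^4 cells; only its top-L gene-side
# singular vectors are ever needed downstream, so each measurement is reduced
# to a genes x L profile without materializing a dense genes x cells matrix:
# the cell-by-cell Gram matrix of the per-cell-normalized data is assembled
# from sparse cross-products, its eigenvectors give the sample-side factors,
# and one sparse product yields the reduced profile. After compression no
# object retains a dimension equal to the cell count.

#' Compress one scRNA-seq measurement to a genes x L profile
#'
#' Normalizes each cell to zero mean and sum of squares N over genes
#' (implicitly, without densifying), applies SVD, and keeps the reduced
#' profile `x_{il} = sum_j x_{ij} v_{lj} = lambda_l u_{li}` for the top `L`
#' components. Cell-side factors are discarded.
#'
#' @param bundle An [scrna_bundle()].
#' @param L Number of components (default 10).
#' @return A `reduced_profile` with `L` columns; `sample_factors` is NULL.
#' @export
compress_scrna <- function(bundle, L = 10L) {
  stopifnot(inherits(bundle, "scrna_bundle"))
  C <- bundle$counts
  N <- nrow(C)
  M <- ncol(C)
  if (L > min(N, M)) stop("L cannot exceed the cell count (", M, ")")
  mu <- Matrix::colMeans(C)
  css <- Matrix::colSums(C^2)
  s2 <- (css - N * mu^2) / N              # per-cell population variance
  if (any(s2 <= 0))
    stop("zero-variance cell: ", bundle$cell_ids[which(s2 <= 0)[1]])
  s <- sqrt(s2)
  # Gram matrix of the normalized data: X^T X with X = (C - 1 mu^T) D_{1/s}
  G <- (as.matrix(Matrix::crossprod(C)) - N * tcrossprod(mu)) / tcrossprod(s)
  e <- eigen(G, symmetric = TRUE)
  keep <- seq_len(L)
  lam2 <- pmax(e$values[keep], 0)
  v <- e$vectors[, keep, drop = FALSE]
  # X v = C (v / s) - 1 ((mu/s)^T v), computed sparsely
  vs <- sweep(v, 1, s, "/")
  reduced <- as.matrix(C %*% vs) -
    matrix(1, N, 1) %*% (crossprod(mu / s, v))
  reduced <- fix_column_signs(reduced)
  colnames(reduced) <- paste0("comp", keep)
  new_reduced_profile(reduced, bundle$gene_ids,
                      singular_values = sqrt(lam2),
                      study_id = bundle$measurement_id)
}

#' Integrate an scRNA-seq collection
#'
#' Compresses each measurement with [compress_scrna()], fixes signs across
#' measurements, stacks the profiles into a genes x L x C tensor and applies
#' the integrated HOSVD. The resulting measurement-mode factors
#' `u_{l3 c}` can be screened against per-measurement group labels with
#' [test_factor_label_association()].
#'
#' @param bundles List of [scrna_bundle()]s sharing the gene universe.
#' @param L Components per measurement (default 10).
#' @param gene_rank Gene-mode rank for the integration (default `L * C`).
#' @return List with `integration` (see [integrate_studies()]), `stacked`,
#'   `profiles`, and `groups` (per-measurement labels, when present).
#' @export
integrate_scrna <- function(bundles, L = 10L, gene_rank = NULL) {
  stopifnot(length(bundles) >= 2)
  gene_ids <- bundles[[1]]$gene_ids
  for (b in bundles)
    if (!identical(b$gene_ids, gene_ids))
      stop("all bundles must share the gene universe")
  profiles <- lapply(seq_along(bundles), function(c) {
    b <- bundles[[c]]
    if (is.null(b$measurement_id)) b$measurement_id <- paste0("meas", c)
    compress_scrna(b, L)
  })
  profiles <- align_signs(profiles)
  stacked <- stack_profiles(profiles, L)
  integration <- integrate_studies(stacked, gene_rank = gene_rank)
  groups <- vapply(bundles, function(b)
    if (is.null(b$group)) NA_character_ else as.character(b$group),
    character(1))
  list(integration = integration, stacked = stacked, profiles = profiles,
       groups = if (all(is.na(groups))) NULL else factor(groups))
}
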