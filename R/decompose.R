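# Per-study reduction, cross-study sign alignment, stacking and integration.
#
# Each study is compressed to a genes x L "reduced profile": for a matrix
# study, x_{i l} = sum_j x_{ij} v_{lj} = lambda_l u_{li} (its own SVD); for a
# tensor study, the contraction with the leading factors of every sample
# mode. Reduced profiles of different studies share nothing but the gene
# axis, which is what makes unmatched studies stackable.

new_reduced_profile <- function(values, gene_ids, sample_factors = NULL,
                                singular_values = NULL, study_id = NULL,
                                provenance = NULL) {
  rownames(values) <- gene_ids
  if (is.null(colnames(values)))
    colnames(values) <- paste0("comp", seq_len(ncol(values)))
  structure(list(values = values, gene_ids = gene_ids,
                 sample_factors = sample_factors,
                 singular_values = singular_values,
                 study_id = study_id, provenance = provenance),
            class = "reduced_profile")
}

#' @export
print.reduced_profile <- function(x, ...) {
  cat(sprintf("<reduced_profile> %d genes x %d components%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$study_id)) "" else paste0(" [", x$study_id, "]")))
  invisible(x)
}

#' Compress a matrix study by SVD
#'
#' Applies SVD `x = sum_l u_l lambda_l v_l` to a (normalized) study and
#' returns both the decomposition and the reduced profile
#' `x_{il} = sum_j x_{ij} v_{lj}`, which equals `lambda_l u_{li}`. Columns
#' are ordered by decreasing singular value. Gene-factor signs follow the
#' deterministic convention (largest-magnitude element positive), with the
#' paired sample factor flipped together with the gene factor.
#'
#' @param x A (normalized) [expression_matrix()].
#' @param L Number of components to keep; must not exceed `min(N, M_k)`.
#' @param study_id Optional identifier stored on the profile.
#' @return List with `svd` (class `svd_result`: `gene_factors` (N x M),
#'   `sample_factors` (M x M), `singular_values`) and `profile`
#'   (a `reduced_profile` of L columns).
#' @export
svd_reduce <- function(x, L, study_id = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  m <- x$values
  if (L > min(dim(m)))
    stop("L cannot exceed M_k (requested ", L, ", study has ",
         ncol(m), " samples and ", nrow(m), " genes)")
  s <- svd(m)
  for (l in seq_len(ncol(s$u))) {
    i <- which.max(abs(s$u[, l]))
    if (s$u[i, l] < 0) {
      s$u[, l] <- -s$u[, l]
      s$v[, l] <- -s$v[, l]
    }
  }
  rownames(s$u) <- x$gene_ids
  rownames(s$v) <- x$sample_ids
  res <- structure(list(gene_factors = s$u, sample_factors = s$v,
                        singular_values = s$d), class = "svd_result")
  keep <- seq_len(L)
  reduced <- m %*% s$v[, keep, drop = FALSE]
  profile <- new_reduced_profile(reduced, x$gene_ids,
                                 sample_factors = s$v[, keep, drop = FALSE],
                                 singular_values = s$d[keep],
                                 study_id = study_id)
  list(svd = res, profile = profile)
}

#' Compress a tensor study by HOSVD
#'
#' Contracts a (normalized) multi-condition study with the leading
#' `L^[s]` left singular vectors of each sample mode's unfolding
#' (classical HOSVD factors), producing a reduced profile with
#' `prod(mode_ranks)` columns. Columns enumerate the rank tuples
#' `(l_1, ..., l_S)` in row-major order (last index varies fastest) and are
#' labelled accordingly. Column signs follow the deterministic convention.
#'
#' @param x A (normalized) [expression_tensor()] (genes on mode 1).
#' @param mode_ranks Integer vector, one rank per sample mode,
#'   each `<=` that mode's size.
#' @param study_id Optional identifier.
#' @return A `reduced_profile`; `provenance` records `mode_ranks` and
#'   `sample_factors` holds the per-mode truncated factor matrices.
#' @export
hosvd_reduce <- function(x, mode_ranks, study_id = NULL) {
  stopifnot(inherits(x, "expression_tensor"))
  d <- dim(x$values)
  S <- length(d) - 1L
  mode_ranks <- as.integer(mode_ranks)
  if (length(mode_ranks) != S)
    stop("mode_ranks must give one rank per sample mode")
  if (any(mode_ranks < 1) || any(mode_ranks > d[-1]))
    stop("each rank must lie in [1, mode size]")
  factors <- vector("list", S)
  red <- x$values
  for (s in seq_len(S)) {
    unf <- unfold(x$values, s + 1L)
    sv <- svd(unf, nu = mode_ranks[s], nv = 0)
    factors[[s]] <- fix_column_signs(sv$u[, seq_len(mode_ranks[s]), drop = FALSE])
    red <- ttm(red, t(factors[[s]]), s + 1L)
  }
  # flatten (l_1, ..., l_S) row-major: last tuple index varies fastest
  if (S > 1) red <- aperm(red, c(1L, (S + 1L):2L))
  dim(red) <- c(d[1], prod(mode_ranks))
  red <- fix_column_signs(red)
  tuples <- do.call(expand.grid, rev(lapply(mode_ranks, seq_len)))
  tuples <- tuples[, rev(seq_len(S)), drop = FALSE]
  colnames(red) <- apply(tuples, 1, paste, collapse = ".")
  new_reduced_profile(red, x$gene_ids, sample_factors = factors,
                      study_id = study_id, provenance = mode_ranks)
}

#' Fix reduced-profile signs across studies
#'
#' Singular vectors are defined only up to a simultaneous sign flip of the
#' gene-side and sample-side factors, so profiles from independent studies
#' cannot be stacked before their signs are reconciled. Every profile column
#' is first put into the deterministic base convention (largest-magnitude
#' element positive), then, for each component and each non-reference study,
#' the column (together with its paired sample factor, when present) is
#' flipped so that its Pearson correlation with the reference study's column
#' is non-negative. Components whose correlation with the reference is
#' essentially zero (|r| < 1e-8, or undefined) keep the base convention and
#' raise a warning.
#'
#' @param profiles List of `reduced_profile`s on a common gene universe.
#' @param reference Index of the reference study (default 1).
#' @return The list with signs fixed.
#' @export
align_signs <- function(profiles, reference = 1L) {
  stopifnot(length(profiles) >= 1, reference >= 1, reference <= length(profiles))
  gene_ids <- profiles[[reference]]$gene_ids
  for (k in seq_along(profiles)) {
    if (!identical(profiles[[k]]$gene_ids, gene_ids))
      stop("profiles must share the gene universe (study ", k, " differs)")
    profiles[[k]] <- canonicalize_profile(profiles[[k]])
  }
  ref <- profiles[[reference]]$values
  for (k in seq_along(profiles)) {
    if (k == reference) next
    p <- profiles[[k]]
    for (l in seq_len(min(ncol(ref), ncol(p$values)))) {
      r <- suppressWarnings(stats::cor(ref[, l], p$values[, l]))
      if (is.na(r) || abs(r) < 1e-8) {
        warning(sprintf(
          "component %d of study %d has ~zero correlation with the reference; keeping base sign",
          l, k))
      } else if (r < 0) {
        profiles[[k]] <- flip_component(profiles[[k]], l)
      }
    }
  }
  profiles
}

canonicalize_profile <- function(p) {
  for (l in seq_len(ncol(p$values))) {
    i <- which.max(abs(p$values[, l]))
    if (p$values[i, l] < 0) p <- flip_component(p, l)
  }
  p
}

flip_component <- function(p, l) {
  p$values[, l] <- -p$values[, l]
  # matrix studies carry one paired sample-factor column per component
  if (is.matrix(p$sample_factors) && l <= ncol(p$sample_factors))
    p$sample_factors[, l] <- -p$sample_factors[, l]
  p
}

#' Stack sign-fixed reduced profiles into a genes x L x K tensor
#'
#' @param profiles List of aligned, sign-fixed `reduced_profile`s sharing the
#'   gene universe; each must have at least `L` columns (extras discarded).
#' @param L Number of components to keep per study.
#' @return Object of class `stacked_tensor`: `values` (array N x L x K),
#'   `gene_ids`, `study_ids`, `L`.
#' @export
stack_profiles <- function(profiles, L) {
  stopifnot(length(profiles) >= 1)
  gene_ids <- profiles[[1]]$gene_ids
  K <- length(profiles)
  arr <- array(0, dim = c(length(gene_ids), L, K))
  study_ids <- character(K)
  for (k in seq_len(K)) {
    p <- profiles[[k]]
    if (!identical(p$gene_ids, gene_ids))
      stop("profiles must share the gene universe")
    if (ncol(p$values) < L)
      stop("profile ", k, " has only ", ncol(p$values),
           " components; L = ", L, " requested")
    arr[, , k] <- p$values[, seq_len(L)]
    study_ids[k] <- if (is.null(p$study_id)) paste0("study", k) else p$study_id
  }
  dimnames(arr) <- list(gene_ids, paste0("comp", seq_len(L)), study_ids)
  structure(list(values = arr, gene_ids = gene_ids, study_ids = study_ids,
                 L = L), class = "stacked_tensor")
}

#' @export
print.stacked_tensor <- function(x, ...) {
  cat(sprintf("<stacked_tensor> %d genes x %d components x %d studies\n",
              length(x$gene_ids), x$L, length(x$study_ids)))
  invisible(x)
}

#' Integrated HOSVD of a stacked tensor
#'
#' Applies HOSVD to the stacked genes x L x K tensor,
#' `x_{ilk} = sum G(l1 l2 l3) u_{l1 i} u_{l2 l} u_{l3 k}`, with full ranks on
#' the component and study modes and the gene mode truncated to `gene_rank`
#' (default `L*K`, which spans the entire nonzero spectrum of the gene-mode
#' unfolding, so nothing informative is discarded).
#'
#' @param stacked A `stacked_tensor`.
#' @param gene_rank Gene-mode rank to keep.
#' @return Object of class `integration`: `core` (gene_rank x L x K),
#'   `gene_factors` (N x gene_rank, orthonormal columns, rownames = gene
#'   ids), `comp_factors` (L x L), `study_factors` (K x K), plus `gene_ids`,
#'   `study_ids`.
#' @export
integrate_studies <- function(stacked, gene_rank = NULL) {
  stopifnot(inherits(stacked, "stacked_tensor"))
  d <- dim(stacked$values)
  if (is.null(gene_rank)) gene_rank <- min(d[1], d[2] * d[3])
  if (gene_rank > d[1]) stop("gene_rank exceeds the gene count")
  h <- hosvd(stacked$values, ranks = c(gene_rank, d[2], d[3]))
  gene_factors <- h$factors[[1]]
  rownames(gene_factors) <- stacked$gene_ids
  study_factors <- h$factors[[3]]
  rownames(study_factors) <- stacked$study_ids
  structure(list(core = h$core, gene_factors = gene_factors,
                 comp_factors = h$factors[[2]], study_factors = study_factors,
                 gene_ids = stacked$gene_ids, study_ids = stacked$study_ids),
            class = "integration")
}

#' @export
print.integration <- function(x, ...) {
  cat(sprintf("<integration> core %s; %d genes, %d studies\n",
              paste(dim(x$core), collapse = " x "),
              length(x$gene_ids), length(x$study_ids)))
  invisible(x)
}

#' Nested HOSVD drug ranking
#'
#' Takes the projection of a drug-response tensor onto the integrated gene
#' factors (coordinates indexed by gene factor l1 x drug x dose x replicate),
#' applies a full-rank HOSVD to the 3-mode slice of each requested l1, and
#' scores each drug by the squared mass of its row over the top `T` drug-mode
#' singular vectors, `sum_{t=1}^{T} (u_{t,drug})^2`. Because the drug factor
#' matrix is orthonormal, scores lie in [0, 1] (and trivially below `T`).
#'
#' @param proj A `sample_projection` over a 3-condition tensor study (see
#'   [project_samples()]) or a plain 4-way array (l1 x drug x dose x rep).
#' @param T Number of leading drug-mode components scored (default 5).
#' @param ell1 Gene-factor indices to analyse (default: all slices).
#' @return Object of class `nested_drug_result`: `drug_scores` (drugs x
#'   length(ell1) matrix), `ranking` (list of drug orderings, descending),
#'   `hosvd` (per-l1 `hosvd_result`s), `T`, `ell1`.
#' @export
nested_hosvd_drug <- function(proj, T = 5L, ell1 = NULL) {
  a <- if (inherits(proj, "sample_projection")) proj$coords else proj
  a <- as.array(a)
  d <- dim(a)
  if (length(d) != 4)
    stop("expected coordinates with modes (gene factor, drug, dose, replicate)")
  if (T > d[2]) stop("T cannot exceed the number of drugs (", d[2], ")")
  if (is.null(ell1)) ell1 <- seq_len(d[1])
  stopifnot(all(ell1 >= 1), all(ell1 <= d[1]))
  drug_ids <- dimnames(a)[[2]]
  if (is.null(drug_ids)) drug_ids <- paste0("drug", seq_len(d[2]))
  scores <- matrix(NA_real_, d[2], length(ell1),
                   dimnames = list(drug_ids, paste0("l1=", ell1)))
  hs <- vector("list", length(ell1))
  for (j in seq_along(ell1)) {
    slice <- array(a[ell1[j], , , ], dim = d[-1])
    if (all(slice == 0)) {              # degenerate slice carries no signal
      scores[, j] <- 0
      next
    }
    h <- hosvd(slice)
    hs[[j]] <- h
    u_drug <- h$factors[[1]]
    scores[, j] <- rowSums(u_drug[, seq_len(T), drop = FALSE]^2)
  }
  ranking <- lapply(seq_along(ell1), function(j)
    drug_ids[order(scores[, j], decreasing = TRUE)])
  names(ranking) <- colnames(scores)
  structure(list(drug_scores = scores, ranking = ranking, hosvd = hs,
                 T = T, ell1 = ell1), class = "nested_drug_result")
}

#' @export
print.nested_drug_result <- function(x, ...) {
  cat(sprintf("<nested_drug_result> %d drugs scored over %d gene factors (T=%d)\n",
              nrow(x$drug_scores), length(x$ell1), x$T))
  invisible(x)
}
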