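# Gene selection: pick gene-mode factors by core-tensor weight, convert the
# chosen factors' loadings to chi-squared P-values under a Gaussian null,
# BH-adjust, threshold.

#' Rank gene-mode factors by squared core-tensor weight
#'
#' Ranks the gene-mode indices `l1` by `sum G(l1, ...)^2`, the summation
#' running over all combinations of the non-gene indices, optionally
#' restricted by per-mode constraints (e.g. only the study-mode index that
#' distinguishes a dataset of interest).
#'
#' @param core Core tensor (array) or an `integration` object.
#' @param fixed_modes Optional named list restricting the summation: names
#'   are non-gene mode numbers (as in the array, e.g. `"2"`, `"3"`), values
#'   are the index vectors allowed to enter the sum.
#' @param top_n How many factor indices to return (default: all, ranked).
#' @return Integer vector of gene-factor indices in decreasing weight order,
#'   with the weights attached as the `weights` attribute (full vector,
#'   indexed by l1).
#' @export
choose_factors <- function(core, fixed_modes = NULL, top_n = NULL) {
  if (inherits(core, "integration")) core <- core$core
  core <- as.array(core)
  d <- dim(core)
  idx <- lapply(d, seq_len)
  if (!is.null(fixed_modes)) {
    for (nm in names(fixed_modes)) {
      mode <- as.integer(nm)
      if (is.na(mode) || mode < 2 || mode > length(d))
        stop("fixed_modes names must be non-gene mode numbers (2..",
             length(d), ")")
      sel <- as.integer(fixed_modes[[nm]])
      if (any(sel < 1) || any(sel > d[mode]))
        stop("constraint index out of range for mode ", mode)
      idx[[mode]] <- sel
    }
  }
  sub <- do.call(`[`, c(list(core), idx, list(drop = FALSE)))
  weights <- apply(sub^2, 1, sum)
  ord <- order(weights, decreasing = TRUE)
  if (!is.null(top_n)) ord <- ord[seq_len(min(top_n, length(ord)))]
  structure(ord, weights = weights)
}

#' Chi-squared P-values for genes from selected gene factors
#'
#' Under the working assumption that the loadings `u_{l1 i}` of an
#' uninformative gene are Gaussian, the statistic
#' `sum_{l1 in omega} (u_{l1 i} / sigma_{l1})^2` follows a chi-squared
#' distribution with `|omega|` degrees of freedom; each gene's P-value is the
#' upper tail at its statistic. By default `sigma_{l1}` is the sample
#' standard deviation of `u_{l1 i}` over all genes in the universe
#' (zero-padded genes included); pass `sigma_genes` to estimate it on a
#' subset instead.
#'
#' @param U Gene-factor matrix (genes x factors, rownames = gene ids) or an
#'   `integration` object.
#' @param omega Integer vector of gene-factor indices entering the statistic.
#' @param sigma Optional per-factor standard deviations overriding the
#'   estimate (recycled to `length(omega)`).
#' @param sigma_genes Optional indices/names of the genes used to estimate
#'   `sigma` (e.g. to exclude zero-padded genes).
#' @return Object of class `gene_selection`: a list with a per-gene
#'   data.frame (`gene_id`, `statistic`, `P`, and after [bh_adjust_selection()]
#'   also `adjP`, `selected`), `omega`, `sigma`, `threshold`.
#' @export
gene_pvalues <- function(U, omega, sigma = NULL, sigma_genes = NULL) {
  if (inherits(U, "integration")) U <- U$gene_factors
  U <- as.matrix(U)
  omega <- as.integer(omega)
  if (length(omega) == 0) stop("omega must be non-empty")
  if (any(omega < 1) || any(omega > ncol(U)))
    stop("omega index out of range")
  sub <- U[, omega, drop = FALSE]
  if (is.null(sigma)) {
    est <- if (is.null(sigma_genes)) sub else sub[sigma_genes, , drop = FALSE]
    sigma <- apply(est, 2, stats::sd)
  } else {
    sigma <- rep_len(sigma, length(omega))
  }
  if (any(sigma <= 0)) stop("sigma must be positive for every selected factor")
  stat <- rowSums(sweep(sub, 2, sigma, "/")^2)
  P <- stats::pchisq(stat, df = length(omega), lower.tail = FALSE)
  ids <- rownames(U)
  if (is.null(ids)) ids <- paste0("gene", seq_len(nrow(U)))
  tab <- data.frame(gene_id = ids, statistic = stat, P = P,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, omega = omega, sigma = sigma, threshold = NA_real_),
            class = "gene_selection")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param P Numeric vector of raw P-values in [0, 1].
#' @return Adjusted P-values (monotone, capped at 1) in the original order.
#' @export
bh_adjust <- function(P) {
  if (any(!is.finite(P)) || any(P < 0) || any(P > 1))
    stop("P-values must lie in [0, 1]")
  stats::p.adjust(P, method = "BH")
}

#' Adjust and threshold a gene selection
#'
#' Applies [bh_adjust()] to the raw P-values and flags genes with adjusted P
#' strictly below `threshold`.
#'
#' @param selection A `gene_selection` from [gene_pvalues()].
#' @param threshold Adjusted-P cutoff (default 0.01).
#' @return The `gene_selection` with `adjP` and `selected` columns filled.
#' @export
bh_adjust_selection <- function(selection, threshold = 0.01) {
  stopifnot(inherits(selection, "gene_selection"))
  selection$table$adjP <- bh_adjust(selection$table$P)
  selection$table$selected <- selection$table$adjP < threshold
  selection$threshold <- threshold
  selection
}

#' Selected gene identifiers
#'
#' @param selection A `gene_selection` with adjusted P-values.
#' @param threshold Optional cutoff overriding the stored one.
#' @return Character vector of gene ids with adjusted P below the threshold,
#'   ordered by ascending adjusted P (gene id breaks ties).
#' @export
select_genes <- function(selection, threshold = NULL) {
  stopifnot(inherits(selection, "gene_selection"))
  tab <- selection$table
  if (is.null(tab$adjP)) stop("adjusted P-values not computed; run bh_adjust_selection()")
  if (is.null(threshold)) threshold <- selection$threshold
  hit <- tab[tab$adjP < threshold, , drop = FALSE]
  hit$gene_id[order(hit$adjP, hit$gene_id)]
}

#' @export
as.data.frame.gene_selection <- function(x, ...) x$table

#' @export
print.gene_selection <- function(x, ...) {
  n_sel <- if (is.null(x$table$selected)) NA_integer_ else sum(x$table$selected)
  cat(sprintf("<gene_selection> %d genes, |omega| = %d%s\n",
              nrow(x$table), length(x$omega),
              if (is.na(n_sel)) "" else
                sprintf(", %d selected at adjP < %g", n_sel, x$threshold)))
  invisible(x)
}
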