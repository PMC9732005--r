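# End-to-end convenience pipeline and the command-line workflow driver.

#' Integrate unmatched studies end to end
#'
#' Runs the full integration: per-sample normalization on each study's
#' native genes, alignment to a common gene universe with zero filling,
#' per-study SVD (matrices) or HOSVD (tensors) reduction, cross-study sign
#' fixing, stacking, and the integrated HOSVD.
#'
#' @param studies List of [expression_matrix()] / [expression_tensor()]
#'   objects.
#' @param L Components kept per study (default: largest value allowed by
#'   every matrix study, capped at 8; tensor studies use `mode_ranks`).
#' @param mode_ranks Optional list (parallel to `studies`) of per-mode ranks
#'   for tensor studies; each must multiply to at least `L`.
#' @param universe `"reference"` or `"union"` (see [align_gene_universe()]).
#' @param reference Reference study index for the universe (default largest).
#' @param gene_rank Gene-mode rank of the integrated HOSVD (default `L*K`).
#' @param normalize Set FALSE if the studies are already normalized.
#' @return Object of class `tdfuse_fit`: `integration`, `stacked`,
#'   `profiles`, `aligned` (the aligned normalized studies), `universe`,
#'   `L`.
#' @export
integrate_unmatched <- function(studies, L = NULL, mode_ranks = NULL,
                                universe = c("reference", "union"),
                                reference = NULL, gene_rank = NULL,
                                normalize = TRUE) {
  universe <- match.arg(universe)
  stopifnot(length(studies) >= 2)
  if (normalize) studies <- lapply(studies, normalize_per_sample)
  al <- align_gene_universe(studies, mode = universe, reference = reference)
  is_mat <- vapply(al$studies, inherits, logical(1), "expression_matrix")
  if (is.null(L)) {
    caps <- vapply(al$studies[is_mat], function(s) ncol(s$values), integer(1))
    L <- min(c(8L, caps))
  }
  profiles <- vector("list", length(studies))
  for (k in seq_along(al$studies)) {
    s <- al$studies[[k]]
    id <- paste0("study", k)
    if (is_mat[k]) {
      profiles[[k]] <- svd_reduce(s, L, study_id = id)$profile
    } else {
      mr <- if (!is.null(mode_ranks)) mode_ranks[[k]] else
        default_mode_ranks(dim(s$values)[-1], L)
      profiles[[k]] <- hosvd_reduce(s, mr, study_id = id)
    }
  }
  profiles <- align_signs(profiles)
  stacked <- stack_profiles(profiles, L)
  integration <- integrate_studies(stacked, gene_rank = gene_rank)
  structure(list(integration = integration, stacked = stacked,
                 profiles = profiles, aligned = al$studies,
                 universe = al$universe, L = L),
            class = "tdfuse_fit")
}

# Smallest per-mode ranks whose product reaches L, greedily raising the
# largest modes first (replicate-like trailing modes stay at rank 1).
default_mode_ranks <- function(mode_sizes, L) {
  r <- rep(1L, length(mode_sizes))
  ord <- order(mode_sizes, decreasing = TRUE)
  repeat {
    if (prod(r) >= L) break
    advanced <- FALSE
    for (m in ord) {
      if (r[m] < mode_sizes[m]) {
        r[m] <- r[m] + 1L
        advanced <- TRUE
        if (prod(r) >= L) break
      }
    }
    if (!advanced) break
  }
  r
}

#' @export
print.tdfuse_fit <- function(x, ...) {
  cat(sprintf("<tdfuse_fit> %d studies integrated over %d genes (L = %d)\n",
              length(x$profiles), length(x$integration$gene_ids), x$L))
  invisible(x)
}

#' Select genes from an integration
#'
#' Chooses the gene-mode factor set Omega from the core tensor (unless
#' pinned), computes chi-squared P-values, BH-adjusts, and thresholds.
#' The automatic Omega keeps gene factors, in decreasing order of squared
#' core mass, whose weight exceeds `omega_gap` times the median weight —
#' i.e. the factors that stand clearly above the noise floor — capped at
#' `omega_size`; at least the top factor is always kept.
#'
#' @param fit A `tdfuse_fit` or `integration`.
#' @param omega Explicit factor set pinning the automatic choice.
#' @param omega_size Cap on the automatic factor set (default 5).
#' @param omega_gap Weight-to-median ratio a factor must exceed to enter the
#'   automatic set (default 2).
#' @param fixed_modes Optional constraints passed to [choose_factors()].
#' @param threshold Adjusted-P cutoff (default 0.01).
#' @return A `gene_selection` with adjusted P-values and flags.
#' @export
extract_genes <- function(fit, omega = NULL, omega_size = 5L, omega_gap = 2,
                          fixed_modes = NULL, threshold = 0.01) {
  integration <- if (inherits(fit, "tdfuse_fit")) fit$integration else fit
  stopifnot(inherits(integration, "integration"))
  if (is.null(omega)) {
    ranked <- choose_factors(integration$core, fixed_modes,
                             top_n = omega_size)
    w <- attr(ranked, "weights")
    keep <- w[ranked] > omega_gap * stats::median(w)
    keep[1] <- TRUE                       # the top factor is always kept
    omega <- as.integer(ranked[keep])
  }
  sel <- gene_pvalues(integration$gene_factors, omega)
  bh_adjust_selection(sel, threshold)
}

#' Associate projected sample coordinates with each study's labels
#'
#' Projects every aligned study onto the integrated gene factors and screens
#' the leading factor coordinates against that study's categorical labels
#' (BH across factors, per study).
#'
#' @param fit A `tdfuse_fit` whose aligned studies carry labels.
#' @param n_factors Leading gene factors to screen (default `fit$L`).
#' @param threshold Adjusted-P cutoff (default 0.05).
#' @param correction `"per_study"` (default) applies BH across factors
#'   within each study's screen; `"global"` applies one BH correction across
#'   all factor-study tests, the right family when asking whether anything
#'   in the whole run associates with labels.
#' @return Named list of `association_report`s, one per labelled study.
#' @export
associate_samples <- function(fit, n_factors = NULL, threshold = 0.05,
                              correction = c("per_study", "global")) {
  stopifnot(inherits(fit, "tdfuse_fit"))
  correction <- match.arg(correction)
  if (is.null(n_factors)) n_factors <- fit$L
  U <- fit$integration$gene_factors[, seq_len(n_factors), drop = FALSE]
  out <- list()
  for (k in seq_along(fit$aligned)) {
    s <- fit$aligned[[k]]
    if (!inherits(s, "expression_matrix") || is.null(s$labels)) next
    proj <- project_samples(U, s)
    out[[fit$stacked$study_ids[k]]] <-
      test_factor_label_association(proj, s$labels, threshold)
  }
  if (correction == "global" && length(out) > 0) {
    raw <- unlist(lapply(out, function(r) r$table$P), use.names = FALSE)
    adj <- bh_adjust(raw)
    at <- 0L
    for (nm in names(out)) {
      n <- nrow(out[[nm]]$table)
      out[[nm]]$table$adjP <- adj[at + seq_len(n)]
      out[[nm]]$table$significant <- out[[nm]]$table$adjP < threshold
      at <- at + n
    }
  }
  out
}

#' Factors associated with classifications in every study
#'
#' The integration seeks gene factors whose sample coordinates follow the
#' class structure of all studies simultaneously; a factor that reaches
#' significance in only one study reflects study-specific structure (or a
#' single screen's false positive). This consensus reduces a list of
#' per-study [test_factor_label_association()] reports to the factors
#' flagged significant in every one of them.
#'
#' @param reports List of `association_report`s (e.g. from
#'   [associate_samples()]).
#' @return Integer vector of factor indices significant in all reports.
#' @export
consensus_factors <- function(reports) {
  stopifnot(length(reports) >= 1)
  sets <- lapply(reports, function(r) r$table$factor[r$table$significant])
  Reduce(intersect, sets)
}
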