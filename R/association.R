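# Sample projection onto the shared gene-factor space and the
# categorical-regression (one-way ANOVA) screen of factor coordinates
# against class labels.

#' Project a study's samples onto the integrated gene factors
#'
#' Computes the coordinates `v_{l1 j k} = sum_i u_{l1 i} x_{i j k}` of each
#' sample in the space spanned by the integrated gene-side singular vectors.
#' For a tensor study the coordinates keep one index per condition mode.
#'
#' @param U Gene-factor matrix (genes x factors, rownames = gene ids) or an
#'   `integration` object.
#' @param x An aligned, normalized [expression_matrix()],
#'   [expression_tensor()], or `reduced_profile` on the same gene universe.
#' @return Object of class `sample_projection`: `coords` (factors x samples
#'   matrix, or factors x condition-modes array), `labels` (passed through
#'   from the study when present), `study_id`.
#' @export
project_samples <- function(U, x) {
  if (inherits(U, "integration")) U <- U$gene_factors
  U <- as.matrix(U)
  gene_ids <- rownames(U)
  xg <- if (inherits(x, "reduced_profile")) x$gene_ids else x$gene_ids
  if (!is.null(gene_ids) && !identical(gene_ids, xg))
    stop("study is not on the gene universe of the factors")
  labels <- NULL
  study_id <- NULL
  if (inherits(x, "expression_matrix")) {
    coords <- crossprod(U, x$values)
    labels <- x$labels
  } else if (inherits(x, "expression_tensor")) {
    coords <- ttm(x$values, t(U), 1)
    dn <- dimnames(x$values)
    dn[[1]] <- paste0("factor", seq_len(ncol(U)))
    dimnames(coords) <- dn
  } else if (inherits(x, "reduced_profile")) {
    coords <- crossprod(U, x$values)
    study_id <- x$study_id
  } else stop("unsupported study type")
  if (is.matrix(coords))
    rownames(coords) <- paste0("factor", seq_len(ncol(U)))
  structure(list(coords = coords, labels = labels, study_id = study_id),
            class = "sample_projection")
}

#' @export
print.sample_projection <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<sample_projection> %d factors x (%s)\n",
              d[1], paste(d[-1], collapse = " x ")))
  invisible(x)
}

#' Screen factor coordinates against categorical labels
#'
#' For each factor, fits the categorical linear model (one-way ANOVA) of the
#' coordinate on the class label and reports the F statistic and its
#' P-value; P-values are BH-adjusted across factors and flagged at adjusted
#' P below `threshold`.
#'
#' @param proj A `sample_projection`, or a plain matrix of coordinates
#'   (factors x observations), or a factor-by-observation matrix such as the
#'   study-mode factors `u_{l3 c}` of an integration (pass its transpose if
#'   observations are on the rows).
#' @param labels Categorical label per observation (>= 2 classes, more
#'   observations than classes).
#' @param threshold Adjusted-P cutoff for the `significant` flag (default 0.05).
#' @return Object of class `association_report`: data.frame with `factor`,
#'   `F`, `df1`, `df2`, `P`, `adjP`, `significant`.
#' @export
test_factor_label_association <- function(proj, labels = NULL, threshold = 0.05) {
  coords <- if (inherits(proj, "sample_projection")) proj$coords else proj
  if (inherits(proj, "sample_projection") && is.null(labels))
    labels <- proj$labels
  coords <- as.matrix(coords)
  if (is.null(labels)) stop("labels are required")
  labels <- droplevels(as.factor(labels))
  if (length(labels) != ncol(coords))
    stop("labels length does not match the number of observations")
  if (nlevels(labels) < 2) stop("at least two label classes are required")
  if (length(labels) <= nlevels(labels))
    stop("more observations than classes are required")
  out <- data.frame(factor = seq_len(nrow(coords)), F = NA_real_,
                    df1 = NA_integer_, df2 = NA_integer_, P = NA_real_)
  for (l in seq_len(nrow(coords))) {
    fit <- stats::lm(coords[l, ] ~ labels)
    an <- stats::anova(fit)
    out$F[l] <- an[1, "F value"]
    out$df1[l] <- an[1, "Df"]
    out$df2[l] <- an[2, "Df"]
    out$P[l] <- an[1, "Pr(>F)"]
  }
  out$adjP <- bh_adjust(out$P)
  out$significant <- out$adjP < threshold
  structure(list(table = out, threshold = threshold, labels = labels),
            class = "association_report")
}

#' @export
as.data.frame.association_report <- function(x, ...) x$table

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("<association_report> %d factors, %d significant at adjP < %g\n",
              nrow(x$table), sum(x$table$significant), x$threshold))
  invisible(x)
}
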