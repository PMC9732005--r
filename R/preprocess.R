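#' Normalize each sample to zero mean and sum of squares N over genes
#'
#' Standardizes every sample profile across its study's native gene set so
#' that, for each sample, the values over genes have mean zero and sum of
#' squares equal to the gene count N (i.e. division by the population
#' standard deviation). For a tensor study each combination of non-gene
#' indices is one sample profile.
#'
#' @param x An [expression_matrix()] or [expression_tensor()].
#' @return The same type, normalized per sample.
#' @export
normalize_per_sample <- function(x) {
  UseMethod("normalize_per_sample")
}

normalize_columns <- function(m, sample_names) {
  n <- nrow(m)
  mu <- colMeans(m)
  centered <- sweep(m, 2, mu, "-")
  s <- sqrt(colSums(centered^2) / n)
  zero <- which(s <= 0)
  if (length(zero))
    stop("zero-variance sample: ", sample_names[zero[1]])
  sweep(centered, 2, s, "/")
}

#' @export
normalize_per_sample.expression_matrix <- function(x) {
  x$values <- normalize_columns(x$values, x$sample_ids)
  x
}

#' @export
normalize_per_sample.expression_tensor <- function(x) {
  d <- dim(x$values)
  m <- matrix(x$values, nrow = d[1])
  m <- normalize_columns(m, paste0("cell#", seq_len(prod(d[-1]))))
  dn <- dimnames(x$values)
  x$values <- array(m, dim = d, dimnames = dn)
  x
}

#' Place studies on a common gene universe with zero filling
#'
#' Aligns a list of studies so that all share the same ordered gene list.
#' In `"union"` mode the universe is the union of all study gene lists in
#' first-seen order; in `"reference"` mode it is one study's gene list
#' (default: the study with the most genes), and genes outside the reference
#' are dropped. Rows a study did not measure are filled with exact zeros, so
#' that (if alignment follows normalization) padded rows carry no signal.
#'
#' @param studies List of [expression_matrix()] / [expression_tensor()]
#'   objects (types may be mixed).
#' @param mode `"reference"` (default) or `"union"`.
#' @param reference Index of the reference study; default the largest.
#' @return A list with `universe` (a `gene_universe`: `gene_ids` plus
#'   per-study index maps) and `studies` (the aligned list).
#' @export
align_gene_universe <- function(studies, mode = c("reference", "union"),
                                reference = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(studies) >= 1)
  gene_lists <- lapply(studies, function(s) s$gene_ids)
  if (mode == "reference") {
    if (is.null(reference)) reference <- which.max(lengths(gene_lists))
    stopifnot(reference >= 1, reference <= length(studies))
    universe <- gene_lists[[reference]]
  } else {
    universe <- unique(unlist(gene_lists, use.names = FALSE))
  }
  if (length(Reduce(intersect, gene_lists)) == 0)
    warning("gene universes of the studies do not intersect")
  maps <- lapply(gene_lists, function(g) {
    idx <- match(g, universe)      # study position -> universe position (NA = dropped)
    idx
  })
  aligned <- vector("list", length(studies))
  for (k in seq_along(studies)) {
    aligned[[k]] <- pad_to_universe(studies[[k]], universe, maps[[k]])
  }
  gu <- structure(list(gene_ids = universe, maps = maps, mode = mode,
                       reference = if (mode == "reference") reference else NA),
                  class = "gene_universe")
  list(universe = gu, studies = aligned)
}

pad_to_universe <- function(study, universe, map) {
  keep <- !is.na(map)
  if (inherits(study, "expression_matrix")) {
    out <- matrix(0, length(universe), ncol(study$values),
                  dimnames = list(universe, study$sample_ids))
    out[map[keep], ] <- study$values[keep, , drop = FALSE]
    expression_matrix(out, labels = study$labels)
  } else if (inherits(study, "expression_tensor")) {
    d <- dim(study$values)
    m <- matrix(study$values, nrow = d[1])
    out <- matrix(0, length(universe), ncol(m))
    out[map[keep], ] <- m[keep, , drop = FALSE]
    arr <- array(out, dim = c(length(universe), d[-1]))
    dn <- dimnames(study$values)
    if (is.null(dn)) dn <- vector("list", length(d))
    dn[[1]] <- universe
    dimnames(arr) <- dn
    expression_tensor(arr, mode_labels = study$mode_labels)
  } else if (inherits(study, "reduced_profile")) {
    out <- matrix(0, length(universe), ncol(study$values),
                  dimnames = list(universe, colnames(study$values)))
    out[map[keep], ] <- study$values[keep, , drop = FALSE]
    study$values <- out
    study$gene_ids <- universe
    study
  } else stop("unsupported study type")
}
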