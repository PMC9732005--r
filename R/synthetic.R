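# Synthetic-data generators with planted ground truth. These emulate the
# study designs the method targets: K unmatched bulk studies sharing one gene
# program across disjoint sample sets, a drug x dose x replicate response
# tensor, and a collection of sparse scRNA-seq measurements with
# group-specific programs. All generators are deterministic given `seed`.

# Centered per-class scores scaled to the range [-1, 1], so planted genes
# shift by +/- effect between the extreme classes.
class_scores <- function(C) {
  z <- seq_len(C) - (C + 1) / 2
  z / max(abs(z))
}

split_classes <- function(M, C) {
  base <- M %/% C
  sizes <- rep(base, C) + c(rep(1L, M %% C), rep(0L, C - M %% C))
  rep(seq_len(C), times = sizes)
}

#' Generate unmatched studies sharing a planted gene program
#'
#' Emulates K independent studies over a shared gene universe whose sample
#' sets are disjoint and whose labels are study-specific. A background of
#' i.i.d. Gaussian noise (`noise_sd`) carries a planted program of `planted`
#' genes: each planted gene shifts by +/- `effect` noise-SD units according
#' to its fixed sign and the study's class structure (class offsets are
#' centered and span `[-effect, effect]`). Each study is then multiplied by
#' a random positive gain, so measurement scale is not shared across
#' studies. Generators emit raw values; run [normalize_per_sample()] as in
#' any real analysis.
#'
#' @param n_genes Gene universe size (default 2000).
#' @param sizes Per-study sample counts (default `c(9, 23, 8)`).
#' @param classes_per_study Classes per study (recycled; default 2).
#' @param planted Number of planted genes (default 100).
#' @param effect Shift of planted genes between the extreme classes and the
#'   center, in noise-SD units (default 2).
#' @param noise_sd Background noise SD (default 1).
#' @param seed Integer seed; fully determines the output.
#' @return List with `studies` (list of [expression_matrix()] with labels)
#'   and `truth` (class `synthetic_truth`: `planted_gene_ids`, `signs`,
#'   `labels`, `effect`, `noise_sd`, `seed`).
#' @export
generate_unmatched_studies <- function(n_genes = 2000L, sizes = c(9L, 23L, 8L),
                                       classes_per_study = 2L, planted = 100L,
                                       effect = 2, noise_sd = 1, seed = 1L) {
  stopifnot(planted <= n_genes, all(sizes >= 2), length(sizes) >= 1)
  classes_per_study <- rep_len(as.integer(classes_per_study), length(sizes))
  stopifnot(all(classes_per_study >= 2), all(sizes >= classes_per_study))
  set.seed(seed)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  planted_idx <- sort(sample.int(n_genes, planted))
  signs <- sample(c(-1, 1), planted, replace = TRUE)
  studies <- vector("list", length(sizes))
  labels <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    M <- sizes[k]
    C <- classes_per_study[k]
    cls <- split_classes(M, C)
    z <- class_scores(C)
    x <- matrix(stats::rnorm(n_genes * M, sd = noise_sd), n_genes, M)
    x[planted_idx, ] <- x[planted_idx, ] +
      effect * noise_sd * outer(signs, z[cls])
    # study-specific measurement scale: units are not shared across studies
    x <- exp(stats::runif(1, -0.5, 0.5)) * x
    labels[[k]] <- factor(paste0("class", cls))
    studies[[k]] <- expression_matrix(
      x, gene_ids = gene_ids,
      sample_ids = sprintf("s%d_%02d", k, seq_len(M)),
      labels = labels[[k]])
  }
  truth <- structure(list(planted_gene_ids = gene_ids[planted_idx],
                          signs = signs, labels = labels,
                          effect = effect, noise_sd = noise_sd, seed = seed),
                     class = "synthetic_truth")
  list(studies = studies, truth = truth)
}

#' Generate a drug-response tensor with effective drugs
#'
#' Emulates a genes x drugs x doses x replicates response screen: effective
#' drugs modulate a planted gene program monotonically in dose (replicates
#' share means), everything else is Gaussian noise.
#'
#' @param n_genes Gene count (default 2000).
#' @param drugs,doses,reps Mode sizes (defaults 10, 4, 3).
#' @param effective Number of effective drugs, or an integer vector of drug
#'   indices (default 3).
#' @param effect Per-gene response amplitude at the highest dose, in
#'   noise-SD units (default 2).
#' @param noise_sd Background noise SD (default 1).
#' @param program Optional planted program: named numeric vector of signed
#'   gene weights (names = gene ids). Default: a fresh random +/-1 program
#'   over `planted` genes.
#' @param planted Program size when `program` is NULL (default 100).
#' @param seed Integer seed.
#' @return List with `tensor` (an [expression_tensor()]) and `truth`
#'   (`effective_drug_ids`, `program`, `seed`).
#' @export
generate_drug_tensor <- function(n_genes = 2000L, drugs = 10L, doses = 4L,
                                 reps = 3L, effective = 3L, effect = 2,
                                 noise_sd = 1, program = NULL, planted = 100L,
                                 seed = 1L) {
  set.seed(seed + 101L)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  if (is.null(program)) {
    idx <- sort(sample.int(n_genes, planted))
    program <- stats::setNames(sample(c(-1, 1), planted, replace = TRUE),
                               gene_ids[idx])
  }
  pidx <- match(names(program), gene_ids)
  if (anyNA(pidx)) stop("program genes must belong to the gene universe")
  eff_idx <- if (length(effective) == 1L)
    sort(sample.int(drugs, effective)) else sort(as.integer(effective))
  stopifnot(all(eff_idx >= 1), all(eff_idx <= drugs))
  x <- array(stats::rnorm(n_genes * drugs * doses * reps, sd = noise_sd),
             dim = c(n_genes, drugs, doses, reps))
  dose_frac <- seq_len(doses) / doses
  for (d in eff_idx) {
    response <- outer(as.numeric(program), effect * noise_sd * dose_frac)
    for (r in seq_len(reps))                   # replicates share means
      x[pidx, d, , r] <- x[pidx, d, , r] + response
  }
  drug_ids <- sprintf("drug%02d", seq_len(drugs))
  dimnames(x) <- list(gene_ids, drug_ids,
                      paste0("dose", seq_len(doses)),
                      paste0("rep", seq_len(reps)))
  tensor <- expression_tensor(x, gene_ids = gene_ids)
  truth <- structure(list(effective_drug_ids = drug_ids[eff_idx],
                          program = program, seed = seed),
                     class = "synthetic_truth")
  list(tensor = tensor, truth = truth)
}

#' Generate a sparse scRNA-seq collection with group-specific programs
#'
#' Emulates a collection of scRNA-seq measurements divided into four groups
#' crossing two arms (e.g. disease status) with two strata (e.g. brain
#' region): per-gene baseline log-expression (`N(base_mean, base_sd)`) is
#' shared by all measurements, each measurement adds its own random effect
#' (`measurement_sd`, the biological variability between samples), and a
#' planted disease program of `planted` genes shifts log-expression by
#' `+/- effect` according to the measurement's arm. Both strata of an arm
#' share the program, so the planted structure spans exactly one direction
#' across measurements; the program is sign-balanced within baseline-matched
#' gene pairs, so both arms have identical marginal expression distributions
#' (the program changes which genes are up or down, not the overall
#' distribution). Measurements alternate arms, keeping the two arms
#' balanced. Counts are drawn per cell as Bernoulli-thinned Poisson on the
#' exponentiated program (thinning rate `keep_prob` controls sparsity).
#'
#' @param n_measurements Number of measurements (default 6), alternating
#'   over the four groups case/ctrl x strA/strB.
#' @param n_genes Gene count (default 1000).
#' @param cells Cells per measurement (recycled; default 500).
#' @param planted Program size, rounded down to even (default 200).
#' @param effect Arm shift of planted genes on the log-expression scale
#'   (default 1).
#' @param base_mean,base_sd Baseline log-expression distribution (defaults
#'   2 and 1).
#' @param measurement_sd Per-measurement random-effect SD on the log scale
#'   (default 0.1).
#' @param keep_prob Bernoulli thinning rate (default 0.5).
#' @param seed Integer seed.
#' @return List with `bundles` (list of [scrna_bundle()] with group labels)
#'   and `truth` (`planted_gene_ids`, `signs`, `groups`, `group_scores`,
#'   `seed`).
#' @export
generate_scrna_collection <- function(n_measurements = 6L, n_genes = 1000L,
                                      cells = 500L, planted = 200L,
                                      effect = 1, base_mean = 2, base_sd = 1,
                                      measurement_sd = 0.1, keep_prob = 0.5,
                                      seed = 1L) {
  groups <- 4L
  stopifnot(n_measurements >= groups, planted <= n_genes)
  set.seed(seed + 202L)
  cells <- rep_len(as.integer(cells), n_measurements)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  planted <- 2L * (as.integer(planted) %/% 2L)
  half <- planted %/% 2L
  pidx <- sort(sample.int(n_genes, planted))
  base <- stats::rnorm(n_genes, mean = base_mean, sd = base_sd)
  base[pidx[half + seq_len(half)]] <- base[pidx[seq_len(half)]]  # matched pairs
  signs <- c(rep(1, half), rep(-1, half))
  # alternate case/ctrl so the arms stay balanced for any collection size
  grp <- rep_len(c(1L, 3L, 2L, 4L), n_measurements)
  group_names <- c("case.strA", "case.strB", "ctrl.strA", "ctrl.strB")
  z <- c(1, 1, -1, -1)          # arm indicator: both strata share the program
  bundles <- vector("list", n_measurements)
  for (c in seq_len(n_measurements)) {
    logmu <- base + stats::rnorm(n_genes, 0, measurement_sd)
    logmu[pidx] <- logmu[pidx] + effect * z[grp[c]] * signs
    mu <- exp(logmu)
    counts <- matrix(stats::rpois(n_genes * cells[c], lambda = mu),
                     n_genes, cells[c])
    keep <- matrix(stats::rbinom(n_genes * cells[c], 1, keep_prob),
                   n_genes, cells[c])
    counts <- counts * keep
    bundles[[c]] <- scrna_bundle(
      Matrix::Matrix(counts, sparse = TRUE),
      gene_ids = gene_ids,
      cell_ids = sprintf("m%d_c%04d", c, seq_len(cells[c])),
      measurement_id = sprintf("meas%02d", c),
      group = group_names[grp[c]])
  }
  truth <- structure(list(planted_gene_ids = gene_ids[pidx], signs = signs,
                          groups = factor(group_names[grp]),
                          group_scores = z, seed = seed),
                     class = "synthetic_truth")
  list(bundles = bundles, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>",
      if (!is.null(x$planted_gene_ids))
        sprintf("%d planted genes;", length(x$planted_gene_ids)) else "",
      if (!is.null(x$effective_drug_ids))
        sprintf("%d effective drugs;", length(x$effective_drug_ids)) else "",
      sprintf("seed %d\n", x$seed))
  invisible(x)
}
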