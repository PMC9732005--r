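# Workflow driver behind the `tdfuse` command-line entry point. Each
# workflow is a thin wiring of the package functions with a validated
# config, deterministic seeding, TSV outputs and a JSON manifest.

default_config <- function() {
  list(
    inputs = NULL,            # list of study declarations: path, format,
                              # orientation, labels (path), modes (tensor)
    universe = list(mode = "reference", reference_study = NULL),
    rank = NULL,              # L
    mode_ranks = NULL,        # per-study tensor ranks
    omega = "auto",           # "auto", or integer vector
    omega_size = 5L,
    adj_p_gene = 0.01,
    adj_p_factor = 0.05,
    drug_T = 5L,
    seed = 1L,
    out = "tdfuse_out"
  )
}

load_config <- function(config) {
  base <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  utils::modifyList(base, config)
}

validate_config <- function(cfg, workflow) {
  if (!is.null(cfg$rank) && (!is.numeric(cfg$rank) || cfg$rank < 1))
    stop("invalid rank in config: must be a positive integer")
  if (!is.numeric(cfg$seed)) stop("invalid seed in config")
  for (nm in c("adj_p_gene", "adj_p_factor")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop("invalid ", nm, " in config: must lie in (0, 1]")
  }
  if (workflow %in% c("integrate", "select", "associate", "drug-rank", "baseline") &&
      is.null(cfg$inputs))
    stop("workflow '", workflow, "' requires config$inputs")
  invisible(cfg)
}

read_declared_study <- function(decl) {
  orientation <- decl$orientation
  if (is.null(orientation)) orientation <- "genes_in_rows"
  labels <- NULL
  if (!is.null(decl$labels)) {
    lt <- data.table::fread(decl$labels, header = TRUE, data.table = FALSE)
    labels <- stats::setNames(as.character(lt[[2]]), as.character(lt[[1]]))
  }
  x <- read_dense_matrix(decl$path, orientation = orientation)
  if (!is.null(labels)) x$labels <- factor(labels[x$sample_ids])
  if (!is.null(decl$modes)) {
    dims <- as.integer(decl$modes)
    if (prod(dims) != ncol(x$values))
      stop("declared tensor modes do not match the sample count of ", decl$path)
    arr <- array(x$values, dim = c(nrow(x$values), dims))
    dimnames(arr)[[1]] <- x$gene_ids
    x <- expression_tensor(arr)
  }
  x
}

write_manifest <- function(out_dir, cfg, workflow, files) {
  manifest <- list(
    workflow = workflow,
    package_version = as.character(utils::packageVersion("tdfuse")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg[setdiff(names(cfg), "inputs")],
    config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
    outputs = files,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run a tdfuse workflow
#'
#' Single entry point wiring the package stages into the supported
#' workflows. `"simulate"` writes synthetic fixtures; `"integrate"` runs
#' normalization, universe alignment, reduction, sign fixing, stacking and
#' the integrated HOSVD; `"select"` adds gene selection; `"associate"` adds
#' the per-study label screen; `"drug-rank"` projects a declared tensor
#' study and ranks its first-mode entries; `"baseline"` runs the
#' concatenation-SVD baseline. Outputs are plain TSV plus a JSON manifest
#' recording the config; runs are deterministic given (config, seed).
#'
#' @param config A config list or path to a YAML file; see the package
#'   vignette for keys. Unset keys take defaults.
#' @param workflow One of `"simulate"`, `"integrate"`, `"select"`,
#'   `"associate"`, `"drug-rank"`, `"baseline"`.
#' @return Invisibly, the output directory. Artifacts are written there.
#' @export
run_workflow <- function(config,
                         workflow = c("integrate", "select", "associate",
                                      "drug-rank", "simulate", "baseline")) {
  workflow <- match.arg(workflow)
  cfg <- load_config(config)
  validate_config(cfg, workflow)
  out_dir <- cfg$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  if (workflow == "simulate") {
    sim <- generate_unmatched_studies(seed = cfg$seed)
    for (k in seq_along(sim$studies)) {
      f <- file.path(out_dir, sprintf("study%d.tsv", k))
      write_dense_matrix(sim$studies[[k]], f)
      lf <- file.path(out_dir, sprintf("study%d_labels.tsv", k))
      data.table::fwrite(data.frame(sample_id = sim$studies[[k]]$sample_ids,
                                    class = sim$studies[[k]]$labels),
                         lf, sep = "\t")
      files <- c(files, f, lf)
    }
    f <- file.path(out_dir, "truth_planted_genes.tsv")
    data.table::fwrite(data.frame(gene_id = sim$truth$planted_gene_ids,
                                  sign = sim$truth$signs), f, sep = "\t")
    files <- c(files, f)
    write_manifest(out_dir, cfg, workflow, files)
    return(invisible(out_dir))
  }

  studies <- lapply(cfg$inputs, read_declared_study)

  if (workflow == "baseline") {
    studies <- lapply(studies, normalize_per_sample)
    al <- align_gene_universe(studies,
                              mode = cfg$universe$mode,
                              reference = cfg$universe$reference_study)
    res <- concat_svd(al$studies)
    sel <- concat_select(res, factor_indices = 1L,
                         threshold = cfg$adj_p_gene)
    f <- file.path(out_dir, "concat_genes.tsv")
    write_gene_table(sel, f)
    files <- c(files, f)
    write_manifest(out_dir, cfg, workflow, files)
    return(invisible(out_dir))
  }

  fit <- integrate_unmatched(studies, L = cfg$rank,
                             mode_ranks = cfg$mode_ranks,
                             universe = cfg$universe$mode,
                             reference = cfg$universe$reference_study)
  f <- file.path(out_dir, "gene_factors.tsv")
  gf <- data.frame(gene_id = fit$integration$gene_ids,
                   fit$integration$gene_factors, check.names = FALSE)
  data.table::fwrite(gf, f, sep = "\t")
  files <- c(files, f)

  if (workflow %in% c("select", "associate", "drug-rank")) {
    omega <- if (identical(cfg$omega, "auto")) NULL else as.integer(cfg$omega)
    sel <- extract_genes(fit, omega = omega, omega_size = cfg$omega_size,
                         threshold = cfg$adj_p_gene)
    f <- file.path(out_dir, "gene_table.tsv")
    write_gene_table(sel, f)
    files <- c(files, f)
  }
  if (workflow == "associate") {
    reports <- associate_samples(fit, threshold = cfg$adj_p_factor)
    for (nm in names(reports)) {
      f <- file.path(out_dir, paste0("association_", nm, ".tsv"))
      data.table::fwrite(as.data.frame(reports[[nm]]), f, sep = "\t")
      files <- c(files, f)
    }
  }
  if (workflow == "drug-rank") {
    is_tensor <- vapply(fit$aligned, inherits, logical(1), "expression_tensor")
    if (!any(is_tensor))
      stop("drug-rank requires one tensor study (drug x dose x replicate)")
    target <- fit$aligned[[which(is_tensor)[1]]]
    proj <- project_samples(fit$integration, target)
    res <- nested_hosvd_drug(proj, T = cfg$drug_T,
                             ell1 = seq_len(min(5L, dim(proj$coords)[1])))
    f <- file.path(out_dir, "drug_scores.tsv")
    data.table::fwrite(data.frame(drug_id = rownames(res$drug_scores),
                                  res$drug_scores, check.names = FALSE),
                       f, sep = "\t")
    files <- c(files, f)
  }
  write_manifest(out_dir, cfg, workflow, files)
  invisible(out_dir)
}
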