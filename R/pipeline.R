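# End-to-end orchestration: a validated run configuration, a staged
# pipeline writing all outputs plus a provenance manifest, and helpers the
# command-line wrapper dispatches to.

#' Build a validated run configuration
#'
#' @param mrna,mirna,meth paths to the omics TSV matrices (any may be NULL;
#'   at least one required).
#' @param mirna_map,probe_map paths to the miRNA-target and probe annotation
#'   tables (required when the matching layer is given).
#' @param gmt path to the gene-set GMT file.
#' @param labels,survival optional paths to the label and survival TSVs.
#' @param out_dir output directory.
#' @param rank CP rank.
#' @param seed RNG seed.
#' @param cdf_threshold assignment cutoff (default 0.6).
#' @param share_frac OCR sharing fraction (default 0.5).
#' @param survival_frac stratum fraction (default 0.2).
#' @param min_overlap minimum pathway overlap (default 2).
#' @param normalization layer normalization method.
#' @param window_bp promoter window (default 2000).
#' @param max_iter,tol solver settings.
#' @param sample_id_trim optional integer: keep only the first N characters
#'   of every sample id across all inputs before matching (a hook for
#'   barcode-style ids whose suffixes differ between platforms). Off
#'   (NULL) by default; sample matching is otherwise exact-string.
#' @return a named list of class `mopa_config`.
#' @export
run_config <- function(mrna = NULL, mirna = NULL, meth = NULL,
                       mirna_map = NULL, probe_map = NULL,
                       gmt, labels = NULL, survival = NULL,
                       out_dir = "mopa_run", rank = 10L, seed = 1L,
                       cdf_threshold = 0.6, share_frac = 0.5,
                       survival_frac = 0.2, min_overlap = 2L,
                       normalization = "minmax_per_gene",
                       window_bp = 2000L, max_iter = 500L, tol = 1e-7,
                       sample_id_trim = NULL) {
  cfg <- list(mrna = mrna, mirna = mirna, meth = meth,
              mirna_map = mirna_map, probe_map = probe_map, gmt = gmt,
              labels = labels, survival = survival, out_dir = out_dir,
              rank = as.integer(rank), seed = as.integer(seed),
              cdf_threshold = cdf_threshold, share_frac = share_frac,
              survival_frac = survival_frac,
              min_overlap = as.integer(min_overlap),
              normalization = normalization,
              window_bp = as.integer(window_bp),
              max_iter = as.integer(max_iter), tol = tol,
              sample_id_trim = if (is.null(sample_id_trim)) NULL else
                as.integer(sample_id_trim))
  if (is.null(mrna) && is.null(mirna) && is.null(meth))
    stopf("at least one omics layer path is required")
  if (!is.null(mirna) && is.null(mirna_map))
    stopf("a miRNA layer requires a mirna_map")
  if (!is.null(meth) && is.null(probe_map))
    stopf("a methylation layer requires a probe_map")
  if (cfg$cdf_threshold <= 0 || cfg$cdf_threshold >= 1)
    stopf("cdf_threshold must be in (0, 1)")
  if (cfg$share_frac <= 0 || cfg$share_frac > 1)
    stopf("share_frac must be in (0, 1]")
  if (cfg$survival_frac <= 0 || cfg$survival_frac > 0.5)
    stopf("survival_frac must be in (0, 0.5]")
  class(cfg) <- "mopa_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Explicit arguments in `...` override values from the file.
#'
#' @param path YAML file path.
#' @param ... overrides for individual config keys.
#' @return a `mopa_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#'
#' @param config a `mopa_config`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline from files to outputs
#'
#' Executes the three stages end to end: gene-level transformation and
#' tensor assembly, decomposition + assignment + scoring, and downstream
#' analyses (OCR when labels exist, survival stratification when a survival
#' table exists, gene ranking, pathway network export). All outputs are
#' written under `config$out_dir` together with a provenance manifest
#' (config, config hash, seed, package version). When `resume = TRUE` and
#' the directory already holds a manifest with the same config hash, the
#' run is skipped: the decomposition is the expensive stage and parameter
#' scans should not repeat it.
#'
#' @param config a `mopa_config`.
#' @param resume skip the run when cached outputs match the config hash
#'   (default FALSE).
#' @return invisibly, a list with the `mopa` fit (NULL when resumed from
#'   cache) and the output directory.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "mopa_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  if (resume && file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path)
    if (identical(prev$config_hash, hash))
      return(invisible(list(fit = NULL, out_dir = config$out_dir)))
  }

  trim <- function(ids) {
    if (is.null(config$sample_id_trim)) return(ids)
    out <- substr(ids, 1L, config$sample_id_trim)
    if (anyDuplicated(out))
      stopf("sample_id_trim=%d collapses distinct sample ids", config$sample_id_trim)
    out
  }
  trim_annotations <- function(ann) {
    if (!is.null(ann$labels)) names(ann$labels) <- trim(names(ann$labels))
    if (!is.null(ann$survival)) rownames(ann$survival) <- trim(rownames(ann$survival))
    ann
  }

  stage <- "input"
  fit <- tryCatch({
    gene_sets <- read_gmt(config$gmt)
    universe <- unique(unlist(gene_sets$pathways, use.names = FALSE))
    layers <- list()
    if (!is.null(config$mrna)) {
      m <- read_omics_matrix(config$mrna, "mrna")
      colnames(m$values) <- trim(colnames(m$values))
      keep <- intersect(rownames(m$values), universe)
      if (length(keep) == 0L) stopf("no mRNA gene matches the gene sets")
      m$values <- m$values[keep, , drop = FALSE]
      layers$mrna <- m
    }
    if (!is.null(config$mirna)) {
      stage <- "genelevel"
      mir <- read_omics_matrix(config$mirna, "mirna")
      colnames(mir$values) <- trim(colnames(mir$values))
      map <- read_feature_map(config$mirna_map, "mirna_target")
      gu <- if (length(layers)) rownames(layers[[1]]$values) else universe
      layers$mirna <- mirna_to_gene(mir, map, gu)
    }
    if (!is.null(config$meth)) {
      stage <- "genelevel"
      me <- read_omics_matrix(config$meth, "methylation")
      colnames(me$values) <- trim(colnames(me$values))
      pm <- read_feature_map(config$probe_map, "probe_promoter")
      gu <- if (length(layers)) rownames(layers[[1]]$values) else universe
      layers$meth <- methylation_to_gene(me, pm, gu, config$window_bp)
    }
    ann <- trim_annotations(read_sample_annotations(config$labels, config$survival))
    stage <- "fit"
    mopa(layers, gene_sets, rank = config$rank, labels =
           if (is.null(ann$labels)) NULL else ann,
         threshold = config$cdf_threshold, share_frac = config$share_frac,
         min_overlap = config$min_overlap, seed = config$seed,
         max_iter = config$max_iter, tol = config$tol,
         normalization = config$normalization)
  }, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))

  out <- config$out_dir
  write_matrix(fit$es$mes, file.path(out, "mes.tsv"), id_col = "sample")
  utils::write.table(fit$es$skipped, file.path(out, "skipped_pathways.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  assign_tab <- data.frame(
    sample = names(fit$assignment$assigned),
    features = vapply(fit$assignment$assigned, paste, character(1),
                      collapse = ","))
  utils::write.table(assign_tab, file.path(out, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(fit$decomposition$S, file.path(out, "loadings_samples.tsv"),
               id_col = "sample")
  write_matrix(fit$decomposition$G, file.path(out, "loadings_genes.tsv"),
               id_col = "gene")
  write_matrix(fit$decomposition$O, file.path(out, "loadings_omics.tsv"),
               id_col = "omics")

  if (!is.null(fit$ocr))
    utils::write.table(ocr_long(fit$ocr), file.path(out, "ocr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ann <- trim_annotations(read_sample_annotations(config$labels, config$survival))
  surv_p <- NULL
  if (!is.null(ann$survival)) {
    stage <- "survival"
    surv_p <- vapply(colnames(fit$es$mes), function(pw) {
      st <- stratify_by_es(fit$es, pw, frac = config$survival_frac)
      suppressWarnings(logrank_test(st, ann)$p)
    }, numeric(1))
    utils::write.table(
      data.frame(pathway = names(surv_p), logrank_p = surv_p),
      file.path(out, "survival.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (!is.null(ann$labels)) {
    stage <- "rank-genes"
    ga <- gene_association(fit$weights, ann)
    utils::write.table(ga, file.path(out, "gene_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fit$ocr)) {
    stage <- "network"
    for (g in dimnames(fit$ocr$ocr)[[1]]) {
      net <- build_pathway_network(
        read_gmt(config$gmt), fit$ocr, surv_p, group = g,
        min_shared = 1L, universe = fit$weights$genes)
      write_sif(net, file.path(out, sprintf("network_%s.sif", g)))
      write_graphml(net, file.path(out, sprintf("network_%s.graphml", g)))
    }
  }

  manifest <- list(config = unclass(config), config_hash = hash,
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("mopa")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fit = fit, out_dir = out))
}
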