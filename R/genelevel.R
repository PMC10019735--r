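# Gene-level transformation: collapse miRNA and methylation layers to genes,
# normalize each layer, and stack the layers into a sample x gene x omics
# tensor.

#' Collapse a miRNA expression matrix to gene level
#'
#' Each gene receives the arithmetic mean expression of the miRNAs that
#' target it (per sample); genes with no targeting miRNA present in the
#' matrix receive 0.
#'
#' @param mirna an `omics_matrix` of miRNA expression (miRNAs x samples).
#' @param map a `feature_gene_map` of kind `"mirna_target"`.
#' @param gene_universe character vector of output gene ids.
#' @return an `omics_matrix` (kind `"mirna"`) with rows = `gene_universe`.
#' @export
mirna_to_gene <- function(mirna, map, gene_universe) {
  stopifnot(inherits(mirna, "omics_matrix"), inherits(map, "feature_gene_map"))
  if (map$kind != "mirna_target") stopf("map kind must be 'mirna_target'")
  gene_universe <- unique(as.character(gene_universe))
  present <- intersect(names(map$entries), rownames(mirna$values))
  if (length(present) == 0L)
    stopf("no miRNA in the target map is present in the expression matrix")
  # gene -> miRNAs (restricted to miRNAs present in the matrix)
  pairs <- data.frame(
    mir = rep(present, lengths(map$entries[present])),
    gene = unlist(map$entries[present], use.names = FALSE),
    stringsAsFactors = FALSE)
  pairs <- pairs[pairs$gene %in% gene_universe, , drop = FALSE]
  out <- matrix(0, length(gene_universe), ncol(mirna$values),
                dimnames = list(gene_universe, colnames(mirna$values)))
  if (nrow(pairs) > 0L) {
    by_gene <- split(pairs$mir, pairs$gene)
    for (g in names(by_gene)) {
      out[g, ] <- colMeans(mirna$values[by_gene[[g]], , drop = FALSE])
    }
  }
  omics_matrix(out, "mirna")
}

#' Collapse a methylation probe matrix to gene level
#'
#' Each gene receives the mean beta value of probes lying in the promoter
#' window upstream of its transcription start site: `[TSS - window_bp, TSS)`
#' on the + strand and `(TSS, TSS + window_bp]` on the - strand (outer edge
#' inclusive, TSS exclusive). Genes without any in-window probe receive 0.
#' Probes whose chromosome conflicts with their gene's (first-seen)
#' chromosome are skipped with a warning.
#'
#' @param meth an `omics_matrix` of beta values (probes x samples).
#' @param probes a `feature_gene_map` of kind `"probe_promoter"`.
#' @param gene_universe character vector of output gene ids.
#' @param window_bp promoter window size in base pairs (default 2000).
#' @return an `omics_matrix` (kind `"methylation"`) with rows = `gene_universe`.
#' @export
methylation_to_gene <- function(meth, probes, gene_universe, window_bp = 2000L) {
  stopifnot(inherits(meth, "omics_matrix"), inherits(probes, "feature_gene_map"))
  if (probes$kind != "probe_promoter") stopf("map kind must be 'probe_promoter'")
  if (window_bp <= 0) stopf("window_bp must be positive")
  gene_universe <- unique(as.character(gene_universe))
  ann <- probes$entries
  ann <- ann[ann$probe %in% rownames(meth$values) & ann$gene %in% gene_universe, ,
             drop = FALSE]
  # chromosome consistency per gene: first row seen defines the reference
  if (nrow(ann) > 0L) {
    ref <- tapply(ann$chrom, ann$gene, function(ch) ch[1])
    bad <- ann$chrom != ref[ann$gene]
    if (any(bad)) {
      warnf("skipping %d probe(s) on a chromosome conflicting with their gene",
            sum(bad))
      ann <- ann[!bad, , drop = FALSE]
    }
  }
  # strand-aware upstream window, TSS exclusive, outer edge inclusive
  dist <- ifelse(ann$strand == "+", ann$tss - ann$pos, ann$pos - ann$tss)
  ann <- ann[dist >= 1L & dist <= window_bp, , drop = FALSE]
  out <- matrix(0, length(gene_universe), ncol(meth$values),
                dimnames = list(gene_universe, colnames(meth$values)))
  if (nrow(ann) > 0L) {
    by_gene <- split(ann$probe, ann$gene)
    for (g in names(by_gene)) {
      out[g, ] <- colMeans(meth$values[by_gene[[g]], , drop = FALSE])
    }
  }
  omics_matrix(out, "methylation")
}

#' Normalize one omics layer
#'
#' `minmax_per_gene` rescales each gene row to \[0, 1\] (constant rows map
#' to 0); `minmax_global` rescales the whole matrix by its global min/max;
#' `none` passes values through unchanged.
#'
#' @param matrix an `omics_matrix`.
#' @param method normalization method.
#' @return an `omics_matrix` of the same kind and shape.
#' @export
normalize_layer <- function(matrix,
                            method = c("minmax_per_gene", "minmax_global", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "omics_matrix"))
  v <- matrix$values
  if (method == "minmax_per_gene") {
    rmin <- apply(v, 1, min)
    rmax <- apply(v, 1, max)
    rng <- rmax - rmin
    v <- (v - rmin) / ifelse(rng > 0, rng, 1)
    v[rng == 0, ] <- 0
  } else if (method == "minmax_global") {
    lo <- min(v); hi <- max(v)
    v <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
  }
  out <- matrix
  out$values <- v
  out
}

#' Assemble gene-level omics layers into a tensor
#'
#' Genes and samples are intersected across layers (in the order of the
#' first layer) and the layers stacked into a nonnegative sample x gene x
#' omics array.
#'
#' @param layers list of gene-level `omics_matrix` objects (>= 1).
#' @return an object of class `mopa_tensor`: a 3-way array with dimnames
#'   (samples, genes, omics kinds).
#' @export
assemble_tensor <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "omics_matrix")))
  genes <- rownames(layers[[1]]$values)
  samples <- colnames(layers[[1]]$values)
  for (l in layers[-1]) {
    genes <- genes[genes %in% rownames(l$values)]
    samples <- samples[samples %in% colnames(l$values)]
  }
  if (length(genes) == 0L) stopf("empty gene intersection across layers")
  if (length(samples) == 0L) stopf("empty sample intersection across layers")
  kinds <- vapply(layers, `[[`, character(1), "kind")
  if (anyDuplicated(kinds))
    kinds <- make.unique(kinds, sep = "_")
  arr <- array(0, dim = c(length(samples), length(genes), length(layers)),
               dimnames = list(samples, genes, kinds))
  for (k in seq_along(layers)) {
    v <- layers[[k]]$values[genes, samples, drop = FALSE]
    if (any(v < 0))
      stopf("negative entries in layer '%s'; tensor must be nonnegative", kinds[k])
    arr[, , k] <- t(v)
  }
  mopa_tensor(arr)
}

#' Construct a gene-level tensor
#'
#' @param values nonnegative 3-way array, samples x genes x omics, with
#'   dimnames on all three axes.
#' @return an object of class `mopa_tensor`.
#' @export
mopa_tensor <- function(values) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  dn <- dimnames(values)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    stopf("tensor needs dimnames on all three axes (samples, genes, omics)")
  if (any(!is.finite(values))) stopf("tensor entries must be finite")
  if (any(values < 0)) stopf("tensor entries must be nonnegative")
  structure(values, class = c("mopa_tensor", "array"))
}

#' @export
print.mopa_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<mopa_tensor> %d samples x %d genes x %d omics (%s)\n",
              d[1], d[2], d[3], paste(dimnames(x)[[3]], collapse = ", ")))
  invisible(x)
}
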