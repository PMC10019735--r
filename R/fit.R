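# The top-level model fit: tensor -> CP decomposition -> component
# assignment -> rank weights -> mES (and OCR when labels are available),
# wrapped in one classed object with the usual modelling methods.

#' Fit the multi-omics pathway activity model
#'
#' Runs the full scoring pipeline on a gene-level tensor: non-negative CP
#' decomposition at the requested rank, optional label-aware component
#' selection, per-sample component assignment by KDE-CDF threshold,
#' computation of gene rank weights, and the per-sample per-pathway
#' enrichment score (mES). When group labels are supplied, the per-group
#' omics contribution rate (OCR) is also computed.
#'
#' @param tensor a `mopa_tensor`, or a list of gene-level `omics_matrix`
#'   objects (assembled and min-max normalized per gene unless already a
#'   tensor).
#' @param gene_sets a `gene_set_collection`.
#' @param rank CP rank R.
#' @param labels optional `sample_annotations` (or named vector) of group
#'   labels; enables supervised component selection and OCR.
#' @param supervised if TRUE (default when labels are given), run the
#'   label-aware component selector before assignment.
#' @param threshold CDF assignment cutoff, default 0.6.
#' @param share_frac group sharing fraction for OCR, default 0.5.
#' @param min_overlap minimum pathway genes in the universe, default 2.
#' @param seed,max_iter,tol passed to [decompose()].
#' @param normalization layer normalization when `tensor` is a list of
#'   layers; see [normalize_layer()].
#' @return an object of class `mopa` with elements `decomposition`
#'   (`mopa_decomp`), `assignment` (`mopa_assignment`), `G_prime`,
#'   `weights` (`mopa_rank_weights`), `es` (`mopa_es`), `ocr` (`mopa_ocr`
#'   or NULL), `labels`, `call`.
#' @examples
#' sim <- generate_tensor(n_groups = 2, samples_per_group = 10, n_genes = 120,
#'                        features_per_group = 2, background_features = 2,
#'                        noise_sigma = 0.05, seed = 7)
#' gs <- generate_gene_sets(sim$truth, n_planted = 3, n_null = 2,
#'                          set_size = 10, seed = 7)
#' fit <- mopa(sim$tensor, gs, rank = 6, labels = sim$truth$labels, seed = 7)
#' summary(fit)
#' @export
mopa <- function(tensor, gene_sets, rank,
                 labels = NULL, supervised = !is.null(labels),
                 threshold = 0.6, share_frac = 0.5, min_overlap = 2L,
                 seed = 1L, max_iter = 500L, tol = 1e-7,
                 normalization = "minmax_per_gene") {
  cl <- match.call()
  if (!inherits(tensor, "mopa_tensor")) {
    if (!is.list(tensor)) stopf("tensor must be a mopa_tensor or a list of omics_matrix layers")
    layers <- lapply(tensor, normalize_layer, method = normalization)
    tensor <- assemble_tensor(layers)
  }
  dec <- decompose(tensor, rank = rank, seed = seed,
                   max_iter = max_iter, tol = tol)
  if (supervised) {
    if (is.null(labels)) stopf("supervised selection requires labels")
    dec <- select_features_supervised(dec, labels)
    if (length(dec$selected_features) < 2L) {
      warnf("fewer than 2 components selected; reverting to all components")
      dec$selected_features <- seq_len(dec$rank)
    }
  }
  assignment <- assign_features(dec, threshold = threshold)
  G_prime <- suppressWarnings(
    normalize_gene_loadings(dec$G, dec$selected_features))
  rownames(G_prime) <- rownames(dec$G)
  weights <- rank_weights(G_prime, assignment)
  es <- score_all(weights, gene_sets, min_overlap = min_overlap)
  ocr <- NULL
  if (!is.null(labels)) {
    ocr <- tryCatch(
      ocr_table(dec, assignment, labels, gene_sets,
                share_frac = share_frac, min_overlap = min_overlap),
      error = function(e) {
        warnf("OCR not computed: %s", conditionMessage(e))
        NULL
      })
  }
  structure(list(decomposition = dec, assignment = assignment,
                 G_prime = G_prime, weights = weights, es = es, ocr = ocr,
                 labels = if (inherits(labels, "sample_annotations"))
                   labels$labels else labels,
                 tensor_dim = dim(tensor), call = cl),
            class = "mopa")
}

#' Extract the mES matrix from a fit
#'
#' @param fit a `mopa` object.
#' @return samples x pathways numeric matrix.
#' @export
mes <- function(fit) {
  stopifnot(inherits(fit, "mopa"))
  fit$es$mes
}

#' @export
print.mopa <- function(x, ...) {
  d <- x$tensor_dim
  cat(sprintf("Multi-omics pathway activity fit (rank %d)\n",
              x$decomposition$rank))
  cat(sprintf("  tensor: %d samples x %d genes x %d omics\n", d[1], d[2], d[3]))
  cat(sprintf("  mES: %d samples x %d pathways (%d skipped)\n",
              nrow(x$es$mes), ncol(x$es$mes), nrow(x$es$skipped)))
  if (!is.null(x$ocr)) cat("  OCR: computed for",
                           dim(x$ocr$ocr)[1], "groups\n")
  invisible(x)
}

#' @export
summary.mopa <- function(object, ...) {
  x <- object
  sz <- lengths(x$assignment$assigned)
  out <- list(
    rank = x$decomposition$rank,
    residual = x$decomposition$residual,
    selected = x$decomposition$selected_features,
    mean_assigned = mean(sz),
    n_pathways = ncol(x$es$mes),
    n_skipped = nrow(x$es$skipped),
    mes_range = range(x$es$mes, na.rm = TRUE),
    has_ocr = !is.null(x$ocr))
  class(out) <- "summary.mopa"
  out
}

#' @export
print.summary.mopa <- function(x, ...) {
  cat(sprintf("Rank %d decomposition, relative residual %.4f\n",
              x$rank, x$residual))
  cat(sprintf("Selected components: %s\n", paste(x$selected, collapse = ", ")))
  cat(sprintf("Mean assigned components per sample: %.2f\n", x$mean_assigned))
  cat(sprintf("mES over %d pathways, range [%.3f, %.3f]; %d pathway(s) skipped\n",
              x$n_pathways, x$mes_range[1], x$mes_range[2], x$n_skipped))
  if (x$has_ocr) cat("OCR table available ($ocr)\n")
  invisible(x)
}

#' Loading matrices of a fit
#'
#' @param object a `mopa` object.
#' @param which `"samples"`, `"genes"` or `"omics"`.
#' @param ... unused.
#' @return the requested loading matrix.
#' @export
coef.mopa <- function(object, which = c("samples", "genes", "omics"), ...) {
  which <- match.arg(which)
  switch(which, samples = object$decomposition$S,
         genes = object$decomposition$G, omics = object$decomposition$O)
}

#' Reconstructed tensor from the CP factors
#'
#' @param object a `mopa` object.
#' @param ... unused.
#' @return a 3-way array of the same shape as the input tensor.
#' @export
fitted.mopa <- function(object, ...) {
  d <- object$decomposition
  arr <- array(0, dim = c(nrow(d$S), nrow(d$G), nrow(d$O)),
               dimnames = list(rownames(d$S), rownames(d$G), rownames(d$O)))
  for (f in seq_len(d$rank))
    arr <- arr + outer(outer(d$S[, f], d$G[, f]), d$O[, f])
  arr
}

#' Relative reconstruction residual of a fit
#'
#' @param object a `mopa` object.
#' @param ... unused.
#' @return the relative Frobenius residual of the decomposition.
#' @export
residuals.mopa <- function(object, ...) object$decomposition$residual

#' Plot method: mES distributions per pathway
#'
#' Boxplots of the per-sample scores for each pathway, the fit's primary
#' output.
#'
#' @param x a `mopa` object.
#' @param max_pathways cap on the number of pathways shown.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.mopa <- function(x, max_pathways = 20L, ...) {
  m <- x$es$mes
  keep <- seq_len(min(ncol(m), max_pathways))
  graphics::boxplot(as.data.frame(m[, keep, drop = FALSE]),
                    las = 2, ylab = "mES", ...)
  invisible(x)
}
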