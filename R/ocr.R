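# Omics Contribution Rate: per sample group and pathway, how the mES-driving
# latent components apportion activity across the omics layers.

#' Components shared within each sample group
#'
#' A component belongs to a group's shared set when it is assigned to at
#' least `share_frac` of the group's samples (boundary inclusive).
#'
#' @param assignment a `mopa_assignment`.
#' @param labels a `sample_annotations` with group labels, or a named
#'   character vector.
#' @param share_frac sharing fraction in (0, 1\]; default 0.5.
#' @return named list: group -> integer vector of shared component indices.
#' @export
group_shared_features <- function(assignment, labels, share_frac = 0.5) {
  stopifnot(inherits(assignment, "mopa_assignment"))
  grp <- if (inherits(labels, "sample_annotations")) labels$labels else labels
  if (is.null(grp)) stopf("group labels are required")
  if (share_frac <= 0 || share_frac > 1) stopf("share_frac must be in (0, 1]")
  samples <- names(assignment$assigned)
  if (!all(samples %in% names(grp)))
    stopf("labels must cover every assigned sample")
  grp <- grp[samples]
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) == 0L) stopf("group '%s' has zero samples", g)
    counts <- table(unlist(assignment$assigned[idx]))
    shared <- as.integer(names(counts)[counts >= share_frac * length(idx)])
    if (length(shared) == 0L)
      stopf("group '%s' has no shared component at share_frac=%.2f; consider lowering share_frac",
            g, share_frac)
    out[[g]] <- sort(shared)
  }
  out
}

#' Strongest associated component per pathway gene
#'
#' For every member gene, the shared component with the largest normalized
#' gene loading; ties go to the lowest component index.
#'
#' @param G_prime normalized gene loadings (genes x selected components,
#'   column names = component indices).
#' @param shared integer vector of a group's shared component indices.
#' @param genes character vector of pathway member genes.
#' @return named integer vector: gene -> component index. Genes absent from
#'   the loading matrix are skipped with a warning.
#' @export
gene_argmax_feature <- function(G_prime, shared, genes) {
  if (length(shared) == 0L) stopf("shared component set is empty")
  cols <- match(as.character(shared), colnames(G_prime))
  if (any(is.na(cols))) stopf("shared components missing from G'")
  missing <- setdiff(genes, rownames(G_prime))
  if (length(missing) > 0L) {
    warnf("%d pathway gene(s) absent from the gene universe; skipped", length(missing))
    genes <- setdiff(genes, missing)
  }
  if (length(genes) == 0L) stopf("no pathway gene present in the universe")
  sub <- G_prime[genes, cols, drop = FALSE]
  # which.max returns the first maximum; columns are in ascending shared
  # order, so ties resolve to the lowest component index
  idx <- apply(sub, 1, which.max)
  setNames(shared[idx], genes)
}

#' Omics contribution vector for one pathway
#'
#' Sums, over the pathway's genes, the omics loading column of each gene's
#' strongest component, then normalizes to fractions.
#'
#' @param O omics loading matrix (L x components).
#' @param argmax_map named integer vector from [gene_argmax_feature()].
#' @return numeric vector of length L summing to 1 (named by omics kind).
#' @export
compute_ocr <- function(O, argmax_map) {
  if (length(argmax_map) == 0L) stopf("empty argmax map")
  C <- rowSums(O[, argmax_map, drop = FALSE])
  tot <- sum(C)
  if (tot <= 0)
    stopf("undefined OCR: total omics contribution is zero for this pathway")
  C / tot
}

#' Full group x pathway x omics contribution table
#'
#' @param decomp a `mopa_decomp`.
#' @param assignment a `mopa_assignment`.
#' @param labels group labels (see [group_shared_features()]).
#' @param gene_sets a `gene_set_collection` (intersected internally with the
#'   gene universe).
#' @param share_frac sharing fraction, default 0.5.
#' @param min_overlap minimum member genes in the universe (default 2).
#' @return an object of class `mopa_ocr`: list with `ocr` (3-way array
#'   group x pathway x omics; NA where undefined), `shared_features` (named
#'   list), `undefined` (data frame group/pathway/reason).
#' @export
ocr_table <- function(decomp, assignment, labels, gene_sets,
                      share_frac = 0.5, min_overlap = 2L) {
  stopifnot(inherits(decomp, "mopa_decomp"),
            inherits(gene_sets, "gene_set_collection"))
  G_prime <- suppressWarnings(
    normalize_gene_loadings(decomp$G, decomp$selected_features))
  rownames(G_prime) <- rownames(decomp$G)
  shared <- group_shared_features(assignment, labels, share_frac)
  universe <- rownames(decomp$G)
  members <- lapply(gene_sets$pathways, function(p) intersect(p, universe))
  members <- members[lengths(members) >= min_overlap &
                       lengths(members) < length(universe)]
  if (length(members) == 0L) stopf("no pathway with sufficient gene overlap")
  groups <- names(shared)
  omics <- rownames(decomp$O)
  ocr <- array(NA_real_, dim = c(length(groups), length(members), length(omics)),
               dimnames = list(groups, names(members), omics))
  undef <- data.frame(group = character(0), pathway = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  for (g in groups) {
    for (t in names(members)) {
      amap <- suppressWarnings(
        tryCatch(gene_argmax_feature(G_prime, shared[[g]], members[[t]]),
                 error = function(e) NULL))
      v <- if (is.null(amap)) NULL else
        tryCatch(compute_ocr(decomp$O, amap), error = function(e) NULL)
      if (is.null(v)) {
        undef <- rbind(undef, data.frame(group = g, pathway = t,
                                         reason = "zero or undefined contribution"))
      } else ocr[g, t, ] <- v
    }
  }
  structure(list(ocr = ocr, shared_features = shared, undefined = undef),
            class = "mopa_ocr")
}

#' @export
print.mopa_ocr <- function(x, ...) {
  d <- dim(x$ocr)
  cat(sprintf("<mopa_ocr> %d groups x %d pathways x %d omics (%d undefined cells)\n",
              d[1], d[2], d[3], nrow(x$undefined)))
  invisible(x)
}

#' Long-format OCR export
#'
#' @param ocr a `mopa_ocr`.
#' @return data frame with columns group, pathway, omics, fraction.
#' @export
ocr_long <- function(ocr) {
  stopifnot(inherits(ocr, "mopa_ocr"))
  d <- dimnames(ocr$ocr)
  out <- expand.grid(group = d[[1]], pathway = d[[2]], omics = d[[3]],
                     stringsAsFactors = FALSE)
  out$fraction <- as.vector(ocr$ocr)
  out[!is.na(out$fraction), , drop = FALSE]
}
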