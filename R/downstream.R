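# Downstream analyses on the mES matrix: survival stratification, K-means
# clustering with ARI, per-gene ANOVA ranking, and pathway-network export.

#' Stratify samples by pathway score
#'
#' Samples are sorted by their mES for one pathway (ties broken by
#' ascending sample id); the top and bottom `floor(frac * n)` samples form
#' the high and low strata.
#'
#' @param es a `mopa_es` (or a samples x pathways matrix).
#' @param pathway pathway id (column).
#' @param frac fraction per stratum in (0, 0.5\]; default 0.2.
#' @return an object of class `mopa_strat`: list with `pathway`, `high`,
#'   `low` (sample id vectors) and `frac`.
#' @export
stratify_by_es <- function(es, pathway, frac = 0.2) {
  mes <- if (inherits(es, "mopa_es")) es$mes else as.matrix(es)
  if (!pathway %in% colnames(mes)) stopf("pathway '%s' not in the score matrix", pathway)
  if (frac <= 0 || frac > 0.5) stopf("frac must be in (0, 0.5]")
  x <- mes[, pathway]
  x <- x[!is.na(x)]
  n <- length(x)
  k <- floor(frac * n)
  if (k < 1L) stopf("frac too small: stratum would be empty (n=%d)", n)
  ids <- names(x)
  if (length(unique(x)) == 1L)
    warnf("all scores equal for pathway '%s'; split is tie-broken by sample id", pathway)
  ord_desc <- order(-x, ids)
  ord_asc <- order(x, ids)
  structure(list(pathway = pathway,
                 high = ids[ord_desc[seq_len(k)]],
                 low = ids[ord_asc[seq_len(k)]],
                 frac = frac),
            class = "mopa_strat")
}

#' Log-rank test between high and low score strata
#'
#' Two-sample log-rank (chi-square, 1 df) comparing survival between the
#' high- and low-score strata. If either stratum has zero events the test
#' is degenerate and p = 1 is returned with a warning.
#'
#' @param strat a `mopa_strat`.
#' @param survival a `sample_annotations` carrying a survival table, or the
#'   table itself (rownames = sample ids, columns time/event).
#' @return list with `p` (p-value), `chisq`, and `data` (the stratified
#'   survival data frame with a `stratum` column) for Kaplan-Meier export.
#' @export
logrank_test <- function(strat, survival) {
  stopifnot(inherits(strat, "mopa_strat"))
  surv <- if (inherits(survival, "sample_annotations")) survival$survival else survival
  if (is.null(surv)) stopf("no survival table supplied")
  ids <- c(strat$high, strat$low)
  if (!all(ids %in% rownames(surv)))
    stopf("survival table missing %d stratified sample(s)",
          sum(!ids %in% rownames(surv)))
  df <- surv[ids, , drop = FALSE]
  df$stratum <- rep(c("high", "low"), c(length(strat$high), length(strat$low)))
  ev <- tapply(df$event, df$stratum, sum)
  if (any(ev == 0)) {
    warnf("a stratum has zero events; log-rank is degenerate, returning p = 1")
    return(list(p = 1, chisq = 0, data = df))
  }
  sd <- tryCatch(survival::survdiff(survival::Surv(time, event) ~ stratum, data = df),
                 error = function(e) NULL)
  if (is.null(sd) || !is.finite(sd$chisq))
    return(list(p = 1, chisq = 0, data = df))
  list(p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       chisq = sd$chisq, data = df)
}

#' K-means clustering of samples on the score matrix
#'
#' @param es a `mopa_es` or samples x pathways matrix.
#' @param k number of clusters (2..n samples).
#' @param seed RNG seed (clustering is deterministic given the seed).
#' @param n_init number of random restarts; the best inertia wins.
#' @return named integer vector: sample id -> cluster label.
#' @export
cluster_samples <- function(es, k, seed = 1L, n_init = 10L) {
  mes <- if (inherits(es, "mopa_es")) es$mes else as.matrix(es)
  mes[is.na(mes)] <- 0
  if (k < 2L || k > nrow(mes)) stopf("k must be in 2..n_samples")
  # Hartigan-Wong needs k < n; fall back to Lloyd for the singleton limit
  alg <- if (k == nrow(mes)) "Lloyd" else "Hartigan-Wong"
  km <- with_seed(seed, stats::kmeans(mes, centers = k, nstart = n_init,
                                      iter.max = 100L, algorithm = alg))
  setNames(as.integer(km$cluster), rownames(mes))
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement: 1 for identical partitions (up to label
#' permutation), about 0 for independent ones.
#'
#' @param labels_a,labels_b partitions of the same samples; if named, they
#'   are aligned by name.
#' @return a single number (<= 1).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stopf("partitions cover different sample sets")
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stopf("partitions have different lengths")
  }
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

#' Rank genes by group association of their rank weights
#'
#' One-way fixed-effects ANOVA of each gene's rank weight across the sample
#' groups, Bonferroni-adjusted over the genes tested. Zero-variance genes
#' are kept with p = 1 and flagged, so the Bonferroni multiplier is stable.
#'
#' @param weights a `mopa_rank_weights`.
#' @param labels group labels (a `sample_annotations` or named vector);
#'   >= 2 groups with >= 2 samples each.
#' @param genes optional character vector restricting the test to a pathway's
#'   genes.
#' @return data frame (gene, p, p_adj, zero_variance, one column of group
#'   means per group), sorted by ascending `p_adj`.
#' @export
gene_association <- function(weights, labels, genes = NULL) {
  stopifnot(inherits(weights, "mopa_rank_weights"))
  grp <- if (inherits(labels, "sample_annotations")) labels$labels else labels
  if (is.null(grp)) stopf("group labels are required")
  samples <- rownames(weights$r)
  if (!all(samples %in% names(grp))) stopf("labels must cover all samples")
  grp <- factor(grp[samples])
  if (nlevels(grp) < 2L) stopf("need >= 2 groups")
  if (any(table(grp) < 2L)) stopf("every group needs >= 2 samples")
  test_genes <- if (is.null(genes)) weights$genes else intersect(genes, weights$genes)
  if (length(test_genes) == 0L) stopf("no gene to test")
  m <- length(test_genes)
  res <- lapply(test_genes, function(g) {
    x <- weights$r[, g]
    mu <- tapply(x, grp, mean)
    if (stats::sd(x) == 0) {
      list(p = 1, zv = TRUE, mu = mu)
    } else {
      p <- tryCatch(stats::oneway.test(x ~ grp, var.equal = TRUE)$p.value,
                    error = function(e) NA_real_)
      if (!is.finite(p)) list(p = 1, zv = TRUE, mu = mu)
      else list(p = p, zv = FALSE, mu = mu)
    }
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  out <- data.frame(gene = test_genes, p = p,
                    p_adj = pmin(1, p * m),
                    zero_variance = vapply(res, `[[`, logical(1), "zv"),
                    stringsAsFactors = FALSE)
  mus <- t(vapply(res, function(z) as.numeric(z$mu), numeric(nlevels(grp))))
  colnames(mus) <- paste0("mean_", levels(grp))
  out <- cbind(out, mus)
  out[order(out$p_adj, out$p, out$gene), , drop = FALSE]
}

#' Build a pathway-similarity network
#'
#' Nodes are pathways (annotated with a group's OCR fractions, survival p
#' and member-gene count); edges connect pathways sharing at least
#' `min_shared` genes, weighted by the shared count. Topology depends only
#' on the gene sets, so networks for different groups differ in annotation
#' only.
#'
#' @param gene_sets a `gene_set_collection`.
#' @param ocr a `mopa_ocr` (or NULL to skip OCR annotation).
#' @param survival_p named numeric vector pathway -> p-value (optional).
#' @param group group label whose OCR annotates the nodes (required when
#'   `ocr` is given).
#' @param min_shared minimum shared genes for an edge (default 1).
#' @param universe optional gene universe to intersect the sets with.
#' @return an object of class `mopa_network`: list with `nodes` (data
#'   frame) and `edges` (data frame pathway_a/pathway_b/shared).
#' @export
build_pathway_network <- function(gene_sets, ocr = NULL, survival_p = NULL,
                                  group = NULL, min_shared = 1L,
                                  universe = NULL) {
  stopifnot(inherits(gene_sets, "gene_set_collection"))
  sets <- gene_sets$pathways
  if (!is.null(universe)) sets <- lapply(sets, intersect, universe)
  if (!is.null(ocr)) {
    stopifnot(inherits(ocr, "mopa_ocr"))
    if (is.null(group) || !group %in% dimnames(ocr$ocr)[[1]])
      stopf("a valid 'group' is required to annotate nodes with OCR")
    sets <- sets[names(sets) %in% dimnames(ocr$ocr)[[2]]]
  }
  ids <- names(sets)
  if (length(ids) == 0L) stopf("no pathway to place in the network")
  nodes <- data.frame(pathway = ids, n_genes = lengths(sets),
                      stringsAsFactors = FALSE)
  if (!is.null(ocr)) {
    om <- dimnames(ocr$ocr)[[3]]
    for (k in om)
      nodes[[paste0("ocr_", k)]] <- ocr$ocr[group, ids, k]
  }
  nodes$surv_p <- if (is.null(survival_p)) NA_real_ else
    unname(survival_p[ids])
  edges <- data.frame(pathway_a = character(0), pathway_b = character(0),
                      shared = integer(0), stringsAsFactors = FALSE)
  if (length(ids) > 1L) {
    comb <- utils::combn(ids, 2)
    shared <- apply(comb, 2, function(pr)
      length(intersect(sets[[pr[1]]], sets[[pr[2]]])))
    keep <- shared >= min_shared
    edges <- data.frame(pathway_a = comb[1, keep], pathway_b = comb[2, keep],
                        shared = as.integer(shared[keep]),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "mopa_network")
}

#' @export
print.mopa_network <- function(x, ...) {
  cat(sprintf("<mopa_network> %d pathways, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a pathway network as SIF
#'
#' One line per edge: `pathway_a<TAB>shares<TAB>pathway_b`.
#'
#' @param network a `mopa_network`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "mopa_network"))
  lines <- sprintf("%s\tshares\t%s", network$edges$pathway_a, network$edges$pathway_b)
  writeLines(lines, path)
  invisible(path)
}

#' Export a pathway network as GraphML
#'
#' Node attributes: `n_genes`, `surv_p` and one `ocr_<omics>` column per
#' omics layer; edge attribute `shared`.
#'
#' @param network a `mopa_network`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "mopa_network"))
  g <- igraph::graph_from_data_frame(
    d = network$edges[, c("pathway_a", "pathway_b", "shared")],
    directed = FALSE, vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
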