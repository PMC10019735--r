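# Synthetic data with planted ground truth: a low-rank nonnegative tensor
# whose components carry group structure and omics preferences, gene sets
# enriched in component genes, survival with a planted pathway effect, and
# raw miRNA/methylation inputs with known gene-level expectations.

#' Generate a planted-structure multi-omics tensor
#'
#' Builds T = sum of rank-1 nonnegative components plus half-normal noise.
#' Each group owns `features_per_group` components whose sample loadings
#' are elevated by `effect` in that group; `background_features` components
#' load uniformly over all samples. Every planted component of a group
#' concentrates most of its omics-vector mass on the group's designated
#' omics layer (groups cycle through the layers), so an omics-contribution
#' ground truth exists per group.
#'
#' @param n_groups number of sample groups (default 3).
#' @param samples_per_group samples per group (default 40).
#' @param n_genes number of genes (default 1000).
#' @param L number of omics layers (default 3).
#' @param features_per_group planted components per group (default 4).
#' @param background_features group-agnostic components (default 8).
#' @param effect additive elevation of in-group sample loadings (default 2).
#' @param noise_sigma scale of the half-normal noise (default 0.1).
#' @param seed RNG seed.
#' @return list with `tensor` (a `mopa_tensor`) and `truth` (list with
#'   planted factor matrices `S`, `G`, `O`, `group_of_feature`,
#'   `feature_omics` (dominant omics per planted component), `group_omics`
#'   (designated omics layer per group), `labels` (named vector sample ->
#'   group), `noise_sigma`, `seed`).
#' @export
generate_tensor <- function(n_groups = 3L, samples_per_group = 40L,
                            n_genes = 1000L, L = 3L,
                            features_per_group = 4L, background_features = 8L,
                            effect = 2, noise_sigma = 0.1, seed = 1L) {
  stopifnot(n_groups >= 1, samples_per_group >= 1, n_genes >= 1, L >= 1,
            features_per_group >= 1, background_features >= 0,
            effect >= 0, noise_sigma >= 0)
  R <- n_groups * features_per_group + background_features
  n <- n_groups * samples_per_group
  max_rank <- min(n * n_genes, n * L, n_genes * L)
  if (R > max_rank)
    stopf("total planted components (%d) exceed tensor capacity", R)
  with_seed(seed, {
    groups <- paste0("G", seq_len(n_groups))
    labels <- setNames(rep(groups, each = samples_per_group),
                       sprintf("S%03d", seq_len(n)))
    group_of_feature <- c(rep(groups, each = features_per_group),
                          rep("background", background_features))
    # sample loadings: weak baseline everywhere, elevated in the owning group
    S <- matrix(stats::runif(n * R, 0, 0.3), n, R)
    for (f in seq_len(R)) {
      if (group_of_feature[f] != "background") {
        idx <- which(labels == group_of_feature[f])
        S[idx, f] <- S[idx, f] + effect * stats::runif(length(idx), 0.5, 1)
      } else {
        S[, f] <- stats::runif(n, 0, 1)
      }
    }
    G <- matrix(stats::runif(n_genes * R, 0, 1), n_genes, R)
    # omics vectors: a group's planted components all concentrate on the
    # group's designated layer
    O <- matrix(0, L, R)
    feature_omics <- integer(R)
    group_omics <- setNames(((seq_len(n_groups) - 1L) %% L) + 1L, groups)
    for (f in seq_len(R)) {
      if (group_of_feature[f] != "background" && L > 1L) {
        dom <- group_omics[[group_of_feature[f]]]
        feature_omics[f] <- dom
        w <- stats::runif(1, 0.7, 0.9)
        rest <- stats::runif(L - 1L)
        rest <- rest / sum(rest) * (1 - w)
        O[dom, f] <- w
        O[-dom, f] <- rest
      } else {
        v <- stats::runif(L, 0.5, 1)
        O[, f] <- v / sum(v)
        feature_omics[f] <- NA_integer_
      }
    }
    arr <- array(0, dim = c(n, n_genes, L))
    for (f in seq_len(R))
      arr <- arr + outer(outer(S[, f], G[, f]), O[, f])
    if (noise_sigma > 0)
      arr <- arr + abs(stats::rnorm(length(arr), 0, noise_sigma))
    dimnames(arr) <- list(names(labels), sprintf("g%04d", seq_len(n_genes)),
                          paste0("omics", seq_len(L)))
    rownames(S) <- names(labels)
    rownames(G) <- dimnames(arr)[[2]]
    rownames(O) <- dimnames(arr)[[3]]
    list(tensor = mopa_tensor(arr),
         truth = list(S = S, G = G, O = O,
                      group_of_feature = group_of_feature,
                      feature_omics = feature_omics,
                      group_omics = if (L > 1L) group_omics else
                        setNames(rep(1L, n_groups), groups),
                      labels = labels,
                      noise_sigma = noise_sigma, seed = as.integer(seed)))
  })
}

#' Generate gene sets enriched in planted components
#'
#' Planted sets draw their genes from the top-loading decile of one planted
#' component's gene vector (components are cycled in order); null sets draw
#' genes uniformly.
#'
#' @param truth the `truth` element from [generate_tensor()].
#' @param n_planted number of planted pathways.
#' @param n_null number of null pathways.
#' @param set_size genes per pathway (< number of genes).
#' @param seed RNG seed.
#' @return a `gene_set_collection` with attribute `planted`: data frame
#'   (pathway, feature, group) with NA feature for null sets.
#' @export
generate_gene_sets <- function(truth, n_planted, n_null, set_size, seed = 1L) {
  n_genes <- nrow(truth$G)
  if (set_size >= n_genes) stopf("set_size must be < number of genes")
  planted_feats <- which(truth$group_of_feature != "background")
  if (n_planted > 0L && length(planted_feats) == 0L)
    stopf("no planted component available")
  dec_n <- ceiling(n_genes / 10)
  if (n_planted > 0L && set_size > dec_n)
    stopf("set_size exceeds the top-decile gene count (%d)", dec_n)
  with_seed(seed, {
    sets <- list(); descr <- character(0)
    planted <- data.frame(pathway = character(0), feature = integer(0),
                          group = character(0), stringsAsFactors = FALSE)
    genes <- rownames(truth$G)
    for (i in seq_len(n_planted)) {
      f <- planted_feats[((i - 1L) %% length(planted_feats)) + 1L]
      top <- genes[order(-truth$G[, f])][seq_len(dec_n)]
      id <- sprintf("planted_%02d", i)
      sets[[id]] <- sample(top, set_size)
      descr[id] <- sprintf("planted on component %d", f)
      planted <- rbind(planted, data.frame(
        pathway = id, feature = f, group = truth$group_of_feature[f]))
    }
    for (i in seq_len(n_null)) {
      id <- sprintf("null_%02d", i)
      sets[[id]] <- sample(genes, set_size)
      descr[id] <- "null pathway"
      planted <- rbind(planted, data.frame(
        pathway = id, feature = NA_integer_, group = NA_character_))
    }
    gs <- gene_set_collection(sets, descr)
    attr(gs, "planted") <- planted
    gs
  })
}

#' Generate survival times with a planted pathway effect
#'
#' Exponential survival times whose hazard is multiplied by `hazard_ratio`
#' for samples in the top half of the chosen pathway's score. Censoring is
#' independent: each sample is censored with probability `censor_frac`, in
#' which case the observed time is uniformly shortened.
#'
#' @param es a `mopa_es` or samples x pathways matrix of scores.
#' @param pathway pathway id.
#' @param hazard_ratio hazard multiplier for the top half (1 = null).
#' @param censor_frac probability of censoring in \[0, 1).
#' @param base_rate baseline exponential rate (default 0.1).
#' @param seed RNG seed.
#' @return a `sample_annotations` with a survival table.
#' @export
generate_survival <- function(es, pathway, hazard_ratio = 1,
                              censor_frac = 0.2, base_rate = 0.1, seed = 1L) {
  if (censor_frac < 0 || censor_frac >= 1) stopf("censor_frac must be in [0, 1)")
  mes <- if (inherits(es, "mopa_es")) es$mes else as.matrix(es)
  if (!pathway %in% colnames(mes)) stopf("pathway '%s' not in score matrix", pathway)
  x <- mes[, pathway]
  top <- names(x)[rank(-x, ties.method = "first") <= length(x) / 2]
  with_seed(seed, {
    rate <- ifelse(names(x) %in% top, base_rate * hazard_ratio, base_rate)
    time <- stats::rexp(length(x), rate)
    event <- as.integer(stats::runif(length(x)) >= censor_frac)
    time[event == 0L] <- time[event == 0L] * stats::runif(sum(event == 0L))
    sample_annotations(
      survival = data.frame(time = time, event = event, row.names = names(x)))
  })
}

#' Generate raw omics inputs with known gene-level expectations
#'
#' Random mRNA, miRNA and methylation matrices plus a miRNA-target map and
#' a probe annotation that places probes both inside and outside the
#' promoter window on both strands. The attribute `expected` on the return
#' value carries hand-computable gene-level means for the miRNA and
#' methylation layers.
#'
#' @param n_mirna number of miRNAs.
#' @param n_probes number of methylation probes.
#' @param n_genes number of genes.
#' @param n_samples number of samples (default 6).
#' @param window_bp promoter window used for probe placement (default 2000).
#' @param seed RNG seed.
#' @return list with `mrna`, `mirna`, `meth` (`omics_matrix` objects),
#'   `mirna_map`, `probe_map` (`feature_gene_map` objects) and
#'   `gene_universe`; attribute `expected` holds the expected gene-level
#'   miRNA and methylation matrices.
#' @export
generate_raw_omics <- function(n_mirna, n_probes, n_genes, n_samples = 6L,
                               window_bp = 2000L, seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    samples <- sprintf("S%02d", seq_len(n_samples))
    mirnas <- sprintf("miR-%03d", seq_len(n_mirna))
    probes <- sprintf("cg%05d", seq_len(n_probes))
    mrna <- omics_matrix(matrix(stats::rexp(n_genes * n_samples, 1 / 50),
                                n_genes, n_samples,
                                dimnames = list(genes, samples)), "mrna")
    mirna <- omics_matrix(matrix(stats::rexp(n_mirna * n_samples, 1 / 20),
                                 n_mirna, n_samples,
                                 dimnames = list(mirnas, samples)), "mirna")
    meth <- omics_matrix(matrix(stats::runif(n_probes * n_samples),
                                n_probes, n_samples,
                                dimnames = list(probes, samples)), "methylation")
    # miRNA -> target genes, 1-3 targets each
    entries <- lapply(mirnas, function(m)
      sample(genes, sample(1:3, 1)))
    names(entries) <- mirnas
    mirna_map <- structure(list(kind = "mirna_target", entries = entries),
                           class = "feature_gene_map")
    # probes: genes alternate strand; probes placed in- and out-of-window
    strand <- rep(c("+", "-"), length.out = n_genes)
    tss <- sample(10000:100000, n_genes)
    gi <- sample(seq_len(n_genes), n_probes, replace = TRUE)
    inside <- stats::runif(n_probes) < 0.6
    offs <- ifelse(inside, sample(1:window_bp, n_probes, replace = TRUE),
                   window_bp + sample(1:5000, n_probes, replace = TRUE))
    pos <- ifelse(strand[gi] == "+", tss[gi] - offs, tss[gi] + offs)
    probe_df <- data.frame(probe = probes, chrom = "chr1", pos = as.integer(pos),
                           gene = genes[gi], tss = as.integer(tss[gi]),
                           strand = strand[gi], stringsAsFactors = FALSE)
    probe_map <- structure(list(kind = "probe_promoter", entries = probe_df),
                           class = "feature_gene_map")
    # hand-computable expectations
    exp_mirna <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples))
    rev_map <- split(rep(mirnas, lengths(entries)), unlist(entries))
    for (g in names(rev_map))
      exp_mirna[g, ] <- colMeans(mirna$values[rev_map[[g]], , drop = FALSE])
    exp_meth <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples))
    in_window <- probe_df[inside, , drop = FALSE]
    for (g in unique(in_window$gene))
      exp_meth[g, ] <- colMeans(
        meth$values[in_window$probe[in_window$gene == g], , drop = FALSE])
    out <- list(mrna = mrna, mirna = mirna, meth = meth,
                mirna_map = mirna_map, probe_map = probe_map,
                gene_universe = genes)
    attr(out, "expected") <- list(mirna = exp_mirna, meth = exp_meth)
    out
  })
}
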