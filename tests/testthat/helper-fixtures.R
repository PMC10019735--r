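# Shared fixtures and independent oracles.

# Small gene-level tensor built directly from factor matrices (no noise).
make_exact_tensor <- function(S, G, O) {
  arr <- array(0, dim = c(nrow(S), nrow(G), nrow(O)),
               dimnames = list(rownames(S) %||% sprintf("S%02d", seq_len(nrow(S))),
                               rownames(G) %||% sprintf("g%03d", seq_len(nrow(G))),
                               rownames(O) %||% paste0("omics", seq_len(nrow(O)))))
  for (f in seq_len(ncol(S)))
    arr <- arr + outer(outer(S[, f], G[, f]), O[, f])
  mopa_tensor(arr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force enrichment score: a literal double-loop over the
# ordered gene list, kept deliberately naive and separate from the package's
# vectorized path.
oracle_mes <- function(r, members, gene_ids = names(r)) {
  stopifnot(!is.null(gene_ids))
  q <- length(r)
  ord <- order(-r, gene_ids)
  in_set <- gene_ids %in% members
  m <- sum(in_set)
  stopifnot(m >= 1, m < q)
  denom_w <- 0
  for (l in seq_len(q)) if (in_set[ord[l]]) denom_w <- denom_w + r[ord[l]]
  d <- numeric(q)
  cw <- 0; cn <- 0
  for (j in seq_len(q)) {
    l <- ord[j]
    if (in_set[l]) cw <- cw + r[l] else cn <- cn + 1
    d[j] <- cw / denom_w - cn / (q - m)
  }
  list(d = d, mes = max(0, max(d)) - abs(min(0, min(d))))
}

# Quadrature oracle for the Gaussian-KDE CDF: numerically integrate the
# kernel density from far below the support up to v.
oracle_kde_cdf <- function(x, v, h) {
  dens <- function(t) sapply(t, function(tt) mean(stats::dnorm((tt - x) / h)) / h)
  stats::integrate(dens, lower = min(x) - 12 * h, upper = v,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Greedy column matching by absolute cosine similarity, for factor recovery.
matched_cosines <- function(est, truth) {
  est <- sweep(est, 2, sqrt(colSums(est^2)), "/")
  truth <- sweep(truth, 2, sqrt(colSums(truth^2)), "/")
  sim <- abs(crossprod(est, truth))
  out <- numeric(ncol(truth))
  for (k in seq_len(ncol(truth))) {
    best <- which(sim == max(sim), arr.ind = TRUE)[1, ]
    out[k] <- sim[best[1], best[2]]
    sim[best[1], ] <- -1
    sim[, best[2]] <- -1
  }
  out
}

# Write a complete raw-input fixture set (omics TSVs, maps, GMT, labels,
# survival) into `dir`, for pipeline-level tests.
sim_fixture_dir <- function(dir, seed = 5) {
  raw <- generate_raw_omics(n_mirna = 30, n_probes = 80, n_genes = 40,
                            n_samples = 16, seed = seed)
  write_matrix(raw$mrna$values, file.path(dir, "mrna.tsv"), id_col = "gene")
  write_matrix(raw$mirna$values, file.path(dir, "mirna.tsv"), id_col = "mirna")
  write_matrix(raw$meth$values, file.path(dir, "meth.tsv"), id_col = "probe")
  mm <- raw$mirna_map$entries
  utils::write.table(
    data.frame(feature = rep(names(mm), lengths(mm)),
               gene = unlist(mm, use.names = FALSE)),
    file.path(dir, "mirna_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(raw$probe_map$entries, file.path(dir, "probe_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  set.seed(seed)
  ids <- sprintf("P%02d", 1:6)
  gs <- gene_set_collection(setNames(
    lapply(ids, function(i) sample(raw$gene_universe, 8)), ids))
  write_gmt(gs, file.path(dir, "sets.gmt"))
  samples <- colnames(raw$mrna$values)
  utils::write.table(
    data.frame(sample = samples,
               group = rep(c("A", "B"), length.out = length(samples))),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = samples, time = rexp(length(samples), 0.1),
               event = rbinom(length(samples), 1, 0.8)),
    file.path(dir, "survival.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  raw
}

mk_config <- function(dir, out, ...) {
  run_config(mrna = file.path(dir, "mrna.tsv"),
             mirna = file.path(dir, "mirna.tsv"),
             meth = file.path(dir, "meth.tsv"),
             mirna_map = file.path(dir, "mirna_map.tsv"),
             probe_map = file.path(dir, "probe_map.tsv"),
             gmt = file.path(dir, "sets.gmt"),
             labels = file.path(dir, "labels.tsv"),
             survival = file.path(dir, "survival.tsv"),
             out_dir = out, rank = 4, seed = 3, max_iter = 150, ...)
}

# A small decomposition-like object with prescribed loadings, for unit tests
# of assignment/scoring without running the solver.
fake_decomp <- function(S, G, O, selected = seq_len(ncol(S))) {
  fn <- paste0("F", seq_len(ncol(S)))
  dimnames(S) <- list(rownames(S) %||% sprintf("S%02d", seq_len(nrow(S))), fn)
  dimnames(G) <- list(rownames(G) %||% sprintf("g%03d", seq_len(nrow(G))), fn)
  dimnames(O) <- list(rownames(O) %||% paste0("omics", seq_len(nrow(O))), fn)
  structure(list(S = S, G = G, O = O, rank = ncol(S), residual = 0,
                 seed = 1L, selected_features = selected,
                 iterations = 0L, converged = TRUE),
            class = "mopa_decomp")
}
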