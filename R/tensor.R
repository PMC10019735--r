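# Non-negative CP (PARAFAC) decomposition of the gene-level tensor by
# hierarchical ALS, plus rank-scan and a label-aware component selector.

#' Non-negative CP (PARAFAC) decomposition
#'
#' Factorizes the sample x gene x omics tensor into `rank` nonnegative
#' rank-1 components, yielding sample (S), gene (G) and omics (O) loading
#' matrices. Fitting uses hierarchical alternating least squares (HALS):
#' each factor column is updated in closed form and projected onto the
#' nonnegative orthant, from a random nonnegative initialization, so all
#' loadings stay nonnegative by construction. After fitting, each
#' component's scale is absorbed into S so that G and O columns have unit
#' Euclidean norm; downstream scoring uses G and O entries directly, so this
#' fixed convention makes results reproducible.
#'
#' @param tensor a `mopa_tensor`.
#' @param rank number of components R (>= 1).
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum number of update sweeps (default 500).
#' @param tol convergence tolerance on the change in relative residual
#'   (default 1e-7).
#' @return an object of class `mopa_decomp` with elements `S`, `G`, `O`
#'   (loading matrices with axis dimnames), `rank`, `residual` (relative
#'   Frobenius reconstruction error), `seed`, `selected_features` (initially
#'   all components), `iterations`, `converged`.
#' @export
decompose <- function(tensor, rank, seed = 1L, max_iter = 500L, tol = 1e-7) {
  stopifnot(inherits(tensor, "mopa_tensor"))
  d <- dim(tensor)
  max_rank <- min(prod(d[-1]), prod(d[-2]), prod(d[-3]))
  if (rank < 1L) stopf("rank must be >= 1")
  if (rank > max_rank)
    stopf("rank %d exceeds the maximum supported by the tensor dimensions (%d); the number of ranks is constrained by the smallest unfolding",
          rank, max_rank)
  X <- unclass(tensor)
  X1 <- unfold3(X, 1); X2 <- unfold3(X, 2); X3 <- unfold3(X, 3)
  normT2 <- sum(X1^2)
  if (normT2 == 0) stopf("tensor is identically zero")
  eps <- 1e-12

  fac <- with_seed(seed, list(
    A = matrix(stats::runif(d[1] * rank, 0.1, 1), d[1], rank),
    B = matrix(stats::runif(d[2] * rank, 0.1, 1), d[2], rank),
    C = matrix(stats::runif(d[3] * rank, 0.1, 1), d[3], rank)))
  A <- fac$A; B <- fac$B; C <- fac$C

  # HALS sweep over one mode: closed-form column updates projected to >= 0.
  # W = X(n) * khatri_rao(other2, other1), V = (t(o1) o1) * (t(o2) o2).
  hals_update <- function(M, W, V) {
    for (r in seq_len(ncol(M))) {
      vrr <- V[r, r]
      if (vrr <= eps) next
      M[, r] <- pmax(0, M[, r] + (W[, r] - M %*% V[, r]) / vrr)
    }
    M
  }

  prev <- Inf
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    A <- hals_update(A, X1 %*% khatri_rao(C, B), crossprod(B) * crossprod(C))
    B <- hals_update(B, X2 %*% khatri_rao(C, A), crossprod(A) * crossprod(C))
    W3 <- X3 %*% khatri_rao(B, A)
    V3 <- crossprod(A) * crossprod(B)
    C <- hals_update(C, W3, V3)
    # residual from the mode-3 quantities: ||T||^2 - 2<C, W3> + <C'C, V3>
    res2 <- max(normT2 - 2 * sum(C * W3) + sum(crossprod(C) * V3), 0)
    cur <- sqrt(res2 / normT2)
    # absolute floor: at an exact fit the residual only fluctuates at
    # cancellation-noise scale and the change criterion cannot fire
    if (cur < 1e-9 || abs(prev - cur) < tol) {
      prev <- cur; converged <- TRUE; break
    }
    prev <- cur
  }
  if (!converged)
    warnf("CP decomposition did not converge within %d iterations (residual %.3g)",
          max_iter, prev)

  # absorb component scales into S; unit-norm G and O columns
  bn <- sqrt(colSums(B^2)); cn <- sqrt(colSums(C^2))
  bn[bn == 0] <- 1; cn[cn == 0] <- 1
  B <- sweep(B, 2, bn, "/")
  C <- sweep(C, 2, cn, "/")
  A <- sweep(A, 2, bn * cn, "*")

  dn <- dimnames(tensor)
  fn <- paste0("F", seq_len(rank))
  dimnames(A) <- list(dn[[1]], fn)
  dimnames(B) <- list(dn[[2]], fn)
  dimnames(C) <- list(dn[[3]], fn)
  structure(list(S = A, G = B, O = C, rank = as.integer(rank),
                 residual = prev, seed = as.integer(seed),
                 selected_features = seq_len(rank),
                 iterations = iter, converged = converged),
            class = "mopa_decomp")
}

#' @export
print.mopa_decomp <- function(x, ...) {
  cat(sprintf("<mopa_decomp> rank %d, %d samples x %d genes x %d omics\n",
              x$rank, nrow(x$S), nrow(x$G), nrow(x$O)))
  cat(sprintf("  relative residual: %.4g (%d iterations%s)\n", x$residual,
              x$iterations, if (x$converged) "" else ", not converged"))
  cat(sprintf("  selected components: %s\n",
              paste(x$selected_features, collapse = ", ")))
  invisible(x)
}

#' Scan decomposition ranks for elbow inspection
#'
#' Fits one decomposition per rank and reports the relative residual, for
#' choosing R by the elbow method.
#'
#' @param tensor a `mopa_tensor`.
#' @param ranks ascending vector of distinct ranks.
#' @param seed seed passed to every fit.
#' @param ... further arguments to [decompose()].
#' @return data frame with columns `rank` and `residual`.
#' @export
rank_scan <- function(tensor, ranks, seed = 1L, ...) {
  if (length(ranks) == 0L) stopf("ranks must be non-empty")
  if (anyDuplicated(ranks)) stopf("duplicate ranks in scan")
  if (is.unsorted(ranks)) stopf("ranks must be ascending")
  res <- vapply(ranks, function(r)
    decompose(tensor, rank = r, seed = seed, ...)$residual, numeric(1))
  data.frame(rank = as.integer(ranks), residual = res)
}

#' Save / load a decomposition as plain text
#'
#' Writes the three loading matrices as TSV plus a small JSON with rank,
#' seed, residual and the selected component indices, so staged
#' command-line runs can pass a decomposition between processes.
#'
#' @param result a `mopa_decomp`.
#' @param dir directory to write into (created if needed).
#' @return invisibly, `dir`.
#' @export
save_decomposition <- function(result, dir) {
  stopifnot(inherits(result, "mopa_decomp"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(result$S, file.path(dir, "loadings_samples.tsv"), id_col = "sample")
  write_matrix(result$G, file.path(dir, "loadings_genes.tsv"), id_col = "gene")
  write_matrix(result$O, file.path(dir, "loadings_omics.tsv"), id_col = "omics")
  meta <- result[c("rank", "residual", "seed", "selected_features",
                   "iterations", "converged")]
  jsonlite::write_json(meta, file.path(dir, "decomposition.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_decomposition
#' @param dir directory written by [save_decomposition()].
#' @return for `load_decomposition`, a `mopa_decomp`.
#' @export
load_decomposition <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "decomposition.json"),
                              simplifyVector = TRUE)
  structure(list(S = read_matrix(file.path(dir, "loadings_samples.tsv")),
                 G = read_matrix(file.path(dir, "loadings_genes.tsv")),
                 O = read_matrix(file.path(dir, "loadings_omics.tsv")),
                 rank = as.integer(meta$rank), residual = meta$residual,
                 seed = as.integer(meta$seed),
                 selected_features = as.integer(meta$selected_features),
                 iterations = meta$iterations, converged = meta$converged),
            class = "mopa_decomp")
}

#' Label-aware component selection
#'
#' A simple pluggable selector: per component, the sample loadings are
#' tested for group differences (Kruskal-Wallis), p-values are
#' Benjamini-Hochberg adjusted, and components significant at `alpha` are
#' kept (capped at `max_features` by ascending adjusted p). If none pass,
#' all components are kept with a warning. An externally computed component
#' index list can be supplied instead via `feature_list` to reproduce runs
#' driven by a different selector.
#'
#' @param result a `mopa_decomp`.
#' @param labels a `sample_annotations` with group labels covering all
#'   samples, or a named character vector.
#' @param alpha BH significance level (default 0.05).
#' @param max_features cap on the number of selected components.
#' @param feature_list optional integer vector of component indices to use
#'   verbatim, bypassing the test.
#' @return the `mopa_decomp` with `selected_features` updated.
#' @export
select_features_supervised <- function(result, labels, alpha = 0.05,
                                       max_features = result$rank,
                                       feature_list = NULL) {
  stopifnot(inherits(result, "mopa_decomp"))
  if (!is.null(feature_list)) {
    feature_list <- sort(unique(as.integer(feature_list)))
    if (any(feature_list < 1L | feature_list > result$rank))
      stopf("feature_list indices outside 1..rank")
    result$selected_features <- feature_list
    return(result)
  }
  grp <- if (inherits(labels, "sample_annotations")) labels$labels else labels
  if (is.null(grp)) stopf("labels are required for supervised selection")
  samples <- rownames(result$S)
  if (!all(samples %in% names(grp)))
    stopf("labels must cover all samples in the decomposition")
  grp <- factor(grp[samples])
  if (nlevels(grp) < 2L) stopf("supervised selection needs >= 2 groups")
  p <- vapply(seq_len(result$rank), function(f) {
    x <- result$S[, f]
    if (stats::sd(x) == 0) return(1)
    stats::kruskal.test(x, grp)$p.value
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  hits <- which(padj <= alpha)
  if (length(hits) == 0L) {
    warnf("no component passed BH at alpha=%.3g; keeping all %d", alpha, result$rank)
    result$selected_features <- seq_len(result$rank)
  } else {
    hits <- hits[order(padj[hits])]
    hits <- sort(hits[seq_len(min(length(hits), max_features))])
    result$selected_features <- hits
  }
  result
}
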