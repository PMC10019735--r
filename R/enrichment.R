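# Multi-omics enrichment scoring: per-sample gene rank weights from the
# assigned components, and the mES per pathway via a weighted
# Kolmogorov-Smirnov random-walk statistic.

#' Z-normalize and positive-shift gene loadings
#'
#' Per selected component, gene loadings are z-normalized (population
#' standard deviation, divisor n) and then shifted so the column minimum is
#' 0; every entry is thus nonnegative and within-column ordering is
#' preserved. Zero-variance columns become all zeros with a warning.
#'
#' @param G gene loading matrix (genes x components).
#' @param features integer indices of the components to keep (default all).
#' @return genes x selected-components matrix `G'` with column minima 0.
#' @export
normalize_gene_loadings <- function(G, features = seq_len(ncol(G))) {
  if (nrow(G) < 2L) stopf("need >= 2 genes to normalize loadings")
  Gp <- G[, features, drop = FALSE]
  for (j in seq_len(ncol(Gp))) {
    x <- Gp[, j]
    sdev <- sqrt(mean((x - mean(x))^2))  # population sd
    if (sdev == 0) {
      warnf("gene loading column %d has zero variance; set to zeros", features[j])
      Gp[, j] <- 0
    } else {
      z <- (x - mean(x)) / sdev
      Gp[, j] <- z - min(z)
    }
  }
  colnames(Gp) <- as.character(features)
  Gp
}

#' Per-sample gene rank weights
#'
#' For sample i with assigned components f, the weight of gene j is
#' `r_ij = sum over f of g'_jf * s'_if`: the normalized gene loadings mixed
#' by the sample's scaled component loadings. Genes are then ordered by
#' descending weight (ties broken by ascending gene id) to form the walk
#' order.
#'
#' @param G_prime normalized gene loadings from
#'   [normalize_gene_loadings()] over the selected components.
#' @param assignment a `mopa_assignment`.
#' @return an object of class `mopa_rank_weights` with elements `r`
#'   (samples x genes weight matrix), `order` (samples x genes matrix of
#'   gene indices, each row a descending-weight permutation) and `genes`.
#' @export
rank_weights <- function(G_prime, assignment) {
  stopifnot(inherits(assignment, "mopa_assignment"))
  feats <- assignment$features
  stopifnot(identical(colnames(G_prime), as.character(feats)))
  samples <- rownames(assignment$scaled)
  genes <- rownames(G_prime)
  r <- matrix(0, length(samples), nrow(G_prime),
              dimnames = list(samples, genes))
  ord <- matrix(0L, length(samples), nrow(G_prime))
  rownames(ord) <- samples
  for (i in seq_along(samples)) {
    fi <- assignment$assigned[[i]]
    if (length(fi) == 0L) stopf("sample '%s' has an empty assigned set", samples[i])
    pos <- match(fi, feats)
    w <- assignment$scaled[i, pos]
    r[i, ] <- as.vector(G_prime[, pos, drop = FALSE] %*% w)
    ord[i, ] <- order(-r[i, ], genes)  # stable: ties by ascending gene id
  }
  structure(list(r = r, order = ord, genes = genes),
            class = "mopa_rank_weights")
}

#' @export
print.mopa_rank_weights <- function(x, ...) {
  cat(sprintf("<mopa_rank_weights> %d samples x %d genes\n",
              nrow(x$r), ncol(x$r)))
  invisible(x)
}

#' Weighted KS random walk over a ranked gene list
#'
#' Walking the genes in descending weight order, the running difference
#' between the weighted fraction of pathway-member mass seen so far and the
#' unweighted fraction of non-members seen so far:
#' `d_j = cum member weight / total member weight - cum non-member count /
#' (q - |members|)`. The walk ends at 0.
#'
#' @param r_i numeric weight vector over all q genes (unsorted).
#' @param order integer permutation sorting `r_i` descending.
#' @param members logical or index vector marking pathway members among the
#'   q genes (unsorted positions).
#' @return numeric vector `d` of length q.
#' @export
ks_walk <- function(r_i, order, members) {
  q <- length(r_i)
  memb <- logical(q)
  memb[members] <- TRUE
  m <- sum(memb)
  if (m == 0L) stopf("pathway has no member genes in the universe")
  if (m == q) stopf("pathway covers the whole gene universe (q - |p| = 0)")
  rs <- r_i[order]
  ms <- memb[order]
  wsum <- sum(rs[ms])
  if (wsum <= 0) stopf("total member weight is zero")
  unname(cumsum(rs * ms) / wsum - cumsum(!ms) / (q - m))
}

#' Enrichment score from a KS walk
#'
#' The score is the maximum positive excursion minus the absolute value of
#' the maximum negative excursion of the walk; it lies in \[-1, 1\].
#'
#' @param d walk vector from [ks_walk()].
#' @return a single number in \[-1, 1\].
#' @export
mes_from_walk <- function(d) {
  if (length(d) == 0L) stopf("empty walk")
  max(0, max(d)) - abs(min(0, min(d)))
}

#' Score all pathways in all samples
#'
#' Pathway gene sets are intersected with the tensor gene universe; sets
#' with fewer than `min_overlap` members, or covering the whole universe,
#' or with zero member weight in a sample, are skipped with a
#' machine-readable reason.
#'
#' @param weights a `mopa_rank_weights`.
#' @param gene_sets a `gene_set_collection`.
#' @param min_overlap minimum member genes in the universe (default 2).
#' @return an object of class `mopa_es` with elements `mes` (samples x
#'   pathways matrix) and `skipped` (data frame pathway/reason).
#' @export
score_all <- function(weights, gene_sets, min_overlap = 2L) {
  stopifnot(inherits(weights, "mopa_rank_weights"),
            inherits(gene_sets, "gene_set_collection"))
  genes <- weights$genes
  q <- length(genes)
  samples <- rownames(weights$r)
  member_idx <- lapply(gene_sets$pathways, function(p) which(genes %in% p))
  sizes <- lengths(member_idx)
  skip <- data.frame(pathway = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  keep <- rep(TRUE, length(member_idx))
  for (t in seq_along(member_idx)) {
    if (sizes[t] < min_overlap) {
      keep[t] <- FALSE
      skip <- rbind(skip, data.frame(pathway = names(member_idx)[t],
                                     reason = "insufficient overlap"))
    } else if (sizes[t] == q) {
      keep[t] <- FALSE
      skip <- rbind(skip, data.frame(pathway = names(member_idx)[t],
                                     reason = "covers whole universe"))
    }
  }
  member_idx <- member_idx[keep]
  if (length(member_idx) == 0L) stopf("no scorable pathway after filtering")
  mes <- matrix(NA_real_, length(samples), length(member_idx),
                dimnames = list(samples, names(member_idx)))
  zero_weight <- character(0)
  for (i in seq_along(samples)) {
    ord <- weights$order[i, ]
    rs <- weights$r[i, ord]
    inv <- integer(q); inv[ord] <- seq_len(q)   # rank of each gene
    cum_nonmem <- seq_len(q)
    for (t in seq_along(member_idx)) {
      ranks <- inv[member_idx[[t]]]
      m <- length(ranks)
      memb_sorted <- logical(q); memb_sorted[ranks] <- TRUE
      wsum <- sum(rs[memb_sorted])
      if (wsum <= 0) {
        zero_weight <- c(zero_weight, names(member_idx)[t])
        next
      }
      d <- cumsum(rs * memb_sorted) / wsum - cumsum(!memb_sorted) / (q - m)
      mes[i, t] <- max(0, max(d)) - abs(min(0, min(d)))
    }
  }
  if (length(zero_weight) > 0L)
    skip <- rbind(skip, data.frame(pathway = unique(zero_weight),
                                   reason = "zero member weight in some sample"))
  structure(list(mes = mes, skipped = skip), class = "mopa_es")
}

#' @export
print.mopa_es <- function(x, ...) {
  cat(sprintf("<mopa_es> %d samples x %d pathways (%d skipped)\n",
              nrow(x$mes), ncol(x$mes), nrow(x$skipped)))
  invisible(x)
}
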