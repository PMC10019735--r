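mk_es <- function(scores, pathway = "P") {
  m <- matrix(scores, ncol = 1,
              dimnames = list(sprintf("S%02d", seq_along(scores)), pathway))
  structure(list(mes = m, skipped = data.frame()), class = "mopa_es")
}

test_that("stratification takes exact floor-sized, disjoint extremes", {
  es <- mk_es(seq(0.1, 1, by = 0.1))
  st <- stratify_by_es(es, "P", frac = 0.2)
  expect_length(st$high, 2L)
  expect_length(st$low, 2L)
  expect_identical(st$high, c("S10", "S09"))
  expect_identical(st$low, c("S01", "S02"))
  expect_length(intersect(st$high, st$low), 0L)

  st2 <- stratify_by_es(mk_es(c(0.4, 0.3, 0.2, 0.1)), "P", frac = 0.5)
  expect_length(st2$high, 2L)
  expect_setequal(c(st2$high, st2$low), sprintf("S%02d", 1:4))

  expect_warning(stratify_by_es(mk_es(rep(0.5, 6)), "P"), "tie")
  tied <- suppressWarnings(stratify_by_es(mk_es(rep(0.5, 6)), "P", 0.2))
  expect_identical(tied$high, "S01")  # deterministic tie-break by sample id
  expect_error(stratify_by_es(es, "P", frac = 0.6), "0.5")
  expect_error(stratify_by_es(es, "missing"), "not in")
})

test_that("log-rank detects a planted hazard difference and not a null", {
  set.seed(19)
  es <- mk_es(runif(200))
  st <- stratify_by_es(es, "P", frac = 0.2)
  alt <- generate_survival(es, "P", hazard_ratio = 3, censor_frac = 0.1,
                           seed = 19)
  expect_lt(logrank_test(st, alt)$p, 0.05)
  null_ps <- vapply(1:10, function(s) {
    nul <- generate_survival(es, "P", hazard_ratio = 1, censor_frac = 0.1,
                             seed = s)
    logrank_test(st, nul)$p
  }, numeric(1))
  expect_gt(median(null_ps), 0.1)
})

test_that("degenerate survival inputs return p = 1 with a warning", {
  es <- mk_es(c(0.9, 0.1))
  st <- stratify_by_es(es, "P", frac = 0.5)
  surv <- data.frame(time = c(5, 5), event = c(0L, 0L),
                     row.names = c("S01", "S02"))
  expect_warning(res <- logrank_test(st, surv), "zero events")
  expect_equal(res$p, 1)
  surv2 <- data.frame(time = c(5, 5), event = c(1L, 1L),
                      row.names = c("S01", "S02"))
  expect_equal(suppressWarnings(logrank_test(st, surv2))$p, 1)
})

test_that("K-means on the score matrix is deterministic and recovers structure", {
  set.seed(8)
  m <- rbind(matrix(rnorm(20 * 5, 0, 0.1), 20, 5),
             matrix(rnorm(20 * 5, 3, 0.1), 20, 5))
  rownames(m) <- sprintf("S%02d", 1:40)
  colnames(m) <- paste0("P", 1:5)
  cl1 <- cluster_samples(m, k = 2, seed = 7)
  cl2 <- cluster_samples(m, k = 2, seed = 7)
  expect_identical(cl1, cl2)
  truth <- rep(1:2, each = 20)
  expect_equal(adjusted_rand_index(cl1, truth), 1)
  expect_error(cluster_samples(m, k = 1), "k must be")

  singles <- cluster_samples(m[1:4, ] + matrix(rnorm(20, 0, 1e-3), 4), k = 4,
                             seed = 1)
  expect_length(unique(singles), 4L)
})

test_that("ARI has its defining properties and matches mclust", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  relab <- c(3, 1, 2)[a]                    # pure relabeling
  expect_equal(adjusted_rand_index(a, relab), 1)
  expect_equal(adjusted_rand_index(a, relab),
               adjusted_rand_index(relab, a))
  set.seed(2)
  b <- sample(1:3, 30, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b),
               mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  # independent partitions average ~0
  set.seed(30)
  aris <- replicate(100, adjusted_rand_index(sample(1:4, 200, replace = TRUE),
                                             sample(1:4, 200, replace = TRUE)))
  expect_lt(abs(mean(aris)), 0.05)
  expect_error(adjusted_rand_index(setNames(a, paste0("x", 1:30)),
                                   setNames(b, paste0("y", 1:30))),
               "different sample sets")
})

test_that("gene association ranks planted group-shifted genes first", {
  set.seed(40)
  n <- 60
  genes <- sprintf("g%02d", 1:20)
  lab <- setNames(rep(c("A", "B"), each = n / 2), sprintf("S%02d", 1:n))
  r <- matrix(rnorm(n * 20), n, 20, dimnames = list(names(lab), genes))
  r[lab == "B", "g01"] <- r[lab == "B", "g01"] + 3   # 3-sigma shift
  r[, "g02"] <- 1                                     # zero variance
  w <- structure(list(r = r, order = NULL, genes = genes),
                 class = "mopa_rank_weights")
  ga <- gene_association(w, lab)
  expect_identical(ga$gene[1], "g01")
  expect_lt(ga$p_adj[1], 0.01)
  zv <- ga[ga$gene == "g02", ]
  expect_true(zv$zero_variance)
  expect_equal(zv$p, 1)
  expect_equal(ga$p_adj, pmin(1, ga$p * 20))
  expect_true(all(c("mean_A", "mean_B") %in% names(ga)))

  lab_bad <- setNames(c("A", rep("B", n - 1)), names(lab))
  expect_error(gene_association(w, lab_bad), ">= 2 samples")
})

test_that("pathway networks share genes on edges and keep topology per group", {
  gs <- gene_set_collection(list(P1 = c("a", "b", "c", "d"),
                                 P2 = c("c", "d", "e"),
                                 P3 = c("x", "y")))
  net <- build_pathway_network(gs, min_shared = 2)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$shared, 2L)
  expect_setequal(c(net$edges$pathway_a, net$edges$pathway_b), c("P1", "P2"))
  expect_equal(net$nodes$n_genes, c(4L, 3L, 2L))

  # with OCR annotation: same topology across groups, different annotation
  set.seed(6)
  d <- fake_decomp(matrix(runif(24), 8, 3), matrix(runif(24), 8, 3),
                   matrix(runif(9, 0.1, 1), 3, 3))
  rownames(d$G) <- c("a", "b", "c", "d", "e", "x", "y", "z")
  a <- assign_features(d, threshold = 0.4)
  lab <- setNames(rep(c("A", "B"), each = 4), rownames(d$S))
  oc <- ocr_table(d, a, lab, gs, share_frac = 0.25)
  netA <- build_pathway_network(gs, oc, group = "A", min_shared = 1)
  netB <- build_pathway_network(gs, oc, group = "B", min_shared = 1)
  expect_identical(netA$edges, netB$edges)
  expect_identical(netA$nodes$pathway, netB$nodes$pathway)
  ocr_cols <- grep("^ocr_", names(netA$nodes), value = TRUE)
  expect_length(ocr_cols, 3L)
  row_sums <- rowSums(as.matrix(netA$nodes[, ocr_cols]))
  expect_true(all(abs(row_sums[!is.na(row_sums)] - 1) < 1e-9))
  expect_equal(netA$nodes[, ocr_cols],
               as.data.frame(oc$ocr["A", netA$nodes$pathway, ],
                             col.names = ocr_cols),
               ignore_attr = TRUE)

  f <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, f)
  expect_identical(readLines(f), "P1\tshares\tP2")
  g <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(netA, g)
  gr <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(gr), nrow(netA$nodes))
  expect_true(all(c("n_genes", "surv_p") %in%
                    igraph::vertex_attr_names(gr)))
})
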