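mk_mirna <- function() {
  omics_matrix(matrix(c(2, 4, 6, 1, 3, 5), 3, 2,
                      dimnames = list(c("miR-1", "miR-2", "miR-3"),
                                      c("S1", "S2"))), "mirna")
}
mk_map <- function(entries) {
  structure(list(kind = "mirna_target", entries = entries),
            class = "feature_gene_map")
}

test_that("miRNA aggregation averages targeting miRNAs and zeros the rest", {
  m <- mk_mirna()
  map <- mk_map(list(`miR-1` = c("GA", "GB"), `miR-2` = "GA", `miR-9` = "GC"))
  out <- mirna_to_gene(m, map, c("GA", "GB", "GC"))
  expect_equal(unname(out$values["GA", ]), c(3, 2))   # mean of miR-1, miR-2
  expect_equal(unname(out$values["GB", ]), c(2, 1))   # miR-1 only
  expect_equal(unname(out$values["GC", ]), c(0, 0))   # miR-9 absent from matrix
  expect_identical(out$kind, "mirna")

  expect_error(mirna_to_gene(m, mk_map(list(`miR-x` = "GA")), c("GA")),
               "no miRNA")
})

test_that("miRNA aggregation is invariant to map order and column permutation", {
  m <- mk_mirna()
  map1 <- mk_map(list(`miR-1` = "GA", `miR-2` = "GA", `miR-3` = "GB"))
  map2 <- mk_map(list(`miR-3` = "GB", `miR-2` = "GA", `miR-1` = "GA"))
  o1 <- mirna_to_gene(m, map1, c("GA", "GB"))
  o2 <- mirna_to_gene(m, map2, c("GA", "GB"))
  expect_equal(o1$values, o2$values)

  m_perm <- omics_matrix(m$values[, c("S2", "S1")], "mirna")
  o3 <- mirna_to_gene(m_perm, map1, c("GA", "GB"))
  expect_equal(o3$values[, c("S1", "S2")], o1$values)
})

mk_meth_fixture <- function() {
  probes <- data.frame(
    probe = c("p1", "p2", "p3", "p4", "p5", "p6"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    # G1 on +, TSS 10000: window [8000, 10000)
    pos = c(9000L, 8000L, 10000L, 10500L, 11000L, 9500L),
    gene = c("G1", "G1", "G1", "G1", "G2", "G1"),
    tss = c(10000L, 10000L, 10000L, 10000L, 10500L, 10000L),
    strand = c("+", "+", "+", "+", "-", "+"),
    stringsAsFactors = FALSE)
  vals <- matrix(c(0.2, 0.4, 0.9, 0.9, 0.6, 0.5,
                   0.4, 0.6, 0.1, 0.1, 0.8, 0.5), 6, 2,
                 dimnames = list(probes$probe, c("S1", "S2")))
  list(meth = omics_matrix(vals, "methylation"),
       map = structure(list(kind = "probe_promoter", entries = probes),
                       class = "feature_gene_map"))
}

test_that("methylation aggregation applies the strand-aware promoter window", {
  fx <- mk_meth_fixture()
  out <- suppressWarnings(
    methylation_to_gene(fx$meth, fx$map, c("G1", "G2", "G3"), 2000L))
  # G1 (+): p1 at distance 1000 in; p2 at exactly 2000 in (outer edge
  # inclusive); p3 at TSS excluded; p4 downstream excluded; p6 wrong chrom
  expect_equal(unname(out$values["G1", ]), c(mean(c(0.2, 0.4)), mean(c(0.4, 0.6))))
  # G2 (-): p5 at pos 11000, TSS 10500 -> distance 500 downstream of TSS on
  # the minus strand = upstream -> included
  expect_equal(unname(out$values["G2", ]), c(0.6, 0.8))
  expect_equal(unname(out$values["G3", ]), c(0, 0))
  expect_warning(methylation_to_gene(fx$meth, fx$map, c("G1", "G2"), 2000L),
                 "chromosome")
})

test_that("layer normalization maps rows to [0,1] and zeroes constants", {
  m <- omics_matrix(matrix(c(2, 4, 6, 5, 5, 5), 2, 3, byrow = TRUE,
                           dimnames = list(c("g1", "g2"), c("S1", "S2", "S3"))),
                    "mrna")
  out <- normalize_layer(m, "minmax_per_gene")
  expect_equal(unname(out$values["g1", ]), c(0, 0.5, 1))
  expect_equal(unname(out$values["g2", ]), c(0, 0, 0))
  expect_equal(normalize_layer(m, "none")$values, m$values)
  g <- normalize_layer(m, "minmax_global")
  expect_equal(range(g$values), c(0, 1))
})

test_that("tensor assembly intersects axes and recovers layer slices", {
  l1 <- omics_matrix(matrix(1:6 / 6, 3, 2,
                            dimnames = list(c("g1", "g2", "g3"), c("S1", "S2"))),
                     "mrna")
  l2 <- omics_matrix(matrix(7:14 / 14, 4, 2,
                            dimnames = list(c("g0", "g1", "g2", "g3"),
                                            c("S2", "S1"))), "mirna")
  tens <- assemble_tensor(list(l1, l2))
  expect_equal(dim(tens), c(2L, 3L, 2L))
  expect_identical(dimnames(tens)[[2]], c("g1", "g2", "g3"))
  # slicing omics k recovers the input layer on the intersection
  expect_equal(tens["S1", , "mrna"], l1$values[, "S1"])
  expect_equal(tens["S2", , "mirna"], l2$values[c("g1", "g2", "g3"), "S2"])

  l3 <- omics_matrix(matrix(1:2 / 2, 1, 2,
                            dimnames = list("gX", c("S1", "S2"))), "other")
  expect_error(assemble_tensor(list(l1, l3)), "gene intersection")
  l4 <- omics_matrix(matrix(1:3 / 3, 3, 1,
                            dimnames = list(c("g1", "g2", "g3"), "SX")), "other")
  expect_error(assemble_tensor(list(l1, l4)), "sample intersection")

  single <- assemble_tensor(list(l1))
  expect_equal(dim(single)[3], 1L)

  neg <- omics_matrix(matrix(c(-1, 1, 2, 3, 4, 5), 3, 2,
                             dimnames = dimnames(l1$values)), "mrna")
  expect_error(assemble_tensor(list(neg)), "nonnegative")
})
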