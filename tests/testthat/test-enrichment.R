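test_that("gene loading normalization z-scores (population sd) and shifts", {
  G <- cbind(c(1, 2, 3))
  out <- normalize_gene_loadings(G)
  # z = (x - 2)/0.8165 -> (-1.2247, 0, 1.2247), shifted to min 0
  expect_equal(unname(out[, 1]), c(0, 1.2247449, 2.4494897), tolerance = 1e-6)

  expect_warning(out2 <- normalize_gene_loadings(cbind(c(5, 5, 5))),
                 "zero variance")
  expect_equal(unname(out2[, 1]), c(0, 0, 0))

  # monotone transform: ordering preserved
  x <- c(0.1, 0.9, 0.4, 0.7)
  out3 <- normalize_gene_loadings(cbind(x))
  expect_equal(order(out3[, 1]), order(x))
  expect_equal(min(out3[, 1]), 0)
})

test_that("rank weights are the assigned-component mix of gene loadings", {
  # one assigned feature, g' column (1,2), s' = 0.5 -> r = (0.5, 1)
  S <- rbind(c(1, 0.5, 0))  # after min-max scaling: (1, 0.5, 0)
  G <- cbind(c(1, 2), c(9, 9), c(9, 9))
  d <- fake_decomp(S, G, matrix(runif(6), 2, 3))
  a <- structure(list(
    scaled = matrix(c(1, 0.5, 0), 1, 3,
                    dimnames = list("S01", as.character(1:3))),
    cdf = matrix(0.5, 1, 3), assigned = list(S01 = 2L),
    threshold = 0.6, features = 1:3), class = "mopa_assignment")
  Gp <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3,
               dimnames = list(c("g1", "g2"), as.character(1:3)))
  w <- rank_weights(Gp, a)
  expect_equal(unname(w$r[1, ]), 0.5 * c(3, 4))

  # two features with s' = (1, 1): weights add
  a$assigned <- list(S01 = c(1L, 2L))
  a$scaled[1, ] <- c(1, 1, 0)
  w2 <- rank_weights(Gp, a)
  expect_equal(unname(w2$r[1, ]), c(1 + 3, 2 + 4))
})

test_that("rank weights match a naive double-loop oracle", {
  set.seed(14)
  n <- 6; R <- 5; ng <- 12
  S <- matrix(runif(n * R), n, R)
  d <- fake_decomp(S, matrix(runif(ng * R), ng, R), matrix(runif(2 * R), 2, R))
  a <- assign_features(d, threshold = 0.5)
  Gp <- normalize_gene_loadings(d$G, 1:R)
  rownames(Gp) <- rownames(d$G)
  w <- rank_weights(Gp, a)
  for (i in seq_len(n)) {
    for (j in seq_len(ng)) {
      acc <- 0
      for (f in a$assigned[[i]])
        acc <- acc + Gp[j, as.character(f)] * a$scaled[i, match(f, 1:R)]
      expect_equal(unname(w$r[i, j]), unname(acc), tolerance = 1e-12)
    }
  }
})

test_that("the KS walk reproduces the hand-computed example and end condition", {
  r <- c(4, 3, 2, 1)
  names(r) <- paste0("g", 1:4)
  # members at sorted ranks {1, 3}
  d <- ks_walk(r, order = 1:4, members = c(1, 3))
  expect_equal(d, c(4 / 6, 4 / 6 - 1 / 2, 1, 0) - c(0, 0, 1 / 2, 0),
               tolerance = 1e-12)
  expect_equal(d, c(2 / 3, 1 / 6, 1 / 2, 0), tolerance = 1e-12)
  expect_equal(mes_from_walk(d), 2 / 3, tolerance = 1e-12)
  expect_equal(d[4], 0, tolerance = 1e-12)

  # top-packed members: walk peaks at exactly 1
  d_top <- ks_walk(r, 1:4, members = c(1, 2))
  expect_equal(max(d_top), 1, tolerance = 1e-12)
  expect_equal(mes_from_walk(d_top), 1, tolerance = 1e-12)

  # bottom-packed members: trough of exactly -1 at the last non-member
  d_bot <- ks_walk(r, 1:4, members = c(3, 4))
  expect_equal(min(d_bot), -1, tolerance = 1e-12)
  expect_equal(mes_from_walk(d_bot), -1, tolerance = 1e-12)

  expect_error(ks_walk(r, 1:4, members = 1:4), "whole")
  expect_error(ks_walk(r, 1:4, members = integer(0)), "no member")
})

test_that("score_all agrees with the brute-force oracle on random instances", {
  set.seed(77)
  for (rep in 1:50) {
    q <- sample(5:50, 1)
    genes <- sprintf("g%03d", seq_len(q))
    n <- sample(2:4, 1)
    r <- matrix(runif(n * q, 0, 5), n, q, dimnames = list(paste0("S", 1:n), genes))
    m <- sample(2:(q - 1), 1)
    members <- sample(genes, m)
    w <- structure(list(r = r,
                        order = t(apply(r, 1, function(x) order(-x, genes))),
                        genes = genes), class = "mopa_rank_weights")
    gs <- gene_set_collection(list(P = members))
    es <- score_all(w, gs, min_overlap = 2)
    for (i in seq_len(n)) {
      want <- oracle_mes(r[i, ], members, genes)$mes
      expect_equal(unname(es$mes[i, "P"]), want, tolerance = 1e-9)
    }
  }
})

test_that("scores are bounded, scale-invariant, and identical rows score alike", {
  set.seed(99)
  q <- 40
  genes <- sprintf("g%02d", 1:q)
  r <- matrix(runif(3 * q, 0, 2), 3, q, dimnames = list(paste0("S", 1:3), genes))
  r[3, ] <- r[1, ] * 7.3   # positive rescaling of sample 1
  w <- structure(list(r = r,
                      order = t(apply(r, 1, function(x) order(-x, genes))),
                      genes = genes), class = "mopa_rank_weights")
  sets <- lapply(1:10, function(i) sample(genes, sample(2:20, 1)))
  names(sets) <- paste0("P", 1:10)
  es <- score_all(w, gene_set_collection(sets))
  expect_true(all(es$mes >= -1 & es$mes <= 1))
  expect_equal(es$mes[1, ], es$mes[3, ], tolerance = 1e-12)
})

test_that("pathways with insufficient overlap are skipped with a reason", {
  genes <- c("g1", "g2", "g3", "g4")
  r <- matrix(c(4, 3, 2, 1), 1, 4, dimnames = list("S1", genes))
  w <- structure(list(r = r, order = matrix(1:4, 1), genes = genes),
                 class = "mopa_rank_weights")
  gs <- gene_set_collection(list(ok = c("g1", "g3"), tiny = "g2",
                                 alien = c("x1", "x2")))
  es <- score_all(w, gs, min_overlap = 2)
  expect_identical(colnames(es$mes), "ok")
  expect_setequal(es$skipped$pathway, c("tiny", "alien"))
  expect_true(all(es$skipped$reason == "insufficient overlap"))
  expect_error(score_all(w, gene_set_collection(list(tiny = "g2"))),
               "no scorable")
})
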