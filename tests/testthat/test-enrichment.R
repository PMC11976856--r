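# enrichment module: fold-change ranking, running-sum ES vs brute force,
# permutation GSEA, NES clustering, over-representation.

test_that("protein fold changes rank and filter as specified", {
  set.seed(2)
  ctrl <- matrix(2^rnorm(30, 10), nrow = 10,
                 dimnames = list(sprintf("P%02d", 1:10), paste0("r", 1:3)))
  tr <- ctrl
  expect_equal(compute_protein_fold_change(tr, ctrl)$score, rep(1, 10))
  tr["P04", ] <- 2 * ctrl["P04", ]
  rk <- compute_protein_fold_change(tr, ctrl)
  expect_equal(rk$protein[1], "P04")
  expect_equal(rk$score[1], 2)
  # min_obs filter drops under-observed proteins with a log line
  tr2 <- tr; tr2["P07", 2:3] <- NA
  expect_message(rk2 <- compute_protein_fold_change(tr2, ctrl, min_obs = 2),
                 "dropped 1 of 10")
  expect_false("P07" %in% rk2$protein)
  rownames(tr2) <- paste0("X", rownames(tr2))
  expect_error(compute_protein_fold_change(tr2, ctrl), "no shared proteins")
  # deterministic id tie-break on equal scores
  eq <- ranked_from(c("b", "a", "c"), c(1, 1, 2))
  expect_equal(eq$protein, c("c", "a", "b"))
})

test_that("enrichment score reproduces the hand-enumerated running sums", {
  r4 <- ranked_from(letters[1:4], c(4, 3, 2, 1))
  expect_equal(enrichment_score(r4, "a", weight = 0)$es, 1)   # top member
  expect_equal(enrichment_score(r4, "d", weight = 0)$es, -1)  # bottom member
  r <- ranked_from(c("p1", "p2", "p3", "p4"), c(3, 2, 1, 0.5))
  es <- enrichment_score(r, c("p1", "p3"), weight = 1)
  expect_equal(es$running_sum, c(0.75, 0.25, 0.5, 0))
  expect_equal(es$es, 0.75)
  expect_equal(es$leading_edge, "p1")
  expect_error(enrichment_score(r, "zz"), "no overlap")
  expect_error(enrichment_score(r, c("p1", "p2", "p3", "p4")),
               "whole ranked universe")
})

test_that("ES equals the brute-force enumeration on exhaustive subsets", {
  set.seed(3)
  scores <- sort(round(abs(rnorm(6, 0, 2)) + 0.1, 3), decreasing = TRUE)
  ids <- sprintf("g%d", 1:6)
  rk <- ranked_from(ids, scores)
  for (w in c(0, 1, 1.5)) {
    for (k in 1:5) {
      combos <- combn(6, k)
      for (j in seq_len(ncol(combos))) {
        hit <- logical(6); hit[combos[, j]] <- TRUE
        got <- enrichment_score(rk, ids[hit], weight = w)
        want <- bf_enrichment_score(scores, hit, w)
        expect_equal(got$es, want$es, tolerance = 1e-12)
        expect_equal(got$running_sum, want$run, tolerance = 1e-12)
      }
    }
  }
})

test_that("ES matches brute force on random N = 12 instances and stays in [-1, 1]", {
  set.seed(4)
  for (i in 1:60) {
    n <- 12
    scores <- sort(rnorm(n), decreasing = TRUE)
    ids <- sprintf("g%02d", 1:n)
    k <- sample(1:(n - 1), 1)
    hit <- logical(n); hit[sample(n, k)] <- TRUE
    w <- sample(c(0, 1, 2), 1)
    got <- enrichment_score(ranked_from(ids, scores)[order(-scores), ],
                            ids[hit], weight = w)
    want <- bf_enrichment_score(scores, hit, w)
    expect_equal(got$es, want$es, tolerance = 1e-12)
    expect_true(abs(got$es) <= 1 + 1e-12)
  }
})

test_that("weight 0 reduces ES to the KS statistic of hit positions", {
  set.seed(6)
  n <- 10
  scores <- sort(rnorm(n), decreasing = TRUE)
  ids <- sprintf("g%d", 1:n)
  hit <- logical(n); hit[c(1, 4, 9)] <- TRUE
  es <- enrichment_score(ranked_from(ids, scores)[order(-scores), ],
                         ids[hit], weight = 0)$es
  # independent KS: sup of (ECDF of hit positions - ECDF of miss positions)
  ph <- cumsum(hit) / sum(hit)
  pm <- cumsum(!hit) / sum(!hit)
  dev <- ph - pm
  expect_equal(abs(es), max(abs(dev)), tolerance = 1e-12)
})

test_that("negating and reversing the ranking negates every ES", {
  set.seed(7)
  n <- 15
  scores <- sort(rnorm(n, 0, 2), decreasing = TRUE)
  ids <- sprintf("g%02d", 1:n)
  members <- sample(ids, 5)
  a <- enrichment_score(ranked_from(ids, scores), members, weight = 1)$es
  b <- enrichment_score(ranked_from(ids, -scores), members, weight = 1)$es
  expect_equal(b, -a, tolerance = 1e-12)
})

test_that("gsea_preranked is seed-reproducible and finds a planted set", {
  sets <- toy_sets(8, 12)
  mats <- generate_protein_matrix(300, sets, list(SET03 = 2), n_reps = 3,
                                  seed = 10)
  rk <- compute_protein_fold_change(mats$treated, mats$control)
  res <- gsea_preranked(rk, sets, n_perm = 1000, weight = 1, seed = 99)
  res2 <- gsea_preranked(rk, sets, n_perm = 1000, weight = 1, seed = 99)
  expect_identical(res, res2)
  planted <- res[res$set == "SET03", ]
  expect_gt(planted$nes, 1.5)
  expect_lt(planted$fdr_q, 0.05)
  expect_true(all(planted$leading_edge[[1]] %in% sets$SET03))
  expect_equal(sign(res$nes[res$nes_defined]),
               sign(res$es[res$nes_defined]))
  expect_error(gsea_preranked(rk, sets, n_perm = 50, seed = 1), ">= 100")
  # sets outside the universe are skipped with a warning, not dropped silently
  sets2 <- c(sets, list(ALIEN = c("Z1", "Z2")))
  expect_warning(res3 <- gsea_preranked(rk, sets2, n_perm = 100, seed = 1),
                 "ALIEN")
  expect_false("ALIEN" %in% res3$set)
})

test_that("nominal p matches the exhaustive permutation null on a tiny universe", {
  set.seed(11)
  n <- 10; k <- 3
  scores <- sort(rnorm(n, 0, 1.5), decreasing = TRUE)
  ids <- sprintf("g%d", 1:n)
  members <- ids[c(1, 2, 5)]
  rk <- ranked_from(ids, scores)[order(-scores), ]
  res <- gsea_preranked(rk, list(S = members), n_perm = 2000, weight = 1,
                        seed = 12)
  null_es <- bf_exhaustive_null(scores, k, weight = 1)
  obs <- enrichment_score(rk, members, weight = 1)$es
  same <- if (obs >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  p_exh <- mean(abs(same) >= abs(obs))
  tol <- 4 * sqrt(max(p_exh, 0.01) * (1 - min(p_exh, 0.99)) / 2000) + 2 / 2000
  expect_lt(abs(res$p_value - p_exh), tol)
})

test_that("NES clustering reproduces the 3-leaf hand dendrogram", {
  m <- rbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(1, 3, 2))
  # cor(A,B)=1 -> d=0; cor(A,C)=cor(B,C)=0.5 -> d=0.5
  cl <- cluster_nes(m, axis = "rows", linkage = "average")
  expect_equal(cl$row_tree$height, c(0, 0.5), tolerance = 1e-12)
  first <- sort(cl$row_tree$merge[1, ])
  expect_equal(first, c(-2, -1))          # A and B merge first, at 0
  expect_true(grepl("^\\(", cl$row_newick))
  # identical rows merge first at distance 0 under euclidean too
  cle <- cluster_nes(m, axis = "rows", distance = "euclidean")
  expect_equal(cle$row_tree$height[1], 0)
})

test_that("clustering is permutation-equivariant with monotone heights", {
  set.seed(14)
  m <- matrix(rnorm(40), nrow = 8,
              dimnames = list(sprintf("r%d", 1:8), sprintf("c%d", 1:5)))
  cl <- cluster_nes(m, axis = "rows")
  expect_true(all(diff(cl$row_tree$height) >= -1e-12))
  perm <- sample(8)
  clp <- cluster_nes(m[perm, ], axis = "rows")
  expect_equal(sort(clp$row_tree$height), sort(cl$row_tree$height),
               tolerance = 1e-12)
  # same partition at every merge height, up to relabeling
  for (h in cl$row_tree$height + 1e-9) {
    a <- stats::cutree(cl$row_tree, h = h)
    b <- stats::cutree(clp$row_tree, h = h)[rownames(m)]
    expect_equal(length(unique(a)), length(unique(b)))
    expect_true(all(tapply(b[names(a)], a, function(x)
      length(unique(x)) == 1L)))
  }
  bad <- m; bad[3, ] <- NA
  expect_error(cluster_nes(bad, axis = "rows"), "r3")
})

test_that("over-representation matches the closed-form hypergeometric", {
  ids <- sprintf("P%02d", 1:10)
  scores <- ranked_from(ids, c(3, 2.5, 2, 1.8, 1.2, 1, 0.9, 0.8, 0.7, 0.6))
  pv <- setNames(c(rep(0.01, 4), rep(0.5, 6)), scores$protein)
  sets <- list(S = scores$protein[1:5])
  res <- overrepresentation_test(scores, pv, sets, fc_cutoff = 1.5,
                                 p_cutoff = 0.05)
  # 4 selected (fc >= 1.5 & p < 0.05), all inside the 5-member set
  expect_equal(res$overlap, 4)
  expect_equal(res$p_hyper, 5 / 210, tolerance = 1e-12)
  expect_equal(res$expected, 4 * 5 / 10)
  expect_true(res$identified)

  # overlap equal to expectation gives z = 0
  sets2 <- list(S = scores$protein)   # whole universe
  res2 <- overrepresentation_test(scores, pv, sets2)
  expect_equal(res2$z, 0)

  # threshold is a strict definition: 1.4 misses, 1.6 passes
  s2 <- ranked_from(c("a", "b"), c(1.6, 1.4))
  pv2 <- c(a = 0.01, b = 0.01)
  r2 <- overrepresentation_test(s2, pv2, list(S = c("a", "b")))
  expect_equal(attr(r2, "n_selected"), 1L)
  # down-regulation side: score <= 1/1.5 selects
  s3 <- ranked_from(c("a", "b"), c(1.0, 0.5))
  r3 <- overrepresentation_test(s3, c(a = 0.01, b = 0.01),
                                list(S = c("a", "b")))
  expect_equal(attr(r3, "n_selected"), 1L)
  expect_warning(
    overrepresentation_test(s2, c(a = 0.9, b = 0.9), list(S = "a")),
    "no protein passes")
})

test_that("protein_pvalues flags shifted proteins and not nulls", {
  set.seed(15)
  ctrl <- matrix(2^rnorm(40, 10, 0.3), nrow = 10,
                 dimnames = list(sprintf("P%02d", 1:10), paste0("r", 1:4)))
  tr <- ctrl * matrix(2^rnorm(40, 0, 0.3), nrow = 10)
  tr["P01", ] <- tr["P01", ] * 16
  pv <- protein_pvalues(tr, ctrl)
  expect_lt(pv[["P01"]], 0.05)
  expect_gt(median(pv[-1]), 0.1)
})
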