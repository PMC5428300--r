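test_that("NJ recovers topology and branch lengths from an additive matrix", {
  # tree ((A:2,B:3):1,C:2,D:4) with the internal edge of length 1
  taxa <- c("A", "B", "C", "D")
  d <- matrix(c(0, 5, 5, 7,
                5, 0, 6, 8,
                5, 6, 0, 6,
                7, 8, 6, 0), 4, 4, dimnames = list(taxa, taxa))
  tr <- nj_tree(d)
  expect_setequal(tr$tip.label, taxa)
  expect_true(has_clade(tr, c("A", "B")))
  # additive matrices are recovered exactly: path lengths reproduce d
  pd <- ape::cophenetic.phylo(tr)[taxa, taxa]
  expect_equal(unname(pd), unname(d), tolerance = 1e-9)
})

test_that("three taxa use the closed-form branch lengths", {
  d <- matrix(c(0, 2, 4,
                2, 0, 6,
                4, 6, 0), 3, 3, dimnames = list(c("x", "y", "z"),
                                                c("x", "y", "z")))
  tr <- nj_tree(d)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len[c("x", "y", "z")]), c(0, 2, 4))
})

test_that("NJ topologies agree with an independent implementation", {
  skip_if_not_installed("ape")
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(5:9, 1)
    # random tree-derived distances plus small noise keep it near-additive
    base <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.3))
    d <- ape::cophenetic.phylo(base)
    d <- d + matrix(runif(n * n, 0, 0.005), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    expect_equal(rf_distance(nj_tree(d), ape::nj(as.dist(d))), 0L,
                 info = paste("seed", seed))
  }
})

test_that("non-symmetric or tiny matrices are rejected", {
  d <- matrix(runif(16), 4, 4)
  expect_error(nj_tree(d), "symmetric")
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("RF distance matches brute-force bipartition comparison", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)

  # caterpillar splits: ab, abc, abcd; balanced: ab, abc (= def), de
  # symmetric difference: {abcd} vs {de}
  cat6 <- ape::read.tree(text = "(((((a,b),c),d),e),f);")
  bal6 <- ape::read.tree(text = "(((a,b),c),((d,e),f));")
  expect_equal(rf_distance(cat6, bal6), 2L)

  skip_if_not_installed("phangorn")
  for (seed in 1:6) {
    set.seed(seed)
    x <- ape::rtree(7); y <- ape::rtree(7)
    x$tip.label <- paste0("t", 1:7); y$tip.label <- paste0("t", 1:7)
    expect_equal(rf_distance(x, y),
                 as.integer(phangorn::RF.dist(ape::unroot(x),
                                              ape::unroot(y))),
                 info = paste("seed", seed))
  }
  expect_error(rf_distance(t1, ape::read.tree(text = "((a,b),(c,e));")),
               "leaf sets")
})

test_that("bootstrap support is 0/100 with one replicate and deterministic", {
  set.seed(61)
  aln <- random_alignment(5, 120, gap_prob = 0, n_prob = 0)
  tr1 <- bootstrap_support(aln, n_reps = 1, seed = 9)
  sup <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  # same seed: bit-identical newick; different seed may differ
  t_a <- bootstrap_support(aln, n_reps = 25, seed = 4)
  t_b <- bootstrap_support(aln, n_reps = 25, seed = 4)
  expect_identical(ape::write.tree(t_a), ape::write.tree(t_b))
})

test_that("well-supported clades reach near-certain bootstrap support", {
  # 4 taxa, 100 diagnostic columns for the (A,B) split, plus invariant bulk
  block <- function(ch, n) strrep(ch, n)
  rows <- c(A = paste0(block("A", 100), block("C", 400)),
            B = paste0(block("A", 100), block("C", 400)),
            C = paste0(block("G", 100), block("C", 400)),
            D = paste0(block("G", 100), block("C", 400)))
  # break the (A,B)/(C,D) symmetry with a few autapomorphies
  substr(rows["C"], 101, 110) <- "TTTTTTTTTT"
  aln <- msa(rows)
  tr <- bootstrap_support(aln, n_reps = 500, seed = 1)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(has_clade(tr, c("A", "B")))
  expect_gte(min(sup, na.rm = TRUE), 99)
})

test_that("a single informative column yields ~63% support", {
  # clades {A,B} vs {C,D} separated by exactly one variable column; taxa are
  # interleaved so the NJ tie-break on empty replicates does not fabricate
  # the tested split. P(column survives resampling) = 1-(1-1/L)^L ~ 0.632.
  L <- 1000
  base <- strrep("A", L - 1)
  rows <- c(A = paste0(base, "C"), C = paste0(base, "G"),
            B = paste0(base, "C"), D = paste0(base, "G"))
  tr <- bootstrap_support(msa(rows), n_reps = 1000, seed = 2)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_length(sup, 1L)
  expect_gt(sup, 55)
  expect_lt(sup, 72)
})

test_that("collapsing respects thresholds: identity at 0, star above 100", {
  set.seed(62)
  aln <- random_alignment(6, 300, gap_prob = 0, n_prob = 0)
  tr <- bootstrap_support(aln, n_reps = 50, seed = 3)
  same <- collapse_low_support(tr, 0)
  expect_equal(rf_distance(same, tr), 0L)
  star <- collapse_low_support(tr, 101)
  expect_equal(star$Nnode, 1L)
  expect_setequal(star$tip.label, tr$tip.label)
  # intermediate threshold: surviving splits are exactly the well-supported
  keep <- collapse_low_support(tr, 50)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_equal(length(superbarcode:::tree_bipartitions(keep)),
               sum(sup >= 50, na.rm = TRUE))
})
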