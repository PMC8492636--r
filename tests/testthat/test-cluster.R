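test_that("Jaccard similarity matches hand enumeration and conventions", {
  vals <- cbind(x = c(1, 1, 0, 1), y = c(1, 0, 1, 1))
  bm <- make_bm(vals, rep("p", 4), samples = c("x", "y"))
  expect_equal(jaccard_similarity(bm)["x", "y"], 0.5)  # a=2, b=1, c=1

  bm_id <- make_bm(cbind(c(1, 0, 1), c(1, 0, 1)), rep("p", 3))
  expect_equal(jaccard_similarity(bm_id)[1, 2], 1)

  bm_disj <- make_bm(cbind(c(1, 0), c(0, 1)), rep("p", 2))
  expect_equal(jaccard_similarity(bm_disj)[1, 2], 0)

  # both blank among co-scored bands: J = 1 by convention
  bm_blank <- make_bm(cbind(c(0, 0), c(0, 0)), rep("p", 2))
  expect_equal(jaccard_similarity(bm_blank)[1, 2], 1)

  # zero co-scored bands is an error naming the pair
  bm_na <- make_bm(cbind(c(1, NA), c(NA, 1)), c("p", "q")) # nolint
  expect_error(jaccard_similarity(bm_na), "no co-scored")
})

test_that("Jaccard is permutation-equivariant and its distance is metric", {
  set.seed(41)
  for (i in 1:10) {
    vals <- matrix(rbinom(60, 1, 0.5), 12, 5)
    vals[1, ] <- 1  # avoid all-blank co-score edge
    bm <- make_bm(vals, rep(paste0("p", 1:4), each = 3))
    sim <- jaccard_similarity(bm)
    expect_true(isSymmetric(sim))
    expect_equal(unname(diag(sim)), rep(1, 5))

    perm <- sample(5)
    bm_p <- make_bm(vals[, perm], rep(paste0("p", 1:4), each = 3),
                    samples = bm$samples[perm])
    sim_p <- jaccard_similarity(bm_p)
    expect_equal(sim_p[bm$samples, bm$samples], sim)

    d <- 1 - sim
    for (a in 1:3) for (b in 2:4) for (cc in 3:5) {
      expect_lte(d[a, b], d[a, cc] + d[cc, b] + 1e-12)
    }
  }
})

test_that("UPGMA reproduces hand-executed merges and heights", {
  # two leaves at distance 0.4 -> one node at height 0.2
  sim2 <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))
  t2 <- upgma(sim2)
  expect_equal(t2$height, 0.2)
  expect_equal(write_newick(t2), "(A:0.2,B:0.2);")

  # d(A,B)=0.2, d(A,C)=d(B,C)=0.6: merge (A,B) at 0.1, then C at 0.3
  d3 <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(1 - d3)
  expect_equal(t3$height, c(0.1, 0.3))
  expect_equal(write_newick(t3), "((A:0.1,B:0.1):0.2,C:0.3);")

  expect_error(upgma(matrix(c(1, 0.2, 0.4, 1), 2,
                            dimnames = list(c("A", "B"), c("A", "B")))),
               "symmetric")
})

test_that("UPGMA heights are monotone and exact on ultrametric input", {
  # build an ultrametric distance from a known tree:
  # ((A,B):h1, (C,D):h2) with cophenetic depths
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.4
  for (x in c("A", "B")) for (y in c("C", "D")) {
    d[x, y] <- d[y, x] <- 0.8
  }
  tree <- upgma(1 - d)
  expect_true(all(diff(tree$height) >= -1e-12))
  # cophenetic merge heights are halved distances; doubling recovers the
  # ultrametric input exactly
  coph <- stats::cophenetic(as.hclust(tree))
  expect_equal(as.matrix(coph)[rownames(d), colnames(d)] * 2,
               d, tolerance = 1e-12)
})

test_that("UPGMA agrees with average-linkage hclust on random matrices", {
  set.seed(43)
  for (i in 1:8) {
    n <- sample(4:8, 1)
    vals <- matrix(rbinom(n * 30, 1, 0.5), 30, n)
    vals[1, ] <- 1
    bm <- make_bm(vals, rep(paste0("p", 1:5), each = 6),
                  samples = paste0("g", seq_len(n)))
    sim <- jaccard_similarity(bm)
    tree <- upgma(sim)
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
    # same merge heights (tie order may differ; heights must agree)
    expect_equal(tree$height, hc$height / 2, tolerance = 1e-12)
    # identical cophenetic distances when all merge heights are distinct
    if (min(diff(hc$height)) > 1e-9) {
      expect_equal(stats::cophenetic(as.hclust(tree)) * 2,
                   stats::cophenetic(hc), tolerance = 1e-12)
    }
  }
})

test_that("Newick export parses back to the same cophenetic structure", {
  skip_if_not_installed("ape")
  sim <- matrix(c(1, .8, .4, .4,
                  .8, 1, .4, .4,
                  .4, .4, 1, .7,
                  .4, .4, .7, 1), 4,
                dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- upgma(sim)
  phy <- ape::read.tree(text = write_newick(tree))
  expect_setequal(phy$tip.label, LETTERS[1:4])
  # tip-to-tip path lengths are twice the merge heights
  cp <- ape::cophenetic.phylo(phy)[LETTERS[1:4], LETTERS[1:4]]
  hc_cp <- as.matrix(stats::cophenetic(as.hclust(tree)))
  expect_equal(cp, 2 * hc_cp[LETTERS[1:4], LETTERS[1:4]], tolerance = 1e-9)
})

test_that("cluster cuts honour k with stable numbering and tie detection", {
  d3 <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(1 - d3)
  expect_equal(unname(cut_clusters(tree, 1)), rep(1L, 3))
  expect_equal(unname(cut_clusters(tree, 3)), 1:3)
  k2 <- cut_clusters(tree, 2)
  expect_equal(k2[["A"]], k2[["B"]])
  expect_false(k2[["A"]] == k2[["C"]])
  expect_error(cut_clusters(tree, 4), "k must be")

  # two merges at identical heights make k = 2 ambiguous
  d4 <- matrix(0.8, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d4) <- 0
  d4["A", "B"] <- d4["B", "A"] <- 0.2
  d4["C", "D"] <- d4["D", "C"] <- 0.2
  t4 <- upgma(1 - d4)
  expect_error(cut_clusters(t4, 3), "ambiguous")
  k2 <- cut_clusters(t4, 2)
  expect_equal(unname(k2), c(1L, 1L, 2L, 2L))
})
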