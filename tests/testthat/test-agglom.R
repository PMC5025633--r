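threePointD <- function() {
  D <- matrix(c(0, .1, .9, .1, 0, .8, .9, .8, 0), 3, 3)
  rownames(D) <- colnames(D) <- c("a", "b", "c")
  D
}

test_that("linkages agree with hand-computed merge heights", {
  D <- threePointD()
  avg <- agglomerate(D, "average")
  expect_identical(avg$merge, rbind(c(-1L, -2L), c(-3L, 1L)))
  expect_equal(avg$height, c(0.1, 0.85))
  expect_equal(agglomerate(D, "complete")$height, c(0.1, 0.9))
  expect_equal(agglomerate(D, "single")$height, c(0.1, 0.8))
  expect_error(agglomerate(matrix(0, 1, 1)), "at least 2")
})

test_that("cutting undoes the last K-1 merges with canonical labels", {
  tr <- agglomerate(threePointD())
  expect_identical(unname(cutClusters(tr, 1)), c(1L, 1L, 1L))
  expect_identical(unname(cutClusters(tr, 3)), c(1L, 2L, 3L))
  expect_identical(unname(cutClusters(tr, 2)), c(1L, 1L, 2L))
  expect_named(cutClusters(tr, 2), c("a", "b", "c"))
  expect_error(cutClusters(tr, 0), "K must be")
  expect_error(cutClusters(tr, 4), "K must be")
})

test_that("merge sequences match the brute-force re-scan oracle", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    D <- randomDissimilarity(n, grid = rep %% 2 == 0)
    for (lk in c("average", "complete", "single")) {
      got <- agglomerate(D, lk)
      want <- bruteAgglom(D, lk)
      expect_identical(got$merge, want$merge)
      expect_equal(got$height, want$height, tolerance = 1e-14)
      expect_true(all(diff(got$height) >= -1e-14))
    }
  }
})

test_that("tie-free trees agree with stats::hclust partitions and heights", {
  set.seed(31)
  for (rep in 1:4) {
    D <- randomDissimilarity(10, grid = FALSE)
    for (lk in c("average", "complete", "single")) {
      ours <- agglomerate(D, lk)
      ref <- stats::hclust(stats::as.dist(D), method = lk)
      expect_equal(sort(ours$height), sort(ref$height), tolerance = 1e-12)
      for (K in 2:6) {
        expect_equal(
          adjustedRand(cutClusters(ours, K), stats::cutree(ref, K)), 1
        )
      }
    }
  }
})

test_that("relabeling observations permutes cuts consistently", {
  set.seed(41)
  D <- randomDissimilarity(9, grid = FALSE) # tie-free so order cannot matter
  p <- sample(9)
  Dp <- D[p, p]
  for (K in c(2, 4)) {
    base <- cutClusters(agglomerate(D), K)
    perm <- cutClusters(agglomerate(Dp), K)
    expect_equal(adjustedRand(perm, base[p]), 1)
  }
})

test_that("an ultrametric dissimilarity is recovered by all linkages", {
  # two nested cherries: {a,b} at .2, {c,d} at .3, root at .9
  D <- matrix(.9, 4, 4)
  D[1, 2] <- D[2, 1] <- .2
  D[3, 4] <- D[4, 3] <- .3
  diag(D) <- 0
  rownames(D) <- colnames(D) <- letters[1:4]
  for (lk in c("average", "complete", "single")) {
    tr <- agglomerate(D, lk)
    expect_equal(tr$height, c(.2, .3, .9))
    expect_identical(unname(cutClusters(tr, 2)), c(1L, 1L, 2L, 2L))
  }
})

test_that("Newick export carries merge heights and round-trips topology", {
  D2 <- matrix(c(0, .4, .4, 0), 2, 2)
  rownames(D2) <- colnames(D2) <- c("a", "b")
  expect_identical(toNewick(agglomerate(D2)), "(a:0.4,b:0.4);")

  tr <- agglomerate(threePointD())
  txt <- toNewick(tr)
  phy <- ape::read.tree(text = txt)
  # cherry {a,b} nested inside the root
  expect_identical(
    sort(ape::extract.clade(phy, ape::getMRCA(phy, c("a", "b")))$tip.label),
    c("a", "b")
  )
  set.seed(51)
  for (rep in 1:3) {
    D <- randomDissimilarity(8, grid = FALSE)
    tr <- agglomerate(D)
    phy <- ape::read.tree(text = toNewick(tr))
    expect_true(ape::all.equal.phylo(phy, ape::as.phylo(tr),
      use.edge.length = FALSE
    ))
    # root-to-leaf path length equals the root height for every leaf
    # (tolerance reflects the digits write.tree prints)
    depths <- ape::node.depth.edgelength(phy)[seq_len(8)]
    expect_equal(unname(depths), rep(max(tr$height), 8), tolerance = 1e-6)
  }
})

test_that("the fused cut path matches agglomerate + cutClusters", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    D <- randomDissimilarity(n, grid = rep %% 2 == 0)
    K <- sample(1:n, 1)
    for (lk in c("average", "complete", "single")) {
      code <- c(average = 0L, complete = 1L, single = 2L)[[lk]]
      expect_identical(
        catens:::.agglom_cut_core(D, code, K),
        unname(cutClusters(agglomerate(D, lk), K))
      )
    }
  }
})
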