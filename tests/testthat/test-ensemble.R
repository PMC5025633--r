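test_that("cluster-count draws are uniform on {kmin..kmax} and seeded", {
  expect_identical(drawClusterCounts(10, 3, 3, seed = 1), rep(3L, 10))
  d <- drawClusterCounts(500, 2, 8, seed = 2)
  expect_true(all(d %in% 2:8))
  expect_identical(d, drawClusterCounts(500, 2, 8, seed = 2))
  expect_error(drawClusterCounts(5, 1, 4), "kmin")
  # frequency of each value within 3 binomial standard errors of 1/7
  big <- drawClusterCounts(1e5, 2, 8, seed = 3)
  freq <- tabulate(big - 1L, 7) / 1e5
  se <- sqrt((1 / 7) * (6 / 7) / 1e5)
  expect_true(all(abs(freq - 1 / 7) < 3 * se))
})

test_that("the default kmax follows the ceiling square-root heuristic", {
  expect_identical(defaultKmax(53), 8L)
  expect_identical(defaultKmax(100), 10L)
  expect_identical(defaultKmax(4), 2L)
  expect_error(defaultKmax(3), "n >= 4")
})

test_that("the incidence matrix stores base cluster indices by column", {
  I <- buildIncidence(list(c(1, 1, 2), c(1, 2, 2)))
  expect_identical(unname(I), rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L)))
  expect_identical(ncol(buildIncidence(list(c(1, 2, 1)))), 1L)
  expect_error(buildIncidence(list(c(1, 1), c(1, 2, 2))), "same observations")
  expect_error(buildIncidence(list(c(1, 3, 1))), "empty cluster")
  # columns reproduce the input clusterings exactly
  set.seed(5)
  cls <- replicate(10, canonicalizeLabels <- {
    l <- sample(1:3, 12, replace = TRUE)
    match(l, unique(l))
  }, simplify = FALSE)
  I <- buildIncidence(cls)
  for (b in seq_along(cls)) expect_identical(unname(I[, b]), cls[[b]])
})

test_that("ensembled dissimilarity is the fraction of separating clusterings", {
  I <- buildIncidence(list(c(1, 1, 2), c(1, 2, 2)))
  expect_identical(
    unname(ensembleDissimilarity(I))[1:3, 1:3],
    rbind(c(0, .5, 1), c(.5, 0, .5), c(1, .5, 0))
  )
  # identical columns give the 0/1 co-membership complement
  I2 <- buildIncidence(rep(list(c(1, 1, 2, 2)), 7))
  co <- outer(c(1, 1, 2, 2), c(1, 1, 2, 2), "!=") * 1
  expect_identical(unname(ensembleDissimilarity(I2))[1:4, 1:4], co)
  # random incidence: entrywise equal to a double-loop recount
  set.seed(9)
  I3 <- matrix(sample.int(4, 15 * 30, replace = TRUE), 15, 30)
  T3 <- ensembleDissimilarity(I3)
  expect_identical(unname(T3)[1:15, 1:15], recountHamming(I3, "mismatch"))
  # conservation: separation fraction + co-clustering fraction = 1
  coFrac <- matrix(0, 15, 15)
  for (b in 1:30) coFrac <- coFrac + outer(I3[, b], I3[, b], "==")
  coFrac <- coFrac / 30
  expect_equal(unname(T3)[1:15, 1:15] + coFrac, matrix(1, 15, 15),
    tolerance = 1e-12
  )
})

test_that("a fixed-K ensemble collapses to the plain K-cut", {
  set.seed(17)
  d <- generateCategorical(30, K = 3, separation = "high", seed = 3)
  K <- 4L
  ens <- ensembleCluster(d$X, B = 25, kmin = K, kmax = K, seed = 8)
  base <- cutClusters(agglomerate(hammingMatrix(d$X)), K)
  # T is exactly the 0/1 complement of the K-cut co-membership
  expect_identical(
    unname(ensembleDistances(ens))[1:30, 1:30],
    unname(outer(base, base, "!=") * 1)
  )
  # and the final clustering at K reproduces the base cut
  expect_identical(unname(cutClusters(finalTree(ens), K)), unname(base))
})

test_that("T entries approach the exact enumeration over cut sizes", {
  d <- generateCategorical(25, K = 3, separation = "high", seed = 4)
  tree <- agglomerate(hammingMatrix(d$X))
  kmin <- 2L
  kmax <- 5L
  sep <- matrix(0, 25, 25)
  for (K in kmin:kmax) {
    cls <- cutClusters(tree, K)
    sep <- sep + outer(cls, cls, "!=")
  }
  expected <- sep / (kmax - kmin + 1L)
  ens <- ensembleCluster(d$X, B = 4000, kmin = kmin, kmax = kmax, seed = 5)
  expect_lt(max(abs(unname(ensembleDistances(ens)) - expected)), 0.03)
  # entries are exact multiples of 1/B in [0, 1]
  T <- ensembleDistances(ens)
  expect_true(all(abs(T * 4000 - round(T * 4000)) < 1e-9))
  expect_true(all(T >= 0 & T <= 1))
})

test_that("a seed makes the full ensemble run bit-reproducible", {
  d <- generateCategorical(40, K = 3, seed = 6)
  e1 <- ensembleCluster(d$X, B = 60, seed = 123)
  e2 <- ensembleCluster(d$X, B = 60, seed = 123)
  expect_identical(ensembleDistances(e1), ensembleDistances(e2))
  expect_identical(incidence(e1), incidence(e2))
  expect_identical(finalTree(e1)$merge, finalTree(e2)$merge)
  expect_error(ensembleCluster(d$X, B = 10, kmax = 40), "smaller than n")
})
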