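test_that("the factorial grid has the documented dimensions", {
  full <- makeDesign()
  expect_identical(nrow(full), 72L)
  expect_identical(sum(full$n == 100), 24L)
  expect_identical(sum(full$n == 300), 24L)
  reduced <- makeDesign(n = 100)
  expect_identical(nrow(reduced), 24L)
  expect_false(anyDuplicated(full$cell) > 0)
  # profile invariants
  expect_identical(
    colCardinalities(generateCategorical(10, profile = "mixed12", seed = 1)$X),
    c(2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 8L, 8L)
  )
  expect_identical(
    colCardinalities(
      generateCategorical(10, profile = "quaternary100", seed = 1)$X
    ),
    rep(4L, 100L)
  )
})

test_that("cluster sizes follow the balance rules", {
  d <- generateCategorical(100, K = 3, balance = "equal", seed = 2)
  expect_identical(as.integer(table(d$labels)), c(34L, 33L, 33L))
  d2 <- generateCategorical(120, K = 3, balance = "unequal", seed = 2)
  expect_identical(unname(as.integer(table(d2$labels))), c(20L, 40L, 60L))
  # sizes always sum to n, with no empty cluster
  for (n in c(50, 101, 307)) {
    for (K in c(3, 5, 7)) {
      d3 <- generateCategorical(n, K = K, balance = "unequal", seed = 3)
      expect_length(d3$labels, n)
      expect_true(all(tabulate(d3$labels, K) >= 1))
    }
  }
})

test_that("generated frequencies match the stored probability vectors", {
  # chi-square goodness of fit per column within one big cluster
  d <- generateCategorical(10000, K = 2, profile = "mixed12",
    separation = "high", balance = "equal", seed = 4
  )
  cd <- codes(d$X)
  for (j in c(1, 5, 11)) { # a binary, a ternary and an octonary column
    v <- cd[d$labels == 1, j]
    p <- d$probs[[1]][[j]]
    obs <- tabulate(v, length(p))
    expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.001)
  }
})

test_that("between/within mismatch rates match closed-form probabilities", {
  # one binary column, two clusters at high separation with pHigh = 0.8:
  # P(mismatch | different clusters) = .8^2 + .2^2 = .68 (preferences differ)
  # P(mismatch | same cluster) = 2 * .8 * .2 = .32
  set.seed(101)
  n <- 4000
  d <- generateCategorical(n, K = 2, profile = "mixed12",
    separation = "high", balance = "equal", seed = 5
  )
  col <- codes(d$X)[, 1] # binary column; preferred categories alternate
  g1 <- col[d$labels == 1]
  g2 <- col[d$labels == 2]
  i1 <- sample(g1, 10000, replace = TRUE)
  i2 <- sample(g2, 10000, replace = TRUE)
  between <- mean(i1 != i2)
  within <- mean(i1 != sample(g1, 10000, replace = TRUE))
  se <- sqrt(0.68 * 0.32 / 10000)
  expect_lt(abs(between - 0.68), 4 * se)
  expect_lt(abs(within - 0.32), 4 * se)
})

test_that("low separation carries no cluster signal", {
  aris <- vapply(1:8, function(s) {
    d <- generateCategorical(90, K = 3, separation = "low", seed = 300 + s)
    cls <- cutClusters(agglomerate(hammingMatrix(d$X)), 3)
    adjustedRand(cls, d$labels)
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("the study runner is reproducible and zero for identical methods", {
  design <- makeDesign(n = 100)[c(1, 14), ]
  s1 <- suppressWarnings(runStudy(design,
    methods = c("hier", "hier"),
    Ks = 3, resamples = 5, seed = 9, B = 30
  ))
  expect_true(all(s1$differences$difference == 0))
  s2 <- suppressWarnings(runStudy(design,
    methods = c("ensemble", "hier"),
    Ks = c(3, 5), resamples = 5, seed = 9, B = 30
  ))
  s3 <- suppressWarnings(runStudy(design,
    methods = c("ensemble", "hier"),
    Ks = c(3, 5), resamples = 5, seed = 9, B = 30
  ))
  expect_identical(s2$medians, s3$medians)
  expect_identical(nrow(s2$differences), 4L) # 2 cells x 2 Ks
  expect_identical(names(s2$by_n), c("n", "difference"))
})
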