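test_that("the Jaccard coefficient of id sets behaves as a set overlap", {
  expect_identical(jaccardIndex(1:3, 2:4), 0.5)
  expect_identical(jaccardIndex(c(5, 9), c(9, 5)), 1)
  expect_identical(jaccardIndex(1:3, 4:6), 0)
  expect_identical(jaccardIndex(integer(0), 1:2), 0)
  expect_error(jaccardIndex(integer(0), integer(0)), "empty")
})

test_that("adjusted Rand matches the reference implementation", {
  expect_identical(adjustedRand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_identical(adjustedRand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_error(adjustedRand(1:3, 1:4), "same observations")
  set.seed(61)
  for (rep in 1:10) {
    a <- sample.int(4, 50, replace = TRUE)
    b <- sample.int(3, 50, replace = TRUE)
    expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b),
      tolerance = 1e-12
    )
  }
  # expectation near zero under independent random labelings
  nulls <- replicate(200, adjustedRand(
    sample.int(3, 40, replace = TRUE), sample.int(3, 40, replace = TRUE)
  ))
  expect_lt(abs(mean(nulls)), 0.05)
})

test_that("perfectly separated clusters are perfectly stable", {
  # two blocks of identical rows: any Hamming clustering at K = 2 recovers
  # them on every resample
  cd <- rbind(
    matrix(1L, 10, 6), matrix(2L, 10, 6)
  )
  rownames(cd) <- paste0("o", 1:20)
  rep <- suppressWarnings(bootstrapStability(
    CategoricalMatrix(cd), "hier",
    Ks = 2, resamples = 20, seed = 3
  ))
  expect_true(all(stabilityTable(rep)$jaccard == 1))
})

test_that("an unstable (random) method is flagged and scored correctly", {
  set.seed(71)
  d <- generateCategorical(40, K = 2, separation = "low", seed = 5)
  randomMethod <- function(X, Ks, seed) {
    n <- nObs(X)
    withr::with_seed(seed, vapply(Ks, function(K) {
      l <- c(seq_len(K), sample.int(K, n - K, replace = TRUE))
      match(l, unique(l))
    }, integer(n)))
  }
  rep <- bootstrapStability(d$X, randomMethod,
    Ks = 2, resamples = 25, seed = 7
  )
  md <- stabilityMedians(rep)
  expect_lt(md$median[md$K == 2], 0.8)

  # recount the max-Jaccard scores on a few resamples with explicit sets
  idx <- withr::with_seed(
    deriveSeed(7, "resampling"),
    matrix(sample.int(40, 40 * 25, replace = TRUE), 40, 25)
  )
  refLab <- randomMethod(d$X, 2, deriveSeed(7, "reference"))[, 1]
  tb <- stabilityTable(rep)
  for (r in 1:5) {
    S <- sort(unique(idx[, r]))
    resLab <- randomMethod(d$X[S, ], 2, deriveSeed(7, paste0("method-", r)))[, 1]
    for (cc in 1:2) {
      C <- intersect(which(refLab == cc), S)
      want <- max(vapply(seq_len(max(resLab)), function(dd) {
        jaccardIndex(C, S[resLab == dd])
      }, numeric(1)))
      got <- tb$jaccard[tb$resample == r & tb$cluster == cc]
      expect_equal(got, want)
    }
  }
})

test_that("stability reports are deterministic given a seed", {
  d <- generateCategorical(30, K = 3, separation = "high", seed = 9)
  r1 <- bootstrapStability(d$X, "ensemble", Ks = c(3, 4), resamples = 5,
    seed = 11, B = 30
  )
  r2 <- bootstrapStability(d$X, "ensemble", Ks = c(3, 4), resamples = 5,
    seed = 11, B = 30
  )
  expect_identical(stabilityTable(r1), stabilityTable(r2))
})

test_that("method comparison reports per-K pooled median differences", {
  d <- generateCategorical(30, K = 3, separation = "high", seed = 13)
  r1 <- suppressWarnings(
    bootstrapStability(d$X, "hier", Ks = c(2, 3), resamples = 10, seed = 1)
  )
  cmp <- compareStability(r1, r1)
  expect_identical(cmp$difference, c(0, 0))
  r2 <- suppressWarnings(
    bootstrapStability(d$X, "kmodes", Ks = c(2, 3), resamples = 10, seed = 1)
  )
  cmp2 <- compareStability(r1, r2)
  expect_identical(cmp2$K, c(2L, 3L))
  expect_equal(cmp2$difference, cmp2$medianA - cmp2$medianB)
  r3 <- suppressWarnings(
    bootstrapStability(d$X, "hier", Ks = 2, resamples = 10, seed = 1)
  )
  expect_error(compareStability(r1, r3), "different K ranges")
})

test_that("resamples too small for K are skipped and reported", {
  cd <- rbind(
    matrix(1L, 6, 4), matrix(2L, 6, 4), matrix(3L, 6, 4)
  )
  cd[, 4] <- rep(1:6, 3) # some within-block variety
  rownames(cd) <- paste0("o", 1:18)
  # K = 12 will exceed the distinct-row count of most bootstrap resamples
  expect_warning(
    rep <- bootstrapStability(CategoricalMatrix(cd), "hier",
      Ks = 12, resamples = 10, seed = 17
    ),
    "skipped"
  )
  expect_gt(rep@skipped$skipped[1], 0)
})
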