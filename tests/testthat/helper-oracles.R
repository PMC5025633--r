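# Independent oracles used to validate the fast implementations. These are
# deliberately naive (double loops, from-scratch re-scans) and share no code
# with the package internals.

# Normalized Hamming distance matrix by explicit double loop.
recountHamming <- function(cd, policy = "pairwise_complete") {
  n <- nrow(cd)
  J <- ncol(cd)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i == k) next
      mism <- 0L
      comp <- 0L
      for (j in seq_len(J)) {
        a <- cd[i, j]
        b <- cd[k, j]
        if (policy == "pairwise_complete") {
          if (!is.na(a) && !is.na(b)) {
            comp <- comp + 1L
            if (a != b) mism <- mism + 1L
          }
        } else {
          if (is.na(a) || is.na(b) || a != b) mism <- mism + 1L
        }
      }
      D[i, k] <- if (policy == "pairwise_complete") {
        if (comp == 0L) 1 else mism / comp
      } else {
        mism / J
      }
    }
  }
  D
}

# Agglomeration by brute-force re-scan: at every step, every cross-cluster
# statistic is recomputed from the original dissimilarity matrix, candidate
# pairs are visited in lexicographic node-id order, and the first strict
# minimum wins.
bruteAgglom <- function(D, linkage = "average") {
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  ids <- seq_len(n)
  code <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  stat <- function(A, B) {
    vals <- D[A, B, drop = FALSE]
    switch(linkage,
      average = sum(vals) / (length(A) * length(B)),
      complete = max(vals),
      single = min(vals)
    )
  }
  for (s in seq_len(n - 1L)) {
    ord <- order(ids)
    best <- Inf
    bi <- 0L
    bj <- 0L
    for (u in seq_len(length(ord) - 1L)) {
      for (v in (u + 1L):length(ord)) {
        a <- ord[u]
        b <- ord[v]
        val <- stat(members[[a]], members[[b]])
        if (val < best) {
          best <- val
          bi <- a
          bj <- b
        }
      }
    }
    merge[s, ] <- c(code[bi], code[bj])
    height[s] <- best
    members[[bi]] <- c(members[[bi]], members[[bj]])
    ids[bi] <- n + s
    code[bi] <- s
    members <- members[-bj]
    ids <- ids[-bj]
    code <- code[-bj]
  }
  list(merge = merge, height = height)
}

# Random symmetric dissimilarity with zero diagonal; values drawn either
# continuously (effectively tie-free) or from a dyadic grid k/64 (tie-rich,
# and exactly representable so oracle and implementation arithmetic agree).
randomDissimilarity <- function(n, grid = FALSE) {
  m <- if (grid) {
    matrix(sample(0:64, n * n, replace = TRUE) / 64, n, n)
  } else {
    matrix(runif(n * n, 0.01, 1), n, n)
  }
  D <- (m + t(m)) / 2
  if (grid) D <- round(D * 64) / 64
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("o", seq_len(n))
  D
}

# Random categorical code matrix, optionally with missing values.
randomCategorical <- function(n, J, M = 4L, missFrac = 0) {
  cd <- matrix(sample.int(M, n * J, replace = TRUE), n, J)
  if (missFrac > 0) {
    drop <- which(runif(n * J) < missFrac)
    cd[drop] <- NA_integer_
  }
  rownames(cd) <- paste0("o", seq_len(n))
  cd
}

# Well-separated synthetic clusters with arbitrary dimension (quaternary
# columns, same concentration scheme as the package generator).
separatedClusters <- function(n, J, K, pHigh = 0.9) {
  sizes <- rep(n %/% K, K)
  sizes[seq_len(n - sum(sizes))] <- sizes[seq_len(n - sum(sizes))] + 1L
  labels <- rep(seq_len(K), sizes)
  cd <- matrix(0L, n, J)
  for (c in seq_len(K)) {
    rows <- which(labels == c)
    for (j in seq_len(J)) {
      pref <- 1L + ((c + j) %% 4L)
      p <- rep((1 - pHigh) / 3, 4)
      p[pref] <- pHigh
      cd[rows, j] <- sample.int(4L, length(rows), replace = TRUE, prob = p)
    }
  }
  rownames(cd) <- paste0("o", seq_len(n))
  list(codes = cd, labels = labels)
}

# Path to the installed CLI script and a runner for it.
cliScript <- function() {
  p <- system.file("scripts", "catens.R", package = "catens")
  stopifnot(nzchar(p))
  p
}

runCli <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  args <- c(cliScript(), ...)
  res <- suppressWarnings(system2(rscript, shQuote(args),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(res, "status")
  list(status = if (is.null(status)) 0L else status, output = res)
}
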