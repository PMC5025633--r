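#' K-modes clustering of categorical data
#'
#' Lloyd-style alternation for categorical data: each observation is assigned
#' to the mode (cluster "center") with the fewest mismatches, and each
#' cluster's mode is recomputed column-wise as the most frequent code. Used
#' here as a non-hierarchical baseline; it is known to be sensitive to the
#' choice of initial modes.
#'
#' Determinism contract: assignment ties go to the lowest cluster index; mode
#' ties go to the smallest code. Mismatches are counted over positions where
#' both the observation and the mode are non-missing. A cluster that empties
#' during reassignment is re-seeded with the observation farthest (most
#' mismatches) from its current mode, keeping k clusters.
#'
#' @param X a \linkS4class{CategoricalMatrix} (or integer code matrix).
#' @param k number of clusters, 1 <= k <= n.
#' @param init either \code{"random"} (k distinct row indices drawn from the
#'   data) or an integer vector of k distinct row indices to use as initial
#'   modes.
#' @param seed optional integer seed (used only for random initialization).
#' @param maxIter iteration cap, default 100.
#' @return list with class \code{"catensKmodes"}: \code{labels} (n integers
#'   in 1..k), \code{modes} (k x J code matrix), \code{iterations},
#'   \code{withindiff} (total within-cluster mismatch count), and
#'   \code{converged}.
#' @examples
#' X <- rbind(c(1, 1, 1), c(1, 1, 1), c(2, 2, 2), c(2, 2, 2))
#' kmodes(CategoricalMatrix(X), 2, init = c(1, 3))$labels
#' @export
kmodes <- function(X, k, init = "random", seed = NULL, maxIter = 100L) {
  cd <- if (is(X, "CategoricalMatrix")) codes(X) else as.matrix(X)
  storage.mode(cd) <- "integer"
  n <- nrow(cd)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must lie in 1..n", call. = FALSE)
  if (identical(init, "random")) {
    init <- withSeed(seed, sample.int(n, k))
  } else {
    init <- as.integer(init)
    if (length(init) != k) stop("init must give k row indices", call. = FALSE)
    if (anyDuplicated(init)) {
      stop("init row indices must be distinct", call. = FALSE)
    }
    if (any(init < 1L | init > n)) stop("init index out of range", call. = FALSE)
  }
  modes <- cd[init, , drop = FALSE]
  rownames(modes) <- NULL
  labels <- integer(n)
  mismatchTo <- function(mode) {
    # per-observation mismatch count against one mode, pairwise-complete
    cmp <- sweep(cd, 2L, mode, "!=")
    rowSums(cmp & !is.na(cmp))
  }
  distm <- function() {
    vapply(seq_len(k), function(c) mismatchTo(modes[c, ]), numeric(n))
  }
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    dm <- distm()
    newLabels <- max.col(-dm, ties.method = "first")
    # re-seed empty clusters deterministically
    used <- integer(0)
    for (c in seq_len(k)) {
      if (!any(newLabels == c)) {
        own <- dm[cbind(seq_len(n), newLabels)]
        own[used] <- -Inf
        far <- which.max(own)
        modes[c, ] <- cd[far, ]
        newLabels[far] <- c
        used <- c(used, far)
      }
    }
    if (it > 1L && all(newLabels == labels)) {
      converged <- TRUE
      labels <- newLabels
      break
    }
    labels <- newLabels
    for (c in seq_len(k)) {
      mem <- cd[labels == c, , drop = FALSE]
      modes[c, ] <- apply(mem, 2L, function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) return(NA_integer_)
        tb <- table(v)
        as.integer(names(tb)[which.max(tb)]) # table is sorted by code:
        # which.max takes the first maximum, i.e. the smallest code
      })
    }
    if (it >= maxIter) break
  }
  dm <- distm()
  objective <- sum(dm[cbind(seq_len(n), labels)])
  structure(
    list(
      labels = stats::setNames(labels, rownames(cd)),
      modes = modes, iterations = it,
      withindiff = as.integer(objective), converged = converged
    ),
    class = "catensKmodes"
  )
}

#' @export
print.catensKmodes <- function(x, ...) {
  cat(sprintf(
    "K-modes fit: k = %d, %d iterations (%sconverged), within-cluster mismatches = %d\n",
    nrow(x$modes), x$iterations, if (x$converged) "" else "not ",
    x$withindiff
  ))
  cat("cluster sizes:", paste(tabulate(x$labels, nrow(x$modes)), collapse = " "), "\n")
  invisible(x)
}
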