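#' Draw random base-clustering sizes
#'
#' Draws B independent cluster counts from the discrete uniform distribution
#' on \{kmin, ..., kmax\}; these are the sizes at which the base tree is cut
#' to form the ensemble. Uses R's global RNG (Mersenne-Twister) via
#' \code{sample.int}; with \code{seed} given the draw is seed-scoped and
#' reproducible without disturbing the global stream.
#'
#' @param B number of draws.
#' @param kmin,kmax inclusive range, 2 <= kmin <= kmax.
#' @param seed optional integer seed.
#' @return integer vector of length B.
#' @examples
#' drawClusterCounts(5, 2, 8, seed = 1)
#' @export
drawClusterCounts <- function(B, kmin = 2L, kmax = 8L, seed = NULL) {
  B <- as.integer(B)
  kmin <- as.integer(kmin)
  kmax <- as.integer(kmax)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (kmin < 2L || kmax < kmin) {
    stop("need 2 <= kmin <= kmax", call. = FALSE)
  }
  withSeed(seed, kmin + sample.int(kmax - kmin + 1L, B, replace = TRUE) - 1L)
}

#' Default upper bound for base-clustering sizes
#'
#' The square-root heuristic for the largest base cluster count:
#' \code{ceiling(sqrt(n))}, clamped to at least 2 and at most n-1.
#'
#' @param n number of observations (>= 4).
#' @return integer.
#' @examples
#' defaultKmax(53) # 8
#' defaultKmax(100) # 10
#' @export
defaultKmax <- function(n) {
  n <- as.integer(n)
  if (n < 4L) stop("need n >= 4 for the sqrt(n) heuristic", call. = FALSE)
  min(max(2L, as.integer(ceiling(sqrt(n)))), n - 1L)
}

#' Assemble the incidence matrix of a collection of clusterings
#'
#' Column b of the incidence matrix holds the cluster index of every
#' observation in the b-th base clustering; entry (i, b) is the index of the
#' cluster to which observation i belongs in clustering b.
#'
#' @param clusterings list of integer label vectors (or a matrix with one
#'   clustering per column), all over the same n observations.
#' @return n x B integer matrix.
#' @examples
#' buildIncidence(list(c(1, 1, 2), c(1, 2, 2)))
#' @export
buildIncidence <- function(clusterings) {
  if (is.matrix(clusterings)) {
    clusterings <- lapply(seq_len(ncol(clusterings)), function(b) {
      clusterings[, b]
    })
  }
  if (!length(clusterings)) stop("no clusterings given", call. = FALSE)
  n <- length(clusterings[[1L]])
  if (any(lengths(clusterings) != n)) {
    stop("all clusterings must cover the same observations", call. = FALSE)
  }
  I <- vapply(clusterings, function(l) as.integer(l), integer(n))
  for (b in seq_len(ncol(I))) {
    Kb <- max(I[, b])
    if (!all(seq_len(Kb) %in% I[, b])) {
      stop("clustering ", b, " has empty cluster indices", call. = FALSE)
    }
  }
  nm <- names(clusterings[[1L]])
  rownames(I) <- if (is.null(nm)) paste0("obs", seq_len(n)) else nm
  I
}

#' Ensembled dissimilarity from an incidence matrix
#'
#' Entry (i, j) is the fraction of base clusterings that place observations i
#' and j in different clusters — the normalized Hamming distance between rows
#' i and j of the incidence matrix.
#'
#' @param I n x B integer incidence matrix, see [buildIncidence()].
#' @return symmetric n x n matrix with entries in \{0, 1/B, ..., 1\}.
#' @examples
#' ensembleDissimilarity(buildIncidence(list(c(1, 1, 2), c(1, 2, 2))))
#' @export
ensembleDissimilarity <- function(I) {
  I <- as.matrix(I)
  storage.mode(I) <- "integer"
  if (anyNA(I)) stop("incidence matrix cannot contain NA", call. = FALSE)
  T <- .hamming_core(I, 1L)
  attr(T, "degenerate_pairs") <- NULL
  labs <- rownames(I)
  if (is.null(labs)) labs <- paste0("obs", seq_len(nrow(I)))
  dimnames(T) <- list(labs, labs)
  T
}

#' Ensemble clustering of categorical data (low-dimensional form)
#'
#' Runs the core ensemble procedure: (i) the normalized Hamming matrix of the
#' data is computed and agglomerated once into a base dendrogram; (ii) the
#' tree is cut at B cluster counts K_b drawn uniformly from
#' \{kmin, ..., kmax\}; (iii) the resulting clusterings are assembled into an
#' incidence matrix whose row-wise Hamming distances form the ensembled
#' dissimilarity matrix T; (iv) a final dendrogram is agglomerated on T.
#'
#' With \code{perturb = "none"} the base tree is deterministic given the data
#' and the cluster-count draw is the only stochastic element; T is then an
#' exact monotone transform of the base tree's merge order, so the final
#' dendrogram encodes the same nested partitions with rescaled heights
#' (longer lifetimes, identical cuts). With \code{perturb = "rows"} every
#' base clustering additionally clusters its own bootstrap resample of
#' observations (reduced to the distinct drawn rows), and each left-out
#' observation joins the cluster of its nearest resampled row (smallest
#' Hamming distance, first index on ties). The row bootstrap gives the base
#' clusterings genuine diversity, which is what lets the consensus smooth
#' out sampling variability — use it when comparing the ensemble's stability
#' against a single clustering.
#'
#' The number of clusters is typically read off the final dendrogram (long
#' branch lifetimes indicate well-separated clusters); no automatic selection
#' is performed, but [cutClusters()] extracts a K-cluster partition from
#' \code{finalTree()} on demand.
#'
#' @param X a \linkS4class{CategoricalMatrix} (or integer code matrix).
#' @param B ensemble size (number of base clusterings), default 200.
#' @param kmin,kmax range of base cluster counts; \code{kmax = NULL} uses
#'   [defaultKmax()]. Must satisfy kmax < n.
#' @param linkage linkage for both the base and the final agglomeration.
#' @param policy missing-data policy for the base Hamming matrix.
#' @param seed optional integer seed making the run fully reproducible.
#' @param perturb per-base-clustering data perturbation: \code{"none"}
#'   (deterministic cuts of one base tree) or \code{"rows"} (each base
#'   clustering fits its own bootstrap row-resample), see Details.
#' @return an \linkS4class{EnsembleClustering}.
#' @examples
#' X <- generateCategorical(40, K = 3, seed = 1)$X
#' ens <- ensembleCluster(X, B = 50, seed = 7)
#' table(cutClusters(finalTree(ens), 3))
#' @export
ensembleCluster <- function(X, B = 200L, kmin = 2L, kmax = NULL,
                            linkage = "average",
                            policy = "pairwise_complete", seed = NULL,
                            perturb = c("none", "rows")) {
  perturb <- match.arg(perturb)
  cd <- if (is(X, "CategoricalMatrix")) codes(X) else as.matrix(X)
  n <- nrow(cd)
  if (is.null(kmax)) kmax <- defaultKmax(n)
  kmax <- as.integer(kmax)
  if (kmax >= n) stop("kmax must be smaller than n", call. = FALSE)
  D <- hammingMatrix(cd, policy)
  # RNG consumption order is fixed: the B cluster counts first, then (for
  # perturb = "rows") the B row resamples in iteration order
  run <- function() {
    Kb <- drawClusterCounts(B, kmin, kmax)
    if (perturb == "none") {
      tree <- agglomerate(D, linkage)
      uK <- sort(unique(Kb))
      cuts <- cutMany(tree, uK)
      I <- cuts[, match(Kb, uK), drop = FALSE]
    } else {
      lk <- c(average = 0L, complete = 1L, single = 2L)[[linkage]]
      I <- matrix(NA_integer_, n, B)
      for (b in seq_len(B)) {
        S <- sort(unique(sample.int(n, n, replace = TRUE)))
        K <- min(Kb[b], length(S))
        lab <- .agglom_cut_core(D[S, S, drop = FALSE], lk, K)
        full <- integer(n)
        full[S] <- lab
        out <- setdiff(seq_len(n), S)
        if (length(out)) {
          nn <- max.col(-D[out, S, drop = FALSE], ties.method = "first")
          full[out] <- lab[nn]
        }
        I[, b] <- canonicalizeLabels(full)
      }
      rownames(I) <- rownames(cd)
    }
    list(I = I, Kb = Kb)
  }
  drawn <- withSeed(seed, run())
  I <- drawn$I
  colnames(I) <- NULL
  T <- ensembleDissimilarity(I)
  new("EnsembleClustering",
    dissimilarity = T, incidence = I,
    tree = agglomerate(T, linkage),
    params = list(
      B = as.integer(B), kmin = as.integer(kmin), kmax = kmax,
      linkage = linkage, policy = policy,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      variant = "lowdim", perturb = perturb, Kb = drawn$Kb
    )
  )
}

#' @rdname EnsembleClustering-class
#' @param x an \linkS4class{EnsembleClustering}.
#' @export
setMethod("ensembleDistances", "EnsembleClustering", function(x) {
  x@dissimilarity
})

#' @rdname EnsembleClustering-class
#' @export
setMethod("incidence", "EnsembleClustering", function(x) x@incidence)

#' @rdname EnsembleClustering-class
#' @export
setMethod("finalTree", "EnsembleClustering", function(x) x@tree)

setMethod("show", "EnsembleClustering", function(object) {
  p <- object@params
  cat(sprintf(
    "EnsembleClustering (%s): %d observations, B = %d base clusterings\n",
    p$variant, nrow(object@dissimilarity), p$B
  ))
  cat(sprintf(
    "  K_b ~ DUnif[%d, %d], linkage = %s, policy = %s, seed = %s\n",
    p$kmin, p$kmax, p$linkage, p$policy, p$seed
  ))
  if (!is.null(p$level)) cat(sprintf("  subspace bootstrap level = %d\n", p$level))
  cat("  access: ensembleDistances(), incidence(), finalTree()\n")
  invisible(NULL)
})
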