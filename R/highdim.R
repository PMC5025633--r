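#' Draw a random variable subspace by bootstrap-with-deduplication
#'
#' Level 1: J indices are drawn i.i.d. uniformly with replacement from
#' \{1, ..., J\} and the distinct values are kept, giving J* <= J columns
#' (expected fraction 1 - (1 - 1/J)^J, about 63\% for large J). Higher levels
#' repeat the draw-and-deduplicate step on the retained set, shrinking it
#' further. Every column has the same inclusion probability at every level.
#'
#' @param J number of available columns.
#' @param level bootstrap depth: 1 (single), 2 (double, the high-dimensional
#'   default) or 3 (triple).
#' @param seed optional integer seed.
#' @return sorted integer vector of distinct column indices.
#' @examples
#' length(bootstrapSubspace(100, level = 1, seed = 1)) # about 63
#' @export
bootstrapSubspace <- function(J, level = 2L, seed = NULL) {
  J <- as.integer(J)
  level <- as.integer(level)
  if (J < 1L) stop("J must be >= 1", call. = FALSE)
  if (!(level %in% 1:3)) stop("level must be 1, 2 or 3", call. = FALSE)
  withSeed(seed, {
    s <- seq_len(J)
    for (l in seq_len(level)) {
      s <- sort(unique(s[sample.int(length(s), length(s), replace = TRUE)]))
    }
    s
  })
}

#' Ensemble clustering of high-dimensional categorical data
#'
#' Random-subspace variant of [ensembleCluster()] for data with many more
#' variables than observations. Each of the B base clusterings draws its own
#' random subspace of columns by bootstrap-with-deduplication (see
#' [bootstrapSubspace()]), computes the normalized Hamming matrix restricted
#' to that subspace, agglomerates it, and cuts the tree at a cluster count
#' K_b drawn uniformly from \{kmin, ..., kmax\}. Because every base
#' clustering sees its own subspace (and hence its own dissimilarity matrix),
#' the subspace draw — not only the K_b draw — contributes ensemble
#' diversity. The incidence matrix of the B clusterings then yields the
#' ensembled dissimilarity T and the final dendrogram exactly as in the
#' low-dimensional form.
#'
#' Per iteration the RNG is consumed in a fixed order (subspace first, then
#' K_b), so a single seed reproduces the full run.
#'
#' @inheritParams ensembleCluster
#' @param B ensemble size, default 100.
#' @param level subspace bootstrap depth, default 2 (double bootstrap).
#' @param subspaceFun subspace generator, by default [bootstrapSubspace()];
#'   replaceable (e.g. by a function returning \code{seq_len(J)}) to disable
#'   subspace randomness.
#' @return an \linkS4class{EnsembleClustering}.
#' @examples
#' X <- generateCategorical(30, profile = "quaternary100", K = 3, seed = 1)$X
#' ens <- ensembleClusterHighDim(X, B = 25, seed = 7)
#' ens
#' @export
ensembleClusterHighDim <- function(X, B = 100L, kmin = 2L, kmax = NULL,
                                   level = 2L, linkage = "average",
                                   policy = "pairwise_complete", seed = NULL,
                                   subspaceFun = bootstrapSubspace) {
  cd <- if (is(X, "CategoricalMatrix")) codes(X) else as.matrix(X)
  n <- nrow(cd)
  J <- ncol(cd)
  if (is.null(kmax)) kmax <- defaultKmax(n)
  kmax <- as.integer(kmax)
  kmin <- as.integer(kmin)
  B <- as.integer(B)
  if (kmax >= n) stop("kmax must be smaller than n", call. = FALSE)
  if (kmin < 2L || kmax < kmin) stop("need 2 <= kmin <= kmax", call. = FALSE)
  lk <- c(average = 0L, complete = 1L, single = 2L)[[linkage]]
  run <- function() {
    labels <- matrix(NA_integer_, n, B)
    subspaces <- vector("list", B)
    for (b in seq_len(B)) {
      Sb <- subspaceFun(J, level)
      Kb <- kmin + sample.int(kmax - kmin + 1L, 1L) - 1L
      Db <- hammingMatrix(cd[, Sb, drop = FALSE], policy)
      labels[, b] <- .agglom_cut_core(unclass(Db), lk, Kb)
      subspaces[[b]] <- Sb
    }
    list(labels = labels, subspaces = subspaces)
  }
  drawn <- withSeed(seed, run())
  I <- drawn$labels
  rownames(I) <- rownames(cd)
  T <- ensembleDissimilarity(I)
  new("EnsembleClustering",
    dissimilarity = T, incidence = I,
    tree = agglomerate(T, linkage),
    params = list(
      B = B, kmin = kmin, kmax = kmax, linkage = linkage, policy = policy,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      variant = "highdim", level = as.integer(level),
      subspaceSizes = lengths(drawn$subspaces)
    )
  )
}
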