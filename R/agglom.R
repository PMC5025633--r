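#' Agglomerative hierarchical clustering of a dissimilarity matrix
#'
#' Standard bottom-up agglomeration with average (default), complete or
#' single linkage, returning a base-R \code{hclust} dendrogram. Merge heights
#' are non-decreasing for all three linkages.
#'
#' Normalized Hamming dissimilarities are multiples of 1/J, so tied minimum
#' distances are common. Ties are resolved deterministically: clusters carry
#' node ids (leaves 1..n, the cluster created at merge s gets id n+s) and
#' among all pairs attaining the minimum linkage value the pair with the
#' lexicographically smallest id pair is merged. This makes dendrograms
#' bit-reproducible across runs and platforms.
#'
#' @param D symmetric dissimilarity matrix (or \code{dist}) with zero
#'   diagonal.
#' @param linkage \code{"average"} (mean of all cross-cluster distances),
#'   \code{"complete"} (maximum) or \code{"single"} (minimum).
#' @return an object of class \code{hclust}.
#' @examples
#' D <- matrix(c(0, .1, .9, .1, 0, .8, .9, .8, 0), 3, 3)
#' tr <- agglomerate(D)
#' tr$height # 0.1, then (0.9 + 0.8) / 2
#' @export
agglomerate <- function(D, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  D <- asDissimilarity(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 observations to cluster", call. = FALSE)
  res <- .agglom_core(
    D, c(average = 0L, complete = 1L, single = 2L)[[linkage]]
  )
  tr <- list(
    merge = res$merge,
    height = as.numeric(res$height),
    order = mergeOrder(res$merge),
    labels = rownames(D),
    method = linkage,
    call = match.call(),
    dist.method = attr(D, "policy")
  )
  class(tr) <- "hclust"
  tr
}

# Leaf ordering by depth-first traversal of the merge tree (left child first),
# as required by the hclust contract.
mergeOrder <- function(merge) {
  n <- nrow(merge) + 1L
  out <- integer(n)
  k <- 0L
  stack <- integer(2L * n)
  top <- 1L
  stack[1L] <- nrow(merge)
  while (top > 0L) {
    nd <- stack[top]
    top <- top - 1L
    if (nd < 0L) {
      k <- k + 1L
      out[k] <- -nd
    } else {
      stack[top + 1L] <- merge[nd, 2L]
      stack[top + 2L] <- merge[nd, 1L]
      top <- top + 2L
    }
  }
  out
}

#' Cut a dendrogram into K clusters
#'
#' Returns the partition obtained by undoing the last K-1 merges of the
#' dendrogram, i.e. applying only its first n-K merges. Labels are
#' canonicalized: the cluster containing the first observation is cluster 1,
#' the next new cluster encountered is 2, and so on.
#'
#' @param tree an \code{hclust} object, e.g. from [agglomerate()].
#' @param K number of clusters, between 1 and n.
#' @return named integer vector of cluster labels in 1..K.
#' @examples
#' D <- matrix(c(0, .1, .9, .1, 0, .8, .9, .8, 0), 3, 3)
#' cutClusters(agglomerate(D), 2) # {1,2} vs {3}
#' @export
cutClusters <- function(tree, K) {
  stopifnot(inherits(tree, "hclust"))
  n <- nrow(tree$merge) + 1L
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L || K > n) {
    stop("K must be a single integer in 1..", n, call. = FALSE)
  }
  labs <- cutAtMergeStep(tree$merge, n, n - K)
  names(labs) <- tree$labels
  labs
}

# Partition after applying the first `steps` merges, canonically labeled.
cutAtMergeStep <- function(merge, n, steps) {
  comp <- seq_len(n)
  nodecomp <- integer(max(steps, 1L))
  for (s in seq_len(steps)) {
    a <- merge[s, 1L]
    b <- merge[s, 2L]
    ca <- if (a < 0L) comp[-a] else nodecomp[a]
    cb <- if (b < 0L) comp[-b] else nodecomp[b]
    comp[comp == cb] <- ca
    if (s > 1L) {
      prev <- seq_len(s - 1L)
      nodecomp[prev][nodecomp[prev] == cb] <- ca
    }
    nodecomp[s] <- ca
  }
  canonicalizeLabels(comp)
}

# All cuts for a vector of K values in one pass over the merge sequence;
# returns an n x length(Ks) integer matrix of canonical labels.
cutMany <- function(tree, Ks) {
  n <- nrow(tree$merge) + 1L
  vapply(as.integer(Ks), function(K) cutClusters(tree, K), integer(n))
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from merge heights: a leaf's branch length is
#' its parent's merge height and an internal branch is the difference of the
#' two merge heights, so root-to-leaf path lengths equal the root height.
#'
#' @param tree an \code{hclust} object.
#' @param path optional file path; when given the string is also written
#'   there (one tree per line, terminated by \code{;}).
#' @return the Newick string, invisibly when \code{path} is given.
#' @export
toNewick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  # as.phylo.hclust halves merge heights (hclust heights are distances);
  # restore the convention that a leaf's branch length is its parent height
  phy$edge.length <- phy$edge.length * 2
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
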