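#' Normalized Hamming dissimilarity between two categorical vectors
#'
#' Fraction of positions at which two equal-length code vectors disagree.
#' Two missing-data policies are available:
#' \describe{
#'   \item{\code{pairwise_complete}}{mismatches are counted over positions
#'     where both values are observed and divided by the number of such
#'     positions — a gap carries no information. A pair with no jointly
#'     observed position is assigned distance 1 with a warning.}
#'   \item{\code{mismatch}}{a position where either value is missing counts
#'     as a mismatch; the denominator is the full vector length.}
#' }
#'
#' @param x,y equal-length integer code vectors, \code{NA} = missing.
#' @param policy missing-data policy, see Details.
#' @return a number in [0, 1]; always an exact ratio k/m of integer counts.
#' @examples
#' pairwiseHamming(c(1, 2, 3, 4), c(1, 2, 4, 4)) # 0.25
#' pairwiseHamming(c(1, NA, 3), c(1, 2, 3)) # 0 over 2 compared positions
#' pairwiseHamming(c(1, NA, 3), c(1, 2, 3), policy = "mismatch") # 1/3
#' @export
pairwiseHamming <- function(x, y,
                            policy = c("pairwise_complete", "mismatch")) {
  policy <- match.arg(policy)
  if (length(x) != length(y)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  x <- as.integer(x)
  y <- as.integer(y)
  if (policy == "pairwise_complete") {
    both <- !is.na(x) & !is.na(y)
    m <- sum(both)
    if (m == 0L) {
      warning("no jointly observed positions; returning distance 1")
      return(1)
    }
    sum(x[both] != y[both]) / m
  } else {
    sum(is.na(x) | is.na(y) | (x != y), na.rm = TRUE) / length(x)
  }
}

#' Normalized Hamming dissimilarity matrix
#'
#' Computes the n x n matrix of pairwise normalized Hamming distances between
#' the rows of a categorical data matrix. Entries are exact integer-count
#' ratios in [0, 1]; the matrix is symmetric with zero diagonal.
#'
#' @param X a \linkS4class{CategoricalMatrix}, or an integer code matrix with
#'   \code{NA} marking missing values.
#' @inheritParams pairwiseHamming
#' @return labeled symmetric numeric matrix.
#' @examples
#' X <- CategoricalMatrix(rbind(c(1, 1), c(1, 2), c(2, 2)))
#' hammingMatrix(X)
#' @export
hammingMatrix <- function(X, policy = c("pairwise_complete", "mismatch")) {
  policy <- match.arg(policy)
  cd <- if (is(X, "CategoricalMatrix")) codes(X) else as.matrix(X)
  storage.mode(cd) <- "integer"
  if (nrow(cd) < 2L) stop("need at least 2 observations", call. = FALSE)
  D <- .hamming_core(cd, if (policy == "pairwise_complete") 0L else 1L)
  deg <- attr(D, "degenerate_pairs")
  attr(D, "degenerate_pairs") <- NULL
  if (policy == "pairwise_complete" && deg > 0L) {
    warning(sprintf(
      "%d pair(s) had no jointly observed positions; distance set to 1", deg
    ))
  }
  labs <- rownames(cd)
  if (is.null(labs)) labs <- paste0("obs", seq_len(nrow(cd)))
  dimnames(D) <- list(labs, labs)
  attr(D, "policy") <- policy
  D
}
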