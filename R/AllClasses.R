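#' @useDynLib catens, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Integer-coded categorical data matrix
#'
#' Container for n categorical observations on J variables. Values are stored
#' as positive integer category codes with \code{NA} marking a missing value
#' (e.g. an alignment gap). Code identity carries no meaning across columns:
#' downstream distances only ever test codes for equality.
#'
#' @slot codes integer matrix (n x J); \code{NA} = missing. Row names are the
#'   observation labels.
#' @slot colLevels list of J character vectors mapping code \code{k} in column
#'   \code{j} to its original label \code{colLevels[[j]][k]}.
#' @slot colCardinalities integer vector of length J: the number of category
#'   codes available in each column (observed distinct labels for tabular
#'   input, alphabet size for encoded sequences).
#'
#' @seealso [CategoricalMatrix()], [readCategoricalTable()],
#'   [readAlignedFasta()], [ctnEncode()]
#' @export
setClass("CategoricalMatrix",
  representation(
    codes = "matrix",
    colLevels = "list",
    colCardinalities = "integer"
  )
)

setValidity("CategoricalMatrix", function(object) {
  codes <- object@codes
  if (!is.integer(codes)) {
    return("'codes' must be an integer matrix (NA = missing)")
  }
  n <- nrow(codes)
  J <- ncol(codes)
  if (n < 2L) return("a CategoricalMatrix needs at least 2 observations")
  if (J < 1L) return("a CategoricalMatrix needs at least 1 variable")
  if (length(object@colCardinalities) != J) {
    return("'colCardinalities' must have one entry per column")
  }
  if (length(object@colLevels) != J) {
    return("'colLevels' must have one entry per column")
  }
  if (any(lengths(object@colLevels) != object@colCardinalities)) {
    return("each colLevels entry must have length colCardinalities[j]")
  }
  for (j in seq_len(J)) {
    v <- codes[, j]
    v <- v[!is.na(v)]
    if (length(v) && (min(v) < 1L || max(v) > object@colCardinalities[j])) {
      return(sprintf(
        "codes in column %d outside 1..%d", j, object@colCardinalities[j]
      ))
    }
  }
  if (is.null(rownames(codes))) return("'codes' must carry row labels")
  TRUE
})

#' Result of an ensemble clustering run
#'
#' Bundles the ensembled dissimilarity matrix T (fraction of base clusterings
#' separating each pair of observations), the n x B incidence matrix of base
#' cluster indices, the final dendrogram fitted on T, and the configuration
#' used.
#'
#' @slot dissimilarity numeric n x n matrix; entries are multiples of 1/B in
#'   [0, 1], symmetric with zero diagonal.
#' @slot incidence integer n x B matrix; column b holds the cluster indices of
#'   base clustering b.
#' @slot tree the final \code{hclust} dendrogram fitted on the ensembled
#'   dissimilarity.
#' @slot params list recording B, kmin, kmax, linkage, policy, seed and (for
#'   the high-dimensional variant) the bootstrap level.
#'
#' @seealso [ensembleCluster()], [ensembleClusterHighDim()]
#' @export
setClass("EnsembleClustering",
  representation(
    dissimilarity = "matrix",
    incidence = "matrix",
    tree = "ANY",
    params = "list"
  )
)

setValidity("EnsembleClustering", function(object) {
  T <- object@dissimilarity
  n <- nrow(T)
  if (ncol(T) != n) return("'dissimilarity' must be square")
  if (nrow(object@incidence) != n) {
    return("'incidence' must have one row per observation")
  }
  if (any(abs(T - t(T)) > 0)) return("'dissimilarity' must be symmetric")
  if (any(diag(T) != 0)) return("'dissimilarity' must have zero diagonal")
  if (any(T < 0 | T > 1)) return("'dissimilarity' entries must lie in [0,1]")
  if (!inherits(object@tree, "hclust")) return("'tree' must be an hclust")
  TRUE
})

#' Bootstrap cluster-stability report
#'
#' Per-cluster bootstrap Jaccard coefficients for a clustering method over a
#' range of cluster counts K: for each K the data are reclustered on bootstrap
#' resamples (reduced to their distinct rows) and each reference cluster is
#' scored by the maximal Jaccard coefficient it attains against the resample
#' clusters.
#'
#' @slot table data.frame with columns \code{K}, \code{cluster},
#'   \code{resample}, \code{jaccard} (long format, one row per reference
#'   cluster per usable resample).
#' @slot skipped data.frame with columns \code{K}, \code{skipped}: resamples
#'   dropped because K exceeded the number of distinct resampled rows.
#' @slot method character descriptor of the clustering procedure assessed.
#' @slot Ks integer vector of evaluated cluster counts.
#' @slot resamples integer, number of bootstrap resamples requested.
#' @slot seed the seed used, or NA.
#'
#' @seealso [bootstrapStability()], [compareStability()]
#' @export
setClass("StabilityReport",
  representation(
    table = "data.frame",
    skipped = "data.frame",
    method = "character",
    Ks = "integer",
    resamples = "integer",
    seed = "ANY"
  )
)

setValidity("StabilityReport", function(object) {
  tb <- object@table
  need <- c("K", "cluster", "resample", "jaccard")
  if (!all(need %in% names(tb))) {
    return("'table' needs columns K, cluster, resample, jaccard")
  }
  if (nrow(tb) && (any(tb$jaccard < 0) || any(tb$jaccard > 1))) {
    return("Jaccard coefficients must lie in [0,1]")
  }
  TRUE
})
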