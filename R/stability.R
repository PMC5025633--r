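#' Jaccard coefficient between two sets of observation ids
#'
#' @param A,B vectors of observation ids (treated as sets); not both empty.
#' @return |A n B| / |A u B|, a number in [0, 1].
#' @examples
#' jaccardIndex(1:3, 2:4) # 0.5
#' @export
jaccardIndex <- function(A, B) {
  A <- unique(A)
  B <- unique(B)
  if (length(A) == 0L && length(B) == 0L) {
    stop("Jaccard coefficient of two empty sets is undefined", call. = FALSE)
  }
  length(intersect(A, B)) / length(union(A, B))
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement computed from the contingency
#' table of the two label vectors: 1 for identical partitions (up to label
#' permutation), expectation 0 under independent random labelings.
#'
#' @param a,b integer label vectors over the same observations.
#' @return a number (at most 1).
#' @examples
#' adjustedRand(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: label-invariant
#' @export
adjustedRand <- function(a, b) {
  if (length(a) != length(b)) {
    stop("partitions must cover the same observations", call. = FALSE)
  }
  tab <- table(a, b)
  n <- length(a)
  sumnij <- sum(choose(tab, 2))
  sumai <- sum(choose(rowSums(tab), 2))
  sumbj <- sum(choose(colSums(tab), 2))
  expected <- sumai * sumbj / choose(n, 2)
  maxind <- (sumai + sumbj) / 2
  if (maxind == expected) {
    return(if (sumnij == expected) 1 else 0)
  }
  (sumnij - expected) / (maxind - expected)
}

# Resolve a clustering method descriptor to a handle
#   function(X, Ks, seed) -> n x length(Ks) matrix of canonical labels.
# Built-in methods share one tree across all Ks where the procedure allows.
resolveMethod <- function(method, B = NULL, level = 2L, linkage = "average",
                          policy = "pairwise_complete", perturb = "rows") {
  if (is.function(method)) {
    return(list(handle = method, name = "custom"))
  }
  method <- match.arg(method, c("hier", "ensemble", "ensemble-hi", "kmodes"))
  handle <- switch(method,
    hier = function(X, Ks, seed) {
      tr <- agglomerate(hammingMatrix(X, policy), linkage)
      cutMany(tr, Ks)
    },
    ensemble = function(X, Ks, seed) {
      n <- if (is(X, "CategoricalMatrix")) nObs(X) else nrow(X)
      ens <- ensembleCluster(X,
        B = if (is.null(B)) 200L else B,
        kmin = 2L, kmax = defaultKmax(n),
        linkage = linkage, policy = policy, seed = seed, perturb = perturb
      )
      cutMany(finalTree(ens), Ks)
    },
    `ensemble-hi` = function(X, Ks, seed) {
      n <- if (is(X, "CategoricalMatrix")) nObs(X) else nrow(X)
      ens <- ensembleClusterHighDim(X,
        B = if (is.null(B)) 100L else B,
        kmin = 2L, kmax = defaultKmax(n), level = level,
        linkage = linkage, policy = policy, seed = seed
      )
      cutMany(finalTree(ens), Ks)
    },
    kmodes = function(X, Ks, seed) {
      n <- if (is(X, "CategoricalMatrix")) nObs(X) else nrow(X)
      vapply(seq_along(Ks), function(i) {
        fit <- kmodes(X, Ks[i],
          init = "random",
          seed = deriveSeed(seed, paste0("kmodes-K", Ks[i]))
        )
        canonicalizeLabels(fit$labels)
      }, integer(n))
    }
  )
  list(handle = handle, name = method)
}

#' Bootstrap Jaccard cluster-stability assessment
#'
#' Measures how reproducible a clustering is under resampling. For each K in
#' \code{Ks}: the reference clustering of the full data is computed; then for
#' each bootstrap resample n row indices are drawn with replacement, the
#' resample is reduced to its distinct rows (duplicate rows sit at Hamming
#' distance 0 and would otherwise dominate the linkage), the data subset is
#' reclustered at K, and each reference cluster C is scored by the maximum
#' over resample clusters D of the Jaccard coefficient between C restricted
#' to the resampled rows and D. High coefficients mean the cluster reappears
#' reliably; coefficients near or below 0.5 flag unstable clusters.
#'
#' A resample whose number of distinct rows is below K cannot be clustered at
#' K and is skipped with a warning; the skip counts are recorded in the
#' report.
#'
#' @param X a \linkS4class{CategoricalMatrix} (or integer code matrix).
#' @param method \code{"hier"} (hierarchical, normalized Hamming + average
#'   linkage), \code{"ensemble"}, \code{"ensemble-hi"}, \code{"kmodes"}, or a
#'   function \code{(X, Ks, seed)} returning an n x length(Ks) label matrix.
#' @param Ks integer vector of cluster counts to assess.
#' @param resamples number of bootstrap resamples (default 100).
#' @param seed optional integer master seed; resample draws and any method
#'   randomness derive sub-seeds from it.
#' @param B ensemble size passed to the ensemble methods (defaults: 200 for
#'   \code{"ensemble"}, 100 for \code{"ensemble-hi"}).
#' @param level subspace bootstrap depth for \code{"ensemble-hi"}.
#' @param perturb base-clustering perturbation for \code{"ensemble"}; the
#'   default \code{"rows"} gives the base clusterings the bootstrap
#'   diversity the consensus needs (see [ensembleCluster()]).
#' @param linkage,policy passed to the underlying clustering.
#' @return a \linkS4class{StabilityReport}.
#' @examples
#' X <- generateCategorical(60, K = 3, separation = "high", seed = 1)$X
#' rep <- bootstrapStability(X, "hier", Ks = 3, resamples = 10, seed = 2)
#' stabilityMedians(rep)
#' @export
bootstrapStability <- function(X, method, Ks, resamples = 100L, seed = NULL,
                               B = NULL, level = 2L, linkage = "average",
                               policy = "pairwise_complete",
                               perturb = c("rows", "none")) {
  perturb <- match.arg(perturb)
  cd <- if (is(X, "CategoricalMatrix")) X else CategoricalMatrix(X)
  n <- nObs(cd)
  Ks <- sort(unique(as.integer(Ks)))
  if (any(Ks < 1L | Ks > n)) stop("every K must lie in 1..n", call. = FALSE)
  resamples <- as.integer(resamples)
  if (resamples < 1L) stop("resamples must be >= 1", call. = FALSE)
  mth <- resolveMethod(method,
    B = B, level = level, linkage = linkage, policy = policy,
    perturb = perturb
  )
  refSeed <- if (is.null(seed)) NULL else deriveSeed(seed, "reference")
  refLabels <- mth$handle(cd, Ks, refSeed)
  idx <- withSeed(
    if (is.null(seed)) NULL else deriveSeed(seed, "resampling"),
    matrix(sample.int(n, n * resamples, replace = TRUE), n, resamples)
  )
  rows <- vector("list", length(Ks) * resamples * max(Ks))
  nrec <- 0L
  skipped <- integer(length(Ks))
  names(skipped) <- Ks
  for (r in seq_len(resamples)) {
    S <- sort(unique(idx[, r]))
    nS <- length(S)
    feasible <- Ks[Ks <= nS]
    if (nS < 2L || !length(feasible)) {
      skipped <- skipped + 1L
      next
    }
    # the ensemble methods need kmax < n on the reduced data
    feasible <- feasible[feasible <= nS]
    resSeed <- if (is.null(seed)) NULL else deriveSeed(seed, paste0("method-", r))
    resLabels <- mth$handle(cd[S, ], feasible, resSeed)
    for (ki in seq_along(Ks)) {
      K <- Ks[ki]
      if (!(K %in% feasible)) {
        skipped[ki] <- skipped[ki] + 1L
        next
      }
      refS <- refLabels[S, ki]
      res <- resLabels[, match(K, feasible)]
      Kref <- max(refLabels[, ki])
      Kres <- max(res)
      tab <- table(
        factor(refS, levels = seq_len(Kref)),
        factor(res, levels = seq_len(Kres))
      )
      aC <- rowSums(tab)
      bD <- colSums(tab)
      Jm <- tab / (outer(aC, bD, "+") - tab)
      jac <- apply(Jm, 1L, max)
      for (cc in seq_len(Kref)) {
        nrec <- nrec + 1L
        rows[[nrec]] <- c(K, cc, r, jac[cc])
      }
    }
  }
  if (any(skipped > 0L)) {
    warning(sprintf(
      "%d resample/K combination(s) skipped (K exceeded distinct rows)",
      sum(skipped)
    ))
  }
  tab <- if (nrec) {
    m <- do.call(rbind, rows[seq_len(nrec)])
    data.frame(
      K = as.integer(m[, 1L]), cluster = as.integer(m[, 2L]),
      resample = as.integer(m[, 3L]), jaccard = m[, 4L]
    )
  } else {
    data.frame(
      K = integer(), cluster = integer(), resample = integer(),
      jaccard = numeric()
    )
  }
  new("StabilityReport",
    table = tab,
    skipped = data.frame(K = Ks, skipped = as.integer(skipped)),
    method = mth$name, Ks = Ks, resamples = resamples,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}

#' @rdname StabilityReport-class
#' @param x a \linkS4class{StabilityReport}.
#' @export
setMethod("stabilityTable", "StabilityReport", function(x) x@table)

#' @rdname StabilityReport-class
#' @export
setMethod("stabilityMedians", "StabilityReport", function(x, aggregate =
    c("pooled", "mean", "per_cluster")) {
  aggregate <- match.arg(aggregate)
  tb <- x@table
  if (aggregate == "per_cluster") {
    out <- stats::aggregate(jaccard ~ K + cluster, tb, stats::median)
    return(out[order(out$K, out$cluster), , drop = FALSE])
  }
  f <- if (aggregate == "pooled") stats::median else mean
  out <- stats::aggregate(jaccard ~ K, tb, f)
  names(out)[2L] <- if (aggregate == "pooled") "median" else "mean"
  out
})

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf(
    "StabilityReport: method = %s, %d resamples, K in {%s}\n",
    object@method, object@resamples, paste(object@Ks, collapse = ", ")
  ))
  md <- stabilityMedians(object)
  for (i in seq_len(nrow(md))) {
    cat(sprintf("  K = %d: pooled median Jaccard = %.3f\n", md$K[i], md$median[i]))
  }
  sk <- sum(object@skipped$skipped)
  if (sk > 0L) cat(sprintf("  (%d resample/K combinations skipped)\n", sk))
  invisible(NULL)
})

#' Compare the stability of two methods
#'
#' Per K, the pooled median bootstrap Jaccard coefficient of each report and
#' their difference (first minus second); by convention the ensembled method
#' is passed first, so positive differences mean the ensemble is more stable.
#'
#' @param reportA,reportB \linkS4class{StabilityReport}s over the same Ks and
#'   resample counts.
#' @param aggregate pooling rule, see [stabilityMedians()].
#' @return data.frame with columns \code{K}, \code{medianA}, \code{medianB},
#'   \code{difference}.
#' @export
compareStability <- function(reportA, reportB,
                             aggregate = c("pooled", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!identical(reportA@Ks, reportB@Ks)) {
    stop("reports cover different K ranges", call. = FALSE)
  }
  if (reportA@resamples != reportB@resamples) {
    stop("reports use different resample counts", call. = FALSE)
  }
  ma <- stabilityMedians(reportA, aggregate)
  mb <- stabilityMedians(reportB, aggregate)
  val <- names(ma)[2L]
  data.frame(
    K = ma$K,
    medianA = ma[[val]],
    medianB = mb[[val]][match(ma$K, mb$K)],
    difference = ma[[val]] - mb[[val]][match(ma$K, mb$K)]
  )
}
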