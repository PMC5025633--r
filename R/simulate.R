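#' Factorial design grid for the simulation study
#'
#' Builds the full-factorial grid over sample size, variable profile
#' (\code{mixed12}: 12 variables with cardinalities 2,2,2,3,3,3,4,4,4,4,8,8;
#' \code{quaternary100}: 100 quaternary variables), true cluster count,
#' cluster-size balance and cluster separation. The default levels give 3 x 2
#' x 3 x 2 x 2 = 72 cells, 24 per sample size; restricting \code{n} (e.g.
#' \code{makeDesign(n = 100)}) yields the reduced 24-cell grid used for
#' desk-scale runs.
#'
#' @param n sample sizes to include.
#' @param profile variable profiles to include.
#' @param K_true true cluster counts to include.
#' @param balance cluster-size balance levels.
#' @param separation cluster separation levels.
#' @return data.frame with one row per design cell and a \code{cell} id.
#' @examples
#' nrow(makeDesign()) # 72
#' nrow(makeDesign(n = 100)) # 24
#' @export
makeDesign <- function(n = c(100L, 300L, 1000L),
                       profile = c("mixed12", "quaternary100"),
                       K_true = c(3L, 5L, 7L),
                       balance = c("equal", "unequal"),
                       separation = c("low", "high")) {
  g <- expand.grid(
    n = as.integer(n), profile = profile, K_true = as.integer(K_true),
    balance = balance, separation = separation,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  g$cell <- sprintf(
    "n%d_%s_K%d_%s_%s", g$n, g$profile, g$K_true, g$balance, g$separation
  )
  g[, c("cell", "n", "profile", "K_true", "balance", "separation")]
}

profileCardinalities <- function(profile) {
  switch(profile,
    mixed12 = c(2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 8L, 8L),
    quaternary100 = rep(4L, 100L),
    stop("unknown profile '", profile, "'", call. = FALSE)
  )
}

# Deterministic cluster sizes. equal: n %/% K each, remainder spread over the
# first clusters. unequal: proportional to (1, 2, ..., K), largest-remainder
# apportionment with ties to the smaller cluster index, every cluster >= 1.
clusterSizes <- function(n, K, balance) {
  if (balance == "equal") {
    base <- n %/% K
    sizes <- rep(base, K)
    rem <- n - base * K
    if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    return(sizes)
  }
  props <- seq_len(K) / sum(seq_len(K))
  sizes <- floor(n * props)
  sizes <- pmax(sizes, 1L)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    frac <- n * props - floor(n * props)
    ord <- order(-frac, seq_len(K))
    add <- ord[seq_len(rem)]
    sizes[add] <- sizes[add] + 1L
  } else if (rem < 0L) {
    ord <- order(sizes, decreasing = TRUE)
    i <- 1L
    while (rem < 0L) {
      c <- ord[i]
      if (sizes[c] > 1L) {
        sizes[c] <- sizes[c] - 1L
        rem <- rem + 1L
      }
      i <- if (i == K) 1L else i + 1L
    }
  }
  as.integer(sizes)
}

# Per-cluster per-column category probabilities.
# low separation: all categories equi-likely everywhere (clusters carry no
# signal). high separation: cluster c concentrates mass pHigh on its
# preferred category 1 + ((c + j) mod m_j) in column j and spreads 1 - pHigh
# uniformly over the remaining categories.
clusterColumnProbs <- function(K, cards, separation, pHigh = 0.8) {
  lapply(seq_len(K), function(c) {
    lapply(seq_along(cards), function(j) {
      m <- cards[j]
      if (separation == "low" || m == 1L) {
        return(rep(1 / m, m))
      }
      pref <- 1L + ((c + j) %% m)
      p <- rep((1 - pHigh) / (m - 1L), m)
      p[pref] <- pHigh
      p
    })
  })
}

#' Generate a multinomial-mixture categorical dataset
#'
#' Draws n observations from a K-component mixture of products of
#' multinomial (categorical) distributions — the generating model of the
#' simulation study. Within a cluster, columns are independent draws from the
#' stored per-cluster per-column probability vectors; there are no missing
#' values.
#'
#' At \code{separation = "high"} each cluster concentrates probability
#' \code{pHigh} (default 0.8) on a cluster-preferred category that rotates
#' across columns (\code{1 + ((c + j) mod m_j)}), making clusters
#' well-separated; at \code{separation = "low"} all categories are
#' equi-likely in every cluster and column, so the labels carry no signal.
#'
#' @param n sample size.
#' @param profile \code{"mixed12"} (J = 12, cardinalities
#'   2,2,2,3,3,3,4,4,4,4,8,8) or \code{"quaternary100"} (J = 100, all
#'   quaternary).
#' @param K number of true clusters.
#' @param balance \code{"equal"} cluster sizes (remainder to the first
#'   clusters) or \code{"unequal"} (proportional to 1,2,...,K).
#' @param separation \code{"high"} or \code{"low"}, see Details.
#' @param pHigh concentration of the preferred category at high separation.
#' @param seed optional integer seed.
#' @return list with elements \code{X} (a
#'   \linkS4class{CategoricalMatrix}), \code{labels} (true cluster of each
#'   row), \code{probs} (per-cluster per-column probability vectors) and
#'   \code{design} (the generating parameters).
#' @examples
#' d <- generateCategorical(100, K = 3, seed = 1)
#' table(d$labels) # 34 33 33
#' @export
generateCategorical <- function(n, profile = c("mixed12", "quaternary100"),
                                K = 3L, balance = c("equal", "unequal"),
                                separation = c("high", "low"), pHigh = 0.8,
                                seed = NULL) {
  profile <- match.arg(profile)
  balance <- match.arg(balance)
  separation <- match.arg(separation)
  n <- as.integer(n)
  K <- as.integer(K)
  cards <- profileCardinalities(profile)
  J <- length(cards)
  sizes <- clusterSizes(n, K, balance)
  probs <- clusterColumnProbs(K, cards, separation, pHigh)
  labels <- rep(seq_len(K), times = sizes)
  cd <- matrix(NA_integer_, n, J)
  withSeed(seed, {
    for (c in seq_len(K)) {
      rows <- which(labels == c)
      for (j in seq_len(J)) {
        cd[rows, j] <- sample.int(cards[j], length(rows),
          replace = TRUE, prob = probs[[c]][[j]]
        )
      }
    }
  })
  rownames(cd) <- paste0("obs", seq_len(n))
  X <- CategoricalMatrix(cd,
    colCardinalities = cards,
    colLevels = lapply(cards, function(m) as.character(seq_len(m)))
  )
  list(
    X = X, labels = stats::setNames(labels, rownames(cd)), probs = probs,
    design = list(
      n = n, profile = profile, K_true = K, balance = balance,
      separation = separation, pHigh = pHigh,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
  )
}

#' Run the ensemble-vs-hierarchical stability study
#'
#' For every design cell (and replicate) a multinomial-mixture dataset is
#' generated and each method's bootstrap Jaccard stability is assessed at
#' every K in \code{Ks}. The output collects the pooled median Jaccard per
#' (cell, K, method), the per-(cell, K) differences between the first two
#' methods (by convention ensemble minus hierarchical), and the averages of
#' those differences grouped by sample size and by variable profile.
#'
#' @param design data.frame from [makeDesign()] (or a subset of its rows).
#' @param methods character vector of method names understood by
#'   [bootstrapStability()]; differences are first minus second.
#' @param Ks cluster counts at which stability is assessed.
#' @param resamples bootstrap resamples per stability assessment.
#' @param replicates independent datasets per design cell.
#' @param seed master integer seed; all generation and resampling derives
#'   sub-seeds from it, making the study bit-reproducible.
#' @param B,level,linkage,policy,perturb passed to [bootstrapStability()].
#' @return list with data.frames \code{medians} (cell x K x method),
#'   \code{differences} (cell x K), \code{by_n}, \code{by_profile} and
#'   \code{overall} (grouped means of the differences).
#' @export
runStudy <- function(design = makeDesign(), methods = c("ensemble", "hier"),
                     Ks = c(3L, 5L, 7L), resamples = 100L, replicates = 1L,
                     seed = 1L, B = NULL, level = 2L, linkage = "average",
                     policy = "pairwise_complete", perturb = "rows") {
  stopifnot(length(methods) >= 1L)
  out <- vector("list", nrow(design) * replicates * length(methods))
  k <- 0L
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    for (r in seq_len(replicates)) {
      ds <- generateCategorical(
        n = row$n, profile = row$profile, K = row$K_true,
        balance = row$balance, separation = row$separation,
        seed = deriveSeed(seed, paste0("data-", row$cell, "-rep", r))
      )
      for (m in methods) {
        rep <- bootstrapStability(ds$X, m, Ks,
          resamples = resamples,
          seed = deriveSeed(seed, paste0("stab-", m, "-", row$cell, "-rep", r)),
          B = B, level = level, linkage = linkage, policy = policy,
          perturb = perturb
        )
        md <- stabilityMedians(rep, "pooled")
        k <- k + 1L
        out[[k]] <- data.frame(
          cell = row$cell, replicate = r, n = row$n, profile = row$profile,
          K_true = row$K_true, balance = row$balance,
          separation = row$separation, K = md$K, method = m,
          median_jaccard = md$median
        )
      }
    }
  }
  medians <- do.call(rbind, out[seq_len(k)])
  rownames(medians) <- NULL
  res <- list(medians = medians)
  if (length(methods) >= 2L) {
    a <- medians[medians$method == methods[1L], ]
    b <- medians[medians$method == methods[2L], ]
    key <- function(d) paste(d$cell, d$replicate, d$K)
    b <- b[match(key(a), key(b)), ]
    diffs <- a
    diffs$method <- NULL
    names(diffs)[names(diffs) == "median_jaccard"] <- "medianA"
    diffs$medianB <- b$median_jaccard
    diffs$difference <- diffs$medianA - diffs$medianB
    res$differences <- diffs
    res$by_n <- stats::aggregate(difference ~ n, diffs, mean)
    res$by_profile <- stats::aggregate(difference ~ profile, diffs, mean)
    res$overall <- mean(diffs$difference)
  }
  res
}
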