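#' Derive a stage-specific sub-seed from a master seed
#'
#' Deterministically maps a master seed plus a stage name to an integer seed
#' below 2^31, so that each stage of a pipeline draws from its own stream and
#' adding a stage never perturbs the draws of earlier stages. The derivation
#' is a fixed LCG-style polynomial hash of the stage string, folded into the
#' master seed modulo 2147483647; it is stable across platforms and versions.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return integer seed in [0, 2147483646].
#' @examples
#' deriveSeed(1, "resample-3")
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  v <- utf8ToInt(as.character(stage))
  h <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (ch in v) h <- (h * 69069 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a local RNG state seeded with `seed`; NULL seed uses
# (and advances) the current global stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Relabel cluster indices so that the cluster of the first observation is 1,
# the next new cluster encountered is 2, and so on.
canonicalizeLabels <- function(labels) {
  match(labels, unique(labels))
}

# Symmetric, zero-diagonal, [0,1]-entry check shared by consumers of
# dissimilarity matrices. Accepts "dist" objects and coerces them.
asDissimilarity <- function(D, what = "dissimilarity matrix") {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 0, check.attributes = FALSE))) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  if (any(diag(D) != 0)) stop(what, " must have a zero diagonal", call. = FALSE)
  if (any(D < 0)) stop(what, " must be non-negative", call. = FALSE)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("obs", seq_len(nrow(D)))
  }
  D
}
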