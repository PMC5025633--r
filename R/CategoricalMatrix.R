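#' Construct a CategoricalMatrix
#'
#' @param codes matrix of positive integer category codes, \code{NA} for
#'   missing values. Numeric storage is coerced to integer.
#' @param colLevels optional list of J character vectors giving the original
#'   label of each code per column; defaults to the codes themselves.
#' @param colCardinalities optional integer vector of per-column category
#'   counts; defaults to the largest observed code per column.
#' @param rowLabels optional character vector of observation labels; defaults
#'   to existing row names or \code{obs1..obsn}.
#'
#' @return a \linkS4class{CategoricalMatrix}.
#' @examples
#' X <- CategoricalMatrix(rbind(c(1, 1), c(1, 2), c(2, 2)))
#' codes(X)
#' colCardinalities(X)
#' @export
CategoricalMatrix <- function(codes, colLevels = NULL, colCardinalities = NULL,
                              rowLabels = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (!is.null(rowLabels)) {
    rownames(codes) <- rowLabels
  } else if (is.null(rownames(codes))) {
    rownames(codes) <- paste0("obs", seq_len(nrow(codes)))
  }
  if (is.null(colCardinalities)) {
    colCardinalities <- apply(codes, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) max(v) else 0L
    })
  }
  colCardinalities <- as.integer(colCardinalities)
  if (is.null(colLevels)) {
    colLevels <- lapply(colCardinalities, function(m) as.character(seq_len(m)))
  }
  new("CategoricalMatrix",
    codes = codes, colLevels = colLevels,
    colCardinalities = colCardinalities
  )
}

#' @rdname CategoricalMatrix-class
#' @export
setMethod("codes", "CategoricalMatrix", function(x) x@codes)

#' @rdname CategoricalMatrix-class
#' @export
setMethod("missingMask", "CategoricalMatrix", function(x) is.na(x@codes))

#' @rdname CategoricalMatrix-class
#' @export
setMethod("rowLabels", "CategoricalMatrix", function(x) rownames(x@codes))

#' @rdname CategoricalMatrix-class
#' @export
setMethod("colCardinalities", "CategoricalMatrix", function(x) {
  x@colCardinalities
})

#' @rdname CategoricalMatrix-class
#' @export
setMethod("colLevels", "CategoricalMatrix", function(x) x@colLevels)

#' @rdname CategoricalMatrix-class
#' @export
setMethod("nObs", "CategoricalMatrix", function(x) nrow(x@codes))

#' @rdname CategoricalMatrix-class
#' @export
setMethod("nVars", "CategoricalMatrix", function(x) ncol(x@codes))

#' @rdname CategoricalMatrix-class
#' @export
setMethod("dim", "CategoricalMatrix", function(x) dim(x@codes))

#' @rdname CategoricalMatrix-class
#' @export
setMethod("as.matrix", "CategoricalMatrix", function(x) x@codes)

#' @rdname CategoricalMatrix-class
#' @param i,j row and column indices.
#' @param drop ignored; subsetting always returns a CategoricalMatrix.
#' @param ... unused.
#' @export
setMethod("[", "CategoricalMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@codes))
  if (missing(j)) j <- seq_len(ncol(x@codes))
  new("CategoricalMatrix",
    codes = x@codes[i, j, drop = FALSE],
    colLevels = x@colLevels[j],
    colCardinalities = x@colCardinalities[j]
  )
})

setMethod("show", "CategoricalMatrix", function(object) {
  n <- nrow(object@codes)
  J <- ncol(object@codes)
  miss <- mean(is.na(object@codes))
  card <- object@colCardinalities
  cat(sprintf(
    "CategoricalMatrix: %d observations x %d variables (%.1f%% missing)\n",
    n, J, 100 * miss
  ))
  cat(
    "column cardinalities:",
    paste(utils::head(card, 10L), collapse = " "),
    if (J > 10L) "..." else "", "\n"
  )
  cat(
    "observations:", paste(utils::head(rownames(object@codes), 5L),
      collapse = ", "
    ),
    if (n > 5L) ", ..." else "", "\n"
  )
  invisible(NULL)
})

#' Decode integer codes back to their original labels
#'
#' Inverse of the encoding performed by [readCategoricalTable()],
#' [readAlignedFasta()] and [ctnEncode()]: every non-missing code is replaced
#' by its stored column label; missing values stay \code{NA}.
#'
#' @param x a \linkS4class{CategoricalMatrix}.
#' @return character matrix with the same dimensions and row labels.
#' @export
decodeCategorical <- function(x) {
  stopifnot(is(x, "CategoricalMatrix"))
  cd <- codes(x)
  out <- matrix(NA_character_, nrow(cd), ncol(cd), dimnames = dimnames(cd))
  lv <- colLevels(x)
  for (j in seq_len(ncol(cd))) {
    ok <- !is.na(cd[, j])
    out[ok, j] <- lv[[j]][cd[ok, j]]
  }
  out
}
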