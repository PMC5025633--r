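#' Default nucleotide alphabet map
#'
#' Character-to-code mapping used when encoding aligned sequences: A, T, C, G
#' become 1, 2, 3, 4; the gap characters \code{-} and \code{.} and the IUPAC
#' ambiguity codes (N, R, Y, S, W, K, M, B, D, H, V) map to missing
#' (\code{NA}). Matching is case-insensitive. An alphabet map is a named
#' integer vector: names are the (upper-case) characters covered, values are
#' the codes, \code{NA} meaning "treat as missing".
#'
#' @return named integer vector.
#' @examples
#' defaultAlphabet()[c("A", "T", "-", "N")]
#' @export
defaultAlphabet <- function() {
  map <- c(
    A = 1L, T = 2L, C = 3L, G = 4L,
    `-` = NA_integer_, `.` = NA_integer_
  )
  amb <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  c(map, stats::setNames(rep(NA_integer_, length(amb)), amb))
}

# Labels of the non-missing codes of an alphabet map, indexed by code.
alphabetLevels <- function(alphabet) {
  obs <- alphabet[!is.na(alphabet)]
  if (any(duplicated(obs))) {
    stop("alphabet map must be injective on non-missing characters",
      call. = FALSE
    )
  }
  lv <- character(max(obs))
  lv[obs] <- names(obs)
  lv
}

#' Encode a character matrix as integer categorical codes
#'
#' Applies an alphabet map to a character matrix (one sequence per row, one
#' aligned position per column): nucleotides become small integer codes and
#' gap/ambiguity characters become missing values. This is the encoding step
#' used for aligned sequence input.
#'
#' @param chars character matrix.
#' @param alphabet named integer alphabet map, see [defaultAlphabet()].
#' @return a \linkS4class{CategoricalMatrix}; every column carries the full
#'   alphabet cardinality.
#' @examples
#' ctnEncode(rbind(c("A", "T"), c("G", "-")))
#' @export
ctnEncode <- function(chars, alphabet = defaultAlphabet()) {
  chars <- as.matrix(chars)
  up <- toupper(chars)
  bad <- !(up %in% names(alphabet))
  if (any(bad)) {
    w <- which(bad)[1L]
    rc <- arrayInd(w, dim(up))
    lab <- rownames(chars)[rc[1L]]
    stop(sprintf(
      "character '%s' (row %s, position %d) is not covered by the alphabet",
      chars[w], if (is.null(lab)) rc[1L] else lab, rc[2L]
    ), call. = FALSE)
  }
  cd <- matrix(alphabet[up], nrow(chars), ncol(chars))
  rownames(cd) <- rownames(chars)
  m <- length(alphabetLevels(alphabet))
  CategoricalMatrix(cd,
    colLevels = rep(list(alphabetLevels(alphabet)), ncol(cd)),
    colCardinalities = rep(m, ncol(cd))
  )
}

#' Read a categorical data table
#'
#' Reads a rectangular CSV/TSV of category labels and codes each column's
#' distinct labels as 1, 2, ... in order of first appearance. Empty cells and
#' \code{NA} become missing values. The label-to-code dictionaries are
#' retained so [decodeCategorical()] can round-trip the data.
#'
#' @param path file path.
#' @param delimiter field separator (default \code{","}).
#' @param header logical, whether the first row holds column names.
#' @param rowNames logical, whether the first column holds observation labels.
#' @return a \linkS4class{CategoricalMatrix}.
#' @export
readCategoricalTable <- function(path, delimiter = ",", header = FALSE,
                                 rowNames = FALSE) {
  df <- utils::read.table(path,
    sep = delimiter, header = header, colClasses = "character",
    stringsAsFactors = FALSE, check.names = FALSE, na.strings = c("NA", ""),
    fill = FALSE, blank.lines.skip = TRUE, quote = "\"", comment.char = ""
  )
  if (rowNames) {
    labs <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
  } else {
    labs <- paste0("obs", seq_len(nrow(df)))
  }
  if (ncol(df) < 1L) stop("table has no data columns", call. = FALSE)
  cd <- matrix(NA_integer_, nrow(df), ncol(df))
  lv <- vector("list", ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- df[[j]]
    if (all(is.na(v))) {
      stop(sprintf("column %d has no non-missing values", j), call. = FALSE)
    }
    u <- unique(v[!is.na(v)])
    cd[, j] <- match(v, u)
    lv[[j]] <- u
  }
  rownames(cd) <- labs
  CategoricalMatrix(cd, colLevels = lv, colCardinalities = lengths(lv))
}

#' Read pre-aligned sequences from a FASTA file
#'
#' Reads a multi-record FASTA of equal-length (already aligned) sequences and
#' encodes them with an alphabet map: nucleotides become integer codes and
#' gaps become missing values. Row labels are the FASTA headers up to the
#' first whitespace. Alignment itself is out of scope: records of unequal
#' length raise an error asking the user to align first.
#'
#' @inheritParams ctnEncode
#' @param path FASTA file path.
#' @return a \linkS4class{CategoricalMatrix}.
#' @export
readAlignedFasta <- function(path, alphabet = defaultAlphabet()) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    stop("no FASTA records found in '", path, "'", call. = FALSE)
  }
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L) {
    stop(
      "FASTA records have unequal lengths (", min(w), "..", max(w),
      "); align the sequences first (any multiple aligner), then re-read",
      call. = FALSE
    )
  }
  chars <- as.matrix(seqs)
  rownames(chars) <- sub("\\s.*$", "", names(seqs))
  ctnEncode(chars, alphabet)
}

#' Write cluster labels to a TSV file
#'
#' @param labels integer cluster assignment, ideally named by observation.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeLabels <- function(labels, path) {
  if (length(labels) == 0L) stop("empty label vector", call. = FALSE)
  nm <- names(labels)
  if (is.null(nm)) nm <- paste0("obs", seq_along(labels))
  utils::write.table(
    data.frame(observation = nm, cluster = as.integer(labels)),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write / read a labeled symmetric dissimilarity matrix
#'
#' The matrix is written in full symmetric form as TSV with a header row and
#' a leading label column; \code{readMatrix} inverts it.
#'
#' @param D symmetric numeric matrix with row labels.
#' @param path file path.
#' @return \code{writeMatrix}: the path, invisibly. \code{readMatrix}: the
#'   labeled numeric matrix.
#' @export
writeMatrix <- function(D, path) {
  D <- asDissimilarity(D)
  df <- data.frame(label = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeMatrix
#' @export
readMatrix <- function(path) {
  df <- utils::read.table(path,
    sep = "\t", header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  labs <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- labs
  colnames(M) <- labs
  M
}
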