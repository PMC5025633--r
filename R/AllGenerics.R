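#' @rdname CategoricalMatrix-class
#' @param object,x a \linkS4class{CategoricalMatrix} (or other object).
#' @export
setGeneric("codes", function(x) standardGeneric("codes"))

#' @rdname CategoricalMatrix-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname CategoricalMatrix-class
#' @export
setGeneric("rowLabels", function(x) standardGeneric("rowLabels"))

#' @rdname CategoricalMatrix-class
#' @export
setGeneric("colCardinalities", function(x) standardGeneric("colCardinalities"))

#' @rdname CategoricalMatrix-class
#' @export
setGeneric("colLevels", function(x) standardGeneric("colLevels"))

#' @rdname CategoricalMatrix-class
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))

#' @rdname CategoricalMatrix-class
#' @export
setGeneric("nVars", function(x) standardGeneric("nVars"))

#' @rdname EnsembleClustering-class
#' @export
setGeneric("ensembleDistances", function(x) standardGeneric("ensembleDistances"))

#' @rdname EnsembleClustering-class
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @rdname EnsembleClustering-class
#' @export
setGeneric("finalTree", function(x) standardGeneric("finalTree"))

#' @rdname StabilityReport-class
#' @export
setGeneric("stabilityTable", function(x) standardGeneric("stabilityTable"))

#' @rdname StabilityReport-class
#' @param aggregate how to pool coefficients per K: \code{"pooled"} (median
#'   over all clusters and resamples, the default), \code{"mean"}, or
#'   \code{"per_cluster"} (median per reference cluster).
#' @export
setGeneric("stabilityMedians",
  function(x, aggregate = c("pooled", "mean", "per_cluster")) {
    standardGeneric("stabilityMedians")
  }
)
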