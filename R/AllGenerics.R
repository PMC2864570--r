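#' @rdname FitnessDataset-class
#' @param object,x a \linkS4class{FitnessDataset}
#' @export
setGeneric("fdScores", function(x) standardGeneric("fdScores"))

#' @rdname FitnessDataset-class
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname FitnessDataset-class
#' @export
setGeneric("zygosity", function(x) standardGeneric("zygosity"))

#' @rdname FitnessDataset-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname FitnessDataset-class
#' @export
setGeneric("conditionIds", function(x) standardGeneric("conditionIds"))

#' @rdname FitnessDataset-class
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Collapse replicate conditions to one column per compound
#'
#' @param ds a \linkS4class{FitnessDataset}
#' @export
setGeneric("collapseReplicates", function(ds) standardGeneric("collapseReplicates"))

#' Extract the similarity/score matrix from a matrix-valued result
#'
#' @param x a \linkS4class{CofitnessMatrix}, \linkS4class{CoinhibitionMatrix}
#'   or \linkS4class{FingerprintMatrix}
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname PRCurve-class
#' @param x a \linkS4class{PRCurve}
#' @export
setGeneric("prPoints", function(x) standardGeneric("prPoints"))

#' @importFrom stats predict
#' @export
setGeneric("predict")
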