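#' Gene identifiers of a molPS object
#' @param x a molPS object.
#' @return character vector of gene symbols (in table/rank order).
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Gene weights as a named numeric vector
#' @param x a [GeneWeightTable-class] or [TrainedModel-class].
#' @return named numeric vector, names are gene symbols.
#' @export
setGeneric("geneWeights", function(x) standardGeneric("geneWeights"))

#' Gene regulation directions (relative to responders)
#' @param x a molPS object carrying directions.
#' @return named character vector of `"up"`/`"down"`.
#' @export
setGeneric("geneDirections", function(x) standardGeneric("geneDirections"))

#' Binary score matrix of a Gene Score table
#' @param x a [GeneScoreTable-class].
#' @return integer matrix, samples x genes, entries 0/1.
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' Binary response vector (1 = responder, 0 = non-responder)
#' @param x a [GeneScoreTable-class] or [MPSResult-class].
#' @return integer vector of 0/1 labels.
#' @export
setGeneric("responseVector", function(x) standardGeneric("responseVector"))

#' Per-gene thresholding medians of a Gene Score table
#' @param x a [GeneScoreTable-class].
#' @return named numeric vector of pooled-cohort medians.
#' @export
setGeneric("geneMedians", function(x) standardGeneric("geneMedians"))

#' Per-sample molecular prognostic scores
#' @param x an [MPSResult-class].
#' @return named numeric vector of mPS values.
#' @export
setGeneric("mpsValues", function(x) standardGeneric("mpsValues"))

#' Empirical ROC curve points
#' @param x an [MPSResult-class].
#' @return two-column matrix of (fpr, tpr), anchored at (0,0) and (1,1).
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' Area under the ROC curve
#' @param x an [MPSResult-class].
#' @return AUC in \[0, 1\].
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' Permutation importances of a gene ranking
#' @param x a [RankedGenes-class].
#' @return named numeric vector (mean decrease in accuracy), rank order.
#' @export
setGeneric("importanceValues", function(x) standardGeneric("importanceValues"))

#' Provenance record of a trained model
#' @param x a [TrainedModel-class].
#' @return named list of seeds, hyperparameters and thresholds.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
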