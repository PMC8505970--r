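## Accessors and show() methods for the S4 containers.

#' Construct an expression cohort
#'
#' Wraps a validated log2 expression matrix (genes x samples) and optional
#' sample annotations into a [UCCohort-class].
#'
#' @param exprs numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty dimnames and no missing values.
#' @param response optional character vector (`"responder"`/`"non_responder"`)
#'   parallel to the samples.
#' @param batch optional vector of batch (source dataset) identifiers.
#' @return a [UCCohort-class].
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' UCCohort(m, response = c("responder", "non_responder"), batch = c(1, 1))
#' @export
UCCohort <- function(exprs, response = NULL, batch = NULL) {
  if (!is.matrix(exprs))
    exprs <- as.matrix(exprs)
  cd <- S4Vectors::DataFrame(row.names = colnames(exprs))
  if (!is.null(response)) cd$response <- as.character(response)
  if (!is.null(batch)) cd$batch <- as.character(batch)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd)
  new("UCCohort", se)
}

#' Log2 expression matrix of a cohort
#' @param x a [UCCohort-class].
#' @return numeric matrix, genes x samples.
#' @export
expressionMatrix <- function(x) {
  SummarizedExperiment::assay(x, "exprs")
}

#' Response labels of a cohort
#' @param x a [UCCohort-class].
#' @return character vector (`"responder"`/`"non_responder"`), or `NULL` when
#'   the cohort carries no labels.
#' @export
responseLabels <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("response" %in% colnames(cd)) as.character(cd$response) else NULL
}

#' Batch identifiers of a cohort
#' @param x a [UCCohort-class].
#' @return character vector of batch ids, or `NULL` when unknown.
#' @export
batchLabels <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("batch" %in% colnames(cd)) as.character(cd$batch) else NULL
}

#' @describeIn GeneWeightTable-class gene symbols.
#' @param x,object a `GeneWeightTable`.
#' @export
setMethod("geneIds", "GeneWeightTable", function(x) x@gene)

#' @describeIn GeneWeightTable-class named weight vector.
#' @export
setMethod("geneWeights", "GeneWeightTable",
          function(x) setNames(x@weight, x@gene))

#' @describeIn GeneWeightTable-class named direction vector.
#' @export
setMethod("geneDirections", "GeneWeightTable",
          function(x) setNames(x@direction, x@gene))

#' @describeIn GeneWeightTable-class number of genes.
#' @export
setMethod("length", "GeneWeightTable", function(x) length(x@gene))

setMethod("show", "GeneWeightTable", function(object) {
  cat(sprintf("GeneWeightTable with %d genes\n", length(object@gene)))
  cat(sprintf("  weights: [%.4f, %.4f]; directions: %d up, %d down\n",
              min(object@weight), max(object@weight),
              sum(object@direction == "up"),
              sum(object@direction == "down")))
})

#' Coerce a GeneWeightTable to a data.frame
#' @param x a [GeneWeightTable-class].
#' @param ... unused.
#' @return data.frame with columns `gene`, `weight`, `direction`.
#' @export
as.data.frame.GeneWeightTable <- function(x, ...) {
  data.frame(gene = x@gene, weight = x@weight, direction = x@direction,
             stringsAsFactors = FALSE)
}

#' @describeIn GeneScoreTable-class signature gene symbols (column order).
#' @param x,object a `GeneScoreTable`.
#' @export
setMethod("geneIds", "GeneScoreTable", function(x) colnames(x@scores))

#' @describeIn GeneScoreTable-class binary score matrix.
#' @export
setMethod("scoreMatrix", "GeneScoreTable", function(x) x@scores)

#' @describeIn GeneScoreTable-class binary response vector.
#' @export
setMethod("responseVector", "GeneScoreTable", function(x) x@response)

#' @describeIn GeneScoreTable-class per-gene thresholding medians.
#' @export
setMethod("geneMedians", "GeneScoreTable", function(x) x@medians)

#' @describeIn GeneScoreTable-class per-gene directions.
#' @export
setMethod("geneDirections", "GeneScoreTable", function(x) x@directions)

setMethod("show", "GeneScoreTable", function(object) {
  cat(sprintf("GeneScoreTable: %d samples x %d genes%s\n",
              nrow(object@scores), ncol(object@scores),
              if (length(object@response)) " (+ response column)" else ""))
})

#' @describeIn RankedGenes-class gene symbols in rank order.
#' @param x,object a `RankedGenes`.
#' @export
setMethod("geneIds", "RankedGenes", function(x) x@gene)

#' @describeIn RankedGenes-class named importances in rank order.
#' @export
setMethod("importanceValues", "RankedGenes",
          function(x) setNames(x@importance, x@gene))

#' @describeIn RankedGenes-class number of ranked genes.
#' @export
setMethod("length", "RankedGenes", function(x) length(x@gene))

setMethod("show", "RankedGenes", function(object) {
  cat(sprintf("RankedGenes: %d genes, %d trees (seed %d)\n",
              length(object@gene), object@nTrees, object@seed))
  k <- min(5L, length(object@gene))
  if (k)
    cat("  top:", paste(sprintf("%s (%.4f)", object@gene[seq_len(k)],
                                object@importance[seq_len(k)]),
                        collapse = ", "), "\n")
})

setMethod("show", "ANNModel", function(object) {
  cat(sprintf("ANNModel: %d inputs -> %d hidden (ReLU) -> %d softmax outputs\n",
              nrow(object@Win), ncol(object@Win), length(object@bOut)))
  if (length(object@trace))
    cat(sprintf("  trained %d epochs; loss %.4f -> %.4f\n",
                length(object@trace), object@trace[1L],
                object@trace[length(object@trace)]))
})

#' @describeIn MPSResult-class per-sample mPS values (named).
#' @param x,object an `MPSResult`.
#' @export
setMethod("mpsValues", "MPSResult",
          function(x) setNames(x@mps, x@sampleIds))

#' @describeIn MPSResult-class binary response labels.
#' @export
setMethod("responseVector", "MPSResult", function(x) x@response)

#' @describeIn MPSResult-class ROC curve points.
#' @export
setMethod("rocPoints", "MPSResult", function(x) x@rocPoints)

#' @describeIn MPSResult-class area under the ROC curve.
#' @export
setMethod("aucValue", "MPSResult", function(x) x@auc)

setMethod("show", "MPSResult", function(object) {
  cat(sprintf("MPSResult: %d samples (%d responders), AUC = %.3f\n",
              length(object@mps), sum(object@response), object@auc))
})

#' @describeIn TrainedModel-class signature gene symbols.
#' @param x,object a `TrainedModel`.
#' @export
setMethod("geneIds", "TrainedModel", function(x) x@weights@gene)

#' @describeIn TrainedModel-class the signature weight table's weights.
#' @export
setMethod("geneWeights", "TrainedModel", function(x) geneWeights(x@weights))

#' @describeIn TrainedModel-class the signature directions.
#' @export
setMethod("geneDirections", "TrainedModel",
          function(x) geneDirections(x@weights))

#' @describeIn TrainedModel-class seeds/hyperparameters/thresholds record.
#' @export
setMethod("provenance", "TrainedModel", function(x) x@provenance)

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %d-gene mPS signature\n",
              length(object@weights@gene)))
  pv <- object@provenance
  if (length(pv))
    cat("  provenance:", paste(names(pv), collapse = ", "), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d genes (%d down/%d up in responders), ",
                     "%d responders / %d non-responders\n"),
              object@nGenes, object@nSigDown, object@nSigUp,
              object@nResp, object@nNonResp))
  cat(sprintf("  delta = %g, sigma = %g, %d batch(es), seed = %d\n",
              object@delta, object@sigma, length(object@batchOffsets),
              object@seed))
})
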