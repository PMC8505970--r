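#' Expression cohort container
#'
#' `UCCohort` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"exprs"` assay of finite log2 expression values (genes in rows,
#' samples in columns). Response labels (`"responder"` / `"non_responder"`)
#' and batch (source dataset) identifiers live in `colData` under the
#' `response` and `batch` columns when known.
#'
#' Values are assumed to be on the log2 scale already (e.g. RMA-normalized
#' microarray intensities); no unit detection is attempted and missing values
#' are rejected rather than imputed.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [UCCohort()] for construction, [expressionMatrix()],
#'   [responseLabels()], [batchLabels()].
#' @name UCCohort-class
#' @exportClass UCCohort
setClass("UCCohort", contains = "SummarizedExperiment")

.validUCCohort <- function(object) {
  msg <- character()
  if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(x))
      msg <- c(msg, "expression values must be numeric")
    else if (any(!is.finite(x)))
      msg <- c(msg, "expression values must be finite (no NA/NaN/Inf)")
    if (is.null(rownames(x)) || is.null(colnames(x)))
      msg <- c(msg, "gene and sample identifiers are required as dimnames")
    else {
      if (anyDuplicated(colnames(x)))
        msg <- c(msg, sprintf("duplicated sample ids: %s",
                              paste(unique(colnames(x)[duplicated(colnames(x))]),
                                    collapse = ", ")))
      if (nrow(x) == 0L || ncol(x) == 0L)
        msg <- c(msg, "expression matrix must be non-empty")
    }
  }
  cd <- SummarizedExperiment::colData(object)
  if ("response" %in% colnames(cd)) {
    bad <- setdiff(unique(as.character(cd$response)),
                   c("responder", "non_responder"))
    if (length(bad))
      msg <- c(msg, sprintf(
        "response labels must be 'responder'/'non_responder'; found: %s",
        paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}
setValidity("UCCohort", .validUCCohort)

#' Signature gene weight table
#'
#' One row per signature gene: the gene symbol, its scalar Gene Weight (the
#' maximum input-to-hidden weight of the trained network), and its regulation
#' direction *relative to responders* (`"up"` = higher expression in
#' responders). The packaged reference table for the published 30-gene
#' infliximab-response signature is returned by [trainingGeneWeights()].
#'
#' @slot gene character vector of unique gene symbols.
#' @slot weight finite numeric weights, parallel to `gene`.
#' @slot direction `"up"` or `"down"` per gene, relative to responders.
#' @seealso [readGeneWeights()], [extractGeneWeights()], [computeMPS()].
#' @exportClass GeneWeightTable
setClass("GeneWeightTable",
         representation(gene = "character", weight = "numeric",
                        direction = "character"))

setValidity("GeneWeightTable", function(object) {
  msg <- character()
  n <- length(object@gene)
  if (length(object@weight) != n || length(object@direction) != n)
    msg <- c(msg, "gene, weight and direction must have equal length")
  if (anyDuplicated(object@gene))
    msg <- c(msg, sprintf("duplicated gene ids: %s",
                          paste(unique(object@gene[duplicated(object@gene)]),
                                collapse = ", ")))
  if (any(!is.finite(object@weight)))
    msg <- c(msg, "weights must be finite")
  if (!all(object@direction %in% c("up", "down")))
    msg <- c(msg, "direction must be 'up' or 'down'")
  if (length(msg)) msg else TRUE
})

#' Binary Gene Score table
#'
#' Samples x signature-genes matrix of 0/1 scores obtained by direction-aware
#' median thresholding ([binarizeGene()]), together with the binary response
#' vector (1 = responder, 0 = non-responder), the per-gene medians used for
#' thresholding, and the gene directions. Stored medians reproduce the scores
#' when re-applied to the same expression values.
#'
#' @slot scores integer matrix, samples x genes, entries in \{0, 1\}.
#' @slot response integer vector in \{0, 1\} (length 0 when labels unknown).
#' @slot medians named numeric, the pooled-cohort median per gene.
#' @slot directions named character, `"up"`/`"down"` per gene.
#' @seealso [buildGeneScoreTable()], [computeMPS()].
#' @exportClass GeneScoreTable
setClass("GeneScoreTable",
         representation(scores = "matrix", response = "integer",
                        medians = "numeric", directions = "character"))

setValidity("GeneScoreTable", function(object) {
  msg <- character()
  s <- object@scores
  if (is.null(rownames(s)) || is.null(colnames(s)))
    msg <- c(msg, "scores must carry sample and gene dimnames")
  if (!all(s %in% c(0L, 1L)))
    msg <- c(msg, "scores must be 0/1")
  if (length(object@response) && length(object@response) != nrow(s))
    msg <- c(msg, "response length must match the number of samples")
  if (length(object@response) && !all(object@response %in% c(0L, 1L)))
    msg <- c(msg, "response must be 0/1")
  if (!identical(names(object@medians), colnames(s)))
    msg <- c(msg, "medians must be named by the score columns")
  if (!identical(names(object@directions), colnames(s)))
    msg <- c(msg, "directions must be named by the score columns")
  if (!all(object@directions %in% c("up", "down")))
    msg <- c(msg, "directions must be 'up' or 'down'")
  if (length(msg)) msg else TRUE
})

#' Random-forest gene ranking
#'
#' Genes ordered by decreasing out-of-bag permutation importance (mean
#' decrease in accuracy), ties broken lexicographically by gene symbol so the
#' top-k selection is reproducible. Ranks run 1..n with no gaps.
#'
#' @slot gene character, in rank order.
#' @slot importance numeric, mean decrease in accuracy per gene.
#' @slot rank integer 1..n.
#' @slot nTrees number of trees grown.
#' @slot seed RNG seed used for the fit.
#' @seealso [rankGenesRF()], [topGenes()].
#' @exportClass RankedGenes
setClass("RankedGenes",
         representation(gene = "character", importance = "numeric",
                        rank = "integer", nTrees = "integer",
                        seed = "integer"))

setValidity("RankedGenes", function(object) {
  msg <- character()
  n <- length(object@gene)
  if (length(object@importance) != n || length(object@rank) != n)
    msg <- c(msg, "gene, importance and rank must have equal length")
  if (n && !identical(object@rank, seq_len(n)))
    msg <- c(msg, "ranks must be 1..n with no gaps")
  if (n > 1) {
    o <- order(-object@importance, object@gene)
    if (!identical(o, seq_len(n)))
      msg <- c(msg, "entries must be sorted by decreasing importance, ties lexicographic")
  }
  if (length(msg)) msg else TRUE
})

#' Shallow neural-network model
#'
#' One-hidden-layer classifier: 10 ReLU hidden units, 2-node softmax output
#' (non-responder, responder), trained by full-batch Adam on mean categorical
#' cross-entropy. `trace` records the loss after each epoch.
#'
#' @slot Win input-to-hidden weights, genes x hidden units.
#' @slot bHidden hidden bias vector.
#' @slot Wout hidden-to-output weights, hidden units x 2.
#' @slot bOut output bias vector (length 2).
#' @slot trace per-epoch training loss.
#' @slot hyperparams list: learning rate, epochs, Adam beta1/beta2/epsilon,
#'   initialization scheme, seed.
#' @seealso [trainANN()], [extractGeneWeights()].
#' @exportClass ANNModel
setClass("ANNModel",
         representation(Win = "matrix", bHidden = "numeric", Wout = "matrix",
                        bOut = "numeric", trace = "numeric",
                        hyperparams = "list"))

setValidity("ANNModel", function(object) {
  msg <- character()
  if (any(!is.finite(object@Win)) || any(!is.finite(object@Wout)) ||
      any(!is.finite(object@bHidden)) || any(!is.finite(object@bOut)))
    msg <- c(msg, "all parameters must be finite")
  if (ncol(object@Win) != length(object@bHidden))
    msg <- c(msg, "Win columns must match hidden bias length")
  if (nrow(object@Wout) != length(object@bHidden) ||
      ncol(object@Wout) != length(object@bOut))
    msg <- c(msg, "Wout must be hidden x output")
  if (any(!is.finite(object@trace)))
    msg <- c(msg, "training trace must be finite")
  if (length(object@trace) >= 2 &&
      object@trace[length(object@trace)] > object@trace[1L] + 1e-8)
    msg <- c(msg, "final training loss exceeds initial loss")
  if (length(msg)) msg else TRUE
})

#' Molecular prognostic score result
#'
#' Per-sample mPS values with labels, the empirical ROC curve and its AUC.
#' The AUC is the tie-corrected Mann-Whitney rank statistic; by construction
#' it agrees with the trapezoidal area under `rocPoints` to 1e-12, and the
#' validity method enforces that agreement.
#'
#' @slot sampleIds character sample identifiers.
#' @slot mps numeric mPS per sample.
#' @slot response integer 0/1 labels (1 = responder).
#' @slot rocPoints two-column matrix (fpr, tpr), anchored at (0,0) and (1,1).
#' @slot auc area under the ROC curve.
#' @seealso [computeMPS()], [rankAUC()], [rocCurve()].
#' @exportClass MPSResult
setClass("MPSResult",
         representation(sampleIds = "character", mps = "numeric",
                        response = "integer", rocPoints = "matrix",
                        auc = "numeric"))

setValidity("MPSResult", function(object) {
  msg <- character()
  n <- length(object@sampleIds)
  if (length(object@mps) != n || length(object@response) != n)
    msg <- c(msg, "sampleIds, mps and response must have equal length")
  rp <- object@rocPoints
  if (ncol(rp) != 2L)
    msg <- c(msg, "rocPoints must have two columns (fpr, tpr)")
  else {
    if (!isTRUE(all.equal(rp[1L, ], c(fpr = 0, tpr = 0), tolerance = 1e-12)) ||
        !isTRUE(all.equal(rp[nrow(rp), ], c(fpr = 1, tpr = 1), tolerance = 1e-12)))
      msg <- c(msg, "rocPoints must be anchored at (0,0) and (1,1)")
    if (is.unsorted(rp[, 1L]) || is.unsorted(rp[, 2L]))
      msg <- c(msg, "rocPoints coordinates must be non-decreasing")
    trap <- sum(diff(rp[, 1L]) * (rp[-1L, 2L] + rp[-nrow(rp), 2L]) / 2)
    if (abs(trap - object@auc) > 1e-12)
      msg <- c(msg, "AUC must equal the trapezoidal area of rocPoints")
  }
  if (object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Trained mPS predictor
#'
#' The reusable artifact of [runTrainingPipeline()]: the 30-gene signature
#' with directions and Gene Weights (one [GeneWeightTable-class], so signature
#' and weights cover identical gene sets by construction) plus full
#' provenance (seeds, hyperparameters, thresholds, package version). External
#' validation reuses the weights and directions unchanged; only the Gene
#' Score medians are recomputed on the new cohort.
#'
#' @slot weights a [GeneWeightTable-class].
#' @slot provenance named list of seeds, hyperparameters and thresholds.
#' @seealso [runTrainingPipeline()], [validateExternal()].
#' @exportClass TrainedModel
setClass("TrainedModel",
         representation(weights = "GeneWeightTable", provenance = "list"))

#' Synthetic cohort configuration
#'
#' Parameters of the two-class Gaussian log-scale cohort generator: planted
#' signature sizes and effect (log2 units), within-class noise, additive
#' per-batch offsets, class/batch layout and seed. `nSigDown` counts genes
#' lower in responders (higher in non-responders); `nSigUp` the converse.
#'
#' @slot nGenes total genes simulated.
#' @slot nSigDown planted genes lower in responders.
#' @slot nSigUp planted genes higher in responders.
#' @slot nResp,nNonResp samples per class.
#' @slot delta planted |log2 fold change| (log2 units).
#' @slot sigma within-class standard deviation (log2 units).
#' @slot batchOffsets additive shift per batch (log2 units).
#' @slot batchAssignment batch index per sample (responders first).
#' @slot baselineRange interval for the per-gene baseline mean.
#' @slot seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @seealso [simConfig()], [defaultTrainingConfig()], [simulateCohort()].
#' @exportClass SimConfig
setClass("SimConfig",
         representation(nGenes = "integer", nSigDown = "integer",
                        nSigUp = "integer", nResp = "integer",
                        nNonResp = "integer", delta = "numeric",
                        sigma = "numeric", batchOffsets = "numeric",
                        batchAssignment = "integer",
                        baselineRange = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSigDown + object@nSigUp > object@nGenes)
    msg <- c(msg, "planted signature larger than nGenes")
  if (any(c(object@nGenes, object@nSigDown, object@nSigUp,
            object@nResp, object@nNonResp) < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (object@sigma <= 0)
    msg <- c(msg, "sigma must be positive")
  if (object@delta < 0)
    msg <- c(msg, "delta must be non-negative")
  n <- object@nResp + object@nNonResp
  if (length(object@batchAssignment) != n)
    msg <- c(msg, "batchAssignment must cover every sample")
  if (length(object@batchAssignment) &&
      (min(object@batchAssignment) < 1L ||
       max(object@batchAssignment) > length(object@batchOffsets)))
    msg <- c(msg, "batchAssignment indexes outside batchOffsets")
  if (length(object@baselineRange) != 2L ||
      object@baselineRange[2L] < object@baselineRange[1L])
    msg <- c(msg, "baselineRange must be an ordered interval")
  if (length(msg)) msg else TRUE
})
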