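## End-to-end orchestration: duplicate collapsing -> batch correction ->
## DEG screen -> random-forest top-k -> Gene Score -> network Gene Weights
## -> mPS -> ROC/AUC, plus external-cohort validation.

#' Run the full mPS training pipeline
#'
#' Chains [collapseDuplicates()], [correctBatchEffect()],
#' [differentialExpression()], [filterDEGs()], [rankGenesRF()],
#' [topGenes()], [buildGeneScoreTable()], [trainANN()],
#' [extractGeneWeights()], [computeMPS()] and the ROC/AUC evaluation on one
#' annotated cohort. Signature directions come from the sign of each gene's
#' log2FC (`"up"` = higher in responders). All seeds and thresholds are
#' recorded in the returned model's provenance; identical inputs and seed
#' reproduce the model bit-exactly.
#'
#' @param cohort an annotated [UCCohort-class] (response and batch).
#' @param k signature size (default 30).
#' @param fdrThreshold,lfcThreshold DEG filter cutoffs (defaults 0.05 / 1,
#'   strict inequalities).
#' @param nTrees random-forest size (default 500).
#' @param epochs,lr network training epochs and learning rate (defaults
#'   3000 / 0.001).
#' @param seed integer master seed; the forest uses `seed` and the network
#'   initialization `seed + 1`.
#' @return list with elements `model` (a [TrainedModel-class]) and `result`
#'   (the in-sample [MPSResult-class]).
#' @seealso [validateExternal()]
#' @export
runTrainingPipeline <- function(cohort, k = 30L, fdrThreshold = 0.05,
                                lfcThreshold = 1, nTrees = 500L,
                                epochs = 3000L, lr = 0.001, seed) {
  if (missing(seed))
    stop("a seed is required", call. = FALSE)
  seed <- as.integer(seed)
  cohort <- collapseDuplicates(cohort)
  if (!is.null(batchLabels(cohort)) &&
      length(unique(batchLabels(cohort))) > 1L)
    cohort <- correctBatchEffect(cohort)
  degTable <- differentialExpression(cohort)
  degs <- filterDEGs(degTable, fdrThreshold, lfcThreshold)
  if (nrow(degs) < k)
    stop(nrow(degs), " genes pass the DEG filter but k = ", k,
         "; lower k or relax the thresholds", call. = FALSE)
  ranked <- rankGenesRF(cohort, genes = degs$gene, nTrees = nTrees,
                        seed = seed)
  sigGenes <- topGenes(ranked, k)
  signature <- data.frame(
    gene = sigGenes,
    direction = degs$direction[match(sigGenes, degs$gene)],
    stringsAsFactors = FALSE)
  scoreTable <- buildGeneScoreTable(cohort, signature)
  ann <- trainANN(scoreTable, epochs = epochs, lr = lr, seed = seed + 1L)
  weights <- extractGeneWeights(ann, geneIds = sigGenes,
                                directions = signature$direction)
  mps <- computeMPS(scoreTable, weights)
  result <- mpsResult(mps, responseVector(scoreTable))
  model <- new("TrainedModel", weights = weights,
               provenance = list(
                 seed = seed, rfSeed = seed, annSeed = seed + 1L,
                 k = as.integer(k), nTrees = as.integer(nTrees),
                 fdrThreshold = fdrThreshold, lfcThreshold = lfcThreshold,
                 epochs = as.integer(epochs), lr = lr,
                 annHyperparams = ann@hyperparams,
                 nDEGs = nrow(degs),
                 package = as.character(packageVersion("molPS"))))
  list(model = model, result = result)
}

#' Validate a trained mPS model on an external cohort
#'
#' Recomputes the Gene Score table with the *validation cohort's own*
#' medians (the "updated" Gene Score), reuses the training weights and
#' directions unchanged, and evaluates mPS by ROC/AUC. Optionally re-runs
#' the random-forest ranking on the validation cohort as a stability
#' diagnostic; this never changes the scoring.
#'
#' @param model a [TrainedModel-class] from [runTrainingPipeline()].
#' @param cohort the external annotated [UCCohort-class]; must contain every
#'   signature gene.
#' @param recheckRF if `TRUE`, also report how many signature genes a fresh
#'   forest on the validation cohort would place in its own top-k
#'   (diagnostic only), as attribute `"rfOverlap"` of the result.
#' @param seed seed for the diagnostic forest (only used with `recheckRF`).
#' @return the validation [MPSResult-class].
#' @export
validateExternal <- function(model, cohort, recheckRF = FALSE, seed = 1L) {
  stopifnot(is(model, "TrainedModel"))
  cohort <- collapseDuplicates(cohort)
  signature <- data.frame(gene = geneIds(model),
                          direction = unname(geneDirections(model)),
                          stringsAsFactors = FALSE)
  scoreTable <- buildGeneScoreTable(cohort, signature)
  if (!length(responseVector(scoreTable)))
    stop("validation cohort carries no response labels", call. = FALSE)
  mps <- computeMPS(scoreTable, model@weights)
  result <- mpsResult(mps, responseVector(scoreTable))
  if (recheckRF) {
    degs <- filterDEGs(differentialExpression(cohort))
    pool <- union(degs$gene, signature$gene)
    ranked <- rankGenesRF(cohort, genes = pool, seed = seed)
    kk <- min(length(signature$gene), length(pool))
    attr(result, "rfOverlap") <-
      length(intersect(topGenes(ranked, kk), signature$gene))
  }
  result
}
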