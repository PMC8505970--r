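## Random-forest screening of DEGs by out-of-bag permutation importance
## ("mean decrease in accuracy"), via the randomForest package.

#' Rank genes by random-forest permutation importance
#'
#' Fits a random-forest classifier (samples as observations, the supplied
#' genes' expression as features, response as class) and ranks genes by
#' unscaled out-of-bag permutation importance: the mean over trees of the
#' drop in OOB accuracy after permuting that gene's values, i.e. the mean
#' decrease in accuracy. Ties are broken lexicographically by gene symbol so
#' rankings are reproducible; the fit itself is deterministic given `seed`.
#'
#' @param cohort an annotated [UCCohort-class].
#' @param genes gene symbols to rank (typically the filtered DEGs); default
#'   all genes in the cohort.
#' @param nTrees number of trees (default 500, the classification default of
#'   the randomForest package).
#' @param seed integer RNG seed (required: forests are stochastic).
#' @param scaled if `TRUE`, divide importances by their standard errors
#'   (z-score variant); the default reports the raw mean decrease.
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @return a [RankedGenes-class].
#' @seealso [topGenes()]
#' @export
rankGenesRF <- function(cohort, genes = rownames(cohort), nTrees = 500L,
                        seed, scaled = FALSE, mtry = NULL) {
  resp <- responseLabels(cohort)
  if (is.null(resp))
    stop("cohort carries no response annotation", call. = FALSE)
  if (missing(seed))
    stop("a seed is required for reproducible forests", call. = FALSE)
  missingGenes <- setdiff(genes, rownames(cohort))
  if (length(missingGenes))
    stop("genes absent from cohort: ",
         paste(missingGenes, collapse = ", "), call. = FALSE)
  if (length(genes) < 2L)
    stop("at least 2 genes are required", call. = FALSE)
  if (min(table(resp)) < 2L)
    stop("each class needs at least 2 samples", call. = FALSE)
  x <- t(expressionMatrix(cohort)[genes, , drop = FALSE])
  y <- factor(resp, levels = c("non_responder", "responder"))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = x, y = y, ntree = as.integer(nTrees),
                                    mtry = mtry, importance = TRUE)
  imp <- randomForest::importance(fit, type = 1L, scale = scaled)[, 1L]
  o <- order(-imp, names(imp))
  new("RankedGenes", gene = names(imp)[o],
      importance = unname(imp[o]), rank = seq_along(o),
      nTrees = as.integer(nTrees), seed = as.integer(seed))
}

#' Select the top-ranked genes
#'
#' @param ranked a [RankedGenes-class].
#' @param k how many genes to keep (default 30, the signature size).
#' @return character vector of the first `k` gene symbols in rank order.
#' @export
topGenes <- function(ranked, k = 30L) {
  stopifnot(is(ranked, "RankedGenes"))
  k <- as.integer(k)
  if (k < 0L)
    stop("k must be non-negative", call. = FALSE)
  if (k > length(ranked@gene))
    stop("k = ", k, " exceeds the ", length(ranked@gene),
         " ranked genes; lower k (or relax the DEG filter upstream)",
         call. = FALSE)
  ranked@gene[seq_len(k)]
}
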