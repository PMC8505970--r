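## The molecular prognostic score and its threshold-free evaluation:
## mPS(sample) = sum over signature genes of GeneScore x GeneWeight;
## discrimination is measured by the tie-corrected Mann-Whitney AUC, with
## the empirical ROC curve exposed for users who need an operating point.

#' Compute per-sample molecular prognostic scores
#'
#' `mps(sample) = sum_genes score(sample, gene) * weight(gene)`. Every scored
#' gene must have a weight; extra weights are ignored.
#'
#' @param table a [GeneScoreTable-class].
#' @param weights a [GeneWeightTable-class] covering the table's genes.
#' @return named numeric vector of mPS values, one per sample.
#' @examples
#' w <- trainingGeneWeights()
#' # a sample scoring 1 only for IL6 gets exactly IL6's weight
#' s <- matrix(as.integer(geneIds(w) == "IL6"), 1,
#'             dimnames = list("s1", geneIds(w)))
#' drop(s %*% geneWeights(w))
#' @export
computeMPS <- function(table, weights) {
  stopifnot(is(table, "GeneScoreTable"), is(weights, "GeneWeightTable"))
  w <- geneWeights(weights)
  genes <- geneIds(table)
  absent <- setdiff(genes, names(w))
  if (length(absent))
    stop("no weight for scored gene(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  drop(scoreMatrix(table) %*% w[genes])
}

#' Tie-corrected AUC (Mann-Whitney rank statistic)
#'
#' `(sum of positive ranks - n1(n1+1)/2) / (n1 n0)` with ties sharing
#' mid-ranks: the probability that a random positive outscores a random
#' negative, counting ties as 1/2. Positives are label 1 (responders).
#'
#' @param scores numeric scores (higher = more responder-like).
#' @param labels 0/1 vector, both classes present.
#' @return AUC in \[0, 1\].
#' @export
rankAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes are required to compute an AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Sweeps the decision threshold over the unique score values (predict
#' positive when score >= threshold), yielding one (fpr, tpr) point per
#' unique score, anchored at (0,0) and (1,1). Tied scores move along the
#' diagonal of their group, so the trapezoidal area equals [rankAUC()]
#' exactly.
#'
#' @inheritParams rankAUC
#' @return two-column matrix `(fpr, tpr)`.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes are required to compute a ROC curve", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  ## group tied scores: each unique threshold contributes one point
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(1L - y)[!duplicated(grp, fromLast = TRUE)]
  cbind(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

#' Bundle scores, labels, ROC and AUC into an MPSResult
#'
#' @param mps named numeric vector of per-sample scores.
#' @param response 0/1 labels parallel to `mps`.
#' @param sampleIds sample identifiers; default `names(mps)`.
#' @return an [MPSResult-class] (its validity method asserts that the
#'   rank-statistic AUC and the trapezoidal ROC area agree to 1e-12).
#' @export
mpsResult <- function(mps, response, sampleIds = names(mps)) {
  if (is.null(sampleIds))
    sampleIds <- sprintf("sample%03d", seq_along(mps))
  new("MPSResult", sampleIds = as.character(sampleIds),
      mps = unname(mps), response = as.integer(response),
      rocPoints = rocCurve(mps, response),
      auc = rankAUC(mps, response))
}
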