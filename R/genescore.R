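## Median-threshold "Gene Score" binarization. Directions are stated
## relative to responders: an "up" gene (higher in responders) scores 1 when
## its value is strictly above the pooled-cohort median; a "down" gene scores
## 1 when its value is at or below the median (the exact complement). Under
## this convention score = 1 co-varies with response = 1 for every signature
## gene, which is what lets the all-positive Gene Weights rank responders
## higher on the mPS scale.

#' Binarize one gene's expression against the cohort median
#'
#' The median is computed over *all* supplied samples (both classes pooled;
#' midpoint median for even n). For `direction = "up"` the score is 1 iff
#' the value is strictly above the median; for `"down"` it is the exact
#' complement (1 iff the value is at or below the median). A value equal to
#' the median therefore scores 0 for up-genes and 1 for down-genes.
#'
#' @param values numeric vector of per-sample expression (log2 units).
#' @param direction `"up"` or `"down"` (relative to responders).
#' @return integer 0/1 vector, same length and names as `values`.
#' @examples
#' binarizeGene(1:5, "up")    # 0 0 0 1 1
#' binarizeGene(1:5, "down")  # 1 1 1 0 0
#' @export
binarizeGene <- function(values, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!length(values))
    stop("empty expression vector", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite expression values", call. = FALSE)
  med <- median(values)
  up <- as.integer(values > med)
  if (direction == "up") up else 1L - up
}

#' Encode response labels as 0/1
#'
#' Responders map to 1, non-responders to 0.
#'
#' @param labels character vector of `"responder"`/`"non_responder"`, or an
#'   annotated [UCCohort-class].
#' @return integer 0/1 vector.
#' @export
labelResponse <- function(labels) {
  if (is(labels, "UCCohort")) {
    labels <- responseLabels(labels)
    if (is.null(labels))
      stop("cohort carries no response annotation", call. = FALSE)
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("responder", "non_responder"))
  if (length(bad))
    stop("unknown response label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  as.integer(labels == "responder")
}

#' Build the binary Gene Score table for a signature
#'
#' Applies [binarizeGene()] per signature gene using *this cohort's own*
#' medians (external validation recomputes medians on the new cohort; the
#' trained weights are what carries over). The per-gene medians and
#' directions are stored so the table can be reproduced.
#'
#' @param cohort a [UCCohort-class] containing every signature gene.
#' @param signature data.frame with columns `gene` and `direction`
#'   (relative to responders), or a [GeneWeightTable-class].
#' @return a [GeneScoreTable-class] (samples x genes scores plus the 0/1
#'   response column when the cohort is labelled).
#' @export
buildGeneScoreTable <- function(cohort, signature) {
  if (is(signature, "GeneWeightTable"))
    signature <- as.data.frame(signature)
  stopifnot(all(c("gene", "direction") %in% colnames(signature)))
  m <- expressionMatrix(cohort)
  absent <- setdiff(signature$gene, rownames(m))
  if (length(absent))
    stop("signature gene(s) absent from cohort: ",
         paste(absent, collapse = ", "), call. = FALSE)
  genes <- signature$gene
  dirs <- setNames(signature$direction, genes)
  scores <- vapply(genes,
                   function(g) binarizeGene(m[g, ], dirs[[g]]),
                   integer(ncol(m)))
  dimnames(scores) <- list(colnames(m), genes)
  meds <- setNames(vapply(genes, function(g) median(m[g, ]), numeric(1L)),
                   genes)
  resp <- responseLabels(cohort)
  new("GeneScoreTable", scores = scores,
      response = if (is.null(resp)) integer(0) else labelResponse(resp),
      medians = meds, directions = dirs)
}
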