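## Differential-expression screening: probe collapsing, batch correction,
## gene-wise Welch tests with BH adjustment, and the FDR/fold-change filter.

#' Collapse duplicate gene entries to the highest-expressed probe
#'
#' For each gene symbol occurring more than once (probe-level input), keeps
#' the row with the highest mean expression across samples and drops the
#' rest. Gene order of the retained rows follows their first occurrence.
#'
#' @param cohort a [UCCohort-class] (duplicate rownames allowed here, unlike
#'   in the validated container path — pass a plain matrix via [UCCohort()]
#'   is impossible with duplicates, so this accepts a matrix too).
#' @param exprs alternatively, a genes x samples matrix with possibly
#'   duplicated rownames.
#' @return a [UCCohort-class] with one row per gene symbol.
#' @export
collapseDuplicates <- function(cohort = NULL, exprs = NULL) {
  if (is.null(exprs)) {
    m <- expressionMatrix(cohort)
    resp <- responseLabels(cohort)
    batch <- batchLabels(cohort)
  } else {
    m <- exprs
    resp <- batch <- NULL
  }
  sym <- rownames(m)
  if (!anyDuplicated(sym)) {
    if (is.null(exprs)) return(cohort)
    return(UCCohort(m))
  }
  means <- rowMeans(m)
  ## per symbol, index of the probe with the highest mean
  keep <- vapply(split(seq_along(sym), factor(sym, levels = unique(sym))),
                 function(ix) ix[which.max(means[ix])], integer(1L))
  out <- m[keep, , drop = FALSE]
  rownames(out) <- unique(sym)
  UCCohort(out, response = resp, batch = batch)
}

#' Remove additive batch effects by gene-wise linear modelling
#'
#' Fits, per gene, a least-squares model with intercept, response indicator
#' and batch terms, then subtracts the fitted batch component (batch
#' coefficients centred so the grand mean is preserved) while protecting the
#' response-associated signal. Delegates to
#' [limma::removeBatchEffect()] with the response in the design matrix.
#'
#' A single-batch cohort is returned unchanged with a message. If any batch
#' contains only one class (batch confounded with response), correction still
#' runs but a warning string is recorded under
#' `metadata(result)$batch_warning`.
#'
#' @param cohort an annotated [UCCohort-class] with `batch` (and ideally
#'   `response`) in its column data.
#' @return a batch-corrected [UCCohort-class].
#' @export
correctBatchEffect <- function(cohort) {
  batch <- batchLabels(cohort)
  if (is.null(batch))
    stop("cohort carries no batch annotation", call. = FALSE)
  if (length(unique(batch)) < 2L) {
    message("single batch: returning input unchanged")
    return(cohort)
  }
  resp <- responseLabels(cohort)
  design <- if (is.null(resp)) matrix(1, ncol(cohort), 1L)
            else stats::model.matrix(~factor(resp))
  corrected <- limma::removeBatchEffect(expressionMatrix(cohort),
                                        batch = factor(batch),
                                        design = design)
  out <- UCCohort(corrected, response = resp, batch = batch)
  if (!is.null(resp)) {
    tab <- table(batch, resp)
    if (any(rowSums(tab > 0L) < 2L)) {
      w <- "batch confounded with response: some batch contains only one class"
      warning(w, call. = FALSE)
      S4Vectors::metadata(out)$batch_warning <- w
    }
  }
  out
}

#' Gene-wise differential expression between responders and non-responders
#'
#' Per gene: `log2fc` = mean(responders) - mean(non-responders) (log2 units,
#' so positive values are *higher in responders*), a two-sided Welch t-test
#' p-value, and BH-adjusted FDR. Genes with zero variance in both classes get
#' p = 1 when the class means agree and p = 0 when they differ (the limiting
#' behaviour of the t-test).
#'
#' @param cohort an annotated [UCCohort-class]; both classes need >= 2
#'   samples (the Welch variance is undefined otherwise).
#' @return data.frame with columns `gene`, `log2fc`, `p_value`, `fdr`,
#'   `direction` (`"up"` when log2fc > 0, i.e. higher in responders).
#' @seealso [filterDEGs()], [benjaminiHochberg()]
#' @export
differentialExpression <- function(cohort) {
  resp <- responseLabels(cohort)
  if (is.null(resp))
    stop("cohort carries no response annotation", call. = FALSE)
  m <- expressionMatrix(cohort)
  g1 <- resp == "responder"
  g2 <- resp == "non_responder"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L)
    stop("each class needs at least 2 samples (responders: ", n1,
         ", non-responders: ", n2, ")", call. = FALSE)
  x1 <- m[, g1, drop = FALSE]; x2 <- m[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  lfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(lfc[zero] == 0, 1, 0)
  res <- data.frame(gene = rownames(m), log2fc = lfc, p_value = p,
                    fdr = benjaminiHochberg(p),
                    direction = ifelse(lfc > 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: `fdr_i = min_{p_(j) >= p_(i)} m p_(j) / j`,
#' clipped to 1 and order-preserving (delegates to
#' [stats::p.adjust()] with `method = "BH"` after range validation).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values, same order as `p`.
#' @export
benjaminiHochberg <- function(p) {
  if (!length(p))
    stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Filter differential-expression records to significant DEGs
#'
#' Keeps genes with `fdr < 0.05` and `|log2fc| > 1` — both inequalities
#' strict, so a gene sitting exactly on either boundary is excluded.
#'
#' @param records data.frame from [differentialExpression()].
#' @param fdrThreshold FDR cutoff (default 0.05, strict `<`).
#' @param lfcThreshold |log2FC| cutoff (default 1, strict `>`).
#' @return the filtered subset, same columns.
#' @export
filterDEGs <- function(records, fdrThreshold = 0.05, lfcThreshold = 1) {
  keep <- records$fdr < fdrThreshold & abs(records$log2fc) > lfcThreshold
  records[keep, , drop = FALSE]
}
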