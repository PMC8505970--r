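## Two-class Gaussian log-scale cohort generator with planted signature
## genes and additive batch offsets. Microarray log2 intensities are well
## approximated by additive Gaussian noise on the log scale, so the model is
## value(g, s) = baseline(g) + class_effect(g, s) + batch_offset(batch(s)) +
## N(0, sigma^2), with class_effect = +/- delta/2 for planted genes.

#' Create a synthetic cohort configuration
#'
#' @param nGenes total number of genes.
#' @param nSigDown planted genes *lower* in responders (higher in
#'   non-responders); the published signature has 28 of these.
#' @param nSigUp planted genes *higher* in responders (2 in the published
#'   signature).
#' @param nResp,nNonResp samples per class.
#' @param delta planted |log2 fold change| between classes (log2 units).
#' @param sigma within-class standard deviation (log2 units).
#' @param batchOffsets additive per-batch shifts (log2 units); one entry per
#'   batch.
#' @param batchAssignment integer batch index per sample, responders first
#'   then non-responders; defaults to a single batch.
#' @param baselineRange interval from which per-gene baseline means are drawn
#'   uniformly (log2 units).
#' @param seed integer RNG seed; identical seeds yield bit-identical cohorts.
#' @return a validated [SimConfig-class].
#' @seealso [defaultTrainingConfig()], [simulateCohort()]
#' @export
simConfig <- function(nGenes = 1000L, nSigDown = 28L, nSigUp = 2L,
                      nResp = 23L, nNonResp = 23L, delta = 2, sigma = 0.5,
                      batchOffsets = 0,
                      batchAssignment = rep(1L, nResp + nNonResp),
                      baselineRange = c(4, 10), seed = 1L) {
  new("SimConfig", nGenes = as.integer(nGenes),
      nSigDown = as.integer(nSigDown), nSigUp = as.integer(nSigUp),
      nResp = as.integer(nResp), nNonResp = as.integer(nNonResp),
      delta = as.numeric(delta), sigma = as.numeric(sigma),
      batchOffsets = as.numeric(batchOffsets),
      batchAssignment = as.integer(batchAssignment),
      baselineRange = as.numeric(baselineRange), seed = as.integer(seed))
}

#' Default configuration mirroring the pooled training cohort
#'
#' Reproduces the class/batch layout of the pooled training data: 46 samples
#' in two source-dataset batches of 24 (8 responders / 16 non-responders) and
#' 22 (12 / 10), i.e. 20 responders and 26 non-responders overall, with a
#' 30-gene planted signature (28 lower / 2 higher in responders). The planted
#' effect delta = 1.5 log2 units sits above the |log2FC| > 1 screening
#' threshold, with sigma = 0.5 within-class noise and modest batch offsets
#' (0, +0.8).
#'
#' @param nGenes number of genes to simulate (default 2000).
#' @param seed integer RNG seed.
#' @return a [SimConfig-class].
#' @export
defaultTrainingConfig <- function(nGenes = 2000L, seed = 1L) {
  ## responders first: 8 from batch 1, 12 from batch 2;
  ## then non-responders: 16 from batch 1, 10 from batch 2.
  assignment <- c(rep(1L, 8L), rep(2L, 12L), rep(1L, 16L), rep(2L, 10L))
  simConfig(nGenes = nGenes, nSigDown = 28L, nSigUp = 2L,
            nResp = 20L, nNonResp = 26L, delta = 1.5, sigma = 0.5,
            batchOffsets = c(0, 0.8), batchAssignment = assignment,
            baselineRange = c(4, 10), seed = seed)
}

#' Simulate a two-class expression cohort with planted signature genes
#'
#' Draws per-gene baselines uniformly from `baselineRange`, plants a
#' symmetric class effect of +/- delta/2 on the signature genes (sign set by
#' each gene's direction relative to responders), adds the per-batch offset
#' and i.i.d. Gaussian noise. Signature genes are named `SIG...`, null genes
#' `G...`; responders are named `R...`, non-responders `N...`.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `cohort` (annotated [UCCohort-class]) and
#'   `truth` (data.frame `gene`, `direction` of the planted signature, with
#'   direction relative to responders).
#' @examples
#' sim <- simulateCohort(simConfig(nGenes = 100, nResp = 5, nNonResp = 5))
#' dim(expressionMatrix(sim$cohort))
#' head(sim$truth)
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  nSig <- config@nSigDown + config@nSigUp
  n <- config@nResp + config@nNonResp
  if (n == 0L || config@nGenes == 0L)
    stop("empty cohort requested", call. = FALSE)
  genes <- c(sprintf("SIG%03d", seq_len(nSig)),
             sprintf("G%05d", seq_len(config@nGenes - nSig)))
  samples <- c(sprintf("R%03d", seq_len(config@nResp)),
               sprintf("N%03d", seq_len(config@nNonResp)))
  response <- rep(c("responder", "non_responder"),
                  c(config@nResp, config@nNonResp))
  isResp <- response == "responder"

  baseline <- runif(config@nGenes, config@baselineRange[1L],
                    config@baselineRange[2L])
  ## direction is stated relative to responders: "down" genes sit higher in
  ## non-responders.
  dirs <- rep(c("down", "up"), c(config@nSigDown, config@nSigUp))
  effect <- matrix(0, config@nGenes, n)
  if (nSig) {
    sign <- ifelse(dirs == "up", 1, -1)                # responder side
    half <- config@delta / 2
    effect[seq_len(nSig), isResp] <- sign * half
    effect[seq_len(nSig), !isResp] <- -sign * half
  }
  batchShift <- config@batchOffsets[config@batchAssignment]
  m <- baseline + effect +
    matrix(batchShift, config@nGenes, n, byrow = TRUE) +
    matrix(rnorm(config@nGenes * n, sd = config@sigma), config@nGenes, n)
  dimnames(m) <- list(genes, samples)

  cohort <- UCCohort(m, response = response,
                     batch = sprintf("batch%d", config@batchAssignment))
  truth <- data.frame(gene = genes[seq_len(nSig)],
                      direction = dirs, stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}
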