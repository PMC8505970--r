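## Shared fixtures and independent oracles. Oracles are deliberately
## naive/brute-force implementations kept separate from the package code
## paths they certify.

randomMatrix <- function(nGenes = 6L, nSamples = 4L, seed = 1L) {
  set.seed(seed)
  m <- matrix(round(runif(nGenes * nSamples, 2, 12), 4), nGenes, nSamples,
              dimnames = list(sprintf("GENE%02d", seq_len(nGenes)),
                              sprintf("S%02d", seq_len(nSamples))))
  m
}

labelledCohort <- function(nGenes = 50L, nPer = 10L, delta = 2, sigma = 0.5,
                           seed = 1L, nSigDown = 28L, nSigUp = 2L) {
  simulateCohort(simConfig(nGenes = nGenes, nSigDown = nSigDown,
                           nSigUp = nSigUp, nResp = nPer, nNonResp = nPer,
                           delta = delta, sigma = sigma, seed = seed))
}

## Brute-force Benjamini-Hochberg step-up: for each p_i, the minimum over
## all p_(j) >= p_i of m * p_(j) / j, clipped to 1.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(which(ps >= ps[i]), function(j) m * ps[j] / j, numeric(1))
    adj[o[i]] <- min(1, cand)
  }
  adj
}

## Brute-force AUC: enumerate every positive-negative pair, ties count 1/2.
bruteForceAUC <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

## Indicator Gene Score table: one sample scoring 1 for `gene` only.
indicatorScoreTable <- function(weights, gene) {
  genes <- geneIds(weights)
  s <- matrix(as.integer(genes == gene), nrow = 1,
              dimnames = list("sample1", genes))
  new("GeneScoreTable", scores = s, response = integer(0),
      medians = setNames(rep(0, length(genes)), genes),
      directions = geneDirections(weights))
}
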