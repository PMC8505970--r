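test_that("simulated cohorts have the configured shape and truth", {
  cfg <- simConfig(nGenes = 1000L, nSigDown = 28L, nSigUp = 2L,
                   nResp = 23L, nNonResp = 23L, delta = 2, sigma = 0.5,
                   seed = 1L)
  sim <- simulateCohort(cfg)
  expect_identical(dim(expressionMatrix(sim$cohort)), c(1000L, 46L))
  expect_identical(nrow(sim$truth), 30L)
  expect_identical(sum(sim$truth$direction == "down"), 28L)
  expect_identical(sum(sim$truth$direction == "up"), 2L)
  expect_identical(sum(responseLabels(sim$cohort) == "responder"), 23L)
})

test_that("identical seeds give bit-identical cohorts, different seeds differ", {
  a <- simulateCohort(simConfig(nGenes = 100L, seed = 7L))
  b <- simulateCohort(simConfig(nGenes = 100L, seed = 7L))
  c <- simulateCohort(simConfig(nGenes = 100L, seed = 8L))
  expect_identical(expressionMatrix(a$cohort), expressionMatrix(b$cohort))
  expect_false(identical(expressionMatrix(a$cohort),
                         expressionMatrix(c$cohort)))
})

test_that("delta = 0 leaves per-gene mean differences centred at zero", {
  sim <- simulateCohort(simConfig(nGenes = 500L, nSigDown = 0L, nSigUp = 0L,
                                  nResp = 20L, nNonResp = 20L, delta = 0,
                                  sigma = 0.5, seed = 2L))
  m <- expressionMatrix(sim$cohort)
  resp <- responseLabels(sim$cohort) == "responder"
  d <- rowMeans(m[, resp]) - rowMeans(m[, !resp])
  expect_lt(abs(mean(d)), 3 * 0.5 * sqrt(2 / 20) / sqrt(500))
  expect_identical(nrow(sim$truth), 0L)
})

test_that("planted genes show the configured log2FC", {
  ## tight noise: every planted gene within +/- 0.1 of +/- delta
  sim <- simulateCohort(simConfig(nGenes = 200L, nResp = 50L, nNonResp = 50L,
                                  delta = 2, sigma = 0.1, seed = 3L))
  m <- expressionMatrix(sim$cohort)
  resp <- responseLabels(sim$cohort) == "responder"
  lfc <- rowMeans(m[, resp]) - rowMeans(m[, !resp])
  expected <- ifelse(sim$truth$direction == "up", 2, -2)
  expect_true(all(abs(lfc[sim$truth$gene] - expected) < 0.1))
  ## consistency at n = 500: the signature-average log2FC per direction is
  ## within +/- 0.05 of the planted effect (per-gene SE is 0.032 here, so
  ## the consistency statement is about the mean)
  sim2 <- simulateCohort(simConfig(nGenes = 60L, nResp = 500L,
                                   nNonResp = 500L, delta = 2, sigma = 0.5,
                                   seed = 4L))
  m2 <- expressionMatrix(sim2$cohort)
  resp2 <- responseLabels(sim2$cohort) == "responder"
  lfc2 <- rowMeans(m2[, resp2]) - rowMeans(m2[, !resp2])
  down <- sim2$truth$gene[sim2$truth$direction == "down"]
  up <- sim2$truth$gene[sim2$truth$direction == "up"]
  expect_lt(abs(mean(lfc2[down]) + 2), 0.05)
  expect_lt(abs(mean(lfc2[up]) - 2), 0.05)
})

test_that("null-gene t statistics look standard normal", {
  sim <- simulateCohort(simConfig(nGenes = 5000L, nSigDown = 0L,
                                  nSigUp = 0L, nResp = 23L, nNonResp = 23L,
                                  delta = 0, sigma = 0.5, seed = 5L))
  m <- expressionMatrix(sim$cohort)
  resp <- responseLabels(sim$cohort) == "responder"
  x1 <- m[, resp]; x2 <- m[, !resp]
  tstat <- (rowMeans(x1) - rowMeans(x2)) /
    sqrt(apply(x1, 1, var) / ncol(x1) + apply(x2, 1, var) / ncol(x2))
  expect_gt(stats::ks.test(tstat, "pnorm")$p.value, 0.01)
})

test_that("batch offsets shift batches additively", {
  cfg <- simConfig(nGenes = 300L, nSigDown = 0L, nSigUp = 0L, nResp = 20L,
                   nNonResp = 20L, delta = 0, sigma = 0.3,
                   batchOffsets = c(0, 1),
                   batchAssignment = rep(1:2, 20), seed = 6L)
  sim <- simulateCohort(cfg)
  m <- expressionMatrix(sim$cohort)
  b <- batchLabels(sim$cohort)
  gap <- mean(m[, b == "batch2"]) - mean(m[, b == "batch1"])
  expect_equal(gap, 1, tolerance = 0.05)
})

test_that("the default configuration mirrors the pooled training cohort", {
  cfg <- defaultTrainingConfig()
  expect_identical(cfg@nResp + cfg@nNonResp, 46L)
  expect_identical(as.integer(table(cfg@batchAssignment)[c("1", "2")]),
                   c(24L, 22L))
  expect_true(validObject(cfg))
  sim <- simulateCohort(cfg)
  expect_identical(ncol(expressionMatrix(sim$cohort)), 46L)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(nGenes = 10L, nSigDown = 20L), "signature")
  expect_error(simConfig(sigma = 0), "sigma")
  expect_error(simConfig(delta = -1), "delta")
  expect_error(simConfig(nResp = 3L, batchAssignment = c(1L, 1L)), "sample")
})
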