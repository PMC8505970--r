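test_that("duplicate probes collapse to the highest-mean probe", {
  m <- rbind(A = c(5, 5, 5), A = c(7, 7, 7), B = c(1, 2, 3))
  colnames(m) <- c("s1", "s2", "s3")
  out <- expressionMatrix(collapseDuplicates(exprs = m))
  expect_identical(rownames(out), c("A", "B"))
  expect_identical(unname(out["A", ]), c(7, 7, 7))
  ## no duplicates -> identity
  sim <- labelledCohort(nGenes = 40L, seed = 1L)
  expect_identical(collapseDuplicates(sim$cohort), sim$cohort)
  ## random planted duplicates match a brute-force group-by oracle
  set.seed(10)
  for (rep in 1:5) {
    base <- randomMatrix(12L, 5L, seed = rep)
    rownames(base) <- sample(sprintf("G%d", 1:6), 12L, replace = TRUE)
    out <- expressionMatrix(collapseDuplicates(exprs = base))
    for (g in unique(rownames(base))) {
      rows <- base[rownames(base) == g, , drop = FALSE]
      expect_identical(unname(out[g, ]),
                       unname(rows[which.max(rowMeans(rows)), ]))
    }
  }
})

test_that("batch correction removes batch shifts but preserves class signal", {
  ## single batch -> identity with a notice
  sim1 <- labelledCohort(nGenes = 30L, seed = 2L)
  expect_message(out1 <- correctBatchEffect(sim1$cohort), "single batch")
  expect_identical(expressionMatrix(out1), expressionMatrix(sim1$cohort))

  cfg <- simConfig(nGenes = 200L, nSigDown = 28L, nSigUp = 2L,
                   nResp = 200L, nNonResp = 200L, delta = 2, sigma = 0.5,
                   batchOffsets = c(0, 1),
                   batchAssignment = rep(1:2, 200L), seed = 3L)
  sim <- simulateCohort(cfg)
  m0 <- expressionMatrix(sim$cohort)
  resp <- responseLabels(sim$cohort) == "responder"
  corrected <- correctBatchEffect(sim$cohort)
  m1 <- expressionMatrix(corrected)
  b <- batchLabels(corrected)

  ## within-class between-batch mean difference ~ 0 (|diff| < 3 SE)
  se <- 3 * 0.5 * sqrt(2 / 100)
  d <- rowMeans(m1[, resp & b == "batch1"]) -
       rowMeans(m1[, resp & b == "batch2"])
  expect_true(all(abs(d) < se))
  ## planted class effect untouched: lfc before == after within 1e-8
  lfcBefore <- rowMeans(m0[, resp]) - rowMeans(m0[, !resp])
  lfcAfter <- rowMeans(m1[, resp]) - rowMeans(m1[, !resp])
  expect_equal(lfcAfter, lfcBefore, tolerance = 1e-8)
})

test_that("confounded batches trigger a recorded warning", {
  ## batch b2 contains only non-responders (single-class batch), but the
  ## design stays full-rank because b1 holds both classes
  m <- randomMatrix(10L, 8L, seed = 4L)
  cohort <- UCCohort(m,
                     response = rep(c("responder", "non_responder"),
                                    each = 4L),
                     batch = c(rep("b1", 5L), rep("b2", 3L)))
  expect_warning(out <- correctBatchEffect(cohort), "confounded")
  expect_match(S4Vectors::metadata(out)$batch_warning, "confounded")
})

test_that("Welch differential expression matches t.test and the stated conventions", {
  ## exact-mean example: responders 2 log2 units above
  m <- rbind(G1 = c(5.0, 5.1, 4.9, 3.0, 3.1, 2.9),
             G2 = c(4, 4, 4, 4, 4, 4))
  colnames(m) <- sprintf("s%d", 1:6)
  cohort <- UCCohort(m, response = rep(c("responder", "non_responder"),
                                       each = 3L))
  de <- differentialExpression(cohort)
  expect_equal(de$log2fc[de$gene == "G1"], 2, tolerance = 1e-12)
  expect_identical(de$direction[de$gene == "G1"], "up")
  ## identical values in both classes -> lfc 0, p 1
  expect_identical(de$log2fc[de$gene == "G2"], 0)
  expect_identical(de$p_value[de$gene == "G2"], 1)

  ## p-values match stats::t.test (Welch) gene by gene on random data
  set.seed(5)
  m2 <- matrix(rnorm(30 * 9), 30, 9,
               dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:9)))
  resp <- c(rep("responder", 4), rep("non_responder", 5))
  de2 <- differentialExpression(UCCohort(m2, response = resp))
  oracle <- apply(m2, 1, function(v)
    stats::t.test(v[resp == "responder"], v[resp == "non_responder"])$p.value)
  expect_equal(de2$p_value, unname(oracle), tolerance = 1e-12)

  ## zero variance with unequal means -> p = 0
  m3 <- rbind(G = c(1, 1, 2, 2))
  colnames(m3) <- sprintf("s%d", 1:4)
  de3 <- differentialExpression(
    UCCohort(m3, response = c("responder", "responder",
                              "non_responder", "non_responder")))
  expect_identical(de3$p_value, 0)

  ## <2 samples in a class -> error
  expect_error(differentialExpression(
    UCCohort(m3[, 1:3, drop = FALSE],
             response = c("responder", "responder", "non_responder"))),
    "at least 2")
})

test_that("differential expression is invariant to sample order and gene shifts", {
  sim <- labelledCohort(nGenes = 40L, seed = 6L)
  de <- differentialExpression(sim$cohort)
  m <- expressionMatrix(sim$cohort)
  perm <- sample(ncol(m))
  shuffled <- UCCohort(m[, perm],
                       response = responseLabels(sim$cohort)[perm])
  expect_equal(differentialExpression(shuffled)$p_value, de$p_value,
               tolerance = 1e-12)
  ## adding a constant to one gene changes nothing but its mean
  m2 <- m; m2[3, ] <- m2[3, ] + 5
  de2 <- differentialExpression(
    UCCohort(m2, response = responseLabels(sim$cohort)))
  expect_equal(de2$p_value, de$p_value, tolerance = 1e-12)
  expect_equal(de2$log2fc, de$log2fc, tolerance = 1e-12)
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_identical(benjaminiHochberg(0.05), 0.05)
  expect_equal(benjaminiHochberg(rep(0.2, 3)), rep(0.2, 3))
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               bruteForceBH(c(0.01, 0.02, 0.03, 0.04)), tolerance = 1e-15)
  set.seed(7)
  for (rep in 1:20) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(benjaminiHochberg(p), bruteForceBH(p), tolerance = 1e-12)
  }
  expect_error(benjaminiHochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(benjaminiHochberg(numeric(0)), "empty")
})

test_that("the DEG filter applies strict thresholds", {
  rec <- data.frame(gene = c("A", "B", "C", "D"),
                    log2fc = c(2, 1.0, -1.5, 1.2),
                    p_value = c(0.001, 0.001, 0.001, 0.2),
                    fdr = c(0.05, 0.01, 0.01, 0.3),
                    direction = c("up", "up", "down", "up"))
  out <- filterDEGs(rec)
  expect_identical(out$gene, "C")  # A fails fdr==0.05, B fails |lfc|==1, D fails fdr
})

test_that("planted signatures pass the filter and null genes rarely do", {
  hits <- falsePos <- numeric(20)
  for (s in 1:20) {
    sim <- simulateCohort(simConfig(nGenes = 300L, nResp = 23L,
                                    nNonResp = 23L, delta = 2, sigma = 0.3,
                                    seed = 100L + s))
    degs <- filterDEGs(differentialExpression(sim$cohort))
    hits[s] <- length(intersect(degs$gene, sim$truth$gene))
    falsePos[s] <- sum(!(degs$gene %in% sim$truth$gene)) / (300 - 30)
  }
  expect_true(all(hits == 30))
  expect_lt(mean(falsePos), 0.01)
})
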