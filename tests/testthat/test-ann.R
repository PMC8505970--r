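## small labelled Gene Score table built directly
scoreTableFor <- function(scores, response) {
  genes <- colnames(scores)
  new("GeneScoreTable", scores = scores, response = as.integer(response),
      medians = setNames(rep(0.5, length(genes)), genes),
      directions = setNames(rep("up", length(genes)), genes))
}

randomScoreTable <- function(n = 16L, p = 4L, seed = 1L) {
  set.seed(seed)
  s <- matrix(rbinom(n * p, 1L, 0.5), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("G%d", 1:p)))
  resp <- rep(c(1L, 0L), length.out = n)
  scoreTableFor(s, resp)
}

test_that("zero-epoch training returns the seeded initialization unchanged", {
  st <- randomScoreTable(seed = 2L)
  model <- trainANN(st, epochs = 0L, seed = 9L)
  init <- molPS:::.annInit(4L, 10L, 9L)
  expect_equal(unname(model@Win), init$Win, tolerance = 0)
  expect_equal(unname(model@Wout), init$Wout, tolerance = 0)
  expect_identical(model@bHidden, rep(0, 10))
  expect_length(model@trace, 0L)
})

test_that("training is deterministic and drives the loss down", {
  for (s in 1:10) {
    st <- randomScoreTable(n = 14L, p = 5L, seed = 100L + s)
    m1 <- trainANN(st, epochs = 150L, seed = s)
    expect_lt(m1@trace[length(m1@trace)], m1@trace[1L])
  }
  st <- randomScoreTable(seed = 3L)
  a <- trainANN(st, epochs = 200L, seed = 4L)
  b <- trainANN(st, epochs = 200L, seed = 4L)
  expect_identical(a@Win, b@Win)
  expect_identical(a@trace, b@trace)
})

test_that("a perfectly separable single-gene problem is learned", {
  resp <- rep(c(1L, 0L), each = 10L)
  s <- matrix(resp, 20L, 1L, dimnames = list(sprintf("s%02d", 1:20), "G1"))
  st <- scoreTableFor(s, resp)
  model <- trainANN(st, seed = 1L)   # default epochs
  expect_identical(annAccuracy(model, st), 1)
  expect_lt(model@trace[length(model@trace)], 0.05)
})

test_that("analytic gradients match central finite differences", {
  h <- 1e-6
  for (s in 1:6) {
    set.seed(s)
    n <- 10L; p <- 4L; nh <- 3L
    x <- matrix(rbinom(n * p, 1L, 0.5), n, p) * 1.0
    yv <- rbinom(n, 1L, 0.5)
    y <- cbind(1 - yv, yv) * 1.0
    par <- molPS:::.annInit(p, nh, s)
    par <- lapply(par, function(z) z + rnorm(length(z), sd = 0.3))
    analytic <- molPS:::.annLossGrad(par, x, y)$grads
    for (nm in names(par)) {
      for (i in seq_along(par[[nm]])) {
        up <- par; up[[nm]][i] <- up[[nm]][i] + h
        dn <- par; dn[[nm]][i] <- dn[[nm]][i] - h
        numeric <- (molPS:::.annLossGrad(up, x, y)$loss -
                    molPS:::.annLossGrad(dn, x, y)$loss) / (2 * h)
        denom <- max(abs(numeric), abs(analytic[[nm]][i]), 1e-8)
        expect_lt(abs(numeric - analytic[[nm]][i]) / denom, 1e-5)
      }
    }
  }
})

test_that("degenerate tables are rejected", {
  st <- randomScoreTable(seed = 5L)
  oneClass <- scoreTableFor(scoreMatrix(st), rep(1L, nrow(scoreMatrix(st))))
  expect_error(trainANN(oneClass, seed = 1L), "both classes")
  expect_error(trainANN(st, epochs = 10L), "seed")
})

test_that("gene weights are the signed row maxima of the input layer", {
  st <- randomScoreTable(n = 12L, p = 3L, seed = 6L)
  model <- trainANN(st, epochs = 50L, seed = 7L)
  ## doctor the input weights to known values
  model@Win <- matrix(c(0.1, -0.5, 0.3,
                        -0.2, -0.1, -0.4,
                        2.0, 0.0, 1.0), 3L, 3L, byrow = TRUE,
                      dimnames = list(c("A", "B", "C"), NULL))
  w <- extractGeneWeights(model, directions = c(A = "up", B = "down",
                                                C = "down"))
  expect_equal(unname(geneWeights(w)), c(0.3, -0.1, 2.0))
  wAbs <- extractGeneWeights(model, absMax = TRUE,
                             directions = c(A = "up", B = "down",
                                            C = "down"))
  expect_equal(unname(geneWeights(wAbs)), c(0.5, 0.4, 2.0))
  expect_identical(unname(geneDirections(w)), c("up", "down", "down"))
  expect_error(extractGeneWeights(model, geneIds = c("A", "B"),
                                  directions = c("up", "down")),
               "does not match")
})

test_that("response-aligned scores yield predominantly positive weights", {
  fracPos <- vapply(1:10, function(s) {
    sim <- simulateCohort(simConfig(nGenes = 40L, nResp = 23L,
                                    nNonResp = 23L, delta = 2, sigma = 0.5,
                                    seed = 2000L + s))
    st <- buildGeneScoreTable(sim$cohort, sim$truth)
    model <- trainANN(st, epochs = 500L, seed = s)
    dirs <- setNames(sim$truth$direction, sim$truth$gene)
    mean(geneWeights(extractGeneWeights(model, directions = dirs)) > 0)
  }, numeric(1))
  expect_true(all(fracPos >= 0.8))
})
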