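## One-hidden-layer network trained from its mathematical definition
## (forward pass, backprop, full-batch Adam) so the gradients can be
## certified against finite differences. Architecture: p binary inputs ->
## 10 ReLU hidden units -> 2-node softmax (non-responder, responder);
## loss = mean categorical cross-entropy.

.annInit <- function(p, nHidden, seed) {
  ## He-uniform: limit sqrt(6 / fan_in), biases zero.
  set.seed(as.integer(seed))
  l1 <- sqrt(6 / p)
  l2 <- sqrt(6 / nHidden)
  list(Win = matrix(runif(p * nHidden, -l1, l1), p, nHidden),
       bHidden = numeric(nHidden),
       Wout = matrix(runif(nHidden * 2L, -l2, l2), nHidden, 2L),
       bOut = numeric(2L))
}

.annForward <- function(par, x) {
  pre <- sweep(x %*% par$Win, 2L, par$bHidden, "+")
  h <- pmax(pre, 0)
  logits <- sweep(h %*% par$Wout, 2L, par$bOut, "+")
  ## numerically stable softmax
  shifted <- logits - apply(logits, 1L, max)
  e <- exp(shifted)
  probs <- e / rowSums(e)
  list(pre = pre, h = h, logits = logits, probs = probs)
}

## Loss and analytic gradients at a parameter point. y is an n x 2 one-hot
## matrix with columns (non_responder, responder).
.annLossGrad <- function(par, x, y) {
  n <- nrow(x)
  fw <- .annForward(par, x)
  loss <- -sum(y * log(pmax(fw$probs, 1e-300))) / n
  dLogits <- (fw$probs - y) / n
  gWout <- crossprod(fw$h, dLogits)
  gbOut <- colSums(dLogits)
  dH <- dLogits %*% t(par$Wout)
  dH[fw$pre <= 0] <- 0
  gWin <- crossprod(x, dH)
  gbHidden <- colSums(dH)
  list(loss = loss,
       grads = list(Win = gWin, bHidden = gbHidden,
                    Wout = gWout, bOut = gbOut))
}

#' Train the Gene Score neural network
#'
#' Trains the two-class shallow network on a [GeneScoreTable-class] (inputs:
#' the binary gene scores; targets: the one-hot response) with full-batch
#' Adam on mean categorical cross-entropy, for a fixed number of epochs.
#' The 3000-epoch default drives separable problems below 0.05 loss at the
#' standard Adam learning rate.
#' Cohorts of a few dozen samples make mini-batching pointless, so one epoch
#' is one deterministic full-batch update and the whole run is reproducible
#' from `seed` (which controls only the He-uniform initialization).
#'
#' @param table a [GeneScoreTable-class] with both classes present.
#' @param epochs number of Adam updates (default 3000).
#' @param lr learning rate (default 0.001).
#' @param beta1,beta2,epsilon Adam moment decays and stabilizer (defaults
#'   0.9 / 0.999 / 1e-8).
#' @param nHidden hidden-layer width (default 10).
#' @param seed integer RNG seed for initialization.
#' @return an [ANNModel-class]; with `epochs = 0` the seeded initialization
#'   is returned untouched (empty training trace).
#' @seealso [extractGeneWeights()]
#' @export
trainANN <- function(table, epochs = 3000L, lr = 0.001, beta1 = 0.9,
                     beta2 = 0.999, epsilon = 1e-8, nHidden = 10L, seed) {
  stopifnot(is(table, "GeneScoreTable"))
  if (missing(seed))
    stop("a seed is required for reproducible initialization", call. = FALSE)
  resp <- responseVector(table)
  if (!length(resp))
    stop("Gene Score table carries no response column", call. = FALSE)
  if (length(unique(resp)) < 2L)
    stop("both classes are required (cross-entropy is degenerate otherwise)",
         call. = FALSE)
  x <- scoreMatrix(table) * 1.0
  y <- cbind(non_responder = 1 - resp, responder = resp) * 1.0
  par <- .annInit(ncol(x), as.integer(nHidden), seed)

  mAdam <- lapply(par, function(z) z * 0)
  vAdam <- lapply(par, function(z) z * 0)
  trace <- numeric(epochs)
  t <- 0L
  for (epoch in seq_len(epochs)) {
    lg <- .annLossGrad(par, x, y)
    t <- t + 1L
    for (nm in names(par)) {
      g <- lg$grads[[nm]]
      mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * g
      vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * g^2
      mHat <- mAdam[[nm]] / (1 - beta1^t)
      vHat <- vAdam[[nm]] / (1 - beta2^t)
      par[[nm]] <- par[[nm]] - lr * mHat / (sqrt(vHat) + epsilon)
    }
    trace[epoch] <- .annLossGrad(par, x, y)$loss
  }
  rownames(par$Win) <- colnames(x)
  new("ANNModel", Win = par$Win, bHidden = par$bHidden, Wout = par$Wout,
      bOut = par$bOut, trace = trace,
      hyperparams = list(lr = lr, epochs = as.integer(epochs),
                         beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                         nHidden = as.integer(nHidden),
                         init = "he-uniform", seed = as.integer(seed)))
}

#' Training accuracy of a fitted network
#' @param model an [ANNModel-class].
#' @param table the [GeneScoreTable-class] it was trained on.
#' @return fraction of samples whose predicted class matches the response.
#' @export
annAccuracy <- function(model, table) {
  x <- scoreMatrix(table) * 1.0
  fw <- .annForward(list(Win = model@Win, bHidden = model@bHidden,
                         Wout = model@Wout, bOut = model@bOut), x)
  pred <- max.col(fw$probs) - 1L          # column 2 = responder
  mean(pred == responseVector(table))
}

#' Extract per-gene "Gene Weights" from a trained network
#'
#' The Gene Weight of a gene is the *signed maximum* over the hidden units
#' of its input-to-hidden weights (`max_j Win[i, j]`) — for an all-negative
#' row the weight is the least-negative entry, not its absolute value. An
#' absolute-maximum reading is available via `absMax = TRUE`.
#'
#' @param model a trained [ANNModel-class].
#' @param geneIds gene symbols matching the rows of the input layer; default
#'   the row names recorded at training time.
#' @param directions named or parallel character vector of `"up"`/`"down"`
#'   per gene (carried through from the signature).
#' @param absMax take the maximum of |weights| instead of the signed maximum.
#' @return a [GeneWeightTable-class], order-aligned with `geneIds`.
#' @export
extractGeneWeights <- function(model, geneIds = rownames(model@Win),
                               directions, absMax = FALSE) {
  stopifnot(is(model, "ANNModel"))
  if (length(geneIds) != nrow(model@Win))
    stop("geneIds length (", length(geneIds),
         ") does not match the input layer (", nrow(model@Win), ")",
         call. = FALSE)
  if (!is.null(names(directions)))
    directions <- directions[geneIds]
  if (length(directions) != length(geneIds))
    stop("directions must cover every gene", call. = FALSE)
  w <- if (absMax) apply(abs(model@Win), 1L, max)
       else apply(model@Win, 1L, max)
  GeneWeightTable(geneIds, unname(w), unname(directions))
}
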