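#' @include mil-model.R
NULL

## ---- losses and metrics -----------------------------------------------

#' Binary cross-entropy loss
#'
#' `-(Y log P + (1 - Y) log(1 - P))`, with P clamped to
#' \[1e-7, 1 - 1e-7\] before the logs.
#'
#' @param Y binary label(s).
#' @param P predicted positive-class probability(ies).
#' @return nonnegative loss value(s).
#' @export
bceLoss <- function(Y, P) {
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  P <- clampProb(P)
  -(Y * log(P) + (1 - Y) * log(1 - P))
}

#' Rank-based AUROC
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted as 1/2 (midrank formula); identical to the normalized
#' Mann-Whitney U statistic.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels, both classes present.
#' @return scalar in \[0, 1\].
#' @export
aurocScore <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

## ---- internal net representation --------------------------------------

netFromModel <- function(model) {
  list(arch = model@architecture, activation = model@attention$activation,
       leakySlope = model@attention$leakySlope, V = model@attention$V,
       w = model@attention$w, layers = model@predictor$layers,
       inputDim = model@inputDim)
}

modelFromNet <- function(net) {
  new("MILModel", architecture = net$arch,
      attention = list(V = net$V, w = net$w, activation = net$activation,
                       leakySlope = net$leakySlope),
      predictor = list(layers = net$layers),
      inputDim = as.integer(net$inputDim))
}

stackBags <- function(bagList) {
  list(H = do.call(rbind, lapply(bagList, function(b) b@embeddings)),
       g = rep(seq_along(bagList),
               vapply(bagList, function(b) nrow(b@embeddings), integer(1))),
       Y = vapply(bagList, function(b) as.numeric(b@label), numeric(1)),
       B = length(bagList))
}

## Forward pass over a stack of bags; returns per-bag positive probabilities
## and, when cache = TRUE, the intermediates needed for backprop.
forwardBatch <- function(net, flat, cache = FALSE) {
  H <- flat$H; g <- flat$g; B <- flat$B
  A1 <- H %*% t(net$V)                                    # N x L
  Tact <- if (net$activation == "tanh") tanh(A1)
  else ifelse(A1 > 0, A1, net$leakySlope * A1)
  attLogits <- drop(Tact %*% net$w)                       # N
  a <- groupedSoftmax(attLogits, g, B)                    # N
  layers <- net$layers
  mlpFwd <- function(X) {
    nl <- length(layers)
    Zs <- vector("list", nl); As <- vector("list", nl + 1L)
    As[[1L]] <- X
    for (k in seq_len(nl)) {
      Z <- As[[k]] %*% t(layers[[k]]$W) +
        matrix(layers[[k]]$b, nrow(X), length(layers[[k]]$b), byrow = TRUE)
      Zs[[k]] <- Z
      As[[k + 1L]] <- if (k < nl) pmax(Z, 0) else Z
    }
    list(Zs = Zs, As = As, out = As[[nl + 1L]])
  }
  if (net$arch == "amil") {
    pooled <- rowsum(a * H, g, reorder = TRUE)            # B x d
    mf <- mlpFwd(pooled)
    prob <- sigmoid(drop(mf$out))
  } else {
    Zin <- a * H                                          # N x d
    mf <- mlpFwd(Zin)
    S <- rowsum(mf$out, g, reorder = TRUE)                # B x 2 class scores
    prob <- sigmoid(S[, 2L] - S[, 1L])
  }
  out <- list(prob = prob)
  if (cache) out <- c(out, list(A1 = A1, Tact = Tact, a = a, mf = mf))
  out
}

## Gradients of the mean BCE over the batch w.r.t. every parameter.
backwardBatch <- function(net, flat, fw) {
  H <- flat$H; g <- flat$g; B <- flat$B; Y <- flat$Y
  layers <- net$layers; nl <- length(layers)
  dErr <- (fw$prob - Y) / B                               # d(meanBCE)/d(bag logit)
  mlpBwd <- function(mf, dOut) {
    gW <- vector("list", nl); gb <- vector("list", nl)
    dZ <- dOut
    for (k in nl:1) {
      gW[[k]] <- crossprod(dZ, mf$As[[k]])                # out x in
      gb[[k]] <- colSums(dZ)
      if (k > 1L)
        dZ <- (dZ %*% layers[[k]]$W) * reluGrad(mf$Zs[[k - 1L]])
    }
    list(gW = gW, gb = gb, dX = dZ %*% layers[[1L]]$W)
  }
  if (net$arch == "amil") {
    mb <- mlpBwd(fw$mf, matrix(dErr, B, 1L))
    dPooled <- mb$dX                                      # B x d
    da <- rowSums(H * dPooled[g, , drop = FALSE])         # N
  } else {
    dS <- cbind(-dErr, dErr)                              # B x 2
    mb <- mlpBwd(fw$mf, dS[g, , drop = FALSE])
    dZin <- mb$dX                                         # N x d
    da <- rowSums(H * dZin)
  }
  ## softmax-over-instances backward
  sg <- as.numeric(rowsum(fw$a * da, g, reorder = TRUE))
  dl <- fw$a * (da - sg[g])                               # N
  dw <- drop(crossprod(fw$Tact, dl))                      # L
  dTact <- tcrossprod(dl, net$w)                          # N x L
  dA1 <- dTact * (if (net$activation == "tanh") 1 - fw$Tact^2
                  else ifelse(fw$A1 > 0, 1, net$leakySlope))
  dV <- crossprod(dA1, H)                                 # L x d
  list(V = dV, w = dw, gW = mb$gW, gb = mb$gb)
}

## ---- Adam ---------------------------------------------------------------

adamInit <- function(net) {
  zeros <- function(x) array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  p <- c(list(V = net$V, w = net$w),
         unlist(lapply(net$layers, function(l) list(l$W, l$b)),
                recursive = FALSE))
  list(m = lapply(p, zeros), v = lapply(p, zeros), t = 0L)
}

adamStep <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  nl <- length(net$layers)
  gl <- c(list(grads$V, grads$w),
          unlist(lapply(seq_len(nl),
                        function(k) list(grads$gW[[k]], grads$gb[[k]])),
                 recursive = FALSE))
  pl <- c(list(net$V, net$w),
          unlist(lapply(net$layers, function(l) list(l$W, l$b)),
                 recursive = FALSE))
  for (i in seq_along(pl)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * gl[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * gl[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    pl[[i]] <- pl[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  net$V <- pl[[1L]]; net$w <- drop(pl[[2L]])
  for (k in seq_len(nl)) {
    net$layers[[k]]$W <- pl[[2L * k + 1L]]
    net$layers[[k]]$b <- drop(pl[[2L * k + 2L]])
  }
  list(net = net, state = state)
}

## ---- training configuration --------------------------------------------

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param epochs passes over the training bags.
#' @param batchSize bags per optimizer step (gradient averaged over the
#'   batch; bags of different sizes are handled by stacking instances, no
#'   padding).
#' @param kFolds cross-validation folds on the training split (default 5).
#' @param testFraction held-out test fraction (default 0.2).
#' @param scheduler `"none"` or `"cosine_annealing"` (annealed over all
#'   steps of one fit).
#' @param etaMin final learning rate of the cosine schedule.
#' @param seed master seed; splits, fold assignment, weight init and batch
#'   shuffling all derive from it.
#' @param nRepeats independent repeat runs with different split seeds.
#' @param attentionWidth,hiddenWidth,leakySlope model hyperparameters passed
#'   to [milModel()].
#' @param verbose print per-epoch loss.
#' @return a config list of class `"MILTrainConfig"`.
#' @export
milTrainConfig <- function(lr = 1e-4, epochs = 50L, batchSize = 8L,
                           kFolds = 5L, testFraction = 0.2,
                           scheduler = c("none", "cosine_annealing"),
                           etaMin = 0, seed = 1L, nRepeats = 5L,
                           attentionWidth = 128L, hiddenWidth = 256L,
                           leakySlope = 0.01, verbose = FALSE) {
  scheduler <- match.arg(scheduler)
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1")
  if (kFolds < 2L) stop("kFolds must be >= 2")
  if (epochs < 1L || batchSize < 1L) stop("epochs and batchSize must be >= 1")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), kFolds = as.integer(kFolds),
                 testFraction = testFraction, scheduler = scheduler,
                 etaMin = etaMin, seed = as.integer(seed),
                 nRepeats = as.integer(nRepeats),
                 attentionWidth = as.integer(attentionWidth),
                 hiddenWidth = as.integer(hiddenWidth),
                 leakySlope = leakySlope, verbose = isTRUE(verbose)),
            class = "MILTrainConfig")
}

## ---- splits -------------------------------------------------------------

#' Stratified train/test split
#'
#' Partitions a bag set into disjoint train and test sets, stratified by bag
#' label (per-class test counts are `round(testFraction * n_class)`).
#'
#' @param bags a [MILBagSet-class].
#' @param testFraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` [MILBagSet-class]s plus `trainIdx`,
#'   `testIdx`.
#' @export
splitTrainTest <- function(bags, testFraction = 0.2, seed = 1L) {
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1")
  if (nBags(bags) < 5L) stop("need at least 5 bags to split")
  labels <- bagLabels(bags)
  testIdx <- withSeed(seed, {
    unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      nTest <- round(testFraction * length(idx))
      if (nTest < 1L || nTest >= length(idx))
        stop("stratification error: class ", cl,
             " would be absent from train or test at this fraction")
      sort(sample(idx, nTest))
    }))
  })
  testIdx <- sort(testIdx)
  trainIdx <- setdiff(seq_len(nBags(bags)), testIdx)
  list(train = bags[trainIdx], test = bags[testIdx],
       trainIdx = trainIdx, testIdx = testIdx)
}

#' Stratified k-fold assignment
#'
#' Assigns bags to k validation folds that partition the input, stratified by
#' label, with fold sizes differing by at most one.
#'
#' @param labels binary bag labels (or a [MILBagSet-class]).
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of k elements, each with `train` and `val` index vectors.
#' @export
kfoldSplits <- function(labels, k = 5L, seed = 1L) {
  if (is(labels, "MILBagSet")) labels <- bagLabels(labels)
  n <- length(labels)
  if (k > n) stop("k must not exceed the number of bags")
  if (k < 2L) stop("k must be >= 2")
  ## shuffle within class, then deal classes cyclically so overall fold
  ## sizes differ by <= 1 while staying stratified
  ord <- withSeed(seed, unlist(lapply(unique(labels), function(cl)
    sample(which(labels == cl)))))
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(k), n)
  lapply(seq_len(k), function(i)
    list(train = which(fold != i), val = which(fold == i)))
}

## ---- fitting ------------------------------------------------------------

#' Fit one MIL model on a set of training bags
#'
#' Minimizes the mean binary cross-entropy of the positive-class probability
#' with Adam; bags are shuffled each epoch and processed in batches by
#' stacking their instances (no padding).
#'
#' @param model an initialized [MILModel-class].
#' @param bags training [MILBagSet-class].
#' @param cfg a [milTrainConfig()].
#' @param seed seed for batch shuffling (defaults to `cfg$seed`).
#' @return list with the fitted `model` and `lossHistory` (mean training BCE
#'   per epoch).
#' @export
fitMILModel <- function(model, bags, cfg, seed = cfg$seed) {
  net <- netFromModel(model)
  bagList <- bags@bags
  nb <- length(bagList)
  if (nb == 0L) stop("no training bags")
  state <- adamInit(net)
  totalSteps <- cfg$epochs * ceiling(nb / cfg$batchSize)
  lossHistory <- numeric(cfg$epochs)
  step <- 0L
  withSeed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(nb)
      epLoss <- 0; epBags <- 0L
      for (start in seq(1L, nb, by = cfg$batchSize)) {
        idx <- ord[start:min(start + cfg$batchSize - 1L, nb)]
        flat <- stackBags(bagList[idx])
        fw <- forwardBatch(net, flat, cache = TRUE)
        loss <- mean(bceLoss(flat$Y, fw$prob))
        if (!is.finite(loss))
          stop("training diverged: non-finite loss at epoch ", ep)
        gr <- backwardBatch(net, flat, fw)
        step <- step + 1L
        lr <- if (cfg$scheduler == "cosine_annealing")
          cfg$etaMin + 0.5 * (cfg$lr - cfg$etaMin) *
            (1 + cos(pi * (step - 1L) / max(totalSteps - 1L, 1L)))
        else cfg$lr
        upd <- adamStep(net, gr, state, lr)
        net <- upd$net; state <- upd$state
        epLoss <- epLoss + loss * length(idx); epBags <- epBags + length(idx)
      }
      lossHistory[ep] <- epLoss / epBags
      if (cfg$verbose)
        message(sprintf("epoch %d/%d: loss %.4f", ep, cfg$epochs,
                        lossHistory[ep]))
    }
  })
  list(model = modelFromNet(net), lossHistory = lossHistory)
}

#' Positive-class probabilities for every bag in a set
#'
#' @param model a [MILModel-class].
#' @param bags a [MILBagSet-class].
#' @return numeric vector of probabilities.
#' @export
predictProbs <- function(model, bags) {
  net <- netFromModel(model)
  bagList <- bags@bags
  ## batch in chunks to bound the stacked matrix size
  probs <- numeric(length(bagList))
  chunk <- 64L
  for (start in seq(1L, length(bagList), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(bagList))
    flat <- stackBags(bagList[idx])
    probs[idx] <- forwardBatch(net, flat)$prob
  }
  probs
}

#' Test AUROC of a model on a bag set
#'
#' @param model a [MILModel-class].
#' @param bags a [MILBagSet-class] containing both classes.
#' @return AUROC in \[0, 1\].
#' @export
evaluateAuroc <- function(model, bags) {
  aurocScore(predictProbs(model, bags), bagLabels(bags))
}

## ---- protocol -----------------------------------------------------------

#' Train one MIL architecture under the full protocol
#'
#' Splits the bags into a stratified 80/20 train/test partition (fraction per
#' config), runs stratified k-fold cross-validation on the training split
#' (one freshly initialized model per fold), selects the fold with the best
#' validation AUROC (ties broken toward the lowest fold index) and reports
#' that model's AUROC on the held-out test set.
#'
#' @param architecture `"amil"`, `"admil"` or `"hybrid"`.
#' @param bags a [MILBagSet-class] containing both classes.
#' @param cfg a [milTrainConfig()].
#' @return list of class `"MILRun"` with elements `model` (the selected
#'   [MILModel-class]), `foldMetrics` (data.frame fold/valAuroc),
#'   `selectedFold`, `testAuroc`, `lossHistory` (per-fold list) and the
#'   split indices.
#' @export
trainModel <- function(architecture, bags, cfg = milTrainConfig()) {
  labels <- bagLabels(bags)
  if (length(unique(labels)) < 2L)
    stop("training requires both classes to be present")
  d <- embedDim(bags)
  split <- splitTrainTest(bags, cfg$testFraction, seed = cfg$seed)
  folds <- kfoldSplits(bagLabels(split$train), cfg$kFolds,
                       seed = deriveSeed(cfg$seed, 1L))
  valAuroc <- numeric(cfg$kFolds)
  models <- vector("list", cfg$kFolds)
  lossHistory <- vector("list", cfg$kFolds)
  for (i in seq_len(cfg$kFolds)) {
    m0 <- milModel(architecture, inputDim = d,
                   attentionWidth = cfg$attentionWidth,
                   hiddenWidth = cfg$hiddenWidth,
                   leakySlope = cfg$leakySlope,
                   seed = deriveSeed(cfg$seed, 2L, i))
    fit <- fitMILModel(m0, split$train[folds[[i]]$train], cfg,
                       seed = deriveSeed(cfg$seed, 3L, i))
    models[[i]] <- fit$model
    lossHistory[[i]] <- fit$lossHistory
    valAuroc[i] <- evaluateAuroc(fit$model, split$train[folds[[i]]$val])
  }
  best <- which.max(valAuroc)   # ties resolve to the lowest index
  structure(list(model = models[[best]],
                 foldMetrics = data.frame(fold = seq_len(cfg$kFolds),
                                          valAuroc = valAuroc),
                 selectedFold = best,
                 testAuroc = evaluateAuroc(models[[best]], split$test),
                 lossHistory = lossHistory,
                 trainIdx = split$trainIdx, testIdx = split$testIdx),
            class = "MILRun")
}

#' Repeat the full protocol over independent split seeds
#'
#' Runs [trainModel()] `nRepeats` times with consecutive master seeds
#' (different random splits and initializations) and aggregates the held-out
#' test AUROC as mean and sample (n-1) standard deviation, the form in which
#' slide-classification results are usually reported.
#'
#' @param architecture `"amil"`, `"admil"` or `"hybrid"`.
#' @param bags a [MILBagSet-class].
#' @param cfg a [milTrainConfig()]; `cfg$seed` seeds the first run.
#' @return list of class `"MILRepeatResult"` with `runs` (one row per run:
#'   run, seed, selectedFold, valAuroc, testAuroc), `meanAuroc`, `sdAuroc`.
#' @export
repeatRuns <- function(architecture, bags, cfg = milTrainConfig()) {
  if (cfg$nRepeats < 2L) stop("nRepeats must be >= 2")
  rows <- vector("list", cfg$nRepeats)
  models <- vector("list", cfg$nRepeats)
  for (r in seq_len(cfg$nRepeats)) {
    cfgR <- cfg
    cfgR$seed <- cfg$seed + r - 1L
    run <- trainModel(architecture, bags, cfgR)
    models[[r]] <- run$model
    rows[[r]] <- data.frame(run = r, seed = cfgR$seed,
                            selectedFold = run$selectedFold,
                            valAuroc = run$foldMetrics$valAuroc[run$selectedFold],
                            testAuroc = run$testAuroc)
  }
  runs <- do.call(rbind, rows)
  structure(list(runs = runs, models = models,
                 meanAuroc = mean(runs$testAuroc),
                 sdAuroc = stats::sd(runs$testAuroc),
                 architecture = architecture),
            class = "MILRepeatResult")
}

#' @export
print.MILRepeatResult <- function(x, ...) {
  cat(sprintf("%s: test AUROC %.3f +/- %.3f over %d runs\n",
              x$architecture, x$meanAuroc, x$sdAuroc, nrow(x$runs)))
  print(x$runs, row.names = FALSE)
  invisible(x)
}
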