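## Shared fixtures, built in code at test time.

## a bag with fixed-seed Gaussian embeddings
makeBag <- function(n = 3L, d = 4L, label = 1L, seed = 1L, coords = FALSE) {
  set.seed(seed)
  co <- if (coords)
    cbind(x = 512L * (seq_len(n) - 1L), y = rep(0L, n))
  else matrix(integer(0), 0L, 2L)
  new("MILBag", embeddings = matrix(rnorm(n * d), n, d),
      label = as.integer(label), bagId = sprintf("bag_s%d", seed),
      coords = co)
}

makeBagSet <- function(nBags = 10L, n = 5L, d = 4L, seed = 1L) {
  labels <- rep(c(0L, 1L), length.out = nBags)
  new("MILBagSet", bags = lapply(seq_len(nBags), function(i)
    makeBag(n, d, label = labels[i], seed = seed * 1000L + i)))
}

## straight-line transcription of the three forward passes, scalar loops only;
## the independent oracle the vectorized implementation is checked against
oracleForward <- function(model, H) {
  att <- model@attention
  n <- nrow(H)
  lg <- numeric(n)
  for (i in seq_len(n)) {
    pre <- as.numeric(att$V %*% H[i, ])
    act <- if (att$activation == "tanh") tanh(pre)
    else ifelse(pre > 0, pre, att$leakySlope * pre)
    lg[i] <- sum(att$w * act)
  }
  a <- exp(lg - max(lg)); a <- a / sum(a)
  layers <- model@predictor$layers
  mlp1 <- function(z) {
    h <- pmax(as.numeric(layers[[1L]]$W %*% z) + layers[[1L]]$b, 0)
    as.numeric(layers[[2L]]$W %*% h) + layers[[2L]]$b
  }
  if (model@architecture == "amil") {
    pooled <- numeric(ncol(H))
    for (i in seq_len(n)) pooled <- pooled + a[i] * H[i, ]
    logit <- mlp1(pooled)
    list(prob = 1 / (1 + exp(-logit)), a = a)
  } else {
    S <- matrix(0, n, 2L)
    for (i in seq_len(n)) S[i, ] <- mlp1(a[i] * H[i, ])
    cs <- colSums(S)
    e <- exp(cs - max(cs))
    list(prob = (e / sum(e))[2L], a = a, S = S)
  }
}

## brute-force all-pairs AUROC (ties = 1/2)
oracleAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## mean attention entropy of a model over a bag set
meanAttentionEntropy <- function(model, bags) {
  mean(vapply(seq_len(nBags(bags)), function(i) {
    a <- predictBag(model, bags[[i]])@attentionWeights
    -sum(a * log(pmax(a, 1e-12)))
  }, numeric(1)))
}

## mean attention mass on witness instances over positive bags
witnessAttentionMass <- function(model, bags) {
  v <- vapply(seq_len(nBags(bags)), function(i) {
    b <- bags[[i]]
    if (bagLabel(b) == 0L || !length(hiddenInstanceLabels(b)))
      return(NA_real_)
    sum(predictBag(model, b)@attentionWeights[hiddenInstanceLabels(b) == 1L])
  }, numeric(1))
  mean(v, na.rm = TRUE)
}

## small synthetic slide reused across prep tests
smallSlide <- function(seed = 5L, strokes = 0L) {
  generateSyntheticSlide(slideSimSpec(width = 1024L, height = 1024L,
                                      nTissueBlobs = 4L,
                                      blobRadiusRange = c(80L, 150L),
                                      artifactStrokes = strokes,
                                      seed = seed))
}

## exhaustive brute-force rescan of every grid tile of a slide against a
## surviving thumbnail pixel set: the preprocessing oracle
bruteForceKeptTiles <- function(P, ratio, slideW, slideH, threshold,
                                tileSize = 512L) {
  ox <- seq.int(0L, slideW - 1L, by = tileSize)
  oy <- seq.int(0L, slideH - 1L, by = tileSize)
  origins <- as.matrix(expand.grid(x = ox, y = oy))
  frac <- tileTissueFractions(origins, P, ratio, slideDim = c(slideW, slideH),
                              tileSize = tileSize)
  origins[frac >= threshold, , drop = FALSE]
}

sortTiles <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  m <- m[order(m[, 2L], m[, 1L]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}
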