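#' @include accessors.R
NULL

## Glorot-uniform matrix init
glorot <- function(nOut, nIn) {
  lim <- sqrt(6 / (nIn + nOut))
  matrix(stats::runif(nOut * nIn, -lim, lim), nOut, nIn)
}

#' Construct a MIL model with seeded random initialization
#'
#' Builds one of the three MIL heads. All heads share the same structure: an
#' attention scoring network `w' act(V h)` (tanh for amil/hybrid, leaky ReLU
#' for admil), per-instance softmax normalization over the bag, and a
#' predictor MLP. For `amil` the predictor classifies the attention-pooled
#' embedding (one logit, sigmoid link); for `admil` and `hybrid` it scores
#' each attention-scaled instance per class and the bag class scores are the
#' sums over instances (softmax link).
#'
#' @param architecture `"amil"`, `"admil"` or `"hybrid"`.
#' @param inputDim embedding dimension d.
#' @param attentionWidth hidden width L of the attention network.
#' @param hiddenWidth hidden width of the predictor MLP.
#' @param leakySlope slope of the leaky-ReLU attention activation (admil).
#' @param seed integer seed for weight initialization.
#' @return a [MILModel-class].
#' @export
milModel <- function(architecture = c("amil", "admil", "hybrid"),
                     inputDim, attentionWidth = 128L, hiddenWidth = 256L,
                     leakySlope = 0.01, seed = 1L) {
  architecture <- match.arg(architecture)
  d <- as.integer(inputDim)
  L <- as.integer(attentionWidth)
  hw <- as.integer(hiddenWidth)
  outW <- if (architecture == "amil") 1L else 2L
  act <- if (architecture == "admil") "leaky_relu" else "tanh"
  withSeed(seed, {
    attention <- list(V = glorot(L, d), w = stats::runif(L, -sqrt(6 / (L + 1)),
                                                         sqrt(6 / (L + 1))),
                      activation = act, leakySlope = leakySlope)
    layers <- list(list(W = glorot(hw, d), b = rep(0, hw)),
                   list(W = glorot(outW, hw), b = rep(0, outW)))
    new("MILModel", architecture = architecture, attention = attention,
        predictor = list(layers = layers), inputDim = d)
  })
}

#' Per-instance attention logits
#'
#' Scores each instance independently as `w' act(V h_i)`; no cross-instance
#' terms enter, so duplicated instances receive identical logits.
#'
#' @param h numeric matrix of embeddings (n x d) or a single embedding vector.
#' @param attention list with `V`, `w`, `activation`, `leakySlope` (as stored
#'   in a [MILModel-class]).
#' @return numeric vector of n scalar logits.
#' @export
attentionLogits <- function(h, attention) {
  if (is.null(dim(h))) h <- matrix(h, nrow = 1L)
  if (ncol(h) != ncol(attention$V))
    stop("embedding dimension does not match attention V")
  A <- h %*% t(attention$V)
  Tact <- if (attention$activation == "tanh") tanh(A)
  else ifelse(A > 0, A, attention$leakySlope * A)
  drop(Tact %*% attention$w)
}

#' Normalize attention logits over the instances of a bag
#'
#' Softmax over the instance axis with max subtraction for numerical
#' stability; the result is nonnegative and sums to 1.
#'
#' @param logits per-instance attention logits.
#' @return numeric vector of attention weights.
#' @export
attentionWeights <- function(logits) {
  if (length(logits) < 1L) stop("need at least one attention logit")
  if (any(!is.finite(logits))) stop("attention logits must be finite")
  stableSoftmax(logits)
}

#' Sigmoid-bounded patch contribution scores
#'
#' Maps unbounded positive-class patch logits to (0, 1). Values below 0.5 are
#' inhibitory (the patch pushes against the positive class), values at or
#' above 0.5 excitatory.
#'
#' @param scores per-instance positive-class logits.
#' @return numeric vector in (0, 1).
#' @export
boundContributions <- function(scores) {
  if (any(!is.finite(scores))) stop("contribution scores must be finite")
  sigmoid(scores)
}

## predictor MLP forward: X (n x d) -> (n x out); ReLU between layers,
## linear output
mlpForward <- function(X, layers) {
  A <- X
  nl <- length(layers)
  for (k in seq_len(nl)) {
    Z <- A %*% t(layers[[k]]$W) +
      matrix(layers[[k]]$b, nrow(A), length(layers[[k]]$b), byrow = TRUE)
    A <- if (k < nl) pmax(Z, 0) else Z
  }
  A
}

#' @describeIn predictBag forward pass for any architecture
setMethod("predictBag", signature("MILModel", "MILBag"), function(model, bag) {
  H <- bag@embeddings
  if (ncol(H) != model@inputDim)
    stop("bag embedding dimension does not match the model")
  logits <- attentionLogits(H, model@attention)
  a <- attentionWeights(logits)
  layers <- model@predictor$layers
  if (model@architecture == "amil") {
    pooled <- colSums(a * H)
    bagLogit <- drop(mlpForward(matrix(pooled, 1L), layers))
    new("BagPrediction", probability = sigmoid(bagLogit), logits = bagLogit,
        attentionWeights = a, attentionLogits = logits,
        contributions = matrix(0, 0L, 2L), bounded = numeric(0))
  } else {
    S <- mlpForward(a * H, layers)            # n x 2 per-instance class scores
    classScores <- colSums(S)
    prob <- sigmoid(classScores[2L] - classScores[1L])  # softmax over 2 sums
    new("BagPrediction", probability = prob, logits = classScores,
        attentionWeights = a, attentionLogits = logits,
        contributions = S, bounded = boundContributions(S[, 2L]))
  }
})

#' Forward pass restricted to the attention-pooling architecture
#'
#' @param bag a [MILBag-class].
#' @param model an `"amil"` [MILModel-class].
#' @return a [BagPrediction-class] (no per-patch contributions).
#' @export
amilForward <- function(bag, model) {
  if (architecture(model) != "amil")
    stop("amilForward requires an 'amil' model, got '",
         architecture(model), "'")
  predictBag(model, bag)
}

#' Forward pass restricted to the additive architectures
#'
#' @param bag a [MILBag-class].
#' @param model an `"admil"` or `"hybrid"` [MILModel-class].
#' @return a [BagPrediction-class] with per-patch contribution scores.
#' @export
additiveForward <- function(bag, model) {
  if (!architecture(model) %in% c("admil", "hybrid"))
    stop("additiveForward requires an 'admil' or 'hybrid' model, got '",
         architecture(model), "'")
  predictBag(model, bag)
}

#' Serialize a MIL model to a single archive file
#'
#' Writes the architecture tag, widths and all weight arrays; reading the
#' archive back restores bit-identical forward passes.
#'
#' @param model a [MILModel-class].
#' @param path file path.
#' @export
saveMILModel <- function(model, path) {
  stopifnot(is(model, "MILModel"))
  saveRDS(list(architecture = model@architecture, attention = model@attention,
               predictor = model@predictor, inputDim = model@inputDim),
          path)
  invisible(path)
}

#' @rdname saveMILModel
#' @return `readMILModel` returns the restored [MILModel-class].
#' @export
readMILModel <- function(path) {
  x <- readRDS(path)
  new("MILModel", architecture = x$architecture, attention = x$attention,
      predictor = x$predictor, inputDim = x$inputDim)
}
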