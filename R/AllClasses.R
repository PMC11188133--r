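#' @import methods
NULL

#' MILBag: one bag of instance embeddings
#'
#' A bag groups the embeddings of the tiles (instances) of one slide together
#' with a single binary bag label. Instance-level labels, when the bag was
#' produced by the synthetic generator, travel in a side channel
#' (`instanceLabels`) that the training code never reads; they exist only so
#' that tests can verify witness localization.
#'
#' @slot embeddings numeric matrix, one row per instance (n x d).
#' @slot label integer scalar, 0 (negative) or 1 (positive).
#' @slot bagId character scalar identifier (e.g. a slide id).
#' @slot coords integer matrix of tile origins (n x 2, columns x,y; 0-based
#'   pixel coordinates at the bag's magnification) or a 0-row matrix when
#'   coordinates are not available.
#' @slot instanceLabels integer vector of hidden per-instance labels (length n)
#'   or `integer(0)` when unknown.
#' @exportClass MILBag
setClass("MILBag",
  representation(
    embeddings = "matrix",
    label = "integer",
    bagId = "character",
    coords = "matrix",
    instanceLabels = "integer"
  ),
  prototype(
    coords = matrix(integer(0), nrow = 0, ncol = 2),
    instanceLabels = integer(0)
  )
)

setValidity("MILBag", function(object) {
  msg <- character(0)
  n <- nrow(object@embeddings)
  if (n < 1L) msg <- c(msg, "a bag must contain at least one instance")
  if (!is.numeric(object@embeddings) || anyNA(object@embeddings))
    msg <- c(msg, "embeddings must be a numeric matrix without NAs")
  if (length(object@label) != 1L || !object@label %in% c(0L, 1L))
    msg <- c(msg, "label must be a single 0/1 integer")
  if (length(object@bagId) != 1L || is.na(object@bagId))
    msg <- c(msg, "bagId must be a single string")
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "coords must have two columns (x, y)")
  if (nrow(object@coords) != 0L && nrow(object@coords) != n)
    msg <- c(msg, "coords must have one row per instance (or none)")
  nl <- length(object@instanceLabels)
  if (nl != 0L && nl != n)
    msg <- c(msg, "instanceLabels must have one entry per instance (or none)")
  if (nl > 0L && !all(object@instanceLabels %in% c(0L, 1L)))
    msg <- c(msg, "instanceLabels must be 0/1")
  if (length(msg)) msg else TRUE
})

#' MILBagSet: a collection of bags sharing one embedding dimension
#'
#' @slot bags list of [MILBag-class] objects, all with the same embedding
#'   dimension d.
#' @exportClass MILBagSet
setClass("MILBagSet", representation(bags = "list"))

setValidity("MILBagSet", function(object) {
  if (!all(vapply(object@bags, is, logical(1), "MILBag")))
    return("all elements must be MILBag objects")
  if (length(object@bags) > 0L) {
    d <- vapply(object@bags, function(b) ncol(b@embeddings), integer(1))
    if (length(unique(d)) > 1L)
      return("all bags must share the same embedding dimension")
  }
  TRUE
})

#' MILModel: parameters of one MIL head
#'
#' Holds the attention module (a one-hidden-layer scoring network with a tanh
#' or leaky-ReLU activation) and the predictor MLP of one of the three
#' architectures:
#' \describe{
#'   \item{amil}{attention pooling: instances are averaged with attention
#'     weights and the pooled embedding is classified (single positive-class
#'     logit, sigmoid link); tanh attention.}
#'   \item{admil}{additive scoring: each attention-scaled instance is scored
#'     per class by the predictor, bag class scores are the sums of instance
#'     scores (softmax link); leaky-ReLU attention.}
#'   \item{hybrid}{the additive head combined with amil's tanh attention.}
#' }
#'
#' @slot architecture one of `"amil"`, `"admil"`, `"hybrid"`.
#' @slot attention list with elements `V` (L x d matrix), `w` (length-L
#'   vector), `activation` (`"tanh"` or `"leaky_relu"`), `leakySlope`.
#' @slot predictor list with element `layers`, a list of layers each holding
#'   `W` (out x in) and `b` (out); ReLU between layers, linear output.
#' @slot inputDim integer embedding dimension d.
#' @exportClass MILModel
setClass("MILModel",
  representation(
    architecture = "character",
    attention = "list",
    predictor = "list",
    inputDim = "integer"
  )
)

setValidity("MILModel", function(object) {
  msg <- character(0)
  arch <- object@architecture
  if (length(arch) != 1L || !arch %in% c("amil", "admil", "hybrid"))
    return("architecture must be one of 'amil', 'admil', 'hybrid'")
  att <- object@attention
  if (!all(c("V", "w", "activation", "leakySlope") %in% names(att)))
    return("attention must contain V, w, activation, leakySlope")
  if (!att$activation %in% c("tanh", "leaky_relu"))
    return("attention activation must be 'tanh' or 'leaky_relu'")
  if (arch %in% c("amil", "hybrid") && att$activation != "tanh")
    msg <- c(msg, "amil and hybrid require tanh attention")
  if (arch == "admil" && att$activation != "leaky_relu")
    msg <- c(msg, "admil requires leaky_relu attention")
  if (att$leakySlope <= 0) msg <- c(msg, "leakySlope must be > 0")
  if (ncol(att$V) != object@inputDim)
    msg <- c(msg, "attention V must have d columns")
  if (length(att$w) != nrow(att$V))
    msg <- c(msg, "attention w must match V's hidden width")
  layers <- object@predictor$layers
  if (is.null(layers) || length(layers) < 1L)
    return("predictor must contain at least one layer")
  if (ncol(layers[[1L]]$W) != object@inputDim)
    msg <- c(msg, "predictor input width must equal d")
  outw <- nrow(layers[[length(layers)]]$W)
  if (arch == "amil" && outw != 1L)
    msg <- c(msg, "amil predictor must output a single logit")
  if (arch %in% c("admil", "hybrid") && outw != 2L)
    msg <- c(msg, "additive predictors must output 2 class scores")
  if (length(msg)) msg else TRUE
})

#' BagPrediction: the forward-pass output for one bag
#'
#' @slot probability positive-class probability in \[0, 1\].
#' @slot logits bag-level logits (length 1 for amil, 2 class scores for the
#'   additive variants).
#' @slot attentionWeights normalized attention weights (sum to 1).
#' @slot attentionLogits raw per-instance attention scores.
#' @slot contributions n x 2 matrix of per-instance per-class additive scores
#'   (0-row for amil).
#' @slot bounded sigmoid-bounded positive-class contributions in (0, 1)
#'   (length 0 for amil); values below 0.5 are inhibitory, at or above 0.5
#'   excitatory.
#' @exportClass BagPrediction
setClass("BagPrediction",
  representation(
    probability = "numeric",
    logits = "numeric",
    attentionWeights = "numeric",
    attentionLogits = "numeric",
    contributions = "matrix",
    bounded = "numeric"
  )
)

setValidity("BagPrediction", function(object) {
  msg <- character(0)
  if (abs(sum(object@attentionWeights) - 1) > 1e-6)
    msg <- c(msg, "attention weights must sum to 1")
  if (any(object@attentionWeights < 0))
    msg <- c(msg, "attention weights must be nonnegative")
  if (object@probability < 0 || object@probability > 1)
    msg <- c(msg, "probability must lie in [0, 1]")
  if (length(object@bounded) &&
      (any(object@bounded <= 0) || any(object@bounded >= 1)))
    msg <- c(msg, "bounded contributions must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' FeatureExtractor: a pluggable tile-to-embedding mapping
#'
#' The interface of the (external) tile feature extractor: a deterministic
#' function from a 512 x 512 RGB tile to a fixed-length embedding (1024 by
#' default, the usual length of pathology foundation embeddings). Register
#' any network behind this contract; the package ships a deterministic toy
#' extractor for testing.
#'
#' @slot name character name.
#' @slot dim integer output dimension.
#' @slot fun function taking a 512 x 512 x 3 array (values 0-255) and
#'   returning a numeric vector of length `dim`.
#' @exportClass FeatureExtractor
setClass("FeatureExtractor",
  representation(name = "character", dim = "integer", fun = "function")
)

setValidity("FeatureExtractor", function(object) {
  if (length(object@dim) != 1L || object@dim < 1L)
    return("dim must be a positive integer")
  TRUE
})
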