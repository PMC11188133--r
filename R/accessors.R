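#' @include AllGenerics.R
NULL

#' Accessors for MIL objects
#'
#' Small accessor functions for the slots of [MILBag-class],
#' [MILBagSet-class] and [MILModel-class] objects.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("instanceEmbeddings", "MILBag", function(x) x@embeddings)

#' @rdname accessors
setMethod("bagLabel", "MILBag", function(x) x@label)

#' @rdname accessors
setMethod("bagId", "MILBag", function(x) x@bagId)

#' @rdname accessors
setMethod("tileCoords", "MILBag", function(x) x@coords)

#' @rdname accessors
setMethod("hiddenInstanceLabels", "MILBag", function(x) x@instanceLabels)

#' @rdname accessors
setMethod("bagLabels", "MILBagSet",
          function(x) vapply(x@bags, bagLabel, integer(1)))

#' @rdname accessors
setMethod("nBags", "MILBagSet", function(x) length(x@bags))

#' @rdname accessors
setMethod("embedDim", "MILBagSet", function(x) {
  if (length(x@bags) == 0L) return(NA_integer_)
  ncol(x@bags[[1L]]@embeddings)
})

#' @rdname accessors
setMethod("embedDim", "MILBag", function(x) ncol(x@embeddings))

#' @rdname accessors
setMethod("architecture", "MILModel", function(x) x@architecture)

#' Number of instances in a bag
#' @param x a MILBag
#' @return integer instance count
#' @export
bagSize <- function(x) {
  stopifnot(is(x, "MILBag"))
  nrow(x@embeddings)
}

#' @describeIn accessors extract bag `i` from a set
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[[", "MILBagSet", function(x, i, j, ...) x@bags[[i]])

#' @describeIn accessors subset a bag set
#' @export
setMethod("[", "MILBagSet", function(x, i, j, ..., drop = TRUE) {
  new("MILBagSet", bags = x@bags[i])
})

#' @rdname accessors
#' @export
setMethod("length", "MILBagSet", function(x) length(x@bags))

setMethod("show", "MILBag", function(object) {
  cat(sprintf("MILBag '%s': %d instances x %d dims, label %d%s\n",
              object@bagId, nrow(object@embeddings),
              ncol(object@embeddings), object@label,
              if (length(object@instanceLabels))
                sprintf(" (%d hidden positives)",
                        sum(object@instanceLabels)) else ""))
})

setMethod("show", "MILBagSet", function(object) {
  lab <- bagLabels(object)
  cat(sprintf("MILBagSet: %d bags (%d positive / %d negative), d = %d\n",
              length(object@bags), sum(lab == 1L), sum(lab == 0L),
              embedDim(object)))
})

setMethod("show", "MILModel", function(object) {
  L <- nrow(object@attention$V)
  widths <- vapply(object@predictor$layers, function(l) nrow(l$W), integer(1))
  cat(sprintf(
    "MILModel [%s]: d = %d, attention %s (L = %d), predictor %s\n",
    object@architecture, object@inputDim, object@attention$activation, L,
    paste(c(object@inputDim, widths), collapse = " -> ")))
})

setMethod("show", "BagPrediction", function(object) {
  cat(sprintf("BagPrediction: P(positive) = %.4f over %d instances%s\n",
              object@probability, length(object@attentionWeights),
              if (nrow(object@contributions))
                sprintf(", %d excitatory patches",
                        sum(object@bounded >= 0.5)) else ""))
})

setMethod("show", "FeatureExtractor", function(object) {
  cat(sprintf("FeatureExtractor '%s': 512x512 RGB tile -> %d-d embedding\n",
              object@name, object@dim))
})
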