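#' @include AllClasses.R
NULL

#' Forward pass of a MIL model on one bag
#'
#' @param model a [MILModel-class].
#' @param bag a [MILBag-class].
#' @return a [BagPrediction-class].
#' @export
setGeneric("predictBag", function(model, bag) standardGeneric("predictBag"))

#' @rdname accessors
#' @export
setGeneric("instanceEmbeddings",
           function(x) standardGeneric("instanceEmbeddings"))

#' @rdname accessors
#' @export
setGeneric("bagLabel", function(x) standardGeneric("bagLabel"))

#' @rdname accessors
#' @export
setGeneric("bagId", function(x) standardGeneric("bagId"))

#' @rdname accessors
#' @export
setGeneric("tileCoords", function(x) standardGeneric("tileCoords"))

#' @rdname accessors
#' @export
setGeneric("hiddenInstanceLabels",
           function(x) standardGeneric("hiddenInstanceLabels"))

#' @rdname accessors
#' @export
setGeneric("bagLabels", function(x) standardGeneric("bagLabels"))

#' @rdname accessors
#' @export
setGeneric("nBags", function(x) standardGeneric("nBags"))

#' @rdname accessors
#' @export
setGeneric("embedDim", function(x) standardGeneric("embedDim"))

#' @rdname accessors
#' @export
setGeneric("architecture", function(x) standardGeneric("architecture"))
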