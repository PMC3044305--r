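#' Accessors for bplaClust objects
#'
#' Small generics giving read access to the slots of the package's S4
#' classes without touching `@` directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors base-pair probability matrix of a profile (or the
#'   0/1 indicator matrix of a fixed structure's profile).
#' @export
setGeneric("pairProb", function(x) standardGeneric("pairProb"))
#' @describeIn accessors per-position probability of pairing downstream.
#' @export
setGeneric("leftProb", function(x) standardGeneric("leftProb"))
#' @describeIn accessors per-position probability of pairing upstream.
#' @export
setGeneric("rightProb", function(x) standardGeneric("rightProb"))
#' @describeIn accessors per-position probability of being unpaired.
#' @export
setGeneric("unpairedProb", function(x) standardGeneric("unpairedProb"))

setMethod("pairProb", "BasePairProfile", function(x) x@pairProb)
setMethod("leftProb", "BasePairProfile", function(x) x@leftProb)
setMethod("rightProb", "BasePairProfile", function(x) x@rightProb)
setMethod("unpairedProb", "BasePairProfile", function(x) x@unpairedProb)

#' @describeIn accessors number of positions / leaves the object spans.
#' @export
setGeneric("nPositions", function(x) standardGeneric("nPositions"))
setMethod("nPositions", "BasePairProfile", function(x) length(x@leftProb))
setMethod("nPositions", "SecondaryStructure", function(x) x@length)

#' @describeIn accessors the (i, j) pair matrix of a fixed structure.
#' @export
setGeneric("structurePairs", function(x) standardGeneric("structurePairs"))
setMethod("structurePairs", "SecondaryStructure", function(x) x@pairs)

#' Binary pairing-state indicators of a fixed structure
#'
#' `leftIndicator(s)[i]` is 1 when position i pairs with a downstream
#' position, `rightIndicator(s)[i]` when it pairs upstream, and
#' `unpairedIndicator(s)[i]` when it is unpaired; at every position exactly
#' one of the three is 1.
#'
#' @param x a [SecondaryStructure-class].
#' @return integer 0/1 vector of length `nPositions(x)`.
#' @name indicators
NULL

#' @rdname indicators
#' @export
setGeneric("leftIndicator", function(x) standardGeneric("leftIndicator"))
#' @rdname indicators
#' @export
setGeneric("rightIndicator", function(x) standardGeneric("rightIndicator"))
#' @rdname indicators
#' @export
setGeneric("unpairedIndicator", function(x) standardGeneric("unpairedIndicator"))

setMethod("leftIndicator", "SecondaryStructure", function(x) {
    v <- integer(x@length)
    if (nrow(x@pairs)) v[x@pairs[, 1]] <- 1L
    v
})
setMethod("rightIndicator", "SecondaryStructure", function(x) {
    v <- integer(x@length)
    if (nrow(x@pairs)) v[x@pairs[, 2]] <- 1L
    v
})
setMethod("unpairedIndicator", "SecondaryStructure", function(x) {
    1L - leftIndicator(x) - rightIndicator(x)
})

#' @describeIn accessors similarity values as a plain named matrix.
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)

#' @describeIn accessors sequence / leaf identifiers.
#' @export
setGeneric("sequenceIds", function(x) standardGeneric("sequenceIds"))
setMethod("sequenceIds", "SimilarityMatrix", function(x) rownames(x@values))
setMethod("sequenceIds", "ClusterTree", function(x) x@labels)

#' @describeIn accessors merge heights of a cluster tree, in merge order.
#' @export
setGeneric("mergeHeights", function(x) standardGeneric("mergeHeights"))
setMethod("mergeHeights", "ClusterTree", function(x) x@height)

#' @describeIn accessors member sequences of a synthetic family.
#' @export
setGeneric("familyMembers", function(x) standardGeneric("familyMembers"))
setMethod("familyMembers", "SyntheticFamily", function(x) x@members)

#' @describeIn accessors consensus structure of a synthetic family.
#' @export
setGeneric("consensusStructure", function(x) standardGeneric("consensusStructure"))
setMethod("consensusStructure", "SyntheticFamily", function(x) x@consensusStructure)

#' Convert a ClusterTree to a stats::hclust object
#'
#' @param tree a [ClusterTree-class].
#' @return an object of class `hclust` (merge/height/order/labels), usable
#'   with [stats::cophenetic()], [stats::cutree()] and plotting.
#' @export
asHclust <- function(tree) {
    stopifnot(is(tree, "ClusterTree"))
    n <- length(tree@labels)
    ord <- function(node) {
        if (node < 0) return(-node)
        c(ord(tree@merge[node, 1]), ord(tree@merge[node, 2]))
    }
    structure(list(merge = tree@merge, height = tree@height,
                   order = ord(n - 1L), labels = tree@labels,
                   method = "wpgma", call = match.call(),
                   dist.method = "one minus similarity"),
              class = "hclust")
}
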