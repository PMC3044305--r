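#' @useDynLib bplaClust, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is setValidity show slot
#' @importFrom stats runif
#' @importFrom utils head read.table write.table
#' @keywords internal
"_PACKAGE"

RNA_ALPHABET <- c("A", "C", "G", "U")
CANONICAL_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Log-linear secondary-structure energy model
#'
#' The Boltzmann weight of a nested secondary structure is the product over
#' its base pairs of `exp(pairScores[type] / temperatureScale)`.  Only the
#' Watson-Crick and GU wobble pair types can carry weight; any other
#' dinucleotide has weight zero.  The model deliberately has no stacking or
#' loop terms so that small ensembles can be enumerated exactly; a
#' thermodynamic folding engine can be substituted via [foldWithBackend()].
#'
#' @slot pairScores named numeric vector of per-pair-type scores; names must
#'   be a subset of `AU, UA, CG, GC, GU, UG`.
#' @slot minLoop integer, minimal number of unpaired bases enclosed by a
#'   pair: a pair (i, j) requires `j - i > minLoop`.
#' @slot temperatureScale positive numeric divisor applied to scores before
#'   exponentiation.
#' @exportClass EnergyModel
setClass("EnergyModel",
    slots = c(pairScores = "numeric", minLoop = "integer",
              temperatureScale = "numeric"))

setValidity("EnergyModel", function(object) {
    msgs <- character()
    nm <- names(object@pairScores)
    if (is.null(nm) || !all(nm %in% CANONICAL_PAIRS))
        msgs <- c(msgs, paste("pairScores must be named with a subset of:",
                              paste(CANONICAL_PAIRS, collapse = " ")))
    if (anyDuplicated(nm))
        msgs <- c(msgs, "duplicated pair types in pairScores")
    if (length(object@minLoop) != 1L || object@minLoop < 0L)
        msgs <- c(msgs, "minLoop must be a single non-negative integer")
    if (length(object@temperatureScale) != 1L ||
        !is.finite(object@temperatureScale) || object@temperatureScale <= 0)
        msgs <- c(msgs, "temperatureScale must be a single positive number")
    if (length(msgs)) msgs else TRUE
})

#' Construct an energy model
#'
#' @param pairScores named numeric vector of scores per allowed pair type;
#'   the default gives every canonical/wobble pair the same score 1.
#' @param minLoop minimal hairpin loop size (default 3, the standard
#'   convention: a pair (i, j) needs j - i > 3).
#' @param temperatureScale positive scale for the exponential weighting.
#' @return An [EnergyModel-class] object.
#' @examples
#' uniform <- energyModel(pairScores = structure(rep(0, 6),
#'   names = c("AU", "UA", "CG", "GC", "GU", "UG")))
#' @export
energyModel <- function(pairScores = structure(rep(1, 6), names = CANONICAL_PAIRS),
                        minLoop = 3L, temperatureScale = 1) {
    new("EnergyModel", pairScores = pairScores,
        minLoop = as.integer(minLoop), temperatureScale = temperatureScale)
}

setMethod("show", "EnergyModel", function(object) {
    cat("EnergyModel: log-linear pair-weight model\n")
    cat("  pair scores:",
        paste(names(object@pairScores), object@pairScores,
              sep = "=", collapse = " "), "\n")
    cat("  minLoop:", object@minLoop,
        " temperatureScale:", object@temperatureScale, "\n")
})

#' A fixed nested secondary structure
#'
#' A set of base pairs (i, j), i < j, over a sequence of a given length, with
#' no crossing pairs and each position in at most one pair.
#'
#' @slot pairs two-column integer matrix of (i, j) pairs, possibly 0-row.
#' @slot length integer sequence length.
#' @exportClass SecondaryStructure
setClass("SecondaryStructure",
    slots = c(pairs = "matrix", length = "integer"))

setValidity("SecondaryStructure", function(object) {
    p <- object@pairs
    n <- object@length
    msgs <- character()
    if (ncol(p) != 2L) return("pairs must be a two-column matrix")
    if (length(n) != 1L || n < 0L) return("length must be a single non-negative integer")
    if (nrow(p)) {
        if (any(p < 1L) || any(p > n))
            msgs <- c(msgs, "pair index out of range 1..length")
        if (any(p[, 1] >= p[, 2]))
            msgs <- c(msgs, "pairs must satisfy i < j")
        if (anyDuplicated(as.vector(p)))
            msgs <- c(msgs, "a position occurs in more than one pair")
        if (nrow(p) > 1L) {
            for (a in seq_len(nrow(p) - 1L)) for (b in (a + 1L):nrow(p)) {
                i <- p[a, 1]; j <- p[a, 2]; k <- p[b, 1]; l <- p[b, 2]
                if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) {
                    msgs <- c(msgs, "crossing pairs (pseudoknot) not allowed")
                    break
                }
            }
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a secondary structure
#'
#' @param pairs two-column matrix (or empty) of 1-based (i, j) pairs, i < j.
#' @param length sequence length the structure lives on.
#' @return A [SecondaryStructure-class] object.
#' @export
secondaryStructure <- function(pairs = matrix(integer(), ncol = 2), length) {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    if (nrow(pairs) > 1L) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    new("SecondaryStructure", pairs = pairs, length = as.integer(length))
}

setMethod("show", "SecondaryStructure", function(object) {
    cat("SecondaryStructure on", object@length, "nt with",
        nrow(object@pairs), "pairs\n")
    if (nrow(object@pairs))
        cat(" ", paste0("(", object@pairs[, 1], ",", object@pairs[, 2], ")",
                        collapse = " "), "\n")
})

#' Base-pairing probability profile
#'
#' For one sequence: the upper-triangular matrix of base-pair probabilities
#' P(i, j) and three per-position marginal profiles -- the probability of
#' pairing with a downstream partner (left), with an upstream partner
#' (right), or of being unpaired.  At every position
#' left + right + unpaired = 1.  A fixed structure corresponds to the
#' degenerate 0/1 profile ([profileFromStructure()]).
#'
#' @slot pairProb numeric length x length matrix, upper triangle holds P(i, j).
#' @slot leftProb,rightProb,unpairedProb numeric per-position marginals.
#' @exportClass BasePairProfile
setClass("BasePairProfile",
    slots = c(pairProb = "matrix", leftProb = "numeric",
              rightProb = "numeric", unpairedProb = "numeric"))

PROFILE_TOL <- 1e-9

setValidity("BasePairProfile", function(object) {
    n <- length(object@leftProb)
    msgs <- character()
    if (!all(dim(object@pairProb) == c(n, n)))
        msgs <- c(msgs, "pairProb dimensions do not match profile length")
    if (length(object@rightProb) != n || length(object@unpairedProb) != n)
        msgs <- c(msgs, "marginal profile lengths differ")
    pp <- object@pairProb
    if (n && (min(pp) < -PROFILE_TOL || max(pp) > 1 + PROFILE_TOL))
        msgs <- c(msgs, "pair probabilities outside [0, 1]")
    tot <- object@leftProb + object@rightProb + object@unpairedProb
    if (n && max(abs(tot - 1)) > PROFILE_TOL)
        msgs <- c(msgs, "left + right + unpaired deviates from 1 beyond 1e-9")
    if (length(msgs)) msgs else TRUE
})

# internal: assemble a profile from a pair-probability matrix, deriving the
# marginals; drift beyond `tol` is an error, smaller drift is clamped
newBasePairProfile <- function(pairProb, tol = PROFILE_TOL) {
    n <- nrow(pairProb)
    if (n && (min(pairProb) < -tol || max(pairProb) > 1 + tol))
        stop("pair probabilities outside [0, 1] beyond tolerance ", tol)
    pairProb[pairProb < 0] <- 0
    pairProb[pairProb > 1] <- 1
    pairProb[lower.tri(pairProb, diag = TRUE)] <- 0
    left <- rowSums(pairProb)
    right <- colSums(pairProb)
    if (n && max(c(left, right)) > 1 + tol)
        stop("marginal pairing probability exceeds 1 beyond tolerance ", tol)
    left <- pmin(left, 1)
    right <- pmin(right, 1)
    unp <- 1 - left - right
    if (n && min(unp) < -tol)
        stop("left + right exceeds 1 beyond tolerance ", tol,
             " -- inconsistent pair-probability matrix")
    unp[unp < 0] <- 0
    new("BasePairProfile", pairProb = pairProb, leftProb = left,
        rightProb = right, unpairedProb = unp)
}

setMethod("show", "BasePairProfile", function(object) {
    n <- length(object@leftProb)
    cat("BasePairProfile over", n, "positions\n")
    if (n) {
        cat("  mean P(unpaired):", round(mean(object@unpairedProb), 4), "\n")
        np <- sum(object@pairProb >= 1e-6)
        cat("  pairs with probability >= 1e-6:", np, "\n")
    }
})

#' Scoring parameters for the local alignment kernel
#'
#' @slot alpha non-negative weight of the structural (paired-state) term.
#' @slot beta non-negative inverse-temperature-like weight on alignment
#'   scores inside the kernel sum.
#' @slot gapOpen,gapExtend gap open/extension scores (typically negative).
#' @slot subst symmetric 4x4 substitution matrix over A, C, G, U.
#' @exportClass KernelParams
setClass("KernelParams",
    slots = c(alpha = "numeric", beta = "numeric", gapOpen = "numeric",
              gapExtend = "numeric", subst = "matrix"))

setValidity("KernelParams", function(object) {
    msgs <- character()
    if (object@alpha < 0) msgs <- c(msgs, "alpha must be >= 0")
    if (object@beta < 0) msgs <- c(msgs, "beta must be >= 0")
    sm <- object@subst
    if (!all(dim(sm) == c(4L, 4L)) ||
        !identical(rownames(sm), RNA_ALPHABET) ||
        !identical(colnames(sm), RNA_ALPHABET))
        msgs <- c(msgs, "subst must be 4x4 with dimnames A C G U")
    else if (max(abs(sm - t(sm))) > 0)
        msgs <- c(msgs, "subst must be symmetric")
    if (length(msgs)) msgs else TRUE
})

#' Construct kernel scoring parameters
#'
#' Defaults are the published BPLA-kernel settings: `alpha = 1`,
#' `beta = 0.1`, gap open `-27`, gap extension `-0.1`, and the RIBOSUM85-60
#' single-nucleotide substitution matrix.
#'
#' @param alpha structure weight (>= 0).
#' @param beta kernel inverse-temperature weight (>= 0).
#' @param gapOpen,gapExtend affine gap scores.
#' @param subst symmetric 4x4 numeric matrix with dimnames A C G U.
#' @return A [KernelParams-class] object.
#' @examples
#' p <- kernelParams()
#' p@beta
#' @export
kernelParams <- function(alpha = 1.0, beta = 0.1, gapOpen = -27,
                         gapExtend = -0.1, subst = ribosumMatrix()) {
    new("KernelParams", alpha = alpha, beta = beta, gapOpen = gapOpen,
        gapExtend = gapExtend, subst = subst)
}

setMethod("show", "KernelParams", function(object) {
    cat("KernelParams: alpha =", object@alpha, " beta =", object@beta,
        " gapOpen =", object@gapOpen, " gapExtend =", object@gapExtend, "\n")
    cat("  substitution matrix diagonal:",
        paste(RNA_ALPHABET, diag(object@subst), sep = "=", collapse = " "),
        "\n")
})

#' Symmetric matrix of normalized kernel similarities
#'
#' Entries are the normalized log local-alignment kernel
#' \eqn{\hat K(x,y) = \log K(x,y) / \sqrt{\log K(x,x)\,\log K(y,y)}}, in
#' `[0, 1]`, with unit diagonal.
#'
#' @slot values symmetric numeric matrix with sequence ids as dimnames.
#' @slot scoring which position scoring produced it
#'   (`"expected"`, `"bpla"` or `"sequence_only"`).
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
    slots = c(values = "matrix", scoring = "character"))

setValidity("SimilarityMatrix", function(object) {
    v <- object@values
    msgs <- character()
    if (nrow(v) != ncol(v) || is.null(rownames(v)) ||
        !identical(rownames(v), colnames(v)))
        return("values must be square with matching row/column ids")
    if (anyDuplicated(rownames(v)))
        msgs <- c(msgs, "duplicated sequence ids")
    if (max(abs(v - t(v))) > 1e-9)
        msgs <- c(msgs, "matrix not symmetric within 1e-9")
    if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
        msgs <- c(msgs, "similarities outside [0, 1]")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimilarityMatrix", function(object) {
    n <- nrow(object@values)
    cat("SimilarityMatrix:", n, "sequences, scoring =", object@scoring, "\n")
    off <- object@values[upper.tri(object@values)]
    if (length(off))
        cat("  off-diagonal similarity range:",
            paste(round(range(off), 4), collapse = " .. "), "\n")
})

#' WPGMA cluster dendrogram
#'
#' Rooted binary merge tree in the `stats::hclust` encoding: row k of
#' `merge` gives the two children joined at `height[k]` (negative entries
#' are leaves, positive entries earlier merges).  Heights are the pairwise
#' cluster distances at merge time and are non-decreasing.
#'
#' @slot labels leaf ids, in input order.
#' @slot merge (n-1) x 2 integer matrix of merges.
#' @slot height numeric merge heights.
#' @exportClass ClusterTree
setClass("ClusterTree",
    slots = c(labels = "character", merge = "matrix", height = "numeric"))

setValidity("ClusterTree", function(object) {
    n <- length(object@labels)
    msgs <- character()
    if (n < 2L) return("need at least two leaves")
    if (!all(dim(object@merge) == c(n - 1L, 2L)))
        msgs <- c(msgs, "merge must be (n-1) x 2")
    if (length(object@height) != n - 1L)
        msgs <- c(msgs, "height length must be n-1")
    if (any(object@height < 0))
        msgs <- c(msgs, "negative merge height")
    if (any(diff(object@height) < -1e-9))
        msgs <- c(msgs, "merge heights decrease: linkage not monotone")
    if (anyDuplicated(object@labels))
        msgs <- c(msgs, "duplicated leaf ids")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "ClusterTree", function(object) {
    cat("ClusterTree (WPGMA):", length(object@labels), "leaves,",
        "root height", round(max(object@height), 4), "\n")
})

#' First-order Markov (dinucleotide) sequence model
#'
#' @slot transition 4x4 row-stochastic matrix of P(next | current).
#' @slot initial distribution over A, C, G, U for the first residue.
#' @exportClass DinucModel
setClass("DinucModel",
    slots = c(transition = "matrix", initial = "numeric"))

setValidity("DinucModel", function(object) {
    tr <- object@transition
    msgs <- character()
    if (!all(dim(tr) == c(4L, 4L)))
        msgs <- c(msgs, "transition must be 4x4")
    else if (max(abs(rowSums(tr) - 1)) > 1e-12)
        msgs <- c(msgs, "transition rows must sum to 1 within 1e-12")
    if (length(object@initial) != 4L || abs(sum(object@initial) - 1) > 1e-12)
        msgs <- c(msgs, "initial must be a distribution over A C G U")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "DinucModel", function(object) {
    cat("DinucModel; initial:",
        paste(RNA_ALPHABET, round(object@initial, 3), sep = "=",
              collapse = " "), "\n")
})

#' A simulated RNA family
#'
#' Members descend from one common ancestor carrying a consensus secondary
#' structure; substitutions at paired positions are compensatory (the pair
#' stays canonical/wobble) and indels are restricted to unpaired regions.
#'
#' @slot members named character vector of member sequences.
#' @slot referenceLabel family (reference cluster) label.
#' @slot targetIdentity the identity level the mutation process aimed for.
#' @slot consensusStructure the ancestor's [SecondaryStructure-class].
#' @slot ancestor the ancestral sequence.
#' @slot memberMaps list of integer vectors mapping ancestor positions to
#'   member positions (NA where deleted), for structure audits.
#' @exportClass SyntheticFamily
setClass("SyntheticFamily",
    slots = c(members = "character", referenceLabel = "character",
              targetIdentity = "numeric",
              consensusStructure = "SecondaryStructure",
              ancestor = "character", memberMaps = "list"))

setMethod("show", "SyntheticFamily", function(object) {
    cat("SyntheticFamily", object@referenceLabel, ":",
        length(object@members), "members, target identity",
        object@targetIdentity, "\n")
})
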