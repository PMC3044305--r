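#' Distance matrix from a similarity matrix
#'
#' Entry-wise `1 - similarity`, with an exactly zero diagonal.
#'
#' @param sim a [SimilarityMatrix-class] or a symmetric numeric matrix with
#'   entries in `[0, 1]` (within 1e-9) and dimnames.
#' @return symmetric numeric distance matrix with zero diagonal.
#' @export
distanceFromSimilarity <- function(sim) {
    v <- if (is(sim, "SimilarityMatrix")) similarityValues(sim) else as.matrix(sim)
    if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
        stop("similarities outside [0, 1] beyond tolerance")
    d <- 1 - pmin(pmax(v, 0), 1)
    diag(d) <- 0
    d
}

#' WPGMA hierarchical clustering
#'
#' Agglomerates the closest pair of clusters repeatedly; after merging A
#' and B, the distance to any other cluster C is
#' `(d(A, C) + d(B, C)) / 2` -- each parent counted equally regardless of
#' size (weighted averaging).  The merge height is the merged pair's
#' distance, so heights live on the same scale as the distances (one minus
#' similarity).  Ties on the minimal distance are broken by the
#' lexicographically smallest pair of cluster representatives (a cluster's
#' representative is its lexicographically smallest leaf id), making the
#' tree independent of input order.
#'
#' @param dist symmetric non-negative matrix with zero diagonal.
#' @param ids leaf ids (default: rownames of `dist`).
#' @return A [ClusterTree-class].
#' @examples
#' d <- matrix(c(0, .1, .5, .1, 0, .5, .5, .5, 0), 3,
#'             dimnames = list(c("a","b","c"), c("a","b","c")))
#' mergeHeights(wpgma(d))
#' @export
wpgma <- function(dist, ids = rownames(dist)) {
    d <- as.matrix(dist)
    n <- nrow(d)
    if (is.null(ids)) ids <- paste0("L", seq_len(n))
    if (n < 2L) stop("need at least two items to cluster")
    if (anyDuplicated(ids)) stop("duplicated ids")
    if (any(!is.finite(d)) || any(d < 0))
        stop("distances must be finite and non-negative")
    if (max(abs(d - t(d))) > 1e-9) stop("distance matrix not symmetric")
    if (any(abs(diag(d)) > 1e-9)) stop("distance matrix diagonal not zero")

    node <- -seq_len(n)          # hclust codes: negative leaf, positive merge
    rep <- ids                   # representative leaf id per active cluster
    active <- seq_len(n)
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        na <- length(active)
        sub <- d[active, active, drop = FALSE]
        best <- Inf; bi <- bj <- 0L; br <- c("", "")
        for (a in seq_len(na - 1L)) for (b in (a + 1L):na) {
            dd <- sub[a, b]
            r <- range(c(rep[active[a]], rep[active[b]]))
            better <- dd < best ||
                (dd == best && (r[1] < br[1] ||
                                (r[1] == br[1] && r[2] < br[2])))
            if (better) { best <- dd; bi <- a; bj <- b; br <- r }
        }
        ca <- active[bi]; cb <- active[bj]
        merge[step, ] <- sort(c(node[ca], node[cb]))
        height[step] <- best
        # WPGMA update: new cluster kept in slot ca
        others <- setdiff(active, c(ca, cb))
        d[ca, others] <- d[others, ca] <- (d[ca, others] + d[cb, others]) / 2
        node[ca] <- step
        rep[ca] <- min(rep[ca], rep[cb])
        active <- setdiff(active, cb)
    }
    new("ClusterTree", labels = ids, merge = merge, height = height)
}

#' Flat clustering by cutting the tree at a distance threshold
#'
#' Clusters are the maximal subtrees all of whose internal merge heights
#' are strictly below `threshold`; a threshold of 0 yields singletons, a
#' threshold above the root height one cluster.  A threshold exactly equal
#' to a merge height splits that merge (strict `<` semantics).
#'
#' @param tree a [ClusterTree-class].
#' @param threshold non-negative cut height.
#' @return named integer vector: cluster label per leaf id.
#' @export
cutTree <- function(tree, threshold) {
    stopifnot(is(tree, "ClusterTree"), threshold >= 0)
    n <- length(tree@labels)
    # node ids: 1..n leaves, n+k the k-th merge
    id <- function(code) if (code < 0L) -code else n + code
    nodeMembers <- vector("list", 2L * n - 1L)
    for (i in seq_len(n)) nodeMembers[[i]] <- i
    alive <- c(rep(TRUE, n), rep(FALSE, n - 1L))
    for (k in seq_len(n - 1L)) {
        ch <- tree@merge[k, ]
        nodeMembers[[n + k]] <- c(nodeMembers[[id(ch[1])]],
                                  nodeMembers[[id(ch[2])]])
        if (tree@height[k] < threshold) {
            alive[id(ch[1])] <- alive[id(ch[2])] <- FALSE
            alive[n + k] <- TRUE
        }
    }
    out <- integer(n)
    cl <- 0L
    for (nd in seq_len(2L * n - 1L)) {
        if (!alive[nd]) next
        cl <- cl + 1L
        out[nodeMembers[[nd]]] <- cl
    }
    # number clusters by first appearance in leaf order
    out <- match(out, unique(out))
    names(out) <- tree@labels
    out
}

# quote a label for Newick if it contains reserved characters
newickLabel <- function(x) {
    if (grepl("[](),:;'[ \t]", x))
        paste0("'", gsub("'", "''", x), "'") else x
}

#' Newick string of a cluster tree
#'
#' Ultrametric branch lengths: each branch is the difference between the
#' parent's and the child's merge height (leaves have height 0), so the
#' path length from any leaf to an ancestor equals that ancestor's merge
#' height.  Ids containing Newick-reserved characters are quoted.
#'
#' @param tree a [ClusterTree-class].
#' @param digits significant digits for branch lengths.
#' @return a single Newick string terminated by `;`.
#' @export
toNewick <- function(tree, digits = 10) {
    stopifnot(is(tree, "ClusterTree"))
    fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
    build <- function(code, parentHeight) {
        if (code < 0L) {
            paste0(newickLabel(tree@labels[-code]), ":", fmt(parentHeight))
        } else {
            h <- tree@height[code]
            paste0("(", build(tree@merge[code, 1], h), ",",
                   build(tree@merge[code, 2], h), "):",
                   fmt(parentHeight - h))
        }
    }
    n <- length(tree@labels)
    root <- n - 1L
    h <- tree@height[root]
    paste0("(", build(tree@merge[root, 1], h), ",",
           build(tree@merge[root, 2], h), ");")
}
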