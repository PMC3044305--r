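# validate a reference clustering against a set of ids
checkReference <- function(ref, ids) {
    if (is.null(names(ref))) stop("reference clustering must be named by id")
    miss <- setdiff(ids, names(ref))
    extra <- setdiff(names(ref), ids)
    if (length(miss) || length(extra))
        stop("id mismatch between tree and reference; missing from reference: [",
             paste(miss, collapse = ", "), "], absent from tree: [",
             paste(extra, collapse = ", "), "]")
    as.character(ref[ids])
}

# pair counts over a cross-tabulation: sum over cells of choose(n, 2)
pairSum <- function(counts) sum(choose(counts, 2))

#' Pairs-based confusion counts at one cut threshold
#'
#' Over all unordered sequence pairs: TP pairs share both their reference
#' cluster and their resultant cluster (from [cutTree()] at `threshold`);
#' FP share only the resultant cluster, FN only the reference cluster, TN
#' neither.  Counts always total `n (n - 1) / 2`.
#'
#' @param tree a [ClusterTree-class].
#' @param ref named vector: reference cluster label per id (same id set as
#'   the tree, any order).
#' @param threshold cut height.
#' @return named numeric vector `c(tp, fp, tn, fn)`.
#' @export
confusionAtThreshold <- function(tree, ref, threshold) {
    ids <- sequenceIds(tree)
    refv <- checkReference(ref, ids)
    res <- cutTree(tree, threshold)
    tab <- table(refv, res[ids])
    n <- length(ids)
    total <- choose(n, 2)
    tp <- pairSum(tab)
    sameRef <- pairSum(rowSums(tab))
    sameRes <- pairSum(colSums(tab))
    c(tp = tp, fp = sameRes - tp, tn = total - sameRef - sameRes + tp,
      fn = sameRef - tp)
}

#' ROC curve of a cluster tree against a reference clustering
#'
#' Sweeps the cut threshold over 0 and every distinct merge height (plus a
#' tiny epsilon so the merge is included), computing
#' `tpr = TP / (TP + FN)` and `fpr = FP / (TN + FP)` at each; points are
#' sorted by fpr then tpr and deduplicated.  The singleton end (fpr 0) and
#' the single-cluster end (1, 1) are always present.
#'
#' @inheritParams confusionAtThreshold
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
rocCurve <- function(tree, ref) {
    ids <- sequenceIds(tree)
    refv <- checkReference(ref, ids)
    nref <- table(refv)
    samePairs <- pairSum(nref)
    totPairs <- choose(length(ids), 2)
    if (samePairs == 0)
        stop("degenerate reference: no same-cluster pair, ",
             "true positive rate undefined")
    if (samePairs == totPairs)
        stop("degenerate reference: all ids in one cluster, ",
             "false positive rate undefined")
    thresholds <- c(0, sort(unique(mergeHeights(tree))) + 1e-12)
    pts <- t(vapply(thresholds, function(th) {
        cc <- confusionAtThreshold(tree, ref, th)
        c(fpr = unname(cc["fp"] / (cc["tn"] + cc["fp"])),
          tpr = unname(cc["tp"] / (cc["tp"] + cc["fn"])))
    }, numeric(2)))
    pts <- as.data.frame(pts)
    pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
    pts <- unique(pts)
    rownames(pts) <- NULL
    pts
}

#' Area under an ROC curve
#'
#' Trapezoidal integration over `fpr` in `[0, 1]`; if the last point has
#' `fpr < 1` the curve is completed as a horizontal step to `fpr = 1`.
#'
#' @param points data.frame (or matrix) with columns `fpr`, `tpr`, sorted
#'   by `fpr`, all values in `[0, 1]`.
#' @return AUC in `[0, 1]`.
#' @export
aucFromPoints <- function(points) {
    pts <- as.data.frame(points)
    x <- pts$fpr; y <- pts$tpr
    if (is.null(x) || is.null(y)) stop("points must have fpr and tpr columns")
    if (any(x < 0 | x > 1 | y < 0 | y > 1))
        stop("ROC points outside the unit square")
    if (is.unsorted(x)) stop("ROC points must be sorted by fpr")
    if (utils::tail(x, 1) < 1) { x <- c(x, 1); y <- c(y, utils::tail(y, 1)) }
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' End-to-end clustering evaluation
#'
#' Composes the pipeline deterministically: all-against-all similarity,
#' distance = 1 - similarity, WPGMA tree, pairs-based ROC, AUC.
#'
#' @inheritParams similarityMatrix
#' @param ref named vector of reference cluster labels per sequence id.
#' @return list with `auc`, `roc` (data.frame), `tree`
#'   ([ClusterTree-class]) and `similarity` ([SimilarityMatrix-class]).
#' @export
evaluateRun <- function(seqs, ref, params = kernelParams(),
                        scoring = c("expected", "bpla", "sequence_only"),
                        model = energyModel(), backend = "builtin",
                        threads = 1L) {
    scoring <- match.arg(scoring)
    sim <- similarityMatrix(seqs, params, scoring, model, backend, threads)
    tree <- wpgma(distanceFromSimilarity(sim))
    roc <- rocCurve(tree, ref)
    list(auc = aucFromPoints(roc), roc = roc, tree = tree, similarity = sim)
}
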