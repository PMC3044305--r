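#' RIBOSUM85-60 single-nucleotide substitution matrix
#'
#' The 4x4 single-nucleotide RIBOSUM85-60 log-odds scores (RSEARCH),
#' bundled with the package and used as the default `s(a, b)`.
#'
#' @return symmetric 4x4 numeric matrix with dimnames A C G U.
#' @export
ribosumMatrix <- function() {
    readSubstMatrix(system.file("extdata", "ribosum85_60.mat",
                                package = "bplaClust", mustWork = TRUE))
}

#' Read a substitution matrix file
#'
#' Whitespace-delimited 4x4 matrix with row and column labels A C G U
#' (order free, T accepted for U); must be symmetric.
#'
#' @param path matrix file.
#' @return symmetric 4x4 numeric matrix with dimnames A C G U.
#' @export
readSubstMatrix <- function(path) {
    m <- as.matrix(read.table(path, header = TRUE, row.names = 1,
                              check.names = FALSE))
    rownames(m) <- chartr("Tt", "UU", toupper(rownames(m)))
    colnames(m) <- chartr("Tt", "UU", toupper(colnames(m)))
    if (!setequal(rownames(m), RNA_ALPHABET) ||
        !setequal(colnames(m), RNA_ALPHABET))
        stop("substitution matrix must be labelled with A C G U: ", path)
    m <- m[RNA_ALPHABET, RNA_ALPHABET]
    if (max(abs(m - t(m))) > 0)
        stop("substitution matrix is not symmetric: ", path)
    m
}

#' Match score of two positions under fixed structures
#'
#' For point-mass (0/1) profiles of fixed structures, the score of matching
#' position `i` of `x` with position `j` of `y` is
#' `alpha * (L_x(i) L_y(j) + R_x(i) R_y(j)) + s(x_i, y_j) U_x(i) U_y(j)`:
#' `alpha` when both positions pair downstream, `alpha` when both pair
#' upstream, the substitution score when both are unpaired, 0 otherwise.
#'
#' @param px,py [BasePairProfile-class] objects (0/1 point-mass profiles).
#' @param seqX,seqY the two sequences (character).
#' @param i,j 1-based positions in `x` and `y`.
#' @param params [KernelParams-class].
#' @return a single numeric score.
#' @export
scoreFixed <- function(px, py, seqX, seqY, i, j, params = kernelParams()) {
    if (i < 1 || i > nPositions(px) || j < 1 || j > nPositions(py))
        stop("position out of range")
    S <- scoreExpected(px, py, seqX, seqY, params)
    S[i, j]
}

# shared checks for the position-score builders
checkProfilePair <- function(px, py, seqX, seqY) {
    seqX <- normalizeRna(seqX); seqY <- normalizeRna(seqY)
    if (nchar(seqX) != nPositions(px))
        stop("profile length ", nPositions(px),
             " does not match sequence length ", nchar(seqX))
    if (nchar(seqY) != nPositions(py))
        stop("profile length ", nPositions(py),
             " does not match sequence length ", nchar(seqY))
    list(cx = strsplit(seqX, "")[[1]], cy = strsplit(seqY, "")[[1]])
}

#' Expected match scores over both structure ensembles
#'
#' The position score matrix whose (i, j) entry is the expectation of the
#' fixed-structure score ([scoreFixed()]) over the two independent
#' Boltzmann ensembles:
#' `alpha * (pL_x(i) pL_y(j) + pR_x(i) pR_y(j)) + s(x_i, y_j) pU_x(i) pU_y(j)`.
#'
#' @inheritParams scoreFixed
#' @return numeric |x| x |y| matrix.
#' @export
scoreExpected <- function(px, py, seqX, seqY, params = kernelParams()) {
    ch <- checkProfilePair(px, py, seqX, seqY)
    params@alpha * (leftProb(px) %o% leftProb(py) +
                    rightProb(px) %o% rightProb(py)) +
        params@subst[ch$cx, ch$cy, drop = FALSE] *
            (unpairedProb(px) %o% unpairedProb(py))
}

#' BPLA-variant match scores (square-root weighting)
#'
#' The BPLA kernel scoring: each probability product in the expected score
#' is replaced by its square root,
#' `alpha * (sqrt(pL pL') + sqrt(pR pR')) + s(x_i, y_j) sqrt(pU pU')`,
#' i.e. coefficients `C = (p p')^(-1/2)` applied to the expectation terms.
#' Since `sqrt(p) >= p` on `[0, 1]`, this up-weights low-probability
#' ("unsure") structure relative to [scoreExpected()].
#'
#' @inheritParams scoreFixed
#' @return numeric |x| x |y| matrix.
#' @export
scoreBPLA <- function(px, py, seqX, seqY, params = kernelParams()) {
    ch <- checkProfilePair(px, py, seqX, seqY)
    params@alpha * (sqrt(leftProb(px) %o% leftProb(py)) +
                    sqrt(rightProb(px) %o% rightProb(py))) +
        params@subst[ch$cx, ch$cy, drop = FALSE] *
            sqrt(unpairedProb(px) %o% unpairedProb(py))
}

#' Position score matrix for a chosen scoring scheme
#'
#' @inheritParams scoreFixed
#' @param scoring `"expected"` (ensemble expectation), `"bpla"`
#'   (square-root variant) or `"sequence_only"` (plain substitution scores;
#'   profiles ignored and may be NULL).
#' @return numeric |x| x |y| matrix.
#' @export
positionScores <- function(seqX, seqY, px = NULL, py = NULL,
                           params = kernelParams(),
                           scoring = c("expected", "bpla", "sequence_only")) {
    scoring <- match.arg(scoring)
    if (scoring == "sequence_only") {
        cx <- strsplit(normalizeRna(seqX), "")[[1]]
        cy <- strsplit(normalizeRna(seqY), "")[[1]]
        return(params@subst[cx, cy, drop = FALSE])
    }
    if (is.null(px) || is.null(py))
        stop("scoring '", scoring, "' needs base-pair profiles")
    switch(scoring,
           expected = scoreExpected(px, py, seqX, seqY, params),
           bpla = scoreBPLA(px, py, seqX, seqY, params))
}

#' Local alignment kernel
#'
#' `K(x, y)` sums `exp(beta * Score(pi))` over every local alignment `pi`
#' of the two sequences -- alignments beginning and ending with a match,
#' with affine gap scoring (`gapOpen` for the first, `gapExtend` for each
#' further gapped residue) -- plus 1 for the empty alignment.  Computed by
#' the sum-product variant of the Smith--Waterman recurrences in O(|x||y|)
#' time and in log space.
#'
#' @param seqX,seqY the two sequences (character; lengths must match `S`).
#' @param S position score matrix, e.g. from [positionScores()].
#' @param params [KernelParams-class] (beta and gap scores are used).
#' @param log return `log K` instead of `K` (recommended for long
#'   sequences, where `K` itself overflows double precision).
#' @return `K(x, y) >= 1`, or its logarithm.
#' @examples
#' p <- kernelParams()
#' laKernel("A", "A", matrix(2, 1, 1), p)  # 1 + exp(0.2)
#' @export
laKernel <- function(seqX, seqY, S, params = kernelParams(), log = FALSE) {
    nx <- nchar(normalizeRna(seqX)); ny <- nchar(normalizeRna(seqY))
    if (nx == 0L || ny == 0L) {
        if (!is.null(S) && length(S) > 0L)
            stop("score matrix dimensions do not match sequence lengths")
        return(if (log) 0 else 1)
    }
    S <- as.matrix(S)
    if (nrow(S) != nx || ncol(S) != ny)
        stop("score matrix is ", nrow(S), "x", ncol(S),
             " but sequences have lengths ", nx, " and ", ny)
    lk <- .log_la_kernel(S, params@beta, params@gapOpen, params@gapExtend)
    if (log) lk else exp(lk)
}

#' Normalized log-kernel similarity of two sequences
#'
#' `log K(x, y) / sqrt(log K(x, x) * log K(y, y))`, clipped to `[0, 1]`.
#' Identical sequences score exactly 1.  Profiles are computed on demand
#' under `model` when not supplied (and not at all for
#' `scoring = "sequence_only"`).
#'
#' @inheritParams positionScores
#' @param model [EnergyModel-class] for on-demand folding.
#' @param backend folding backend passed to [foldWithBackend()].
#' @return similarity in `[0, 1]`.
#' @export
normalizedSimilarity <- function(seqX, seqY, px = NULL, py = NULL,
                                 params = kernelParams(),
                                 scoring = c("expected", "bpla", "sequence_only"),
                                 model = energyModel(),
                                 backend = "builtin") {
    scoring <- match.arg(scoring)
    seqX <- normalizeRna(seqX); seqY <- normalizeRna(seqY)
    if (scoring != "sequence_only") {
        if (is.null(px)) px <- foldWithBackend(seqX, backend, model)
        if (is.null(py)) py <- foldWithBackend(seqY, backend, model)
    }
    lxy <- laKernel(seqX, seqY, positionScores(seqX, seqY, px, py, params,
                                               scoring), params, log = TRUE)
    lxx <- laKernel(seqX, seqX, positionScores(seqX, seqX, px, px, params,
                                               scoring), params, log = TRUE)
    lyy <- laKernel(seqY, seqY, positionScores(seqY, seqY, py, py, params,
                                               scoring), params, log = TRUE)
    if (lxx <= 0) stop("degenerate self-kernel (log K(x,x) <= 0) for ", seqX)
    if (lyy <= 0) stop("degenerate self-kernel (log K(y,y) <= 0) for ", seqY)
    min(1, max(0, lxy / sqrt(lxx * lyy)))
}

#' All-against-all similarity matrix
#'
#' Folds every sequence once (unless `scoring = "sequence_only"`), then
#' evaluates the normalized kernel similarity for every unordered pair;
#' each pair is computed once and mirrored, so the result is exactly
#' symmetric with unit diagonal.
#'
#' @param seqs named character vector of RNA sequences (>= 2, unique ids).
#' @inheritParams normalizedSimilarity
#' @param threads number of worker processes for the pairwise loop; cells
#'   are independent, so any thread count yields output identical to
#'   serial execution.
#' @return A [SimilarityMatrix-class].
#' @export
similarityMatrix <- function(seqs, params = kernelParams(),
                             scoring = c("expected", "bpla", "sequence_only"),
                             model = energyModel(), backend = "builtin",
                             threads = 1L) {
    scoring <- match.arg(scoring)
    if (length(seqs) < 2L) stop("need at least two sequences")
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)) ||
        any(!nzchar(names(seqs))))
        stop("sequences must carry unique non-empty ids")
    seqs <- normalizeRna(seqs)
    n <- length(seqs)
    profiles <- if (scoring == "sequence_only") vector("list", n)
                else lapply(seqs, foldWithBackend, backend = backend,
                            model = model)
    selfLog <- vapply(seq_len(n), function(i)
        laKernel(seqs[i], seqs[i],
                 positionScores(seqs[i], seqs[i], profiles[[i]],
                                profiles[[i]], params, scoring),
                 params, log = TRUE), numeric(1))
    bad <- which(selfLog <= 0)
    if (length(bad))
        stop("degenerate self-kernel (log K <= 0) for sequence ",
             names(seqs)[bad[1]])
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    onePair <- function(k) {
        i <- idx[k, 1]; j <- idx[k, 2]
        lxy <- laKernel(seqs[i], seqs[j],
                        positionScores(seqs[i], seqs[j], profiles[[i]],
                                       profiles[[j]], params, scoring),
                        params, log = TRUE)
        min(1, max(0, lxy / sqrt(selfLog[i] * selfLog[j])))
    }
    vals <- if (threads > 1L)
        unlist(parallel::mclapply(seq_len(nrow(idx)), onePair,
                                  mc.cores = threads, mc.preschedule = TRUE))
    else vapply(seq_len(nrow(idx)), onePair, numeric(1))
    m <- diag(1, n)
    m[upper.tri(m)] <- vals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    dimnames(m) <- list(names(seqs), names(seqs))
    new("SimilarityMatrix", values = m, scoring = scoring)
}
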