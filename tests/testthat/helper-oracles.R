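# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's DP code paths: structures are enumerated as filtered
# pair subsets, alignments as explicit chains of matched positions.

RNA4 <- c("A", "C", "G", "U")
CANON6 <- c("AU", "UA", "CG", "GC", "GU", "UG")

randomRna <- function(n) paste(sample(RNA4, n, replace = TRUE), collapse = "")

uniformModel <- function() {
    energyModel(pairScores = structure(rep(0, 6), names = CANON6))
}

# all admissible (pair-type + min-loop) position pairs of a sequence
admissiblePairs <- function(seq, model) {
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    out <- list()
    for (i in seq_len(n)) for (j in seq_len(n))
        if (j - i > model@minLoop &&
            paste0(ch[i], ch[j]) %in% names(model@pairScores))
            out[[length(out) + 1L]] <- c(i, j)
    out
}

# every nested structure as a subset of admissible pairs (exponential scan;
# only for sequences with few admissible pairs)
bruteStructures <- function(seq, model = energyModel()) {
    cand <- admissiblePairs(seq, model)
    res <- list(matrix(integer(), ncol = 2))
    if (!length(cand)) return(res)
    stopifnot(length(cand) <= 18)
    for (mask in seq_len(2^length(cand) - 1)) {
        sel <- which(bitwAnd(mask, 2^(seq_along(cand) - 1)) > 0)
        p <- do.call(rbind, cand[sel])
        if (anyDuplicated(as.vector(p))) next
        ok <- TRUE
        if (nrow(p) > 1) {
            for (a in seq_len(nrow(p) - 1)) {
                for (b in (a + 1):nrow(p)) {
                    i <- p[a, 1]; j <- p[a, 2]; k <- p[b, 1]; l <- p[b, 2]
                    if ((i < k && k < j && j < l) ||
                        (k < i && i < l && l < j)) { ok <- FALSE; break }
                }
                if (!ok) break
            }
        }
        if (ok) res[[length(res) + 1L]] <- p
    }
    res
}

# Boltzmann weight of a pair set, computed from the model definition
oracleWeight <- function(pairs, seq, model) {
    if (!nrow(pairs)) return(1)
    ch <- strsplit(seq, "")[[1]]
    prod(vapply(seq_len(nrow(pairs)), function(k)
        exp(model@pairScores[[paste0(ch[pairs[k, 1]], ch[pairs[k, 2]])]] /
            model@temperatureScale), numeric(1)))
}

# enumeration-based pair probability matrix (uses the package's grammar
# enumerator, which is independent of the inside-outside DP)
enumPairProbs <- function(seq, model = energyModel()) {
    n <- nchar(seq)
    structs <- enumerateStructures(seq, model)
    w <- vapply(structs, function(s) oracleWeight(structurePairs(s), seq,
                                                  model), numeric(1))
    P <- matrix(0, n, n)
    for (k in seq_along(structs)) {
        p <- structurePairs(structs[[k]])
        if (nrow(p)) P[p] <- P[p] + w[k]
    }
    P / sum(w)
}

# fixed-structure position score matrix straight from the definition
fixedScoreMatrix <- function(pairsX, pairsY, seqX, seqY, alpha, subst) {
    cx <- strsplit(seqX, "")[[1]]; cy <- strsplit(seqY, "")[[1]]
    nx <- length(cx); ny <- length(cy)
    Lx <- Rx <- integer(nx); Ly <- Ry <- integer(ny)
    if (nrow(pairsX)) { Lx[pairsX[, 1]] <- 1L; Rx[pairsX[, 2]] <- 1L }
    if (nrow(pairsY)) { Ly[pairsY[, 1]] <- 1L; Ry[pairsY[, 2]] <- 1L }
    Ux <- 1L - Lx - Rx; Uy <- 1L - Ly - Ry
    alpha * (Lx %o% Ly + Rx %o% Ry) + subst[cx, cy, drop = FALSE] * (Ux %o% Uy)
}

# all local alignments as chains of matched (i, j) positions, strictly
# increasing in both coordinates (the empty chain included)
enumChains <- function(n, m) {
    out <- list(matrix(integer(), ncol = 2))
    grow <- function(chain, i0, j0) {
        for (i in seq.int(i0, n)) for (j in seq.int(j0, m)) {
            ch <- rbind(chain, c(i, j))
            out[[length(out) + 1L]] <<- ch
            if (i < n && j < m) grow(ch, i + 1L, j + 1L)
        }
    }
    if (n >= 1 && m >= 1) grow(matrix(integer(), ncol = 2), 1L, 1L)
    out
}

# affine-gap score of one chain: matches plus, between consecutive matches,
# one gap block per sequence with a gap (open g, each extension d)
chainScore <- function(ch, S, g, d) {
    sc <- sum(S[ch])
    if (nrow(ch) > 1) for (k in 2:nrow(ch)) {
        dx <- ch[k, 1] - ch[k - 1, 1] - 1L
        dy <- ch[k, 2] - ch[k - 1, 2] - 1L
        if (dx > 0) sc <- sc + g + (dx - 1) * d
        if (dy > 0) sc <- sc + g + (dy - 1) * d
    }
    sc
}

# brute-force kernel value and optimal local alignment score
bruteKernel <- function(S, beta, g, d) {
    chains <- enumChains(nrow(S), ncol(S))
    sum(vapply(chains, function(ch)
        if (nrow(ch) == 0) 1 else exp(beta * chainScore(ch, S, g, d)),
        numeric(1)))
}
bruteOptimal <- function(S, g, d) {
    chains <- enumChains(nrow(S), ncol(S))
    max(vapply(chains, function(ch)
        if (nrow(ch) == 0) 0 else chainScore(ch, S, g, d), numeric(1)))
}

# confusion counts by explicit double loop over unordered id pairs
naiveConfusion <- function(flat, ref) {
    ids <- names(flat)
    tp <- fp <- tn <- fn <- 0L
    for (a in seq_along(ids)[-length(ids)]) for (b in (a + 1):length(ids)) {
        sameRef <- ref[[ids[a]]] == ref[[ids[b]]]
        sameRes <- flat[[ids[a]]] == flat[[ids[b]]]
        if (sameRef && sameRes) tp <- tp + 1L
        else if (!sameRef && sameRes) fp <- fp + 1L
        else if (!sameRef && !sameRes) tn <- tn + 1L
        else fn <- fn + 1L
    }
    c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# a profile with arbitrary (consistent) marginals, for scoring-variant tests
profileFromMarginals <- function(left, right) {
    n <- length(left)
    new("BasePairProfile", pairProb = matrix(0, n, n),
        leftProb = left, rightProb = right,
        unpairedProb = 1 - left - right)
}

# mean pairwise percent identity of a set of sequences, via global alignment
meanPairwiseIdentity <- function(seqs) {
    n <- length(seqs)
    vals <- c()
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        aln <- Biostrings::pairwiseAlignment(seqs[[a]], seqs[[b]],
                                             type = "global")
        vals <- c(vals, Biostrings::pid(aln) / 100)
    }
    mean(vals)
}
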