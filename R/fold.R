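# 4x4 matrix of log pair weights implied by an EnergyModel (-Inf = disallowed)
logPairWeights <- function(model) {
    lw <- matrix(-Inf, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
    for (pt in names(model@pairScores)) {
        a <- substr(pt, 1, 1); b <- substr(pt, 2, 2)
        lw[a, b] <- model@pairScores[[pt]] / model@temperatureScale
    }
    lw
}

#' Enumerate all nested secondary structures of a short sequence
#'
#' Explicitly realizes the structure ensemble: every pair set that is
#' nested, uses only the model's allowed pair types, and respects the
#' minimal hairpin loop, including the empty structure.  Intended as an
#' exact small-scale companion to [foldPartition()]; refuses sequences
#' longer than `cap`.
#'
#' @param seq RNA sequence (character, normalized on input).
#' @param model an [EnergyModel-class].
#' @param cap maximal sequence length accepted (default 16).
#' @return list of [SecondaryStructure-class] objects, no duplicates.
#' @examples
#' length(enumerateStructures("GAAAC"))  # {} and {(1,5)}
#' @export
enumerateStructures <- function(seq, model = energyModel(), cap = 16L) {
    seq <- normalizeRna(seq)
    n <- nchar(seq)
    if (n > cap)
        stop("sequence length ", n, " exceeds the enumeration cap (", cap,
             "); exhaustive enumeration is only for short sequences -- ",
             "use foldPartition() instead")
    chars <- strsplit(seq, "")[[1]]
    lw <- logPairWeights(model)
    minLoop <- model@minLoop
    memo <- new.env(parent = emptyenv())
    span <- function(i, j) {
        if (i > j) return(list(matrix(integer(), ncol = 2)))
        key <- paste0(i, ",", j)
        hit <- memo[[key]]
        if (!is.null(hit)) return(hit)
        out <- lapply(span(i + 1L, j), identity)  # i unpaired
        ks <- seq.int(i + minLoop + 1L, length.out = max(0L, j - i - minLoop))
        for (k in ks) {
            if (!is.finite(lw[chars[i], chars[k]])) next
            for (inner in span(i + 1L, k - 1L))
                for (rest in span(k + 1L, j))
                    out[[length(out) + 1L]] <-
                        rbind(matrix(c(i, k), ncol = 2), inner, rest)
        }
        memo[[key]] <- out
        out
    }
    lapply(span(1L, n), secondaryStructure, length = n)
}

# Boltzmann weight of a fixed structure under a model (linear scale)
structureWeight <- function(s, seq, model) {
    p <- s@pairs
    if (!nrow(p)) return(1)
    chars <- strsplit(normalizeRna(seq), "")[[1]]
    lw <- logPairWeights(model)
    exp(sum(lw[cbind(chars[p[, 1]], chars[p[, 2]])]))
}

#' Base-pairing probabilities over the full structure ensemble
#'
#' Computes the probability of every base pair (i, j) under the Boltzmann
#' distribution of the log-linear pair-weight model -- the partition
#' function analogue of the McCaskill algorithm for this model -- together
#' with the per-position left/right/unpaired marginals.  Inside--outside
#' recursions run in O(n^3) time and in log space, so long sequences do
#' not overflow.
#'
#' @param seq RNA sequence (character).
#' @param model an [EnergyModel-class].
#' @return A [BasePairProfile-class].
#' @examples
#' pf <- foldPartition("GGGAAAACCC")
#' unpairedProb(pf)
#' @export
foldPartition <- function(seq, model = energyModel()) {
    seq <- normalizeRna(seq)
    n <- nchar(seq)
    if (n < 1L) stop("cannot fold an empty sequence")
    P <- .fold_bppm(encodeRna(seq), logPairWeights(model), model@minLoop)
    newBasePairProfile(P)
}

#' Degenerate profile of one fixed structure
#'
#' The point-mass profile: pair probabilities are the 0/1 indicator of the
#' structure and the marginals are the binary L/R/U pairing-state
#' indicators.
#'
#' @param s a [SecondaryStructure-class].
#' @param length sequence length (defaults to the structure's own).
#' @return A [BasePairProfile-class] with 0/1 entries.
#' @export
profileFromStructure <- function(s, length = nPositions(s)) {
    length <- as.integer(length)
    p <- s@pairs
    if (nrow(p) && (min(p) < 1L || max(p) > length))
        stop("pair index out of range 1..", length)
    P <- matrix(0, length, length)
    if (nrow(p)) P[p] <- 1
    newBasePairProfile(P)
}

#' Fold with a pluggable backend
#'
#' `"builtin"` is [foldPartition()] under the package's log-linear pair
#' model.  `"vienna"` shells out to the RNAfold executable (ViennaRNA) in
#' partition-function mode and parses its base-pair probabilities, giving
#' profiles under the full thermodynamic nearest-neighbor model; the
#' contract (profile invariants) is identical.
#'
#' @param seq RNA sequence.
#' @param backend `"builtin"` or `"vienna"`.
#' @param model [EnergyModel-class] used by the builtin backend.
#' @return A [BasePairProfile-class].
#' @export
foldWithBackend <- function(seq, backend = c("builtin", "vienna"),
                            model = energyModel()) {
    backend <- match.arg(backend)
    if (backend == "builtin") return(foldPartition(seq, model))
    seq <- normalizeRna(seq)
    exe <- Sys.which("RNAfold")
    if (!nzchar(exe))
        stop("backend 'vienna' needs the RNAfold executable on PATH; ",
             "falling back is possible with backend = \"builtin\"")
    n <- nchar(seq)
    dir <- tempfile("vienna")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    owd <- setwd(dir)
    on.exit(setwd(owd), add = TRUE)
    out <- suppressWarnings(system2(exe, c("-p", "--noPS"),
                                    input = c(">bpprof", seq),
                                    stdout = TRUE, stderr = TRUE))
    dp <- file.path(dir, "bpprof_dp.ps")
    if (!file.exists(dp))
        stop("RNAfold did not produce a dot plot (output: ",
             paste(utils::tail(out, 2), collapse = " | "), ")")
    lines <- grep("ubox$", readLines(dp), value = TRUE)
    lines <- grep("^[0-9]", lines, value = TRUE)
    P <- matrix(0, n, n)
    if (length(lines)) {
        f <- do.call(rbind, lapply(strsplit(lines, "\\s+"), function(v)
            as.numeric(v[1:3])))
        P[f[, 1:2, drop = FALSE]] <- f[, 3]^2  # ps stores sqrt(p)
    }
    newBasePairProfile(P)
}

#' Write a profile as TSV
#'
#' Columns: position, left_prob, right_prob, unpaired_prob.  With
#' `pairs = TRUE` a second block of `(i, j, prob)` triples for pair
#' probabilities >= 1e-6 is written to `<path>.pairs.tsv`.
#'
#' @param profile a [BasePairProfile-class].
#' @param path output TSV path.
#' @param pairs also dump the sparse pair-probability list.
#' @return invisibly, the path.
#' @export
writeProfileTSV <- function(profile, path, pairs = FALSE) {
    df <- data.frame(position = seq_len(nPositions(profile)),
                     left_prob = leftProb(profile),
                     right_prob = rightProb(profile),
                     unpaired_prob = unpairedProb(profile))
    writeAtomic(path, function(tmp)
        write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
    if (pairs) {
        pp <- pairProb(profile)
        idx <- which(pp >= 1e-6, arr.ind = TRUE)
        pdf <- data.frame(i = idx[, 1], j = idx[, 2], prob = pp[idx])
        pdf <- pdf[order(pdf$i, pdf$j), , drop = FALSE]
        writeAtomic(paste0(path, ".pairs.tsv"), function(tmp)
            write.table(pdf, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
    }
    invisible(path)
}
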