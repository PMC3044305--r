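# run code under a fixed RNG seed without disturbing the caller's stream;
# seed = NULL uses (and advances) the current stream
withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(seed)
    force(code)
}

# round-half-up (R's round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

#' Fit a dinucleotide (first-order Markov) model to a sequence
#'
#' Transition probabilities proportional to the sliding-window
#' dinucleotide counts with add-one smoothing (so no row is zero);
#' the initial distribution is the mononucleotide frequency.
#'
#' @param seq RNA sequence of length >= 2.
#' @return A [DinucModel-class].
#' @export
fitDinuc <- function(seq) {
    seq <- normalizeRna(seq)
    n <- nchar(seq)
    if (n < 2L) stop("need length >= 2 to count dinucleotides")
    ch <- strsplit(seq, "")[[1]]
    counts <- table(factor(ch[-n], RNA_ALPHABET), factor(ch[-1], RNA_ALPHABET))
    tr <- (unclass(counts) + 1) / (rowSums(counts) + 4)
    init <- as.vector(table(factor(ch, RNA_ALPHABET))) / n
    names(init) <- RNA_ALPHABET
    dimnames(tr) <- list(RNA_ALPHABET, RNA_ALPHABET)
    new("DinucModel", transition = tr, initial = init)
}

#' Sample a random sequence from a dinucleotide model
#'
#' First residue from the initial distribution, then first-order Markov
#' steps; reproducible under `seed`.
#'
#' @param model a [DinucModel-class].
#' @param length output length (>= 1).
#' @param seed optional integer seed.
#' @return a single RNA sequence string.
#' @export
sampleRandom <- function(model, length, seed = NULL) {
    stopifnot(is(model, "DinucModel"), length >= 1)
    withSeed(seed, {
        out <- character(length)
        out[1] <- sample(RNA_ALPHABET, 1, prob = model@initial)
        for (i in seq_len(length - 1L))
            out[i + 1L] <- sample(RNA_ALPHABET, 1,
                                  prob = model@transition[out[i], ])
        paste(out, collapse = "")
    })
}

#' Exact dinucleotide-preserving shuffle
#'
#' Altschul--Erikson shuffle: returns a random sequence with exactly the
#' same dinucleotide counts (hence the same length, mononucleotide counts,
#' and first/last residue) as the input.
#'
#' @param seq RNA sequence of length >= 2.
#' @param seed optional integer seed.
#' @return shuffled sequence string.
#' @export
dinucShuffle <- function(seq, seed = NULL) {
    seq <- normalizeRna(seq)
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    if (n < 2L) stop("need length >= 2 to shuffle dinucleotides")
    withSeed(seed, {
        verts <- unique(ch)
        last <- ch[n]
        # out-edge lists of the dinucleotide multigraph
        edges <- lapply(verts, function(v) ch[which(ch[-n] == v) + 1L])
        names(edges) <- verts
        repeat {
            # pick a random last-exit edge for every vertex except `last`,
            # accept when the chosen edges form an arborescence toward `last`
            lastEdge <- vapply(verts, function(v) {
                if (v == last || !length(edges[[v]])) NA_character_
                else sample(edges[[v]], 1)
            }, character(1))
            ok <- TRUE
            for (v in verts) {
                if (v == last) next
                seen <- character()
                w <- v
                while (w != last) {
                    if (w %in% seen || is.na(lastEdge[[w]])) { ok <- FALSE; break }
                    seen <- c(seen, w)
                    w <- lastEdge[[w]]
                }
                if (!ok) break
            }
            if (ok) break
        }
        ordered <- lapply(verts, function(v) {
            e <- edges[[v]]
            if (v == last || !length(e)) return(sample(e))
            # remove one instance of the chosen last edge, shuffle, append it
            drop <- match(lastEdge[[v]], e)
            c(sample(e[-drop]), lastEdge[[v]])
        })
        names(ordered) <- verts
        ptr <- structure(rep(1L, length(verts)), names = verts)
        out <- character(n)
        out[1] <- ch[1]
        for (i in 2:n) {
            v <- out[i - 1L]
            out[i] <- ordered[[v]][ptr[[v]]]
            ptr[[v]] <- ptr[[v]] + 1L
        }
        paste(out, collapse = "")
    })
}

#' Add dinucleotide-matched flanking regions
#'
#' Emulates unknown transcript boundaries: concatenates random sequences
#' to both ends of the input, each of a quarter of its length (round half
#' up) and sampled from the input's own dinucleotide model, so the output
#' has length `n + 2 * round(n / 4)` and contains the original sequence
#' verbatim as its core.
#'
#' @param seq RNA sequence of length >= 4.
#' @param seed optional integer seed.
#' @return flanked sequence string.
#' @export
addFlanks <- function(seq, seed = NULL) {
    seq <- normalizeRna(seq)
    n <- nchar(seq)
    if (n < 4L) stop("need length >= 4 to add quarter-length flanks")
    q <- roundHalfUp(n / 4)
    model <- fitDinuc(seq)
    withSeed(seed, {
        left <- sampleRandom(model, q)
        right <- sampleRandom(model, q)
        paste0(left, seq, right)
    })
}

#' Add unrelated singleton decoy clusters
#'
#' Emulates transcriptional noise: appends `round(k / 4)` false reference
#' clusters (k = number of true clusters), each containing one random
#' sequence matched in length and dinucleotide content to a randomly
#' chosen real member -- by Markov-model sampling (`method = "markov"`) or
#' by exact dinucleotide shuffling (`method = "shuffle"`).
#'
#' @param dataset list with `sequences` (named character) and `reference`
#'   (named character labels, same ids).
#' @param seed optional integer seed.
#' @param method `"markov"` or `"shuffle"`.
#' @return dataset list of the same shape with decoys appended.
#' @export
addUnrelated <- function(dataset, seed = NULL,
                         method = c("markov", "shuffle")) {
    method <- match.arg(method)
    seqs <- dataset$sequences
    ref <- dataset$reference[names(seqs)]
    nTrue <- length(unique(ref))
    if (nTrue < 4L)
        stop("need at least 4 true reference clusters (got ", nTrue,
             ") so that the quarter count of decoys is at least 1")
    nFalse <- roundHalfUp(nTrue / 4)
    withSeed(seed, {
        for (k in seq_len(nFalse)) {
            src <- seqs[[sample(length(seqs), 1)]]
            decoy <- if (method == "markov")
                sampleRandom(fitDinuc(src), nchar(src)) else dinucShuffle(src)
            id <- sprintf("unrelated_%02d", k)
            lab <- sprintf("FALSE%02d", k)
            while (id %in% names(seqs)) id <- paste0(id, "x")
            while (lab %in% ref) lab <- paste0(lab, "x")
            seqs[[id]] <- decoy
            ref[[id]] <- lab
        }
        list(sequences = seqs, reference = ref)
    })
}

# draw a hairpin layout for a family consensus: list of stems
# (stemLen, loopLen) separated by unpaired spacers, covering `length` nt
drawLayout <- function(length) {
    pos <- 1L
    pairs <- matrix(integer(), ncol = 2)
    repeat {
        spacer <- sample(3:8, 1)
        stem <- sample(7:13, 1)
        loop <- sample(4:8, 1)
        need <- spacer + 2L * stem + loop
        if (pos + need - 1L > length - 3L) break
        start <- pos + spacer
        for (s in seq_len(stem))
            pairs <- rbind(pairs, c(start + s - 1L,
                                    start + 2L * stem + loop - s))
        pos <- start + 2L * stem + loop
    }
    pairs
}

PAIR_TYPE_PROBS <- c(AU = 0.20, UA = 0.20, CG = 0.25, GC = 0.25,
                     GU = 0.05, UG = 0.05)

#' Simulate one structured RNA family
#'
#' Draws an ancestor with an embedded multi-hairpin consensus structure
#' (paired positions filled with canonical/wobble pairs, GC-biased), then
#' derives each member by independent mutation at rate
#' `1 - targetIdentity`: paired positions receive compensatory double
#' substitutions (the pair is redrawn from the six canonical/wobble
#' types), unpaired positions free substitutions, and unpaired runs may
#' absorb rare single-nucleotide indels.
#'
#' @param nMembers number of member sequences (>= 2).
#' @param length ancestor length.
#' @param targetIdentity aimed-for pairwise identity, in `[0.2, 0.99]`.
#' @param seed optional integer seed.
#' @param indelProb per unpaired-run probability of one indel.
#' @return A [SyntheticFamily-class].
#' @export
makeFamily <- function(nMembers, length, targetIdentity, seed = NULL,
                       indelProb = 0.15) {
    if (nMembers < 2L) stop("nMembers must be >= 2")
    if (targetIdentity < 0.2 || targetIdentity > 0.99)
        stop("targetIdentity must be in [0.2, 0.99]")
    if (length < 30L) stop("family length must be >= 30")
    mu <- 1 - targetIdentity
    withSeed(seed, {
        pairs <- drawLayout(length)
        paired <- sort(as.vector(pairs))
        unpaired <- setdiff(seq_len(length), paired)
        anc <- character(length)
        anc[unpaired] <- sample(RNA_ALPHABET, base::length(unpaired),
                                replace = TRUE)
        types <- sample(names(PAIR_TYPE_PROBS), nrow(pairs), replace = TRUE,
                        prob = PAIR_TYPE_PROBS)
        anc[pairs[, 1]] <- substr(types, 1, 1)
        anc[pairs[, 2]] <- substr(types, 2, 2)

        members <- character(nMembers)
        maps <- vector("list", nMembers)
        for (m in seq_len(nMembers)) {
            ch <- anc
            # compensatory substitution at pairs
            for (p in seq_len(nrow(pairs))) {
                if (runif(1) >= mu) next
                cur <- paste0(ch[pairs[p, 1]], ch[pairs[p, 2]])
                alt <- setdiff(names(PAIR_TYPE_PROBS), cur)
                nt <- sample(alt, 1, prob = PAIR_TYPE_PROBS[alt])
                ch[pairs[p, 1]] <- substr(nt, 1, 1)
                ch[pairs[p, 2]] <- substr(nt, 2, 2)
            }
            # free substitution in loops/spacers
            for (u in unpaired)
                if (runif(1) < mu)
                    ch[u] <- sample(setdiff(RNA_ALPHABET, ch[u]), 1)
            # rare single-nt indels within unpaired runs
            pieces <- as.list(ch)           # per-ancestor-position strings
            runs <- split(unpaired, cumsum(c(1, diff(unpaired) != 1)))
            for (r in runs) {
                if (runif(1) >= indelProb) next
                at <- r[sample(base::length(r), 1)]
                if (runif(1) < 0.5) {
                    pieces[[at]] <- paste0(pieces[[at]],
                                           sample(RNA_ALPHABET, 1))
                } else {
                    pieces[[at]] <- ""
                }
            }
            lens <- nchar(unlist(pieces))
            ends <- cumsum(lens)
            map <- ifelse(lens == 0L, NA_integer_, ends - lens + 1L)
            members[m] <- paste(unlist(pieces), collapse = "")
            maps[[m]] <- as.integer(map)
        }
        names(members) <- sprintf("S%02d", seq_len(nMembers))
        new("SyntheticFamily", members = members, referenceLabel = "FAM",
            targetIdentity = targetIdentity,
            consensusStructure = secondaryStructure(pairs, length),
            ancestor = paste(anc, collapse = ""), memberMaps = maps)
    })
}

#' Fraction of consensus pairs kept canonical in each member
#'
#' For every member, the proportion of consensus base pairs whose two
#' positions survive (no deletion) and still form a canonical/wobble pair.
#'
#' @param family a [SyntheticFamily-class].
#' @return numeric vector, one value per member.
#' @export
familyPairFidelity <- function(family) {
    pairs <- structurePairs(family@consensusStructure)
    vapply(seq_along(family@members), function(m) {
        ch <- strsplit(family@members[[m]], "")[[1]]
        map <- family@memberMaps[[m]]
        ok <- 0L
        for (p in seq_len(nrow(pairs))) {
            mi <- map[pairs[p, 1]]; mj <- map[pairs[p, 2]]
            if (!is.na(mi) && !is.na(mj) &&
                paste0(ch[mi], ch[mj]) %in% CANONICAL_PAIRS)
                ok <- ok + 1L
        }
        ok / max(1L, nrow(pairs))
    }, numeric(1))
}

#' Build a synthetic clustering benchmark
#'
#' Composes [makeFamily()] per reference cluster, then optionally applies
#' the two dataset perturbations: `"flanks"` adds quarter-length
#' dinucleotide-matched flanking regions to every sequence, `"unrelated"`
#' appends a quarter count of singleton decoy clusters
#' ([addUnrelated()]).  Member ids are `F<family>_S<member>`; reference
#' labels are `F<family>`.
#'
#' @param nFamilies number of true reference clusters.
#' @param membersPerFamily members per cluster.
#' @param length ancestor length per family.
#' @param identityBand length-2 numeric: each family's target identity is
#'   drawn uniformly from this band.
#' @param variant `"normal"`, `"flanks"` or `"unrelated"`.
#' @param seed optional integer seed.
#' @return list with `sequences` (named character), `reference` (named
#'   labels), `families` (list of [SyntheticFamily-class]), `variant` and
#'   `seed`.
#' @export
makeBenchmark <- function(nFamilies = 4L, membersPerFamily = 4L,
                          length = 120L, identityBand = c(0.25, 0.40),
                          variant = c("normal", "flanks", "unrelated"),
                          seed = NULL) {
    variant <- match.arg(variant)
    stopifnot(nFamilies >= 2L, membersPerFamily >= 2L,
              base::length(identityBand) == 2L)
    withSeed(seed, {
        seqs <- character()
        ref <- character()
        fams <- vector("list", nFamilies)
        for (f in seq_len(nFamilies)) {
            tid <- runif(1, identityBand[1], identityBand[2])
            fam <- makeFamily(membersPerFamily, length, tid)
            fam@referenceLabel <- sprintf("F%02d", f)
            ids <- sprintf("F%02d_S%02d", f, seq_len(membersPerFamily))
            mm <- familyMembers(fam)
            names(mm) <- ids
            fam@members <- mm
            fams[[f]] <- fam
            seqs[ids] <- mm
            ref[ids] <- sprintf("F%02d", f)
        }
        out <- list(sequences = seqs, reference = ref, families = fams,
                    variant = variant, seed = seed)
        if (variant == "flanks") {
            out$sequences <- vapply(out$sequences, addFlanks, character(1))
        } else if (variant == "unrelated") {
            aug <- addUnrelated(list(sequences = out$sequences,
                                     reference = out$reference))
            out$sequences <- unlist(aug$sequences)
            out$reference <- unlist(aug$reference)
        }
        out
    })
}

#' Read reference clusters from aligned FASTA alignments
#'
#' Convenience reader for benchmark collections distributed as one
#' multiple alignment per family (aligned FASTA): every file becomes one
#' reference cluster, gap characters `-` and `.` are stripped from the
#' sequences.
#'
#' @param paths character vector of aligned FASTA files.
#' @param labels cluster labels (default: file base names).
#' @return list with `sequences` and `reference` as in [makeBenchmark()].
#' @export
readAlignedFasta <- function(paths, labels = NULL) {
    if (is.null(labels))
        labels <- sub("\\.[^.]*$", "", basename(paths))
    seqs <- character(); ref <- character()
    for (k in seq_along(paths)) {
        set <- Biostrings::readBStringSet(paths[k])
        raw <- gsub("[-.]", "", as.character(set))
        ids <- sub("\\s.*$", "", names(set))
        raw <- normalizeRna(structure(raw, names = ids))
        seqs[ids] <- raw
        ref[ids] <- labels[k]
    }
    if (anyDuplicated(names(seqs))) stop("duplicate sequence ids across alignments")
    list(sequences = seqs, reference = ref)
}
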