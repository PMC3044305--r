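dinucCounts <- function(seq) {
    ch <- strsplit(seq, "")[[1]]
    n <- length(ch)
    table(factor(paste0(ch[-n], ch[-1]),
                 levels = as.vector(outer(RNA4, RNA4, paste0))))
}

test_that("dinucleotide model fitting matches a sliding-window tally", {
    m <- fitDinuc("ACACACACAC")
    expect_equal(m@transition["A", "C"], 6 / 9)   # (5+1)/(5+4), add-one smoothed
    expect_equal(m@transition["C", "A"], 5 / 8)
    expect_equal(which.max(m@transition["A", ]), c(C = 2L))
    mh <- fitDinuc("AAAA")
    expect_equal(mh@transition["A", "A"], 4 / 7)
    expect_equal(which.max(mh@transition["A", ]), c(A = 1L))
    expect_error(fitDinuc("A"), "length >= 2")

    set.seed(181)
    s <- randomRna(300)
    m <- fitDinuc(s)
    cnt <- dinucCounts(s)
    ch <- strsplit(s, "")[[1]]
    for (a in RNA4) for (b in RNA4) {
        from <- sum(cnt[paste0(a, RNA4)])
        expect_equal(m@transition[a, b],
                     (cnt[[paste0(a, b)]] + 1) / (from + 4))
    }
    expect_equal(unname(m@initial),
                 as.vector(table(factor(ch, RNA4))) / 300)
    expect_equal(rowSums(m@transition), c(A = 1, C = 1, G = 1, U = 1),
                 tolerance = 1e-12)
})

test_that("Markov sampling is seeded, tracks degenerate models, and obeys the LLN", {
    m <- fitDinuc("ACGUACGUGCA")
    expect_identical(sampleRandom(m, 50, seed = 7),
                     sampleRandom(m, 50, seed = 7))
    expect_false(sampleRandom(m, 50, seed = 7) == sampleRandom(m, 50, seed = 8))

    # near-deterministic alternating model leaks only through smoothing
    alt <- fitDinuc(strrep("AC", 250))
    s <- sampleRandom(alt, 1000, seed = 11)
    ch <- strsplit(s, "")[[1]]
    breaks <- sum(ch[-1000] == "A" & ch[-1] != "C") +
        sum(ch[-1000] == "C" & ch[-1] != "A")
    expect_lt(breaks / 999, 0.05)

    # long samples reproduce the source dinucleotide frequencies
    src <- strrep("ACGU", 1000)
    big <- sampleRandom(fitDinuc(src), 10000, seed = 13)
    p <- dinucCounts(src) / sum(dinucCounts(src))
    q <- dinucCounts(big) / sum(dinucCounts(big))
    expect_lt(sum(abs(p - q)) / 2, 0.02)
})

test_that("the exact shuffle preserves dinucleotide counts and endpoints", {
    set.seed(191)
    for (t in 1:10) {
        s <- randomRna(sample(20:120, 1))
        sh <- dinucShuffle(s, seed = t)
        expect_identical(dinucCounts(sh), dinucCounts(s))
        expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
        n <- nchar(s)
        expect_identical(substr(sh, n, n), substr(s, n, n))
    }
    expect_identical(dinucShuffle("ACGGAUCCGAAGGCUA", seed = 3),
                     dinucShuffle("ACGGAUCCGAAGGCUA", seed = 3))
})

test_that("flanking adds quarter-length dinucleotide-matched ends around an intact core", {
    set.seed(201)
    s <- randomRna(100)
    f <- addFlanks(s, seed = 5)
    expect_equal(nchar(f), 150L)
    expect_identical(substr(f, 26, 125), s)        # core at offset round(n/4)
    f2 <- addFlanks(s, seed = 6)
    expect_false(f == f2)
    expect_identical(substr(f2, 26, 125), s)
    # round-half-up of the quarter length
    expect_equal(nchar(addFlanks(randomRna(10), seed = 1)), 10L + 2L * 3L)
    expect_identical(addFlanks(s, seed = 5), addFlanks(s, seed = 5))
})

test_that("unrelated decoys arrive as a quarter count of singleton clusters", {
    mk <- function(nclust) {
        ids <- paste0("s", seq_len(2 * nclust))
        set.seed(3)
        seqs <- structure(vapply(ids, function(i) randomRna(80), character(1)),
                          names = ids)
        list(sequences = seqs,
             reference = structure(rep(paste0("C", seq_len(nclust)), each = 2),
                                   names = ids))
    }
    aug8 <- addUnrelated(mk(8), seed = 31)
    expect_equal(length(aug8$sequences), 18L)       # 16 + round(8/4)
    expect_equal(length(unique(aug8$reference)), 10L)
    newIds <- setdiff(names(aug8$sequences), names(mk(8)$sequences))
    expect_equal(length(newIds), 2L)
    for (id in newIds)
        expect_equal(sum(aug8$reference == aug8$reference[[id]]), 1L)
    expect_false(anyDuplicated(names(aug8$sequences)) > 0)

    aug4 <- addUnrelated(mk(4), seed = 32)
    expect_equal(length(aug4$sequences), 9L)
    expect_equal(nchar(aug4$sequences[[9]]) %in% nchar(aug4$sequences[1:8]),
                 TRUE)                              # length matched to a member

    sh <- addUnrelated(mk(4), seed = 33, method = "shuffle")
    decoy <- sh$sequences[[9]]
    expect_true(any(vapply(sh$sequences[1:8], function(s)
        identical(dinucCounts(s), dinucCounts(decoy)), logical(1))))

    expect_error(addUnrelated(mk(3), seed = 1), "at least 4")
})

test_that("simulated families hit their identity target and keep pairs canonical", {
    fam <- makeFamily(4, 120, 0.95, seed = 41)
    expect_identical(familyMembers(fam),
                     familyMembers(makeFamily(4, 120, 0.95, seed = 41)))
    expect_false(identical(familyMembers(fam),
                           familyMembers(makeFamily(4, 120, 0.95, seed = 42))))

    ids <- vapply(1:20, function(s)
        meanPairwiseIdentity(familyMembers(makeFamily(3, 100, 0.95, seed = s))),
        numeric(1))
    expect_gte(mean(ids), 0.85)

    for (s in 1:20) {
        fam <- makeFamily(3, 100, sample(c(0.3, 0.6, 0.9), 1), seed = s)
        expect_true(all(familyPairFidelity(fam) >= 0.95))
        expect_true(validObject(consensusStructure(fam)))
    }
    expect_error(makeFamily(1, 100, 0.9), "nMembers")
    expect_error(makeFamily(3, 100, 0.1), "targetIdentity")
})

test_that("benchmark composition follows the variant rules", {
    b <- makeBenchmark(4, 4, 120, c(0.25, 0.40), "normal", seed = 51)
    expect_length(b$sequences, 16L)
    expect_equal(length(unique(b$reference)), 4L)
    expect_identical(names(b$sequences), names(b$reference))

    bu <- makeBenchmark(4, 4, 120, c(0.25, 0.40), "unrelated", seed = 51)
    expect_length(bu$sequences, 17L)
    expect_equal(length(unique(bu$reference)), 5L)
    # true-member pair structure untouched: original ids keep their labels
    expect_identical(bu$reference[names(b$reference)], b$reference)

    bf <- makeBenchmark(4, 4, 120, c(0.25, 0.40), "flanks", seed = 51)
    core <- makeBenchmark(4, 4, 120, c(0.25, 0.40), "normal", seed = 51)
    expect_identical(bf$reference, core$reference)
    for (id in names(bf$sequences)) {
        nc <- nchar(core$sequences[[id]])
        expect_equal(nchar(bf$sequences[[id]]), nc + 2 * round(nc / 4 + 1e-9))
        expect_true(grepl(core$sequences[[id]], bf$sequences[[id]],
                          fixed = TRUE))
    }

    expect_identical(makeBenchmark(3, 3, 80, c(0.5, 0.6), "normal", seed = 7),
                     makeBenchmark(3, 3, 80, c(0.5, 0.6), "normal", seed = 7))
})

test_that("aligned-FASTA reference reader strips gaps and labels by file", {
    d <- tempfile(); dir.create(d)
    f1 <- file.path(d, "famA.fa"); f2 <- file.path(d, "famB.fa")
    writeLines(c(">x1", "GG-GAA..ACCC", ">x2", "GGG-AAAC.CC-"), f1)
    writeLines(c(">y1", "AAUU--GGCC"), f2)
    ds <- readAlignedFasta(c(f1, f2))
    expect_equal(ds$sequences[["x1"]], "GGGAAACCC")
    expect_equal(ds$reference[["x2"]], "famA")
    expect_equal(ds$reference[["y1"]], "famB")
})
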