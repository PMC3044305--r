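test_that("fixed-structure match scores cover exactly the three paired/unpaired cases", {
    subst <- matrix(2, 4, 4, dimnames = list(RNA4, RNA4))
    p <- kernelParams(alpha = 1.0, subst = subst)
    # x: (1,5) paired hairpin; y: (2,6) paired
    px <- profileFromStructure(secondaryStructure(matrix(c(1L, 5L), ncol = 2), 5))
    py <- profileFromStructure(secondaryStructure(matrix(c(2L, 6L), ncol = 2), 6))
    x <- "GAAAC"; y <- "AGAAAC"
    expect_equal(scoreFixed(px, py, x, y, 1, 2, p), 1.0)  # both left-paired
    expect_equal(scoreFixed(px, py, x, y, 5, 6, p), 1.0)  # both right-paired
    expect_equal(scoreFixed(px, py, x, y, 1, 3, p), 0)    # left vs unpaired
    expect_equal(scoreFixed(px, py, x, y, 5, 3, p), 0)    # right vs unpaired
    expect_equal(scoreFixed(px, py, x, y, 2, 3, p), 2)    # both unpaired: s(A,A)
    expect_error(scoreFixed(px, py, x, y, 6, 1, p), "out of range")
})

test_that("expected scores follow the marginal-product formula", {
    subst <- matrix(2, 4, 4, dimnames = list(RNA4, RNA4))
    p <- kernelParams(alpha = 1.0, subst = subst)
    px <- profileFromMarginals(left = c(0.5), right = c(0))   # pU = 0.5
    py <- profileFromMarginals(left = c(0.2), right = c(0))   # pU = 0.8
    S <- scoreExpected(px, py, "A", "A", p)
    expect_equal(S[1, 1], 1 * 0.5 * 0.2 + 2 * 0.5 * 0.8)     # 0.9
    # fully unpaired positions degenerate to the substitution score
    ux <- profileFromMarginals(0, 0); uy <- profileFromMarginals(0, 0)
    expect_equal(scoreExpected(ux, uy, "G", "C", kernelParams())[1, 1],
                 ribosumMatrix()["G", "C"])
    expect_error(scoreExpected(px, py, "AA", "A", p), "does not match")
})

test_that("expected scores equal the exhaustive two-ensemble expectation of fixed scores", {
    model <- energyModel(pairScores = c(AU = 1, UA = 1, CG = 1.5, GC = 1.5,
                                        GU = 0.3, UG = 0.3))
    p <- kernelParams()
    set.seed(404)
    for (t in 1:8) {
        x <- randomRna(sample(4:10, 1)); y <- randomRna(sample(4:10, 1))
        sx <- enumerateStructures(x, model); sy <- enumerateStructures(y, model)
        wx <- vapply(sx, function(s) oracleWeight(structurePairs(s), x, model),
                     numeric(1))
        wy <- vapply(sy, function(s) oracleWeight(structurePairs(s), y, model),
                     numeric(1))
        E <- matrix(0, nchar(x), nchar(y))
        for (a in seq_along(sx)) for (b in seq_along(sy))
            E <- E + wx[a] * wy[b] *
                fixedScoreMatrix(structurePairs(sx[[a]]),
                                 structurePairs(sy[[b]]), x, y,
                                 p@alpha, p@subst)
        E <- E / (sum(wx) * sum(wy))
        S <- scoreExpected(foldPartition(x, model), foldPartition(y, model),
                           x, y, p)
        expect_lt(max(abs(S - E)), 1e-9)
    }
})

test_that("BPLA scoring is the square-root variant: equal on point masses, larger otherwise", {
    p <- kernelParams()
    px <- profileFromStructure(secondaryStructure(matrix(c(1L, 5L), ncol = 2), 5))
    x <- "GAAAC"
    expect_equal(scoreBPLA(px, px, x, x, p), scoreExpected(px, px, x, x, p))

    qx <- profileFromMarginals(c(0.25), c(0))
    qy <- profileFromMarginals(c(0.25), c(0))
    zero <- kernelParams(subst = matrix(0, 4, 4, dimnames = list(RNA4, RNA4)))
    expect_equal(scoreBPLA(qx, qy, "A", "A", zero)[1, 1], 0.25)
    expect_equal(scoreExpected(qx, qy, "A", "A", zero)[1, 1], 0.0625)

    u3 <- profileFromMarginals(rep(1 / 3, 4), rep(1 / 3, 4))
    S <- scoreBPLA(u3, u3, "ACGU", "ACGU", zero)
    expect_equal(unname(S), matrix(2 / 3, 4, 4), tolerance = 1e-12)

    # entry-wise dominance for non-negative substitution scores
    pos <- kernelParams(subst = matrix(1, 4, 4, dimnames = list(RNA4, RNA4)))
    set.seed(505)
    for (t in 1:20) {
        n <- sample(2:6, 1); m <- sample(2:6, 1)
        mk <- function(k) {
            l <- runif(k, 0, 0.5); r <- runif(k, 0, 0.5)
            profileFromMarginals(l, r)
        }
        ax <- mk(n); ay <- mk(m)
        x <- randomRna(n); y <- randomRna(m)
        expect_true(all(scoreBPLA(ax, ay, x, y, pos) >=
                        scoreExpected(ax, ay, x, y, pos) - 1e-12))
    }
})

test_that("kernel DP equals the brute-force sum over all local alignments", {
    set.seed(606)
    p <- kernelParams(beta = 0.25, gapOpen = -3, gapExtend = -0.4)
    for (t in 1:40) {
        n <- sample(0:5, 1); m <- sample(1:5, 1)
        S <- matrix(rnorm(n * m, 0, 2), n, m)
        x <- strrep("A", n); y <- strrep("C", m)
        K <- laKernel(x, y, if (n) S else NULL, p)
        Kbf <- if (n == 0) 1 else bruteKernel(S, p@beta, p@gapOpen, p@gapExtend)
        expect_equal(K, Kbf, tolerance = 1e-9)
    }
    expect_equal(laKernel("", "", NULL, p), 1)
    expect_equal(laKernel("A", "A", matrix(2, 1, 1), kernelParams()),
                 1 + exp(0.2), tolerance = 1e-15)
    expect_error(laKernel("AA", "A", matrix(0, 1, 1), p), "dimensions|lengths")
})

test_that("kernel is symmetric under transposing the score matrix", {
    set.seed(707)
    p <- kernelParams(beta = 0.1)
    for (t in 1:10) {
        n <- sample(2:30, 1); m <- sample(2:30, 1)
        S <- matrix(rnorm(n * m), n, m)
        k1 <- laKernel(strrep("A", n), strrep("A", m), S, p, log = TRUE)
        k2 <- laKernel(strrep("A", m), strrep("A", n), t(S), p, log = TRUE)
        expect_equal(k1, k2, tolerance = 1e-12)
    }
})

test_that("at large beta the scaled log kernel approaches the optimal local alignment score", {
    set.seed(808)
    p <- kernelParams(beta = 50, gapOpen = -2, gapExtend = -0.5)
    for (t in 1:15) {
        n <- sample(2:5, 1); m <- sample(2:5, 1)
        S <- matrix(rnorm(n * m, 1, 1), n, m)
        soft <- laKernel(strrep("A", n), strrep("A", m), S, p, log = TRUE) / p@beta
        hard <- max(0, bruteOptimal(S, p@gapOpen, p@gapExtend))
        expect_lt(abs(soft - hard), 0.1)
    }
})

test_that("normalized similarity is 1 on identical sequences and in [0,1) otherwise", {
    x <- "GGGCAAAAGCCC"
    for (sc in c("expected", "bpla", "sequence_only"))
        expect_equal(normalizedSimilarity(x, x, scoring = sc), 1.0)

    set.seed(909)
    a <- randomRna(100); b <- randomRna(100)
    v <- normalizedSimilarity(a, b, scoring = "expected")
    expect_true(v >= 0 && v < 1)
    expect_equal(v, normalizedSimilarity(a, b, scoring = "expected"))  # deterministic
})

test_that("similarity matrices are symmetric, reuse folds, and match pairwise calls", {
    s3 <- c(a = "GGGCAAAAGCCC", b = "GGCAAAAAGCC", c = "AUAUAUUUAAUA")
    sm <- similarityMatrix(s3, scoring = "expected")
    v <- similarityValues(sm)
    expect_identical(v, t(v))
    expect_equal(unname(diag(v)), rep(1, 3))
    for (pair in list(c("a", "b"), c("a", "c"), c("b", "c")))
        expect_equal(v[pair[1], pair[2]],
                     normalizedSimilarity(s3[[pair[1]]], s3[[pair[2]]],
                                          scoring = "expected"),
                     tolerance = 1e-12)

    same <- c(x = "GGGAAAACCC", y = "GGGAAAACCC", z = "GGGAAAACCC")
    expect_equal(unname(similarityValues(similarityMatrix(same))),
                 matrix(1, 3, 3))
    expect_error(similarityMatrix(c(a = "ACGU", a = "ACGU")), "unique")
    expect_equal(similarityValues(similarityMatrix(s3, scoring = "expected",
                                                   threads = 2L)), v)
})

test_that("log-space kernel survives long sequences without overflow", {
    set.seed(111)
    x <- randomRna(500); y <- randomRna(500)
    p <- kernelParams()
    S <- positionScores(x, y, params = p, scoring = "sequence_only")
    lk <- laKernel(x, y, S, p, log = TRUE)
    expect_true(is.finite(lk) && lk > 0)
    v <- normalizedSimilarity(x, y, params = p, scoring = "sequence_only")
    expect_true(v >= 0 && v <= 1)
})

test_that("substitution-matrix IO: bundled RIBOSUM is symmetric and readable", {
    m <- ribosumMatrix()
    expect_identical(m, t(m))
    expect_equal(m["A", "A"], 2.22)
    expect_equal(m["G", "U"], -1.74)
    bad <- tempfile()
    writeLines(c("\tA\tC\tG\tU",
                 "A\t1\t0\t0\t0", "C\t0\t1\t0\t0",
                 "G\t0\t0\t1\t0", "U\t0\t0\t0.5\t1"), bad)
    expect_error(readSubstMatrix(bad), "symmetric")
})
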