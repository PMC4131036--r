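test_that("panel generation is deterministic and byte-identical on disk", {
    specs <- list(genomeSpec("A", 5e3, divergence = 0.03, group = "g",
                             seed = 1L),
                  genomeSpec("B", 5e3, divergence = 0.03, group = "g",
                             seed = 2L, nFraction = 0.05))
    p1 <- generatePanel(specs, ancestorSeed = 9L)
    p2 <- generatePanel(specs, ancestorSeed = 9L)
    f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
    writePanel(p1, f1); writePanel(p2, f2)
    expect_identical(readLines(f1), readLines(f2))

    rs1 <- simulateReads(p1, mixtureSpec(c(A = 50, B = 50), 200, seed = 3L))
    rs2 <- simulateReads(p2, mixtureSpec(c(A = 50, B = 50), 200, seed = 3L))
    q1 <- tempfile(fileext = ".fq"); q2 <- tempfile(fileext = ".fq")
    writeReads(rs1, q1); writeReads(rs2, q2)
    expect_identical(readLines(q1), readLines(q2))
    unlink(c(f1, f2, q1, q2, paste0(c(q1, q2), ".truth.tsv")))
})

test_that("zero divergence reproduces the ancestor exactly", {
    specs <- list(genomeSpec("anc", 2e4, divergence = 0, group = "g",
                             seed = 5L),
                  genomeSpec("mut", 2e4, divergence = 0.1, group = "g",
                             seed = 6L))
    p <- generatePanel(specs, ancestorSeed = 11L)
    a <- charToRaw(as.character(p[["anc"]]))
    m <- charToRaw(as.character(p[["mut"]]))
    d <- mean(a != m)
    ## "anc" is the unmutated ancestor, so the anc-mut difference measures
    ## a single divergence step
    expect_gt(d, 0.09)
    expect_lt(d, 0.11)
})

test_that("pairwise divergence of two mutated copies matches the closed form", {
    ## two independent copies at rate d differ at 2d(1-d) + 2d^2/3 of sites
    specs <- list(genomeSpec("X", 1e6, divergence = 0.05, group = "g",
                             seed = 21L),
                  genomeSpec("Y", 1e6, divergence = 0.05, group = "g",
                             seed = 22L))
    p <- generatePanel(specs, ancestorSeed = 31L)
    d <- mean(charToRaw(as.character(p[["X"]])) !=
              charToRaw(as.character(p[["Y"]])))
    expected <- 2 * 0.05 * 0.95 + 2 * 0.05^2 / 3  # ~0.0967
    expect_lt(abs(d - expected), 0.003)
})

test_that("N masking realizes the requested fraction in contiguous runs", {
    p <- generatePanel(list(genomeSpec("A", 1e5, nFraction = 0.10,
                                       seed = 41L)), 7L)
    nN <- unname(ambiguousCounts(p)[["A"]])
    expect_gte(nN, 9000)
    expect_lte(nN, 11000)
    expect_equal(unname(qualityFactors(p)[["A"]]), (nN + 1e5) / 1e5)
})

test_that("error-free reads are exact substrings of their source strand", {
    p <- generatePanel(list(genomeSpec("A", 1e4, seed = 51L)), 3L)
    rs <- simulateReads(p, mixtureSpec(c(A = 100), 500, errorRate = 0,
                                       seed = 52L))
    g <- as.character(p[["A"]])
    tr <- truth(rs)
    win <- substring(g, tr$position, tr$position + 99L)
    minus <- tr$strand == "-"
    win[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(win[minus])))
    expect_identical(unname(as.character(reads(rs))), unname(win))
    expect_true(any(minus) && any(!minus))  # both strands sampled
})

test_that("reads avoid N regions and match the declared length", {
    p <- generatePanel(list(genomeSpec("A", 5e4, nFraction = 0.2,
                                       seed = 61L)), 13L)
    rs <- simulateReads(p, mixtureSpec(c(A = 100), 1000, errorRate = 0.01,
                                       seed = 62L))
    expect_true(all(Biostrings::width(reads(rs)) == 100L))
    expect_false(any(grepl("N", as.character(reads(rs)), fixed = TRUE)))
    ## source windows themselves are N-free
    g <- as.character(p[["A"]])
    tr <- truth(rs)
    expect_false(any(grepl("N", substring(g, tr$position,
                                          tr$position + 99L), fixed = TRUE)))
})

test_that("empirical error rate matches the binomial model", {
    p <- generatePanel(list(genomeSpec("A", 5e4, seed = 71L)), 17L)
    rs <- simulateReads(p, mixtureSpec(c(A = 100), 12000, errorRate = 0.01,
                                       seed = 72L))
    g <- as.character(p[["A"]])
    tr <- truth(rs)
    win <- substring(g, tr$position, tr$position + 99L)
    minus <- tr$strand == "-"
    win[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(win[minus])))
    mism <- mapply(function(r, w) sum(charToRaw(r) != charToRaw(w)),
                   as.character(reads(rs)), win)
    expect_lt(abs(mean(mism) - 1.0), 0.05)
    ## per-base frequency within 3 binomial standard deviations
    nb <- 12000 * 100
    expect_lt(abs(sum(mism) / nb - 0.01), 3 * sqrt(0.01 * 0.99 / nb))
})

test_that("exact-count allocation reproduces the declared mixture", {
    props <- c(cattle = 3, horse = 25, human = 1, pig = 10, rat = 1,
               sheep = 60)
    expect_identical(AFSeq:::largestRemainder(props, 1e6L),
                     c(cattle = 30000L, horse = 250000L, human = 10000L,
                       pig = 100000L, rat = 10000L, sheep = 600000L))
    ## uneven case: counts still sum to the total
    odd <- c(a = 33.33, b = 33.33, c = 33.34)
    expect_equal(sum(AFSeq:::largestRemainder(odd, 1000L)), 1000L)

    p <- smallPanel()
    rs <- simulateReads(p, mixtureSpec(c(A = 3, B = 25, C = 72), 999,
                                       exactCounts = TRUE, seed = 81L))
    tr <- table(truth(rs)$origin)
    expect_identical(as.integer(tr[c("A", "B", "C")]),
                     as.integer(AFSeq:::largestRemainder(
                         c(A = 3, B = 25, C = 72), 999L)))
})

test_that("paired-end mates respect the insert model and count as two reads", {
    p <- generatePanel(list(genomeSpec("A", 5e4, seed = 91L)), 19L)
    rs <- simulateReads(p, mixtureSpec(c(A = 100), 400, errorRate = 0,
                                       paired = TRUE, insertMean = 300,
                                       insertSd = 30, seed = 92L))
    expect_length(reads(rs), 400L)
    tr <- truth(rs)
    m1 <- tr[grepl("/1$", tr$read_id), ]
    m2 <- tr[grepl("/2$", tr$read_id), ]
    ins <- m2$position + 100L - m1$position
    expect_true(all(ins >= 100L))
    expect_lt(abs(mean(ins) - 300), 15)
})

test_that("mixture and spec validation reject inconsistent inputs", {
    expect_error(mixtureSpec(c(A = 50, B = 49), 100), "sum to 100")
    expect_error(genomeSpec("A", 100, divergence = 0.7), "divergence")
    p <- smallPanel()
    expect_error(simulateReads(p, mixtureSpec(c(Z = 100), 10, seed = 1L)),
                 "not in panel")
    specs <- list(genomeSpec("A", 100, seed = 1L),
                  genomeSpec("A", 100, seed = 2L))
    expect_error(generatePanel(specs), "unique")
})
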