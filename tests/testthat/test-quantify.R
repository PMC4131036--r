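test_that("iterative mapping resolves reads in the first admissible round", {
    panel <- smallPanel(len = 5e3)
    g <- as.character(panel[["A"]])
    set.seed(3)
    reads <- c(clean = substr(g, 101, 200),
               twoerr = plantErrors(substr(g, 1001, 1100), 2L))
    at <- iterativeMap(reads, panel, schedule = 0:3)
    a <- assignments(at)
    expect_equal(a$round[a$read_id == "clean"], 1L)   # k = 0
    expect_equal(at@schedule[a$round[a$read_id == "twoerr"]], 2L)
    expect_identical(as.character(a$genomes[[which(a$read_id == "clean")]]),
                     "A")
    ## a [1]-only schedule leaves the 2-error read unmapped
    at1 <- iterativeMap(reads, panel, schedule = 1L)
    expect_identical(unmappedReads(at1), "twoerr")
    expect_error(iterativeMap(reads, panel, schedule = c(2L, 1L)),
                 "strictly increasing")
    expect_error(iterativeMap(c(a = "ACGT", a = "ACGT"), panel, 0L),
                 "duplicate read ids")
})

test_that("unmapped fraction at one allowed mismatch follows the binomial tail", {
    panel <- smallPanel(len = 5e4, seed = 320)
    rs <- simulateReads(panel, mixtureSpec(c(A = 40, B = 30, C = 30), 20000,
                                           errorRate = 0.01, seed = 21L))
    at <- iterativeMap(rs, panel, schedule = 1L)
    frac <- sum(assignments(at)$status == "unmapped") / 20000
    ## P(>= 2 errors | Bin(100, 0.01)) ~ 0.2642
    expect_lt(abs(frac - 0.2642), 0.01)
    ## conservation: unique + multi + unmapped = total
    expect_equal(sum(statusCounts(at)), 20000L)
})

test_that("multi-read redistribution follows unique proportions and conserves reads", {
    mk <- function(pairs, ids) assignmentFromAlignments(
        data.frame(read_id = pairs$read, genome = pairs$genome,
                   stringsAsFactors = FALSE),
        readIds = ids, panelNames = c("A", "B", "C", "D"))
    ## U = {A: 3, B: 1}; one multi {A,B} -> A + 0.75, B + 0.25
    tab <- mk(list(read = c("u1", "u2", "u3", "u4", "m1", "m1"),
                   genome = c("A", "A", "A", "B", "A", "B")),
              c("u1", "u2", "u3", "u4", "m1"))
    aug <- redistributeMulti(tab)
    expect_equal(aug[["A"]], 3.75)
    expect_equal(aug[["B"]], 1.25)
    expect_equal(sum(aug), 5)
    ## no unique support anywhere in the candidate set -> uniform split
    tab0 <- mk(list(read = c("m1", "m1"), genome = c("C", "D")), "m1")
    expect_message(aug0 <- redistributeMulti(tab0), "no unique support")
    expect_equal(aug0[["C"]], 0.5)
    expect_equal(aug0[["D"]], 0.5)
})

test_that("redistribution conserves reads over random candidate sets", {
    set.seed(17)
    genomes <- c("A", "B", "C", "D")
    nuniq <- 500L; nmulti <- 2000L
    reads <- character(0); gen <- character(0)
    for (i in seq_len(nuniq)) {
        reads <- c(reads, paste0("u", i))
        gen <- c(gen, sample(genomes, 1, prob = c(0.5, 0.3, 0.2, 0)))
    }
    for (i in seq_len(nmulti)) {
        S <- sample(genomes, sample(2:4, 1))
        reads <- c(reads, rep(paste0("m", i), length(S)))
        gen <- c(gen, S)
    }
    tab <- assignmentFromAlignments(
        data.frame(read_id = reads, genome = gen, stringsAsFactors = FALSE),
        panelNames = genomes)
    aug <- suppressMessages(redistributeMulti(tab))
    expect_equal(sum(aug), nuniq + nmulti, tolerance = 1e-12)
})

test_that("quality factor is the closed form f = (n + c)/c", {
    expect_equal(unname(qualityCorrect(
        c(A = 1000), data.frame(genome = "A", c = 1e6, n = 0))), 1000)
    expect_equal(unname(qualityCorrect(
        c(A = 1000), data.frame(genome = "A", c = 1e6, n = 1e5))), 1100)
    expect_error(qualityCorrect(c(Z = 5), data.frame(genome = "A", c = 1,
                                                     n = 0)),
                 "no quality record")
})

test_that("quality correction recovers proportions lost to reference N-masking", {
    ## truth panel: two divergent genomes; reference panel: one of them 10%
    ## N-masked. Reads come from the unmasked truth, so ~10% of that
    ## species' reads cannot map and f = 1.1 compensates.
    truthPanel <- smallPanel(len = 1e5, seed = 510)
    truthPanel <- GenomePanel(truthPanel@sequences[c("A", "B")])
    refPanel <- maskGenome(truthPanel, "B", 0.10, seed = 511L)
    rs <- simulateReads(truthPanel, mixtureSpec(c(A = 50, B = 50), 20000,
                                                errorRate = 0.01,
                                                seed = 512L))
    qOff <- quantifySample(rs, refPanel,
                           quantConfig(schedule = 1L,
                                       applyQualityFactor = FALSE))
    qOn <- quantifySample(rs, refPanel,
                          quantConfig(schedule = 1L,
                                      applyQualityFactor = TRUE))
    pOff <- with(reportTable(qOff$report),
                 proportion[species == "B"])
    pOn <- with(reportTable(qOn$report),
                proportion[species == "B"])
    expect_lt(pOff, 48.5)   # uncorrected: ~47.4 %
    expect_gt(pOff, 45.5)
    expect_lt(abs(pOn - 50), 1)
    expect_gt(rawTotalPercent(qOn$report), 100)
    expect_equal(rawTotalPercent(qOff$report), 100)
})

test_that("proportion report arithmetic and degenerate cases", {
    r <- proportionReport(c(A = 600, B = 400))
    expect_equal(reportTable(r)$proportion, c(60, 40))
    expect_equal(sum(reportTable(r)$proportion), 100, tolerance = 1e-6)
    r1 <- proportionReport(c(solo = 123))
    expect_equal(reportTable(r1)$proportion, 100)
    expect_error(proportionReport(c(A = 0, B = 0)), "zero")
    ## target = 0 (decoy rows): relative difference is NA, shown as n.a.
    r2 <- proportionReport(c(A = 990, decoy = 10),
                           targets = c(A = 100, decoy = 0))
    tab <- reportTable(r2)
    expect_true(is.na(tab$difference_rel[tab$species == "decoy"]))
    expect_equal(tab$difference_abs[tab$species == "decoy"], 1)
    expect_output(show(r2), "n\\.a\\.")
    ## declared species missing from the panel gets a zero row
    r3 <- proportionReport(c(A = 100), targets = c(A = 94.11, Ecoli = 5.89))
    tab3 <- reportTable(r3)
    expect_equal(tab3$proportion[tab3$species == "Ecoli"], 0)
    expect_equal(tab3$difference_abs[tab3$species == "Ecoli"], 5.89)
})

test_that("unique-read accuracy is scored against the ground truth", {
    ids <- sprintf("r%03d", 1:1000)
    tab <- assignmentFromAlignments(
        data.frame(read_id = ids,
                   genome = c(rep("A", 999), "B"),
                   stringsAsFactors = FALSE),
        readIds = ids, panelNames = c("A", "B"))
    tr <- data.frame(read_id = ids, origin = "A", genome = "A",
                     position = 1L, strand = "+")
    acc <- accuracyFromTruth(tab, tr)
    expect_equal(acc$overall, 99.9)
    expect_equal(unname(acc$perSpecies[["A"]]), 99.9)
    expect_error(accuracyFromTruth(tab, data.frame()), "no ground-truth")
})

test_that("saturation deviations shrink with subsample size", {
    panel <- smallPanel(len = 5e4, seed = 610)
    tg <- c(A = 60, B = 30, C = 10)
    rs <- simulateReads(panel, mixtureSpec(tg, 20000, errorRate = 0.01,
                                           seed = 611L))
    sat <- saturationCurve(rs, panel, quantConfig(schedule = 1L),
                           sizes = c(1000L, 20000L), targets = tg,
                           replicates = 5L, seed = 612L)
    expect_true(sat$mean_deviation[2] <= sat$mean_deviation[1])
    ## the full-pool subsample equals the plain full run exactly
    full <- quantifySample(rs, panel, quantConfig(schedule = 1L),
                           targets = tg)
    dev <- sum(reportTable(full$report)$difference_abs)
    expect_equal(attr(sat, "replicates")[2, ], rep(dev, 5),
                 tolerance = 1e-9)
    expect_error(saturationCurve(rs, panel, quantConfig(schedule = 1L),
                                 sizes = 30000L, targets = tg),
                 "exceeds the read pool")
})
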