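test_that("both taxonomy dialects parse to the same tree", {
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("1\t1\troot\troot",
                 "2\t1\tkingdom\tAnimalia",
                 "3\t2\tspecies\tcattle"), tsv)
    t1 <- readTaxonomy(tsv)
    nodes <- tempfile(); nms <- tempfile()
    writeLines(c("1\t|\t1\t|\troot\t|",
                 "2\t|\t1\t|\tkingdom\t|",
                 "3\t|\t2\t|\tspecies\t|"), nodes)
    writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
                 "2\t|\tAnimalia\t|\t\t|\tscientific name\t|",
                 "2\t|\tanimals\t|\t\t|\tcommon name\t|",
                 "3\t|\tcattle\t|\t\t|\tscientific name\t|"), nms)
    t2 <- readTaxonomy(nodes, nms)
    expect_identical(t1@id, t2@id)
    expect_identical(t1@parent, t2@parent)
    expect_identical(t1@name, t2@name)
    expect_equal(t1@root, 1L)
    ## rootless / cyclic inputs are rejected
    expect_error(Taxonomy(1:2, c(2L, 1L), c("a", "b"), c("a", "b")),
                 "root")
    unlink(c(tsv, nodes, nms))
})

test_that("LCA is idempotent, commutative and climbs across kingdoms", {
    tax <- tinyTaxonomy()
    expect_equal(lcaTaxa(tax, 11L), 11L)            # single taxon: itself
    expect_equal(lcaTaxa(tax, c(11L, 11L)), 11L)
    expect_equal(lcaTaxa(tax, c(11L, 12L)), 10L)    # sister species: family
    expect_equal(lcaTaxa(tax, c(12L, 11L)), 10L)
    expect_equal(lcaTaxa(tax, c(11L, 21L)), 2L)     # cross-family: kingdom
    expect_equal(lcaTaxa(tax, c(11L, 31L)), 1L)     # cross-kingdom: root
    ## associativity over hit sets
    expect_equal(lcaTaxa(tax, c(lcaTaxa(tax, c(11L, 12L)), 21L)),
                 lcaTaxa(tax, c(11L, 12L, 21L)))
    ## unknown ids are dropped with a note; nothing left -> NA
    expect_message(r <- lcaTaxa(tax, c(11L, 999L)), "absent")
    expect_equal(r, 11L)
    expect_message(r2 <- lcaTaxa(tax, 999L), "absent")
    expect_true(is.na(r2))
})

test_that("tabular parsing keeps the best three hits with deterministic ties", {
    m8 <- tempfile(fileext = ".m8")
    df <- data.frame(q = "r1", s = paste0("s", 1:5), bits = c(200, 190, 180,
                                                              180, 170))
    writeM8(df, m8)
    map <- stats::setNames(11:15, paste0("s", 1:5))
    hits <- parseM8(m8, map, maxHitsPerRead = 3L)
    expect_equal(nrow(hits), 3L)
    expect_identical(hits$subject, c("s1", "s2", "s3"))  # s3 < s4 at 180
    ## unmapped subjects are dropped with a note
    expect_message(h2 <- parseM8(m8, map[1:2], maxHitsPerRead = 3L),
                   "unmapped subject")
    expect_equal(nrow(h2), 2L)
    ## malformed record reports its line number; empty file yields no hits
    writeLines(c("r1\ts1\t99\t100\t1\t0\t1\t100\t1\t100\t1e-10\t200",
                 "r2\ts1\t99"), m8)
    expect_error(parseM8(m8, map), "line 2")
    file.create(m8)
    expect_equal(nrow(parseM8(m8, map)), 0L)
    unlink(m8)
})

test_that("trinucleotide-entropy complexity separates repeats from random", {
    expect_equal(readComplexity(strrep("A", 100)), 0)
    expect_equal(readComplexity(strrep("AC", 50)), 1 / log2(64),
                 tolerance = 1e-12)
    set.seed(5)
    rnd <- vapply(1:1000, function(i)
        paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
        character(1))
    expect_gt(mean(readComplexity(rnd)), 0.9)
    expect_error(readComplexity("AC"), "at least 3")
})

test_that("filtered LCA assignment applies score, top-percent and complexity rules", {
    tax <- tinyTaxonomy()
    mk <- function(q, s, bits) data.frame(
        read_id = q, subject = s, pident = 99, length = 100L,
        mismatches = 1L, gapopen = 0L, qstart = 1L, qend = 100L,
        sstart = 1L, send = 100L, evalue = 1e-20, bitscore = bits,
        taxon = c(cattle = 11L, sheep = 12L, pig = 21L, Ecoli = 31L)[s],
        stringsAsFactors = FALSE)
    ## hits to two sister species -> their family
    h <- mk(c("r1", "r1"), c("cattle", "sheep"), c(200, 200))
    a <- assignReads(h, reads = NULL, taxonomy = tax)
    expect_equal(a$taxon[a$read_id == "r1"], 10L)
    ## a hit below min score is unusable
    h2 <- mk("r2", "cattle", 74.9)
    a2 <- assignReads(h2, reads = NULL, taxonomy = tax)
    expect_identical(a2$category, "unassigned")
    ## top-percent 1.0: second hit at 197 vs best 200 misses the 198 cutoff
    h3 <- mk(c("r3", "r3"), c("cattle", "pig"), c(200, 197))
    a3 <- assignReads(h3, reads = NULL, taxonomy = tax)
    expect_equal(a3$taxon, 11L)
    ## ... but at 198.5 it survives and forces the LCA up to the kingdom
    h4 <- mk(c("r4", "r4"), c("cattle", "pig"), c(200, 198.5))
    a4 <- assignReads(h4, reads = NULL, taxonomy = tax)
    expect_equal(a4$taxon, 2L)
    ## low-complexity reads are set aside before any hit is considered
    rl <- c(r5 = strrep("AT", 50), r6 = paste(rep(c("ACGT", "TGCA", "GGAC",
                                                    "CTTG", "ACCA"), 5),
                                              collapse = ""))
    h5 <- mk(c("r5", "r6"), c("cattle", "cattle"), c(200, 200))
    a5 <- assignReads(h5, reads = rl, taxonomy = tax)
    expect_identical(a5$category[a5$read_id == "r5"], "low_complexity")
    expect_identical(a5$category[a5$read_id == "r6"], "assigned")
    ## conservation: every input read lands in exactly one category
    expect_setequal(a5$read_id, c("r5", "r6"))
})

test_that("minimum-support folding conserves reads and flags promotions", {
    tax <- tinyTaxonomy()
    assigned <- data.frame(
        read_id = sprintf("r%04d", 1:1200),
        category = "assigned",
        taxon = c(rep(31L, 700), rep(11L, 400), rep(12L, 50), rep(21L, 50)),
        stringsAsFactors = FALSE)
    assigned$category[1:30] <- "unassigned"
    assigned$taxon[1:30] <- NA_integer_
    s <- summarizeTaxa(assigned, tax,
                       lcaParams(minSupport = 50L, promoteThreshold = 500L))
    cnt <- taxonCounts(s)
    ## exactly 50 reads ("more than 50" is strict) fold into the parent,
    ## recursively until a supported ancestor: both 50-read species climb
    ## to the kingdom (their families only accumulate 50 as well)
    expect_false(any(c(12L, 21L, 10L, 20L) %in% cnt$taxon_id))
    expect_equal(cnt$reads[cnt$taxon_id == 2L], 100L)
    expect_equal(cnt$reads[cnt$taxon_id == 11L], 400L)
    expect_equal(cnt$reads[cnt$taxon_id == 31L], 670L)
    ## folding loses no reads
    expect_equal(sum(cnt$reads) + s@unassigned + s@lowComplexity, 1200L)
    ## only the strongly supported unexpected taxon is recommended
    expect_identical(promotions(s), "Ecoli")
    ## discard mode drops under-supported taxa instead
    s2 <- summarizeTaxa(assigned, tax,
                        lcaParams(minSupport = 50L, foldMode = "discard"))
    expect_equal(sum(taxonCounts(s2)$reads), 670L + 400L)
})

test_that("synthetic hit fixtures follow the 12-column contract", {
    tax <- tinyTaxonomy()
    panel <- smallPanel(len = 2e3)
    rs <- simulateReads(panel, mixtureSpec(c(A = 50, B = 50), 100,
                                           errorRate = 0, seed = 33L))
    m8 <- tempfile(fileext = ".m8")
    ## noise off: one hit per read, to the true leaf, bitscore 200
    fx <- makeM8Fixture(rs, tax, c(A = 11L, B = 21L), m8, confounders = 0L,
                        seed = 5L)
    lines <- readLines(m8)
    expect_length(lines, 100L)
    expect_true(all(lengths(strsplit(lines, "\t")) == 12L))
    hits <- parseM8(m8, fx$subjectMap)
    expect_equal(unname(
        hits$taxon[match(truth(rs)$read_id, hits$read_id)]),
        unname(c(A = 11L, B = 21L)[truth(rs)$origin]))
    expect_true(all(hits$bitscore == 200))
    ## with 2 confounders: 3 records per read; confounders at 90% of the
    ## best score are discarded by the top-percent filter downstream
    fx2 <- makeM8Fixture(rs, tax, c(A = 11L, B = 21L), m8, confounders = 2L,
                         seed = 6L)
    expect_length(readLines(m8), 300L)
    hits2 <- parseM8(m8, fx2$subjectMap)
    a <- assignReads(hits2, reads = rs, taxonomy = tax)
    expect_true(all(a$category == "assigned"))
    expect_equal(unname(a$taxon[match(truth(rs)$read_id, a$read_id)]),
                 unname(c(A = 11L, B = 21L)[truth(rs)$origin]))
    expect_error(makeM8Fixture(rs, tax, c(A = 11L), m8), "not mapped")
    unlink(c(m8, paste0(m8, ".taxmap.tsv")))
})
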