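#' Quantification strategy configuration
#'
#' The two standard strategies differ only in their mismatch schedule:
#' `"quant"` (best quantification) maps iteratively at allowances 0, 1, 2, 3
#' -- each round remaps only the reads left unmapped by the previous one --
#' while `"spec"` (best specificity) performs a single round at 0 mismatches.
#' A custom strictly increasing schedule may be supplied instead.
#'
#' @param strategy `"quant"` or `"spec"`.
#' @param schedule Optional integer vector of mismatch allowances overriding
#'   the strategy default; must be strictly increasing.
#' @param applyQualityFactor Multiply final counts by the per-genome quality
#'   factor \eqn{f = (n + c)/c}.
#' @param sizeNormalize Additionally divide counts by genome length
#'   (off by default; read counts from total DNA already scale with genome
#'   representation in the sample, and empirically tissue packing largely
#'   compensates genome-size differences).
#' @return A `list` with class `"QuantConfig"`.
#' @examples
#' quantConfig("spec")
#' quantConfig(schedule = c(1L))
#' @export
quantConfig <- function(strategy = c("quant", "spec"), schedule = NULL,
                        applyQualityFactor = TRUE, sizeNormalize = FALSE) {
    if (is.null(schedule)) {
        strategy <- match.arg(strategy)
        schedule <- if (strategy == "quant") 0:3 else 0L
    } else {
        strategy <- if (!missing(strategy)) match.arg(strategy) else "custom"
    }
    schedule <- as.integer(schedule)
    if (length(schedule) == 0L || any(diff(schedule) <= 0L))
        stop("mismatch schedule must be non-empty and strictly increasing")
    structure(list(strategy = strategy, schedule = schedule,
                   applyQualityFactor = applyQualityFactor,
                   sizeNormalize = sizeNormalize),
              class = "QuantConfig")
}

#' Iterative multi-round read mapping
#'
#' Round `j` maps, at mismatch allowance `schedule[j]`, only the reads that
#' every earlier round left unmapped. Each mapped read is classified by the
#' set of genomes it hit in its resolving round: `unique` (one genome),
#' `multi` (two or more); reads unmapped after the last round stay
#' `unmapped` and feed the metagenomic stage.
#'
#' @param reads A [TaggedReadSet-class], `DNAStringSet` or named character
#'   vector with unique ids.
#' @param panel A [GenomePanel-class] (ignored when `index` is given).
#' @param schedule Strictly increasing integer mismatch allowances.
#' @param index Optional prebuilt [SeedIndex-class] over `panel`.
#' @param seedLength Seed length for index construction; `NULL` picks the
#'   largest pigeonhole-safe value up to 20 for the shortest read.
#' @return An [AssignmentTable-class].
#' @examples
#' panel <- generatePanel(list(genomeSpec("A", 5000, seed = 1)), 2)
#' rs <- simulateReads(panel, mixtureSpec(c(A = 100), 100, errorRate = 0,
#'                                        seed = 3))
#' statusCounts(iterativeMap(rs, panel, schedule = 0L))
#' @export
iterativeMap <- function(reads, panel, schedule = 0:3, index = NULL,
                         seedLength = NULL) {
    rv <- .readVector(reads)
    schedule <- as.integer(schedule)
    if (length(schedule) == 0L || any(diff(schedule) <= 0L))
        stop("mismatch schedule must be non-empty and strictly increasing")
    n <- length(rv)
    kmax <- max(schedule)
    if (is.null(index)) {
        minL <- if (n) min(nchar(rv)) else 100L
        if (is.null(seedLength))
            seedLength <- max(10L, min(20L, minL %/% (kmax + 1L)))
        index <- buildIndex(panel, seedLength, maxMismatch = kmax,
                            readLength = max(seedLength * (kmax + 1L), minL))
    }
    G <- length(index@panelNames)
    allRead <- integer(0)
    allGenome <- integer(0)
    roundIdx <- rep(NA_integer_, n)
    active <- seq_len(n)
    nshort <- 0L
    for (j in seq_along(schedule)) {
        if (length(active) == 0L)
            break
        res <- afs_map_reads(index@ptr, unname(rv[active]), schedule[j])
        nshort <- max(nshort, length(res$too_short))
        if (length(res$read) == 0L)
            next
        glob <- active[res$read]
        keep <- !duplicated(as.double(glob) * (G + 1) + res$genome)
        allRead <- c(allRead, glob[keep])
        allGenome <- c(allGenome, res$genome[keep])
        mappedLocal <- unique(res$read)
        roundIdx[active[mappedLocal]] <- j
        active <- active[-mappedLocal]
    }
    if (nshort > 0L)
        warning(nshort, " read(s) shorter than the pigeonhole minimum ",
                "were reported unmapped")
    o <- order(allRead)
    widths <- tabulate(allRead, nbins = n)
    genomes <- IRanges::relist(
        index@panelNames[allGenome[o]],
        IRanges::PartitioningByWidth(widths))
    status <- ifelse(widths == 0L, "unmapped",
                     ifelse(widths == 1L, "unique", "multi"))
    new("AssignmentTable",
        assignments = DataFrame(read_id = names(rv), status = status,
                                round = roundIdx, genomes = genomes),
        schedule = schedule, panelNames = index@panelNames)
}

#' Build an assignment table from externally produced alignments
#'
#' Lets SAM files from an external mapper (see [readSam()]) enter the
#' quantification stage. All alignments are treated as one mapping round.
#'
#' @param alignments `data.frame` with columns `read_id` and `genome`.
#' @param readIds Character vector of all read ids in the run (mapped or
#'   not); defaults to the reads present in `alignments`.
#' @param panelNames Names of all panel genomes.
#' @param schedule The mismatch schedule the alignments were produced under
#'   (bookkeeping only).
#' @return An [AssignmentTable-class].
#' @export
assignmentFromAlignments <- function(alignments, readIds = NULL,
                                     panelNames = NULL, schedule = 0L) {
    if (is.null(readIds))
        readIds <- unique(alignments$read_id)
    if (anyDuplicated(readIds))
        stop("duplicate read ids")
    if (is.null(panelNames))
        panelNames <- sort(unique(alignments$genome))
    pair <- unique(data.frame(read = match(alignments$read_id, readIds),
                              genome = alignments$genome,
                              stringsAsFactors = FALSE))
    if (anyNA(pair$read))
        stop("alignments reference read ids absent from readIds")
    n <- length(readIds)
    o <- order(pair$read)
    widths <- tabulate(pair$read, nbins = n)
    genomes <- IRanges::relist(pair$genome[o],
                               IRanges::PartitioningByWidth(widths))
    status <- ifelse(widths == 0L, "unmapped",
                     ifelse(widths == 1L, "unique", "multi"))
    new("AssignmentTable",
        assignments = DataFrame(read_id = readIds, status = status,
                                round = ifelse(widths == 0L, NA_integer_, 1L),
                                genomes = genomes),
        schedule = as.integer(schedule), panelNames = panelNames)
}

#' Redistribute multi-mapped reads over their candidate genomes
#'
#' Unique reads are counted directly; each multi-mapped read with candidate
#' set S contributes, to every genome g in S, the weight
#' \eqn{U_g / \sum_{h \in S} U_h}, where U are the unique-read counts pooled
#' over all mapping rounds. If no candidate has unique support the read is
#' split uniformly over S (logged). The total augmented count equals
#' unique + multi exactly (conservation).
#'
#' @param x An [AssignmentTable-class].
#' @return Named numeric vector of augmented per-genome counts covering
#'   every panel genome.
#' @examples
#' ## U = {A: 3, B: 1}; one multi read {A, B} -> A 3.75, B 1.25
#' @export
redistributeMulti <- function(x) {
    a <- x@assignments
    gl <- x@panelNames
    uniq <- a$status == "unique"
    U <- table(factor(unlist(a$genomes[uniq]), levels = gl))
    aug <- stats::setNames(as.numeric(U), gl)
    multi <- a$genomes[a$status == "multi"]
    if (length(multi) > 0L) {
        sig <- vapply(as.list(multi), paste, character(1), collapse = "\r")
        tab <- table(sig)
        degenerate <- 0L
        for (s in names(tab)) {
            S <- strsplit(s, "\r", fixed = TRUE)[[1]]
            w <- as.numeric(U[S])
            if (sum(w) == 0) {
                w <- rep(1 / length(S), length(S))
                degenerate <- degenerate + as.integer(tab[[s]])
            } else {
                w <- w / sum(w)
            }
            aug[S] <- aug[S] + tab[[s]] * w
        }
        if (degenerate > 0L)
            message(degenerate, " multi-mapped read(s) had no unique ",
                    "support in their candidate set; split uniformly")
    }
    aug
}

#' Correct counts by the genome quality factor
#'
#' Multiplies each genome's count by \eqn{f = (n + c)/c} (c = total
#' reference length including ambiguous positions, n = ambiguous positions),
#' compensating reads lost to N stretches of draft references.
#'
#' @param counts Named numeric per-genome counts.
#' @param quality A [GenomePanel-class], or a named numeric vector of `f`
#'   values, or a `data.frame` with columns `genome`, `c`, `n`.
#' @return Corrected counts (same names).
#' @examples
#' qualityCorrect(c(A = 1000), data.frame(genome = "A", c = 1e6, n = 1e5))
#' @export
qualityCorrect <- function(counts, quality) {
    f <- if (is(quality, "GenomePanel")) {
        qualityFactors(quality)
    } else if (is.data.frame(quality)) {
        stats::setNames((quality$n + quality$c) / quality$c, quality$genome)
    } else {
        quality
    }
    missing <- setdiff(names(counts), names(f))
    if (length(missing))
        stop("no quality record for genome(s): ",
             paste(missing, collapse = ", "))
    counts * f[names(counts)]
}

#' Species proportions, with optional declared-target comparison
#'
#' Converts corrected per-genome counts into percentages (renormalized to
#' sum to 100); when declared target percentages are supplied, the absolute
#' difference `|proportion - target|` and relative difference
#' `difference_abs / target * 100` are added (relative difference is NA,
#' shown as "n.a.", for a 0% target).
#'
#' @param corrected Named numeric corrected counts (all-zero is an error).
#' @param targets Optional named numeric declared percentages.
#' @param mappedTotal Total mapped reads (unique + multi) used for the raw
#'   (pre-renormalization) total; defaults to `sum(corrected)`.
#' @param strategy Strategy label carried into the report.
#' @return A [ProportionReport-class].
#' @examples
#' proportionReport(c(A = 600, B = 400), targets = c(A = 59, B = 41))
#' @export
proportionReport <- function(corrected, targets = NULL,
                             mappedTotal = sum(corrected), strategy = "") {
    if (sum(corrected) <= 0)
        stop("all counts are zero; nothing to report")
    ## species declared in the targets but absent from the panel counts are
    ## reported with zero counts (their absolute difference is their target)
    absent <- setdiff(names(targets), names(corrected))
    if (length(absent))
        corrected <- c(corrected,
                       stats::setNames(rep(0, length(absent)), absent))
    prop <- corrected / sum(corrected) * 100
    df <- data.frame(species = names(corrected),
                     reads_assigned = unname(corrected),
                     proportion = unname(prop),
                     stringsAsFactors = FALSE)
    if (!is.null(targets)) {
        tg <- stats::setNames(rep(0, length(corrected)), names(corrected))
        tg[intersect(names(targets), names(tg))] <-
            targets[intersect(names(targets), names(tg))]
        df$target <- unname(tg)
        df$difference_abs <- abs(df$proportion - df$target)
        df$difference_rel <- ifelse(df$target > 0,
                                    df$difference_abs / df$target * 100,
                                    NA_real_)
    }
    new("ProportionReport", report = df,
        rawTotalPercent = sum(corrected) / mappedTotal * 100,
        strategy = strategy)
}

#' Mapping accuracy of unique reads against the simulation ground truth
#'
#' Fraction of uniquely mapped reads whose assigned genome equals their true
#' origin species, overall and per species, in percent.
#'
#' @param x An [AssignmentTable-class].
#' @param truth A truth `data.frame` (see [TaggedReadSet-class]) or a
#'   [TaggedReadSet-class].
#' @return A list with `overall` (percent) and `perSpecies` (named percent
#'   vector, by true origin).
#' @export
accuracyFromTruth <- function(x, truth) {
    if (is(truth, "TaggedReadSet"))
        truth <- truth@truth
    if (is.null(truth) || nrow(truth) == 0L)
        stop("reads carry no ground-truth tags")
    a <- x@assignments
    uniq <- a$status == "unique"
    assigned <- unlist(a$genomes[uniq])
    origin <- truth$origin[match(a$read_id[uniq], truth$read_id)]
    if (anyNA(origin))
        stop("ground truth missing for some uniquely mapped reads")
    ok <- assigned == origin
    per <- tapply(ok, origin, mean) * 100
    list(overall = mean(ok) * 100,
         perSpecies = stats::setNames(as.numeric(per), names(per)))
}

#' One-call quantification of a read set against a panel
#'
#' Runs iterative mapping, multi-read redistribution, optional quality
#' correction and proportion calculation under one configuration.
#'
#' @param reads Reads (see [iterativeMap()]).
#' @param panel A [GenomePanel-class].
#' @param config A [quantConfig()].
#' @param targets Optional declared percentages for the difference columns.
#' @param index Optional prebuilt [SeedIndex-class].
#' @return A list with `report` ([ProportionReport-class]), `assignment`
#'   ([AssignmentTable-class]) and `counts` (augmented, post-correction).
#' @export
quantifySample <- function(reads, panel, config = quantConfig(),
                           targets = NULL, index = NULL) {
    stopifnot(inherits(config, "QuantConfig"))
    at <- iterativeMap(reads, panel, schedule = config$schedule,
                       index = index)
    counts <- redistributeMulti(at)
    mappedTotal <- sum(counts)
    if (config$applyQualityFactor)
        counts <- qualityCorrect(counts, panel)
    if (config$sizeNormalize)
        counts <- counts / genomeLengths(panel)[names(counts)]
    rep <- proportionReport(counts, targets = targets,
                            mappedTotal = mappedTotal,
                            strategy = config$strategy)
    list(report = rep, assignment = at, counts = counts)
}

#' Proportion-deviation saturation curve over subsample sizes
#'
#' For each subsample size, draws `replicates` random subsets of the read
#' pool without replacement, runs the full quantification, and records the
#' summed absolute deviation of observed from declared proportions,
#' \eqn{\sum_g |observed_g - expected_g|} (percentage points). Deviations
#' shrink as read numbers grow, locating the read count at which
#' quantification saturates.
#'
#' @param reads Read pool ([TaggedReadSet-class] or named character).
#' @param panel A [GenomePanel-class].
#' @param config A [quantConfig()].
#' @param sizes Integer subsample sizes (each at most the pool size).
#' @param targets Named declared percentages (required).
#' @param replicates Replicates per size.
#' @param seed Integer seed; each replicate draws under a fresh derived
#'   seed.
#' @param index Optional prebuilt [SeedIndex-class].
#' @return A `data.frame` with columns `size`, `mean_deviation`,
#'   `sd_deviation`; per-replicate deviations in attribute `"replicates"`.
#' @export
saturationCurve <- function(reads, panel, config = quantConfig(),
                            sizes, targets, replicates = 3L, seed = 1L,
                            index = NULL) {
    rv <- .readVector(reads)
    n <- length(rv)
    sizes <- as.integer(sizes)
    if (any(sizes > n))
        stop("subsample size exceeds the read pool (", n, ")")
    if (is.null(targets))
        stop("declared targets are required")
    if (is.null(index))
        index <- buildIndex(panel,
                            seedLength = max(10L, min(20L,
                                min(nchar(rv)) %/% (max(config$schedule) + 1L))),
                            maxMismatch = max(config$schedule),
                            readLength = min(nchar(rv)))
    devs <- matrix(NA_real_, nrow = length(sizes), ncol = replicates)
    counter <- 0L
    for (i in seq_along(sizes)) {
        for (r in seq_len(replicates)) {
            counter <- counter + 1L
            sub <- withSeed(childSeed(seed, counter),
                            sample.int(n, sizes[i]))
            q <- quantifySample(rv[sub], panel, config, targets = targets,
                                index = index)
            tab <- reportTable(q$report)
            devs[i, r] <- sum(tab$difference_abs)
        }
    }
    out <- data.frame(size = sizes,
                      mean_deviation = rowMeans(devs),
                      sd_deviation = apply(devs, 1, stats::sd))
    attr(out, "replicates") <- devs
    out
}
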