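#' Describe one synthetic reference genome
#'
#' Parameter bundle for [generatePanel()]. Genomes sharing a `group` label are
#' derived from one common ancestor sequence, each as an independently mutated
#' copy at its own per-site `divergence`; genomes in singleton groups are
#' unrelated random sequences. Two genomes derived from the same ancestor at
#' divergence \eqn{d} each show an expected pairwise difference fraction of
#' \eqn{2d(1-d) + 2d^2/3} (independent substitutions coincide on the same
#' target base a third of the time).
#'
#' @param name Species label (panel genome name).
#' @param length Genome length in bases.
#' @param gc Target GC fraction of the ancestor, in `[0, 1]`.
#' @param divergence Per-site substitution probability against the shared
#'   ancestor, in `[0, 0.5]`.
#' @param nFraction Fraction of positions replaced by runs of N, in `[0, 1)`;
#'   runs have geometric length with mean 1 kb.
#' @param group Ancestor-sharing group label; defaults to `name` (unrelated).
#' @param seed Integer seed for this genome's mutation and masking.
#' @return A `list` with class `"GenomeSpec"`.
#' @examples
#' genomeSpec("cattle", 5e4, divergence = 0.05, group = "mammal", seed = 1)
#' @export
genomeSpec <- function(name, length, gc = 0.42, divergence = 0,
                       nFraction = 0, group = name, seed = 1L) {
    stopifnot(is.character(name), nchar(name) > 0,
              length >= 1, gc >= 0, gc <= 1,
              nFraction >= 0, nFraction < 1)
    if (divergence < 0 || divergence > 0.5)
        stop("divergence must lie in [0, 0.5]")
    structure(list(name = name, length = as.integer(length), gc = gc,
                   divergence = divergence, nFraction = nFraction,
                   group = group, seed = as.integer(seed)),
              class = "GenomeSpec")
}

#' Generate a synthetic reference genome panel
#'
#' One ancestor sequence is generated per `group` of specs; each genome is an
#' independently mutated copy of its group's ancestor at its `divergence`,
#' optionally N-masked to its `nFraction`. Fully deterministic under the
#' given seeds.
#'
#' @param specs A list of [genomeSpec()] objects with unique names.
#' @param ancestorSeed Integer seed for the shared ancestor sequences.
#' @return A [GenomePanel-class].
#' @examples
#' sp <- list(genomeSpec("A", 1e4, divergence = 0.05, group = "g", seed = 1),
#'            genomeSpec("B", 1e4, divergence = 0.05, group = "g", seed = 2))
#' panel <- generatePanel(sp, ancestorSeed = 99)
#' genomeLengths(panel)
#' @export
generatePanel <- function(specs, ancestorSeed = 1L) {
    if (inherits(specs, "GenomeSpec"))
        specs <- list(specs)
    nm <- vapply(specs, `[[`, character(1), "name")
    if (anyDuplicated(nm))
        stop("genome names must be unique")
    groups <- vapply(specs, `[[`, character(1), "group")
    ugroups <- unique(groups)
    ancestors <- vector("list", length(ugroups))
    names(ancestors) <- ugroups
    for (i in seq_along(ugroups)) {
        members <- specs[groups == ugroups[i]]
        len <- max(vapply(members, `[[`, integer(1), "length"))
        gc <- members[[1]]$gc
        ancestors[[i]] <- withSeed(childSeed(ancestorSeed, i),
                                   randomDnaRaw(len, gc))
    }
    seqs <- character(length(specs))
    for (i in seq_along(specs)) {
        sp <- specs[[i]]
        g <- ancestors[[sp$group]][seq_len(sp$length)]
        g <- withSeed(sp$seed, {
            g <- mutateRaw(g, sp$divergence)
            if (sp$nFraction > 0)
                g <- maskRawN(g, sp$nFraction)
            g
        })
        seqs[i] <- rawToChar(g)
    }
    dss <- DNAStringSet(seqs)
    names(dss) <- nm
    new("GenomePanel", sequences = dss)
}

#' Construct a panel from existing sequences
#'
#' @param sequences A named [Biostrings::DNAStringSet] or named character
#'   vector of genome sequences.
#' @return A [GenomePanel-class].
#' @export
GenomePanel <- function(sequences) {
    if (is.character(sequences)) {
        nm <- names(sequences)
        sequences <- DNAStringSet(sequences)
        names(sequences) <- nm
    }
    new("GenomePanel", sequences = sequences)
}

#' Mask a fraction of one panel genome with N runs
#'
#' Returns a copy of the panel in which `round(fraction * length)` positions
#' of `genome` are replaced by contiguous N blocks (geometric lengths, mean
#' `blockMean`). Used to emulate draft references with ambiguous regions:
#' reads originating from the masked regions of the true genome cannot map,
#' and the quality factor \eqn{f = (n + c)/c} compensates for the loss.
#'
#' @param panel A [GenomePanel-class].
#' @param genome Name of the genome to mask.
#' @param fraction Fraction of positions to mask, in `[0, 1)`.
#' @param blockMean Mean N-run length in bases.
#' @param seed Integer seed.
#' @return A new [GenomePanel-class].
#' @export
maskGenome <- function(panel, genome, fraction, blockMean = 1000,
                       seed = 1L) {
    stopifnot(genome %in% panelNames(panel))
    seqs <- as.character(panel@sequences)
    g <- charToRaw(seqs[[genome]])
    g <- withSeed(seed, maskRawN(g, fraction, blockMean))
    seqs[[genome]] <- rawToChar(g)
    GenomePanel(seqs)
}

#' Describe a read mixture to simulate
#'
#' @param components Named numeric vector of species percentages summing to
#'   100 (names must be panel genome names).
#' @param totalReads Total number of reads to simulate.
#' @param readLength Read length in bases (the validation experiments use
#'   100 bp; 50 bp is also supported).
#' @param errorRate Per-base substitution probability, in `[0, 1)`.
#' @param paired Simulate paired-end mates (counted as two reads).
#' @param insertMean,insertSd Insert size model for paired mode (truncated
#'   normal, minimum `readLength`).
#' @param exactCounts If `TRUE` (the default, used by all validation runs),
#'   allocate per-species read counts deterministically by largest-remainder
#'   rounding of `percentage/100 * totalReads`; otherwise sample counts from
#'   a multinomial.
#' @param seed Integer seed.
#' @return A `list` with class `"MixtureSpec"`.
#' @examples
#' mixtureSpec(c(A = 60, B = 40), totalReads = 1000, seed = 7)
#' @export
mixtureSpec <- function(components, totalReads, readLength = 100L,
                        errorRate = 0.01, paired = FALSE,
                        insertMean = 300, insertSd = 50,
                        exactCounts = TRUE, seed = 1L) {
    if (abs(sum(components) - 100) > 1e-9)
        stop("component percentages must sum to 100")
    stopifnot(totalReads > 0, errorRate >= 0, errorRate < 1,
              !is.null(names(components)))
    structure(list(components = components,
                   totalReads = as.integer(totalReads),
                   readLength = as.integer(readLength),
                   errorRate = errorRate, paired = paired,
                   insertMean = insertMean, insertSd = insertSd,
                   exactCounts = exactCounts, seed = as.integer(seed)),
              class = "MixtureSpec")
}

#' Simulate tagged sequencing reads from a genome panel
#'
#' Reads are drawn uniformly at random from N-free windows of the component
#' genomes, on either strand, then each base is substituted independently
#' with probability `errorRate` (uniform choice among the three other bases;
#' no indels). Every read carries its ground-truth origin in the read id and
#' in the truth table of the returned object.
#'
#' @param panel A [GenomePanel-class].
#' @param mix A [mixtureSpec()].
#' @return A [TaggedReadSet-class].
#' @examples
#' panel <- generatePanel(list(genomeSpec("A", 2000, seed = 1)), 5)
#' rs <- simulateReads(panel, mixtureSpec(c(A = 100), 50, errorRate = 0,
#'                                        seed = 3))
#' length(reads(rs))
#' @export
simulateReads <- function(panel, mix) {
    stopifnot(inherits(mix, "MixtureSpec"))
    comps <- mix$components
    missing <- setdiff(names(comps), panelNames(panel))
    if (length(missing))
        stop("mixture component(s) not in panel: ",
             paste(missing, collapse = ", "))
    L <- mix$readLength
    if (L > min(genomeLengths(panel)[names(comps)]))
        stop("read length exceeds the shortest component genome")
    withSeed(mix$seed, {
        counts <- if (mix$exactCounts)
            largestRemainder(comps, mix$totalReads)
        else
            stats::setNames(as.integer(
                stats::rmultinom(1, mix$totalReads, comps / 100)),
                names(comps))
        seqs <- character(0)
        truth <- vector("list", length(comps))
        genomeChars <- as.character(panel@sequences)
        for (si in seq_along(comps)) {
            sp <- names(comps)[si]
            n <- counts[[si]]
            if (n == 0L) {
                truth[[si]] <- NULL
                next
            }
            g <- genomeChars[[sp]]
            if (mix$paired) {
                res <- .simulatePairs(g, sp, n, L, mix$insertMean,
                                      mix$insertSd)
            } else {
                valid <- validWindowStarts(g, L)
                if (length(valid) == 0L)
                    stop("insufficient non-N sequence in genome ", sp)
                starts <- valid[sample.int(length(valid), n, replace = TRUE)]
                strand <- sample(c("+", "-"), n, replace = TRUE)
                sq <- substring(g, starts, starts + L - 1L)
                res <- list(seq = sq, position = starts, strand = strand,
                            id = sprintf("%s_%07d", sp, seq_len(n)))
            }
            minus <- res$strand == "-"
            if (any(minus))
                res$seq[minus] <- as.character(
                    reverseComplement(DNAStringSet(res$seq[minus])))
            seqs <- c(seqs, res$seq)
            truth[[si]] <- data.frame(read_id = res$id, origin = sp,
                                      genome = sp, position = res$position,
                                      strand = res$strand,
                                      stringsAsFactors = FALSE)
        }
        truth <- do.call(rbind, truth)
        seqs <- .injectErrors(seqs, L, mix$errorRate)
        dss <- DNAStringSet(seqs)
        names(dss) <- truth$read_id
        new("TaggedReadSet", reads = dss, truth = truth)
    })
}

## Paired-end fragments: insert from a truncated normal (minimum = read
## length), mate 1 forward at the fragment start, mate 2 reverse at the end.
.simulatePairs <- function(g, sp, n, L, insertMean, insertSd) {
    stopifnot(n %% 2L == 0L)
    npair <- n %/% 2L
    ins <- pmax(L, round(stats::rnorm(npair, insertMean, insertSd)))
    ins <- pmin(ins, nchar(g))
    bytes <- charToRaw(g)
    isN <- as.integer(!(bytes %in% .BASES))
    cs <- c(0L, cumsum(isN))
    starts <- integer(npair)
    for (i in seq_len(npair)) {
        ok <- FALSE
        for (try in seq_len(1000L)) {
            s <- sample.int(nchar(g) - ins[i] + 1L, 1L)
            if (cs[s + ins[i]] - cs[s] == 0L) { ok <- TRUE; break }
        }
        if (!ok)
            stop("insufficient non-N sequence in genome ", sp)
        starts[i] <- s
    }
    p1 <- starts
    p2 <- starts + ins - L
    id <- sprintf("%s_%07d", sp, seq_len(npair))
    list(seq = c(substring(g, p1, p1 + L - 1L),
                 substring(g, p2, p2 + L - 1L)),
         position = c(p1, p2),
         strand = rep(c("+", "-"), each = npair),
         id = c(paste0(id, "/1"), paste0(id, "/2")))
}

## Uniform substitution errors over all reads at once: the per-base i.i.d.
## model is applied by drawing the total error count Binomial(n_bases, rate)
## and scattering the errors uniformly over the concatenated bases.
.injectErrors <- function(seqs, L, rate) {
    if (rate <= 0 || length(seqs) == 0L)
        return(seqs)
    all <- charToRaw(paste(seqs, collapse = ""))
    all <- mutateRaw(all, rate)
    offs <- (seq_along(seqs) - 1L) * L
    substring(rawToChar(all), offs + 1L, offs + L)
}

#' Write panel genomes as FASTA
#'
#' @param panel A [GenomePanel-class].
#' @param path Output FASTA path (wrapped at 70 columns).
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path) {
    writeXStringSet(panel@sequences, path, width = 70L)
    invisible(path)
}

#' Read a panel from FASTA file(s)
#'
#' @param paths One or more FASTA paths; all records are pooled.
#' @return A [GenomePanel-class].
#' @export
readPanel <- function(paths) {
    dss <- do.call(c, unname(lapply(unname(paths), readDNAStringSet)))
    names(dss) <- sub("\\s.*$", "", names(dss))
    GenomePanel(dss)
}

#' Write reads as FASTQ plus a ground-truth sidecar
#'
#' FASTQ qualities are constant `'I'` (Phred+33 = 40): the simulator has no
#' quality-dependent error model. When the read set carries a truth table it
#' is written next to the FASTQ as `<path>.truth.tsv`.
#'
#' @param x A [TaggedReadSet-class].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
writeReads <- function(x, path) {
    quals <- Biostrings::BStringSet(strrep("I", width(x@reads)))
    writeXStringSet(x@reads, path, format = "fastq", qualities = quals)
    if (nrow(x@truth) > 0L)
        utils::write.table(x@truth, paste0(path, ".truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a FASTQ file (optionally with its truth sidecar) into a read set
#'
#' @param path FASTQ path; if `<path>.truth.tsv` exists it is attached.
#' @return A [TaggedReadSet-class].
#' @export
readReads <- function(path) {
    dss <- readDNAStringSet(path, format = "fastq")
    names(dss) <- sub("\\s.*$", "", names(dss))
    sidecar <- paste0(path, ".truth.tsv")
    truth <- if (file.exists(sidecar))
        utils::read.delim(sidecar, stringsAsFactors = FALSE)
    else
        data.frame()
    new("TaggedReadSet", reads = dss, truth = truth)
}

#' Generate a synthetic 12-column tabular hit file for the LCA stage
#'
#' Stand-in for a similarity search against a sequence database: per read one
#' hit to the read's true leaf taxon at `bestScore`, plus `confounders`
#' hits to randomly drawn other leaf taxa at `confounderFrac * bestScore`.
#' Output follows the standard 12-column tabular convention (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bitscore); subject ids are `subj<taxid>`.
#'
#' @param reads A [TaggedReadSet-class] whose truth origins appear in
#'   `originTaxa`.
#' @param taxonomy A [Taxonomy-class].
#' @param originTaxa Named integer vector mapping origin species labels to
#'   leaf taxon ids.
#' @param path Output path for the tabular file.
#' @param confounders Number of extra hits per read to random other leaves.
#' @param confounderFrac Bitscore of confounder hits as a fraction of
#'   `bestScore`.
#' @param bestScore Bitscore of the true hit.
#' @param seed Integer seed.
#' @return Invisibly, a list with `path` and `subjectMap` (a `data.frame`
#'   mapping subject ids to taxon ids, also written to
#'   `<path>.taxmap.tsv`).
#' @export
makeM8Fixture <- function(reads, taxonomy, originTaxa, path,
                          confounders = 0L, confounderFrac = 0.9,
                          bestScore = 200, seed = 1L) {
    truth <- reads@truth
    if (nrow(truth) == 0L)
        stop("read set carries no ground truth")
    missing <- setdiff(unique(truth$origin), names(originTaxa))
    if (length(missing))
        stop("origin label(s) not mapped to taxa: ",
             paste(missing, collapse = ", "))
    leaves <- setdiff(taxonomy@id, taxonomy@parent)
    withSeed(seed, {
        n <- nrow(truth)
        qid <- truth$read_id
        taxid <- unname(originTaxa[truth$origin])
        L <- width(reads@reads)
        rows <- data.frame(qid = qid, sid = paste0("subj", taxid),
                           pident = 99.0, len = L, mism = 1L, gap = 0L,
                           qs = 1L, qe = L, ss = 101L, se = 100L + L,
                           evalue = 1e-30, bits = bestScore,
                           stringsAsFactors = FALSE)
        if (confounders > 0L) {
            conf <- leaves[sample.int(length(leaves), n * confounders,
                                      replace = TRUE)]
            crows <- data.frame(qid = rep(qid, each = confounders),
                                sid = paste0("subj", conf),
                                pident = 90.0, len = rep(L, each = confounders),
                                mism = 10L, gap = 0L, qs = 1L,
                                qe = rep(L, each = confounders), ss = 201L,
                                se = 200L + rep(L, each = confounders),
                                evalue = 1e-10,
                                bits = confounderFrac * bestScore,
                                stringsAsFactors = FALSE)
            rows <- rbind(rows, crows)
            rows <- rows[order(match(rows$qid, qid), -rows$bits, rows$sid), ]
        }
        utils::write.table(rows, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        subjectMap <- unique(data.frame(
            subject = rows$sid,
            taxon = as.integer(sub("^subj", "", rows$sid)),
            stringsAsFactors = FALSE))
        utils::write.table(subjectMap, paste0(path, ".taxmap.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
        invisible(list(path = path, subjectMap = subjectMap))
    })
}
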