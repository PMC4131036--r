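#' Construct a taxonomy from vectors
#'
#' @param id Integer node ids.
#' @param parent Integer parent ids; the root must be its own parent.
#' @param rank Character ranks (e.g. "species", "genus").
#' @param name Character scientific names.
#' @return A [Taxonomy-class].
#' @examples
#' tax <- Taxonomy(id = c(1L, 2L, 3L), parent = c(1L, 1L, 2L),
#'                 rank = c("root", "genus", "species"),
#'                 name = c("root", "Genus", "Genus species"))
#' @export
Taxonomy <- function(id, parent, rank, name) {
    id <- as.integer(id); parent <- as.integer(parent)
    root <- id[id == parent]
    if (length(root) != 1L)
        stop("taxonomy must have exactly one root (a self-parent node)")
    new("Taxonomy", id = id, parent = parent, rank = as.character(rank),
        name = as.character(name), root = root)
}

#' Read a taxonomy file
#'
#' Two dialects are accepted: the NCBI dump pair (`nodes.dmp` with
#' `names.dmp`, fields separated by `\\t|\\t`; only "scientific name" rows
#' of `names.dmp` are used) and a headerless 4-column TSV
#' (id, parent id, rank, name).
#'
#' @param nodes Path to `nodes.dmp` or to the 4-column TSV.
#' @param names Path to `names.dmp`; `NULL` selects the TSV dialect.
#' @return A [Taxonomy-class].
#' @export
readTaxonomy <- function(nodes, names = NULL) {
    if (is.null(names)) {
        df <- utils::read.delim(nodes, header = FALSE,
                                col.names = c("id", "parent", "rank", "name"),
                                stringsAsFactors = FALSE)
        return(Taxonomy(df$id, df$parent, df$rank, df$name))
    }
    nd <- readLines(nodes)
    nf <- strsplit(nd, "\t|\t", fixed = TRUE)
    id <- as.integer(vapply(nf, `[`, character(1), 1))
    parent <- as.integer(vapply(nf, `[`, character(1), 2))
    rank <- vapply(nf, `[`, character(1), 3)
    nm <- readLines(names)
    mf <- strsplit(nm, "\t|\t", fixed = TRUE)
    cls <- sub("\t\\|\\s*$", "", vapply(mf, `[`, character(1), 4))
    sci <- trimws(cls) == "scientific name"
    nmid <- as.integer(vapply(mf, `[`, character(1), 1))[sci]
    nmval <- vapply(mf, `[`, character(1), 2)[sci]
    name <- nmval[match(id, nmid)]
    name[is.na(name)] <- paste0("taxid:", id[is.na(name)])
    Taxonomy(id, parent, rank, name)
}

## path from a node up to (and including) the root, as ids
.taxPath <- function(tax, id) {
    pos <- match(id, tax@id)
    if (is.na(pos))
        return(integer(0))
    path <- integer(0)
    repeat {
        path <- c(path, tax@id[pos])
        if (tax@id[pos] == tax@root)
            break
        pos <- match(tax@parent[pos], tax@id)
    }
    path
}

#' Lowest common ancestor of a set of taxa
#'
#' The LCA of a single taxon is itself; taxa from different kingdoms climb
#' to their first common ancestor (ultimately the root). Ids absent from
#' the taxonomy are dropped (logged); an empty surviving set yields `NA`.
#'
#' @param tax A [Taxonomy-class].
#' @param ids Integer taxon ids.
#' @return The LCA taxon id (integer), or `NA` for an empty set.
#' @examples
#' tax <- Taxonomy(id = 1:4, parent = c(1L, 1L, 2L, 2L),
#'                 rank = c("root", "genus", "species", "species"),
#'                 name = c("root", "G", "G a", "G b"))
#' lcaTaxa(tax, c(3L, 4L))  # -> 2 (their genus)
#' @export
lcaTaxa <- function(tax, ids) {
    ids <- unique(as.integer(ids))
    known <- ids %in% tax@id
    if (any(!known)) {
        message(sum(!known), " hit taxon id(s) absent from the taxonomy; ",
                "dropped")
        ids <- ids[known]
    }
    if (length(ids) == 0L)
        return(NA_integer_)
    path <- .taxPath(tax, ids[1])
    for (i in ids[-1]) {
        p <- .taxPath(tax, i)
        path <- path[match(TRUE, path %in% p):length(path)]
    }
    path[1]
}

#' LCA-stage parameter set
#'
#' Defaults follow the standard parameterization of MEGAN-style filtered-LCA
#' classification of short-read BLAST output: minimum bitscore 75, top
#' percent 1.0, minimum read complexity 0.44, best three hits per read, and
#' a minimum support of 50 reads per reported taxon ("more than 50"
#' is strict: a taxon with exactly 50 reads is folded into its parent).
#'
#' @param minScore Minimum bitscore for a hit to survive.
#' @param topPercent Retain hits with bitscore at least
#'   `(1 - topPercent/100)` times the read's best surviving bitscore.
#' @param minComplexity Minimum [readComplexity()] score; reads below it are
#'   set aside as low-complexity.
#' @param maxHitsPerRead Best hits retained per read (by bitscore).
#' @param minSupport Strict minimum read count for a taxon to be reported
#'   rather than folded into its ancestor.
#' @param promoteThreshold Read count above which a taxon is recommended for
#'   promotion into the mapping panel.
#' @param foldMode `"fold"` merges under-supported taxa into their nearest
#'   supported ancestor (conserves reads); `"discard"` drops them.
#' @return A `list` with class `"LcaParams"`.
#' @export
lcaParams <- function(minScore = 75, topPercent = 1, minComplexity = 0.44,
                      maxHitsPerRead = 3L, minSupport = 50L,
                      promoteThreshold = 500L,
                      foldMode = c("fold", "discard")) {
    stopifnot(minScore >= 0, topPercent >= 0, topPercent <= 100,
              minComplexity >= 0, maxHitsPerRead >= 1, minSupport >= 0,
              promoteThreshold >= 0)
    structure(list(minScore = minScore, topPercent = topPercent,
                   minComplexity = minComplexity,
                   maxHitsPerRead = as.integer(maxHitsPerRead),
                   minSupport = as.integer(minSupport),
                   promoteThreshold = as.integer(promoteThreshold),
                   foldMode = match.arg(foldMode)),
              class = "LcaParams")
}

#' Parse 12-column tabular similarity-search output
#'
#' Reads the standard tabular convention (query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bitscore), attaches subject taxon ids, and
#' keeps the best `maxHitsPerRead` hits per read by descending bitscore
#' (ties broken by lexicographically smallest subject id, for determinism).
#' Subjects absent from the map are logged and dropped.
#'
#' @param path Path to the tabular file; an empty file yields zero hits.
#' @param subjectTaxonMap Named integer vector (names = subject ids) or a
#'   2-column `data.frame`/TSV path mapping subject id to taxon id.
#' @param maxHitsPerRead Hits retained per read.
#' @return A `data.frame` with columns `read_id`, `subject`, `pident`,
#'   `length`, `mismatches`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`, `taxon`.
#' @export
parseM8 <- function(path, subjectTaxonMap, maxHitsPerRead = 3L) {
    if (is.character(subjectTaxonMap) && length(subjectTaxonMap) == 1L &&
        file.exists(subjectTaxonMap))
        subjectTaxonMap <- utils::read.delim(subjectTaxonMap, header = FALSE,
                                             stringsAsFactors = FALSE)
    if (is.data.frame(subjectTaxonMap))
        subjectTaxonMap <- stats::setNames(
            as.integer(subjectTaxonMap[[2]]),
            as.character(subjectTaxonMap[[1]]))
    if (file.size(path) == 0L)
        return(data.frame(read_id = character(0), subject = character(0),
                          pident = numeric(0), length = integer(0),
                          mismatches = integer(0), gapopen = integer(0),
                          qstart = integer(0), qend = integer(0),
                          sstart = integer(0), send = integer(0),
                          evalue = numeric(0), bitscore = numeric(0),
                          taxon = integer(0), stringsAsFactors = FALSE))
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    bad <- which(nf != 12L)
    if (length(bad))
        stop("malformed tabular record at line ", bad[1], " of ", path,
             " (", nf[bad[1]], " fields, expected 12)")
    df <- utils::read.delim(path, header = FALSE, quote = "",
                            stringsAsFactors = FALSE,
                            col.names = c("read_id", "subject", "pident",
                                          "length", "mismatches", "gapopen",
                                          "qstart", "qend", "sstart", "send",
                                          "evalue", "bitscore"))
    df$taxon <- unname(subjectTaxonMap[df$subject])
    if (anyNA(df$taxon)) {
        message(sum(is.na(df$taxon)),
                " hit(s) with unmapped subject id dropped")
        df <- df[!is.na(df$taxon), , drop = FALSE]
    }
    df <- df[order(match(df$read_id, unique(df$read_id)), -df$bitscore,
                   df$subject), , drop = FALSE]
    keep <- stats::ave(seq_len(nrow(df)), df$read_id,
                       FUN = seq_along) <= maxHitsPerRead
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Sequence complexity score
#'
#' Shannon entropy of the overlapping trinucleotide frequency distribution,
#' normalized by \eqn{\log_2(\min(64, L - 2))} so the score lies in
#' `[0, 1]`: a homopolymer scores 0, uniform-random sequence close to 1.
#' Used to set aside low-complexity reads (microsatellites and other simple
#' repeats) that attract spurious database hits.
#'
#' @param x Character vector, `DNAStringSet` or [TaggedReadSet-class];
#'   every sequence must be at least 3 bases long.
#' @return Numeric scores in `[0, 1]`, one per sequence.
#' @examples
#' readComplexity(c(strrep("A", 100), strrep("AC", 50)))
#' @export
readComplexity <- function(x) {
    if (is(x, "TaggedReadSet"))
        x <- x@reads
    if (!is(x, "DNAStringSet"))
        x <- DNAStringSet(x)
    if (any(width(x) < 3L))
        stop("sequences must be at least 3 bases long")
    tri <- Biostrings::oligonucleotideFrequency(x, width = 3L)
    tot <- rowSums(tri)
    p <- tri / tot
    h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
    h / log2(pmin(64L, width(x) - 2L))
}

#' Assign reads to taxa by filtered lowest-common-ancestor classification
#'
#' Filtering order: reads with complexity below `minComplexity` are set
#' aside as `low_complexity`; hits with bitscore below `minScore` are
#' dropped; of the remainder, only hits within `topPercent` percent of the
#' read's best surviving bitscore are retained; the read is assigned to the
#' LCA of the surviving hits' taxa. Reads with no surviving hits are
#' `unassigned`.
#'
#' @param hits A hit `data.frame` from [parseM8()].
#' @param reads Reads supplying sequences for the complexity filter; `NULL`
#'   skips that filter.
#' @param taxonomy A [Taxonomy-class].
#' @param params An [lcaParams()].
#' @return A `data.frame` with columns `read_id`, `category`
#'   (`assigned` / `unassigned` / `low_complexity`) and `taxon` (NA unless
#'   assigned). Reads present in `reads` but absent from `hits` are
#'   included as `unassigned`.
#' @export
assignReads <- function(hits, reads = NULL, taxonomy,
                        params = lcaParams()) {
    ids <- unique(hits$read_id)
    low <- character(0)
    if (!is.null(reads)) {
        rv <- .readVector(reads)
        ids <- union(ids, names(rv))
        cx <- readComplexity(rv)
        low <- names(rv)[cx < params$minComplexity]
    }
    out <- data.frame(read_id = ids, category = "unassigned",
                      taxon = NA_integer_, stringsAsFactors = FALSE)
    h <- hits[hits$bitscore >= params$minScore &
              !(hits$read_id %in% low), , drop = FALSE]
    if (nrow(h) > 0L) {
        best <- tapply(h$bitscore, h$read_id, max)
        cutoff <- best[h$read_id] * (1 - params$topPercent / 100)
        h <- h[h$bitscore >= cutoff, , drop = FALSE]
        byRead <- split(h$taxon, h$read_id)
        lca <- vapply(byRead, function(t) lcaTaxa(taxonomy, t), integer(1))
        pos <- match(names(lca), out$read_id)
        out$taxon[pos] <- unname(lca)
        out$category[pos][!is.na(out$taxon[pos])] <- "assigned"
    }
    out$category[out$read_id %in% low] <- "low_complexity"
    out$taxon[out$category != "assigned"] <- NA_integer_
    rownames(out) <- NULL
    out
}

#' Summarize per-read taxon assignments
#'
#' Tallies reads per taxon, folds taxa supported by at most `minSupport`
#' reads into their nearest supported ancestor (recursively, bottom-up;
#' reads are conserved -- or dropped under `foldMode = "discard"`), and
#' flags taxa whose final count exceeds `promoteThreshold` as candidates
#' for promotion into the mapping panel.
#'
#' @param assigned A `data.frame` from [assignReads()].
#' @param taxonomy A [Taxonomy-class].
#' @param params An [lcaParams()].
#' @return A [TaxonSummary-class].
#' @export
summarizeTaxa <- function(assigned, taxonomy, params = lcaParams()) {
    ok <- assigned$category == "assigned"
    counts <- table(assigned$taxon[ok])
    cnt <- stats::setNames(rep(0, length(taxonomy@id)),
                           as.character(taxonomy@id))
    cnt[names(counts)] <- as.numeric(counts)
    pos <- match(taxonomy@parent, taxonomy@id)
    depth <- taxDepths(taxonomy@id, pos, taxonomy@root)
    ord <- order(depth, decreasing = TRUE)
    for (i in ord) {
        tid <- as.character(taxonomy@id[i])
        if (taxonomy@id[i] == taxonomy@root)
            next
        if (cnt[[tid]] > 0 && cnt[[tid]] <= params$minSupport) {
            if (params$foldMode == "fold") {
                pid <- as.character(taxonomy@parent[i])
                cnt[[pid]] <- cnt[[pid]] + cnt[[tid]]
            }
            cnt[[tid]] <- 0
        }
    }
    keep <- cnt > 0
    df <- data.frame(taxon_id = taxonomy@id[keep],
                     name = taxonomy@name[keep],
                     rank = taxonomy@rank[keep],
                     reads = as.integer(cnt[keep]),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$reads), , drop = FALSE]
    rownames(df) <- NULL
    promo <- df$name[df$reads > params$promoteThreshold]
    new("TaxonSummary", counts = df, promotions = promo,
        unassigned = sum(assigned$category == "unassigned"),
        lowComplexity = sum(assigned$category == "low_complexity"))
}
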