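#' Build an exact-seed index over a genome panel
#'
#' Indexes every N-free seed of length `seedLength` at every position of
#' every panel genome (forward strand; the reverse strand is handled at
#' query time by looking up the reverse complement of the read). The index
#' backs the pigeonhole k-mismatch mapper: a read is split into `k + 1`
#' non-overlapping seeds, so any alignment with at most `k` mismatches
#' leaves at least one seed exact and is guaranteed to be found.
#'
#' @param panel A [GenomePanel-class].
#' @param seedLength Seed length in bases (default 20: pigeonhole-safe up to
#'   k = 3 for 100 bp reads, and up to k = 1 for 50 bp reads).
#' @param maxMismatch Largest mismatch allowance the index is intended for;
#'   used only to reject seed lengths that would break the pigeonhole
#'   guarantee for the stated read length.
#' @param readLength Intended read length for the guarantee check.
#' @return A [SeedIndex-class].
#' @examples
#' panel <- GenomePanel(c(g = "ACGTACGTACGTACGTACGTACGTACGT"))
#' idx <- buildIndex(panel, seedLength = 10, maxMismatch = 1,
#'                   readLength = 20)
#' @export
buildIndex <- function(panel, seedLength = 20L, maxMismatch = 3L,
                       readLength = 100L) {
    seedLength <- as.integer(seedLength)
    if (seedLength < 10L)
        stop("seedLength must be >= 10")
    if (seedLength * (maxMismatch + 1L) > readLength)
        stop("seedLength too large: ", maxMismatch + 1L,
             " non-overlapping seeds of ", seedLength,
             " bases do not fit in a ", readLength,
             " bp read; the pigeonhole guarantee would break")
    ptr <- afs_build_index(as.character(panel@sequences), seedLength)
    new("SeedIndex", ptr = ptr, seedLength = seedLength,
        panelNames = panelNames(panel),
        panelWidths = unname(genomeLengths(panel)))
}

#' Map reads against an indexed panel with at most k mismatches
#'
#' Reports every alignment (either strand, any genome, any position) whose
#' Hamming distance to the reference window is at most `maxMismatch`; an N
#' in the reference counts as a mismatch to any base. Reads shorter than
#' `(maxMismatch + 1) * seedLength` cannot carry the pigeonhole guarantee
#' and are reported unmapped with a warning.
#'
#' @param reads A [TaggedReadSet-class], [Biostrings::DNAStringSet] or named
#'   character vector.
#' @param index A [SeedIndex-class].
#' @param maxMismatch Mismatch allowance k (0--3 in the standard schedules).
#' @return A `data.frame` of alignments with columns `read_id`, `genome`,
#'   `position` (1-based leftmost on the forward strand), `strand`
#'   (`"+"`/`"-"`) and `mismatches`.
#' @examples
#' panel <- GenomePanel(c(g = strrep("ACGT", 20)))
#' idx <- buildIndex(panel, 10, maxMismatch = 0, readLength = 40)
#' mapReads(c(r1 = strrep("ACGT", 10)), idx, 0)
#' @export
mapReads <- function(reads, index, maxMismatch = 1L) {
    rv <- .readVector(reads)
    res <- afs_map_reads(index@ptr, unname(rv), as.integer(maxMismatch))
    if (length(res$too_short))
        warning(length(res$too_short), " read(s) shorter than ",
                (maxMismatch + 1L) * index@seedLength,
                " bp reported unmapped (pigeonhole precondition)")
    data.frame(read_id = names(rv)[res$read],
               genome = index@panelNames[res$genome],
               position = res$pos,
               strand = ifelse(res$strand > 0L, "+", "-"),
               mismatches = res$mismatches,
               stringsAsFactors = FALSE)
}

.readVector <- function(reads) {
    if (is(reads, "TaggedReadSet"))
        reads <- reads@reads
    if (is(reads, "DNAStringSet")) {
        nm <- names(reads)
        reads <- as.character(reads)
        names(reads) <- nm
    }
    if (!is.character(reads))
        stop("reads must be a TaggedReadSet, DNAStringSet or character")
    if (is.null(names(reads)))
        names(reads) <- sprintf("read_%07d", seq_along(reads))
    if (anyDuplicated(names(reads)))
        stop("duplicate read ids")
    reads
}
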