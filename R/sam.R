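#' Write alignments as a SAM file
#'
#' Emits a SAM 1.x file with `@SQ` headers for every panel genome and one
#' record per alignment carrying the mismatch count in the `NM` tag; reads
#' present in `reads` but absent from `alignments` are written as unmapped
#' records (flag 4). Minus-strand records store the reverse-complemented
#' sequence, per the SAM convention.
#'
#' @param alignments A `data.frame` as returned by [mapReads()].
#' @param reads Reads ([TaggedReadSet-class], `DNAStringSet` or named
#'   character) supplying sequences; may be `NULL` to write `*` sequences.
#' @param panel The [GenomePanel-class] mapped against.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(alignments, reads = NULL, panel, path) {
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", panelNames(panel),
                     unname(genomeLengths(panel))))
    rv <- if (is.null(reads)) character(0) else .readVector(reads)
    seqOf <- function(ids) {
        if (length(rv) == 0L) return(rep("*", length(ids)))
        out <- unname(rv[ids])
        out[is.na(out)] <- "*"
        out
    }
    body <- character(0)
    if (nrow(alignments) > 0L) {
        sq <- seqOf(alignments$read_id)
        minus <- alignments$strand == "-" & sq != "*"
        if (any(minus))
            sq[minus] <- as.character(
                reverseComplement(DNAStringSet(sq[minus])))
        qual <- ifelse(sq == "*", "*", strrep("I", nchar(sq)))
        cig <- ifelse(sq == "*", "*", paste0(nchar(sq), "M"))
        body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                        alignments$read_id,
                        ifelse(alignments$strand == "-", 16L, 0L),
                        alignments$genome, alignments$position, cig,
                        sq, qual, alignments$mismatches)
    }
    unmapped <- setdiff(names(rv), alignments$read_id)
    if (length(unmapped)) {
        sq <- seqOf(unmapped)
        qual <- ifelse(sq == "*", "*", strrep("I", nchar(sq)))
        body <- c(body,
                  sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                          unmapped, sq, qual))
    }
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Parses mapped records (via Rsamtools) into the same `data.frame` shape
#' that [mapReads()] produces, recovering the mismatch count from the `NM`
#' tag, and returns unmapped read ids alongside. Records mapped to genomes
#' outside the panel are rejected. Lets an external mapper substitute for
#' the built-in one.
#'
#' @param path SAM path (must contain `@SQ` headers).
#' @param panel Optional [GenomePanel-class]; when given, reference names in
#'   the SAM must be a subset of the panel.
#' @return A list with elements `alignments` (`data.frame` with `read_id`,
#'   `genome`, `position`, `strand`, `mismatches`) and `unmapped`
#'   (character read ids).
#' @export
readSam <- function(path, panel = NULL) {
    lines <- readLines(path)
    isHdr <- startsWith(lines, "@")
    if (!any(startsWith(lines, "@SQ")))
        stop("SAM file has no @SQ headers: ", path)
    bad <- which(!isHdr & nzchar(lines) &
                 vapply(strsplit(lines, "\t", fixed = TRUE), length,
                        integer(1)) < 11L)
    if (length(bad))
        stop("malformed SAM record at line ", bad[1], " of ", path)
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "strand"),
        tag = "NM")
    res <- Rsamtools::scanBam(bam, param = p)[[1]]
    unlink(bam)
    isUnmapped <- bitwAnd(res$flag, 4L) != 0L
    aln <- data.frame(read_id = res$qname[!isUnmapped],
                      genome = as.character(res$rname[!isUnmapped]),
                      position = res$pos[!isUnmapped],
                      strand = as.character(res$strand[!isUnmapped]),
                      mismatches = {
                          nm <- res$tag$NM
                          if (is.null(nm)) rep(NA_integer_, sum(!isUnmapped))
                          else nm[!isUnmapped]
                      },
                      stringsAsFactors = FALSE)
    if (!is.null(panel)) {
        outside <- setdiff(unique(aln$genome), panelNames(panel))
        if (length(outside))
            stop("SAM records map to genome(s) outside the panel: ",
                 paste(outside, collapse = ", "))
    }
    list(alignments = aln,
         unmapped = setdiff(unique(res$qname[isUnmapped]),
                            aln$read_id))
}
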