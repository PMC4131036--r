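#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   alphabetFrequency readDNAStringSet writeXStringSet width subseq
#' @useDynLib AFSeq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Reference genome panel
#'
#' A named set of reference genome sequences a sample is quantified against.
#' Ambiguity (N) counts per genome are tracked so that the per-genome quality
#' factor \eqn{f = (n + c)/c} can be applied downstream, where \eqn{c} is the
#' total reference length and \eqn{n} its number of ambiguous positions.
#'
#' @slot sequences A named [Biostrings::DNAStringSet] of reference genomes.
#'
#' @seealso [generatePanel()], [readPanel()], [qualityFactors()]
#' @export
setClass("GenomePanel", representation(sequences = "DNAStringSet"))

setValidity("GenomePanel", function(object) {
    nm <- names(object@sequences)
    if (length(object@sequences) == 0L)
        return("panel must contain at least one genome")
    if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
        return("genomes must carry unique non-empty names")
    if (any(width(object@sequences) == 0L))
        return("genomes must have non-zero length")
    TRUE
})

#' Simulated or imported sequencing reads with optional ground truth
#'
#' Reads are stored as a named [Biostrings::DNAStringSet]; simulated reads
#' additionally carry a truth table (origin species, source genome, 1-based
#' position, strand) used to score mapping accuracy.
#'
#' @slot reads A named [Biostrings::DNAStringSet].
#' @slot truth A `data.frame` with columns `read_id`, `origin`, `genome`,
#'   `position`, `strand`, or a zero-row frame for untagged reads.
#'
#' @seealso [simulateReads()], [accuracyFromTruth()]
#' @export
setClass("TaggedReadSet",
         representation(reads = "DNAStringSet", truth = "data.frame"))

setValidity("TaggedReadSet", function(object) {
    nm <- names(object@reads)
    if (length(object@reads) > 0L && (is.null(nm) || anyDuplicated(nm)))
        return("reads must carry unique ids")
    if (nrow(object@truth) > 0L) {
        need <- c("read_id", "origin", "genome", "position", "strand")
        if (!all(need %in% colnames(object@truth)))
            return(paste("truth table must have columns:",
                         paste(need, collapse = ", ")))
        if (nrow(object@truth) != length(object@reads))
            return("truth table must describe every read")
    }
    TRUE
})

#' Exact-seed index over a genome panel
#'
#' Hash/search index of all N-free fixed-length seeds of every panel genome,
#' backing the k-mismatch pigeonhole mapper. The index lives in native memory
#' and is rebuilt (deterministically) rather than serialized.
#'
#' @slot ptr External pointer to the native index.
#' @slot seedLength Integer seed length in bases.
#' @slot panelNames Genome names, in index order.
#' @slot panelWidths Genome lengths.
#'
#' @seealso [buildIndex()], [mapReads()]
#' @export
setClass("SeedIndex",
         representation(ptr = "externalptr", seedLength = "integer",
                        panelNames = "character", panelWidths = "integer"))

#' Per-read mapping outcome over a panel
#'
#' Each read is `unique` (hit exactly one genome), `multi` (hit two or more)
#' or `unmapped`, together with the genome set and the index of the mapping
#' round (mismatch allowance) that resolved it.
#'
#' @slot assignments A [S4Vectors::DataFrame] with columns `read_id`,
#'   `status`, `round` (NA for unmapped) and `genomes` (a
#'   [IRanges::CharacterList] of candidate genome names).
#' @slot schedule The increasing mismatch schedule the table was built under.
#' @slot panelNames Names of all genomes in the panel mapped against.
#'
#' @seealso [iterativeMap()], [redistributeMulti()]
#' @export
setClass("AssignmentTable",
         representation(assignments = "DataFrame", schedule = "integer",
                        panelNames = "character"))

setValidity("AssignmentTable", function(object) {
    a <- object@assignments
    need <- c("read_id", "status", "round", "genomes")
    if (!all(need %in% colnames(a)))
        return(paste("assignments must have columns:",
                     paste(need, collapse = ", ")))
    if (anyDuplicated(a$read_id))
        return("every read must appear exactly once")
    n <- lengths(a$genomes)
    if (any(a$status == "unique" & n != 1L))
        return("unique reads must have exactly one candidate genome")
    if (any(a$status == "multi" & n < 2L))
        return("multi reads must have at least two candidate genomes")
    if (any(a$status == "unmapped" & n != 0L))
        return("unmapped reads must have an empty genome set")
    TRUE
})

#' Species proportion report
#'
#' Per-species unique counts, redistributed multi-read shares, quality-
#' corrected counts and renormalized proportions, with optional declared
#' target percentages and absolute/relative differences.
#'
#' @slot report A `data.frame` with one row per species.
#' @slot rawTotalPercent Sum of corrected counts over mapped reads, in
#'   percent, before renormalization (100 exactly when no quality correction
#'   was applied).
#' @slot strategy Label of the quantification strategy that produced it.
#'
#' @seealso [proportionReport()]
#' @export
setClass("ProportionReport",
         representation(report = "data.frame", rawTotalPercent = "numeric",
                        strategy = "character"))

#' Taxonomy tree
#'
#' Rooted taxonomy as parallel vectors of node id, parent id, rank and name.
#'
#' @slot id Integer node ids.
#' @slot parent Integer parent ids (the root is its own parent).
#' @slot rank Character ranks.
#' @slot name Character scientific names.
#' @slot root Integer id of the root.
#'
#' @seealso [readTaxonomy()], [lcaTaxa()]
#' @export
setClass("Taxonomy",
         representation(id = "integer", parent = "integer",
                        rank = "character", name = "character",
                        root = "integer"))

setValidity("Taxonomy", function(object) {
    if (anyDuplicated(object@id)) return("node ids must be unique")
    if (!(object@root %in% object@id)) return("root id must be a node")
    if (!all(object@parent %in% object@id))
        return("every parent must be a node")
    ## every chain must reach the root without cycles
    pos <- match(object@parent, object@id)
    depth <- taxDepths(object@id, pos, object@root)
    if (anyNA(depth)) return("parent chains must terminate at the root")
    TRUE
})

#' Per-taxon summary of the metagenomic stage
#'
#' Read counts per taxon after minimum-support folding, the taxa flagged for
#' promotion into the mapping panel, and the unassigned / low-complexity
#' tallies.
#'
#' @slot counts A `data.frame` with columns `taxon_id`, `name`, `rank`,
#'   `reads`.
#' @slot promotions Character names of taxa recommended for the panel.
#' @slot unassigned Number of reads with no surviving hit.
#' @slot lowComplexity Number of reads discarded by the complexity filter.
#'
#' @seealso [summarizeTaxa()]
#' @export
setClass("TaxonSummary",
         representation(counts = "data.frame", promotions = "character",
                        unassigned = "integer", lowComplexity = "integer"))

## depth of every node, NA on a broken/cyclic chain (shared with validity)
taxDepths <- function(id, parentPos, root) {
    n <- length(id)
    depth <- rep(NA_integer_, n)
    depth[id == root] <- 0L
    for (i in seq_len(n)) {
        if (!is.na(depth[i])) next
        chain <- i
        j <- i
        repeat {
            j <- parentPos[j]
            if (is.na(j) || length(chain) > n) break
            if (!is.na(depth[j])) {
                depth[chain] <- depth[j] + rev(seq_along(chain))
                break
            }
            chain <- c(chain, j)
        }
    }
    depth
}
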