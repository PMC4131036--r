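#' @rdname GenomePanel-class
#' @param x,object A [GenomePanel-class].
#' @export
setGeneric("panelNames", function(x) standardGeneric("panelNames"))

#' @rdname GenomePanel-class
#' @export
setMethod("panelNames", "GenomePanel", function(x) names(x@sequences))

#' @rdname GenomePanel-class
#' @export
setGeneric("genomeLengths", function(x) standardGeneric("genomeLengths"))

#' @rdname GenomePanel-class
#' @export
setMethod("genomeLengths", "GenomePanel", function(x)
    stats::setNames(width(x@sequences), names(x@sequences)))

#' @rdname GenomePanel-class
#' @export
setGeneric("ambiguousCounts", function(x) standardGeneric("ambiguousCounts"))

#' @rdname GenomePanel-class
#' @details `ambiguousCounts` counts every non-ACGT position (N and IUPAC
#'   ambiguity codes) per genome; `qualityFactors` returns
#'   \eqn{f = (n + c)/c} per genome, where `c` is the genome length and `n`
#'   its ambiguous count, so `f >= 1` with equality iff the genome has no
#'   ambiguous positions.
#' @export
setMethod("ambiguousCounts", "GenomePanel", function(x) {
    af <- alphabetFrequency(x@sequences)
    acgt <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
    stats::setNames(width(x@sequences) - acgt, names(x@sequences))
})

#' @rdname GenomePanel-class
#' @export
setGeneric("qualityFactors", function(x) standardGeneric("qualityFactors"))

#' @rdname GenomePanel-class
#' @export
setMethod("qualityFactors", "GenomePanel", function(x) {
    cc <- genomeLengths(x)
    nn <- ambiguousCounts(x)
    (nn + cc) / cc
})

#' @rdname GenomePanel-class
#' @export
setMethod("length", "GenomePanel", function(x) length(x@sequences))

#' @rdname GenomePanel-class
#' @param i Genome name or index.
#' @export
setMethod("[[", "GenomePanel", function(x, i) x@sequences[[i]])

setMethod("show", "GenomePanel", function(object) {
    cat("GenomePanel with", length(object), "genome(s)\n")
    n <- ambiguousCounts(object)
    df <- data.frame(genome = panelNames(object),
                     length = unname(genomeLengths(object)),
                     ambiguous = unname(n),
                     f = round(unname(qualityFactors(object)), 5))
    print(utils::head(df, 10), row.names = FALSE)
    if (nrow(df) > 10) cat("...\n")
})

#' @rdname TaggedReadSet-class
#' @param x,object A [TaggedReadSet-class].
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))

#' @rdname TaggedReadSet-class
#' @export
setMethod("reads", "TaggedReadSet", function(x) x@reads)

#' @rdname TaggedReadSet-class
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' @rdname TaggedReadSet-class
#' @export
setMethod("truth", "TaggedReadSet", function(x) x@truth)

#' @rdname TaggedReadSet-class
#' @export
setMethod("length", "TaggedReadSet", function(x) length(x@reads))

setMethod("show", "TaggedReadSet", function(object) {
    cat("TaggedReadSet with", length(object), "read(s)")
    if (length(object))
        cat(", width", paste(range(width(object@reads)), collapse = "-"))
    cat(if (nrow(object@truth)) ", ground truth attached" else
        ", no ground truth", "\n")
})

#' @rdname AssignmentTable-class
#' @param x,object An [AssignmentTable-class].
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname AssignmentTable-class
#' @export
setMethod("assignments", "AssignmentTable", function(x) x@assignments)

#' @rdname AssignmentTable-class
#' @details `statusCounts` tallies unique / multi / unmapped reads;
#'   their sum always equals the number of input reads.
#' @export
setGeneric("statusCounts", function(x) standardGeneric("statusCounts"))

#' @rdname AssignmentTable-class
#' @export
setMethod("statusCounts", "AssignmentTable", function(x) {
    s <- factor(x@assignments$status,
                levels = c("unique", "multi", "unmapped"))
    table(s)
})

#' @rdname AssignmentTable-class
#' @export
setGeneric("unmappedReads", function(x) standardGeneric("unmappedReads"))

#' @rdname AssignmentTable-class
#' @export
setMethod("unmappedReads", "AssignmentTable", function(x)
    x@assignments$read_id[x@assignments$status == "unmapped"])

setMethod("show", "AssignmentTable", function(object) {
    tc <- statusCounts(object)
    cat("AssignmentTable:", sum(tc), "reads; schedule k = [",
        paste(object@schedule, collapse = ","), "]\n")
    cat(sprintf("  unique %d | multi %d | unmapped %d\n",
                tc[["unique"]], tc[["multi"]], tc[["unmapped"]]))
})

#' @rdname ProportionReport-class
#' @param x,object A [ProportionReport-class].
#' @details The report's `proportion` column is renormalized to sum to 100;
#'   the pre-renormalization total (which can exceed 100 after quality
#'   correction) is kept in `rawTotalPercent()`. When a declared target is
#'   present, `difference_abs = |proportion - target|` and `difference_rel =
#'   difference_abs / target * 100` (NA when the target is 0, shown as
#'   "n.a.").
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname ProportionReport-class
#' @export
setMethod("reportTable", "ProportionReport", function(x) x@report)

#' @rdname ProportionReport-class
#' @export
setGeneric("rawTotalPercent", function(x) standardGeneric("rawTotalPercent"))

#' @rdname ProportionReport-class
#' @export
setMethod("rawTotalPercent", "ProportionReport", function(x)
    x@rawTotalPercent)

setMethod("show", "ProportionReport", function(object) {
    cat("ProportionReport",
        if (nzchar(object@strategy))
            paste0("(", object@strategy, ")"), "\n")
    df <- object@report
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) round(v, 4))
    if ("difference_rel" %in% colnames(df))
        df$difference_rel <- ifelse(is.na(df$difference_rel), "n.a.",
                                    format(df$difference_rel))
    print(df, row.names = FALSE)
    cat(sprintf("raw total: %.4f%%\n", object@rawTotalPercent))
})

#' @rdname TaxonSummary-class
#' @param x,object A [TaxonSummary-class].
#' @export
setGeneric("taxonCounts", function(x) standardGeneric("taxonCounts"))

#' @rdname TaxonSummary-class
#' @export
setMethod("taxonCounts", "TaxonSummary", function(x) x@counts)

#' @rdname TaxonSummary-class
#' @export
setGeneric("promotions", function(x) standardGeneric("promotions"))

#' @rdname TaxonSummary-class
#' @export
setMethod("promotions", "TaxonSummary", function(x) x@promotions)

setMethod("show", "TaxonSummary", function(object) {
    cat("TaxonSummary:", sum(object@counts$reads), "assigned read(s),",
        object@unassigned, "unassigned,",
        object@lowComplexity, "low-complexity\n")
    print(utils::head(object@counts[order(-object@counts$reads), ], 10),
          row.names = FALSE)
    if (length(object@promotions))
        cat("promotion candidates:",
            paste(object@promotions, collapse = ", "), "\n")
})

setMethod("show", "Taxonomy", function(object) {
    cat("Taxonomy with", length(object@id), "node(s); root:",
        object@name[match(object@root, object@id)], "\n")
})

setMethod("show", "SeedIndex", function(object) {
    cat("SeedIndex: seed length", object@seedLength, "over",
        length(object@panelNames), "genome(s),",
        format(afs_index_size(object@ptr), big.mark = ","),
        "indexed seeds\n")
})
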