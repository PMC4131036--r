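#' Discard reads shorter than a minimum length
#'
#' Mirrors the minimum-length post-trimming filter applied upstream of
#' mapping (50 bp for 100 bp libraries, 20 bp for 50 bp libraries). Reads
#' strictly shorter than `minLength` are removed. Further quality/adapter
#' trimming is delegated to upstream tools and is not implemented here.
#'
#' @param reads A [TaggedReadSet-class], `DNAStringSet` or named character.
#' @param minLength Minimum retained read length in bases.
#' @return A list with `reads` (same type as the input where possible),
#'   `retained` and `removed` counts.
#' @export
lengthFilter <- function(reads, minLength = 50L) {
    stopifnot(minLength >= 1L)
    if (is(reads, "TaggedReadSet")) {
        keep <- width(reads@reads) >= minLength
        truth <- reads@truth
        if (nrow(truth) > 0L)
            truth <- truth[truth$read_id %in% names(reads@reads)[keep], ,
                           drop = FALSE]
        out <- new("TaggedReadSet", reads = reads@reads[keep],
                   truth = truth)
    } else {
        rv <- .readVector(reads)
        keep <- nchar(rv) >= minLength
        out <- rv[keep]
    }
    list(reads = out, retained = sum(keep), removed = sum(!keep))
}

#' Subset a tagged read set by read ids
#'
#' @param x A [TaggedReadSet-class].
#' @param ids Read ids to keep.
#' @return A [TaggedReadSet-class].
#' @export
subsetReads <- function(x, ids) {
    keep <- names(x@reads) %in% ids
    truth <- x@truth
    if (nrow(truth) > 0L)
        truth <- truth[match(names(x@reads)[keep], truth$read_id), ,
                       drop = FALSE]
    new("TaggedReadSet", reads = x@reads[keep], truth = truth)
}

#' Full-run configuration
#'
#' Bundles every stage parameter of one pipeline run: length filter,
#' iterative mapping strategy, quality correction, optional metagenomic
#' (LCA) stage and the promotion loop that re-runs the mapping with a
#' flagged taxon's genome added to the panel.
#'
#' @param panel A [GenomePanel-class] or FASTA path(s).
#' @param reads A [TaggedReadSet-class] or FASTQ path.
#' @param strategy,schedule,applyQualityFactor,sizeNormalize See
#'   [quantConfig()].
#' @param minReadLength Minimum read length (default 50, suited to 100 bp
#'   data; use 20 for 50 bp data).
#' @param targets Optional named declared percentages.
#' @param subsample Optional number of reads to subsample (without
#'   replacement, under `seed`) before mapping.
#' @param lca Optional list configuring the metagenomic stage: either
#'   `hits` (tabular path) and `subjectMap`, or `fixture = TRUE` with
#'   `originTaxa` (named taxon ids) to synthesize hits from the simulation
#'   ground truth; plus `taxonomy` (a [Taxonomy-class]) and optional
#'   `params` (an [lcaParams()]).
#' @param promotion Optional list: `enabled`, `libraryDir` (directory of
#'   candidate genomes named `<taxon name>.fa`, spaces as underscores) and
#'   `maxIterations` (>= 1; 1 disables re-mapping).
#' @param seed Integer seed for every stochastic stage.
#' @param outDir Optional output directory for reports and the manifest.
#' @return A `list` with class `"RunConfig"`.
#' @export
afsConfig <- function(panel, reads, strategy = "quant", schedule = NULL,
                      applyQualityFactor = TRUE, sizeNormalize = FALSE,
                      minReadLength = 50L, targets = NULL,
                      subsample = NULL, lca = NULL,
                      promotion = list(enabled = FALSE, libraryDir = NULL,
                                       maxIterations = 2L),
                      seed = 1L, outDir = NULL) {
    if (is.null(promotion$maxIterations))
        promotion$maxIterations <- 2L
    if (is.null(promotion$enabled))
        promotion$enabled <- FALSE
    if (promotion$maxIterations < 1L)
        stop("maxIterations must be >= 1")
    structure(list(panel = panel, reads = reads,
                   quant = quantConfig(strategy = strategy,
                                       schedule = schedule,
                                       applyQualityFactor = applyQualityFactor,
                                       sizeNormalize = sizeNormalize),
                   minReadLength = as.integer(minReadLength),
                   targets = targets, subsample = subsample, lca = lca,
                   promotion = promotion, seed = as.integer(seed),
                   outDir = outDir),
              class = "RunConfig")
}

#' Run the full quantification pipeline
#'
#' Stages: length filter, (optional) subsampling, iterative mapping,
#' multi-read redistribution, quality correction, proportion report;
#' residual unmapped reads are classified by the LCA stage when configured,
#' and taxa flagged for promotion whose genomes exist in the panel library
#' are added to the panel for another mapping iteration (up to
#' `maxIterations`). Read-count conservation is asserted at every stage
#' transition and recorded in the manifest.
#'
#' @param config A [afsConfig()].
#' @return A list with `report` (final [ProportionReport-class]),
#'   `assignment` (final [AssignmentTable-class]), `taxonSummary`
#'   ([TaxonSummary-class] or `NULL`), `iterations` (per-iteration reports),
#'   `promoted` (genome names added by the loop) and `manifest`.
#' @export
runAFS <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    panel <- config$panel
    if (is.character(panel))
        panel <- readPanel(panel)
    if (length(panel) == 0L)
        stop("stage panel: empty genome panel")
    reads <- config$reads
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- readReads(reads)
    nInput <- length(if (is(reads, "TaggedReadSet")) reads@reads else reads)

    flt <- lengthFilter(reads, config$minReadLength)
    reads <- flt$reads
    stopifnot(flt$retained + flt$removed == nInput)
    if (!is.null(config$subsample)) {
        rv <- if (is(reads, "TaggedReadSet")) names(reads@reads)
              else names(.readVector(reads))
        keep <- withSeed(childSeed(config$seed, 1L),
                         sample(rv, min(config$subsample, length(rv))))
        reads <- if (is(reads, "TaggedReadSet")) subsetReads(reads, keep)
                 else .readVector(reads)[keep]
    }
    nRetained <- length(if (is(reads, "TaggedReadSet")) reads@reads
                        else reads)

    iterations <- list()
    promoted <- character(0)
    taxonSummary <- NULL
    iter <- 1L
    repeat {
        q <- quantifySample(reads, panel, config$quant,
                            targets = config$targets)
        tc <- statusCounts(q$assignment)
        stopifnot(sum(tc) == nRetained)
        iterations[[iter]] <- q
        unmappedIds <- unmappedReads(q$assignment)

        if (!is.null(config$lca) && length(unmappedIds) > 0L) {
            taxonSummary <- .runLcaStage(config, reads, unmappedIds)
            foldMode <- if (is.null(config$lca$params)) "fold"
                        else config$lca$params$foldMode
            if (foldMode == "fold")
                stopifnot(sum(taxonCounts(taxonSummary)$reads) +
                          taxonSummary@unassigned +
                          taxonSummary@lowComplexity ==
                          length(unmappedIds))
        }
        canPromote <- config$promotion$enabled &&
            iter < config$promotion$maxIterations &&
            !is.null(taxonSummary) && length(promotions(taxonSummary)) > 0L
        if (!canPromote)
            break
        newGenomes <- .lookupPanelLibrary(promotions(taxonSummary),
                                          config$promotion$libraryDir,
                                          panelNames(panel))
        if (length(newGenomes) == 0L) {
            message("promotion recommended for: ",
                    paste(promotions(taxonSummary), collapse = ", "),
                    " but no genome found in the panel library")
            break
        }
        add <- readPanel(unlist(newGenomes))
        panel <- GenomePanel(c(panel@sequences, add@sequences))
        promoted <- c(promoted, panelNames(add))
        iter <- iter + 1L
    }
    final <- iterations[[length(iterations)]]
    manifest <- list(
        seed = config$seed,
        strategy = config$quant$strategy,
        schedule = config$quant$schedule,
        minReadLength = config$minReadLength,
        panel = panelNames(panel),
        promoted = promoted,
        stages = list(input = nInput, filtered = flt$removed,
                      retained = nRetained,
                      unique = as.integer(statusCounts(final$assignment)[["unique"]]),
                      multi = as.integer(statusCounts(final$assignment)[["multi"]]),
                      unmapped = as.integer(statusCounts(final$assignment)[["unmapped"]])),
        iterations = length(iterations),
        version = as.character(utils::packageVersion("AFSeq")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    out <- list(report = final$report, assignment = final$assignment,
                taxonSummary = taxonSummary, iterations = iterations,
                promoted = promoted, manifest = manifest)
    if (!is.null(config$outDir))
        .writeRunOutputs(out, reads, config$outDir)
    out
}

.runLcaStage <- function(config, reads, unmappedIds) {
    lc <- config$lca
    if (is.null(lc$params))
        lc$params <- lcaParams()
    unmapped <- if (is(reads, "TaggedReadSet"))
        subsetReads(reads, unmappedIds)
    else
        .readVector(reads)[unmappedIds]
    if (!is.null(lc$hits)) {
        hits <- parseM8(lc$hits, lc$subjectMap,
                        maxHitsPerRead = lc$params$maxHitsPerRead)
        hits <- hits[hits$read_id %in% unmappedIds, , drop = FALSE]
    } else if (isTRUE(lc$fixture)) {
        path <- tempfile(fileext = ".m8")
        fx <- makeM8Fixture(unmapped, lc$taxonomy, lc$originTaxa, path,
                            seed = childSeed(config$seed, 2L))
        hits <- parseM8(path, fx$subjectMap,
                        maxHitsPerRead = lc$params$maxHitsPerRead)
        unlink(path)
    } else {
        stop("lca config needs either a hits file or fixture = TRUE")
    }
    assigned <- assignReads(hits, reads = unmapped, taxonomy = lc$taxonomy,
                            params = lc$params)
    stopifnot(nrow(assigned) == length(
        if (is(unmapped, "TaggedReadSet")) unmapped@reads else unmapped))
    summarizeTaxa(assigned, lc$taxonomy, lc$params)
}

## taxon name -> FASTA file in the panel library (spaces as underscores)
.lookupPanelLibrary <- function(taxa, libraryDir, have) {
    if (is.null(libraryDir))
        return(character(0))
    out <- character(0)
    for (t in setdiff(taxa, have)) {
        base <- file.path(libraryDir, gsub(" ", "_", t))
        for (ext in c(".fa", ".fasta")) {
            if (file.exists(paste0(base, ext))) {
                out[t] <- paste0(base, ext)
                break
            }
        }
    }
    out
}

.writeRunOutputs <- function(out, reads, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    tab <- reportTable(out$report)
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(v) round(v, 6))
    utils::write.table(tab, file.path(outDir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(tab, file.path(outDir, "report.json"),
                         dataframe = "rows", digits = NA)
    if (!is.null(out$taxonSummary)) {
        utils::write.table(taxonCounts(out$taxonSummary),
                           file.path(outDir, "taxa.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        writeLines(promotions(out$taxonSummary),
                   file.path(outDir, "promotions.txt"))
    }
    unmappedIds <- unmappedReads(out$assignment)
    if (is(reads, "TaggedReadSet") && length(unmappedIds))
        writeReads(subsetReads(reads, unmappedIds),
                   file.path(outDir, "unmapped.fastq"))
    jsonlite::write_json(out$manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(outDir)
}

#' Run both mapping strategies on identical inputs
#'
#' Quantifies the same reads under AFS-quant (iterative, 0--3 mismatches)
#' and AFS-spec (single round, 0 mismatches) and reports them side by side,
#' the shape used to study the specificity/quantification trade-off with a
#' near-identical decoy genome in the panel.
#'
#' @param reads Reads (see [iterativeMap()]).
#' @param panel A [GenomePanel-class].
#' @param targets Optional named declared percentages.
#' @param applyQualityFactor Passed to both strategies.
#' @return A list with `quant` and `spec` (each as returned by
#'   [quantifySample()]) and `comparison`, a merged `data.frame` with one
#'   row per species and per-strategy proportion/difference columns.
#' @export
compareStrategies <- function(reads, panel, targets = NULL,
                              applyQualityFactor = TRUE) {
    rv <- .readVector(reads)
    resQ <- quantifySample(rv, panel,
                           quantConfig("quant",
                                       applyQualityFactor = applyQualityFactor),
                           targets = targets)
    resS <- quantifySample(rv, panel,
                           quantConfig("spec",
                                       applyQualityFactor = applyQualityFactor),
                           targets = targets)
    tq <- reportTable(resQ$report)
    ts <- reportTable(resS$report)
    comparison <- merge(tq, ts, by = "species",
                        suffixes = c("_quant", "_spec"), sort = TRUE)
    list(quant = resQ, spec = resS, comparison = comparison)
}
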