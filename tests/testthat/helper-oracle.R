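## Independent brute-force mapping oracle: exhaustive Hamming scan of every
## window on both strands of every genome, vectorised over window starts.
## An N (or any non-ACGT) reference position mismatches every read base.
bruteForceMap <- function(read, panel, k) {
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(read)))
    L <- nchar(read)
    out <- list()
    for (g in panelNames(panel)) {
        gs <- as.character(panel[[g]])
        n <- nchar(gs)
        if (n < L) next
        gb <- strsplit(gs, "")[[1]]
        notBase <- !(gb %in% c("A", "C", "G", "T"))
        nwin <- n - L + 1L
        for (orient in c("+", "-")) {
            rb <- strsplit(if (orient == "+") read else rc, "")[[1]]
            mm <- integer(nwin)
            for (s in 0:(L - 1L)) {
                idx <- (1L + s):(nwin + s)
                mm <- mm + as.integer(gb[idx] != rb[s + 1L] | notBase[idx])
            }
            hit <- which(mm <= k)
            if (length(hit))
                out[[length(out) + 1L]] <-
                    data.frame(genome = g, position = hit, strand = orient,
                               mismatches = mm[hit],
                               stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L)
        return(data.frame(genome = character(0), position = integer(0),
                          strand = character(0), mismatches = integer(0),
                          stringsAsFactors = FALSE))
    df <- do.call(rbind, out)
    df[order(df$genome, df$position, df$strand), , drop = FALSE]
}

## canonical sortable form of an alignment data.frame for set comparison
alignmentKey <- function(df) {
    sort(paste(df$genome, df$position, df$strand, df$mismatches, sep = ":"))
}

## plant exactly n substitution errors at distinct positions of a sequence
plantErrors <- function(seq, n) {
    if (n == 0L) return(seq)
    b <- strsplit(seq, "")[[1]]
    pos <- sample.int(length(b), n)
    for (p in pos) {
        others <- setdiff(c("A", "C", "G", "T"), b[p])
        b[p] <- sample(others, 1L)
    }
    paste(b, collapse = "")
}
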