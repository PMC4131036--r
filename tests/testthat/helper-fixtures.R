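## Small hand-built taxonomy used across the LCA tests:
## root(1) -> Animalia(2) -> Bovidae(10) -> cattle(11), sheep(12)
##                        -> Suidae(20)  -> pig(21)
##         -> Bacteria(3)  -> Enterobacteriaceae(30) -> Ecoli(31)
tinyTaxonomy <- function() {
    Taxonomy(id     = c(1L, 2L, 3L, 10L, 11L, 12L, 20L, 21L, 30L, 31L),
             parent = c(1L, 1L, 1L, 2L,  10L, 10L, 2L,  20L, 3L,  30L),
             rank = c("root", "kingdom", "kingdom", "family", "species",
                      "species", "family", "species", "family", "species"),
             name = c("root", "Animalia", "Bacteria", "Bovidae", "cattle",
                      "sheep", "Suidae", "pig", "Enterobacteriaceae",
                      "Ecoli"))
}

## three related 50 kb genomes (pairwise divergence ~9.7%) for mid-size tests
smallPanel <- function(len = 5e4, divergence = 0.05, seed = 400) {
    specs <- list(
        genomeSpec("A", len, divergence = divergence, group = "grp",
                   seed = seed + 1L),
        genomeSpec("B", len, divergence = divergence, group = "grp",
                   seed = seed + 2L),
        genomeSpec("C", len, divergence = divergence, group = "grp",
                   seed = seed + 3L))
    generatePanel(specs, ancestorSeed = seed)
}

## write a 12-column tabular hit file from a data.frame of partial columns
writeM8 <- function(df, path) {
    full <- data.frame(q = df$q, s = df$s,
                       pident = df$pident %||% 99,
                       len = df$len %||% 100L,
                       mism = 1L, gap = 0L, qs = 1L, qe = 100L,
                       ss = 1L, se = 100L,
                       evalue = 1e-20, bits = df$bits)
    write.table(full, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
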