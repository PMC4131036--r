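## Internal helpers shared across modules.

.BASES <- charToRaw("ACGT")

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is untouched. seed = NULL means "use current stream".
withSeed <- function(seed, code) {
    if (is.null(seed))
        return(force(code))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    force(code)
}

## Largest-remainder (Hamilton) allocation of `total` items at percentages
## `props` (summing to 100); exact when round(p/100 * total) already sums.
largestRemainder <- function(props, total) {
    stopifnot(total > 0, all(props >= 0))
    raw <- props / 100 * total
    base <- floor(raw)
    left <- as.integer(round(total - sum(base)))
    if (left > 0L) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
        base[extra] <- base[extra] + 1L
    }
    out <- as.integer(base)
    names(out) <- names(props)
    out
}

## Uniform random DNA as raw bytes at a target GC fraction.
randomDnaRaw <- function(n, gc = 0.5) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    sample(.BASES, n, replace = TRUE, prob = p)
}

## Substitute each position independently with probability `rate`, drawing
## the replacement uniformly from the three other bases.
mutateRaw <- function(x, rate) {
    if (rate <= 0)
        return(x)
    nmut <- stats::rbinom(1L, length(x), rate)
    if (nmut == 0L)
        return(x)
    pos <- sample.int(length(x), nmut)
    idx <- match(x[pos], .BASES)
    shift <- sample.int(3L, nmut, replace = TRUE)
    x[pos] <- .BASES[((idx - 1L + shift) %% 4L) + 1L]
    x
}

## Overwrite non-overlapping blocks with N until ~`round(fraction * len)`
## positions are masked; block lengths are geometric with the given mean,
## the final block truncated to land on the target exactly.
maskRawN <- function(x, fraction, blockMean = 1000) {
    len <- length(x)
    target <- round(fraction * len)
    if (target <= 0L)
        return(x)
    lens <- integer(0)
    while (sum(lens) < target)
        lens <- c(lens, stats::rgeom(1L, 1 / blockMean) + 1L)
    lens[length(lens)] <- lens[length(lens)] - (sum(lens) - target)
    lens <- lens[lens > 0L]
    free <- len - sum(lens)
    if (free < 0L)
        stop("n_fraction too large for genome length")
    gaps <- sort(sample.int(free + 1L, length(lens), replace = TRUE) - 1L)
    starts <- gaps + c(0L, cumsum(lens[-length(lens)])) + 1L
    for (i in seq_along(lens))
        x[starts[i]:(starts[i] + lens[i] - 1L)] <- as.raw(78L)  # 'N'
    x
}

## 1-based start positions at which a window of `width` bases is N-free.
validWindowStarts <- function(seqChar, width) {
    bytes <- charToRaw(seqChar)
    len <- length(bytes)
    if (len < width)
        return(integer(0))
    isN <- as.integer(!(bytes %in% .BASES))
    cs <- c(0L, cumsum(isN))
    n <- len - width + 1L
    starts <- seq_len(n)
    starts[cs[starts + width] - cs[starts] == 0L]
}

## Derive a child seed from a base seed, kept inside 32-bit integer range.
childSeed <- function(seed, offset) {
    if (is.null(seed))
        return(NULL)
    as.integer((as.double(seed) * 1103L + offset) %% 2147483587)
}
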