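# Internal helpers shared across modules.

# Evaluate expr with a locally-seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("seed must be a single integer")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Split a sequence (character scalar or XString) into single characters.
seqChars <- function(x) strsplit(toupper(as.character(x)), "")[[1L]]

# Split a gapless nucleotide string into codons; errors on partial codons.
splitCodons <- function(x) {
    s <- toupper(as.character(x))
    n <- nchar(s)
    if (n %% 3L != 0L)
        stop(sprintf("sequence length %d is not a multiple of 3", n))
    substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Translate one codon with the standard code; non-ACGT codons give "X".
codonAA <- function(codon) {
    aa <- Biostrings::GENETIC_CODE[codon]
    ifelse(is.na(aa), "X", aa)
}

# Empty disruption table with the canonical columns.
emptyDisruptions <- function() {
    data.frame(kind = character(), refPos = integer(),
               indelLen = integer(), note = character(),
               stringsAsFactors = FALSE)
}

disruptionRow <- function(kind, refPos, indelLen = 0L, note = "") {
    data.frame(kind = kind, refPos = as.integer(refPos),
               indelLen = as.integer(indelLen), note = note,
               stringsAsFactors = FALSE)
}
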