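#' Human nuclear codon frequency table
#'
#' Standard human nuclear codon usage (per-thousand counts over coding
#' sequences, scaled to frequencies). This is the widely used GenBank-derived
#' table; an alternative table can be supplied to the scoring functions,
#' since published tables differ slightly by source.
#'
#' @return named numeric vector over the 64 codons, summing to 1.
#' @export
humanCodonFreqs <- function() {
    per1000 <- c(
        TTT = 17.6, TTC = 20.3, TTA = 7.7, TTG = 12.9,
        CTT = 13.2, CTC = 19.6, CTA = 7.2, CTG = 39.6,
        ATT = 16.0, ATC = 20.8, ATA = 7.5, ATG = 22.0,
        GTT = 11.0, GTC = 14.5, GTA = 7.1, GTG = 28.1,
        TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG = 4.4,
        CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
        ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1,
        GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG = 7.4,
        TAT = 12.2, TAC = 15.3, TAA = 1.0, TAG = 0.8,
        CAT = 10.9, CAC = 15.1, CAA = 12.3, CAG = 34.2,
        AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
        GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6,
        TGT = 10.6, TGC = 12.6, TGA = 1.6, TGG = 13.2,
        CGT = 4.5, CGC = 10.4, CGA = 6.2, CGG = 11.4,
        AGT = 12.1, AGC = 19.5, AGA = 12.2, AGG = 12.0,
        GGT = 10.8, GGC = 22.2, GGA = 16.5, GGG = 16.5)
    per1000 / sum(per1000)
}

# Validate a codon table; optionally renormalize over the 61 sense codons.
.senseFreqs <- function(table, renormalize = TRUE) {
    if (is.null(names(table)) || !all(nchar(names(table)) == 3L))
        stop("codon table must be named by triplets")
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    miss <- setdiff(sense, names(table))
    if (length(miss))
        stop("codon table lacks codons: ", paste(utils::head(miss, 5L),
            collapse = ", "))
    f <- table[sense]
    if (any(f < 0)) stop("codon frequencies must be non-negative")
    if (renormalize) f / sum(f) else f
}

#' Codon usage bias score
#'
#' Guigo-style log-likelihood ratio of a coding sequence against a uniform
#' null: the product of table frequencies of its codons over the product of
#' the null frequency 1/64, reported as the per-codon mean so that scores
#' of genes of different lengths are comparable,
#' \deqn{s = \frac{1}{n}\sum_{i=1}^{n} \log\frac{F(C_i)}{1/64}.}
#' Table frequencies are renormalized over the 61 sense codons; the
#' terminal stop codon must be removed before scoring.
#'
#' @param cds coding nucleotide sequence (character or \code{DNAString}),
#'   length a multiple of 3, no stop codons.
#' @param table codon frequency table (default \code{\link{humanCodonFreqs}}).
#' @param logBase base of the logarithm (default natural log).
#' @param normalize divide by the number of codons (default \code{TRUE});
#'   \code{FALSE} returns the raw sum, which is additive over concatenation.
#' @param pseudocount added to every sense-codon frequency before
#'   renormalization; the default 0 makes a zero-frequency codon in the
#'   sequence an error.
#' @param renormalizeSense renormalize table frequencies to sum to 1 over
#'   the 61 sense codons (default \code{TRUE}); set \code{FALSE} to use
#'   the table frequencies exactly as given, e.g. for a literal uniform
#'   1/64 null.
#' @return the bias score (0 for a uniform table).
#' @examples
#' unif <- stats::setNames(rep(1 / 64, 64), names(Biostrings::GENETIC_CODE))
#' codonUsageScore("AAAGGG", table = unif, renormalizeSense = FALSE)  # 0
#' codonUsageScore("AAAGGG", table = c(AAA = 0.04, GGG = 0.01,
#'     humanCodonFreqs()[-c(43, 64)]), renormalizeSense = FALSE)
#' @export
codonUsageScore <- function(cds, table = humanCodonFreqs(),
                            logBase = exp(1), normalize = TRUE,
                            pseudocount = 0, renormalizeSense = TRUE) {
    codons <- splitCodons(cds)
    if (any(codons %in% STOP_CODONS))
        stop("sequence contains a stop codon; remove the terminal stop before scoring")
    f <- .senseFreqs(table, renormalizeSense)
    if (pseudocount > 0) {
        f <- f + pseudocount
        if (renormalizeSense) f <- f / sum(f)
    }
    fr <- f[codons]
    if (anyNA(fr))
        stop("sequence contains non-ACGT codons: ",
            paste(unique(codons[is.na(fr)]), collapse = ", "))
    if (any(fr == 0))
        stop("zero-frequency codon ", paste(unique(codons[fr == 0]),
            collapse = ", "), "; set a pseudocount to score it")
    s <- sum(log(fr * 64, base = logBase))
    if (normalize) s / length(codons) else s
}

#' Permutation significance of a codon usage score
#'
#' Reshuffles the nucleotides of the sequence uniformly at random (so every
#' permutation preserves length and base composition), rescores each
#' permutation in frame, and reports the frequency of permutation scores at
#' least as large as the observed score. Permutations that happen to contain
#' in-frame stop codons are scored like any other sequence (no rejection);
#' the raw frequency is reported, so the smallest attainable p-value is
#' \code{1/nReps}.
#'
#' @inheritParams codonUsageScore
#' @param nReps number of reshuffling replicates (default 10000).
#' @param seed RNG seed; results are bit-reproducible given the seed.
#' @return a \code{\link{CodonUsageResult-class}} object.
#' @examples
#' res <- reshufflePvalue("ATGGCCGCCAAGAAG", nReps = 200, seed = 1)
#' res
#' @export
reshufflePvalue <- function(cds, table = humanCodonFreqs(), nReps = 10000,
                            seed = 1, logBase = exp(1), pseudocount = 0,
                            renormalizeSense = TRUE) {
    if (nReps <= 0) stop("nReps must be positive")
    score1 <- function(chars) {
        codons <- paste(chars[c(TRUE, FALSE, FALSE)],
                        chars[c(FALSE, TRUE, FALSE)],
                        chars[c(FALSE, FALSE, TRUE)], sep = "")
        mean(log(f[codons] * 64, base = logBase))
    }
    chars <- seqChars(cds)
    if (length(chars) %% 3L != 0L)
        stop("sequence length must be a multiple of 3")
    f <- .senseFreqs(table, renormalizeSense)
    if (pseudocount > 0) {
        f <- f + pseudocount
        if (renormalizeSense) f <- f / sum(f)
    }
    # permuted sequences may contain stop codons; give stops their table
    # frequency so they are scored rather than rejected
    full <- table[names(Biostrings::GENETIC_CODE)]
    names(full) <- names(Biostrings::GENETIC_CODE)
    full[names(f)] <- f
    full[is.na(full)] <- 0
    f <- full
    observed <- codonUsageScore(cds, table = table, logBase = logBase,
        pseudocount = pseudocount, renormalizeSense = renormalizeSense)
    perm <- withSeed(seed, vapply(seq_len(nReps), function(i)
        score1(sample(chars)), 0))
    if (anyNA(perm))
        stop("zero-frequency codon arose in a permutation; set a pseudocount")
    p <- sum(perm >= observed) / nReps
    methods::new("CodonUsageResult", score = observed, pValue = p,
        nReps = as.integer(nReps), seed = as.integer(seed))
}
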