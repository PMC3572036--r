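# NG86-style counting estimation of synonymous / nonsynonymous rates.

#' Jukes-Cantor multiple-hit correction
#'
#' @param p observed proportion of differing sites, \code{0 <= p < 0.75}.
#' @return corrected distance \code{-(3/4) * log(1 - 4p/3)}.
#' @examples
#' jcCorrect(0.3)   # 0.3831...
#' @export
jcCorrect <- function(p) {
    if (any(p < 0)) stop("proportion must be non-negative")
    if (any(p >= 0.75))
        stop("proportion >= 0.75: Jukes-Cantor correction saturates")
    -0.75 * log(1 - 4 * p / 3)
}

# Synonymous fraction of mutational opportunity per codon position:
# s[pos] = (# of the 3 single-base changes at pos that preserve the amino
# acid) / 3. Changes to stop codons count as nonsynonymous.
.codonSiteFractions <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        gc <- Biostrings::GENETIC_CODE
        bases <- c("A", "C", "G", "T")
        codons <- names(gc)
        m <- matrix(0, length(codons), 3L, dimnames = list(codons, NULL))
        for (cd in codons) {
            ch <- strsplit(cd, "")[[1L]]
            for (pos in 1:3) {
                syn <- 0L
                for (b in setdiff(bases, ch[pos])) {
                    alt <- ch; alt[pos] <- b
                    altc <- paste(alt, collapse = "")
                    if (gc[altc] != "*" && gc[altc] == gc[cd]) syn <- syn + 1L
                }
                m[cd, pos] <- syn / 3
            }
        }
        cache <<- m
        m
    }
})

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# codons: all orderings of the differing positions, equal weights. A step
# is synonymous when it preserves the amino acid (stop treated as the "*"
# residue, so a step into or out of a stop is nonsynonymous unless both
# codons are stops).
.codonPairDiffs <- function(c1, c2) {
    if (c1 == c2) return(c(syn = 0, nonsyn = 0))
    ch1 <- strsplit(c1, "")[[1L]]
    ch2 <- strsplit(c2, "")[[1L]]
    pos <- which(ch1 != ch2)
    gc <- Biostrings::GENETIC_CODE
    perms <- function(v) {
        if (length(v) <= 1L) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (rest in perms(v[-i]))
                out[[length(out) + 1L]] <- c(v[i], rest)
        out
    }
    paths <- perms(pos)
    syn <- 0; nonsyn <- 0
    for (path in paths) {
        cur <- ch1
        for (p in path) {
            nxt <- cur; nxt[p] <- ch2[p]
            if (gc[paste(cur, collapse = "")] == gc[paste(nxt, collapse = "")])
                syn <- syn + 1
            else nonsyn <- nonsyn + 1
            cur <- nxt
        }
    }
    c(syn = syn / length(paths), nonsyn = nonsyn / length(paths))
}

#' NG86 site and difference counts for a pair of codon sequences
#'
#' Counts synonymous and nonsynonymous sites by per-position mutational
#' opportunity (averaged over the two sequences) and synonymous and
#' nonsynonymous differences with equal-weight averaging over all minimal
#' mutational pathways for multi-difference codons.
#'
#' @param seq1,seq2 gapless nucleotide sequences of equal length, a
#'   multiple of 3.
#' @return named numeric vector \code{synSites}, \code{nonsynSites},
#'   \code{synDiffs}, \code{nonsynDiffs}; sites sum to 3 x codons.
#' @examples
#' ng86Counts("TTT", "TTC")   # one synonymous difference (Phe/Phe)
#' @export
ng86Counts <- function(seq1, seq2) {
    cd1 <- splitCodons(seq1)
    cd2 <- splitCodons(seq2)
    if (length(cd1) != length(cd2))
        stop("sequences differ in length")
    sf <- .codonSiteFractions()
    s1 <- sum(sf[cd1, , drop = FALSE])
    s2 <- sum(sf[cd2, , drop = FALSE])
    synSites <- (s1 + s2) / 2
    nonsynSites <- 3 * length(cd1) - synSites
    d <- c(syn = 0, nonsyn = 0)
    for (i in seq_along(cd1))
        d <- d + .codonPairDiffs(cd1[i], cd2[i])
    c(synSites = synSites, nonsynSites = nonsynSites,
      synDiffs = unname(d["syn"]), nonsynDiffs = unname(d["nonsyn"]))
}

# Drop codon columns containing a gap or non-ACGT character in any sequence.
.filterCodonColumns <- function(seqs) {
    mats <- lapply(seqs, seqChars)
    len <- unique(lengths(mats))
    if (length(len) != 1L) stop("aligned sequences differ in length")
    if (len %% 3L != 0L) stop("alignment length is not a multiple of 3")
    ok <- rep(TRUE, len %/% 3L)
    for (m in mats) {
        bad <- !m %in% c("A", "C", "G", "T")
        ok <- ok & !vapply(seq_len(len %/% 3L), function(k)
            any(bad[(3L * k - 2L):(3L * k)]), NA)
    }
    lapply(mats, function(m) {
        keep <- rep(ok, each = 3L)
        paste(m[keep], collapse = "")
    })
}

.kaksFromCounts <- function(cnt, strict = TRUE) {
    pS <- if (cnt["synSites"] > 0) cnt["synDiffs"] / cnt["synSites"] else 0
    pN <- if (cnt["nonsynSites"] > 0) cnt["nonsynDiffs"] / cnt["nonsynSites"] else 0
    if (!strict && (pS >= 0.75 || pN >= 0.75))
        return(c(ka = NA_real_, ks = NA_real_))
    c(ka = unname(jcCorrect(pN)), ks = unname(jcCorrect(pS)))
}

#' Ka/Ks with a Monte-Carlo confidence interval
#'
#' Computes NG86 counts for the reference against every other species of a
#' codon alignment, pools the counts (sums across pairs), converts the
#' pooled proportions to Ka and Ks with the Jukes-Cantor correction, and
#' attaches a parametric Monte-Carlo 95\% confidence interval: \code{nSim}
#' pairs of binomial difference counts are redrawn at the estimated
#' per-site proportions and re-estimated, and the 2.5/97.5 percentiles of
#' the simulated ratios are reported. Codon columns with a gap or
#' ambiguous base in any retained species are dropped before counting.
#'
#' @param aln named list or character vector of aligned codon sequences
#'   (equal lengths, multiple of 3; gaps allowed and filtered listwise),
#'   or a \code{DNAStringSet}.
#' @param refSpecies name of the reference sequence.
#' @param nSim number of Monte-Carlo simulations (default 1000).
#' @param seed RNG seed.
#' @return a \code{\link{KaKsResult-class}}; the ratio is \code{NA} and the
#'   CI omitted when Ks = 0.
#' @examples
#' aln <- c(hu = "ATGAAACGTTTGGCC", ch = "ATGAAGCGATTGGCG",
#'          rh = "ATGAGACGTCTGGCC")
#' kaksWithCI(aln, "hu", nSim = 200, seed = 7)
#' @export
kaksWithCI <- function(aln, refSpecies, nSim = 1000, seed = 1) {
    if (methods::is(aln, "DNAStringSet"))
        aln <- stats::setNames(as.character(aln), names(aln))
    aln <- as.list(aln)
    if (length(aln) < 2L) stop("need at least two sequences")
    if (!refSpecies %in% names(aln))
        stop("reference '", refSpecies, "' not in alignment")
    seqs <- .filterCodonColumns(aln)
    others <- setdiff(names(seqs), refSpecies)
    pair <- lapply(others, function(sp)
        ng86Counts(seqs[[refSpecies]], seqs[[sp]]))
    names(pair) <- others
    pooled <- Reduce(`+`, pair)
    perPair <- do.call(rbind, lapply(others, function(sp) {
        kk <- .kaksFromCounts(pair[[sp]], strict = FALSE)
        data.frame(species = sp, ka = kk["ka"], ks = kk["ks"],
            ratio = if (!is.na(kk["ks"]) && kk["ks"] > 0)
                kk["ka"] / kk["ks"] else NA_real_,
            row.names = NULL, stringsAsFactors = FALSE)
    }))

    kk <- .kaksFromCounts(pooled)
    ka <- kk["ka"]; ks <- kk["ks"]
    if (ks == 0) {
        warning("Ks = 0: Ka/Ks undefined, confidence interval omitted")
        return(methods::new("KaKsResult", ka = unname(ka), ks = unname(ks),
            ratio = NA_real_, ciLow = NULL, ciHigh = NULL,
            nSim = as.integer(nSim), seed = as.integer(seed),
            perPair = perPair))
    }
    pS <- pooled["synDiffs"] / pooled["synSites"]
    pN <- pooled["nonsynDiffs"] / pooled["nonsynSites"]
    nS <- max(1L, round(pooled["synSites"]))
    nN <- max(1L, round(pooled["nonsynSites"]))
    sims <- withSeed(seed, {
        sdS <- stats::rbinom(nSim, nS, pS) / nS
        sdN <- stats::rbinom(nSim, nN, pN) / nN
        ok <- sdS < 0.75 & sdN < 0.75 & sdS > 0
        ifelse(ok, jcCorrect(pmin(sdN, 0.7499)) / jcCorrect(pmin(sdS, 0.7499)),
            NA_real_)
    })
    qs <- stats::quantile(sims, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    methods::new("KaKsResult", ka = unname(ka), ks = unname(ks),
        ratio = unname(ka / ks),
        ciLow = min(qs[1L], unname(ka / ks)),
        ciHigh = max(qs[2L], unname(ka / ks)),
        nSim = as.integer(nSim), seed = as.integer(seed), perPair = perPair)
}
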