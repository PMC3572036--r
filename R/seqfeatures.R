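# Promoter characterization, in-silico PCR, conservation-track summaries.
#
# TSS-relative coordinates follow promoter convention: the TSS base is +1,
# the base immediately upstream is -1, and there is no position 0.

# string index -> TSS-relative position
.toTssRel <- function(i, tssIndex) ifelse(i >= tssIndex,
    i - tssIndex + 1L, i - tssIndex)

# TSS-relative position -> string index
.fromTssRel <- function(p, tssIndex) ifelse(p > 0L,
    tssIndex + p - 1L, tssIndex + p)

#' GC content of a window centred on the TSS
#'
#' @param seq nucleotide sequence (character or \code{DNAString}).
#' @param tssIndex 1-based string index of the transcription start site.
#' @param halfwidth half-width of the window; the window spans
#'   \code{2 * halfwidth + 1} bases centred on the TSS.
#' @return fraction of G+C in the window.
#' @examples
#' gcWindow(strrep("AT", 150), 150, 100)   # 0
#' @export
gcWindow <- function(seq, tssIndex, halfwidth = 100) {
    s <- toupper(as.character(seq))
    lo <- tssIndex - halfwidth
    hi <- tssIndex + halfwidth
    if (lo < 1L || hi > nchar(s))
        stop(sprintf("window [%d, %d] exceeds sequence of length %d",
            lo, hi, nchar(s)))
    win <- substr(s, lo, hi)
    chars <- strsplit(win, "")[[1L]]
    sum(chars %in% c("G", "C", "g", "c")) / nchar(win)
}

#' Classify a promoter by GC content
#'
#' GC-poor promoters are typically TATA-dependent and insensitive to CpG
#' methylation; GC-rich promoters are CpG-island-like. The threshold is a
#' configurable convention and is recorded on the result.
#'
#' @param gc GC fraction in [0, 1].
#' @param threshold class boundary (default 0.45); \code{gc < threshold}
#'   is GC-poor, otherwise GC-rich (the boundary itself is GC-rich).
#' @return \code{"GC-poor"} or \code{"GC-rich"}, with the threshold in
#'   attribute \code{"threshold"}.
#' @examples
#' classifyPromoter(0.35)   # GC-poor
#' @export
classifyPromoter <- function(gc, threshold = 0.45) {
    if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
    structure(if (gc < threshold) "GC-poor" else "GC-rich",
        threshold = threshold)
}

#' Define a promoter motif
#'
#' @param name motif name.
#' @param consensus IUPAC consensus string.
#' @param windowMin,windowMax TSS-relative window for the motif start
#'   (positions skip 0: ... -2, -1, +1, +2 ...).
#' @return a \code{data.frame} row usable with \code{\link{scanMotifs}};
#'   rows can be \code{rbind}-ed into a motif set.
#' @export
motifDef <- function(name, consensus, windowMin, windowMax) {
    if (!nzchar(consensus)) stop("consensus must be non-empty")
    if (windowMin > windowMax) stop("windowMin must not exceed windowMax")
    if (windowMin == 0L || windowMax == 0L)
        stop("TSS-relative coordinates have no position 0")
    data.frame(name = name, consensus = toupper(consensus),
        windowMin = as.integer(windowMin), windowMax = as.integer(windowMax),
        stringsAsFactors = FALSE)
}

#' Canonical core-promoter motifs of the focal gene
#'
#' The TATA box, CCAAT box and initiator consensus strings with the
#' TSS-relative windows in which they are expected.
#'
#' @return a motif \code{data.frame} (see \code{\link{motifDef}}).
#' @export
corePromoterMotifs <- function() {
    rbind(
        motifDef("TATA", "GATATATTT", -40L, 40L),
        motifDef("CCAAT", "GCCAAT", -200L, -1L),
        motifDef("Inr", "AATCTAA", -60L, 60L))
}

#' Scan a promoter for IUPAC consensus motifs
#'
#' Exact IUPAC matching on the given strand via
#' \code{Biostrings::matchPattern(fixed = FALSE)}; a hit is reported when
#' the motif's TSS-relative start position falls inside its window.
#'
#' @param seq promoter sequence.
#' @param tssIndex 1-based string index of the TSS.
#' @param motifs motif \code{data.frame} from \code{\link{motifDef}} /
#'   \code{\link{corePromoterMotifs}}.
#' @return \code{data.frame} with columns \code{name}, \code{match}
#'   (matched text) and \code{tssPos} (TSS-relative start); empty when
#'   nothing matches.
#' @examples
#' prom <- paste0(strrep("A", 147), "GCCAAT", strrep("A", 100))
#' scanMotifs(prom, 200, motifDef("CCAAT", "GCCAAT", -200, -1))
#' @export
scanMotifs <- function(seq, tssIndex, motifs) {
    s <- Biostrings::DNAString(toupper(as.character(seq)))
    hits <- data.frame(name = character(), match = character(),
        tssPos = integer(), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(motifs))) {
        m <- Biostrings::matchPattern(motifs$consensus[i], s, fixed = FALSE)
        if (length(m) == 0L) next
        starts <- Biostrings::start(m)
        rel <- .toTssRel(starts, tssIndex)
        keep <- rel >= motifs$windowMin[i] & rel <= motifs$windowMax[i]
        if (!any(keep)) next
        hits <- rbind(hits, data.frame(name = motifs$name[i],
            match = as.character(m[keep]), tssPos = rel[keep],
            stringsAsFactors = FALSE))
    }
    rownames(hits) <- NULL
    hits
}

#' Annotate a promoter sequence
#'
#' Combines \code{\link{gcWindow}}, \code{\link{classifyPromoter}} and
#' \code{\link{scanMotifs}} into one annotation.
#'
#' @inheritParams scanMotifs
#' @param halfwidth GC window half-width (default 100).
#' @param threshold GC class threshold (default 0.45).
#' @return list with \code{gcContent}, \code{promoterClass} and
#'   \code{hits}.
#' @export
annotatePromoter <- function(seq, tssIndex, motifs = corePromoterMotifs(),
                             halfwidth = 100, threshold = 0.45) {
    gc <- gcWindow(seq, tssIndex, halfwidth)
    list(gcContent = gc,
         promoterClass = classifyPromoter(gc, threshold),
         hits = scanMotifs(seq, tssIndex, motifs))
}

#' In-silico PCR on a template sequence
#'
#' Finds exact matches of the forward primer on the template and of the
#' reverse-complemented reverse primer downstream of each, and reports the
#' lengths of all products up to \code{maxProduct}, sorted. Matching is
#' exact (no mismatches, no melting model): the intended use is predicting
#' amplicon sizes from a reference cDNA.
#'
#' @param template template sequence (character or \code{DNAString}).
#' @param fwdPrimer,revPrimer primer sequences, 5'-3', at least 10 nt.
#' @param maxProduct maximum reported product length (default 5000).
#' @return sorted integer vector of product lengths (empty when no
#'   product forms).
#' @examples
#' tmpl <- paste0("AAGGAACCAGAAATATGAGG", strrep("A", 317),
#'                as.character(Biostrings::reverseComplement(
#'                    Biostrings::DNAString("TTTGGATAAGTAGAGAAGAC"))))
#' insilicoPcr(tmpl, "AAGGAACCAGAAATATGAGG", "TTTGGATAAGTAGAGAAGAC") # 357
#' @export
insilicoPcr <- function(template, fwdPrimer, revPrimer, maxProduct = 5000) {
    if (nchar(fwdPrimer) < 10L || nchar(revPrimer) < 10L)
        stop("primers must be at least 10 nt")
    s <- Biostrings::DNAString(toupper(as.character(template)))
    fwd <- Biostrings::matchPattern(toupper(fwdPrimer), s)
    revrc <- Biostrings::reverseComplement(
        Biostrings::DNAString(toupper(revPrimer)))
    rev <- Biostrings::matchPattern(revrc, s)
    if (length(fwd) == 0L || length(rev) == 0L) return(integer())
    out <- integer()
    for (fs in Biostrings::start(fwd)) {
        ends <- Biostrings::end(rev)
        ok <- ends >= fs + nchar(fwdPrimer)
        len <- ends[ok] - fs + 1L
        out <- c(out, len[len <= maxProduct])
    }
    sort(unique(out))
}

#' Summarize a per-base conservation track
#'
#' Arithmetic mean and population (n-denominator) standard deviation of
#' per-base scores over an interval; missing values are skipped and their
#' count reported.
#'
#' @param values numeric vector of per-base scores (\code{NA} = missing).
#' @return named vector \code{mean}, \code{sd} with attributes
#'   \code{nUsed}, \code{nMissing} and \code{sdType = "population"}.
#' @examples
#' summarizeTrack(c(-1, 0, 1))   # mean 0, sd 0.8165
#' @export
summarizeTrack <- function(values) {
    miss <- sum(is.na(values))
    v <- values[!is.na(values)]
    if (length(v) == 0L) stop("no values left after skipping missing bases")
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    structure(c(mean = m, sd = s),
        nUsed = length(v), nMissing = miss, sdType = "population")
}
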