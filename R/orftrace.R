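#' Protein length from ORF nucleotide coordinates
#'
#' Number of amino acids encoded by a 1-based inclusive nucleotide span
#' that includes the terminal stop codon.
#'
#' @param cdsStart,cdsEnd 1-based inclusive ORF coordinates.
#' @return integer number of amino acids (stop excluded).
#' @examples
#' orfLengthAA(96, 503)   # 135
#' @export
orfLengthAA <- function(cdsStart, cdsEnd) {
    span <- cdsEnd - cdsStart + 1L
    if (span < 3L || span %% 3L != 0L)
        stop(sprintf("ORF span %d is not a positive multiple of 3", span))
    as.integer(span / 3L - 1L)
}

#' Fraction of the reference protein upstream of the first ORF disruption
#'
#' The protein-homology fraction is measured in coding nucleotides: the
#' bases strictly before the first disrupting event, over the coding length
#' excluding the stop codon. A lost start (event position 0) gives 0; an
#' intact ORF (no event) gives 1.
#'
#' @param firstEventPos 1-based reference CDS position of the first
#'   disruption (0 for a lost start; \code{codingLen + 1} when absent).
#' @param codingLen coding nucleotides excluding the stop codon.
#' @return fraction in [0, 1].
#' @examples
#' homologyFraction(12, 405)   # 11/405, rounds to 3%
#' @export
homologyFraction <- function(firstEventPos, codingLen) {
    if (firstEventPos < 0) stop("event position must be non-negative")
    if (codingLen <= 0) stop("coding length must be positive")
    if (firstEventPos == 0) return(0)
    min(1, max(0, (firstEventPos - 1) / codingLen))
}

# Per-column view of one species against the reference: for every column in
# the reference CDS span, the species char, the reference char, and the
# reference position (NA on insertion columns).
.speciesColumns <- function(aln, species) {
    cm <- aln@colMap
    span <- cm[1L]:cm[length(cm)]
    sp <- seqChars(aln@rows[[species]])[span]
    rf <- seqChars(aln@rows[[aln@refSpecies]])[span]
    refpos <- rep(NA_integer_, length(span))
    refpos[match(cm, span)] <- seq_along(cm)
    list(sp = sp, rf = rf, refpos = refpos)
}

#' Scan a species row for ORF-disrupting events
#'
#' Walks the reference CDS left to right and reports, in reference
#' coordinates, every event that disrupts translation of the
#' reference-homologous protein: loss of the codon-1 ATG, frameshifting
#' indel runs (each maximal gap run whose length is not a multiple of 3 is
#' an event of its own, so compensating indels are each reported), the
#' first premature in-frame stop, and the absence of any in-frame stop
#' through the aligned span (non-stop). The species sequence is translated
#' in the frame established by the start codon and shifted by the
#' cumulative indel offset; stops in other frames are ignored.
#'
#' The protein-homology fraction is determined by the first event alone
#' (see \code{\link{homologyFraction}}); the denominator is the coding
#' length without the stop codon.
#'
#' @param aln a \code{\link{CdsAlignment}} whose reference row is a valid
#'   ORF (ATG ... stop).
#' @param species species row to scan.
#' @param geneticCode named codon-to-AA map; default the standard code.
#' @return a \code{\link{SpeciesOrfReport-class}} object.
#' @examples
#' aln <- CdsAlignment(c(hg19 = "ATGAAACCCTAG",
#'                       mm9  = "ATGAAACC-TAG"), "hg19")
#' scanSpeciesOrf(aln, "mm9")
#' @export
scanSpeciesOrf <- function(aln, species, geneticCode = Biostrings::GENETIC_CODE) {
    stopifnot(methods::is(aln, "CdsAlignment"))
    if (!species %in% names(aln@rows))
        stop(sprintf("unknown species '%s'; available: %s", species,
            paste(names(aln@rows), collapse = ", ")))
    L <- aln@refLength
    refseq <- as.character(refCds(aln))
    refCodons <- splitCodons(refseq)
    if (refCodons[1L] != "ATG")
        stop("reference ORF invalid: CDS does not start with ATG")
    lastCodon <- refCodons[length(refCodons)]
    if (is.na(geneticCode[lastCodon]) || geneticCode[lastCodon] != "*")
        stop("reference ORF invalid: CDS does not end with a stop codon")

    v <- .speciesColumns(aln, species)
    events <- emptyDisruptions()

    ## start codon: species chars at reference positions 1..3
    startChars <- v$sp[match(1:3, v$refpos)]
    hasStart <- all(startChars == c("A", "T", "G"))
    if (!hasStart) {
        note <- if (all(startChars == "-")) "unaligned" else ""
        events <- rbind(events, disruptionRow("start_loss", 0L, 0L, note))
    }

    ## indel runs: species gaps over reference bases (deletions) and species
    ## bases over reference gaps (insertions); both-gap columns are inert
    isDel <- !is.na(v$refpos) & v$sp == "-"
    isIns <- is.na(v$refpos) & v$sp != "-" & v$rf == "-"
    runs <- rle(ifelse(isDel, "D", ifelse(isIns, "I", ".")))
    at <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
    for (r in seq_along(runs$lengths)) {
        len <- runs$lengths[r]
        if (runs$values[r] == "." || len %% 3L == 0L) next
        first <- at[r]; last <- at[r] + len - 1L
        if (runs$values[r] == "D") {
            events <- rbind(events,
                disruptionRow("frameshift_deletion", v$refpos[first], len))
        } else {
            # an insertion sits before the next reference base
            nxtpos <- suppressWarnings(min(v$refpos[seq(last, length(v$refpos))],
                na.rm = TRUE))
            if (!is.finite(nxtpos)) nxtpos <- L + 1L
            events <- rbind(events,
                disruptionRow("frameshift_insertion", nxtpos, len))
        }
    }

    ## translation in the cumulative-offset frame: concatenated species bases,
    ## each anchored to the reference position at or before its column
    baseIdx <- which(v$sp != "-")
    spSeq <- v$sp[baseIdx]
    anchor <- vapply(baseIdx, function(j) {
        p <- v$refpos[j]
        if (!is.na(p)) return(p)
        prior <- v$refpos[seq_len(j)]
        prior <- prior[!is.na(prior)]
        if (length(prior)) prior[length(prior)] else 0L
    }, 0L)
    nCodon <- length(spSeq) %/% 3L
    stopEvent <- NULL
    stopOrderPos <- NA_integer_
    foundTerminal <- FALSE
    for (k in seq_len(nCodon)) {
        codon <- paste(spSeq[(3L * k - 2L):(3L * k)], collapse = "")
        aa <- geneticCode[codon]
        if (is.na(aa) || aa != "*") next
        pos <- anchor[3L * k - 2L]
        if (pos < L - 2L) {
            stopEvent <- disruptionRow("premature_stop", max(pos, 1L), 0L)
            # a stop codon completes only at its last base: an indel inside
            # the codon's span precedes the stop in translation order even
            # when the stop's first base anchors upstream of it
            stopOrderPos <- anchor[3L * k]
        } else {
            foundTerminal <- TRUE
        }
        break
    }
    if (!is.null(stopEvent)) {
        events <- rbind(events, stopEvent)
    } else if (!foundTerminal && length(spSeq) > 0L) {
        events <- rbind(events, disruptionRow("nonstop", L + 1L, 0L))
    }

    events <- events[order(events$refPos, match(events$kind, .DISRUPTION_KINDS)), ,
        drop = FALSE]
    rownames(events) <- NULL

    codingLen <- L - 3L
    homology <- if (nrow(events) == 0L) 1 else {
        orderPos <- ifelse(events$kind == "premature_stop",
            stopOrderPos, events$refPos)
        first <- events$refPos[which.min(orderPos)]
        homologyFraction(min(first, codingLen + 1L), codingLen)
    }

    methods::new("SpeciesOrfReport",
        species = species,
        alignableFraction = alignableFraction(aln, species),
        proteinHomology = homology,
        disruptions = events,
        hasStart = hasStart)
}

#' Scan every species of an alignment
#'
#' The reference is included by default: its identity report (full
#' alignability, no disruptions) anchors downstream event placement, which
#' must not extend an event's clade through reference-only branches.
#'
#' @param aln a \code{CdsAlignment}.
#' @param geneticCode codon table passed to \code{\link{scanSpeciesOrf}}.
#' @param includeRef also report the reference species (default
#'   \code{TRUE}).
#' @return named list of \code{SpeciesOrfReport}, one per species.
#' @export
scanAllSpecies <- function(aln, geneticCode = Biostrings::GENETIC_CODE,
                           includeRef = TRUE) {
    sp <- names(aln@rows)
    if (!includeRef) sp <- setdiff(sp, aln@refSpecies)
    stats::setNames(lapply(sp, scanSpeciesOrf, aln = aln,
        geneticCode = geneticCode), sp)
}
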