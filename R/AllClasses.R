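#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#' @importFrom S4Vectors metadata metadata<-
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Reference-anchored multi-species alignment of a CDS
#'
#' A \code{CdsAlignment} holds a gapped multiple alignment of the coding
#' sequence of a focal gene, anchored to a designated reference species.
#' The reference row, once ungapped, is exactly the reference CDS
#' (stop codon included); \code{colMap} maps every 1-based reference CDS
#' position to the alignment column that carries it, so downstream code can
#' reason in reference coordinates while still seeing insertion columns
#' (reference gaps) between them.
#'
#' @slot refSpecies name of the reference species (must be a row).
#' @slot refLength reference CDS length in nucleotides, stop codon included.
#' @slot rows named \code{DNAStringSet} of equal-width gapped rows
#'   (gap character \code{"-"}).
#' @slot colMap integer vector of length \code{refLength}; strictly
#'   increasing alignment column indices of reference positions 1..refLength.
#'
#' @exportClass CdsAlignment
setClass("CdsAlignment",
    slots = c(
        refSpecies = "character",
        refLength  = "integer",
        rows       = "DNAStringSet",
        colMap     = "integer"
    )
)

setValidity("CdsAlignment", function(object) {
    msg <- character()
    rows <- object@rows
    if (length(object@refSpecies) != 1L)
        msg <- c(msg, "refSpecies must be a single species name")
    if (is.null(names(rows)) || anyDuplicated(names(rows)))
        msg <- c(msg, "rows must be uniquely named by species")
    if (length(msg)) return(msg)
    if (!object@refSpecies %in% names(rows))
        return(sprintf("reference species '%s' is not a row", object@refSpecies))
    w <- unique(Biostrings::width(rows))
    if (length(w) != 1L)
        return("all rows must have equal gapped length")
    refchars <- strsplit(as.character(rows[[object@refSpecies]]), "")[[1L]]
    ungapped <- sum(refchars != "-")
    if (ungapped != object@refLength)
        msg <- c(msg, sprintf(
            "ungapped reference row has %d nt, expected refLength = %d",
            ungapped, object@refLength))
    cm <- object@colMap
    if (length(cm) != object@refLength)
        msg <- c(msg, "colMap must have one entry per reference CDS position")
    else {
        if (any(diff(cm) <= 0L))
            msg <- c(msg, "colMap must be strictly increasing")
        if (any(cm < 1L) || any(cm > w))
            msg <- c(msg, "colMap indices outside alignment columns")
        else if (any(refchars[cm] == "-"))
            msg <- c(msg, "colMap points at gap columns of the reference row")
    }
    if (length(msg)) msg else TRUE
})

#' Per-species ORF integrity report
#'
#' Produced by \code{\link{scanSpeciesOrf}}: the alignable fraction of the
#' reference CDS, the fraction of the reference protein N-terminal to the
#' first ORF disruption, and the ordered table of disruptions themselves.
#'
#' @slot species species name.
#' @slot alignableFraction fraction of reference CDS positions at which the
#'   species contributes an aligned (non-gap, non-N) base.
#' @slot proteinHomology fraction of the reference protein upstream of the
#'   first ORF disruption (1 for an intact ORF, 0 for a lost start).
#' @slot disruptions data.frame with columns \code{kind}, \code{refPos},
#'   \code{indelLen}, \code{note}, sorted by \code{refPos}.
#' @slot hasStart whether the species carries an intact ATG at codon 1.
#'
#' @exportClass SpeciesOrfReport
setClass("SpeciesOrfReport",
    slots = c(
        species           = "character",
        alignableFraction = "numeric",
        proteinHomology   = "numeric",
        disruptions       = "data.frame",
        hasStart          = "logical"
    )
)

.DISRUPTION_KINDS <- c("start_loss", "frameshift_insertion",
    "frameshift_deletion", "premature_stop", "nonstop")

setValidity("SpeciesOrfReport", function(object) {
    msg <- character()
    d <- object@disruptions
    need <- c("kind", "refPos", "indelLen", "note")
    if (!all(need %in% names(d)))
        return(sprintf("disruptions must have columns %s",
            paste(need, collapse = ", ")))
    if (!all(d$kind %in% .DISRUPTION_KINDS))
        msg <- c(msg, "unknown disruption kind")
    if (is.unsorted(d$refPos))
        msg <- c(msg, "disruptions must be sorted by refPos")
    fs <- d$kind %in% c("frameshift_insertion", "frameshift_deletion")
    if (any(d$indelLen[fs] %% 3L == 0L))
        msg <- c(msg, "frameshift indelLen must not be a multiple of 3")
    if (object@alignableFraction < 0 || object@alignableFraction > 1)
        msg <- c(msg, "alignableFraction outside [0,1]")
    if (object@proteinHomology < 0 || object@proteinHomology > 1)
        msg <- c(msg, "proteinHomology outside [0,1]")
    if (!object@hasStart && object@proteinHomology != 0)
        msg <- c(msg, "proteinHomology must be 0 when the start codon is lost")
    if (nrow(d) == 0L && object@proteinHomology != 1)
        msg <- c(msg, "proteinHomology must be 1 when there are no disruptions")
    if (length(msg)) msg else TRUE
})

#' Codon usage bias score with permutation significance
#'
#' @slot score per-codon mean log-likelihood ratio against the uniform
#'   1/64 null.
#' @slot pValue permutation p-value (raw frequency; minimum reportable
#'   value is 1/nReps).
#' @slot nReps number of reshuffling replicates the p-value is based on.
#' @slot seed RNG seed used for the replicates.
#'
#' @exportClass CodonUsageResult
setClass("CodonUsageResult",
    slots = c(score = "numeric", pValue = "numeric",
              nReps = "integer", seed = "integer"))

setValidity("CodonUsageResult", function(object) {
    if (object@pValue < 0 || object@pValue > 1) "pValue outside [0,1]"
    else if (object@nReps < 1L) "nReps must be positive"
    else TRUE
})

#' Ka/Ks estimate with Monte-Carlo confidence interval
#'
#' @slot ka nonsynonymous substitutions per nonsynonymous site.
#' @slot ks synonymous substitutions per synonymous site.
#' @slot ratio Ka/Ks, or \code{NA} when Ks = 0.
#' @slot ciLow,ciHigh 2.5/97.5 Monte-Carlo percentiles of the ratio
#'   (\code{NULL} when the ratio is undefined).
#' @slot nSim number of Monte-Carlo simulations.
#' @slot seed RNG seed.
#' @slot perPair per-pair Ka/Ks table (reference vs each other species).
#'
#' @exportClass KaKsResult
setClass("KaKsResult",
    slots = c(ka = "numeric", ks = "numeric", ratio = "numeric",
              ciLow = "numericOrNULL", ciHigh = "numericOrNULL",
              nSim = "integer", seed = "integer", perPair = "data.frame"))

setValidity("KaKsResult", function(object) {
    if (object@ka < 0 || object@ks < 0)
        return("ka and ks must be non-negative")
    if (!is.na(object@ratio) && !is.null(object@ciLow) &&
        !is.null(object@ciHigh) &&
        !anyNA(c(object@ciLow, object@ciHigh))) {
        if (object@ciLow > object@ratio || object@ciHigh < object@ratio)
            return("confidence interval must bracket the point estimate")
    }
    TRUE
})
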