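#' @rdname CdsAlignment-class
#' @param object,x a \code{CdsAlignment}.
#' @export
setGeneric("refSpecies", function(x) standardGeneric("refSpecies"))

#' @rdname CdsAlignment-class
#' @export
setGeneric("refLength", function(x) standardGeneric("refLength"))

#' @rdname CdsAlignment-class
#' @export
setGeneric("colMap", function(x) standardGeneric("colMap"))

#' @rdname CdsAlignment-class
#' @export
setGeneric("alnRows", function(x) standardGeneric("alnRows"))

#' @rdname CdsAlignment-class
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

setMethod("refSpecies", "CdsAlignment", function(x) x@refSpecies)
setMethod("refLength", "CdsAlignment", function(x) x@refLength)
setMethod("colMap", "CdsAlignment", function(x) x@colMap)
setMethod("alnRows", "CdsAlignment", function(x) x@rows)
setMethod("speciesNames", "CdsAlignment", function(x) names(x@rows))

#' Reference CDS of an alignment
#'
#' Ungaps the reference row and returns the reference coding sequence
#' (stop codon included).
#'
#' @param x a \code{CdsAlignment}.
#' @return a \code{DNAString} of length \code{refLength(x)}.
#' @export
setGeneric("refCds", function(x) standardGeneric("refCds"))

setMethod("refCds", "CdsAlignment", function(x) {
    s <- as.character(x@rows[[x@refSpecies]])
    Biostrings::DNAString(gsub("-", "", s, fixed = TRUE))
})

setMethod("show", "CdsAlignment", function(object) {
    cat(sprintf("CdsAlignment: %d species x %d columns\n",
        length(object@rows), unique(Biostrings::width(object@rows))))
    cat(sprintf("  reference: %s (%d coding nt incl. stop)\n",
        object@refSpecies, object@refLength))
    sp <- names(object@rows)
    cat(sprintf("  species: %s%s\n",
        paste(utils::head(sp, 6L), collapse = ", "),
        if (length(sp) > 6L) sprintf(", ... (%d more)", length(sp) - 6L) else ""))
    invisible(NULL)
})

#' @rdname SpeciesOrfReport-class
#' @param x a \code{SpeciesOrfReport}.
#' @export
setGeneric("disruptions", function(x) standardGeneric("disruptions"))

#' @rdname SpeciesOrfReport-class
#' @export
setGeneric("proteinHomology", function(x) standardGeneric("proteinHomology"))

#' @rdname SpeciesOrfReport-class
#' @export
setGeneric("alignableFrac", function(x) standardGeneric("alignableFrac"))

#' @rdname SpeciesOrfReport-class
#' @export
setGeneric("hasStart", function(x) standardGeneric("hasStart"))

setMethod("disruptions", "SpeciesOrfReport", function(x) x@disruptions)
setMethod("proteinHomology", "SpeciesOrfReport", function(x) x@proteinHomology)
setMethod("alignableFrac", "SpeciesOrfReport", function(x) x@alignableFraction)
setMethod("hasStart", "SpeciesOrfReport", function(x) x@hasStart)

setMethod("show", "SpeciesOrfReport", function(object) {
    cat(sprintf("SpeciesOrfReport for %s\n", object@species))
    cat(sprintf("  alignable fraction: %.3f\n", object@alignableFraction))
    cat(sprintf("  protein homology:   %.3f\n", object@proteinHomology))
    cat(sprintf("  start codon intact: %s\n", object@hasStart))
    d <- object@disruptions
    if (nrow(d) == 0L) {
        cat("  no ORF disruptions\n")
    } else {
        cat(sprintf("  %d disruption(s):\n", nrow(d)))
        for (i in seq_len(nrow(d)))
            cat(sprintf("    %s at ref nt %d%s\n", d$kind[i], d$refPos[i],
                if (d$indelLen[i] > 0L)
                    sprintf(" (%d nt)", d$indelLen[i]) else ""))
    }
    invisible(NULL)
})

setMethod("show", "CodonUsageResult", function(object) {
    cat(sprintf("Codon usage bias score: %.4f\n", object@score))
    cat(sprintf("  permutation p = %.4g (%d replicates, seed %d; min p = %.3g)\n",
        object@pValue, object@nReps, object@seed, 1 / object@nReps))
    invisible(NULL)
})

setMethod("show", "KaKsResult", function(object) {
    cat(sprintf("Ka = %.4f, Ks = %.4f\n", object@ka, object@ks))
    if (is.na(object@ratio)) {
        cat("  Ka/Ks undefined (Ks = 0)\n")
    } else {
        cat(sprintf("  Ka/Ks = %.3f", object@ratio))
        if (!is.null(object@ciLow))
            cat(sprintf(" (95%% MC CI %.3f-%.3f, %d simulations)",
                object@ciLow, object@ciHigh, object@nSim))
        cat("\n")
    }
    invisible(NULL)
})
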