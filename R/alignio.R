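#' Read a MULTIZ-style MAF file
#'
#' Parses the UCSC MAF dialect: alignment blocks introduced by an \code{a}
#' line, with one \code{s} line per species row. Only \code{s} lines are
#' interpreted; other line types (\code{i}, \code{e}, \code{q}, comments)
#' are ignored. The species of a row is the part of the \code{src} field
#' before the first dot (\code{hg19.chr6} belongs to species \code{hg19}).
#'
#' @param path path to a MAF file.
#' @return a list of blocks; each block is a \code{data.frame} with columns
#'   \code{src}, \code{species}, \code{chrom}, \code{start} (0-based, as in
#'   MAF), \code{size}, \code{strand}, \code{srcSize} and \code{text}
#'   (gapped row). An empty file yields an empty list.
#' @examples
#' maf <- tempfile(fileext = ".maf")
#' writeLines(c("##maf version=1", "a score=0",
#'   "s hg19.chr1 0 6 + 1000 ATG---AAA",
#'   "s oth.chr5  0 9 + 2000 ATGCCCAAA"), maf)
#' length(readMAF(maf))
#' @export
readMAF <- function(path) {
    lines <- readLines(path)
    blocks <- list()
    cur <- NULL
    flush <- function(cur) {
        if (is.null(cur) || nrow(cur) == 0L) return(NULL)
        if (length(unique(nchar(cur$text))) != 1L)
            stop(sprintf(
                "MAF block ending near line %d: rows differ in gapped length",
                cur$line[nrow(cur)]))
        cur
    }
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (grepl("^a($|\\s)", ln)) {
            b <- flush(cur)
            if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
            cur <- data.frame(src = character(), species = character(),
                chrom = character(), start = integer(), size = integer(),
                strand = character(), srcSize = numeric(), text = character(),
                line = integer(), stringsAsFactors = FALSE)
        } else if (grepl("^s\\s", ln)) {
            if (is.null(cur))
                stop(sprintf("line %d: 's' line outside an alignment block", i))
            f <- strsplit(trimws(ln), "\\s+")[[1L]]
            if (length(f) != 7L)
                stop(sprintf("line %d: malformed 's' line (expected 7 fields, got %d)",
                    i, length(f)))
            start <- suppressWarnings(as.integer(f[3L]))
            size <- suppressWarnings(as.integer(f[4L]))
            if (is.na(start) || is.na(size) || !f[5L] %in% c("+", "-"))
                stop(sprintf("line %d: malformed 's' line fields", i))
            src <- f[2L]
            dot <- regexpr(".", src, fixed = TRUE)
            species <- if (dot > 0L) substr(src, 1L, dot - 1L) else src
            chrom <- if (dot > 0L) substr(src, dot + 1L, nchar(src)) else NA_character_
            text <- toupper(f[7L])
            if (sum(seqChars(text) != "-") != size)
                stop(sprintf("line %d: row size %d does not match %d non-gap characters",
                    i, size, sum(seqChars(text) != "-")))
            cur <- rbind(cur, data.frame(src = src, species = species,
                chrom = chrom, start = start, size = size, strand = f[5L],
                srcSize = as.numeric(f[6L]), text = text, line = i,
                stringsAsFactors = FALSE))
        }
    }
    b <- flush(cur)
    if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
    lapply(blocks, function(b) b[setdiff(names(b), "line")])
}

#' Construct a CdsAlignment
#'
#' @param rows named character vector or \code{DNAStringSet} of equal-width
#'   gapped rows (gap \code{"-"}).
#' @param refSpecies name of the reference row.
#' @param colMap optional column map; when \code{NULL} it is derived from
#'   the non-gap positions of the reference row.
#' @return a \code{\link{CdsAlignment-class}} object.
#' @examples
#' aln <- CdsAlignment(c(hg19 = "ATGAAATAG", sp2 = "ATGAA-TAG"), "hg19")
#' alignableFraction(aln, "sp2")
#' @export
CdsAlignment <- function(rows, refSpecies, colMap = NULL) {
    if (!methods::is(rows, "DNAStringSet"))
        rows <- Biostrings::DNAStringSet(toupper(rows))
    if (is.null(names(rows)))
        stop("rows must be named by species")
    if (!refSpecies %in% names(rows))
        stop(sprintf("reference species '%s' not among rows: %s",
            refSpecies, paste(names(rows), collapse = ", ")))
    refchars <- seqChars(rows[[refSpecies]])
    if (is.null(colMap))
        colMap <- which(refchars != "-")
    methods::new("CdsAlignment", refSpecies = refSpecies,
        refLength = length(colMap), rows = rows,
        colMap = as.integer(colMap))
}

#' Read an aligned FASTA into a CdsAlignment
#'
#' All records must share the same gapped width; the reference defaults to
#' the first record.
#'
#' @param path FASTA path.
#' @param refSpecies reference record name; default first record.
#' @return a \code{CdsAlignment}.
#' @export
readAlignedFasta <- function(path, refSpecies = NULL) {
    rows <- Biostrings::readDNAStringSet(path)
    if (length(rows) == 0L) stop("no records in ", path)
    names(rows) <- sub("\\s.*$", "", names(rows))
    if (is.null(refSpecies)) refSpecies <- names(rows)[1L]
    if (length(unique(Biostrings::width(rows))) != 1L)
        stop("aligned FASTA records differ in gapped length")
    CdsAlignment(rows, refSpecies)
}

#' Describe a 1-based inclusive genomic interval
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates, \code{start <= end}.
#' @param strand \code{"+"} or \code{"-"}.
#' @return a length-1 \code{GRanges}.
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
genomicInterval <- function(chrom, start, end, strand = "+") {
    if (start > end) stop("interval start must not exceed end")
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand)
}

#' Stitch MAF blocks into a reference-anchored CDS alignment
#'
#' Extracts the alignment columns that carry the reference CDS interval
#' (a single-exon CDS) from a set of MAF blocks, drops columns outside it,
#' and emits a \code{\link{CdsAlignment}}. Reference positions covered by no
#' block become \code{N} in the reference row and gaps in every other row.
#' Insertion columns (reference gaps) between retained reference positions
#' are kept so that downstream ORF tracing can see species-specific
#' insertions. When blocks overlap on a reference position, the block with
#' more species rows wins (ties: first encountered) and the conflict is
#' reported via \code{message()}. Minus-strand intervals are
#' reverse-complemented so that CDS position 1 is the first coding base.
#'
#' @param blocks block list from \code{\link{readMAF}}.
#' @param refInterval length-1 \code{GRanges} (see
#'   \code{\link{genomicInterval}}) giving the CDS locus on the reference
#'   genome.
#' @param refSpecies reference species (MAF src prefix, e.g. \code{"hg19"}).
#' @return a \code{CdsAlignment} whose \code{refLength} equals the interval
#'   width.
#' @importFrom GenomicRanges seqnames start end strand
#' @export
stitchCds <- function(blocks, refInterval, refSpecies) {
    stopifnot(length(refInterval) == 1L)
    chrom <- as.character(GenomicRanges::seqnames(refInterval))
    istart <- GenomicRanges::start(refInterval)
    iend <- GenomicRanges::end(refInterval)
    strand <- as.character(GenomicRanges::strand(refInterval))
    if (!strand %in% c("+", "-"))
        stop("refInterval strand must be '+' or '-'")

    keep <- list()
    for (b in blocks) {
        ri <- which(b$species == refSpecies)
        if (length(ri) == 0L) {
            warning("MAF block without reference row skipped")
            next
        }
        ri <- ri[1L]
        if (b$strand[ri] != "+")
            stop("reference rows on the '-' strand are not supported")
        if (!is.na(b$chrom[ri]) && b$chrom[ri] != chrom) next
        gstart <- b$start[ri] + 1L
        gend <- b$start[ri] + b$size[ri]
        if (gend < istart || gstart > iend) next
        chars <- lapply(b$text, seqChars)
        refchars <- chars[[ri]]
        refpos <- ifelse(refchars != "-",
            cumsum(refchars != "-") + gstart - 1L, NA_integer_)
        keep[[length(keep) + 1L]] <- list(
            species = b$species, chars = chars, refpos = refpos,
            quality = length(b$species))
    }
    if (length(keep) == 0L)
        stop("CDS absent from alignment: no block covers ", chrom, ":",
             istart, "-", iend, " for ", refSpecies)

    ng <- iend - istart + 1L
    winner <- integer(ng)          # block index per genomic offset, 0 = none
    conflict <- FALSE
    for (k in seq_along(keep)) {
        cov <- keep[[k]]$refpos[!is.na(keep[[k]]$refpos)]
        cov <- cov[cov >= istart & cov <= iend] - istart + 1L
        taken <- winner[cov] != 0L
        if (any(taken)) {
            conflict <- TRUE
            better <- keep[[k]]$quality >
                vapply(winner[cov[taken]], function(w) keep[[w]]$quality, 0)
            winner[cov[taken][better]] <- k
        }
        winner[cov[!taken]] <- k
    }
    if (conflict)
        message("overlapping MAF blocks: kept the block with more species rows per position")

    used <- sort(unique(winner[winner != 0L]))
    allsp <- unique(c(refSpecies,
        unlist(lapply(keep[used], function(b) b$species))))
    cols <- vector("list", 0L)     # each entry: named chars incl. ref
    colmapPlus <- integer(ng)
    emit <- function(chr) {
        col <- rep("-", length(allsp)); names(col) <- allsp
        col[names(chr)] <- chr
        cols[[length(cols) + 1L]] <<- col
        length(cols)
    }
    for (g in seq_len(ng)) {
        p <- istart + g - 1L
        k <- winner[g]
        if (k == 0L) {
            chr <- stats::setNames("N", refSpecies)
            colmapPlus[g] <- emit(chr)
            next
        }
        b <- keep[[k]]
        j <- which(!is.na(b$refpos) & b$refpos == p)
        chr <- vapply(b$chars, `[`, "", j)
        names(chr) <- b$species
        colmapPlus[g] <- emit(chr)
        # trailing insertion columns (reference gaps) before the next ref base
        jj <- j + 1L
        while (jj <= length(b$refpos) && is.na(b$refpos[jj])) {
            chr <- vapply(b$chars, `[`, "", jj)
            names(chr) <- b$species
            chr[b$species == refSpecies] <- "-"
            if (any(chr != "-")) emit(chr)
            jj <- jj + 1L
        }
    }

    mat <- do.call(cbind, cols)    # species x columns
    rows <- apply(mat, 1L, paste, collapse = "")
    rows <- Biostrings::DNAStringSet(rows)
    names(rows) <- allsp
    if (strand == "-") {
        rows <- Biostrings::reverseComplement(rows)
        nc <- ncol(mat)
        colmapPlus <- nc + 1L - rev(colmapPlus)
    }
    CdsAlignment(rows, refSpecies, colMap = colmapPlus)
}

#' Fraction of the reference CDS alignable to a species
#'
#' The proportion of reference CDS positions at which the species row
#' carries an aligned base. IUPAC ambiguity codes other than \code{N}
#' count as aligned; \code{N} (low-quality fill in MULTIZ) and gaps do not.
#'
#' @param aln a \code{CdsAlignment}.
#' @param species species name.
#' @return a fraction in [0, 1].
#' @examples
#' aln <- CdsAlignment(c(hg19 = "ATGAAATAG", sp2 = "ATG---TAG"), "hg19")
#' alignableFraction(aln, "sp2")   # 6/9
#' @export
alignableFraction <- function(aln, species) {
    stopifnot(methods::is(aln, "CdsAlignment"))
    if (!species %in% names(aln@rows))
        stop(sprintf("unknown species '%s'; available: %s", species,
            paste(names(aln@rows), collapse = ", ")))
    chars <- seqChars(aln@rows[[species]])[aln@colMap]
    sum(!chars %in% c("-", "N")) / aln@refLength
}
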