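# Synthetic-data generators: a CDS evolved down a tree with scripted ORF
# disruptions, expression matrices with planted correlations and group
# effects, and promoter sequences with planted motifs. Everything is
# deterministic given its seed, and every generator returns the ground
# truth next to the data so downstream recovery can be tested exactly.

#' Script an ORF-disrupting event onto a tree branch
#'
#' Positions are in root-CDS coordinates (which equal reference
#' coordinates whenever no indel is scripted on the reference lineage).
#'
#' @param branch child-node id of the branch (tip label or
#'   \code{node<N>}).
#' @param kind one of \code{start_loss}, \code{premature_stop}
#'   (\code{refPos} must be the first base of a codon), \code{stop_loss},
#'   \code{frameshift_deletion}, \code{frameshift_insertion}.
#' @param refPos 1-based root-CDS position of the event (ignored for
#'   \code{start_loss} and \code{stop_loss}).
#' @param indelLen indel length in nt for the frameshift kinds.
#' @return one-row \code{data.frame} to pass to \code{\link{evolSpec}}.
#' @export
scriptedEvent <- function(branch, kind, refPos = NA_integer_,
                          indelLen = NA_integer_) {
    kinds <- c("start_loss", "premature_stop", "stop_loss",
        "frameshift_deletion", "frameshift_insertion")
    if (!kind %in% kinds)
        stop("kind must be one of: ", paste(kinds, collapse = ", "))
    if (kind %in% c("frameshift_deletion", "frameshift_insertion")) {
        if (is.na(indelLen) || indelLen %% 3L == 0L)
            stop("frameshift indelLen must be given and not a multiple of 3")
    } else indelLen <- 0L
    if (kind == "premature_stop" && (is.na(refPos) || refPos %% 3L != 1L))
        stop("premature_stop refPos must be the first base of a codon")
    data.frame(branch = branch, kind = kind, refPos = as.integer(refPos),
        indelLen = as.integer(indelLen), stringsAsFactors = FALSE)
}

#' Specify a CDS evolution scenario
#'
#' @param tree rooted \code{phylo}; branch lengths, when present, scale
#'   the per-branch rates (unit length assumed otherwise).
#' @param rootCds root coding sequence: a valid ORF (\code{ATG} ... stop).
#' @param refSpecies tip used as the alignment reference (default first
#'   tip).
#' @param subsRate substitution probability per site per unit branch
#'   length (default 0.01); transitions are favored 2:1 over each
#'   transversion.
#' @param indelRate expected indels per site per unit branch length
#'   (default 0); indel lengths are geometric with mean 2, so 1-nt
#'   frameshifts are the most common event.
#' @param events scripted events: \code{rbind} of
#'   \code{\link{scriptedEvent}} rows, applied deterministically on their
#'   branches.
#' @return an \code{evolSpec} list understood by
#'   \code{\link{simulateCdsEvolution}}.
#' @export
evolSpec <- function(tree, rootCds, refSpecies = tree$tip.label[1L],
                     subsRate = 0.01, indelRate = 0,
                     events = NULL) {
    rootCds <- toupper(as.character(rootCds))
    codons <- splitCodons(rootCds)
    if (codons[1L] != "ATG" || !codons[length(codons)] %in% STOP_CODONS ||
        any(codons[-length(codons)] %in% STOP_CODONS))
        stop("rootCds must be a valid ORF: ATG start, one terminal stop")
    if (!refSpecies %in% tree$tip.label)
        stop("refSpecies must be a tip of the tree")
    if (is.null(events)) events <- scriptedEvent("x", "start_loss")[0L, ]
    structure(list(tree = tree, rootCds = rootCds, refSpecies = refSpecies,
        subsRate = subsRate, indelRate = indelRate, events = events),
        class = "evolSpec")
}

#' Generate a random valid ORF
#'
#' @param nCodons number of sense codons (stop codon added on top).
#' @param seed RNG seed.
#' @return character CDS of \code{3 * (nCodons + 1)} nt.
#' @export
randomOrf <- function(nCodons, seed = 1) {
    sense <- setdiff(names(Biostrings::GENETIC_CODE)[
        Biostrings::GENETIC_CODE != "*"], "ATG")
    withSeed(seed, paste(c("ATG",
        sample(sense, nCodons - 1L, replace = TRUE), "TAA"), collapse = ""))
}

# HKY-flavored single-base mutation: transition twice as likely as each
# transversion.
.mutateBase <- function(base) {
    ts <- c(A = "G", G = "A", C = "T", T = "C")
    tv <- list(A = c("C", "T"), G = c("C", "T"),
               C = c("A", "G"), T = c("A", "G"))
    if (!base %in% names(ts)) return(base)
    sample(c(ts[[base]], tv[[base]]), 1L, prob = c(0.5, 0.25, 0.25))
}

#' Evolve a CDS down a tree with scripted disruptions
#'
#' Starting from the root ORF, each branch applies (in order) its scripted
#' events, then background substitutions at \code{subsRate}, then
#' background indels at \code{indelRate} with geometric (mean 2) lengths.
#' The true alignment is known by construction (insertions open gap
#' columns in every other lineage; deletions leave gap characters), so no
#' realignment step is involved and ORF tracing can be tested against the
#' exact truth.
#'
#' @param spec an \code{\link{evolSpec}}.
#' @param seed RNG seed; output is byte-identical for identical spec and
#'   seed.
#' @return list with \code{aln} (a \code{\link{CdsAlignment}} over the
#'   tips) and \code{truth}, a \code{data.frame} of the scripted events as
#'   the ORF scanner should see them from the reference: columns
#'   \code{branch}, \code{scriptedKind}, \code{kind}, \code{refPos},
#'   \code{indelLen} (e.g. a scripted \code{stop_loss} surfaces as a
#'   \code{nonstop} disruption at \code{refLength + 1}).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' sp <- evolSpec(tr, randomOrf(20), subsRate = 0,
#'     events = scriptedEvent("C", "frameshift_deletion", 12, 1))
#' sim <- simulateCdsEvolution(sp, seed = 7)
#' proteinHomology(scanSpeciesOrf(sim$aln, "C"))
#' @export
simulateCdsEvolution <- function(spec, seed = 1) {
    stopifnot(inherits(spec, "evolSpec"))
    tree <- spec$tree
    nt <- length(tree$tip.label)
    root <- nt + 1L
    L <- nchar(spec$rootCds)
    withSeed(seed, {
        rows <- list()                       # node -> char vector (aligned)
        rows[[root]] <- seqChars(spec$rootCds)
        colRootPos <- 1:L                    # root coordinate per column, NA = inserted

        insertColumns <- function(at, bases, intoNode) {
            # open gap columns before column `at` in every stored row;
            # write `bases` only into intoNode's row
            k <- length(bases)
            for (n in seq_along(rows)) {
                if (is.null(rows[[n]])) next
                v <- rows[[n]]
                fill <- if (n == intoNode) bases else rep("-", k)
                rows[[n]] <<- append(v, fill, after = at - 1L)
            }
            colRootPos <<- append(colRootPos, rep(NA_integer_, k),
                after = at - 1L)
        }

        colOfRootPos <- function(p) {
            j <- which(!is.na(colRootPos) & colRootPos == p)
            if (length(j) != 1L)
                stop("scripted event position ", p,
                     " is outside the root CDS")
            j
        }

        applyScripted <- function(seqv, ev, node) {
            switch(ev$kind,
                start_loss = {
                    j <- colOfRootPos(1L)
                    if (seqv[j] == "-")
                        stop("scripted start_loss on an already-deleted start")
                    seqv[j] <- "G"
                },
                premature_stop = {
                    js <- vapply(ev$refPos + 0:2, colOfRootPos, 0L)
                    if (any(seqv[js] == "-"))
                        stop("scripted premature_stop over deleted bases")
                    seqv[js] <- c("T", "A", "A")
                },
                stop_loss = {
                    js <- vapply((L - 2L):L, colOfRootPos, 0L)
                    seqv[js] <- c("C", "A", "G")
                },
                frameshift_deletion = {
                    js <- vapply(ev$refPos + seq_len(ev$indelLen) - 1L,
                        colOfRootPos, 0L)
                    if (any(seqv[js] == "-"))
                        stop("scripted deletion over already-deleted bases")
                    seqv[js] <- "-"
                },
                frameshift_insertion = {
                    j <- colOfRootPos(ev$refPos)
                    bases <- sample(c("A", "C", "G", "T"), ev$indelLen,
                        replace = TRUE)
                    rows[[node]] <<- seqv
                    insertColumns(j, bases, node)
                    seqv <- rows[[node]]
                })
            seqv
        }

        tree <- stats::reorder(tree, "cladewise")   # edges in preorder
        edges <- tree$edge
        elen <- if (is.null(tree$edge.length)) rep(1, nrow(edges)) else
            tree$edge.length
        for (e in seq_len(nrow(edges))) {
            p <- edges[e, 1L]; ch <- edges[e, 2L]
            seqv <- rows[[p]]
            branchId <- nodeId(tree, ch)
            evs <- spec$events[spec$events$branch == branchId, , drop = FALSE]
            rows[[ch]] <- seqv
            for (i in seq_len(nrow(evs)))
                rows[[ch]] <- applyScripted(rows[[ch]], evs[i, ], ch)
            seqv <- rows[[ch]]
            # background substitutions
            live <- which(seqv != "-")
            pSub <- min(1, spec$subsRate * elen[e])
            if (pSub > 0 && length(live)) {
                hit <- live[stats::runif(length(live)) < pSub]
                for (j in hit) seqv[j] <- .mutateBase(seqv[j])
            }
            # background indels
            if (spec$indelRate > 0 && length(live)) {
                nIndel <- stats::rpois(1L, spec$indelRate * elen[e] *
                    length(live))
                for (k in seq_len(nIndel)) {
                    len <- stats::rgeom(1L, 0.5) + 1L
                    live <- which(seqv != "-")
                    if (length(live) < len + 3L) break
                    at <- sample(live, 1L)
                    if (stats::runif(1L) < 0.5) {
                        idx <- live[live >= at][seq_len(len)]
                        idx <- idx[!is.na(idx)]
                        seqv[idx] <- "-"
                    } else {
                        bases <- sample(c("A", "C", "G", "T"), len,
                            replace = TRUE)
                        rows[[ch]] <- seqv
                        insertColumns(at, bases, ch)
                        seqv <- rows[[ch]]
                    }
                }
            }
            rows[[ch]] <- seqv
        }

        tipRows <- vapply(seq_len(nt), function(i)
            paste(rows[[i]], collapse = ""), "")
        names(tipRows) <- tree$tip.label
        aln <- CdsAlignment(tipRows, spec$refSpecies)

        ev <- spec$events
        truth <- data.frame(branch = character(), scriptedKind = character(),
            kind = character(), refPos = integer(), indelLen = integer(),
            stringsAsFactors = FALSE)
        if (nrow(ev)) {
            obsKind <- ifelse(ev$kind == "stop_loss", "nonstop", ev$kind)
            obsPos <- ifelse(ev$kind == "start_loss", 0L,
                ifelse(ev$kind == "stop_loss", L + 1L, ev$refPos))
            truth <- data.frame(branch = ev$branch, scriptedKind = ev$kind,
                kind = obsKind, refPos = as.integer(obsPos),
                indelLen = ev$indelLen, stringsAsFactors = FALSE)
        }
        list(aln = aln, truth = truth)
    })
}

#' Simulate an expression matrix with planted structure
#'
#' The focal gene is standard normal across samples; each planted partner
#' is \eqn{r \cdot \mathrm{focal} + \sqrt{1-r^2}\,\varepsilon}, so its
#' population correlation with the focal gene is exactly \code{r}; the
#' remaining genes are independent noise. Optional additive effects shift
#' the focal gene by annotation level, emulating group or treatment
#' designs.
#'
#' @param nGenes,nSamples matrix dimensions.
#' @param planted \code{data.frame} with columns \code{gene}, \code{r}
#'   (|r| < 1).
#' @param colData optional \code{data.frame} of per-sample annotations.
#' @param effects optional named list: for annotation column \code{nm},
#'   \code{effects[[nm]]} is a named numeric of additive shifts applied to
#'   the focal gene per level of \code{colData[[nm]]}.
#' @param focalGene focal gene id (default \code{"FOCAL"}).
#' @param seed RNG seed.
#' @return a \code{SummarizedExperiment} (assay \code{expr}); the planted
#'   truth sits in \code{metadata()$truth}.
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @export
simulateExpression <- function(nGenes = 1000, nSamples = 60,
        planted = data.frame(gene = character(), r = numeric()),
        colData = NULL, effects = NULL, focalGene = "FOCAL", seed = 1) {
    if (nrow(planted) && any(abs(planted$r) >= 1))
        stop("planted correlations must satisfy |r| < 1")
    if (!is.null(effects) && is.null(colData))
        stop("effects require colData")
    withSeed(seed, {
        genes <- c(focalGene, planted$gene,
            sprintf("G%04d", seq_len(max(0L,
                nGenes - 1L - nrow(planted)))))
        focal <- stats::rnorm(nSamples)
        m <- matrix(stats::rnorm(length(genes) * nSamples),
            nrow = length(genes), dimnames = list(genes, NULL))
        m[focalGene, ] <- focal
        for (i in seq_len(nrow(planted))) {
            r <- planted$r[i]
            m[planted$gene[i], ] <- r * focal +
                sqrt(1 - r^2) * stats::rnorm(nSamples)
        }
        if (!is.null(effects)) {
            for (nm in names(effects)) {
                lev <- as.character(colData[[nm]])
                shift <- effects[[nm]][lev]
                shift[is.na(shift)] <- 0
                m[focalGene, ] <- m[focalGene, ] + shift
            }
        }
        colnames(m) <- sprintf("S%03d", seq_len(nSamples))
        cd <- if (is.null(colData)) S4Vectors::DataFrame(
            row.names = colnames(m)) else S4Vectors::DataFrame(colData,
            row.names = colnames(m))
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(expr = m), colData = cd)
        S4Vectors::metadata(se)$truth <- list(focalGene = focalGene,
            planted = planted, effects = effects, seed = seed)
        se
    })
}

#' Generate a promoter sequence with planted motifs
#'
#' Background bases are drawn i.i.d. with \eqn{P(G) = P(C) =
#' \mathrm{gcTarget}/2}, so the realized GC content matches the target in
#' expectation; motif texts are then written at their TSS-relative
#' positions (no position 0).
#'
#' @param length sequence length.
#' @param plants \code{data.frame} with columns \code{motif} (text to
#'   plant) and \code{tssPos} (TSS-relative start); plants must not
#'   overlap.
#' @param gcTarget background GC fraction (default 0.5).
#' @param tssIndex 1-based string index of the TSS.
#' @param seed RNG seed.
#' @return list with \code{seq} (character) and \code{truth} (plants with
#'   their resolved string indices).
#' @examples
#' pr <- makePromoter(400, data.frame(motif = "GCCAAT", tssPos = -53),
#'     gcTarget = 0.35, tssIndex = 200, seed = 3)
#' scanMotifs(pr$seq, 200, corePromoterMotifs())
#' @export
makePromoter <- function(length, plants = NULL, gcTarget = 0.5,
                         tssIndex = ceiling(length / 2), seed = 1) {
    withSeed(seed, {
        chars <- sample(c("G", "C", "A", "T"), length, replace = TRUE,
            prob = c(gcTarget / 2, gcTarget / 2,
                     (1 - gcTarget) / 2, (1 - gcTarget) / 2))
        truth <- data.frame(motif = character(), tssPos = integer(),
            index = integer(), stringsAsFactors = FALSE)
        if (!is.null(plants) && nrow(plants)) {
            idx <- .fromTssRel(plants$tssPos, tssIndex)
            ends <- idx + nchar(plants$motif) - 1L
            if (any(idx < 1L) || any(ends > length))
                stop("plant outside the sequence")
            iv <- unlist(mapply(seq, idx, ends, SIMPLIFY = FALSE))
            if (anyDuplicated(iv)) stop("overlapping plants")
            for (i in seq_len(nrow(plants)))
                chars[idx[i]:ends[i]] <-
                    strsplit(toupper(plants$motif[i]), "")[[1L]]
            truth <- data.frame(motif = toupper(plants$motif),
                tssPos = plants$tssPos, index = idx,
                stringsAsFactors = FALSE)
        }
        list(seq = paste(chars, collapse = ""), truth = truth)
    })
}
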