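# Shared fixtures and independent oracles for the test suite.

# Toy two-block MAF: 15-nt CDS at chr6:100-114 on the plus strand.
writeToyMaf <- function(path) {
    writeLines(c(
        "##maf version=1", "",
        "a score=1",
        "s hg19.chr6 99 9 + 1000 ATG--AAACCC",
        "s mm9.chr4  10 11 + 500 ATGGGAAACCC",
        "s rn4.chr1  50 9 + 300  ATG--AAACCC",
        "",
        "a score=2",
        "s hg19.chr6 108 6 + 1000 TTTTAG",
        "s mm9.chr4  21  6 + 500  TTTTAG",
        "s rn4.chr1  59  5 + 300  TT-TAG"), path)
    invisible(path)
}

# Mutate characters of a CDS string at given positions.
withChars <- function(cds, at, to) {
    ch <- strsplit(cds, "")[[1L]]
    ch[at] <- to
    paste(ch, collapse = "")
}

# Two-species alignment of a reference against a variant of itself.
pairAln <- function(refSeq, otherSeq, ref = "hg19", other = "sp") {
    rows <- c(refSeq, otherSeq)
    names(rows) <- c(ref, other)
    CdsAlignment(rows, ref)
}

# Construct a SpeciesOrfReport directly (for placement tests that do not
# need an alignment); homology is derived from the first event.
makeReport <- function(species, frac = 1, events = NULL) {
    if (is.null(events))
        events <- orfgenesis:::emptyDisruptions()
    events <- events[order(events$refPos), , drop = FALSE]
    hasStart <- !"start_loss" %in% events$kind
    hom <- if (nrow(events) == 0L) 1 else
        homologyFraction(min(events$refPos[1L], 406L), 405L)
    methods::new("SpeciesOrfReport", species = species,
        alignableFraction = frac, proteinHomology = hom,
        disruptions = events, hasStart = hasStart)
}

disr <- function(kind, refPos, indelLen = 0L) {
    orfgenesis:::disruptionRow(kind, refPos, indelLen)
}

# --- independent oracles ---------------------------------------------------

# Exhaustive parsimony: minimum changes and per-node MPR state sets by
# enumerating every internal labeling over the observed states.
bruteForceParsimony <- function(tree, tipStates) {
    states <- sort(unique(unname(tipStates)))
    nt <- length(tree$tip.label)
    nn <- tree$Nnode
    grid <- as.matrix(expand.grid(rep(list(states), nn),
        stringsAsFactors = FALSE))
    full <- cbind(matrix(rep(unname(tipStates[tree$tip.label]),
        each = nrow(grid)), nrow = nrow(grid)), grid)
    changes <- rowSums(matrix(sapply(seq_len(nrow(tree$edge)), function(e)
        full[, tree$edge[e, 1L]] != full[, tree$edge[e, 2L]]),
        nrow = nrow(full)))
    best <- min(changes)
    sets <- lapply(seq_len(nt + nn), function(n)
        sort(unique(full[changes == best, n])))
    list(changes = best, sets = sets)
}

# All permutations of a vector (small n only).
allPerms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in allPerms(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
    out
}

# Pathway-averaged NG86 difference counts for one codon pair, written
# independently of the package internals (explicit ordering enumeration
# with amino-acid comparison through Biostrings translation).
oracleCodonPairDiffs <- function(c1, c2) {
    aaOf <- function(cd) as.character(Biostrings::translate(
        Biostrings::DNAString(cd), no.init.codon = TRUE))
    pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
    if (!length(pos)) return(c(syn = 0, nonsyn = 0))
    orders <- allPerms(pos)
    syn <- nonsyn <- 0
    for (ord in orders) {
        cur <- strsplit(c1, "")[[1L]]
        tgt <- strsplit(c2, "")[[1L]]
        for (p in ord) {
            nxt <- cur
            nxt[p] <- tgt[p]
            if (aaOf(paste(cur, collapse = "")) ==
                aaOf(paste(nxt, collapse = ""))) syn <- syn + 1
            else nonsyn <- nonsyn + 1
            cur <- nxt
        }
    }
    c(syn = syn / length(orders), nonsyn = nonsyn / length(orders))
}

# Jukes-Cantor point mutation of every site independently with prob p.
jcMutate <- function(seq, p) {
    ch <- strsplit(seq, "")[[1L]]
    hit <- which(stats::runif(length(ch)) < p)
    for (j in hit)
        ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
    paste(ch, collapse = "")
}

# Expand an IUPAC consensus into every concrete DNA string it matches.
expandIupac <- function(consensus) {
    codes <- list(A = "A", C = "C", G = "G", T = "T",
        R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
        W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
        B = c("C", "G", "T"), D = c("A", "G", "T"),
        H = c("A", "C", "T"), V = c("A", "C", "G"),
        N = c("A", "C", "G", "T"))
    parts <- codes[strsplit(toupper(consensus), "")[[1L]]]
    apply(as.matrix(expand.grid(parts, stringsAsFactors = FALSE)), 1L,
        paste, collapse = "")
}
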