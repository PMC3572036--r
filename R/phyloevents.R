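#' @importFrom ape read.tree getMRCA Ntip
NULL

# Stable id for a node: tip label for tips, node label when present,
# otherwise "node<N>" with N the ape node number.
nodeId <- function(tree, node) {
    nt <- length(tree$tip.label)
    if (node <= nt) return(tree$tip.label[node])
    lbl <- tree$node.label
    if (!is.null(lbl) && !is.na(lbl[node - nt]) && nzchar(lbl[node - nt]))
        return(lbl[node - nt])
    paste0("node", node)
}

# Tip labels below a node (the node itself when it is a tip).
tipsBelow <- function(tree, node) {
    nt <- length(tree$tip.label)
    if (node <= nt) return(tree$tip.label[node])
    stack <- node
    tips <- integer()
    while (length(stack)) {
        n <- stack[[1L]]; stack <- stack[-1L]
        kids <- tree$edge[tree$edge[, 1L] == n, 2L]
        tips <- c(tips, kids[kids <= nt])
        stack <- c(stack, kids[kids > nt])
    }
    tree$tip.label[sort(tips)]
}

.parentOf <- function(tree, node) {
    p <- tree$edge[tree$edge[, 2L] == node, 1L]
    if (length(p)) p else NA_integer_
}

#' Fitch parsimony ancestral state reconstruction
#'
#' Two-pass (down then up) parsimony over a rooted tree with unit change
#' cost, implemented as a Sankoff dynamic program so that multifurcations
#' are handled exactly. For every node it reports the full set of states
#' that occur in at least one most-parsimonious reconstruction; internal
#' nodes with ties therefore carry the complete ambiguous set.
#'
#' @param tree a rooted \code{phylo} object.
#' @param tipStates named vector of discrete states, one per tip label.
#' @return a list with \code{states} (named list of state sets per node,
#'   internal nodes named \code{node<N>}) and \code{changes} (minimum
#'   number of state changes).
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' fitchAncestral(tr, c(a = "A", b = "A", c = "B", d = "B"))$changes  # 1
#' @export
fitchAncestral <- function(tree, tipStates) {
    tips <- tree$tip.label
    miss <- setdiff(tips, names(tipStates))
    if (length(miss))
        stop("missing state for tip(s): ", paste(miss, collapse = ", "))
    states <- sort(unique(as.character(tipStates[tips])))
    S <- length(states)
    nt <- length(tips)
    N <- nt + tree$Nnode
    root <- nt + 1L
    BIG <- 1e6

    D <- matrix(0, N, S)                 # min changes within subtree
    for (i in seq_len(nt)) {
        D[i, ] <- BIG
        D[i, match(as.character(tipStates[tips[i]]), states)] <- 0
    }
    po <- stats::reorder(tree, "postorder")$edge
    contrib <- function(childCosts)      # min_t(cost_t + [s != t]) per s
        pmin(childCosts, min(childCosts) + 1)
    for (e in seq_len(nrow(po))) {
        p <- po[e, 1L]; ch <- po[e, 2L]
        D[p, ] <- D[p, ] + contrib(D[ch, ])
    }
    changes <- min(D[root, ])

    U <- matrix(0, N, S)                 # min changes outside subtree
    for (e in rev(seq_len(nrow(po)))) {
        p <- po[e, 1L]; ch <- po[e, 2L]
        Tp <- U[p, ] + D[p, ] - contrib(D[ch, ])  # parent cost w/o this child
        U[ch, ] <- pmin(Tp, min(Tp) + 1)
    }

    total <- D + U
    out <- lapply(seq_len(N), function(n)
        states[abs(total[n, ] - changes) < 0.5])
    names(out) <- vapply(seq_len(N), function(n) nodeId(tree, n), "")
    list(states = out, changes = as.integer(changes))
}

#' Lower bound on an ancestor's alignable sequence content
#'
#' A clade's ancestor must have carried at least as much of the reference
#' CDS as the best-preserved modern member, so the maximum tip fraction in
#' the clade is a lower bound on the ancestral alignable fraction.
#'
#' @param tree a \code{phylo}.
#' @param node an internal node number, a tip label, or a clade name
#'   resolvable through \code{clades}.
#' @param tipFractions named numeric vector of per-tip alignable fractions
#'   (tips without a value are ignored).
#' @param clades optional named list mapping clade names to tip-label sets
#'   (see \code{\link{placentalClades}}).
#' @return the maximum fraction over annotated tips in the clade.
#' @examples
#' tr <- ape::read.tree(text = "((Horse,Megabat),(Mouse,Rat));")
#' cladeLowerBound(tr, ape::getMRCA(tr, c("Horse", "Megabat")),
#'                 c(Horse = 0.97, Megabat = 0.97, Mouse = 0.4))
#' @export
cladeLowerBound <- function(tree, node, tipFractions, clades = NULL) {
    tips <- if (is.character(node)) {
        if (node %in% tree$tip.label) node
        else if (!is.null(clades) && node %in% names(clades)) clades[[node]]
        else stop(sprintf("'%s' is neither a tip nor a known clade", node))
    } else {
        tipsBelow(tree, node)
    }
    vals <- tipFractions[intersect(tips, names(tipFractions))]
    vals <- vals[!is.na(vals)]
    if (!length(vals))
        stop("no annotated tips below the requested node")
    max(vals)
}

# Signature used to match one disruption across species.
.eventKey <- function(d)
    sprintf("%s@%d+%d", d$kind, d$refPos, d$indelLen)

#' Place shared ORF disruptions on tree branches
#'
#' Events are matched across species by (kind, reference position, indel
#' length) and placed Dollo-style: a single gain on the stem branch of the
#' maximal clade in which every reliably-aligned tip carries the event.
#' Events private to one species map to its terminal branch. When the
#' carrier set is not monophyletic (given the eligible tips) the event is
#' flagged ambiguous and the maximal carrier-only subclades are listed.
#' Tips whose alignable fraction is below \code{minAlignable} are excluded
#' from matching: their ORF calls are unreliable.
#'
#' @param tree a rooted \code{phylo} whose tips cover the report species.
#' @param reports list of \code{\link{SpeciesOrfReport-class}} objects.
#' @param minAlignable eligibility floor on the alignable fraction
#'   (default 0.10).
#' @return a \code{data.frame} with one row per distinct event: columns
#'   \code{kind}, \code{refPos}, \code{indelLen}, \code{branch} (child-node
#'   id of the placement branch; \code{NA} when ambiguous),
#'   \code{ambiguous}, \code{nCarriers}, \code{carriers} and
#'   \code{altBranches} (semicolon-separated candidate branches for
#'   ambiguous events).
#' @export
placeEvents <- function(tree, reports, minAlignable = 0.10) {
    sp <- vapply(reports, function(r) r@species, "")
    names(reports) <- sp
    unknown <- setdiff(sp, tree$tip.label)
    if (length(unknown))
        stop("species not on the tree: ", paste(unknown, collapse = ", "))
    eligible <- sp[vapply(reports, function(r)
        r@alignableFraction >= minAlignable, NA)]

    evtab <- do.call(rbind, lapply(eligible, function(s) {
        d <- reports[[s]]@disruptions
        if (nrow(d) == 0L) return(NULL)
        cbind(d, species = s)
    }))
    out <- data.frame(kind = character(), refPos = integer(),
        indelLen = integer(), branch = character(), ambiguous = logical(),
        nCarriers = integer(), carriers = character(),
        altBranches = character(), stringsAsFactors = FALSE)
    if (is.null(evtab) || nrow(evtab) == 0L) return(out)

    evtab$key <- .eventKey(evtab)
    for (key in unique(evtab$key)) {
        rows <- evtab[evtab$key == key, , drop = FALSE]
        carriers <- unique(rows$species)
        branch <- NA_character_; ambiguous <- FALSE; alt <- ""
        if (length(carriers) == 1L) {
            branch <- carriers
        } else {
            m <- ape::getMRCA(tree, carriers)
            inClade <- intersect(tipsBelow(tree, m), eligible)
            if (all(inClade %in% carriers)) {
                repeat {   # extend rootward while eligible tips all carry it
                    p <- .parentOf(tree, m)
                    if (is.na(p)) break
                    eligUp <- intersect(tipsBelow(tree, p), eligible)
                    if (all(eligUp %in% carriers)) m <- p else break
                }
                branch <- nodeId(tree, m)
            } else {
                ambiguous <- TRUE
                alt <- paste(.maximalCarrierClades(tree, carriers, eligible),
                    collapse = ";")
            }
        }
        out <- rbind(out, data.frame(kind = rows$kind[1L],
            refPos = rows$refPos[1L], indelLen = rows$indelLen[1L],
            branch = branch, ambiguous = ambiguous,
            nCarriers = length(carriers),
            carriers = paste(sort(carriers), collapse = ","),
            altBranches = alt, stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out[order(out$refPos), , drop = FALSE]
}

# Highest nodes whose eligible descendants are all carriers: the candidate
# independent-gain branches for a non-monophyletic carrier set.
.maximalCarrierClades <- function(tree, carriers, eligible) {
    nodes <- match(carriers, tree$tip.label)
    res <- character()
    for (n in nodes) {
        cur <- n
        repeat {
            p <- .parentOf(tree, cur)
            if (is.na(p)) break
            elig <- intersect(tipsBelow(tree, p), eligible)
            if (all(elig %in% carriers)) cur <- p else break
        }
        res <- c(res, nodeId(tree, cur))
    }
    unique(res)
}

#' The study phylogeny of placental mammals
#'
#' A rooted tree of the human genome plus 31 placental mammal genomes,
#' following the accepted placental topology used by the UCSC 46-way
#' MULTIZ alignments (Boreoeutheria split into Euarchontoglires and
#' Laurasiatheria, sister to Atlantogenata).
#'
#' @return a \code{phylo} with 32 tips.
#' @export
placentalTree <- function() {
    ape::read.tree(system.file("extdata", "placental_tree.nwk",
        package = "orfgenesis", mustWork = TRUE))
}

#' Named clades of the study phylogeny
#'
#' @return named list mapping clade names to tip-label sets of
#'   \code{\link{placentalTree}}.
#' @export
placentalClades <- function() {
    tr <- placentalTree()
    primates <- c("Human", "Chimp", "Gorilla", "Orangutan", "Rhesus",
        "Marmoset", "Tarsier", "MouseLemur", "Bushbaby")
    glires <- c("Mouse", "Rat", "KangarooRat", "GuineaPig", "Squirrel",
        "Rabbit", "Pika")
    laurasiatheria <- c("Alpaca", "Dolphin", "Cow", "Horse", "Cat", "Dog",
        "Microbat", "Megabat", "Hedgehog", "Shrew")
    atlantogenata <- c("Elephant", "RockHyrax", "Tenrec", "Sloth",
        "Armadillo")
    list(
        Hominidae = c("Human", "Chimp", "Gorilla", "Orangutan"),
        Primates = primates,
        Glires = glires,
        Euarchontoglires = c(primates, "TreeShrew", glires),
        Laurasiatheria = laurasiatheria,
        Boreoeutheria = c(primates, "TreeShrew", glires, laurasiatheria),
        Atlantogenata = atlantogenata
    )
}
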