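test_that("rate-free evolution reproduces the root at every tip", {
    tr <- ape::read.tree(text = "((A,B),(C,D));")
    root <- randomOrf(20, seed = 3)
    sim <- simulateCdsEvolution(evolSpec(tr, root, subsRate = 0), seed = 1)
    rows <- as.character(alnRows(sim$aln))
    expect_true(all(rows == root))
    for (sp in c("B", "C", "D"))
        expect_equal(proteinHomology(scanSpeciesOrf(sim$aln, sp)), 1)
    expect_equal(nrow(sim$truth), 0L)
})

test_that("simulation output is byte-identical for identical spec and seed", {
    tr <- ape::rtree(6, br = NULL)
    spec <- evolSpec(tr, randomOrf(30, seed = 5), subsRate = 0.05,
        indelRate = 0.01)
    s1 <- simulateCdsEvolution(spec, seed = 42)
    s2 <- simulateCdsEvolution(spec, seed = 42)
    expect_identical(as.character(alnRows(s1$aln)),
        as.character(alnRows(s2$aln)))
    s3 <- simulateCdsEvolution(spec, seed = 43)
    expect_false(identical(as.character(alnRows(s1$aln)),
        as.character(alnRows(s3$aln))))
})

test_that("a scripted 1-bp deletion at nt 12 reproduces the 3% homology", {
    tr <- placentalTree()
    spec <- evolSpec(tr, randomOrf(135, seed = 2), refSpecies = "Human",
        subsRate = 0,
        events = scriptedEvent("Dog", "frameshift_deletion", 12L, 1L))
    sim <- simulateCdsEvolution(spec, seed = 3)
    rep <- scanSpeciesOrf(sim$aln, "Dog")
    d <- disruptions(rep)
    expect_equal(d$kind[1L], "frameshift_deletion")
    expect_equal(d$refPos[1L], 12L)
    expect_equal(round(100 * proteinHomology(rep)), 3)
})

test_that("an internal-branch stop loss propagates to all descendants", {
    tr <- placentalTree()
    node <- paste0("node", ape::getMRCA(tr, c("Cat", "Dog")))
    spec <- evolSpec(tr, randomOrf(135, seed = 2), refSpecies = "Human",
        subsRate = 0, events = scriptedEvent(node, "stop_loss"))
    sim <- simulateCdsEvolution(spec, seed = 4)
    for (sp in c("Cat", "Dog"))
        expect_equal(disruptions(scanSpeciesOrf(sim$aln, sp))$kind,
            "nonstop")
    expect_equal(nrow(disruptions(scanSpeciesOrf(sim$aln, "Horse"))), 0L)
    pl <- placeEvents(tr, scanAllSpecies(sim$aln))
    expect_equal(pl$branch, node)
})

test_that("scripted events out of range are rejected", {
    tr <- ape::read.tree(text = "((A,B),(C,D));")
    spec <- evolSpec(tr, randomOrf(20, seed = 1), subsRate = 0,
        events = scriptedEvent("C", "frameshift_deletion", 2000L, 1L))
    expect_error(simulateCdsEvolution(spec, seed = 1), "outside the root CDS")
    expect_error(scriptedEvent("C", "frameshift_deletion", 10L, 3L),
        "not a multiple of 3")
    expect_error(scriptedEvent("C", "premature_stop", 11L),
        "first base of a codon")
})

test_that("expression simulation plants correlations at the stated r", {
    se0 <- simulateExpression(nGenes = 50, nSamples = 400,
        planted = data.frame(gene = "NULLG", r = 0), seed = 2)
    m0 <- SummarizedExperiment::assay(se0)
    expect_lt(abs(cor(m0["FOCAL", ], m0["NULLG", ])), 2 / sqrt(400))

    se <- simulateExpression(nGenes = 50, nSamples = 200,
        planted = data.frame(gene = "SHH", r = 0.9), seed = 6)
    m <- SummarizedExperiment::assay(se)
    r <- cor(m["FOCAL", ], m["SHH", ])
    expect_gte(r, 0.85); expect_lte(r, 0.95)
    expect_error(simulateExpression(planted = data.frame(gene = "x", r = 1)),
        "\\|r\\| < 1")
    # determinism
    se2 <- simulateExpression(nGenes = 50, nSamples = 200,
        planted = data.frame(gene = "SHH", r = 0.9), seed = 6)
    expect_identical(m, SummarizedExperiment::assay(se2))
})

test_that("planted group effects give the expected test power", {
    cd <- data.frame(group = rep(c("ctl", "case"), each = 20))
    se <- simulateExpression(nGenes = 20, nSamples = 40, colData = cd,
        effects = list(group = c(case = 2, ctl = 0)), seed = 12)
    m <- SummarizedExperiment::assay(se)
    p <- oneTailedTTest(m["FOCAL", cd$group == "ctl"],
        m["FOCAL", cd$group == "case"], "b>a")["p"]
    expect_lt(unname(p), 0.01)
})

test_that("promoter generation hits the GC target and plants motifs", {
    pr <- makePromoter(10000, gcTarget = 0.35, tssIndex = 5000, seed = 21)
    chars <- strsplit(pr$seq, "")[[1L]]
    expect_lt(abs(mean(chars %in% c("G", "C")) - 0.35), 0.02)
    expect_lt(abs(gcWindow(pr$seq, 5000, 2500) - 0.35), 0.02)

    planted <- makePromoter(600, data.frame(
        motif = c("GATATATTT", "GCCAAT", "AATCTAA"),
        tssPos = c(4, -53, -30)), gcTarget = 0.35, tssIndex = 300,
        seed = 13)
    hits <- scanMotifs(planted$seq, 300, corePromoterMotifs())
    expect_true(all(c(4, -53, -30) %in% hits$tssPos))
    expect_error(makePromoter(600, data.frame(motif = c("AAAA", "TTTT"),
        tssPos = c(10, 12)), tssIndex = 300), "overlapping")
    expect_error(makePromoter(100, data.frame(motif = "AAAA",
        tssPos = 90), tssIndex = 50), "outside")
})

test_that("unplanted promoters hit 9-mers at the background rate", {
    pr <- makePromoter(20000, gcTarget = 0.5, tssIndex = 10000, seed = 31)
    set.seed(32)
    probes <- replicate(60, paste(sample(c("A", "C", "G", "T"), 9,
        replace = TRUE), collapse = ""))
    hits <- sum(vapply(probes, function(w)
        length(Biostrings::matchPattern(w,
            Biostrings::DNAString(pr$seq))), 0L))
    lambda <- 60 * (20000 - 8) / 4^9
    expect_lte(hits, stats::qpois(0.999, lambda) + 1)
})
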