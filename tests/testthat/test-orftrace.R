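ref <- randomOrf(135, seed = 2)   # 408 nt incl. stop, like the focal CDS

test_that("ORF length arithmetic matches the coordinate convention", {
    expect_identical(orfLengthAA(96, 503), 135L)
    expect_identical(orfLengthAA(1, 6), 1L)
    expect_identical(orfLengthAA(1, 3), 0L)
    expect_error(orfLengthAA(1, 5), "multiple of 3")
})

test_that("homology fraction counts coding nt strictly before the event", {
    expect_equal(homologyFraction(12, 405), 11 / 405)
    expect_equal(round(100 * homologyFraction(12, 405)), 3)
    expect_equal(homologyFraction(0, 405), 0)
    expect_equal(homologyFraction(406, 405), 1)
    expect_error(homologyFraction(-1, 405), "non-negative")
    # monotone non-decreasing in the event position
    h <- vapply(0:406, homologyFraction, 0, codingLen = 405)
    expect_true(all(diff(h) >= 0))
})

test_that("an identical ortholog yields the identity report", {
    r <- scanSpeciesOrf(pairAln(ref, ref), "sp")
    expect_true(hasStart(r))
    expect_equal(nrow(disruptions(r)), 0L)
    expect_equal(proteinHomology(r), 1)
    expect_equal(alignableFrac(r), 1)
    # the reference against itself is always the identity report
    rr <- scanSpeciesOrf(pairAln(ref, ref), "hg19")
    expect_equal(nrow(disruptions(rr)), 0L)
})

test_that("start-codon loss eliminates the reading frame", {
    r <- scanSpeciesOrf(pairAln(ref, withChars(ref, 1, "G")), "sp")
    expect_false(hasStart(r))
    expect_equal(disruptions(r)$kind[1L], "start_loss")
    expect_equal(disruptions(r)$refPos[1L], 0L)
    expect_equal(proteinHomology(r), 0)
    # fully unaligned codon 1 is a start loss with an "unaligned" note
    r2 <- scanSpeciesOrf(pairAln(ref, withChars(ref, 1:6, "-")), "sp")
    expect_false(hasStart(r2))
    expect_equal(disruptions(r2)$note[disruptions(r2)$kind == "start_loss"],
        "unaligned")
})

test_that("a 1-nt deletion at position 12 limits homology to 3%", {
    r <- scanSpeciesOrf(pairAln(ref, withChars(ref, 12, "-")), "sp")
    d <- disruptions(r)
    expect_equal(d$kind[1L], "frameshift_deletion")
    expect_equal(d$refPos[1L], 12L)
    expect_equal(d$indelLen[1L], 1L)
    expect_equal(proteinHomology(r), 11 / 405)
    expect_equal(round(100 * proteinHomology(r)), 3)
})

test_that("an in-frame premature stop at 88 limits homology to ~21%", {
    r <- scanSpeciesOrf(pairAln(ref, withChars(ref, 88:90, c("T", "A", "A"))),
        "sp")
    d <- disruptions(r)
    expect_equal(d$kind, "premature_stop")
    expect_equal(d$refPos, 88L)
    expect_equal(proteinHomology(r), 87 / 405)
})

test_that("loss of the terminal stop with no downstream stop is non-stop", {
    # replace the stop codon by a sense codon
    r <- scanSpeciesOrf(pairAln(ref, withChars(ref, 406:408,
        c("C", "A", "G"))), "sp")
    d <- disruptions(r)
    expect_equal(d$kind, "nonstop")
    expect_equal(d$refPos, 409L)
})

test_that("frame-shifted stops are searched in the cumulative-offset frame", {
    # a 1-nt deletion shifts the frame; a stop readable only in the original
    # frame downstream must not be called, while the first stop in the
    # shifted frame must be
    orth <- withChars(ref, 12, "-")
    r <- scanSpeciesOrf(pairAln(ref, orth), "sp")
    d <- disruptions(r)
    stops <- d[d$kind == "premature_stop", ]
    if (nrow(stops)) {
        # verify against direct translation of the gapless ortholog
        gapless <- gsub("-", "", orth)
        trimmed <- substr(gapless, 1L, 3L * (nchar(gapless) %/% 3L))
        aa <- strsplit(as.character(Biostrings::translate(
            Biostrings::DNAString(trimmed))), "")[[1L]]
        firstStopCodon <- which(aa == "*")[1L]
        # species base index of that stop, mapped back to ref coordinates
        # (every species base at index i >= 12 sits at ref position i + 1)
        spIdx <- 3L * (firstStopCodon - 1L) + 1L
        expect_equal(stops$refPos[1L], spIdx + 1L)
    }
})

test_that("a stop codon spanning the indel does not pre-empt the indel", {
    # after a 1-bp deletion at nt 12, a shifted codon can read ref bases
    # 10, 11 and 13; if that codon is a stop it anchors at ref 10, yet the
    # deletion is the first disruption in translation order, so homology
    # must still be 11/405 (3%), not 9/405
    ref3 <- randomOrf(135, seed = 3)
    r <- scanSpeciesOrf(pairAln(ref3, withChars(ref3, 12, "-")), "sp")
    d <- disruptions(r)
    expect_true(any(d$kind == "frameshift_deletion" & d$refPos == 12L))
    expect_equal(proteinHomology(r), 11 / 405)
    expect_equal(round(100 * proteinHomology(r)), 3)
})

test_that("compensating indels are each flagged; the first sets homology", {
    # +1 insertion after ref 30, then a 1-nt deletion at ref 60: net 0
    ch <- strsplit(ref, "")[[1L]]
    refRow <- paste(c(ch[1:30], "-", ch[31:408]), collapse = "")
    spCh <- ch; spCh[60] <- "-"
    spRow <- paste(c(spCh[1:30], "G", spCh[31:408]), collapse = "")
    aln <- CdsAlignment(c(hg19 = refRow, sp = spRow), "hg19")
    d <- disruptions(scanSpeciesOrf(aln, "sp"))
    fs <- d[grepl("frameshift", d$kind), ]
    expect_equal(fs$kind, c("frameshift_insertion", "frameshift_deletion"))
    expect_equal(fs$refPos, c(31L, 60L))
    expect_equal(proteinHomology(scanSpeciesOrf(aln, "sp")), 30 / 405)
})

test_that("invalid reference ORFs are rejected", {
    bad <- withChars(ref, 1, "C")
    expect_error(scanSpeciesOrf(pairAln(bad, bad), "sp"),
        "reference ORF invalid")
    bad2 <- withChars(ref, 406:408, c("A", "A", "A"))
    expect_error(scanSpeciesOrf(pairAln(bad2, bad2), "sp"),
        "reference ORF invalid")
})
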