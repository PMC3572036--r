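test_that("readMAF parses blocks, rows and coordinates", {
    maf <- withr::local_tempfile(fileext = ".maf")
    writeToyMaf(maf)
    b <- readMAF(maf)
    expect_length(b, 2L)
    expect_equal(nrow(b[[1L]]), 3L)
    expect_equal(nrow(b[[2L]]), 3L)
    expect_equal(b[[1L]]$species, c("hg19", "mm9", "rn4"))
    expect_equal(b[[1L]]$start[1L], 99L)
    expect_equal(b[[2L]]$text[3L], "TT-TAG")
})

test_that("readMAF handles the empty file and rejects malformed blocks", {
    empty <- withr::local_tempfile(fileext = ".maf")
    writeLines("##maf version=1", empty)
    expect_length(readMAF(empty), 0L)

    bad <- withr::local_tempfile(fileext = ".maf")
    writeLines(c("a", "s a.c 0 3 + 10 ATG", "s b.c 0 5 + 10 ATGGA"), bad)
    expect_error(readMAF(bad), "differ in gapped length")

    badsize <- withr::local_tempfile(fileext = ".maf")
    writeLines(c("a", "s a.c 0 4 + 10 ATG"), badsize)
    expect_error(readMAF(badsize), "line 2")
})

test_that("stitching one exact block gives an identity column map", {
    maf <- withr::local_tempfile(fileext = ".maf")
    writeLines(c("a",
        "s hg19.chr1 9 9 + 100 ATGAAATAG",
        "s mm9.chr2  0 9 + 100 ATGCAATAG"), maf)
    aln <- stitchCds(readMAF(maf), genomicInterval("chr1", 10, 18, "+"),
        "hg19")
    expect_equal(colMap(aln), 1:9)
    expect_equal(as.character(refCds(aln)), "ATGAAATAG")
    expect_equal(refLength(aln), 9L)
})

test_that("two abutting blocks stitch to the hand-built alignment", {
    maf <- withr::local_tempfile(fileext = ".maf")
    writeToyMaf(maf)
    aln <- stitchCds(readMAF(maf), genomicInterval("chr6", 100, 114, "+"),
        "hg19")
    rows <- as.character(alnRows(aln))
    expect_equal(unname(rows["hg19"]), "ATG--AAACCCTTTTAG")
    expect_equal(unname(rows["mm9"]),  "ATGGGAAACCCTTTTAG")
    expect_equal(unname(rows["rn4"]),  "ATG--AAACCCTT-TAG")
    expect_equal(colMap(aln), c(1:3, 6:17))
    # stitching then ungapping the reference reproduces the input CDS
    expect_equal(as.character(refCds(aln)), "ATGAAACCCTTTTAG")
    expect_identical(validObject(aln), TRUE)
})

test_that("minus-strand intervals are reverse-complemented to coding order", {
    cds <- "ATGAAACCCTTTTAG"
    genomicText <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    maf <- withr::local_tempfile(fileext = ".maf")
    writeLines(c("a",
        paste("s hg19.chr6 99 15 + 1000", genomicText),
        paste("s mm9.chr4  0 15 + 500 ", genomicText)), maf)
    aln <- stitchCds(readMAF(maf), genomicInterval("chr6", 100, 114, "-"),
        "hg19")
    expect_equal(as.character(refCds(aln)), cds)
    expect_equal(alignableFraction(aln, "mm9"), 1)
})

test_that("uncovered reference positions become N/gap columns", {
    maf <- withr::local_tempfile(fileext = ".maf")
    writeLines(c("a",
        "s hg19.chr1 9 6 + 100 ATGAAA",
        "s mm9.chr2  0 6 + 100 ATGCAA"), maf)
    aln <- stitchCds(readMAF(maf), genomicInterval("chr1", 10, 21, "+"),
        "hg19")
    expect_equal(refLength(aln), 12L)
    rows <- as.character(alnRows(aln))
    expect_equal(unname(rows["hg19"]), "ATGAAANNNNNN")
    expect_equal(unname(rows["mm9"]), "ATGCAA------")
    expect_equal(alignableFraction(aln, "mm9"), 0.5)
    expect_error(
        stitchCds(readMAF(maf), genomicInterval("chr1", 50, 60, "+"), "hg19"),
        "CDS absent")
})

test_that("alignable fraction counts non-gap non-N bases over the CDS", {
    ref <- randomOrf(135, seed = 11)          # 408 nt
    expect_equal(alignableFraction(pairAln(ref, ref), "sp"), 1)
    gaps <- paste(rep("-", 408), collapse = "")
    expect_equal(alignableFraction(pairAln(ref, gaps), "sp"), 0)
    gapped <- withChars(ref, 101:112, "-")    # 12 gapped positions
    expect_equal(alignableFraction(pairAln(ref, gapped), "sp"), 396 / 408)
    # N is unaligned, other ambiguity codes are aligned
    expect_equal(alignableFraction(pairAln(ref, withChars(ref, 5, "N")), "sp"),
        407 / 408)
    expect_equal(alignableFraction(pairAln(ref, withChars(ref, 5, "R")), "sp"),
        1)
    expect_error(alignableFraction(pairAln(ref, ref), "nope"),
        "available")
})

test_that("alignable fraction is invariant under joint column permutation", {
    aln <- CdsAlignment(c(hg19 = "ATG--AAACCCTTTTAG",
                          mm9  = "ATGGGAA-CCCTTTTAG"), "hg19")
    base <- alignableFraction(aln, "mm9")
    set.seed(42)
    for (i in 1:10) {
        perm <- sample(17L)
        chars <- strsplit(as.character(alnRows(aln)[["mm9"]]), "")[[1L]]
        cmNew <- match(colMap(aln), perm)   # new positions of CDS columns
        permuted <- chars[perm]
        expect_equal(sum(!permuted[cmNew] %in% c("-", "N")) / refLength(aln),
            base)
    }
})
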