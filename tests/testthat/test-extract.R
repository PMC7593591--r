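makeRefs <- function(seqs) ReferenceSet(seqs, taxonomy = rep("", length(seqs)))

test_that("reference index counts postings as expected", {
    set.seed(11)
    s <- rndSeq(100)
    idx <- buildRefIndex(makeRefs(c(r1 = s)), k = 13)
    expect_equal(sum(idx$postStrand == "+"), 88)  # L - k + 1
    # two identical references: every k-mer posted twice per strand
    idx2 <- buildRefIndex(makeRefs(c(a = s, b = s)), k = 13)
    expect_equal(length(idx2$postRef), 4 * 88)
    # fully masked reference contributes nothing
    masked <- makeRefs(c(m = strrep("N", 100)))
    expect_length(buildRefIndex(masked, k = 13)$postRef, 0)
    expect_error(buildRefIndex(makeRefs(c(s = rndSeq(10))), k = 13),
                 "shortest")
})

test_that("verbatim, divergent and one-sided pairs behave per contract", {
    set.seed(12)
    refs <- makeRefs(c(R1 = rndSeq(500), R2 = rndSeq(500)))
    idx <- buildRefIndex(refs)
    r1seq <- as.character(refSeqs(refs)[["R1"]])
    verbatim <- substr(r1seq, 101, 200)
    junk <- rndSeq(100)
    pairs <- PairedReads(c(p1 = verbatim, p2 = junk),
                         c(p1 = revcompChr(substr(r1seq, 221, 320)),
                           p2 = junk))
    ex <- extractReads(pairs, idx)
    h1 <- ex$hits[ex$hits$readId == "p1" & ex$hits$mate == 1, ]
    expect_equal(h1$identity, 1.0)
    expect_equal(h1$refId, "R1")
    expect_equal(h1$refStart, 101L)
    expect_equal(h1$strand, "+")
    # insert size from outer distance of the two mates
    expect_equal(unique(ex$hits$insertSize[ex$hits$readId == "p1"]), 220L)
    # p2 matches nothing: dropped entirely
    expect_false("p2" %in% readIds(ex$retained))
    expect_true("p1" %in% readIds(ex$retained))
    # pair with only one aligning mate: both mates retained in output
    pairs2 <- PairedReads(c(q = verbatim), c(q = junk))
    ex2 <- extractReads(pairs2, idx)
    expect_equal(length(ex2$retained), 1L)
    expect_equal(IRanges::width(mateSeqs(ex2$retained, 2)), 100L)
})

test_that("reads below the identity cutoff are rejected", {
    set.seed(13)
    refs <- makeRefs(c(R1 = rndSeq(500)))
    idx <- buildRefIndex(refs)
    ref <- as.character(refSeqs(refs)[["R1"]])
    far <- mutSeq(substr(ref, 101, 200), 45)   # ~55% identity
    pairs <- PairedReads(c(p = far), c(p = rndSeq(100)))
    ex <- extractReads(pairs, idx, minIdentity = 0.70)
    expect_equal(nrow(ex$hits), 0)
    expect_equal(length(ex$retained), 0)
})

test_that("stored identities agree with independent CIGAR rescoring", {
    spec <- fixtureSpec(seed = 21, nTaxa = 5, nPairs = 60, fractionSsu = 0.5)
    db <- genReferenceDb(spec)
    idx <- buildRefIndex(db$refs)
    rd <- genReads(spec, db$refs)
    ex <- extractReads(rd$pairs, idx)
    expect_gt(nrow(ex$hits), 0)
    refChr <- as.character(refSeqs(db$refs))
    for (i in seq_len(nrow(ex$hits))) {
        h <- ex$hits[i, ]
        readSeq <- as.character(mateSeqs(rd$pairs, h$mate)[[h$readId]])
        expect_equal(rescoreHit(readSeq, refChr[[h$refId]], h$refStart,
                                h$strand, h$cigar),
                     h$identity, tolerance = 1e-12)
    }
    # pair retention: retained <=> has a hit
    expect_setequal(readIds(ex$retained), unique(ex$hits$readId))
})

test_that("identity and insert histograms conserve counts", {
    hits <- data.frame(readId = c("a", "a", "b"), mate = c(1L, 2L, 1L),
                       refId = "R", identity = c(1, 1, 1),
                       insertSize = c(300L, 300L, NA))
    h <- alignmentHistograms(hits)
    expect_equal(sum(h$identity$count), 3)
    expect_equal(h$identity$count[h$identity$bin == 100], 3)
    expect_equal(h$insert, data.frame(bin = 300L, count = 1L))
    none <- alignmentHistograms(hits[hits$mate == 1 & hits$readId == "b", ])
    expect_equal(nrow(none$insert), 0)
})

test_that("fixture pairs simulated at a fixed insert land in one bin", {
    spec <- fixtureSpec(seed = 31, nTaxa = 4, nPairs = 40, fractionSsu = 1,
                        insertMean = 300, insertSd = 0, errorRate = 0)
    db <- genReferenceDb(spec)
    rd <- genReads(spec, db$refs)
    ex <- extractReads(rd$pairs, buildRefIndex(db$refs))
    h <- alignmentHistograms(ex$hits)
    expect_equal(h$insert$bin, 300L)
})

test_that("SAM pairing repair is consistent and idempotent", {
    sam <- data.frame(
        qname = c("r1/1", "r1/2", "r2/1", "r2/2", "r3/1"),
        flag = c(0L, 0L, 0L, 4L, 0L),
        rname = c("A", "A", "A", "*", "B"),
        pos = c(10L, 200L, 50L, 0L, 70L),
        mapq = 255L, cigar = "100M",
        rnext = "*", pnext = 0L, tlen = 0L, seq = "ACGT", qual = "*",
        stringsAsFactors = FALSE)
    sam$flag[2] <- 16L   # mate 2 on the reverse strand
    rep1 <- repairSamPairing(sam)
    expect_equal(rep1$qname, c("r1", "r1", "r2", "r2", "r3"))
    expect_true(all(bitwAnd(rep1$flag, 1L) == 1L))
    expect_equal(bitwAnd(rep1$flag[1:2], c(64L, 128L)), c(64L, 128L))
    # r1: proper pair, mate fields point at each other
    expect_true(all(bitwAnd(rep1$flag[1:2], 2L) == 2L))
    expect_equal(rep1$rnext[1:2], c("=", "="))
    expect_equal(rep1$pnext[1:2], c(200L, 10L))
    # mate-strand bit mirrored
    expect_equal(bitwAnd(rep1$flag[1], 32L), 32L)
    expect_equal(bitwAnd(rep1$flag[2], 32L), 0L)
    # r2: mate unmapped propagated, not proper
    expect_equal(bitwAnd(rep1$flag[3], 8L), 8L)
    expect_equal(bitwAnd(rep1$flag[3], 2L), 0L)
    expect_equal(rep1$rnext[3], "=")
    # r3: orphan flagged, not dropped
    expect_true(rep1$orphan[5])
    expect_equal(nrow(rep1), 5)
    # idempotence
    rep2 <- repairSamPairing(rep1)
    expect_identical(rep1, rep2)
})

test_that("extraction SAM round-trips through write and read", {
    spec <- fixtureSpec(seed = 41, nTaxa = 4, nPairs = 30, fractionSsu = 0.5)
    db <- genReferenceDb(spec)
    idx <- buildRefIndex(db$refs)
    ex <- extractReads(genReads(spec, db$refs)$pairs, idx)
    sam <- extractionToSam(ex, idx)
    f <- tempfile(fileext = ".sam")
    writeSamFile(sam, f)
    back <- readSam(f)
    expect_equal(back$qname, sam$qname)
    expect_equal(back$flag, sam$flag)
    expect_equal(back$pos, sam$pos)
    expect_true(any(startsWith(attr(back, "header"), "@SQ")))
    # repair of an already-consistent SAM changes nothing
    again <- repairSamPairing(back)
    expect_equal(again$flag, back$flag)
    expect_equal(again$rnext, back$rnext)
})
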