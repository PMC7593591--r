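test_that("assembly k-mer rule matches the published mapping", {
    expect_identical(chooseKmers(150), c(99L, 111L, 127L))
    expect_identical(chooseKmers(134), c(99L, 111L, 127L))
    expect_identical(chooseKmers(100), c(73L, 83L, 93L))
    expect_error(chooseKmers(30), "at least 40")
    # odd, ascending, below the read length, for every read length
    for (rl in 40:250) {
        km <- chooseKmers(rl)
        expect_true(all(km %% 2 == 1))
        expect_true(all(diff(km) > 0))
        expect_true(all(km < rl))
    }
})

test_that("EM-assembler insert rule follows read length and observed mean", {
    expect_equal(emirgeInsertRule(250)$mode, "single")
    long <- emirgeInsertRule(153, 400)
    expect_equal(long$mode, "single")
    expect_true(is.na(long$insert))
    obs <- emirgeInsertRule(100, 300)
    expect_equal(obs$mode, "paired")
    expect_equal(obs$insert, 300)
    # observed mean below 2.2x read length: floor of 2.2 * L + 0.5
    low <- emirgeInsertRule(100, 180)
    expect_equal(low$insert, 220.5)
    expect_equal(low$iterations, 40)
    expect_error(emirgeInsertRule(100, -5), "negative")
})

test_that("SSU region extraction filters exactly like the exhaustive oracle", {
    set.seed(71)
    contigs <- Biostrings::DNAStringSet(
        setNames(vapply(1:3, function(i) rndSeq(2000), character(1)),
                 c("c1", "c2", "c3")))
    hits <- featureHits(
        targetId = c("c1", "c1", "c2", "c3", "c3"),
        model = c("ssu_bac", "ssu_euk", "ssu_bac", "ssu_arc", "ssu_bac"),
        evalue = c(1e-150, 1e-150, 1e-50, 1e-150, 1e-200),
        modelFraction = c(0.65, 0.5, 0.9, 0.8, 0.7),
        start = c(100L, 300L, 100L, 500L, 1200L),
        end = c(1000L, 800L, 1000L, 1400L, 1900L),
        strand = c("+", "+", "+", "-", "+"))
    regions <- extractSsuRegions(contigs, hits)
    # oracle: exhaustive filter on both thresholds
    pass <- hits[hits$evalue <= 1e-100 & hits$modelFraction >= 0.6, ]
    expect_setequal(regions$contigId, pass$targetId)
    expect_equal(nrow(regions), 3)
    # plus-strand region emitted verbatim
    r1 <- regions[regions$contigId == "c1", ]
    expect_equal(r1$seq,
                 as.character(Biostrings::subseq(contigs[["c1"]], 100, 1000)))
    # minus-strand region equals the reverse complement of the slice
    r3 <- regions[regions$contigId == "c3" & regions$strand == "-", ]
    expect_equal(r3$seq,
                 revcompChr(as.character(Biostrings::subseq(contigs[["c3"]],
                                                            500, 1400))))
    # out-of-bounds hit is an input-consistency error
    bad <- featureHits("c1", "ssu_bac", 1e-150, 0.9, 1500L, 2500L, "+")
    expect_error(extractSsuRegions(contigs, bad), "bounds")
})

test_that("overlapping same-model hits keep the lowest E-value", {
    set.seed(72)
    contigs <- Biostrings::DNAStringSet(c(c1 = rndSeq(2000)))
    hits <- featureHits(
        targetId = c("c1", "c1"), model = "ssu_bac",
        evalue = c(1e-150, 1e-180), modelFraction = c(0.8, 0.9),
        start = c(100L, 150L), end = c(1000L, 1050L), strand = "+")
    regions <- extractSsuRegions(contigs, hits)
    expect_equal(nrow(regions), 1)
    expect_equal(regions$evalue, 1e-180)
})

test_that("assembled fraction reflects read origin and identity cutoff", {
    set.seed(73)
    gene <- rndSeq(1500)
    other <- rndSeq(1500)
    pos <- seq(1, 1300, by = 50)
    fromGene <- setNames(substring(gene, pos, pos + 99), paste0("g", pos))
    fromOther <- setNames(substring(other, pos, pos + 99), paste0("o", pos))
    allPairs <- PairedReads(c(fromGene, fromOther),
                            setNames(vapply(
                                c(fromGene, fromOther), revcompChr,
                                character(1)),
                                names(c(fromGene, fromOther))))
    # every read drawn verbatim from the assembled gene: fraction 1
    onlyGene <- PairedReads(fromGene,
                            setNames(vapply(fromGene, revcompChr,
                                            character(1)), names(fromGene)))
    expect_equal(assembledFraction(onlyGene, c(asm = gene)), 1.0)
    # no assembled sequences: 0; no reads: absent
    expect_equal(assembledFraction(onlyGene, character(0)), 0)
    expect_true(is.na(assembledFraction(
        PairedReads(Biostrings::DNAStringSet(), Biostrings::DNAStringSet()),
        c(asm = gene))))
    # half the reads derive from the assembled gene
    half <- assembledFraction(allPairs, c(asm = gene))
    expect_equal(half, 0.5, tolerance = 0.05)
    # monotone non-increasing in the identity cutoff
    spec <- fixtureSpec(seed = 74, nTaxa = 4, nPairs = 80, fractionSsu = 1,
                        errorRate = 0.02)
    db <- genReferenceDb(spec)
    rd <- genReads(spec, db$refs)
    asm <- as.character(refSeqs(db$refs))[1:2]
    fr <- vapply(c(0.80, 0.90, 0.98, 1.0), function(mi)
        assembledFraction(rd$pairs, asm, minIdentity = mi), numeric(1))
    expect_true(all(diff(fr) <= 1e-12))
})

test_that("closest reference respects the cutoff and tie-breaking", {
    set.seed(75)
    a <- rndSeq(1500)
    refs <- ReferenceSet(c(refB = a, refA = a, refC = rndSeq(1500)),
                         taxonomy = rep("", 3))
    # identical region: identity 1, lexicographically first id on the tie
    hit <- closestReference(a, refs)
    expect_equal(hit$refId, "refA")
    expect_equal(hit$identity, 1.0)
    # heavily diverged region: no qualifying reference
    expect_null(closestReference(mutSeq(a, 700), refs))
    expect_null(closestReference(a, refs[character(0)]))
})
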