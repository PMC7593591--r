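test_that("LSU-fragment removal applies both thresholds and flags only", {
    set.seed(101)
    seqs <- setNames(replicate(4, rndSeq(1200)), c("W", "X", "Y", "Z"))
    refs <- ReferenceSet(seqs, taxonomy = rep("Bacteria;P;C", 4))
    hits <- featureHits(
        targetId = c("X", "Y", "Z"), model = rep("lsu", 3),
        evalue = c(1e-12, 1e-8, 1e-12), modelFraction = c(0.15, 0.15, 0.08),
        start = c(1, 1, 1), end = c(180, 180, 96), strand = "+")
    out <- removeLsuFragments(refs, hits)
    expect_equal(unname(isKept(out)[c("W", "X", "Y", "Z")]),
                 c(TRUE, FALSE, TRUE, TRUE))
    expect_equal(unname(dropReason(out)["X"]), "lsu_fragment")
    # sequence content untouched
    expect_identical(as.character(refSeqs(out)), as.character(refSeqs(refs)))
    # unknown target id is an input-consistency error
    bad <- featureHits("NOPE", "lsu", 1e-12, 0.5, 1, 100, "+")
    expect_error(removeLsuFragments(refs, bad), "unknown")
})

test_that("alphabet normalization transcribes U and resolves ambiguity", {
    refs <- ReferenceSet(c(a = "ACGU", b = "RACGT", c = "ACGT"),
                         taxonomy = rep("", 3))
    out <- normalizeAlphabet(refs, seed = 5)
    expect_equal(as.character(refSeqs(out)[["a"]]), "ACGT")
    expect_true(substr(as.character(refSeqs(out)[["b"]]), 1, 1) %in%
                c("A", "G"))
    expect_equal(as.character(refSeqs(out)[["c"]]), "ACGT")
    # reproducible for a fixed seed
    again <- normalizeAlphabet(refs, seed = 5)
    expect_identical(as.character(refSeqs(out)), as.character(refSeqs(again)))
    # non-IUPAC characters are rejected at the container boundary already
    expect_error(ReferenceSet(c(x = "ACGQ"), ""))
})

test_that("low-complexity masking agrees with the window-entropy oracle", {
    set.seed(202)
    for (rep in 1:3) {
        rnd <- rndSeq(200)
        s <- paste0(substr(rnd, 1, 75), strrep("A", 50), substr(rnd, 126, 200))
        refs <- ReferenceSet(setNames(c(rnd, s), c("rand", "homo")),
                             taxonomy = c("", ""))
        out <- maskLowComplexity(refs)
        # fully random sequence: no window flagged, nothing masked
        expect_length(maskedRanges(out)[["rand"]], 0)
        # homopolymer: exactly one interval, covering the run +/- <= kmax
        r <- maskedRanges(out)[["homo"]]
        expect_length(r, 1)
        expect_lte(abs(IRanges::start(r) - 76), 8)
        expect_lte(abs(IRanges::end(r) - 125), 8)
        # masked region replaced by N in the sequence
        masked <- substr(as.character(refSeqs(out)[["homo"]]),
                         IRanges::start(r), IRanges::end(r))
        expect_true(grepl("^N+$", masked))
        # oracle agreement on the masked position set: repeated content
        # must recur at every k in the range
        pos <- sort(Reduce(intersect, lapply(4:8, function(k)
            oracleMaskPositions(s, k, 0.7))))
        got <- unlist(lapply(seq_len(length(r)), function(i)
            IRanges::start(r)[i]:IRanges::end(r)[i]))
        # oracle positions merged and length-filtered must equal the output
        oracleRuns <- IRanges::reduce(IRanges::IRanges(start = pos,
                                                       width = 1))
        oracleRuns <- oracleRuns[IRanges::width(oracleRuns) >= 20]
        expect_equal(got, unlist(lapply(seq_along(oracleRuns), function(i)
            IRanges::start(oracleRuns)[i]:IRanges::end(oracleRuns)[i])))
    }
})

test_that("short homopolymers below the minimum masked length survive", {
    set.seed(203)
    rnd <- rndSeq(200)
    s <- paste0(substr(rnd, 1, 95), strrep("A", 10), substr(rnd, 106, 200))
    out <- maskLowComplexity(ReferenceSet(c(x = s), taxonomy = ""))
    expect_length(maskedRanges(out)[["x"]], 0)
    expect_equal(as.character(refSeqs(out)[["x"]]), s)
})

test_that("vector screening trims matches and drops short remnants", {
    set.seed(303)
    vec <- rndSeq(600)
    # 1,000-bp record with one exact vector 27-mer at 1-based 11..37
    base <- rndSeq(1000)
    withVec <- paste0(substr(base, 1, 10), substr(vec, 100, 126),
                      substr(base, 38, 1000))
    # 850-bp record with the vector k-mer in the middle: both fragments < 800
    mid <- rndSeq(850)
    midVec <- paste0(substr(mid, 1, 410), substr(vec, 200, 226),
                     substr(mid, 438, 850))
    clean <- rndSeq(900)
    refs <- ReferenceSet(setNames(c(withVec, midVec, clean),
                                  c("a", "b", "c")),
                         taxonomy = rep("", 3))
    out <- screenVector(refs, vec)
    # the exact 27-mer spans 11..37; windows overhanging the insert by one
    # or two bases are themselves genuine Hamming-1 matches, so the trimmed
    # fragment can be a few bp shorter than the 963 bp of the exact span
    expect_true(isKept(out)[["a"]])
    expect_gte(IRanges::width(refSeqs(out))[[1]], 957)
    expect_lte(IRanges::width(refSeqs(out))[[1]], 963)
    expect_false(isKept(out)[["b"]])
    expect_equal(unname(dropReason(out)[["b"]]), "too_short_after_trim")
    expect_equal(as.character(refSeqs(out)[["c"]]), clean)
    # invariant: no vector k-mer within Hamming distance 1 survives
    expect_false(oracleVectorMatch(as.character(refSeqs(out)[["a"]]),
                                   vec, 27, 11, 1))
    expect_error(screenVector(refs, vec, k = 27, kEnd = 30), "kEnd")
})

test_that("vector screening catches Hamming-1 and end-anchored matches", {
    set.seed(304)
    vec <- rndSeq(600)
    km <- substr(vec, 50, 76)
    kmMut <- mutSeq(km, 1)                 # Hamming distance 1
    endK <- substr(vec, 300, 314)          # 15-mer, below k, above kEnd
    base <- rndSeq(1900)
    s <- paste0(endK, substr(base, 16, 950), kmMut, substr(base, 978, 1900))
    out <- screenVector(ReferenceSet(c(x = s), taxonomy = ""), vec)
    expect_false(oracleVectorMatch(as.character(refSeqs(out)[["x"]]),
                                   vec, 27, 11, 1))
    # the 5' end-anchored 15-mer must have been trimmed off
    expect_false(startsWith(as.character(refSeqs(out)[["x"]]), endK))
})

test_that("greedy clustering matches pairwise-identity oracle and ordering", {
    set.seed(404)
    s1 <- rndSeq(1500)
    s2 <- mutSeq(s1, 5)     # ~99.7% identity
    s3 <- mutSeq(s1, 75)    # ~95% identity
    # derived expectation from the independent Biostrings oracle
    expect_gte(oracleGlobalIdentity(s2, s1), 0.99)
    expect_lt(oracleGlobalIdentity(s3, s1), 0.99)
    cl <- greedyCluster(Biostrings::DNAStringSet(c(s1 = s1, s2 = s2,
                                                   s3 = s3)), 0.99)
    expect_setequal(cl$centroidId[cl$memberId %in% c("s1", "s2")], "s1")
    expect_equal(cl$centroidId[cl$memberId == "s3"], "s3")
    # identical sequences collapse to one cluster at identity 1
    cl2 <- greedyCluster(Biostrings::DNAStringSet(c(a = s1, b = s1)), 0.99)
    expect_equal(sort(unique(cl2$centroidId)), "a")
    expect_equal(cl2$identityToCentroid, c(1, 1))
    # every non-centroid meets the threshold; centroids are their own members
    expect_true(all(cl$identityToCentroid >= 0.99))
    # cluster count is non-increasing as the threshold loosens
    seqs <- Biostrings::DNAStringSet(setNames(
        c(s1, s2, s3, mutSeq(s1, 150), mutSeq(s1, 40)), paste0("q", 1:5)))
    nClusters <- vapply(c(0.999, 0.99, 0.97, 0.90), function(th)
        length(unique(greedyCluster(seqs, th)$centroidId)), numeric(1))
    expect_true(all(diff(nClusters) <= 0))
    expect_equal(nrow(greedyCluster(Biostrings::DNAStringSet(), 0.99)), 0)
})

test_that("full curation pass is idempotent", {
    spec <- fixtureSpec(seed = 17, nTaxa = 6, ssuLength = 1200,
                        lsuFraction = 0.2, lowComplexityFraction = 0.2,
                        vectorInsertFraction = 0.2)
    db <- genReferenceDb(spec)
    pass1 <- curateReferences(db$refs, lsuHits = db$lsuHits,
                              vectors = db$vectors, seed = 9)
    pass2 <- curateReferences(pass1$refs, lsuHits = db$lsuHits,
                              vectors = db$vectors, seed = 9)
    expect_identical(as.character(refSeqs(pass1$refs)),
                     as.character(refSeqs(pass2$refs)))
    expect_identical(isKept(pass1$refs), isKept(pass2$refs))
    expect_identical(pass1$clusters, pass2$clusters)
    # truth-flagged artifacts were handled
    expect_false(any(isKept(pass1$refs)[db$truth$id[db$truth$injectedLsu]]))
    lowIds <- db$truth$id[db$truth$injectedLowComplexity &
                          isKept(pass1$refs)[db$truth$id]]
    for (id in lowIds) {
        r <- maskedRanges(pass1$refs)[[id]]
        expect_gte(sum(IRanges::width(r)), 50)
    }
})
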