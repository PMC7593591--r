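writeTempFastg <- function(lines) {
    f <- tempfile(fileext = ".fastg")
    writeLines(lines, f)
    f
}

test_that("Fastg parsing collapses orientations into one undirected graph", {
    g <- parseFastg(writeTempFastg(c(">A:B;", "ACGT", ">B;", "GGCC")))
    expect_setequal(graphContigs(g)$id, c("A", "B"))
    expect_equal(nrow(graphEdges(g)), 1)
    expect_setequal(as.vector(graphEdges(g)), c("A", "B"))
    # orientation markers collapse to the same edge, enumerated dialect cases
    cases <- list(c(">A':B;", "A", ">B;", "C"),
                  c(">A:B';", "A", ">B;", "C"),
                  c(">A':B';", "A", ">B;", "C"),
                  c(">A:B;", "A", ">B':A';", "C"))
    for (cs in cases) {
        gc <- parseFastg(writeTempFastg(cs))
        expect_equal(nrow(graphEdges(gc)), 1)
        expect_setequal(as.vector(graphEdges(gc)), c("A", "B"))
    }
    # isolated node
    g1 <- parseFastg(writeTempFastg(c(">A;", "ACGT")))
    expect_equal(nrow(graphEdges(g1)), 0)
    # SPAdes headers parsed for length and coverage
    g2 <- parseFastg(writeTempFastg(c(
        ">EDGE_1_length_4_cov_12.5:EDGE_2_length_4_cov_3.0;", "ACGT",
        ">EDGE_2_length_4_cov_3.0;", "GGCC")))
    expect_equal(graphContigs(g2)$coverage, c(12.5, 3.0))
    expect_equal(graphContigs(g2)$length, c(4L, 4L))
    # dangling adjacency names the offending record
    expect_error(parseFastg(writeTempFastg(c(">A:Z;", "ACGT"))), "Z")
})

test_that("Fastg round-trip reparses to an isomorphic graph", {
    spec <- fixtureSpec(seed = 91, nTaxa = 4, ssuLength = 800)
    fg <- genFastg(spec)
    f <- tempfile(fileext = ".fastg")
    writeFastg(fg$graph, f)
    back <- parseFastg(f)
    expect_setequal(graphContigs(back)$id, graphContigs(fg$graph)$id)
    norm <- function(e) sort(paste(pmin(e[, 1], e[, 2]),
                                   pmax(e[, 1], e[, 2])))
    expect_equal(norm(graphEdges(back)), norm(graphEdges(fg$graph)))
    expect_equal(as.character(graphSeqs(back)[graphContigs(back)$id]),
                 as.character(graphSeqs(fg$graph)[graphContigs(back)$id]))
})

test_that("fishing returns the BFS component of each seed", {
    # chain A - B - C with the SSU on A
    g <- AssemblyGraph(
        data.frame(id = c("A", "B", "C", "D"), length = 1000L,
                   coverage = 1.0),
        edges = rbind(c("A", "B"), c("B", "C")))
    hits <- featureHits("A", "ssu_bac", 1e-150, 0.9, 1L, 900L, "+")
    cl <- fishClusters(g, hits)
    expect_length(cl, 1)
    expect_equal(cl[[1]]$members, c("A", "B", "C"))
    expect_equal(cl[[1]]$seeds, "A")
    # second disjoint component without a seed is not reported
    expect_false("D" %in% unlist(lapply(cl, `[[`, "members")))
    # sub-threshold hits do not seed
    weak <- featureHits("D", "ssu_bac", 1e-20, 0.9, 1L, 900L, "+")
    expect_warning(expect_length(fishClusters(g, weak), 0), "no SSU")
    # small clusters are flagged, not dropped
    cl2 <- fishClusters(g, hits, minClusterSizeBp = 10000)
    expect_true(cl2[[1]]$flaggedSmall)
})

test_that("fishing agrees with a plain BFS oracle on random graphs", {
    set.seed(92)
    for (rep in 1:10) {
        n <- 50
        ids <- paste0("n", 1:n)
        edges <- NULL
        for (i in 2:n) {
            if (runif(1) < 0.8)
                edges <- rbind(edges, c(ids[sample.int(i - 1, 1)], ids[i]))
        }
        g <- AssemblyGraph(data.frame(id = ids, length = 1000L,
                                      coverage = 1.0), edges = edges)
        seed <- sample(ids, 1)
        hits <- featureHits(seed, "ssu_bac", 1e-150, 0.9, 1L, 900L, "+")
        cl <- fishClusters(g, hits)
        expect_length(cl, 1)
        expect_equal(cl[[1]]$members,
                     oracleBfsComponent(g@edges, ids, seed))
    }
})

test_that("planted-genome fixtures are fished back exactly", {
    spec <- fixtureSpec(seed = 93, nTaxa = 3, ssuLength = 800,
                        contigsPerGenome = 5)
    fg <- genFastg(spec)
    cl <- fishClusters(fg$graph, fg$ssuHits)
    expect_length(cl, 3)
    got <- lapply(cl, `[[`, "members")
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(fg$truth, paste, character(1), collapse = ","))
    # members never exceed the node set and seed sets are disjoint
    expect_lte(length(unique(unlist(got))), nrow(graphContigs(fg$graph)))
})

test_that("bin linking reports majorities, ties and missing contigs", {
    g <- AssemblyGraph(data.frame(id = c("A", "B", "C"), length = 1000L,
                                  coverage = 1.0),
                       edges = rbind(c("A", "B"), c("B", "C")))
    hits <- featureHits("A", "ssu_bac", 1e-150, 0.9, 1L, 900L, "+")
    cl <- fishClusters(g, hits)
    linked <- linkBins(cl, data.frame(contig = c("A", "B"),
                                      bin = c("b1", "b1")), g)
    expect_equal(linked[[1]]$binOverlap$majorityBin, "b1")
    expect_equal(linked[[1]]$binOverlap$fraction, 2 / 3)
    expect_false(linked[[1]]$binOverlap$ambiguous)
    # no member binned
    none <- linkBins(cl, data.frame(contig = "Z", bin = "b9"))
    expect_length(none[[1]]$binOverlap$counts, 0)
    # tie between bins: both reported, flagged ambiguous
    tie <- linkBins(cl, data.frame(contig = c("A", "B"),
                                   bin = c("b1", "b2")))
    expect_equal(tie[[1]]$binOverlap$majorityBin, c("b1", "b2"))
    expect_true(tie[[1]]$binOverlap$ambiguous)
    # contig absent from the graph is warned about
    expect_warning(linkBins(cl, data.frame(contig = "Q", bin = "b1"), g),
                   "absent")
})

test_that("targeted-SSU matching honors the cutoff and tie-breaking", {
    set.seed(94)
    gene <- rndSeq(800)
    contig <- paste0(rndSeq(100), gene, rndSeq(100))
    g <- AssemblyGraph(
        data.frame(id = c("A", "B"), length = c(1000L, 500L),
                   coverage = 1.0),
        edges = rbind(c("A", "B")),
        seqs = Biostrings::DNAStringSet(c(A = contig, B = rndSeq(500))))
    hits <- featureHits("A", "ssu_bac", 1e-150, 0.9, 101L, 900L, "+")
    cl <- fishClusters(g, hits)
    # identical targeted sequence: identity 1; tie broken lexicographically
    m <- matchTargetedSsu(cl, g, c(t2 = gene, t1 = gene))
    expect_equal(m[[1]]$matchedSsu$ssuId, "t1")
    expect_equal(m[[1]]$matchedSsu$identity, 1.0)
    # 90%-identity best match is below the 0.98 cutoff
    far <- mutSeq(gene, 80)
    m2 <- matchTargetedSsu(cl, g, c(t1 = far))
    expect_equal(nrow(m2[[1]]$matchedSsu), 0)
})
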