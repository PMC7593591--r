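# Seeded synthetic fixture generators for every input the pipeline consumes:
# reference databases with SILVA-style taxonomy and curated artifacts,
# paired-end read libraries with ground truth, and Fastg assembly graphs with
# planted genomes. One global seed fans out to independent per-generator
# streams so adding a generator never perturbs the others.

.BASES <- c("A", "C", "G", "T")

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                              collapse = "")

# substitute a fraction `rate` of positions with a different base
.mutateSeq <- function(seq, rate) {
    if (rate <= 0) return(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    idx <- which(runif(length(ch)) < rate)
    for (i in idx) {
        ch[i] <- sample(setdiff(.BASES, ch[i]), 1)
    }
    paste(ch, collapse = "")
}

#' Specification of a synthetic fixture
#'
#' Defaults emulate a low-to-moderate diversity shotgun library: a dozen
#' taxa with roughly phylum-to-species level divergence between their
#' ~1,500-bp SSU genes, 100-bp paired-end reads with a 220 +/- 110 bp insert
#' profile, 1\% substitution error, and one tenth of the pairs originating
#' from SSU genes.
#'
#' @param seed global seed; all generator randomness flows from it.
#' @param nTaxa number of taxa / reference SSU genes (>= 2).
#' @param ssuLength SSU gene length in bp.
#' @param nPairs total read pairs to simulate.
#' @param readLen read length in bp.
#' @param insertMean,insertSd insert size distribution (outer distance).
#' @param errorRate per-base substitution error rate.
#' @param fractionSsu fraction of pairs drawn from SSU genes (the rest is
#'   random background).
#' @param divergence per-rank substitution rates along the 7-level taxonomy
#'   (domain first).
#' @param lsuFraction,lowComplexityFraction,vectorInsertFraction fractions of
#'   reference records receiving, respectively, an LSU-fragment tail, a 60-bp
#'   homopolymer run, and an embedded vector 27-mer (truth-flagged).
#' @param contigsPerGenome,extraEdgeProb,binErrors assembly-graph shape:
#'   contigs per planted genome, probability of extra intra-genome edges,
#'   number of deliberately mis-assigned bin-table rows.
#' @return list of class \code{ssuflash_fixture_spec}.
#' @export
fixtureSpec <- function(seed = 42, nTaxa = 12, ssuLength = 1500,
                        nPairs = 10000, readLen = 100, insertMean = 220,
                        insertSd = 110, errorRate = 0.01, fractionSsu = 0.1,
                        divergence = c(0.08, 0.05, 0.03, 0.02, 0.012,
                                       0.008, 0.004),
                        lsuFraction = 0, lowComplexityFraction = 0,
                        vectorInsertFraction = 0, contigsPerGenome = 5,
                        extraEdgeProb = 0.2, binErrors = 0) {
    stopifnot(nTaxa >= 2, fractionSsu >= 0, fractionSsu <= 1,
              errorRate >= 0, errorRate <= 1, length(divergence) == 7)
    set.seed(seed)
    streams <- sample.int(2^31 - 2, 4)
    structure(list(seed = seed, streams = streams, nTaxa = nTaxa,
                   ssuLength = ssuLength, nPairs = nPairs, readLen = readLen,
                   insertMean = insertMean, insertSd = insertSd,
                   errorRate = errorRate, fractionSsu = fractionSsu,
                   divergence = divergence, lsuFraction = lsuFraction,
                   lowComplexityFraction = lowComplexityFraction,
                   vectorInsertFraction = vectorInsertFraction,
                   contigsPerGenome = contigsPerGenome,
                   extraEdgeProb = extraEdgeProb, binErrors = binErrors),
              class = "ssuflash_fixture_spec")
}

.RANKS <- c("Domain", "Phylum", "Class", "Order", "Family", "Genus",
            "Species")

#' Generate a synthetic SSU reference database with ground truth
#'
#' Simulates a root SSU sequence mutated along a random 7-level taxonomy
#' hierarchy (one leaf per taxon), then injects curation artifacts into
#' designated, truth-flagged records: LSU-fragment tails (with a matching
#' LSU hit table), 60-bp homopolymer runs, and vector 27-mers drawn from a
#' synthetic vector sequence.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return list with \code{refs} (\code{\link{ReferenceSet}}),
#'   \code{lsuHits} (hit table), \code{vectors} (DNAStringSet with the
#'   synthetic vector), and \code{truth} (data.frame id, taxonomy,
#'   injectedLsu, injectedLowComplexity, injectedVector).
#' @export
genReferenceDb <- function(spec) {
    set.seed(spec$streams[1])
    n <- spec$nTaxa
    root <- .randSeq(spec$ssuLength)
    # recursive hierarchy: split the taxon set at each rank, mutating the
    # ancestral sequence once per group
    seqs <- rep(root, n)
    labels <- matrix("", nrow = n, ncol = 7)
    groups <- list(seq_len(n))
    counter <- 0L
    for (r in 1:7) {
        newGroups <- list()
        for (g in groups) {
            nsub <- if (r == 7) length(g)
                    else if (r == 1) min(2L, length(g))
                    else min(length(g), sample.int(3L, 1))
            parts <- split(g, sort(rep_len(seq_len(nsub), length(g))))
            for (p in parts) {
                counter <- counter + 1L
                mut <- .mutateSeq(seqs[p[1]], spec$divergence[r])
                seqs[p] <- mut
                labels[p, r] <- paste0(.RANKS[r], "_", counter)
                newGroups[[length(newGroups) + 1L]] <- p
            }
        }
        groups <- newGroups
    }
    ids <- sprintf("REF_%04d", seq_len(n))
    tax <- apply(labels, 1, paste, collapse = ";")
    # allocate artifact injections to disjoint records
    ord <- sample.int(n)
    nLsu <- round(spec$lsuFraction * n)
    nLow <- round(spec$lowComplexityFraction * n)
    nVec <- round(spec$vectorInsertFraction * n)
    if (nLsu + nLow + nVec > n)
        stop("injection fractions exceed the record count")
    iLsu <- ord[seq_len(nLsu)]
    iLow <- ord[nLsu + seq_len(nLow)]
    iVec <- ord[nLsu + nLow + seq_len(nVec)]
    vector <- .randSeq(600)
    lsuHits <- NULL
    for (i in iLsu) {
        tail <- .randSeq(300)
        pos <- nchar(seqs[i]) + 1L
        seqs[i] <- paste0(seqs[i], tail)
        lsuHits <- rbind(lsuHits, data.frame(
            targetId = ids[i], model = "lsu", evalue = 1e-12,
            modelFraction = 0.15, start = pos, end = pos + 299L,
            strand = "+", stringsAsFactors = FALSE))
    }
    for (i in iLow) {
        at <- sample(200:(nchar(seqs[i]) - 260), 1)
        substr(seqs[i], at, at + 59L) <- strrep("A", 60)
    }
    for (i in iVec) {
        vAt <- sample(seq_len(600 - 26), 1)
        at <- sample(200:(nchar(seqs[i]) - 230), 1)
        substr(seqs[i], at, at + 26L) <- substr(vector, vAt, vAt + 26L)
    }
    refs <- ReferenceSet(setNames(seqs, ids), taxonomy = tax)
    if (is.null(lsuHits))
        lsuHits <- featureHits(character(0), character(0), numeric(0),
                               numeric(0), integer(0), integer(0),
                               character(0))
    truth <- data.frame(id = ids, taxonomy = tax,
                        injectedLsu = seq_len(n) %in% iLsu,
                        injectedLowComplexity = seq_len(n) %in% iLow,
                        injectedVector = seq_len(n) %in% iVec,
                        stringsAsFactors = FALSE)
    list(refs = refs, lsuHits = lsuHits,
         vectors = DNAStringSet(c(synthetic_vector = vector)), truth = truth)
}

#' Simulate a paired-end read library with ground truth
#'
#' Pairs are drawn either from the reference SSU genes (forward/reverse
#' fragments with a normal insert-size profile and uniform substitution
#' errors) or from random background sequence. Truth alignment records for
#' the SSU-origin mates are returned both as a table and as SAM records.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param refs the \code{\link{ReferenceSet}} to draw SSU fragments from.
#' @return list with \code{pairs} (\code{\link{PairedReads}}), \code{truth}
#'   (data.frame readId, origin, fragStart, fragStrand, insert) and
#'   \code{truthSam} (SAM data.frame of the error-free mate placements).
#' @export
genReads <- function(spec, refs) {
    set.seed(spec$streams[2])
    seqs <- as.character(refSeqs(refs))
    if (length(seqs) == 0) stop("empty reference set")
    if (spec$readLen > min(nchar(seqs)))
        stop("read length exceeds the SSU gene length")
    nSsu <- round(spec$nPairs * spec$fractionSsu)
    nBg <- spec$nPairs - nSsu
    ids <- sprintf("RP%06d", seq_len(spec$nPairs))
    r1 <- character(spec$nPairs); r2 <- character(spec$nPairs)
    origin <- rep("background", spec$nPairs)
    fragStart <- rep(NA_integer_, spec$nPairs)
    fragStrand <- rep(NA_character_, spec$nPairs)
    insert <- rep(NA_integer_, spec$nPairs)
    sam <- list()
    if (nSsu > 0) {
        src <- sample.int(length(seqs), nSsu, replace = TRUE)
        for (i in seq_len(nSsu)) {
            s <- seqs[src[i]]
            L <- nchar(s)
            ins <- round(rnorm(1, spec$insertMean, spec$insertSd))
            ins <- max(spec$readLen, min(ins, L))
            st <- sample.int(L - ins + 1L, 1)
            frag <- substr(s, st, st + ins - 1L)
            strand <- sample(c("+", "-"), 1)
            if (strand == "-")
                frag <- as.character(reverseComplement(DNAString(frag)))
            m1 <- substr(frag, 1, spec$readLen)
            m2 <- as.character(reverseComplement(DNAString(
                substr(frag, ins - spec$readLen + 1L, ins))))
            origin[i] <- names(seqs)[src[i]]
            fragStart[i] <- st; fragStrand[i] <- strand; insert[i] <- ins
            # truth placements on the reference forward strand
            if (strand == "+") {
                p1 <- st; s1 <- "+"
                p2 <- st + ins - spec$readLen; s2 <- "-"
            } else {
                p1 <- st + ins - spec$readLen; s1 <- "-"
                p2 <- st; s2 <- "+"
            }
            sam[[length(sam) + 1L]] <- data.frame(
                qname = ids[i],
                flag = c(1L + 64L + ifelse(s1 == "-", 16L, 0L) +
                             ifelse(s2 == "-", 32L, 0L),
                         1L + 128L + ifelse(s2 == "-", 16L, 0L) +
                             ifelse(s1 == "-", 32L, 0L)),
                rname = names(seqs)[src[i]], pos = c(p1, p2), mapq = 255L,
                cigar = paste0(spec$readLen, "M"), rnext = "=",
                pnext = c(p2, p1), tlen = c(ins, -ins), seq = c(m1, m2),
                qual = "*", stringsAsFactors = FALSE)
            r1[i] <- .mutateSeq(m1, spec$errorRate)
            r2[i] <- .mutateSeq(m2, spec$errorRate)
        }
    }
    if (nBg > 0) {
        for (i in nSsu + seq_len(nBg)) {
            r1[i] <- .randSeq(spec$readLen)
            r2[i] <- .randSeq(spec$readLen)
        }
    }
    truth <- data.frame(readId = ids, origin = origin,
                        fragStart = fragStart, fragStrand = fragStrand,
                        insert = insert, stringsAsFactors = FALSE)
    truthSam <- if (length(sam)) do.call(rbind, sam) else NULL
    list(pairs = PairedReads(setNames(r1, ids), setNames(r2, ids)),
         truth = truth, truthSam = truthSam)
}

#' Generate a Fastg assembly graph with planted genomes
#'
#' One planted "genome" per taxon: a connected random contig graph (a random
#' spanning tree plus optional extra edges) wired to one SSU-bearing contig
#' carrying that taxon's gene; no edges connect different genomes. A matching
#' bin table (with a configurable number of deliberate mis-assignments) and
#' the SSU hit table are emitted alongside the component truth.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param refs optional \code{\link{ReferenceSet}} supplying the SSU genes;
#'   generated from \code{spec} when omitted.
#' @return list with \code{graph} (\code{\link{AssemblyGraph}}),
#'   \code{ssuHits}, \code{binTable} (data.frame contig, bin) and
#'   \code{truth} (named list genome -> contig ids).
#' @export
genFastg <- function(spec, refs = NULL) {
    if (is.null(refs)) refs <- genReferenceDb(spec)$refs
    set.seed(spec$streams[3])
    genes <- as.character(refSeqs(refs))[seq_len(min(spec$nTaxa,
                                                     length(refs)))]
    ids <- character(0); seqs <- character(0)
    edges <- NULL; hits <- NULL; binTable <- NULL; truth <- list()
    cn <- 0L
    for (g in seq_along(genes)) {
        m <- spec$contigsPerGenome
        lens <- sample(500:3000, m, replace = TRUE)
        cseqs <- vapply(lens, .randSeq, character(1))
        # first contig of each genome carries the SSU gene with 100-bp flanks
        gene <- genes[g]
        cseqs[1] <- paste0(.randSeq(100), gene, .randSeq(100))
        lens[1] <- nchar(cseqs[1])
        cids <- sprintf("EDGE_%d_length_%d_cov_%.1f", cn + seq_len(m), lens,
                        runif(m, 5, 50))
        cn <- cn + m
        ids <- c(ids, cids); seqs <- c(seqs, cseqs)
        truth[[paste0("genome_", g)]] <- sort(cids)
        if (m > 1) {
            # random spanning tree keeps each genome connected
            for (i in 2:m)
                edges <- rbind(edges, c(cids[sample.int(i - 1L, 1)], cids[i]))
            extra <- which(runif(m) < spec$extraEdgeProb)
            for (i in extra) {
                j <- sample.int(m, 1)
                if (j != i) edges <- rbind(edges, c(cids[i], cids[j]))
            }
        }
        hits <- rbind(hits, data.frame(
            targetId = cids[1], model = "ssu_bac", evalue = 1e-150,
            modelFraction = 1.0, start = 101L, end = 100L + nchar(gene),
            strand = "+", stringsAsFactors = FALSE))
        binTable <- rbind(binTable, data.frame(
            contig = cids, bin = paste0("bin_", g), stringsAsFactors = FALSE))
    }
    if (spec$binErrors > 0) {
        wrong <- sample.int(nrow(binTable), min(spec$binErrors,
                                                nrow(binTable)))
        allBins <- unique(binTable$bin)
        for (i in wrong) {
            others <- setdiff(allBins, binTable$bin[i])
            if (length(others)) binTable$bin[i] <- sample(others, 1)
        }
    }
    contigs <- data.frame(id = ids, length = nchar(seqs),
                          coverage = as.numeric(sub(".*_cov_", "", ids)),
                          stringsAsFactors = FALSE)
    graph <- AssemblyGraph(contigs, edges = edges,
                           seqs = DNAStringSet(setNames(seqs, ids)))
    list(graph = graph, ssuHits = hits, binTable = binTable, truth = truth)
}
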