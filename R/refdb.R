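# Reference database curation: LSU-fragment removal, alphabet normalization,
# low-complexity masking, vector screening, greedy identity clustering.

#' Flag reference records contaminated with LSU rRNA fragments
#'
#' Records with at least one LSU-model hit passing both the E-value cutoff
#' and the model-fraction threshold are flagged \code{kept = FALSE} with
#' \code{dropReason = "lsu_fragment"}. Sequence content is never altered.
#'
#' @param refs A \code{\link{ReferenceSet}}.
#' @param hits hit table from \code{\link{featureHits}} /
#'   \code{\link{readFeatureHits}}.
#' @param evalueCutoff maximum E-value for a hit to count (default 1e-10).
#' @param minModelFraction hits must cover strictly more than this fraction
#'   of the full model length (default 0.10).
#' @return The updated \code{ReferenceSet}.
#' @export
removeLsuFragments <- function(refs, hits, evalueCutoff = 1e-10,
                               minModelFraction = 0.10) {
    if (nrow(hits) && !all(hits$targetId %in% refIds(refs)))
        stop("hit table references unknown record ids: ",
             paste(setdiff(hits$targetId, refIds(refs)), collapse = ", "))
    bad <- unique(hits$targetId[hits$model == "lsu" &
                                hits$evalue <= evalueCutoff &
                                hits$modelFraction > minModelFraction])
    hit <- refIds(refs) %in% bad & refs@kept
    refs@kept[hit] <- FALSE
    refs@dropReason[hit] <- "lsu_fragment"
    validObject(refs)
    refs
}

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = "N")   # N is the hard mask and must survive curation

#' Normalize RNA/ambiguity alphabet to A, C, G, T
#'
#' U is transcribed to T; every partial IUPAC ambiguity code is replaced by
#' a base drawn uniformly from the bases it denotes, using a seeded
#' generator so the result is reproducible. N is left untouched: it doubles
#' as the hard mask, so replacing it would undo masking and break the
#' idempotence of the curation pass.
#'
#' @param refs A \code{\link{ReferenceSet}}.
#' @param seed integer seed for the replacement draws.
#' @return The updated \code{ReferenceSet}.
#' @export
normalizeAlphabet <- function(refs, seed) {
    set.seed(seed)
    seqs <- as.character(refs@seqs)
    out <- vapply(seqs, function(s) {
        s <- chartr("u", "U", toupper(s))
        s <- chartr("U", "T", s)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        amb <- which(!(ch %in% c("A", "C", "G", "T")))
        if (length(amb)) {
            unknown <- setdiff(ch[amb], names(.IUPAC))
            if (length(unknown))
                stop("non-IUPAC character(s) in sequence: ",
                     paste(unknown, collapse = ", "))
            ch[amb] <- vapply(ch[amb], function(code) {
                opts <- .IUPAC[[code]]
                opts[sample.int(length(opts), 1L)]
            }, character(1))
            s <- paste(ch, collapse = "")
        }
        s
    }, character(1), USE.NAMES = FALSE)
    refs@seqs <- DNAStringSet(setNames(out, refIds(refs)))
    refs
}

# Flagged-window low-complexity detection for one sequence. Returns merged
# IRanges of masked positions. A window (length `window`, step 1) is flagged
# when its normalized k-mer entropy H / log2(min(4^k, valid k-mers)) falls
# below `entropyCutoff`; within a flagged window the low-complexity content
# is the positions covered by k-mers occurring more than once in that
# window. A position is masked when it is flagged as repeated content at
# EVERY k in [kmin, kmax]: genuine repeats and homopolymers recur at all k,
# whereas chance k-mer collisions in random sequence do not survive the
# larger k, so masked intervals track the offending run to within one k-mer
# length. Runs shorter than `minMaskedLen` after merging are not masked.
.lowComplexityRanges <- function(seq, kmin, kmax, entropyCutoff,
                                 minMaskedLen, window) {
    L <- nchar(seq)
    if (L == 0) stop("empty sequence")
    if (L <= kmax) stop("sequence length must exceed kmax")
    w <- min(window, L)
    maskedPos <- rep(TRUE, L)
    for (k in kmin:kmax) {
        posK <- logical(L)
        he <- .cppWindowEntropy(seq, k, w)
        Hmax <- log2(pmin(4^k, he[, 2]))
        flagged <- which(he[, 2] >= 2 & he[, 1] < entropyCutoff * Hmax)
        kmers <- substring(seq, seq_len(L - k + 1), seq_len(L - k + 1) + k - 1)
        valid <- !grepl("[^ACGT]", kmers)
        for (ws in flagged) {
            ks <- ws:(ws + w - k)          # k-mer start positions in window
            ks <- ks[valid[ks]]
            if (length(ks) < 2) next
            dup <- kmers[ks] %in% kmers[ks][duplicated(kmers[ks])]
            for (p in ks[dup]) posK[p:(p + k - 1)] <- TRUE
        }
        maskedPos <- maskedPos & posK
        if (!any(maskedPos)) break
    }
    r <- IRanges::reduce(IRanges(maskedPos))
    r[IRanges::width(r) >= minMaskedLen]
}

#' Mask low-complexity and repeat regions with N
#'
#' Slides a window across each kept sequence and computes the normalized
#' k-mer entropy for every k in [kmin, kmax]; positions covered, at every k
#' in the range, by repeated k-mer content inside windows falling below the
#' entropy cutoff are hard-masked with N, provided the merged masked run is
#' at least \code{minMaskedLen}. Masked intervals
#' are recorded on the \code{ReferenceSet} and excluded from downstream
#' k-mer indexing.
#'
#' @param refs A \code{\link{ReferenceSet}}.
#' @param kmin,kmax k-mer length range (defaults 4 and 8).
#' @param entropyCutoff normalized entropy threshold in [0, 1] (default 0.7).
#' @param minMaskedLen minimum masked run length in bp (default 20).
#' @param window sliding window length in bp (default 100).
#' @return The updated \code{ReferenceSet}.
#' @export
maskLowComplexity <- function(refs, kmin = 4, kmax = 8, entropyCutoff = 0.7,
                              minMaskedLen = 20, window = 100) {
    stopifnot(kmin <= kmax)
    seqs <- as.character(refs@seqs)
    masked <- as.list(refs@masked)
    for (i in which(refs@kept)) {
        r <- .lowComplexityRanges(seqs[i], kmin, kmax, entropyCutoff,
                                  minMaskedLen, window)
        if (length(r)) {
            seqs[i] <- as.character(replaceAt(DNAString(seqs[i]),
                                              r, strrep("N", width(r))))
            masked[[i]] <- IRanges::reduce(c(masked[[i]], r))
        }
    }
    refs@seqs <- DNAStringSet(setNames(seqs, refIds(refs)))
    refs@masked <- IRangesList(masked)
    validObject(refs)
    refs
}

#' Screen and trim vector contamination
#'
#' Positions covered by any vector k-mer match within the Hamming-distance
#' tolerance are trimmed: full-length k-mers anywhere in the sequence,
#' shortened k-mers (down to \code{kEnd}) only when anchored at either
#' sequence end. Both strands of the vector set are screened. The longest
#' retained fragment replaces the sequence; records whose longest fragment is
#' below \code{minLenAfter} are dropped with
#' \code{dropReason = "too_short_after_trim"}.
#'
#' @param refs A \code{\link{ReferenceSet}}.
#' @param vectors DNAStringSet (or character) of vector sequences.
#' @param k full k-mer length (default 27).
#' @param kEnd minimum end-anchored k-mer length (default 11).
#' @param maxHamming maximum Hamming distance for a match (default 1).
#' @param minLenAfter minimum fragment length to keep a record (default 800).
#' @return The updated \code{ReferenceSet}.
#' @export
screenVector <- function(refs, vectors, k = 27, kEnd = 11, maxHamming = 1,
                         minLenAfter = 800) {
    if (kEnd > k) stop("kEnd must be <= k")
    if (!is(vectors, "DNAStringSet")) vectors <- DNAStringSet(vectors)
    vecs <- as.character(c(vectors, reverseComplement(vectors)))
    seqs <- as.character(refs@seqs)
    masked <- as.list(refs@masked)
    for (i in which(refs@kept)) {
        m <- .cppVectorHits(seqs[i], vecs, k, kEnd, maxHamming)
        if (nrow(m) == 0) next
        hit <- IRanges::reduce(IRanges(start = m[, 1], end = m[, 2]))
        keepR <- IRanges::gaps(hit, start = 1L, end = nchar(seqs[i]))
        if (length(keepR) == 0 || max(width(keepR)) < minLenAfter) {
            refs@kept[i] <- FALSE
            refs@dropReason[i] <- "too_short_after_trim"
            next
        }
        frag <- keepR[which.max(width(keepR))]
        seqs[i] <- substr(seqs[i], start(frag), end(frag))
        # shift retained masked intervals into fragment coordinates
        mi <- IRanges::restrict(masked[[i]], start(frag), end(frag))
        masked[[i]] <- IRanges::shift(mi, 1L - start(frag))
    }
    refs@seqs <- DNAStringSet(setNames(seqs, refIds(refs)))
    refs@masked <- IRangesList(masked)
    validObject(refs)
    refs
}

#' Greedy centroid clustering at an identity threshold
#'
#' Kept records are processed in decreasing length order (ties broken by id,
#' ascending). Each record joins the first existing centroid whose global
#' pairwise identity (matching columns / alignment columns) is at least the
#' threshold, otherwise it founds a new centroid.
#'
#' @param refs A \code{\link{ReferenceSet}} (only kept records are
#'   clustered) or a named DNAStringSet.
#' @param identityThreshold clustering identity in (0, 1], e.g. 0.99 for
#'   NR99 and 0.96 for NR96.
#' @return data.frame with columns memberId, centroidId,
#'   identityToCentroid; centroids are their own members with identity 1.
#' @export
greedyCluster <- function(refs, identityThreshold) {
    stopifnot(identityThreshold > 0, identityThreshold <= 1)
    seqs <- if (is(refs, "ReferenceSet")) refSeqs(refs, keptOnly = TRUE)
            else DNAStringSet(refs)
    if (length(seqs) == 0)
        return(data.frame(memberId = character(0), centroidId = character(0),
                          identityToCentroid = numeric(0)))
    ord <- order(-width(seqs), names(seqs))
    seqs <- seqs[ord]
    chr <- as.character(seqs)
    centroids <- integer(0)
    memberOf <- integer(length(seqs))
    identity <- numeric(length(seqs))
    for (i in seq_along(seqs)) {
        assigned <- FALSE
        for (ci in centroids) {
            a <- alignPair(chr[i], chr[ci], mode = "global")
            if (a$identity >= identityThreshold) {
                memberOf[i] <- ci
                identity[i] <- a$identity
                assigned <- TRUE
                break
            }
        }
        if (!assigned) {
            centroids <- c(centroids, i)
            memberOf[i] <- i
            identity[i] <- 1
        }
    }
    data.frame(memberId = names(seqs), centroidId = names(seqs)[memberOf],
               identityToCentroid = identity, stringsAsFactors = FALSE)
}

#' Full reference database curation pass
#'
#' Runs, in order: LSU-fragment removal, alphabet normalization (RNA to DNA,
#' ambiguity replacement), low-complexity masking, vector screening, and
#' greedy clustering at each requested identity (99\% and 96\% by default).
#'
#' @param refs A \code{\link{ReferenceSet}} (e.g. from
#'   \code{\link{readSilvaFasta}}).
#' @param lsuHits optional LSU hit table (see \code{\link{featureHits}}).
#' @param vectors optional vector sequences (DNAStringSet or character).
#' @param seed seed for ambiguity replacement.
#' @param evalueCutoff,minModelFraction LSU-removal thresholds.
#' @param kmin,kmax,entropyCutoff,minMaskedLen,window masking parameters.
#' @param vectorK,vectorKEnd,maxHamming,minLenAfter vector-screen parameters.
#' @param clusterIds identity thresholds to cluster at.
#' @return list with elements \code{refs} (curated ReferenceSet) and
#'   \code{clusters} (named list of cluster tables, one per threshold).
#' @export
curateReferences <- function(refs, lsuHits = NULL, vectors = NULL, seed = 1,
                             evalueCutoff = 1e-10, minModelFraction = 0.10,
                             kmin = 4, kmax = 8, entropyCutoff = 0.7,
                             minMaskedLen = 20, window = 100,
                             vectorK = 27, vectorKEnd = 11, maxHamming = 1,
                             minLenAfter = 800,
                             clusterIds = c(0.99, 0.96)) {
    if (!is.null(lsuHits))
        refs <- removeLsuFragments(refs, lsuHits, evalueCutoff,
                                   minModelFraction)
    refs <- normalizeAlphabet(refs, seed = seed)
    refs <- maskLowComplexity(refs, kmin, kmax, entropyCutoff, minMaskedLen,
                              window)
    if (!is.null(vectors))
        refs <- screenVector(refs, vectors, vectorK, vectorKEnd, maxHamming,
                             minLenAfter)
    clusters <- lapply(clusterIds, function(th) greedyCluster(refs, th))
    names(clusters) <- format(clusterIds)
    list(refs = refs, clusters = clusters)
}
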