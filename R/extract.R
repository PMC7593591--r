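# SSU rRNA read extraction: k-mer seeded, affine-gap extended alignment of
# read pairs against the curated reference at a minimum identity cutoff.

#' Build a k-mer seed index over curated references
#'
#' Indexes every ambiguity-free k-mer of the kept reference sequences on both
#' strands; hard-masked (N) regions contribute nothing. Postings record the
#' reference, the 1-based start of the k-mer on the forward strand, and the
#' strand.
#'
#' @param refs A \code{\link{ReferenceSet}}.
#' @param k odd seed length (default 13).
#' @return An object of class \code{ssuflash_index}.
#' @export
buildRefIndex <- function(refs, k = 13) {
    stopifnot(k %% 2 == 1)
    seqs <- refSeqs(refs, keptOnly = TRUE)
    if (length(seqs) && k > min(width(seqs)))
        stop("k exceeds the shortest reference length")
    tax <- refTaxonomy(refs, keptOnly = TRUE)
    pk <- character(0); pr <- integer(0); pp <- integer(0); ps <- character(0)
    chr <- as.character(seqs)
    for (i in seq_along(chr)) {
        L <- nchar(chr[i])
        pos <- seq_len(L - k + 1)
        km <- substring(chr[i], pos, pos + k - 1)
        ok <- !grepl("[^ACGT]", km)
        km <- km[ok]; pos <- pos[ok]
        if (!length(km)) next
        rc <- as.character(reverseComplement(DNAStringSet(km)))
        pk <- c(pk, km, rc)
        pr <- c(pr, rep.int(i, 2 * length(km)))
        pp <- c(pp, pos, pos)
        ps <- c(ps, rep("+", length(km)), rep("-", length(km)))
    }
    structure(list(k = k, ids = names(seqs), lens = width(seqs),
                   taxonomy = unname(tax), seqs = chr,
                   postRef = pr, postPos = pp, postStrand = ps,
                   lookup = split(seq_along(pk), pk)),
              class = "ssuflash_index")
}

#' @export
print.ssuflash_index <- function(x, ...) {
    cat(sprintf("ssuflash k-mer index: %d references, k = %d, %d postings\n",
                length(x$ids), x$k, length(x$postRef)))
    invisible(x)
}

# Seed-and-extend a set of query sequences against an index. Queries are
# seeded with shared k-mers; candidates with >= minSeeds co-linear seeds
# (same diagonal bucket of width `band`, adjacent buckets pooled) are
# extended with a glocal affine alignment of the full query against the
# seeded reference window. Hits with identity >= minIdentity are kept; among
# them only the tied best-scoring hits per query are reported, ordered by
# reference id.
.seedAndExtend <- function(queries, index, minIdentity, minSeeds = 2,
                           band = 16, maxCandidates = 32, chunk = 4000L) {
    k <- index$k
    empty <- data.frame(queryId = character(0), refId = character(0),
                        identity = numeric(0), score = numeric(0),
                        refStart = integer(0), refEnd = integer(0),
                        strand = character(0), cigar = character(0),
                        matches = integer(0), columns = integer(0),
                        stringsAsFactors = FALSE)
    if (length(index$lookup) == 0 || length(queries) == 0) return(empty)
    chr <- as.character(queries)
    qids <- names(queries)
    out <- vector("list", 0)
    for (off in seq(1L, length(chr), by = chunk)) {
        sel <- off:min(off + chunk - 1L, length(chr))
        # seed table for this chunk
        sl <- lapply(sel, function(i) {
            L <- nchar(chr[i])
            if (L < k) return(NULL)
            pos <- seq_len(L - k + 1)
            km <- substring(chr[i], pos, pos + k - 1)
            ok <- !grepl("[^ACGT]", km)
            if (!any(ok)) return(NULL)
            list(i = i, q = pos[ok], km = km[ok])
        })
        sl <- sl[!vapply(sl, is.null, logical(1))]
        if (!length(sl)) next
        qi <- rep.int(vapply(sl, `[[`, integer(1), "i"),
                      vapply(sl, function(x) length(x$q), integer(1)))
        qpos <- unlist(lapply(sl, `[[`, "q"), use.names = FALSE)
        kms <- unlist(lapply(sl, `[[`, "km"), use.names = FALSE)
        post <- index$lookup[kms]
        nm <- lengths(post)
        if (sum(nm) == 0) next
        pidx <- unlist(post, use.names = FALSE)
        qi <- rep.int(qi, nm); qpos <- rep.int(qpos, nm)
        refi <- index$postRef[pidx]
        rpos <- index$postPos[pidx]
        strand <- index$postStrand[pidx]
        L <- nchar(chr)[qi]
        diag <- ifelse(strand == "+", rpos - qpos,
                       rpos - (L - qpos - k + 2L))
        key <- paste(qi, refi, strand, sep = "\r")
        groups <- split(diag, key)
        hits <- vector("list", length(groups))
        gi <- 0L
        for (gk in names(groups)) {
            d <- groups[[gk]]
            b <- d %/% band
            tb <- table(b)
            bn <- as.integer(names(tb))
            # pool adjacent buckets to catch diagonals straddling an edge
            pooled <- as.integer(tb) +
                ifelse(match(bn + 1L, bn, nomatch = 0L) > 0,
                       as.integer(tb)[match(bn + 1L, bn, nomatch = 1L)], 0L)
            if (max(pooled) < minSeeds) next
            wb <- bn[which.max(pooled)]
            dd <- d[b %in% c(wb, wb + 1L)]
            parts <- strsplit(gk, "\r", fixed = TRUE)[[1]]
            i <- as.integer(parts[1]); ri <- as.integer(parts[2])
            st <- parts[3]
            Lq <- nchar(chr[i])
            ws <- max(1L, min(dd) + 1L - band)
            we <- min(index$lens[ri], max(dd) + Lq + band)
            if (we - ws + 1L < k) next
            pat <- if (st == "+") chr[i] else
                as.character(reverseComplement(DNAString(chr[i])))
            a <- .cppAlign(pat, substr(index$seqs[ri], ws, we),
                           .SCORING$match, .SCORING$mismatch,
                           .SCORING$gapOpen, .SCORING$gapExt, glocal = TRUE)
            idy <- if (a$columns > 0) a$matches / a$columns else 0
            if (idy < minIdentity) next
            gi <- gi + 1L
            hits[[gi]] <- data.frame(
                queryId = qids[i], refId = index$ids[ri], identity = idy,
                score = a$score, refStart = ws + a$sstart - 1L,
                refEnd = ws + a$send - 1L, strand = st, cigar = a$cigar,
                matches = a$matches, columns = a$columns,
                stringsAsFactors = FALSE)
        }
        if (gi) out[[length(out) + 1L]] <- do.call(rbind, hits[seq_len(gi)])
    }
    if (!length(out)) return(empty)
    hits <- do.call(rbind, out)
    # per query: retain all tied best-scoring hits, ordered by refId
    keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$queryId),
                          function(ii) {
        ii <- ii[hits$score[ii] == max(hits$score[ii])]
        ii <- ii[order(hits$refId[ii], hits$strand[ii])]
        head(ii, maxCandidates)
    }), use.names = FALSE)
    hits <- hits[sort(keep), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Extract SSU rRNA read pairs by seeded alignment
#'
#' Each mate is seeded against the reference index (shared k-mers, at least
#' \code{minSeeds} co-linear seeds per candidate reference) and extended with
#' a banded affine alignment around the seed diagonal. Hits with identity
#' (matching columns / alignment columns) at or above \code{minIdentity} are
#' reported, retaining all tied best-scoring hits per read. A pair is
#' retained when at least one mate has at least one hit; both mates of a
#' retained pair are kept.
#'
#' @param pairs A \code{\link{PairedReads}}.
#' @param index index from \code{\link{buildRefIndex}}.
#' @param minIdentity minimum alignment identity (default 0.70).
#' @param minSeeds minimum co-linear seeds per candidate (default 2).
#' @param band diagonal band width in bp (default 16).
#' @return list with \code{hits} (data.frame with one row per alignment hit:
#'   readId, mate, refId, identity, score, refStart, refEnd, strand, cigar,
#'   insertSize, taxonomy) and \code{retained} (a \code{PairedReads} of the
#'   retained pairs).
#' @export
extractReads <- function(pairs, index, minIdentity = 0.70, minSeeds = 2,
                         band = 16) {
    stopifnot(minIdentity > 0, minIdentity <= 1)
    hitsByMate <- lapply(1:2, function(m) {
        h <- .seedAndExtend(mateSeqs(pairs, m), index, minIdentity,
                            minSeeds, band)
        if (nrow(h)) h$mate <- m
        h
    })
    hits <- do.call(rbind, hitsByMate[vapply(hitsByMate, nrow,
                                             integer(1)) > 0])
    if (is.null(hits) || nrow(hits) == 0) {
        hits <- data.frame(readId = character(0), mate = integer(0),
                           refId = character(0), identity = numeric(0),
                           score = numeric(0), refStart = integer(0),
                           refEnd = integer(0), strand = character(0),
                           cigar = character(0), insertSize = integer(0),
                           taxonomy = character(0), stringsAsFactors = FALSE)
        return(list(hits = hits,
                    retained = PairedReads(DNAStringSet(), DNAStringSet())))
    }
    names(hits)[names(hits) == "queryId"] <- "readId"
    hits <- hits[order(hits$readId, hits$mate, hits$refId), , drop = FALSE]
    rownames(hits) <- NULL
    # insert sizes: defined when both mates hit the same reference on
    # opposite strands; outer distance of the two alignments
    hits$insertSize <- NA_integer_
    for (rid in unique(hits$readId[duplicated(hits$readId)])) {
        ii <- which(hits$readId == rid)
        h1 <- ii[hits$mate[ii] == 1]; h2 <- ii[hits$mate[ii] == 2]
        for (r in intersect(hits$refId[h1], hits$refId[h2])) {
            a <- h1[hits$refId[h1] == r][1]
            b <- h2[hits$refId[h2] == r][1]
            if (hits$strand[a] != hits$strand[b]) {
                ins <- max(hits$refEnd[c(a, b)]) - min(hits$refStart[c(a, b)]) + 1L
                hits$insertSize[c(a, b)] <- ins
            }
        }
    }
    hits$taxonomy <- index$taxonomy[match(hits$refId, index$ids)]
    retainedIds <- intersect(readIds(pairs), unique(hits$readId))
    retained <- PairedReads(mateSeqs(pairs, 1)[retainedIds],
                            mateSeqs(pairs, 2)[retainedIds])
    list(hits = hits, retained = retained)
}

#' Identity and insert-size histograms of an extraction
#'
#' Identity is binned at 1\% resolution on [100 * minIdentity, 100]; insert
#' sizes (one per read pair per reference with both mates aligned) are
#' binned at 10-bp resolution. Counts conserve the number of contributing
#' hits / pairs.
#'
#' @param hits hit table from \code{\link{extractReads}}.
#' @param minIdentity identity cutoff used for the extraction (default 0.70).
#' @return list with data.frames \code{identity} (bin, count; bin is percent
#'   identity rounded down) and \code{insert} (bin, count; bin is the 10-bp
#'   left edge).
#' @export
alignmentHistograms <- function(hits, minIdentity = 0.70) {
    lo <- floor(minIdentity * 100)
    idb <- pmin(floor(hits$identity * 100), 100)
    idTab <- table(factor(idb, levels = lo:100))
    identity <- data.frame(bin = as.integer(names(idTab)),
                           count = as.integer(idTab))
    sel <- hits$mate == 1 & !is.na(hits$insertSize)
    ins <- hits$insertSize[sel][!duplicated(paste(hits$readId[sel],
                                                  hits$refId[sel]))]
    if (length(ins)) {
        ib <- floor(ins / 10) * 10
        it <- table(ib)
        insert <- data.frame(bin = as.integer(names(it)),
                             count = as.integer(it))
    } else insert <- data.frame(bin = integer(0), count = integer(0))
    list(identity = identity, insert = insert)
}
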