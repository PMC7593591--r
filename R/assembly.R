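# Targeted-assembly support: parameter rules for the assemblers, SSU region
# extraction from contig hit tables, assembled-fraction accounting, and
# closest-reference assignment.

.nextLowerOdd <- function(x) ifelse(x %% 2 == 1, x, x - 1)

#' Assembly k-mer lengths for a read length
#'
#' For reads of at least 134 bp, k-mer lengths 99, 111 and 127 are used. For
#' shorter reads, the k-mers are the next lower odd number to the read length
#' minus 27, 17 and 7 bp.
#'
#' @param readLen read length in bp (>= 40).
#' @return integer vector of three ascending odd k-mer lengths.
#' @examples
#' chooseKmers(150)  # 99 111 127
#' chooseKmers(100)  # 73 83 93
#' @export
chooseKmers <- function(readLen) {
    if (readLen < 40) stop("read length must be at least 40 bp")
    if (readLen >= 134) return(c(99L, 111L, 127L))
    as.integer(.nextLowerOdd(readLen - c(27, 17, 7)))
}

#' Paired/single mode and insert size rule for EM-based targeted assembly
#'
#' Read pairs are run as single reads when their length exceeds 152 bp. For
#' paired-end input the observed mean insert size (from the initial mapping)
#' is used if it exceeds 2.2 times the read length; otherwise a minimum
#' insert size of 2.2 times the read length plus 0.5 is imposed.
#'
#' @param readLen read length in bp.
#' @param observedInsertMean mean insert size from the mapping histogram
#'   (ignored in single-read mode).
#' @param iterations number of EM iterations to request (default 40).
#' @return list with \code{mode} ("paired" or "single"), \code{insert}
#'   (numeric or NA in single mode) and \code{iterations}.
#' @export
emirgeInsertRule <- function(readLen, observedInsertMean = NA,
                             iterations = 40) {
    if (readLen <= 0) stop("read length must be positive")
    if (!is.na(observedInsertMean) && observedInsertMean < 0)
        stop("negative insert size")
    if (readLen > 152)
        return(list(mode = "single", insert = NA_real_,
                    iterations = iterations))
    ins <- if (!is.na(observedInsertMean) &&
               observedInsertMean > 2.2 * readLen) observedInsertMean
           else 2.2 * readLen + 0.5
    list(mode = "paired", insert = ins, iterations = iterations)
}

#' Export assembly parameters as a machine-readable list / JSON
#'
#' @param readLen read length in bp.
#' @param observedInsertMean optional observed mean insert size.
#' @param path optional JSON output path.
#' @return list with \code{kmers} and the insert rule fields.
#' @export
assemblyParams <- function(readLen, observedInsertMean = NA, path = NULL) {
    params <- c(list(readLen = readLen, kmers = chooseKmers(readLen)),
                emirgeInsertRule(readLen, observedInsertMean))
    if (!is.null(path))
        jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA)
    params
}

#' Extract SSU rRNA regions from contigs
#'
#' Contig regions with an SSU-model hit passing the E-value cutoff and
#' covering at least \code{minModelFraction} of the full model are extracted
#' (reverse-complemented for minus-strand hits). When hits on the same contig
#' and model overlap by 50\% or more, only the lowest-E-value hit is kept.
#'
#' @param contigs named DNAStringSet of contigs.
#' @param hits hit table (see \code{\link{featureHits}}) with SSU models.
#' @param evalueCutoff maximum E-value (default 1e-100).
#' @param minModelFraction minimum model coverage (default 0.6).
#' @return data.frame with columns contigId, start, end, strand, model,
#'   evalue, modelFraction, seq; region ids are
#'   "contigId:start-end:strand:model".
#' @export
extractSsuRegions <- function(contigs, hits, evalueCutoff = 1e-100,
                              minModelFraction = 0.6) {
    ssu <- hits[hits$model != "lsu" & hits$evalue <= evalueCutoff &
                hits$modelFraction >= minModelFraction, , drop = FALSE]
    if (nrow(ssu)) {
        if (!all(ssu$targetId %in% names(contigs)))
            stop("hit on unknown contig: ",
                 paste(setdiff(ssu$targetId, names(contigs)), collapse = ", "))
        lens <- width(contigs)[match(ssu$targetId, names(contigs))]
        if (any(ssu$start < 1 | ssu$end > lens))
            stop("hit coordinates outside contig bounds")
        # resolve >= 50% overlaps per contig and model: keep lowest E-value
        ssu <- ssu[order(ssu$evalue), , drop = FALSE]
        keep <- rep(TRUE, nrow(ssu))
        for (i in seq_len(nrow(ssu))) {
            if (!keep[i]) next
            for (j in seq_len(i - 1L)) {
                if (!keep[j] || ssu$targetId[i] != ssu$targetId[j] ||
                    ssu$model[i] != ssu$model[j]) next
                ov <- min(ssu$end[i], ssu$end[j]) -
                    max(ssu$start[i], ssu$start[j]) + 1L
                if (ov >= 0.5 * min(ssu$end[i] - ssu$start[i] + 1L,
                                    ssu$end[j] - ssu$start[j] + 1L)) {
                    keep[i] <- FALSE
                    break
                }
            }
        }
        ssu <- ssu[keep, , drop = FALSE]
    }
    seqs <- character(nrow(ssu))
    for (i in seq_len(nrow(ssu))) {
        s <- subseq(contigs[[ssu$targetId[i]]], ssu$start[i], ssu$end[i])
        if (ssu$strand[i] == "-") s <- reverseComplement(s)
        seqs[i] <- as.character(s)
    }
    out <- data.frame(contigId = ssu$targetId, start = ssu$start,
                      end = ssu$end, strand = ssu$strand, model = ssu$model,
                      evalue = ssu$evalue, modelFraction = ssu$modelFraction,
                      seq = seqs, stringsAsFactors = FALSE)
    out$regionId <- sprintf("%s:%d-%d:%s:%s", out$contigId, out$start,
                            out$end, out$strand, out$model)
    rownames(out) <- NULL
    out
}

#' Fraction of extracted reads that assembled
#'
#' Remaps the retained reads against the assembled SSU sequences with the
#' extraction aligner at a high identity cutoff (98\% by default) and
#' returns mapped reads / extracted reads.
#'
#' @param extracted A \code{\link{PairedReads}} of the retained pairs.
#' @param assembled named character vector or DNAStringSet of assembled SSU
#'   sequences (e.g. the \code{seq} column of
#'   \code{\link{extractSsuRegions}} output).
#' @param minIdentity remapping identity cutoff (default 0.98).
#' @return numeric in [0, 1], or NA if there are no extracted reads.
#' @export
assembledFraction <- function(extracted, assembled, minIdentity = 0.98) {
    nReads <- 2L * length(extracted)
    if (nReads == 0) return(NA_real_)
    if (length(assembled) == 0) return(0)
    if (!is(assembled, "DNAStringSet")) assembled <- DNAStringSet(assembled)
    if (is.null(names(assembled)))
        names(assembled) <- paste0("asm", seq_along(assembled))
    targets <- ReferenceSet(assembled,
                            taxonomy = character(length(assembled)))
    idx <- buildRefIndex(targets, k = 13)
    mapped <- 0L
    for (m in 1:2) {
        h <- .seedAndExtend(mateSeqs(extracted, m), idx, minIdentity)
        mapped <- mapped + length(unique(h$queryId))
    }
    mapped / nReads
}

#' Closest reference sequence for an assembled SSU region
#'
#' Finds the highest-identity match in the curated database at a minimum
#' identity (70\% by default); identity is matches / alignment columns of a
#' global alignment of the region against the aligned reference stretch.
#' Ties are broken by reference id, ascending.
#'
#' @param regionSeq character(1) or DNAString, the assembled region sequence.
#' @param refs A \code{\link{ReferenceSet}} (kept records are searched).
#' @param minIdentity minimum identity to report a match (default 0.70).
#' @return list with \code{refId} and \code{identity}, or NULL when no
#'   reference qualifies.
#' @export
closestReference <- function(regionSeq, refs, minIdentity = 0.70) {
    seqs <- refSeqs(refs, keptOnly = TRUE)
    if (length(seqs) == 0) return(NULL)
    q <- as.character(regionSeq)
    qr <- as.character(reverseComplement(DNAString(q)))
    best <- NULL
    for (id in sort(names(seqs))) {
        s <- as.character(seqs[[id]])
        a <- alignPair(q, s, mode = "glocal")
        b <- alignPair(qr, s, mode = "glocal")
        idy <- max(a$identity, b$identity)
        if (idy >= minIdentity && (is.null(best) || idy > best$identity))
            best <- list(refId = id, identity = idy)
    }
    best
}
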