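# Minimal text-level SAM support. Alignments produced by the extraction
# module are written as valid SAM; SAM produced by external mappers can be
# read back and its pairing flags repaired (some rRNA extraction tools do not
# emit complete pairing information).

.FLAG <- c(paired = 1L, proper = 2L, unmapped = 4L, munmapped = 8L,
           reverse = 16L, mreverse = 32L, first = 64L, second = 128L,
           secondary = 256L)

.hasFlag <- function(flag, bit) bitwAnd(flag, .FLAG[[bit]]) != 0L
.setFlag <- function(flag, bit, on) {
    on <- rep_len(on, length(flag))
    ifelse(on, bitwOr(flag, .FLAG[[bit]]),
           bitwAnd(flag, bitwNot(.FLAG[[bit]])))
}

#' Read a SAM file into a data.frame
#'
#' Only the 11 mandatory columns are kept; header lines are preserved in the
#' \code{"header"} attribute.
#'
#' @param path SAM file.
#' @return data.frame with columns qname, flag, rname, pos, mapq, cigar,
#'   rnext, pnext, tlen, seq, qual.
#' @export
readSam <- function(path) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "@")]
    rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (length(rec)) {
        f <- strsplit(rec, "\t", fixed = TRUE)
        df <- data.frame(qname = vapply(f, `[`, "", 1),
                         flag = as.integer(vapply(f, `[`, "", 2)),
                         rname = vapply(f, `[`, "", 3),
                         pos = as.integer(vapply(f, `[`, "", 4)),
                         mapq = as.integer(vapply(f, `[`, "", 5)),
                         cigar = vapply(f, `[`, "", 6),
                         rnext = vapply(f, `[`, "", 7),
                         pnext = as.integer(vapply(f, `[`, "", 8)),
                         tlen = as.integer(vapply(f, `[`, "", 9)),
                         seq = vapply(f, `[`, "", 10),
                         qual = vapply(f, `[`, "", 11),
                         stringsAsFactors = FALSE)
    } else {
        df <- data.frame(qname = character(0), flag = integer(0),
                         rname = character(0), pos = integer(0),
                         mapq = integer(0), cigar = character(0),
                         rnext = character(0), pnext = integer(0),
                         tlen = integer(0), seq = character(0),
                         qual = character(0), stringsAsFactors = FALSE)
    }
    attr(df, "header") <- hdr
    df
}

#' Write a SAM data.frame to file
#'
#' @param sam data.frame as from \code{\link{readSam}}; its \code{"header"}
#'   attribute (if any) is written first.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSamFile <- function(sam, path) {
    con <- file(path, "w")
    on.exit(close(con))
    hdr <- attr(sam, "header")
    if (length(hdr)) writeLines(hdr, con)
    if (nrow(sam))
        writeLines(do.call(paste, c(unname(as.list(sam[, seq_len(11)])),
                                    sep = "\t")), con)
    invisible(path)
}

#' Convert an extraction result to SAM records
#'
#' Emits one record per alignment hit (first hit of each mate is primary,
#' further hits are secondary) plus placeholder records for unaligned mates
#' of retained pairs, then repairs pairing flags so the output is
#' self-consistent.
#'
#' @param extraction list from \code{\link{extractReads}}.
#' @param index the index used for the extraction (for @SQ header lines).
#' @return SAM data.frame (see \code{\link{readSam}}).
#' @export
extractionToSam <- function(extraction, index) {
    hits <- extraction$hits
    pairs <- extraction$retained
    recs <- list()
    for (rid in readIds(pairs)) {
        for (m in 1:2) {
            hi <- which(hits$readId == rid & hits$mate == m)
            sq <- as.character(mateSeqs(pairs, m)[[rid]])
            if (length(hi) == 0) {
                recs[[length(recs) + 1L]] <- data.frame(
                    qname = rid, flag = .FLAG[["unmapped"]] +
                        ifelse(m == 1, .FLAG[["first"]], .FLAG[["second"]]) +
                        .FLAG[["paired"]],
                    rname = "*", pos = 0L, mapq = 0L, cigar = "*",
                    rnext = "*", pnext = 0L, tlen = 0L, seq = sq,
                    qual = "*", stringsAsFactors = FALSE)
            } else {
                for (j in seq_along(hi)) {
                    h <- hits[hi[j], ]
                    flag <- .FLAG[["paired"]] +
                        ifelse(m == 1, .FLAG[["first"]], .FLAG[["second"]])
                    if (h$strand == "-") flag <- flag + .FLAG[["reverse"]]
                    if (j > 1) flag <- flag + .FLAG[["secondary"]]
                    oseq <- if (h$strand == "-")
                        as.character(reverseComplement(DNAString(sq))) else sq
                    recs[[length(recs) + 1L]] <- data.frame(
                        qname = rid, flag = flag, rname = h$refId,
                        pos = h$refStart, mapq = 255L, cigar = h$cigar,
                        rnext = "*", pnext = 0L,
                        tlen = ifelse(is.na(h$insertSize), 0L, h$insertSize),
                        seq = oseq, qual = "*", stringsAsFactors = FALSE)
                }
            }
        }
    }
    sam <- if (length(recs)) do.call(rbind, recs) else NULL
    if (is.null(sam) || !nrow(sam)) {
        sam <- data.frame(qname = character(0), flag = integer(0),
                          rname = character(0), pos = integer(0),
                          mapq = integer(0), cigar = character(0),
                          rnext = character(0), pnext = integer(0),
                          tlen = integer(0), seq = character(0),
                          qual = character(0), stringsAsFactors = FALSE)
    }
    attr(sam, "header") <- c("@HD\tVN:1.6\tSO:unknown",
                             sprintf("@SQ\tSN:%s\tLN:%d", index$ids,
                                     index$lens),
                             "@PG\tID:ssuflash\tPN:ssuflash")
    repairSamPairing(sam)
}

#' Repair paired-end consistency of SAM records
#'
#' Strips /1 and /2 read-name suffixes (setting the first/second-in-pair
#' flags from them), then makes the paired, proper-pair, mate-unmapped and
#' mate-strand flag bits and the mate reference/position fields mutually
#' consistent across each read pair, using each mate's primary record as the
#' source of truth. Orphan records (mate record absent) are flagged in the
#' returned \code{orphan} column, never dropped. The operation is
#' idempotent.
#'
#' @param sam SAM data.frame (see \code{\link{readSam}}).
#' @return The repaired SAM data.frame, with an added logical column
#'   \code{orphan}.
#' @export
repairSamPairing <- function(sam) {
    if (nrow(sam) == 0) { sam$orphan <- logical(0); return(sam) }
    sfx <- sub("^.*/([12])$", "\\1", sam$qname)
    hasSfx <- grepl("/[12]$", sam$qname)
    sam$qname <- sub("/[12]$", "", sam$qname)
    sam$flag <- .setFlag(sam$flag, "first",
                         ifelse(hasSfx & sfx == "1", TRUE,
                                .hasFlag(sam$flag, "first")))
    sam$flag <- .setFlag(sam$flag, "second",
                         ifelse(hasSfx & sfx == "2", TRUE,
                                .hasFlag(sam$flag, "second")))
    sam$flag <- .setFlag(sam$flag, "paired", TRUE)
    sam$orphan <- FALSE
    for (q in unique(sam$qname)) {
        ii <- which(sam$qname == q)
        # records lacking both mate bits: assign by order of appearance
        noMate <- !(.hasFlag(sam$flag[ii], "first") |
                    .hasFlag(sam$flag[ii], "second"))
        if (any(noMate)) {
            first <- ii[noMate][1]
            sam$flag[first] <- .setFlag(sam$flag[first], "first", TRUE)
            rest <- ii[noMate][-1]
            if (length(rest))
                sam$flag[rest] <- .setFlag(sam$flag[rest], "second", TRUE)
        }
        prim1 <- ii[.hasFlag(sam$flag[ii], "first") &
                    !.hasFlag(sam$flag[ii], "secondary")][1]
        prim2 <- ii[.hasFlag(sam$flag[ii], "second") &
                    !.hasFlag(sam$flag[ii], "secondary")][1]
        for (i in ii) {
            other <- if (.hasFlag(sam$flag[i], "first")) prim2 else prim1
            if (is.na(other)) {
                sam$orphan[i] <- TRUE
                sam$flag[i] <- .setFlag(sam$flag[i], "munmapped", TRUE)
                sam$flag[i] <- .setFlag(sam$flag[i], "proper", FALSE)
                sam$rnext[i] <- "*"; sam$pnext[i] <- 0L
                next
            }
            oUnmapped <- .hasFlag(sam$flag[other], "unmapped")
            sam$flag[i] <- .setFlag(sam$flag[i], "munmapped", oUnmapped)
            sam$flag[i] <- .setFlag(sam$flag[i], "mreverse",
                                    .hasFlag(sam$flag[other], "reverse"))
            selfMapped <- !.hasFlag(sam$flag[i], "unmapped")
            if (!oUnmapped) {
                sam$rnext[i] <- ifelse(sam$rname[other] == sam$rname[i],
                                       "=", sam$rname[other])
                sam$pnext[i] <- sam$pos[other]
            } else if (selfMapped) {
                sam$rnext[i] <- "="; sam$pnext[i] <- sam$pos[i]
            } else {
                sam$rnext[i] <- "*"; sam$pnext[i] <- 0L
            }
            proper <- selfMapped && !oUnmapped &&
                sam$rname[other] == sam$rname[i] &&
                (.hasFlag(sam$flag[i], "reverse") !=
                 .hasFlag(sam$flag[other], "reverse"))
            sam$flag[i] <- .setFlag(sam$flag[i], "proper", proper)
        }
    }
    sam
}

#' Resolve taxonomy for SAM hits and convert to an alignment-hit table
#'
#' Reconstructs the hit table used by the profiling module from SAM records
#' (e.g. from an external mapper), resolving taxonomy via reference ids.
#'
#' @param sam SAM data.frame.
#' @param refs A \code{\link{ReferenceSet}} providing the taxonomy.
#' @return data.frame with columns readId, mate, refId, identity (NA when it
#'   cannot be derived), taxonomy.
#' @export
samToHits <- function(sam, refs) {
    mapped <- sam[!.hasFlag(sam$flag, "unmapped"), , drop = FALSE]
    if (nrow(mapped) == 0)
        return(data.frame(readId = character(0), mate = integer(0),
                          refId = character(0), identity = numeric(0),
                          taxonomy = character(0), stringsAsFactors = FALSE))
    tax <- refTaxonomy(refs)
    data.frame(readId = mapped$qname,
               mate = ifelse(.hasFlag(mapped$flag, "second"), 2L, 1L),
               refId = mapped$rname, identity = NA_real_,
               taxonomy = unname(tax[mapped$rname]),
               stringsAsFactors = FALSE)
}
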