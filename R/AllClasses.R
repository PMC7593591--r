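#' ReferenceSet: a curated set of SSU rRNA reference sequences
#'
#' Wraps a \code{\link[Biostrings]{DNAStringSet}} of reference sequences with
#' their SILVA-style taxonomy paths and curation state. Masked low-complexity
#' regions are recorded per sequence as an \code{IRangesList} (1-based,
#' closed intervals, the Bioconductor convention). A record that fails a
#' curation step keeps its row but has \code{kept = FALSE} and a
#' \code{dropReason} of \code{"lsu_fragment"} or \code{"too_short_after_trim"}.
#'
#' @slot seqs DNAStringSet, names are accession ids.
#' @slot taxonomy character, semicolon-delimited rank path per sequence.
#' @slot kept logical curation flag per sequence.
#' @slot dropReason character, one of "none", "lsu_fragment",
#'   "too_short_after_trim".
#' @slot masked IRangesList of masked intervals per sequence.
#' @export
setClass("ReferenceSet",
    representation(seqs = "DNAStringSet", taxonomy = "character",
                   kept = "logical", dropReason = "character",
                   masked = "IRangesList"))

.DROP_REASONS <- c("none", "lsu_fragment", "too_short_after_trim")

setValidity("ReferenceSet", function(object) {
    n <- length(object@seqs)
    msg <- character(0)
    if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
        msg <- c(msg, "sequences must have unique names (accessions)")
    if (length(object@taxonomy) != n || length(object@kept) != n ||
        length(object@dropReason) != n || length(object@masked) != n)
        msg <- c(msg, "all slots must be parallel to 'seqs'")
    if (!all(object@dropReason %in% .DROP_REASONS))
        msg <- c(msg, "invalid dropReason")
    if (any(object@kept != (object@dropReason == "none")))
        msg <- c(msg, "kept must be FALSE iff dropReason != 'none'")
    if (n > 0) {
        bad <- any(vapply(seq_len(n), function(i) {
            r <- object@masked[[i]]
            length(r) > 0 && (min(IRanges::start(r)) < 1 ||
                              max(IRanges::end(r)) > width(object@seqs)[i])
        }, logical(1)))
        if (bad) msg <- c(msg, "masked intervals out of sequence bounds")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ReferenceSet
#'
#' @param seqs named DNAStringSet (or named character vector) of sequences.
#' @param taxonomy character vector of semicolon-delimited taxonomy paths.
#' @param kept logical vector; defaults to all TRUE.
#' @param dropReason character vector; defaults to "none".
#' @param masked IRangesList of masked intervals; defaults to empty.
#' @return A \code{ReferenceSet}.
#' @examples
#' rs <- ReferenceSet(c(A1 = "ACGTACGT"), taxonomy = "Bacteria;Proteobacteria")
#' @export
ReferenceSet <- function(seqs, taxonomy = character(length(seqs)),
                         kept = rep(TRUE, length(seqs)),
                         dropReason = rep("none", length(seqs)),
                         masked = NULL) {
    if (is.character(seqs)) seqs <- chartr("Uu", "Tt", seqs)  # accept RNA
    if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
    if (is.null(masked))
        masked <- IRangesList(lapply(seq_along(seqs), function(i) IRanges()))
    new("ReferenceSet", seqs = seqs, taxonomy = taxonomy, kept = kept,
        dropReason = dropReason, masked = masked)
}

#' @describeIn ReferenceSet-accessors accession ids
#' @export
refIds <- function(x) names(x@seqs)

#' Accessors for ReferenceSet
#'
#' @param x A \code{ReferenceSet}.
#' @param keptOnly logical; restrict to records that passed curation.
#' @name ReferenceSet-accessors
#' @return \code{refSeqs}: DNAStringSet; \code{refTaxonomy}: character;
#'   \code{isKept}: logical; \code{dropReason}: character;
#'   \code{maskedRanges}: IRangesList.
NULL

#' @rdname ReferenceSet-accessors
#' @export
refSeqs <- function(x, keptOnly = FALSE) {
    if (keptOnly) x@seqs[x@kept] else x@seqs
}

#' @rdname ReferenceSet-accessors
#' @export
refTaxonomy <- function(x, keptOnly = FALSE) {
    tx <- setNames(x@taxonomy, refIds(x))
    if (keptOnly) tx[x@kept] else tx
}

#' @rdname ReferenceSet-accessors
#' @export
isKept <- function(x) setNames(x@kept, refIds(x))

#' @rdname ReferenceSet-accessors
#' @export
dropReason <- function(x) setNames(x@dropReason, refIds(x))

#' @rdname ReferenceSet-accessors
#' @export
maskedRanges <- function(x) setNames(x@masked, refIds(x))

setMethod("show", "ReferenceSet", function(object) {
    cat("ReferenceSet with", length(object@seqs), "records (",
        sum(object@kept), "kept )\n")
    if (length(object@seqs)) {
        n <- min(3L, length(object@seqs))
        for (i in seq_len(n))
            cat(sprintf("  %s  %d bp  %s\n", refIds(object)[i],
                        width(object@seqs)[i],
                        substr(object@taxonomy[i], 1, 50)))
        if (length(object@seqs) > n) cat("  ...\n")
    }
})

#' @export
setMethod("length", "ReferenceSet", function(x) length(x@seqs))

#' @export
setMethod("[", "ReferenceSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, refIds(x))
    new("ReferenceSet", seqs = x@seqs[i], taxonomy = x@taxonomy[i],
        kept = x@kept[i], dropReason = x@dropReason[i], masked = x@masked[i])
})

#' PairedReads: a paired-end read library
#'
#' Holds the two mates of a paired-end library as parallel DNAStringSets
#' sharing read names. The optional \code{truthOrigin} metadata column on
#' mate 1 (reference id or "background") is set by the fixture generators.
#'
#' @slot r1,r2 DNAStringSet of mate 1 / mate 2 sequences, identically named.
#' @export
setClass("PairedReads", representation(r1 = "DNAStringSet",
                                       r2 = "DNAStringSet"))

setValidity("PairedReads", function(object) {
    if (length(object@r1) != length(object@r2))
        return("mates differ in length")
    if (!identical(names(object@r1), names(object@r2)))
        return("mate names differ")
    if (length(object@r1) && any(width(object@r1) == 0 |
                                 width(object@r2) == 0))
        return("zero-length read sequence")
    TRUE
})

#' Construct a PairedReads object
#'
#' @param r1,r2 named DNAStringSets (or character vectors) of the two mates;
#'   alternatively file paths to FASTQ files. Trailing /1 and /2 read-name
#'   suffixes are stripped.
#' @return A \code{PairedReads}.
#' @examples
#' pr <- PairedReads(c(p1 = "ACGT"), c(p1 = "TTTT"))
#' @export
PairedReads <- function(r1, r2) {
    asSet <- function(x) {
        if (is.character(x) && length(x) == 1 && file.exists(x))
            x <- readDNAStringSet(x, format = "fastq")
        if (!is(x, "DNAStringSet")) x <- DNAStringSet(x)
        names(x) <- sub("/[12]$", "", sub("\\s.*$", "", names(x)))
        x
    }
    new("PairedReads", r1 = asSet(r1), r2 = asSet(r2))
}

#' @export
setMethod("length", "PairedReads", function(x) length(x@r1))

setMethod("show", "PairedReads", function(object) {
    cat("PairedReads with", length(object@r1), "pairs\n")
})

#' @describeIn PairedReads-accessors read ids
#' @export
readIds <- function(x) names(x@r1)

#' Accessors for PairedReads
#' @param x A \code{PairedReads}.
#' @param mate 1 or 2.
#' @name PairedReads-accessors
#' @return \code{mateSeqs}: DNAStringSet of the requested mate.
#' @export
mateSeqs <- function(x, mate) {
    stopifnot(mate %in% 1:2)
    if (mate == 1) x@r1 else x@r2
}

#' TaxProfile: per-sample taxon counts at a summarization level
#'
#' Counts of LCA-consensus taxa for one sample, summarized at a taxonomic
#' level between domain (1) and species (7). Count names are
#' semicolon-delimited paths; paths shorter than the requested level are
#' reads whose LCA was above that level and are displayed as
#' "(unclassified) <last-known-rank>".
#'
#' @slot sampleId character(1).
#' @slot level integer summarization level, 1 = domain ... 7 = species.
#' @slot counts named integer vector of pair counts per taxon path.
#' @slot total integer, total classified pairs (equals \code{sum(counts)}).
#' @export
setClass("TaxProfile", representation(sampleId = "character",
                                      level = "integer",
                                      counts = "integer",
                                      total = "integer"))

setValidity("TaxProfile", function(object) {
    msg <- character(0)
    if (object@level < 1L || object@level > 7L)
        msg <- c(msg, "level must be in 1..7")
    if (length(object@counts) && any(object@counts < 0))
        msg <- c(msg, "negative counts")
    if (sum(object@counts) != object@total)
        msg <- c(msg, "total must equal sum(counts)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TaxProfile", function(object) {
    cat(sprintf("TaxProfile '%s': %d pairs in %d taxa at level %d\n",
                object@sampleId, object@total, length(object@counts),
                object@level))
    cnt <- sort(object@counts, decreasing = TRUE)
    for (i in seq_len(min(5L, length(cnt))))
        cat(sprintf("  %6d  %s\n", cnt[i], profileLabel(names(cnt)[i],
                                                        object@level)))
})

#' Accessors for TaxProfile
#' @param x A \code{TaxProfile}.
#' @name TaxProfile-accessors
#' @return \code{profileCounts}: named integer vector; \code{profileTotal}:
#'   integer; \code{sampleId}: character(1); \code{profileLevel}: integer.
NULL

#' @rdname TaxProfile-accessors
#' @export
profileCounts <- function(x) x@counts

#' @rdname TaxProfile-accessors
#' @export
profileTotal <- function(x) x@total

#' @rdname TaxProfile-accessors
#' @export
sampleId <- function(x) x@sampleId

#' @rdname TaxProfile-accessors
#' @export
profileLevel <- function(x) x@level

#' Display label of a taxon path at a level
#'
#' Paths shorter than the requested level are labelled
#' "(unclassified) <last-known-rank>".
#' @param path semicolon-delimited taxon path (character vector).
#' @param level requested summarization level.
#' @return character vector of display labels.
#' @export
profileLabel <- function(path, level) {
    vapply(path, function(p) {
        ranks <- strsplit(p, ";", fixed = TRUE)[[1]]
        if (length(ranks) < level)
            paste0("(unclassified) ", ranks[length(ranks)])
        else p
    }, character(1), USE.NAMES = FALSE)
}

#' AssemblyGraph: contigs plus undirected adjacency from a Fastg file
#'
#' Nodes are contigs (forward and reverse-complement records collapsed to one
#' node); edges are undirected unordered contig pairs recovered from Fastg
#' adjacency records. SPAdes-style "EDGE_x_length_y_cov_z" headers are parsed
#' for length and coverage when present.
#'
#' @slot contigs data.frame with columns id, length, coverage.
#' @slot seqs DNAStringSet of contig sequences (possibly a subset).
#' @slot edges two-column character matrix of undirected edges.
#' @export
setClass("AssemblyGraph", representation(contigs = "data.frame",
                                         seqs = "DNAStringSet",
                                         edges = "matrix"))

setValidity("AssemblyGraph", function(object) {
    msg <- character(0)
    if (!all(c("id", "length", "coverage") %in% colnames(object@contigs)))
        msg <- c(msg, "contigs must have id, length, coverage columns")
    if (nrow(object@edges) > 0 &&
        !all(as.vector(object@edges) %in% object@contigs$id))
        msg <- c(msg, "edge endpoints must exist in contigs")
    if (length(msg)) msg else TRUE
})

#' Construct an AssemblyGraph
#' @param contigs data.frame with columns id, length, coverage.
#' @param edges two-column character matrix (or data.frame) of edges.
#' @param seqs optional named DNAStringSet of contig sequences.
#' @return An \code{AssemblyGraph}.
#' @export
AssemblyGraph <- function(contigs, edges = NULL, seqs = NULL) {
    if (is.null(seqs)) seqs <- DNAStringSet()
    if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
    edges <- as.matrix(edges)
    if (nrow(edges)) {
        edges <- t(apply(edges, 1, sort))   # undirected: canonical order
        edges <- unique(edges)
    }
    new("AssemblyGraph", contigs = contigs, seqs = seqs, edges = edges)
}

setMethod("show", "AssemblyGraph", function(object) {
    cat("AssemblyGraph:", nrow(object@contigs), "contigs,",
        nrow(object@edges), "edges\n")
})

#' Accessors for AssemblyGraph
#' @param x An \code{AssemblyGraph}.
#' @name AssemblyGraph-accessors
#' @return \code{graphContigs}: data.frame; \code{graphEdges}: character
#'   matrix; \code{graphSeqs}: DNAStringSet.
NULL

#' @rdname AssemblyGraph-accessors
#' @export
graphContigs <- function(x) x@contigs

#' @rdname AssemblyGraph-accessors
#' @export
graphEdges <- function(x) x@edges

#' @rdname AssemblyGraph-accessors
#' @export
graphSeqs <- function(x) x@seqs
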