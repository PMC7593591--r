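# File-format I/O: SILVA-style FASTA, GFF-like hit tables, cluster and bin
# tables. GFF-like tables use 1-based inclusive coordinates at the boundary;
# everything else in the package uses IRanges (1-based closed).

#' Read a FASTA file with SILVA-style taxonomy headers
#'
#' Headers are of the form ">accession Domain;Phylum;...;Species"; everything
#' after the first whitespace is taken as the semicolon-delimited taxonomy
#' path (may be empty). RNA-alphabet sequences (SILVA exports) are
#' transcribed to DNA on the way in.
#'
#' @param path FASTA file.
#' @return A \code{\link{ReferenceSet}}.
#' @export
readSilvaFasta <- function(path) {
    ss <- Biostrings::readBStringSet(path)
    ss <- DNAStringSet(chartr("Uu", "Tt", as.character(ss)))
    hdr <- names(ss)
    acc <- sub("\\s.*$", "", hdr)
    tax <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
    names(ss) <- acc
    ReferenceSet(ss, taxonomy = tax)
}

#' Write a ReferenceSet as SILVA-style FASTA
#'
#' @param refs A \code{ReferenceSet}.
#' @param path output file.
#' @param keptOnly write only records that passed curation (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeSilvaFasta <- function(refs, path, keptOnly = TRUE) {
    idx <- if (keptOnly) which(isKept(refs)) else seq_along(refs@seqs)
    ss <- refs@seqs[idx]
    tax <- refs@taxonomy[idx]
    names(ss) <- ifelse(nzchar(tax), paste(names(ss), tax), names(ss))
    writeXStringSet(ss, path)
    invisible(path)
}

.MODELS <- c("ssu_bac", "ssu_arc", "ssu_euk", "lsu")

#' Read an rRNA-model hit table (GFF-like TSV)
#'
#' Nine columns: seqid, source, type (the rRNA model), start (1-based), end
#' (inclusive), score (E-value), strand, frame, attributes (containing
#' \code{model_fraction=...}).
#'
#' @param path TSV file; lines starting with '#' are ignored.
#' @return data.frame with columns targetId, model, evalue, modelFraction,
#'   start, end, strand.
#' @export
readFeatureHits <- function(path) {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (ncol(df) != 9)
        stop("expected 9-column GFF-like hit table: ", path)
    frac <- as.numeric(sub(".*model_fraction=([0-9.eE+-]+).*", "\\1", df[[9]]))
    featureHits(targetId = df[[1]], model = df[[3]],
                evalue = as.numeric(df[[6]]), modelFraction = frac,
                start = as.integer(df[[4]]), end = as.integer(df[[5]]),
                strand = df[[7]])
}

#' Construct a validated rRNA feature-hit table
#'
#' @param targetId,model,evalue,modelFraction,start,end,strand parallel
#'   vectors; coordinates 1-based inclusive; model one of ssu_bac, ssu_arc,
#'   ssu_euk, lsu.
#' @return data.frame of hits.
#' @export
featureHits <- function(targetId, model, evalue, modelFraction, start, end,
                        strand) {
    df <- data.frame(targetId = as.character(targetId),
                     model = as.character(model),
                     evalue = as.numeric(evalue),
                     modelFraction = as.numeric(modelFraction),
                     start = as.integer(start), end = as.integer(end),
                     strand = as.character(strand),
                     stringsAsFactors = FALSE)
    if (nrow(df)) {
        stopifnot(all(df$model %in% .MODELS), all(df$evalue > 0),
                  all(df$modelFraction >= 0 & df$modelFraction <= 1),
                  all(df$start <= df$end), all(df$strand %in% c("+", "-")))
    }
    df
}

#' Write an rRNA-model hit table (GFF-like TSV)
#'
#' @param hits data.frame as returned by \code{\link{featureHits}}.
#' @param path output file.
#' @param source value of the GFF source column.
#' @return \code{path}, invisibly.
#' @export
writeFeatureHits <- function(hits, path, source = "ssuflash") {
    if (nrow(hits) == 0) {
        writeLines(character(0), path)
        return(invisible(path))
    }
    out <- data.frame(hits$targetId, source, hits$model, hits$start,
                      hits$end, format(hits$evalue), hits$strand, ".",
                      paste0("model_fraction=", hits$modelFraction))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read a contig-to-bin membership table
#'
#' @param path two-column TSV (contig, bin), no header.
#' @return data.frame with columns contig, bin.
#' @export
readBinTable <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    data.frame(contig = as.character(df[[1]]), bin = as.character(df[[2]]),
               stringsAsFactors = FALSE)
}

#' Write a cluster assignment table
#'
#' @param clusters data.frame from \code{\link{greedyCluster}}.
#' @param path output TSV (member, centroid, identity).
#' @return \code{path}, invisibly.
#' @export
writeClusterTsv <- function(clusters, path) {
    write.table(clusters, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a paired-end library as two FASTQ files
#'
#' Qualities are constant ('I') since the package does not model base
#' quality.
#'
#' @param pairs A \code{\link{PairedReads}}.
#' @param r1Path,r2Path output FASTQ files.
#' @return c(r1Path, r2Path), invisibly.
#' @export
writePairedFastq <- function(pairs, r1Path, r2Path) {
    w1 <- mateSeqs(pairs, 1); w2 <- mateSeqs(pairs, 2)
    names(w1) <- paste0(names(w1), "/1")
    names(w2) <- paste0(names(w2), "/2")
    writeXStringSet(w1, r1Path, format = "fastq")
    writeXStringSet(w2, r2Path, format = "fastq")
    invisible(c(r1Path, r2Path))
}
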