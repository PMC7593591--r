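# Pipeline orchestration and reporting: run extract -> entropy QC ->
# taxonomic profile -> assembly support under one output prefix, emit
# plain-text/TSV reports, a self-contained HTML report, and an archive.

#' Run the SSU rRNA profiling pipeline on one sample
#'
#' Executes, in order: read extraction against the curated reference,
#' informational-redundancy QC of the extracted reads, LCA taxonomic
#' profiling, and (when contigs and their rRNA hit table are supplied)
#' SSU-region extraction with assembled-fraction accounting and
#' closest-reference assignment. All intermediate files are written under
#' \code{outPrefix}; the report is assembled from stage outputs only. A
#' failing stage is recorded in \code{report$failures} and later stages that
#' depend on it are skipped; the run then returns a partial report.
#'
#' @param refs curated \code{\link{ReferenceSet}} (the mapping database).
#' @param pairs \code{\link{PairedReads}}, or list(r1 =, r2 =) FASTQ paths.
#' @param outPrefix output path prefix for all files.
#' @param sampleIdentifier sample name (default: basename of the prefix).
#' @param minIdentity extraction identity cutoff (default 0.70).
#' @param level taxonomic summarization level (default 3, class).
#' @param entropyK k for the redundancy statistic (default 5).
#' @param contigs optional named DNAStringSet of assembled contigs.
#' @param contigHits optional rRNA hit table on the contigs.
#' @param html also write a self-contained HTML report.
#' @param archive also bundle all outputs into one .tar.gz.
#' @return list of class \code{ssuflash_report}.
#' @export
runPipeline <- function(refs, pairs, outPrefix,
                        sampleIdentifier = basename(outPrefix),
                        minIdentity = 0.70, level = 3, entropyK = 5,
                        contigs = NULL, contigHits = NULL, html = FALSE,
                        archive = FALSE) {
    if (is.list(pairs) && !is(pairs, "PairedReads"))
        pairs <- PairedReads(pairs$r1, pairs$r2)
    dir.create(dirname(outPrefix), showWarnings = FALSE, recursive = TRUE)
    report <- list(sampleId = sampleIdentifier, inputPairs = length(pairs),
                   parameters = list(minIdentity = minIdentity,
                                     level = level, entropyK = entropyK),
                   failures = character(0),
                   timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   version = as.character(utils::packageVersion("ssuflash")),
                   files = character(0))
    class(report) <- "ssuflash_report"
    addFile <- function(p) report$files <<- c(report$files, p)

    # stage 1: extraction
    extraction <- tryCatch({
        idx <- buildRefIndex(refs)
        ex <- extractReads(pairs, idx, minIdentity = minIdentity)
        sam <- extractionToSam(ex, idx)
        addFile(writeSamFile(sam, paste0(outPrefix, ".extracted.sam")))
        if (length(ex$retained))
            addFile(writePairedFastq(ex$retained,
                                     paste0(outPrefix, ".extracted_R1.fastq"),
                                     paste0(outPrefix, ".extracted_R2.fastq")))
        ex
    }, error = function(e) {
        report$failures <<- c(report$failures,
                              paste("extract:", conditionMessage(e)))
        NULL
    })
    report$extractedPairs <- if (is.null(extraction)) NA_integer_
                             else length(extraction$retained)
    if (!is.null(extraction)) {
        hi <- alignmentHistograms(extraction$hits, minIdentity)
        report$identityHistogram <- hi$identity
        report$insertHistogram <- hi$insert
        histLong <- rbind(
            data.frame(histogram = rep("identity", nrow(hi$identity)),
                       bin = hi$identity$bin, count = hi$identity$count),
            data.frame(histogram = rep("insert", nrow(hi$insert)),
                       bin = hi$insert$bin, count = hi$insert$count))
        write.table(histLong, paste0(outPrefix, ".histograms.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        addFile(paste0(outPrefix, ".histograms.tsv"))
    }

    # stage 2: redundancy QC of the extracted reads
    if (!is.null(extraction) && length(extraction$retained) > 0) {
        qc <- tryCatch({
            ent <- rbind(computeEntropy(mateSeqs(extraction$retained, 1),
                                        k = entropyK),
                         computeEntropy(mateSeqs(extraction$retained, 2),
                                        k = entropyK))
            addFile(writeEntropyTsv(ent, paste0(outPrefix, ".entropy.tsv")))
            redundancySummary(ent)
        }, error = function(e) {
            report$failures <<- c(report$failures,
                                  paste("entropy:", conditionMessage(e)))
            NULL
        })
        report$redundancy <- qc
    }

    # stage 3: taxonomic profile
    profile <- NULL
    if (!is.null(extraction)) {
        profile <- tryCatch({
            asg <- classifyPairs(extraction$hits)
            pr <- summarizeProfile(asg, level = level,
                                   sampleIdentifier = sampleIdentifier)
            addFile(writeProfileTsv(pr, paste0(outPrefix, ".profile.tsv")))
            addFile(writeProfileJson(pr, paste0(outPrefix, ".profile.json")))
            pr
        }, error = function(e) {
            report$failures <<- c(report$failures,
                                  paste("profile:", conditionMessage(e)))
            NULL
        })
    }
    report$profile <- profile

    # stage 4: assembly support
    if (!is.null(contigs) && !is.null(contigHits) && !is.null(extraction)) {
        asm <- tryCatch({
            regions <- extractSsuRegions(contigs, contigHits)
            if (nrow(regions)) {
                ss <- DNAStringSet(setNames(regions$seq, regions$regionId))
                writeXStringSet(ss, paste0(outPrefix, ".ssu.fasta"))
                addFile(paste0(outPrefix, ".ssu.fasta"))
            }
            frac <- assembledFraction(extraction$retained,
                                      setNames(regions$seq,
                                               regions$regionId))
            closest <- lapply(seq_len(nrow(regions)), function(i) {
                hit <- closestReference(regions$seq[i], refs)
                data.frame(regionId = regions$regionId[i],
                           refId = if (is.null(hit)) NA_character_
                                   else hit$refId,
                           identity = if (is.null(hit)) NA_real_
                                      else hit$identity,
                           stringsAsFactors = FALSE)
            })
            closest <- if (length(closest)) do.call(rbind, closest) else
                data.frame(regionId = character(0), refId = character(0),
                           identity = numeric(0))
            write.table(closest, paste0(outPrefix, ".closest.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            addFile(paste0(outPrefix, ".closest.tsv"))
            list(regions = regions, assembledFraction = frac,
                 closest = closest)
        }, error = function(e) {
            report$failures <<- c(report$failures,
                                  paste("assembly:", conditionMessage(e)))
            NULL
        })
        report$assembly <- asm
    }

    addFile(writeReportText(report, paste0(outPrefix, ".report.txt")))
    if (html)
        addFile(renderHtml(report, paste0(outPrefix, ".report.html")))
    if (archive)
        report$archive <- archiveResults(outPrefix)
    report
}

#' @export
print.ssuflash_report <- function(x, ...) {
    cat(sprintf("ssuflash report '%s': %d input pairs, %s extracted\n",
                x$sampleId, x$inputPairs,
                ifelse(is.na(x$extractedPairs), "NA", x$extractedPairs)))
    if (length(x$failures)) cat("  FAILED stages:", x$failures, "\n")
    invisible(x)
}

#' Write the plain-text report
#'
#' @param report list from \code{\link{runPipeline}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReportText <- function(report, path) {
    con <- file(path, "w")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("ssuflash v%s report", report$version)
    w("sample: %s", report$sampleId)
    w("run at: %s", report$timestamp)
    w("parameters: min identity %.2f, level %d, entropy k %d",
      report$parameters$minIdentity, report$parameters$level,
      report$parameters$entropyK)
    w("input read pairs: %d", report$inputPairs)
    w("extracted SSU rRNA pairs: %s", format(report$extractedPairs))
    if (!is.null(report$redundancy))
        w("mean informational redundancy of extracted reads: %.4f",
          report$redundancy$meanR)
    if (!is.null(report$profile)) {
        w("")
        w("taxonomic summary (level %d), %d classified pairs:",
          profileLevel(report$profile), profileTotal(report$profile))
        cnt <- sort(profileCounts(report$profile), decreasing = TRUE)
        for (i in seq_along(cnt))
            w("  %6d  %s", cnt[i],
              profileLabel(names(cnt)[i], profileLevel(report$profile)))
    }
    if (!is.null(report$assembly)) {
        w("")
        w("assembled SSU regions: %d", nrow(report$assembly$regions))
        w("fraction of extracted reads mapping to assembled sequences: %s",
          format(report$assembly$assembledFraction))
    }
    if (length(report$failures)) {
        w("")
        for (f in report$failures) w("STAGE FAILURE: %s", f)
    }
    invisible(path)
}

.htmlEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a self-contained HTML report
#'
#' Single file, inline SVG, no remote assets; every number shown equals the
#' corresponding TSV output.
#'
#' @param report list from \code{\link{runPipeline}}.
#' @param path output HTML file.
#' @return \code{path}, invisibly.
#' @export
renderHtml <- function(report, path) {
    h <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'/>",
           sprintf("<title>ssuflash report: %s</title>",
                   .htmlEscape(report$sampleId)),
           "<style>body{font-family:sans-serif;margin:2em}",
           "table{border-collapse:collapse}",
           "td,th{border:1px solid #999;padding:2px 8px}</style>",
           "</head><body>",
           sprintf("<h1>ssuflash report: %s</h1>",
                   .htmlEscape(report$sampleId)),
           sprintf("<p>version %s, run at %s</p>", report$version,
                   report$timestamp),
           sprintf("<p>input read pairs: %d<br/>extracted pairs: %s</p>",
                   report$inputPairs, format(report$extractedPairs)))
    if (length(report$failures))
        h <- c(h, sprintf("<p><b>STAGE FAILURE:</b> %s</p>",
                          .htmlEscape(report$failures)))
    pr <- report$profile
    if (is.null(pr) || profileTotal(pr) == 0) {
        h <- c(h, "<p><b>no SSU rRNA detected</b></p>")
    } else {
        cnt <- sort(profileCounts(pr), decreasing = TRUE)
        lab <- profileLabel(names(cnt), profileLevel(pr))
        h <- c(h, sprintf("<h2>Taxonomic summary (level %d)</h2>",
                          profileLevel(pr)),
               "<table><tr><th>taxon</th><th>pairs</th></tr>",
               sprintf("<tr><td>%s</td><td>%d</td></tr>",
                       .htmlEscape(lab), cnt),
               "</table>")
        # inline SVG barplot of the top taxa
        top <- head(cnt, 10)
        bw <- 360 * as.numeric(top) / max(top)
        y <- 22 * seq_along(top)
        h <- c(h, sprintf("<svg width='700' height='%d'>", max(y) + 30),
               sprintf(paste0("<rect x='220' y='%d' width='%.1f' ",
                              "height='18' fill='#4878a8'/>"),
                       y - 14, bw),
               sprintf(paste0("<text x='215' y='%d' text-anchor='end' ",
                              "font-size='11'>%s</text>"),
                       y, .htmlEscape(substr(profileLabel(
                           names(top), profileLevel(pr)), 1, 34))),
               sprintf("<text x='%.1f' y='%d' font-size='11'>%d</text>",
                       226 + bw, y, as.integer(top)),
               "</svg>")
    }
    if (!is.null(report$redundancy))
        h <- c(h, sprintf(paste0("<p>mean informational redundancy of ",
                                 "extracted reads: %.4f</p>"),
                          report$redundancy$meanR))
    if (!is.null(report$assembly))
        h <- c(h, sprintf(paste0("<p>assembled SSU regions: %d; fraction ",
                                 "of extracted reads mapping to them: ",
                                 "%s</p>"), nrow(report$assembly$regions),
                          format(report$assembly$assembledFraction)))
    h <- c(h, "</body></html>")
    writeLines(h, path)
    invisible(path)
}

#' Archive all run outputs into one .tar.gz with a checksum manifest
#'
#' @param prefix the output prefix used by \code{\link{runPipeline}}.
#' @return path of the archive, invisibly.
#' @export
archiveResults <- function(prefix) {
    dir <- dirname(prefix)
    base <- basename(prefix)
    files <- list.files(dir, pattern = paste0("^", base, "\\."),
                        full.names = TRUE)
    files <- files[!grepl("\\.tar\\.gz$", files)]
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    manifestPath <- file.path(dir, paste0(base, ".manifest.tsv"))
    write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    archive <- paste0(prefix, ".tar.gz")
    owd <- setwd(dir)
    on.exit(setwd(owd))
    utils::tar(basename(archive),
               files = c(basename(files), basename(manifestPath)),
               compression = "gzip", tar = "internal")
    invisible(archive)
}
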