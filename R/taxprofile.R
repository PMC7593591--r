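# LCA taxonomic profiling: per-pair consensus taxonomy from database hits,
# summarized at a chosen rank ("NTU" counts).

#' Last common ancestor of taxonomy paths
#'
#' The longest common prefix of the given semicolon-delimited paths
#' (case-sensitive exact label comparison); an empty prefix yields the root,
#' reported as "Unclassified".
#'
#' @param paths character vector of semicolon-delimited taxonomy paths.
#' @return character(1), the LCA path.
#' @examples
#' taxLca(c("Bacteria;Proteobacteria;Alpha", "Bacteria;Proteobacteria;Gamma"))
#' @export
taxLca <- function(paths) {
    if (length(paths) == 0) stop("taxLca needs at least one path")
    sp <- strsplit(paths, ";", fixed = TRUE)
    common <- sp[[1]]
    for (p in sp[-1]) {
        n <- min(length(common), length(p))
        eq <- common[seq_len(n)] == p[seq_len(n)]
        cut <- if (all(eq)) n else which(!eq)[1] - 1L
        common <- common[seq_len(cut)]
        if (length(common) == 0) break
    }
    if (length(common) == 0) "Unclassified"
    else paste(common, collapse = ";")
}

#' Classify read pairs by the LCA of all their hits
#'
#' Hits of both mates are pooled per read pair; the pair's taxonomic
#' affiliation is the LCA over the taxonomy paths of all its database hits.
#' Pairs without hits do not appear (they were never extracted).
#'
#' @param hits hit table from \code{\link{extractReads}} or
#'   \code{\link{samToHits}} (columns readId, taxonomy).
#' @return named character vector: read id -> LCA taxonomy path.
#' @export
classifyPairs <- function(hits) {
    if (nrow(hits) == 0) return(setNames(character(0), character(0)))
    tax <- hits$taxonomy
    tax[is.na(tax) | !nzchar(tax)] <- "Unclassified"
    vapply(split(tax, hits$readId), taxLca, character(1))
}

#' Summarize pair classifications at a taxonomic level
#'
#' Paths are truncated to \code{level} ranks (1 = domain ... 7 = species);
#' pairs whose LCA is above that level are counted under their maximal-depth
#' path and displayed as "(unclassified) <last-known-rank>".
#'
#' @param assignments named character vector from \code{\link{classifyPairs}}.
#' @param level summarization level, 1-7 (default 3, class).
#' @param sampleIdentifier sample id stored on the profile.
#' @return A \code{\link{TaxProfile}}.
#' @export
summarizeProfile <- function(assignments, level = 3,
                             sampleIdentifier = "sample") {
    if (level < 1 || level > 7) stop("level must be between 1 and 7")
    trunc <- vapply(assignments, function(p) {
        ranks <- strsplit(p, ";", fixed = TRUE)[[1]]
        paste(ranks[seq_len(min(level, length(ranks)))], collapse = ";")
    }, character(1), USE.NAMES = FALSE)
    tab <- table(trunc)
    counts <- setNames(as.integer(tab), names(tab))
    new("TaxProfile", sampleId = sampleIdentifier, level = as.integer(level),
        counts = counts, total = sum(counts))
}

#' Write a TaxProfile as a TSV "NTU table"
#'
#' @param profile A \code{\link{TaxProfile}}.
#' @param path output TSV (columns: taxon display label, path, count).
#' @return \code{path}, invisibly.
#' @export
writeProfileTsv <- function(profile, path) {
    cnt <- sort(profileCounts(profile), decreasing = TRUE)
    df <- data.frame(taxon = profileLabel(names(cnt), profileLevel(profile)),
                     path = names(cnt), count = as.integer(cnt))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a TaxProfile as JSON
#'
#' @param profile A \code{\link{TaxProfile}}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
writeProfileJson <- function(profile, path) {
    jsonlite::write_json(
        list(sampleId = sampleId(profile), level = profileLevel(profile),
             total = profileTotal(profile),
             counts = as.list(profileCounts(profile))),
        path, auto_unbox = TRUE)
    invisible(path)
}

#' Read a TaxProfile from JSON
#'
#' @param path JSON file written by \code{\link{writeProfileJson}}.
#' @return A \code{\link{TaxProfile}}.
#' @export
readProfileJson <- function(path) {
    x <- jsonlite::read_json(path)
    counts <- setNames(as.integer(unlist(x$counts)), names(x$counts))
    new("TaxProfile", sampleId = x$sampleId, level = as.integer(x$level),
        counts = counts, total = as.integer(x$total))
}
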