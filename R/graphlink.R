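# Assembly-graph fishing: parse Fastg, locate SSU-bearing contigs, collect
# their connected components and link them to genome bins.

# collapse an orientation-marked Fastg name to its node id
.fastgNodeId <- function(x) sub("'$", "", x)

# SPAdes-style "EDGE_5_length_100_cov_3.5" headers carry length and coverage
.parseSpadesName <- function(id) {
    m <- regmatches(id, regexec("^EDGE_([^_]+)_length_([0-9]+)_cov_([0-9.eE+-]+)$",
                                id))[[1]]
    if (length(m) == 4)
        list(length = as.integer(m[3]), coverage = as.numeric(m[4]))
    else list(length = NA_integer_, coverage = NA_real_)
}

#' Parse a Fastg assembly graph
#'
#' Header lines are ">u[:v1,v2,...];" where any name may carry a trailing
#' "'" reverse-complement marker; forward and reverse-complement records of a
#' contig are collapsed to a single node and every adjacency becomes one
#' undirected edge. Sequences are attached when present. SPAdes-style
#' "EDGE_x_length_y_cov_z" names are parsed for length and coverage; other
#' header styles fall back to raw ids.
#'
#' @param path Fastg file.
#' @return An \code{\link{AssemblyGraph}}.
#' @export
parseFastg <- function(path) {
    lines <- readLines(path)
    hdrIdx <- which(startsWith(lines, ">"))
    if (!length(hdrIdx)) stop("no records in Fastg file: ", path)
    ends <- c(hdrIdx[-1] - 1L, length(lines))
    ids <- character(0); seqs <- character(0)
    edges <- matrix(character(0), ncol = 2)
    adjList <- list()
    for (i in seq_along(hdrIdx)) {
        hdr <- sub("^>", "", sub(";\\s*$", "", lines[hdrIdx[i]]))
        parts <- strsplit(hdr, ":", fixed = TRUE)[[1]]
        u <- .fastgNodeId(parts[1])
        seq <- if (ends[i] > hdrIdx[i])
            paste(lines[(hdrIdx[i] + 1):ends[i]], collapse = "") else ""
        if (!(u %in% ids)) {
            ids <- c(ids, u)
            seqs <- c(seqs, seq)
        } else if (nzchar(seq) && !nzchar(seqs[match(u, ids)])) {
            seqs[match(u, ids)] <- seq
        }
        if (length(parts) > 1) {
            vs <- .fastgNodeId(strsplit(paste(parts[-1], collapse = ":"),
                                        ",", fixed = TRUE)[[1]])
            adjList[[length(adjList) + 1L]] <-
                cbind(rep(u, length(vs)), vs, deparse.level = 0)
        }
    }
    if (length(adjList)) {
        edges <- do.call(rbind, adjList)
        unknown <- setdiff(as.vector(edges), ids)
        if (length(unknown))
            stop("dangling adjacency target(s) in Fastg: ",
                 paste(unknown, collapse = ", "))
    }
    meta <- lapply(ids, .parseSpadesName)
    lens <- vapply(meta, `[[`, integer(1), "length")
    lens[is.na(lens)] <- nchar(seqs)[is.na(lens)]
    contigs <- data.frame(id = ids, length = lens,
                          coverage = vapply(meta, `[[`, numeric(1),
                                            "coverage"),
                          stringsAsFactors = FALSE)
    keep <- nzchar(seqs)
    ss <- DNAStringSet(setNames(seqs[keep], ids[keep]))
    AssemblyGraph(contigs, edges = edges, seqs = ss)
}

#' Write an AssemblyGraph as Fastg
#'
#' One record per contig with its adjacencies (both orientations collapsed;
#' the round trip through \code{\link{parseFastg}} yields an isomorphic
#' graph).
#'
#' @param graph An \code{\link{AssemblyGraph}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFastg <- function(graph, path) {
    con <- file(path, "w")
    on.exit(close(con))
    ids <- graphContigs(graph)$id
    e <- graphEdges(graph)
    seqs <- graphSeqs(graph)
    for (u in ids) {
        adj <- sort(unique(c(e[e[, 1] == u, 2], e[e[, 2] == u, 1])))
        hdr <- if (length(adj)) paste0(">", u, ":",
                                       paste(adj, collapse = ","), ";")
               else paste0(">", u, ";")
        writeLines(hdr, con)
        if (u %in% names(seqs))
            writeLines(as.character(seqs[[u]]), con)
    }
    invisible(path)
}

#' Fish connected components around SSU-bearing contigs
#'
#' Seeds are contigs carrying an SSU hit passing the region-extraction
#' thresholds; each connected component of the assembly graph containing at
#' least one seed becomes one cluster. Clusters whose total contig length is
#' below \code{minClusterSizeBp} are flagged, not dropped.
#'
#' @param graph An \code{\link{AssemblyGraph}}.
#' @param ssuHits hit table on contigs (see \code{\link{featureHits}}).
#' @param minClusterSizeBp minimum total length before a cluster is flagged
#'   small (default 0).
#' @param evalueCutoff,minModelFraction thresholds the seeds must pass
#'   (defaults 1e-100 and 0.6).
#' @return list of clusters; each is a list with \code{seeds},
#'   \code{members}, \code{totalBp}, \code{flaggedSmall}, and placeholders
#'   \code{binOverlap} and \code{matchedSsu}. Empty (with a warning) when
#'   there are no seeds.
#' @export
fishClusters <- function(graph, ssuHits, minClusterSizeBp = 0,
                         evalueCutoff = 1e-100, minModelFraction = 0.6) {
    pass <- ssuHits[ssuHits$model != "lsu" &
                    ssuHits$evalue <= evalueCutoff &
                    ssuHits$modelFraction >= minModelFraction, , drop = FALSE]
    seeds <- unique(pass$targetId)
    seeds <- seeds[seeds %in% graphContigs(graph)$id]
    if (!length(seeds)) {
        warning("no SSU-bearing seed contigs in graph")
        return(list())
    }
    g <- igraph::graph_from_data_frame(
        d = as.data.frame(graphEdges(graph), stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = graphContigs(graph)$id))
    comp <- igraph::components(g)$membership
    lens <- setNames(graphContigs(graph)$length, graphContigs(graph)$id)
    out <- list()
    for (ci in sort(unique(comp[seeds]))) {
        members <- sort(names(comp)[comp == ci])
        totalBp <- sum(lens[members], na.rm = TRUE)
        out[[length(out) + 1L]] <- list(
            seeds = sort(intersect(seeds, members)), members = members,
            totalBp = totalBp,
            flaggedSmall = totalBp < minClusterSizeBp,
            binOverlap = NULL, matchedSsu = NULL)
    }
    out
}

#' Overlay bin memberships onto fished clusters
#'
#' Counts cluster members per bin; the majority bin is reported with its
#' fraction of cluster members, ties are reported together and flagged
#' ambiguous. Bin-table contigs absent from the graph are warned about and
#' ignored.
#'
#' @param clusters list from \code{\link{fishClusters}}.
#' @param binTable data.frame (contig, bin), e.g. from
#'   \code{\link{readBinTable}}.
#' @param graph optional \code{\link{AssemblyGraph}} to validate the bin
#'   table against.
#' @return clusters with \code{binOverlap} filled in: a list with
#'   \code{counts} (named), \code{majorityBin} (character, >1 on tie),
#'   \code{fraction}, \code{ambiguous}.
#' @export
linkBins <- function(clusters, binTable, graph = NULL) {
    if (!is.null(graph)) {
        missing <- setdiff(binTable$contig, graphContigs(graph)$id)
        if (length(missing))
            warning("bin table contig(s) absent from graph: ",
                    paste(head(missing, 5), collapse = ", "))
    }
    bins <- setNames(binTable$bin, binTable$contig)
    lapply(clusters, function(cl) {
        b <- bins[intersect(cl$members, names(bins))]
        if (!length(b)) {
            cl$binOverlap <- list(counts = integer(0),
                                  majorityBin = character(0),
                                  fraction = NA_real_, ambiguous = FALSE)
            return(cl)
        }
        tab <- sort(table(b), decreasing = TRUE)
        top <- names(tab)[tab == max(tab)]
        cl$binOverlap <- list(
            counts = setNames(as.integer(tab), names(tab)),
            majorityBin = sort(top),
            fraction = max(tab) / length(cl$members),
            ambiguous = length(top) > 1)
        cl
    })
}

#' Match fished SSU contigs to targeted-assembly sequences
#'
#' For every seed contig with a sequence, finds the best targeted SSU
#' sequence by glocal identity (the shorter sequence aligned end-to-end
#' within the longer, both strands). Matches at or above \code{minIdentity}
#' are recorded; ties are broken by target id, ascending.
#'
#' @param clusters list from \code{\link{fishClusters}}.
#' @param graph the \code{\link{AssemblyGraph}} carrying seed sequences.
#' @param targeted named character vector or DNAStringSet of SSU sequences
#'   from the targeted assembly.
#' @param minIdentity minimum identity (default 0.98).
#' @return clusters with \code{matchedSsu} filled in: data.frame (seed,
#'   ssuId, identity), zero rows when nothing qualifies.
#' @export
matchTargetedSsu <- function(clusters, graph, targeted, minIdentity = 0.98) {
    if (!is(targeted, "DNAStringSet")) targeted <- DNAStringSet(targeted)
    seqs <- graphSeqs(graph)
    lapply(clusters, function(cl) {
        rows <- list()
        for (s in cl$seeds) {
            if (!(s %in% names(seqs))) next
            cseq <- as.character(seqs[[s]])
            best <- NULL
            for (tid in sort(names(targeted))) {
                tseq <- as.character(targeted[[tid]])
                # align the shorter within the longer
                if (nchar(tseq) <= nchar(cseq)) {
                    p <- tseq; su <- cseq
                } else {
                    p <- cseq; su <- tseq
                }
                pr <- as.character(reverseComplement(DNAString(p)))
                idy <- max(alignPair(p, su, mode = "glocal")$identity,
                           alignPair(pr, su, mode = "glocal")$identity)
                if (idy >= minIdentity &&
                    (is.null(best) || idy > best$identity))
                    best <- list(ssuId = tid, identity = idy)
            }
            if (!is.null(best))
                rows[[length(rows) + 1L]] <- data.frame(
                    seed = s, ssuId = best$ssuId, identity = best$identity,
                    stringsAsFactors = FALSE)
        }
        cl$matchedSsu <- if (length(rows)) do.call(rbind, rows) else
            data.frame(seed = character(0), ssuId = character(0),
                       identity = numeric(0), stringsAsFactors = FALSE)
        cl
    })
}
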