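# Multi-sample comparison: cumulative-count taxonomy trees, the normalized
# abundance-weighted taxonomic Unifrac-like metric, and barplot/heatmap
# matrices.

.pathPrefixes <- function(path, d) {
    ranks <- strsplit(path, ";", fixed = TRUE)[[1]]
    n <- min(length(ranks), d)
    vapply(seq_len(n), function(i) paste(ranks[seq_len(i)], collapse = ";"),
           character(1))
}

#' Build a cumulative-count taxonomy tree over samples
#'
#' Treats the hierarchical taxonomy as a tree in which every taxon at depth
#' <= d is a node with a branch of unit length. For each node and sample the
#' count is the number of pairs classified to that node or any of its
#' descendants; a pair classified above depth d contributes only to its
#' ancestors.
#'
#' @param profiles named list: sample id -> either a \code{\link{TaxProfile}}
#'   or a character vector of per-pair taxonomy paths.
#' @param d taxonomic depth of the comparison (e.g. 4 for order).
#' @return list with \code{counts} (matrix nodes x samples of cumulative
#'   counts), \code{depths} (node depths) and \code{totals} (per-sample
#'   totals).
#' @export
buildTaxTree <- function(profiles, d) {
    if (d < 1) stop("d must be >= 1")
    tallies <- lapply(profiles, function(p) {
        if (is(p, "TaxProfile")) {
            paths <- names(profileCounts(p))
            n <- as.integer(profileCounts(p))
        } else {
            tab <- table(p)
            paths <- names(tab)
            n <- as.integer(tab)
        }
        acc <- list()
        for (i in seq_along(paths)) {
            for (pre in .pathPrefixes(paths[i], d))
                acc[[pre]] <- (acc[[pre]] %||% 0L) + n[i]
        }
        acc
    })
    nodes <- sort(unique(unlist(lapply(tallies, names))))
    counts <- matrix(0L, nrow = length(nodes), ncol = length(profiles),
                     dimnames = list(nodes, names(profiles)))
    for (s in seq_along(tallies)) {
        t <- tallies[[s]]
        if (length(t)) counts[names(t), s] <- unlist(t)
    }
    depths <- lengths(strsplit(nodes, ";", fixed = TRUE))
    totals <- vapply(profiles, function(p) {
        if (is(p, "TaxProfile")) profileTotal(p) else length(p)
    }, numeric(1))
    list(counts = counts, depths = depths, totals = totals, d = d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalized abundance-weighted taxonomic Unifrac-like distance
#'
#' With A_i, B_i the cumulative counts of node i in samples A and B and
#' A_T, B_T the sample totals, the raw weighted value is
#' u = sum_i |A_i / A_T - B_i / B_T| over all tree nodes; because every
#' branch has unit length and the tree is ultrametric, the normalization
#' factor is D = 2 d at comparison depth d, giving u' = u / (2 d) in [0, 1].
#'
#' @param tree from \code{\link{buildTaxTree}}.
#' @param a,b sample names or column indices.
#' @return u' in [0, 1].
#' @export
unifracLike <- function(tree, a, b) {
    A <- tree$counts[, a]; B <- tree$counts[, b]
    AT <- tree$totals[[a]]; BT <- tree$totals[[b]]
    if (AT == 0 || BT == 0)
        stop("undefined distance: empty sample")
    u <- sum(abs(A / AT - B / BT))
    u / (2 * tree$d)
}

#' Pairwise Unifrac-like distance matrix
#'
#' @param profiles named list of \code{\link{TaxProfile}}s or per-pair
#'   assignment vectors (>= 2 samples).
#' @param d comparison depth (default 4, order level).
#' @return symmetric matrix of u' values with zero diagonal.
#' @export
unifracMatrix <- function(profiles, d = 4) {
    if (length(profiles) < 2) stop("need at least 2 samples")
    tree <- buildTaxTree(profiles, d)
    n <- length(profiles)
    m <- matrix(0, n, n, dimnames = list(names(profiles), names(profiles)))
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            m[i, j] <- m[j, i] <- unifracLike(tree, i, j)
        }
    }
    attr(m, "level") <- d
    m
}

#' Barplot/heatmap tables and distance matrix for multi-sample comparison
#'
#' Taxon abundances are expressed as percent of classified pairs per sample;
#' taxa below the top \code{topN} (by mean percentage) are pooled into
#' "Other". Samples are ordered by average-linkage clustering on the
#' Unifrac-like distance (or on Euclidean distance of the percentage columns)
#' and taxa by average-linkage clustering on Euclidean distance of the
#' percentage rows; the pooled "Other" row is excluded from clustering and
#' appended last.
#'
#' @param profiles named list of \code{\link{TaxProfile}}s (>= 2 samples, all
#'   at the same level).
#' @param topN number of taxa kept unpooled (default 30).
#' @param clusterOn "unifrac" (default) or "euclidean" sample distance.
#' @param d depth for the Unifrac-like distance (defaults to the profile
#'   level).
#' @return list with \code{heatmap} (matrix taxa x samples, percent),
#'   \code{barplot} (long data.frame sample, taxon, percent),
#'   \code{distance} (sample distance matrix).
#' @export
comparisonMatrices <- function(profiles, topN = 30,
                               clusterOn = c("unifrac", "euclidean"),
                               d = NULL) {
    clusterOn <- match.arg(clusterOn)
    if (length(profiles) < 2) stop("need at least 2 samples")
    if (is.null(names(profiles)))
        names(profiles) <- vapply(profiles, sampleId, character(1))
    level <- profileLevel(profiles[[1]])
    if (is.null(d)) d <- level
    taxa <- sort(unique(unlist(lapply(profiles,
                                      function(p) names(profileCounts(p))))))
    pct <- matrix(0, nrow = length(taxa), ncol = length(profiles),
                  dimnames = list(taxa, names(profiles)))
    for (s in names(profiles)) {
        cnt <- profileCounts(profiles[[s]])
        if (profileTotal(profiles[[s]]) > 0)
            pct[names(cnt), s] <- 100 * cnt / profileTotal(profiles[[s]])
    }
    dist <- unifracMatrix(profiles, d = d)
    # pool minor taxa
    if (nrow(pct) > topN) {
        ord <- order(rowMeans(pct), decreasing = TRUE)
        major <- pct[ord[seq_len(topN)], , drop = FALSE]
        other <- colSums(pct[ord[-seq_len(topN)], , drop = FALSE])
        pct <- major
    } else other <- NULL
    # order samples and taxa by hierarchical clustering
    sampleOrder <- seq_len(ncol(pct))
    if (ncol(pct) > 2) {
        sd <- if (clusterOn == "unifrac") as.dist(dist)
              else stats::dist(t(pct))
        sampleOrder <- hclust(sd, method = "average")$order
    }
    taxonOrder <- seq_len(nrow(pct))
    if (nrow(pct) > 2)
        taxonOrder <- hclust(stats::dist(pct), method = "average")$order
    pct <- pct[taxonOrder, sampleOrder, drop = FALSE]
    if (!is.null(other)) pct <- rbind(pct, Other = other[colnames(pct)])
    rownames(pct) <- ifelse(rownames(pct) == "Other", "Other",
                            profileLabel(rownames(pct), level))
    bar <- data.frame(sample = rep(colnames(pct), each = nrow(pct)),
                      taxon = rep(rownames(pct), ncol(pct)),
                      percent = as.vector(pct), stringsAsFactors = FALSE)
    list(heatmap = pct, barplot = bar,
         distance = dist[colnames(pct), colnames(pct)])
}
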