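# Informational redundancy QC: per-sequence k-mer entropy H and redundancy
# R = 1 - H / log2(A), used to flag low-complexity read extraction artifacts.

#' Per-sequence k-mer entropy and informational redundancy
#'
#' k-mers are counted with a sliding window of width k across the sequence
#' (literal, not canonical). With w_i the occurrences of k-mer i among the
#' L - k + 1 windows and p_i = w_i / sum(w), the entropy is
#' H = -sum(p_i * log2(p_i)) bits. The attainable alphabet size is
#' A = 4^k when L - k + 1 > 4^k and A = L - k + 1 otherwise, and the
#' redundancy is R = 1 - H / log2(A), which lies in [0, 1] (0 = maximum
#' entropy, 1 = zero entropy). Windows containing N or other ambiguity are
#' skipped and the effective window count adjusted accordingly.
#'
#' @param seqs DNAStringSet or character vector of sequences (named).
#' @param k k-mer length (default 5).
#' @return data.frame with columns readId, k, L, H, A, R (one row per
#'   sequence).
#' @examples
#' computeEntropy(c(r1 = "ACGTACGT"), k = 2)
#' @export
computeEntropy <- function(seqs, k = 5) {
    if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
    if (length(seqs) == 0)
        return(data.frame(readId = character(0), k = integer(0),
                          L = integer(0), H = numeric(0), A = numeric(0),
                          R = numeric(0)))
    if (any(width(seqs) < k))
        stop("sequence(s) shorter than k")
    counts <- oligonucleotideFrequency(seqs, width = k, step = 1)
    tot <- rowSums(counts)          # valid windows only (N windows skipped)
    if (any(tot == 0))
        stop("sequence(s) with no valid (ambiguity-free) k-mer window")
    H <- vapply(seq_len(nrow(counts)), function(i) {
        p <- counts[i, counts[i, ] > 0] / tot[i]
        -sum(p * log2(p))
    }, numeric(1))
    A <- ifelse(tot > 4^k, 4^k, tot)
    R <- ifelse(A > 1, 1 - H / log2(A), 1)
    data.frame(readId = if (is.null(names(seqs)))
                   as.character(seq_along(seqs)) else names(seqs),
               k = k, L = width(seqs), H = H, A = A, R = R,
               stringsAsFactors = FALSE)
}

#' Summarize redundancy statistics over a read set
#'
#' @param stats data.frame from \code{\link{computeEntropy}}.
#' @param binWidth histogram bin width on R (default 0.01).
#' @return list with \code{n}, \code{meanR}, \code{medianR} and
#'   \code{histogram} (data.frame bin, count; bins are left edges).
#' @export
redundancySummary <- function(stats, binWidth = 0.01) {
    if (nrow(stats) == 0) stop("empty entropy table")
    bins <- floor(stats$R / binWidth) * binWidth
    bins[stats$R >= 1] <- 1 - binWidth   # R = 1 falls in the top bin
    tab <- table(factor(format(bins, nsmall = 2),
                        levels = format(seq(0, 1 - binWidth, by = binWidth),
                                        nsmall = 2)))
    list(n = nrow(stats), meanR = mean(stats$R), medianR = median(stats$R),
         histogram = data.frame(bin = as.numeric(names(tab)),
                                count = as.integer(tab)))
}

#' Write a per-read entropy table as TSV
#'
#' @param stats data.frame from \code{\link{computeEntropy}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEntropyTsv <- function(stats, path) {
    write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
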