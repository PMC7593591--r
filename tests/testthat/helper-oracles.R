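# Shared fixture builders and independent brute-force oracles. Oracles are
# deliberately naive (plain loops, or Biostrings where it provides an
# independent implementation) and never call the code paths they check.

BASES <- c("A", "C", "G", "T")

rndSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

mutSeq <- function(s, nmut) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in sample(length(ch), nmut))
        ch[i] <- sample(setdiff(BASES, ch[i]), 1)
    paste(ch, collapse = "")
}

revcompChr <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# independent global identity: Biostrings pairwiseAlignment with the same
# scoring scheme; identity = matches / alignment columns
oracleGlobalIdentity <- function(p, s) {
    a <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(p), Biostrings::DNAString(s), type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
        gapOpening = 5, gapExtension = 2)
    Biostrings::nmatch(a) / nchar(as.character(Biostrings::alignedPattern(a)))
}

# brute-force whole-sequence k-mer entropy/redundancy
oracleEntropy <- function(seq, k) {
    n <- nchar(seq) - k + 1
    kmers <- substring(seq, 1:n, 1:n + k - 1)
    kmers <- kmers[!grepl("[^ACGT]", kmers)]
    w <- table(kmers)
    p <- w / sum(w)
    H <- -sum(p * log2(p))
    A <- if (sum(w) > 4^k) 4^k else sum(w)
    list(H = H, A = A, R = if (A > 1) 1 - H / log2(A) else 1)
}

# brute-force per-window normalized entropy for the masking rule: returns,
# for one k, the set of 1-based positions the rule should mask (positions
# covered by k-mers occurring >1 time inside any window whose normalized
# entropy is below the cutoff)
oracleMaskPositions <- function(seq, k, cutoff, window = 100) {
    L <- nchar(seq)
    w <- min(window, L)
    pos <- logical(L)
    for (ws in 1:(L - w + 1)) {
        ks <- ws:(ws + w - k)
        kmers <- substring(seq, ks, ks + k - 1)
        ok <- !grepl("[^ACGT]", kmers)
        kmers <- kmers[ok]; ks <- ks[ok]
        if (length(kmers) < 2) next
        tab <- table(kmers)
        p <- tab / sum(tab)
        H <- -sum(p * log2(p))
        Hmax <- log2(min(4^k, length(kmers)))
        if (H < cutoff * Hmax) {
            dup <- kmers %in% names(tab)[tab > 1]
            for (q in ks[dup]) pos[q:(q + k - 1)] <- TRUE
        }
    }
    which(pos)
}

# brute-force Hamming scan: does `seq` contain any window matching any
# vector window within Hamming distance maxd (full k anywhere, short l only
# end-anchored)?
oracleVectorMatch <- function(seq, vectors, k, kEnd, maxd) {
    hamming <- function(a, b) {
        sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }
    vecs <- c(vectors, vapply(vectors, revcompChr, character(1)))
    L <- nchar(seq)
    scanLen <- function(l, starts) {
        vw <- unlist(lapply(vecs, function(v) {
            if (nchar(v) < l) return(character(0))
            substring(v, 1:(nchar(v) - l + 1), l:nchar(v))
        }))
        for (st in starts) {
            q <- substr(seq, st, st + l - 1)
            if (any(vapply(vw, function(x) hamming(q, x) <= maxd,
                           logical(1)))) return(TRUE)
        }
        FALSE
    }
    if (L >= k && scanLen(k, 1:(L - k + 1))) return(TRUE)
    for (l in kEnd:(k - 1)) {
        if (L < l) next
        if (scanLen(l, unique(c(1L, L - l + 1L)))) return(TRUE)
    }
    FALSE
}

# brute-force Unifrac-like value by explicit prefix enumeration over two
# assignment vectors (per-pair taxonomy paths)
oracleUnifrac <- function(pathsA, pathsB, d) {
    prefixes <- function(p) {
        r <- strsplit(p, ";", fixed = TRUE)[[1]]
        n <- min(length(r), d)
        sapply(seq_len(n), function(i) paste(r[1:i], collapse = ";"))
    }
    tally <- function(paths) {
        acc <- new.env()
        for (p in paths) for (pre in prefixes(p))
            assign(pre, (if (exists(pre, acc)) get(pre, acc) else 0) + 1, acc)
        acc
    }
    ea <- tally(pathsA); eb <- tally(pathsB)
    nodes <- union(ls(ea), ls(eb))
    u <- 0
    for (nd in nodes) {
        ai <- if (exists(nd, ea)) get(nd, ea) else 0
        bi <- if (exists(nd, eb)) get(nd, eb) else 0
        u <- u + abs(ai / length(pathsA) - bi / length(pathsB))
    }
    u / (2 * d)
}

# random taxonomy path of depth `depth` over a small label alphabet
rndPath <- function(depth, breadth = 3) {
    paste(paste0("t", seq_len(depth), "_",
                 sample.int(breadth, depth, replace = TRUE)),
          collapse = ";")
}

# plain BFS connected component containing `start` on an undirected edge list
oracleBfsComponent <- function(edges, nodes, start) {
    adj <- lapply(setNames(vector("list", length(nodes)), nodes),
                  function(x) character(0))
    if (!is.null(edges) && nrow(edges)) {
        for (i in seq_len(nrow(edges))) {
            adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
            adj[[edges[i, 2]]] <- c(adj[[edges[i, 2]]], edges[i, 1])
        }
    }
    seen <- start
    queue <- start
    while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
            if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
        }
    }
    sort(seen)
}

# rescore a reported hit from its CIGAR against the reference sequence,
# independently of the aligner: returns matches / columns
rescoreHit <- function(readSeq, refSeq, refStart, strand, cigar) {
    q <- if (strand == "-") revcompChr(readSeq) else readSeq
    ops <- regmatches(cigar, gregexpr("[0-9]+[MID]", cigar))[[1]]
    qi <- 1L; ri <- refStart
    matches <- 0L; columns <- 0L
    for (op in ops) {
        n <- as.integer(sub("[MID]", "", op))
        type <- sub("[0-9]+", "", op)
        if (type == "M") {
            for (j in seq_len(n)) {
                columns <- columns + 1L
                if (substr(q, qi, qi) == substr(refSeq, ri, ri))
                    matches <- matches + 1L
                qi <- qi + 1L; ri <- ri + 1L
            }
        } else if (type == "I") {
            columns <- columns + n; qi <- qi + n
        } else {
            columns <- columns + n; ri <- ri + n
        }
    }
    matches / columns
}
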