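---
title: "SSU rRNA profiling from shotgun metagenomes: methods and design"
author: "ssuflash"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSU rRNA profiling from shotgun metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssuflash)
```

## Scope and model

The small-subunit (SSU) rRNA gene — 16S in prokaryotes and archaea, 18S in
eukaryotes — is the standard marker for taxonomic profiling across all
domains of life, yet it is chronically missing from metagenome-assembled
genomes (MAGs) because its conserved regions tangle assembly graphs.
`ssuflash` implements the computational core of an SSU-centered metagenome
workflow:

1. **Reference curation** (`curateReferences`): a SILVA-style SSU reference
   set is purged of LSU rRNA fragments, normalized to the DNA alphabet,
   hard-masked for low-complexity/repeat content, screened for cloning
   vector k-mers, and de-replicated into NR99/NR96 representative sets by
   greedy identity clustering.
2. **Read extraction** (`extractReads`): paired-end shotgun reads are mapped
   against the curated reference by a k-mer seeded, affine-gap aligner with
   a minimum identity cutoff (70% by default); a pair is retained when at
   least one mate aligns, and all tied best-scoring hits are kept.
3. **Redundancy QC** (`computeEntropy`): per-read k-mer entropy `H` and
   informational redundancy `R = 1 - H / log2(A)` flag low-complexity
   extraction artifacts, with `A = 4^k` when the read supplies more than
   `4^k` sliding windows and `A = L - k + 1` otherwise.
4. **LCA profiling** (`classifyPairs`, `summarizeProfile`): every retained
   pair is assigned the last common ancestor (longest common prefix) of the
   taxonomy strings of *all* its hits, mates pooled, and counts are
   summarized at a chosen rank (class by default).
5. **Assembly support** (`chooseKmers`, `emirgeInsertRule`,
   `extractSsuRegions`, `assembledFraction`, `closestReference`): pure
   parameter rules for downstream assemblers, extraction of SSU regions from
   contig hit tables (E ≤ 1e-100 and ≥ 0.6 of the full model), accounting
   of the fraction of extracted reads that remap to assembled sequences at
   98% identity, and closest-database-hit assignment at 70%.
6. **Multi-sample comparison** (`unifracLike`, `comparisonMatrices`): the
   taxonomy is treated as a tree of unit-length branches; with cumulative
   node counts `A_i`, `B_i` and totals `A_T`, `B_T`, the raw distance is
   `u = sum_i |A_i/A_T - B_i/B_T|` and the normalized metric is
   `u' = u / (2d)` at comparison depth `d` (4 at order level), which lies in
   [0, 1].
7. **Graph fishing** (`parseFastg`, `fishClusters`, `linkBins`,
   `matchTargetedSsu`): Fastg assembly graphs are parsed into an undirected,
   orientation-collapsed contig graph; the connected component around each
   SSU-bearing contig is "fished" and linked to genome bins by majority
   membership.

External mappers, HMM scanners and assemblers are *not* invoked: the package
consumes and produces their standard formats (FASTA, FASTQ, SAM, GFF-like
hit tables, Fastg, TSV bin tables) and substitutes fully specified internal
operators where the surrounding workflow needs one (the seeded aligner, the
entropy masker, the vector screen). This makes every default cutoff testable
in isolation.

## Key parameters

| parameter | default | where | meaning |
|---|---|---|---|
| LSU removal | E ≤ 1e-10, fraction > 0.10 | `removeLsuFragments` | drop references carrying LSU fragments |
| masking | k in 4–8, cutoff 0.7, min run 20 bp, window 100 bp | `maskLowComplexity` | hard-mask repeats/low complexity |
| vector screen | k 27, end-k 11, Hamming ≤ 1, min 800 bp after trim | `screenVector` | UniVec-style decontamination |
| clustering | 99% ("NR99") and 96% ("NR96") | `greedyCluster` | representative sets |
| extraction | min identity 0.70, seed k 13, ≥ 2 co-linear seeds, band 16 | `extractReads` | SSU read recovery |
| redundancy | k = 5 | `computeEntropy` | QC statistic |
| profile level | 3 (class); 1 = domain … 7 = species | `summarizeProfile` | NTU summary rank |
| assembly k-mers | [99, 111, 127] for reads ≥ 134 bp, else next-lower-odd(L − 27/17/7) | `chooseKmers` | de Bruijn k selection |
| EM assembler | single-read when reads > 152 bp; insert = max(observed, 2.2·L + 0.5); 40 iterations | `emirgeInsertRule` | paired-mode rules |
| region extraction | E ≤ 1e-100, ≥ 0.6 model | `extractSsuRegions` | full-length SSU regions |
| remap accounting | 98% identity | `assembledFraction` | assembled read fraction |
| comparison | d = 4 (order), top 30 taxa, average linkage | `comparisonMatrices` | heatmap/distance |

Identity everywhere means matching columns divided by total alignment
columns (gap columns included) of an affine-gap alignment with match 1,
mismatch −2, gap open −5, gap extend −2. The k-mer rule for short reads
applies next-lower-odd *after* the subtraction; the ≥ 134 bp branch is a
fixed override (134 − 27 = 107, not 99, so the two branches are genuinely
separate rules).

## Design choices where the design was open

* **Masking operator.** The parameterization (k 4–8, entropy cutoff 0.7,
  minimum masked length 20 bp) is published, but the masking algorithm
  itself is delegated to an external tool. We define it as sliding-window
  (100 bp, step 1) normalized k-mer entropy, `H / log2(min(4^k, valid
  k-mers))`; inside a window below the cutoff, the masked positions are
  those covered by k-mers occurring more than once in that window, and a
  position must qualify at **every** k in the range. Genuine repeats and
  homopolymers recur at all k, whereas chance collisions of 4-mers in random
  sequence do not survive k = 8; the masked interval therefore tracks the
  offending run to within one k-mer length. Masked runs shorter than 20 bp
  are left alone. Masks are hard (N), so downstream k-mer indexing can never
  seed inside them.
* **N survives alphabet normalization.** Partial IUPAC ambiguity codes are
  replaced by a seeded uniform draw from the bases they denote; N is kept,
  because N doubles as the hard mask and replacing it would make curation
  non-idempotent.
* **Vector screening trims, not discards.** Internal matches cut the
  sequence and the longest fragment is kept; a record is only dropped when
  that fragment is shorter than 800 bp. Windows overhanging an embedded
  vector k-mer by one or two bases are themselves legitimate
  Hamming-1 matches and are trimmed too, so trimmed fragments can be a few
  bases shorter than the exact insert span.
* **Clustering order and identity.** Records are processed longest-first
  (ties by id) and join the first centroid at or above the threshold;
  identity is computed on a global alignment. The published workflow names a
  tool, not a formula; this makes the operation deterministic and testable.
* **LCA over all hits.** All hits above the identity cutoff (not only tied
  best) from both mates are pooled before the LCA, matching the
  "all database hits" reading; sub-best hits are not down-weighted.
* **Unifrac-like truncation.** A pair classified above depth `d` contributes
  to its ancestors only; this is what keeps `u' ≤ 1` without any special
  casing, and nodes at zero count in both samples contribute nothing.
* **closestReference / matchTargetedSsu use query-global (glocal)
  alignment**, the semantics of a `usearch_global`-style search, since an
  assembled region is usually a fragment of the full-length reference.
* **Fishing is orientation-blind and unbounded.** A contig and its reverse
  complement are one node; the whole connected component is collected. The
  goal is linking, not path reconstruction, and the component is the
  superset any hop-bounded variant would return.
* **Coordinates.** Intervals are IRanges (1-based, closed) throughout, the
  Bioconductor convention; GFF-like tables at the I/O boundary are 1-based
  inclusive.

## Synthetic fixtures: what they emulate and what they do not

`fixtureSpec()` defaults encode the study conditions used throughout the
tests: a 7-rank taxonomy over 12 taxa derived from one ~1,500-bp root SSU
sequence with per-rank divergence 8/5/3/2/1.2/0.8/0.4% (leaf-to-leaf
identities span roughly 70–99.9%, like a phylum-level mock community);
10,000 read pairs of 100 bp with a 220 ± 110 bp insert profile, 10% of pairs
drawn from SSU genes and the rest random background, and 1% uniform
substitution error. Curation artifacts (LSU tails, 60-bp homopolymer runs,
embedded vector 27-mers) are injected into truth-flagged records on demand.
Planted assembly graphs wire one SSU-bearing contig into a random connected
contig graph per genome, with a matching bin table.

The generators deliberately do **not** model quality-score-dependent error
profiles, indels in reads, chimeras, coverage bias, or real SILVA taxonomy
idiosyncrasies. Passing tests therefore demonstrate the correctness of the
algorithms under clean, known-truth conditions — extraction sensitivity on
real libraries will be lower and depends on how well the reference covers
the community, exactly as the underlying workflow's evaluations show.

Problem sizes in the test-suite and acceptance script (10,000 pairs for
extraction, 1,000 random profile pairs for the metric oracle, 100 random
graphs for fishing) were chosen as the smallest sets that exercise the
statistics meaningfully while keeping a full run in the minutes range on a
single CPU.

## Numerical notes and degenerate inputs

* Entropy windows containing N or other ambiguity are skipped and the
  denominator adjusted; a sequence with no valid window is an error.
  `R` is defined as 1 when only a single k-mer window exists.
* The aligner is exact dynamic programming (no heuristics beyond seeding);
  ties among equal-scoring references are all reported, ordered by
  reference id, so output order is deterministic. Candidates require at
  least two co-linear seeds on one diagonal bucket (width 16), which keeps
  random background reads out of the alignment stage.
* Empty inputs: an empty library produces a zero-count report (no crash);
  an empty reference index yields no hits; `assembledFraction` is absent
  (NA) with no extracted reads and 0 with no assembled sequences;
  `fishClusters` warns and returns an empty list with no seeds.
* Insert sizes are defined only when both mates align to the same reference
  on opposite strands, as the outer distance of the two alignments.
* All randomness (fixtures, ambiguity replacement) flows from explicit
  seeds; a rerun with the same seed and configuration is byte-identical.

## Known limitations

* The internal aligner is parameter-compatible with external mappers only
  at the identity-cutoff level; it is a desk-scale substitute, not a
  high-throughput mapper, and quality scores are ignored.
* Chimerism scoring, HMM scanning, and the assemblers themselves are out of
  scope; hit tables and contigs are consumed as inputs.
* `greedyCluster` is O(n · centroids) full global alignments and is meant
  for reference sets of hundreds to a few thousand sequences, not the full
  SILVA database.
* The Unifrac-like metric uses unit branch lengths on the taxonomy tree; it
  is not phylogenetic UniFrac and inherits the taxonomy's granularity.

## A minimal worked run

```{r example, eval = FALSE}
spec <- fixtureSpec(seed = 42, nTaxa = 8, nPairs = 500, fractionSsu = 0.2)
db <- genReferenceDb(spec)
curated <- curateReferences(db$refs, lsuHits = db$lsuHits,
                            vectors = db$vectors, seed = 42)
reads <- genReads(spec, db$refs)
report <- runPipeline(curated$refs, reads$pairs,
                      outPrefix = file.path(tempdir(), "demo"),
                      level = 3, html = TRUE)
report$profile
```
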