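# Shared fixtures: a tiny two-amplicon panel with fixed sequences, and
# helpers for constructing tagged reads by hand.

TINY_INSERT1 <- "ACGGTCATTCGAGGTCCATAGGCTTACCGATTGCAAGTCC"  # 40 bp
TINY_INSERT2 <- "TTGCACGATACCGGATTCAGCATGCCATTGGACCGTAGCA"  # 40 bp

tinyPanel <- function() {
  amp <- data.frame(
    amplicon_id = c("AMP1", "AMP2"),
    chrom = c("chr1", "chr2"),
    insert_start = c(101L, 501L),
    insert_end = c(140L, 540L),
    fwd_primer = c("ACGTACGTACGT", "TTGACCGGTTCA"),
    rev_primer = c("GGCCTTAAGGCC", "CAGTTCAGGACC"),
    pool_id = c(1L, 2L),
    ref_insert = c(TINY_INSERT1, TINY_INSERT2),
    stringsAsFactors = FALSE)
  # hotspot at chr1:120 = insert-relative position 20 of AMP1
  hs <- data.frame(chrom = "chr1", pos = 120L,
                   ref = substr(TINY_INSERT1, 20L, 20L), alt = "G",
                   label = "HS1", stringsAsFactors = FALSE)
  ampliconPanel(amp, hs)
}

refInsertOf <- function(panel, ampliconId) {
  a <- amplicons(panel)
  a$ref_insert[match(ampliconId, a$amplicon_id)]
}

# substitute one base at an insert-relative position
subsBase <- function(seq, relPos, alt) {
  paste0(substr(seq, 1L, relPos - 1L), alt, substr(seq, relPos + 1L, nchar(seq)))
}

# a single tagged-read row
readRow <- function(ampliconId, umt5, umt3, sequence, id = "r1", sample = "S1") {
  data.frame(read_id = id, sample_id = sample, amplicon_id = ampliconId,
             sequence = sequence, qualities = strrep("I", nchar(sequence)),
             umt5 = umt5, umt3 = umt3, primer_trimmed = TRUE,
             stringsAsFactors = FALSE)
}

# n copies of a read with distinct ids
readRows <- function(n, ampliconId, umt5, umt3, sequence, prefix = "r",
                     sample = "S1") {
  do.call(rbind, lapply(seq_len(n), function(i)
    readRow(ampliconId, umt5, umt3, sequence, id = paste0(prefix, i),
            sample = sample)))
}

# a raw (untrimmed) read for parse tests
rawReadFor <- function(panel, ampliconId, umt5, umt3, insert) {
  a <- amplicons(panel)
  i <- match(ampliconId, a$amplicon_id)
  paste0(umt5, a$fwd_primer[i], insert, a$rev_primer[i], umt3)
}

# a one-amplicon panel + its spiked variant, for deep plasma simulations
singleAmpliconPanel <- function() {
  p <- egfrDilutionPanel()
  ampliconPanel(amplicons(p)[1L, , drop = FALSE],
                hotspots(p)[1L, , drop = FALSE])
}

# independent exact binomial tail oracle: direct summation of pmf terms
binomTailOracle <- function(k, n, p) {
  if (k <= 0) return(1)
  ks <- k:n
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}
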