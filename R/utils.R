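# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

#' Hamming distance between two equal-length strings
#' @noRd
.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("Hamming distance requires equal-length strings")
  if (nchar(a) == 0L) return(0L)
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Vectorised Hamming distance of each string in `x` (all nchar(pattern) long)
# against a single fixed pattern.
.hammingToPattern <- function(x, pattern) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  mm <- integer(length(x))
  for (i in seq_along(pc)) mm <- mm + (substr(x, i, i) != pc[i])
  mm
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# n random DNA strings of length len (uses the current RNG stream)
.randomSeqs <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(.BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Trim a (pos, REF, ALT) allele record to its canonical minimal
# left-anchored form: drop the shared suffix, then the shared prefix
# (always keeping at least one base on each side; pos advances with the
# prefix). This is the usual VCF-style normalisation so that the same
# event described from different reads collapses to one record.
.normalizeAllele <- function(pos, ref, alt) {
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  ac <- strsplit(alt, "", fixed = TRUE)[[1]]
  # shared suffix
  while (length(rc) > 1L && length(ac) > 1L && rc[length(rc)] == ac[length(ac)]) {
    rc <- rc[-length(rc)]
    ac <- ac[-length(ac)]
  }
  # shared prefix
  while (length(rc) > 1L && length(ac) > 1L && rc[1L] == ac[1L]) {
    rc <- rc[-1L]
    ac <- ac[-1L]
    pos <- pos + 1L
  }
  list(pos = pos, ref = paste(rc, collapse = ""), alt = paste(ac, collapse = ""))
}

# Variant class from normalised REF/ALT strings.
.alleleClass <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  ifelse(na > nr, "INS", ifelse(na < nr, "DEL", "SNV"))
}

# Does the reference insert contain a homopolymer run of at least
# `minRun` bases overlapping or adjacent to insert-relative positions
# [from, to]?
.homopolymerContext <- function(refInsert, from, to, minRun = 4L) {
  rc <- strsplit(refInsert, "", fixed = TRUE)[[1]]
  r <- rle(rc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$lengths >= minRun & starts <= (to + 1L) & ends >= (from - 1L)
  any(hit)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
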