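## Read parsing: UMT excision, primer trimming, amplicon assignment.
##
## Raw read structure (single-ended, oriented 5'->3' along the amplicon):
##   [5' UMT] [fwd primer] [insert] [rev primer] [3' UMT]
## Both UMTs have the configured fixed length (default 6). Primer matching
## is Hamming-only (no indels) within a mismatch budget shared across the
## primer pair.

#' Assign a read to a panel amplicon by its observed primer pair
#'
#' Computes the Hamming distance of the observed forward/reverse primer
#' sequences against every amplicon whose primers have the same lengths, and
#' returns the unique amplicon within \code{maxMismatch} total mismatches.
#' Ties (two amplicons at the same minimal distance) and no-matches both
#' yield \code{NA}, with the reason in the \code{"reason"} attribute
#' (\code{"ambiguous"} or \code{"unassigned"}).
#'
#' @param fwdObserved observed forward primer sequence.
#' @param revObserved observed reverse primer sequence.
#' @param panel an \code{AmpliconPanel}.
#' @param maxMismatch total mismatch budget over both primers (default 2).
#' @return The matching \code{amplicon_id}, or \code{NA} with a
#'   \code{"reason"} attribute.
#' @export
assignAmplicon <- function(fwdObserved, revObserved, panel, maxMismatch = 2L) {
  a <- amplicons(panel)
  if (nrow(a) == 0L) .stopf("panel has no amplicons")
  d <- vapply(seq_len(nrow(a)), function(i) {
    if (nchar(fwdObserved) != nchar(a$fwd_primer[i]) ||
        nchar(revObserved) != nchar(a$rev_primer[i])) return(NA_integer_)
    .hamming(fwdObserved, a$fwd_primer[i]) + .hamming(revObserved, a$rev_primer[i])
  }, integer(1))
  ok <- which(!is.na(d) & d <= maxMismatch)
  if (length(ok) == 0L) return(structure(NA_character_, reason = "unassigned"))
  best <- min(d[ok])
  hits <- ok[d[ok] == best]
  if (length(hits) > 1L) return(structure(NA_character_, reason = "ambiguous"))
  a$amplicon_id[hits]
}

#' Parse raw tagged reads into structured reads
#'
#' Excises the 5' and 3' UMTs, matches the flanking primers against the
#' panel within the mismatch budget, assigns each read to the unique best
#' matching amplicon and returns the retained insert sequence and qualities.
#' Reads shorter than the structural minimum are rejected with reason
#' \code{"too_short"}; reads whose primers match no amplicon (or tie between
#' two) are rejected with reason \code{"unassigned"} / \code{"ambiguous"}.
#' Conservation holds per batch: every input read is either accepted or
#' rejected with exactly one reason.
#'
#' @param sequences character vector of raw read sequences.
#' @param qualities character vector of Phred+33 quality strings (same
#'   lengths as \code{sequences}).
#' @param panel an \code{AmpliconPanel}.
#' @param sampleId sample name stored in the output reads.
#' @param umtLength UMT length per end (default 6).
#' @param maxMismatch total primer mismatch budget (default 2; no indels).
#' @param readIds optional read identifiers; autogenerated when missing.
#' @return A list with elements \code{reads} (a
#'   \code{\linkS4class{TaggedReads}}) and \code{rejected} (data.frame
#'   \code{read_id}, \code{reason}).
#' @export
parseTaggedReads <- function(sequences, qualities, panel, sampleId = "S1",
                             umtLength = 6L, maxMismatch = 2L, readIds = NULL) {
  umtLength <- as.integer(umtLength)
  n <- length(sequences)
  if (is.null(readIds)) readIds <- sprintf("read%06d", seq_len(n))
  if (length(qualities) != n) .stopf("sequences and qualities differ in length")
  a <- amplicons(panel)
  if (nrow(a) == 0L) .stopf("panel has no amplicons")
  sequences <- toupper(sequences)
  len <- nchar(sequences)
  minStruct <- 2L * umtLength + min(nchar(a$fwd_primer) + nchar(a$rev_primer)) + 1L

  tooShort <- len < minStruct
  # per-amplicon total primer mismatches (NA when the read is too short for
  # that amplicon's primer lengths)
  mm <- matrix(NA_integer_, nrow = n, ncol = nrow(a))
  for (i in seq_len(nrow(a))) {
    f <- nchar(a$fwd_primer[i]); r <- nchar(a$rev_primer[i])
    fits <- !tooShort & len >= 2L * umtLength + f + r + 1L
    if (!any(fits)) next
    obsF <- substr(sequences[fits], umtLength + 1L, umtLength + f)
    obsR <- substr(sequences[fits], len[fits] - umtLength - r + 1L, len[fits] - umtLength)
    mm[fits, i] <- .hammingToPattern(obsF, a$fwd_primer[i]) +
      .hammingToPattern(obsR, a$rev_primer[i])
  }
  mm[!is.na(mm) & mm > maxMismatch] <- NA_integer_
  nHit <- rowSums(!is.na(mm))
  best <- rep(NA_integer_, n)
  hasHit <- nHit > 0L
  if (any(hasHit)) {
    bestD <- apply(mm[hasHit, , drop = FALSE], 1L, min, na.rm = TRUE)
    nBest <- rowSums(mm[hasHit, , drop = FALSE] == bestD, na.rm = TRUE)
    bi <- apply(mm[hasHit, , drop = FALSE], 1L, which.min)
    bi[nBest > 1L] <- NA_integer_
    best[hasHit] <- bi
  }

  reason <- rep(NA_character_, n)
  reason[tooShort] <- "too_short"
  reason[!tooShort & nHit == 0L] <- "unassigned"
  reason[!tooShort & hasHit & is.na(best)] <- "ambiguous"
  acc <- is.na(reason)

  if (any(acc)) {
    ai <- best[acc]
    f <- nchar(a$fwd_primer)[ai]; r <- nchar(a$rev_primer)[ai]
    li <- len[acc]
    insFrom <- umtLength + f + 1L
    insTo <- li - umtLength - r
    out <- data.frame(
      read_id = readIds[acc],
      sample_id = sampleId,
      amplicon_id = a$amplicon_id[ai],
      sequence = substr(sequences[acc], insFrom, insTo),
      qualities = substr(qualities[acc], insFrom, insTo),
      umt5 = substr(sequences[acc], 1L, umtLength),
      umt3 = substr(sequences[acc], li - umtLength + 1L, li),
      primer_trimmed = TRUE,
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(read_id = character(), sample_id = character(),
                      amplicon_id = character(), sequence = character(),
                      qualities = character(), umt5 = character(),
                      umt3 = character(), primer_trimmed = logical())
  }
  rejected <- data.frame(read_id = readIds[!acc], reason = reason[!acc],
                         stringsAsFactors = FALSE)
  list(reads = taggedReads(out, umtLength = umtLength), rejected = rejected)
}

#' Parse a FASTQ file of raw tagged reads
#'
#' Reads a 4-line FASTQ (Phred+33) with \code{Biostrings} and runs
#' \code{\link{parseTaggedReads}} on it.
#'
#' @inheritParams parseTaggedReads
#' @param path FASTQ file path.
#' @return As \code{\link{parseTaggedReads}}.
#' @export
parseFastqFile <- function(path, panel, sampleId = "S1", umtLength = 6L,
                           maxMismatch = 2L) {
  # Biostrings warns about dropping (empty) mcols when re-wrapping the
  # quality-scaled set; nothing of ours is lost
  fq <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  parseTaggedReads(as.character(fq),
                   as.character(Biostrings::quality(fq)),
                   panel, sampleId = sampleId, umtLength = umtLength,
                   maxMismatch = maxMismatch, readIds = names(fq))
}

#' Read / write the pre-tagged TSV read dialect
#'
#' A plain tab-separated representation of parsed reads
#' (\code{read_id, sample_id, amplicon_id, umt5, umt3, sequence, qualities})
#' used to decouple caller tests and workflows from FASTQ parsing.
#'
#' @param path file path.
#' @param umtLength UMT length per end (default 6).
#' @return A \code{\linkS4class{TaggedReads}}.
#' @export
readTaggedReadsTSV <- function(path, umtLength = 6L) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("read_id", "sample_id", "amplicon_id", "umt5", "umt3", "sequence")
  if (!all(need %in% names(tab)))
    .stopf("tagged-read TSV must have columns: %s", paste(need, collapse = ", "))
  if (is.null(tab$qualities)) tab$qualities <- strrep("I", nchar(tab$sequence))
  tab$primer_trimmed <- TRUE
  taggedReads(tab[, c("read_id", "sample_id", "amplicon_id", "sequence",
                      "qualities", "umt5", "umt3", "primer_trimmed")],
              umtLength = umtLength)
}

#' @rdname readTaggedReadsTSV
#' @param reads a \code{TaggedReads} object.
#' @export
writeTaggedReadsTSV <- function(reads, path) {
  r <- readsTable(reads)
  write.table(r[, c("read_id", "sample_id", "amplicon_id", "umt5", "umt3",
                    "sequence", "qualities")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a rejection log
#'
#' @param rejected data.frame with \code{read_id} and \code{reason} (as
#'   returned by \code{\link{parseTaggedReads}}).
#' @param path output TSV path.
#' @export
writeRejectionLog <- function(rejected, path) {
  write.table(rejected, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
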