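## Panel input/output: BED-like amplicon table + hotspot table.

#' Load an amplicon panel and hotspot list from tab-separated files
#'
#' The amplicon table is a BED-like tab-separated file with columns
#' \code{chrom, start, end, amplicon_id, fwd_primer, rev_primer} and
#' optionally \code{pool_id} and \code{ref_insert}; coordinates are 1-based
#' inclusive, declared in a leading \code{# coords=1-based-inclusive} header
#' line. The reference insert sequence of each amplicon can alternatively be
#' supplied through \code{refFasta}, a FASTA file whose record names are
#' amplicon ids.
#'
#' The hotspot table is tab-separated with columns
#' \code{chrom, pos, ref, alt, label}; every hotspot position must fall
#' inside some amplicon insert.
#'
#' @param ampliconFile path to the amplicon table.
#' @param hotspotFile path to the hotspot table, or \code{NULL} for none
#'   (all variants are then treated as non-hotspot).
#' @param refFasta optional FASTA of reference inserts keyed by amplicon id.
#' @return An \code{\linkS4class{AmpliconPanel}}.
#' @seealso \code{\link{writePanelFiles}} for the inverse.
#' @export
loadPanel <- function(ampliconFile, hotspotFile = NULL, refFasta = NULL) {
  if (!file.exists(ampliconFile)) .stopf("amplicon file not found: %s", ampliconFile)
  first <- readLines(ampliconFile, n = 1L)
  if (!grepl("^#", first) || !grepl("1-based-inclusive", first))
    warning("amplicon table has no '# coords=1-based-inclusive' header; assuming 1-based inclusive coordinates")
  tab <- read.delim(ampliconFile, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 6L)
    .stopf("amplicon table must have at least 6 columns (chrom, start, end, amplicon_id, fwd_primer, rev_primer); got %d", ncol(tab))
  amp <- data.frame(
    amplicon_id = as.character(tab[[4L]]),
    chrom = as.character(tab[[1L]]),
    insert_start = as.integer(tab[[2L]]),
    insert_end = as.integer(tab[[3L]]),
    fwd_primer = toupper(as.character(tab[[5L]])),
    rev_primer = toupper(as.character(tab[[6L]])),
    pool_id = if (ncol(tab) >= 7L) as.integer(tab[[7L]]) else 1L,
    ref_insert = if (ncol(tab) >= 8L) toupper(as.character(tab[[8L]])) else NA_character_,
    stringsAsFactors = FALSE)
  if (anyDuplicated(amp$amplicon_id))
    .stopf("duplicate amplicon_id in %s: %s", ampliconFile,
           paste(unique(amp$amplicon_id[duplicated(amp$amplicon_id)]), collapse = ", "))
  if (!is.null(refFasta)) {
    fa <- Biostrings::readDNAStringSet(refFasta)
    miss <- setdiff(amp$amplicon_id, names(fa))
    if (length(miss) > 0L)
      .stopf("reference FASTA lacks insert(s) for amplicon(s): %s", paste(miss, collapse = ", "))
    amp$ref_insert <- as.character(fa[amp$amplicon_id])
  }
  if (anyNA(amp$ref_insert))
    .stopf("no reference insert for amplicon(s): %s (supply an 8th column or refFasta)",
           paste(amp$amplicon_id[is.na(amp$ref_insert)], collapse = ", "))
  hs <- data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), label = character())
  if (!is.null(hotspotFile)) {
    if (!file.exists(hotspotFile)) .stopf("hotspot file not found: %s", hotspotFile)
    htab <- tryCatch(
      read.delim(hotspotFile, header = FALSE, comment.char = "#",
                 stringsAsFactors = FALSE),
      error = function(e) NULL)
    if (!is.null(htab) && nrow(htab) > 0L) {
      if (ncol(htab) < 4L)
        .stopf("hotspot table must have columns chrom, pos, ref, alt[, label]")
      hs <- data.frame(
        chrom = as.character(htab[[1L]]),
        pos = as.integer(htab[[2L]]),
        ref = toupper(as.character(htab[[3L]])),
        alt = toupper(as.character(htab[[4L]])),
        label = if (ncol(htab) >= 5L) as.character(htab[[5L]]) else NA_character_,
        stringsAsFactors = FALSE)
      outside <- !vapply(seq_len(nrow(hs)), function(i) {
        any(amp$chrom == hs$chrom[i] & amp$insert_start <= hs$pos[i] &
              amp$insert_end >= hs$pos[i])
      }, logical(1))
      if (any(outside))
        .stopf("hotspot outside all amplicon inserts (%s row %s): %s:%d",
               hotspotFile, paste(which(outside), collapse = ","),
               hs$chrom[which(outside)[1L]], hs$pos[which(outside)[1L]])
    }
  }
  ampliconPanel(amp, hs)
}

#' Write a panel back to its tab-separated file representation
#'
#' Writes the 8-column amplicon table (with the coordinate-convention header
#' line) and, when hotspots are present, the 5-column hotspot table.
#'
#' @param panel an \code{AmpliconPanel}.
#' @param ampliconFile output path for the amplicon table.
#' @param hotspotFile output path for the hotspot table (optional).
#' @return Invisibly, the panel.
#' @export
writePanelFiles <- function(panel, ampliconFile, hotspotFile = NULL) {
  a <- amplicons(panel)
  out <- data.frame(a$chrom, a$insert_start, a$insert_end, a$amplicon_id,
                    a$fwd_primer, a$rev_primer, a$pool_id, a$ref_insert)
  writeLines("# coords=1-based-inclusive", ampliconFile)
  suppressWarnings(write.table(out, ampliconFile, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE, append = TRUE))
  if (!is.null(hotspotFile)) {
    h <- hotspots(panel)
    write.table(h[, c("chrom", "pos", "ref", "alt", "label")], hotspotFile,
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(panel)
}
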