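## Conventional read-level tumor-normal caller (the non-MB baseline).
## UMTs are ignored entirely, including PCR duplicates, as in conventional
## amplicon analysis.

#' Read-level allele tally
#'
#' Counts, per locus and alternate allele, the number of reads carrying the
#' allele, ignoring molecular tags. Depth is per amplicon (every read covers
#' its whole insert).
#'
#' @param reads a \code{\linkS4class{TaggedReads}} object.
#' @param panel the \code{\linkS4class{AmpliconPanel}}.
#' @return A \code{\linkS4class{RawTally}}.
#' @export
rawTally <- function(reads, panel) {
  r <- as.data.table(readsTable(reads))
  a <- as.data.table(amplicons(panel))
  depths <- merge(a[, .(amplicon_id, chrom, insert_start, insert_end)],
                  if (nrow(r) > 0L) r[, .(read_depth = .N), by = amplicon_id]
                  else data.table(amplicon_id = character(), read_depth = integer()),
                  by = "amplicon_id", all.x = TRUE)
  depths[is.na(read_depth), read_depth := 0L]
  if (nrow(r) == 0L) {
    return(new("RawTally",
               alleles = data.frame(amplicon_id = character(), chrom = character(),
                                    pos = integer(), ref = character(),
                                    alt = character(), variant_class = character(),
                                    alt_reads = integer()),
               depths = as.data.frame(depths)))
  }
  mt <- .memberVariantTables(as.data.frame(r), panel)
  m <- merge(r[, .(read_id, amplicon_id, sequence)], mt$uids,
             by = c("amplicon_id", "sequence"), sort = FALSE)
  mv <- merge(m[, .(read_id, uid)], mt$variants, by = "uid",
              allow.cartesian = TRUE)
  alleles <- if (nrow(mv) > 0L)
    mv[, .(alt_reads = .N),
       by = .(amplicon_id, chrom, pos, ref, alt, variant_class)]
  else data.table(amplicon_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  variant_class = character(), alt_reads = integer())
  setorder(alleles, chrom, pos, alt)
  new("RawTally", alleles = as.data.frame(alleles), depths = as.data.frame(depths))
}

#' @describeIn rawTally Per-allele read counts.
#' @param x a \code{RawTally}.
#' @export
rawAlleles <- function(x) x@alleles

#' @describeIn rawTally Per-amplicon read depths.
#' @export
rawDepths <- function(x) x@depths

.rawDepthAt <- function(tally, ch, p) {
  d <- tally@depths
  sum(d$read_depth[d$chrom == ch & d$insert_start <= p & d$insert_end >= p])
}

#' Conventional read-level tumor-normal variant calling
#'
#' Applies the conventional amplicon filter set to read-level tallies: at
#' least \code{min_alt_reads} (default 10) variant-supporting reads, depth
#' at least \code{min_depth} (default 20), common-SNP position exclusion,
#' and a confident-somatic check against the matched normal (at most
#' \code{normal_max_alt_reads} supporting reads and normal VAF at most
#' \code{normal_max_vaf}). When no normal tally is supplied a call is marked
#' \code{"no_normal"} and cannot PASS. An optional VAF operating floor
#' (\code{min_vaf}) can model the practical detection limit of conventional
#' sequencing.
#'
#' @param tumor a \code{\linkS4class{RawTally}} for the tumor (or plasma)
#'   sample.
#' @param normal a \code{RawTally} for the matched normal, or \code{NULL}.
#' @param config a \code{\linkS4class{NonMBFilterConfig}}.
#' @param vcfPath optional VCF 4.2 output path (INFO keys DP, AO, VAF).
#' @return data.frame of calls with verdict columns, \code{status}
#'   (\code{PASS}/\code{FAIL}/\code{no_normal}) and \code{filter}.
#' @export
callRawVariants <- function(tumor, normal = NULL, config = nonMBFilterConfig(),
                            vcfPath = NULL) {
  al <- as.data.table(tumor@alleles)
  if (nrow(al) == 0L) {
    out <- data.frame()
    if (!is.null(vcfPath)) .writeVcfFile(out, vcfPath, mode = "nonmb")
    return(out)
  }
  al[, read_depth := vapply(seq_len(.N),
                            function(i) .rawDepthAt(tumor, chrom[i], pos[i]),
                            numeric(1))]
  al[, vaf := readLevelVaf(alt_reads, read_depth)]
  if (!is.null(normal)) {
    nal <- as.data.table(normal@alleles)
    al <- merge(al, nal[, .(chrom, pos, ref, alt, normal_alt_reads = alt_reads)],
                by = c("chrom", "pos", "ref", "alt"), all.x = TRUE)
    al[is.na(normal_alt_reads), normal_alt_reads := 0L]
    al[, normal_depth := vapply(seq_len(.N),
                                function(i) .rawDepthAt(normal, chrom[i], pos[i]),
                                numeric(1))]
  } else {
    al[, `:=`(normal_alt_reads = NA_integer_, normal_depth = NA_integer_)]
  }
  al[, flt_min_alt_reads := alt_reads >= config@min_alt_reads]
  al[, flt_min_depth := read_depth >= config@min_depth]
  al[, flt_common_snp := !(paste0(chrom, ":", pos) %in% config@common_snp_positions)]
  al[, flt_confident_somatic := !is.na(normal_alt_reads) &
       normal_alt_reads <= config@normal_max_alt_reads &
       (normal_depth == 0L |
          normal_alt_reads / pmax(normal_depth, 1L) <= config@normal_max_vaf)]
  al[, flt_min_vaf := vaf >= config@min_vaf]
  fltCols <- c("flt_min_alt_reads", "flt_min_depth", "flt_common_snp",
               "flt_confident_somatic", "flt_min_vaf")
  verdicts <- as.matrix(al[, fltCols, with = FALSE])
  al[, status := ifelse(is.na(normal_alt_reads), "no_normal",
                        ifelse(rowSums(!verdicts) == 0L, "PASS", "FAIL"))]
  firstFail <- apply(verdicts, 1L, function(v) {
    w <- which(!v)
    if (length(w) == 0L) "PASS" else sub("^flt_", "", fltCols[w[1L]])
  })
  al[, filter := ifelse(status == "no_normal", "no_normal", firstFail)]
  al[, vaf_percent := formatVafPercent(vaf)]
  out <- as.data.frame(al[order(chrom, pos, alt)])
  rownames(out) <- NULL
  if (!is.null(vcfPath)) .writeVcfFile(out, vcfPath, mode = "nonmb")
  out
}
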