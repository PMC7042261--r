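## Molecular-barcode variant caller: functional-family tallies, molecular
## VAF, binomial background-error p-value, and the MB filter cascade.

#' Tally functional-family allele support per locus
#'
#' Counts, per genomic locus and alternate allele, the number of functional
#' families whose unanimous consensus carries the allele. Families that are
#' ambiguous at a position (members disagree) contribute molecular depth but
#' support no allele. \code{family_depth} is the number of functional
#' families covering the position; \code{read_depth} the number of reads.
#'
#' @param families a \code{\linkS4class{MolecularFamilies}} object.
#' @param loci optional data.frame (\code{chrom}, \code{pos}, and optionally
#'   \code{ref}, \code{alt}) forcing rows for these loci even without any
#'   supporting family (counts 0) -- used e.g. for rescue reporting at
#'   tumor-mutated loci.
#' @return A \code{data.frame}, one row per (locus, alternate allele):
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{variant_class},
#'   \code{amplicon_id}, \code{alt_families}, \code{min_supp_family_size},
#'   \code{family_depth}, \code{ambiguous_families}, \code{ref_families},
#'   \code{read_depth}.
#' @export
tallyLoci <- function(families, loci = NULL) {
  fam <- as.data.table(familyStats(families))
  useable <- fam[functional == TRUE & consensus_failed == FALSE]
  a <- as.data.table(amplicons(families@panel))
  members <- as.data.table(families@members)

  depthByAmp <- useable[, .(family_depth = .N), by = amplicon_id]
  readsByAmp <- members[, .(read_depth = .N), by = amplicon_id]

  sup <- as.data.table(familySupports(families))
  sup <- sup[family_id %in% useable$family_id]
  sup <- merge(sup, fam[, .(family_id, size)], by = "family_id")
  tal <- if (nrow(sup) > 0L)
    sup[, .(alt_families = .N, min_supp_family_size = min(size)),
        by = .(chrom, pos, ref, alt, variant_class, amplicon_id)]
  else
    data.table(chrom = character(), pos = integer(), ref = character(),
               alt = character(), variant_class = character(),
               amplicon_id = character(), alt_families = integer(),
               min_supp_family_size = integer())

  if (!is.null(loci)) {
    loci <- as.data.table(as.data.frame(loci))
    if (is.null(loci$ref)) loci[, ref := NA_character_]
    if (is.null(loci$alt)) loci[, alt := NA_character_]
    covering <- function(ch, p) {
      hit <- a[chrom == ch & insert_start <= p & insert_end >= p]
      if (nrow(hit) > 0L) hit$amplicon_id[1L] else NA_character_
    }
    extra <- loci[, .(chrom, pos = as.integer(pos), ref, alt)]
    extra[, amplicon_id := mapply(covering, chrom, pos)]
    if (anyNA(extra$amplicon_id))
      .stopf("locus outside all amplicon inserts: %s:%d",
             extra$chrom[is.na(extra$amplicon_id)][1L],
             extra$pos[is.na(extra$amplicon_id)][1L])
    # fill reference base where not given
    noRef <- which(is.na(extra$ref))
    for (i in noRef) {
      ai <- a[amplicon_id == extra$amplicon_id[i]]
      extra$ref[i] <- substr(ai$ref_insert, extra$pos[i] - ai$insert_start + 1L,
                             extra$pos[i] - ai$insert_start + 1L)
    }
    extra[, variant_class := ifelse(is.na(alt), "SNV", .alleleClass(ref, alt))]
    have <- tal[, paste(chrom, pos, ref, alt)]
    extra <- extra[!paste(chrom, pos, ref, alt) %in% have]
    if (nrow(extra) > 0L) {
      extra[, `:=`(alt_families = 0L, min_supp_family_size = NA_integer_)]
      tal <- rbind(tal, extra, use.names = TRUE)
    }
  }

  if (nrow(tal) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), variant_class = character(),
                      amplicon_id = character(), alt_families = integer(),
                      min_supp_family_size = integer(), family_depth = integer(),
                      ambiguous_families = integer(), ref_families = integer(),
                      read_depth = integer())
    return(out)
  }

  tal <- merge(tal, depthByAmp, by = "amplicon_id", all.x = TRUE)
  tal[is.na(family_depth), family_depth := 0L]
  tal <- merge(tal, readsByAmp, by = "amplicon_id", all.x = TRUE)
  tal[is.na(read_depth), read_depth := 0L]

  amb <- as.data.table(familyAmbiguities(families))
  amb <- amb[family_id %in% useable$family_id]
  ambByPos <- if (nrow(amb) > 0L)
    amb[, .(ambiguous_families = length(unique(family_id))), by = .(chrom, pos)]
  else data.table(chrom = character(), pos = integer(),
                  ambiguous_families = integer())
  tal <- merge(tal, ambByPos, by = c("chrom", "pos"), all.x = TRUE)
  tal[is.na(ambiguous_families), ambiguous_families := 0L]

  totAlt <- tal[, .(tot_alt = sum(alt_families)), by = .(chrom, pos)]
  tal <- merge(tal, totAlt, by = c("chrom", "pos"))
  tal[, ref_families := pmax(0L, family_depth - ambiguous_families - tot_alt)]
  tal[, tot_alt := NULL]
  setorder(tal, chrom, pos, alt)
  as.data.frame(tal[, .(chrom, pos, ref, alt, variant_class, amplicon_id,
                        alt_families, min_supp_family_size, family_depth,
                        ambiguous_families, ref_families, read_depth)])
}

#' Molecular variant allele fraction
#'
#' \code{altCount / depth}, the fraction of functional families (molecules)
#' supporting an alternate allele; by convention 0 when depth is 0, flagged
#' in the \code{"no_coverage"} attribute. Vectorised.
#'
#' @param altCount supporting molecule count(s).
#' @param depth functional-family depth(s).
#' @return Numeric fraction(s); attribute \code{"no_coverage"} marks
#'   zero-depth entries.
#' @examples
#' molecularVaf(9, 249780)    # 3.6e-05, printed as 0.0036%
#' formatVafPercent(molecularVaf(2145, 236446))  # "0.91"
#' @export
molecularVaf <- function(altCount, depth) {
  if (any(depth < 0)) .stopf("depth must be >= 0")
  if (any(altCount < 0) || any(altCount > depth))
    .stopf("altCount must satisfy 0 <= altCount <= depth")
  v <- ifelse(depth == 0, 0, altCount / depth)
  if (any(depth == 0)) attr(v, "no_coverage") <- depth == 0
  v
}

#' Read-level variant allele fraction
#'
#' Same arithmetic as \code{\link{molecularVaf}} but on raw read counts
#' (conventional calling).
#'
#' @inheritParams molecularVaf
#' @export
readLevelVaf <- function(altCount, depth) molecularVaf(altCount, depth)

#' Render a VAF fraction as a percentage at reporting precision
#'
#' Two decimal places for percentages of at least 0.01, two significant
#' figures below that (so 9/249,780 renders as \code{"0.0036"}, and
#' 6/9,859 as \code{"0.06"}).
#'
#' @param frac VAF fraction(s) in [0,1].
#' @return Character vector of percentages (without the \% sign).
#' @export
formatVafPercent <- function(frac) {
  pct <- 100 * as.numeric(frac)
  out <- character(length(pct))
  big <- pct >= 0.01
  out[big] <- sprintf("%.2f", pct[big])
  out[!big] <- format(signif(pct[!big], 2), trim = TRUE, scientific = FALSE)
  out[pct == 0] <- "0.00"
  out
}

#' Background-error p-value (exact binomial tail)
#'
#' One-sided exact binomial tail probability
#' \eqn{P(X \ge altCount)} for \eqn{X \sim Binomial(depth, errorRate)}:
#' the probability of seeing at least the observed number of supporting
#' molecules by background error alone. Monotone non-increasing in
#' \code{altCount} at fixed depth; 1 when depth is 0 (or altCount 0).
#' Vectorised.
#'
#' @param altCount observed supporting molecule count(s).
#' @param depth functional-family depth(s).
#' @param errorRate per-molecule per-allele background error rate in (0,1).
#' @return p-value(s) in [0,1].
#' @examples
#' backgroundPvalue(0, 1000, 1e-4)  # 1
#' backgroundPvalue(5, 5, 0.01)     # 0.01^5
#' @export
backgroundPvalue <- function(altCount, depth, errorRate) {
  if (any(errorRate <= 0) || any(errorRate >= 1))
    .stopf("errorRate must be in (0,1)")
  if (any(altCount < 0) || any(altCount > depth))
    .stopf("altCount must satisfy 0 <= altCount <= depth")
  p <- ifelse(depth == 0, 1,
              pbinom(altCount - 1, size = depth, prob = errorRate,
                     lower.tail = FALSE))
  pmin(pmax(p, 0), 1)
}

# Per-class background error rate lookup: scalar rate applies to all
# classes; a named vector is indexed by SNV/INS/DEL.
.classErrorRate <- function(cls, rate) {
  if (length(rate) == 1L && is.null(names(rate))) return(rep(rate, length(cls)))
  out <- unname(rate[cls])
  out[is.na(out)] <- unname(rate[1L])
  out
}

#' Apply the MB filter cascade to draft calls
#'
#' Evaluates, in order, (1) the class-specific supporting-family minimum
#' (SNV and hotspot 2, INDEL 6); (2) alternate allele count of at least 2;
#' (3) common-SNP position exclusion; (4) background p-value below 0.02;
#' (5) for INDELs, molecular VAF of at least 0.002 and more than 3
#' supporting molecules; (6) for non-hotspot variants, more than 3
#' supporting molecules; (7) for homopolymer-context INDELs, every
#' supporting family at least the functional size; (8) in tumor context
#' only, molecular VAF of at least 0.005. Every verdict is evaluated and
#' recorded (columns \code{flt_*}); \code{status} is \code{"PASS"} iff all
#' applicable verdicts pass, and \code{filter} names the first failed rule.
#'
#' @param draft data.frame of draft calls with columns \code{chrom},
#'   \code{pos}, \code{variant_class}, \code{hotspot}, \code{homopolymer},
#'   \code{alt_families}, \code{family_depth}, \code{vaf}, \code{p_value},
#'   \code{min_supp_family_size}.
#' @param config an \code{\linkS4class{MBFilterConfig}}.
#' @param context \code{"plasma"} or \code{"tumor"}; the VAF cutoff of
#'   0.005 applies in tumor context only.
#' @return The draft with verdict columns, \code{status} and \code{filter}
#'   appended.
#' @export
applyMBFilters <- function(draft, config = mbFilterConfig(),
                           context = c("plasma", "tumor")) {
  context <- match.arg(context)
  d <- as.data.table(as.data.frame(draft))
  if (nrow(d) > 0L && !all(d$variant_class %in% c("SNV", "INS", "DEL")))
    .stopf("unknown variant class: %s",
           paste(setdiff(unique(d$variant_class), c("SNV", "INS", "DEL")),
                 collapse = ", "))
  isIndel <- d$variant_class %in% c("INS", "DEL")
  minFam <- ifelse(isIndel, config@min_indel_supporting_families,
                   ifelse(d$hotspot, config@min_hotspot_supporting_families,
                          config@min_snp_supporting_families))
  d[, flt_supporting_families := alt_families >= minFam]
  d[, flt_alt_allele_count := alt_families >= config@min_alt_allele_count]
  d[, flt_common_snp := !(paste0(chrom, ":", pos) %in% config@common_snp_positions)]
  d[, flt_p_value := p_value < config@max_p_value]
  d[, flt_indel_evidence := !isIndel |
      (vaf >= config@min_indel_vaf & alt_families >= config@min_indel_alt_count)]
  d[, flt_nonhotspot_alt_count := hotspot |
      alt_families >= config@min_nonhotspot_alt_count]
  d[, flt_homopolymer_family_size := !(isIndel & d$homopolymer) |
      (!is.na(min_supp_family_size) &
         min_supp_family_size >= config@homopolymer_indel_family_size)]
  d[, flt_tumor_vaf := context != "tumor" | vaf >= config@tumor_vaf_cutoff]
  fltCols <- c("flt_supporting_families", "flt_alt_allele_count",
               "flt_common_snp", "flt_p_value", "flt_indel_evidence",
               "flt_nonhotspot_alt_count", "flt_homopolymer_family_size",
               "flt_tumor_vaf")
  verdicts <- as.matrix(d[, fltCols, with = FALSE])
  d[, status := ifelse(rowSums(!verdicts) == 0L, "PASS", "FAIL")]
  firstFail <- apply(verdicts, 1L, function(v) {
    w <- which(!v)
    if (length(w) == 0L) "PASS" else sub("^flt_", "", fltCols[w[1L]])
  })
  d[, filter := if (nrow(d) > 0L) firstFail else character(0)]
  as.data.frame(d)
}

#' Call variants from molecular families
#'
#' End-to-end molecular-barcode calling: tallies functional-family support
#' per locus, computes molecular VAF and the binomial background-error
#' p-value, annotates hotspot membership and homopolymer context, and
#' applies the MB filter cascade. One call row is produced for every
#' (locus, alternate allele) with at least one supporting functional
#' family; output order is (chrom, pos, alt).
#'
#' @param families a \code{\linkS4class{MolecularFamilies}} object.
#' @param config an \code{\linkS4class{MBFilterConfig}}.
#' @param context \code{"plasma"} or \code{"tumor"}.
#' @param restrictTo optional data.frame (\code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}): keep only calls at these loci (e.g. plasma
#'   calling restricted to the loci mutated in the paired tumor).
#' @param vcfPath optional path: write the calls as VCF 4.2 with INFO keys
#'   FDP (functional family depth), FAO (alt family count), MVAF
#'   (molecular VAF), PV (p-value), HS (hotspot flag).
#' @return data.frame of calls with tallies, \code{vaf}, \code{vaf_percent},
#'   \code{p_value}, verdicts, \code{status} and \code{filter}.
#' @export
callVariants <- function(families, config = mbFilterConfig(),
                         context = c("plasma", "tumor"), restrictTo = NULL,
                         vcfPath = NULL) {
  context <- match.arg(context)
  tal <- as.data.table(tallyLoci(families))
  tal <- tal[alt_families >= 1L]
  if (!is.null(restrictTo)) {
    rt <- as.data.frame(restrictTo)
    keys <- paste(rt$chrom, rt$pos, rt$ref, rt$alt)
    tal <- tal[paste(chrom, pos, ref, alt) %in% keys]
  }
  if (nrow(tal) == 0L) {
    out <- data.frame()
    if (!is.null(vcfPath)) .writeVcfFile(out, vcfPath, mode = "mb",
                                         sample = .sampleOf(families))
    return(out)
  }
  hs <- hotspots(families@panel)
  tal[, hotspot := paste(chrom, pos, ref, alt) %in%
        paste(hs$chrom, hs$pos, hs$ref, hs$alt)]
  a <- amplicons(families@panel)
  tal[, homopolymer := vapply(seq_len(.N), function(i) {
    if (!variant_class[i] %in% c("INS", "DEL")) return(FALSE)
    ai <- match(amplicon_id[i], a$amplicon_id)
    from <- pos[i] - a$insert_start[ai] + 1L
    .homopolymerContext(a$ref_insert[ai], from, from + nchar(ref[i]) - 1L,
                        config@homopolymer_min_run)
  }, logical(1))]
  tal[, vaf := molecularVaf(alt_families, family_depth)]
  tal[, p_value := backgroundPvalue(
    alt_families, family_depth,
    .classErrorRate(variant_class, config@background_error_rate))]
  out <- applyMBFilters(as.data.frame(tal), config, context)
  out$vaf_percent <- formatVafPercent(out$vaf)
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(vcfPath))
    .writeVcfFile(out, vcfPath, mode = "mb", sample = .sampleOf(families))
  out
}

.sampleOf <- function(families) {
  s <- unique(familyStats(families)$sample_id)
  if (length(s) == 0L) "SAMPLE" else s[1L]
}

#' Rescue report: sub-threshold tallies at given loci
#'
#' Reports the molecular tally (supporting families, depth, VAF) at a
#' supplied list of loci regardless of filter outcomes -- mirroring the
#' manual review step in which known tumor-mutated loci are inspected in
#' plasma even when the automatic cascade does not call them.
#'
#' @param families a \code{\linkS4class{MolecularFamilies}} object.
#' @param loci data.frame with \code{chrom}, \code{pos} and optionally
#'   \code{ref}, \code{alt} (e.g. the tumor call set).
#' @return data.frame of tallies with \code{vaf} and \code{vaf_percent}.
#' @export
rescueReport <- function(families, loci) {
  tal <- tallyLoci(families, loci = loci)
  keys <- paste(loci$chrom, loci$pos)
  tal <- tal[paste(tal$chrom, tal$pos) %in% keys, , drop = FALSE]
  tal$vaf <- molecularVaf(tal$alt_families, tal$family_depth)
  tal$vaf_percent <- formatVafPercent(tal$vaf)
  rownames(tal) <- NULL
  tal
}

## --------------------------------------------------------------------------
## VCF output (plain VCF 4.2 text; round-trips through standard VCF readers)
## --------------------------------------------------------------------------

.writeVcfFile <- function(calls, path, mode = c("mb", "nonmb"), sample = "SAMPLE") {
  mode <- match.arg(mode)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=MBAmplicon(%s)", mode))
  if (mode == "mb") {
    hdr <- c(hdr,
      '##INFO=<ID=FDP,Number=1,Type=Integer,Description="Functional family depth">',
      '##INFO=<ID=FAO,Number=1,Type=Integer,Description="Alternate allele functional family count">',
      '##INFO=<ID=MVAF,Number=1,Type=Float,Description="Molecular variant allele fraction">',
      '##INFO=<ID=PV,Number=1,Type=Float,Description="Binomial background error p-value">',
      '##INFO=<ID=HS,Number=0,Type=Flag,Description="Hotspot variant">')
  } else {
    hdr <- c(hdr,
      '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
      '##INFO=<ID=AO,Number=1,Type=Integer,Description="Alternate allele read count">',
      '##INFO=<ID=VAF,Number=1,Type=Float,Description="Read-level variant allele fraction">')
  }
  hdr <- c(hdr, paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                    "FILTER", "INFO"), collapse = "\t")))
  lines <- hdr
  if (nrow(calls) > 0L) {
    info <- if (mode == "mb") {
      paste0("FDP=", calls$family_depth, ";FAO=", calls$alt_families,
             ";MVAF=", signif(calls$vaf, 6), ";PV=", signif(calls$p_value, 6),
             ifelse(calls$hotspot, ";HS", ""))
    } else {
      paste0("DP=", calls$read_depth, ";AO=", calls$alt_reads,
             ";VAF=", signif(calls$vaf, 6))
    }
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  calls$filter, info, sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}
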