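#' @import methods
#' @import data.table
#' @importFrom stats pbinom rbinom rpois runif cor setNames
#' @importFrom utils head read.delim write.table
NULL

# data.table NSE variables used throughout; silences R CMD check notes
utils::globalVariables(c(
  ".", ".N", ".SD", "alt", "alt_families", "alt_reads", "ambiguous_families",
  "amplicon_id", "chrom", "class_", "consensus_failed", "family_depth",
  "family_id", "functional", "hotspot", "insert_end", "insert_start",
  "min_supp_family_size", "n_members", "nN", "normal_alt_reads",
  "normal_depth", "nsupp", "p_value", "pos", "read_depth", "ref", "rid",
  "sample_id", "size", "status", "uid", "umt3", "umt5", "unanimous", "vaf",
  "variant_class", "J", "mol_id", "n_seq_errors", "key_", "absorber",
  "read_id", "label", "vaf_percent", "tot_alt", "source_label",
  "flt_supporting_families", "flt_alt_allele_count", "flt_common_snp",
  "flt_p_value", "flt_indel_evidence", "flt_nonhotspot_alt_count",
  "flt_homopolymer_family_size", "flt_tumor_vaf", "flt_min_alt_reads",
  "flt_min_depth", "flt_confident_somatic", "flt_min_vaf", "filter"
))

## ---------------------------------------------------------------------------
## AmpliconPanel
## ---------------------------------------------------------------------------

#' Amplicon panel with hotspot list
#'
#' An \code{AmpliconPanel} bundles the amplicon definitions of a targeted
#' panel (one row per amplicon: genomic insert coordinates, the forward and
#' reverse primer sequences and the primer pool) together with a list of
#' hotspot variants that are granted the lower hotspot evidence threshold by
#' the molecular-barcode caller. Coordinates are 1-based inclusive.
#'
#' The \code{ref_insert} column carries the reference sequence of the
#' inter-primer insert; it is what simulated reads are generated from and
#' what observed reads are compared against when per-position alleles are
#' derived.
#'
#' @slot amplicons \code{data.frame} with columns \code{amplicon_id},
#'   \code{chrom}, \code{insert_start}, \code{insert_end}, \code{fwd_primer},
#'   \code{rev_primer}, \code{pool_id}, \code{ref_insert}.
#' @slot hotspots \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{label}; may have zero rows.
#'
#' @export
setClass("AmpliconPanel",
  representation(amplicons = "data.frame", hotspots = "data.frame"))

setValidity("AmpliconPanel", function(object) {
  a <- object@amplicons
  h <- object@hotspots
  need <- c("amplicon_id", "chrom", "insert_start", "insert_end",
            "fwd_primer", "rev_primer", "pool_id", "ref_insert")
  if (!all(need %in% names(a)))
    return(paste("amplicons must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(a$amplicon_id))
    return("duplicate amplicon_id in panel")
  if (any(a$insert_start > a$insert_end))
    return("insert_start must be <= insert_end")
  if (any(nchar(a$fwd_primer) == 0L) || any(nchar(a$rev_primer) == 0L))
    return("primers must be non-empty")
  if (any(grepl("[^ACGT]", c(a$fwd_primer, a$rev_primer))))
    return("primer alphabet must be {A,C,G,T}")
  if (any(nchar(a$ref_insert) != a$insert_end - a$insert_start + 1L))
    return("ref_insert length must equal insert_end - insert_start + 1")
  needH <- c("chrom", "pos", "ref", "alt", "label")
  if (!all(needH %in% names(h)))
    return(paste("hotspots must have columns:", paste(needH, collapse = ", ")))
  if (nrow(h) > 0L) {
    inside <- vapply(seq_len(nrow(h)), function(i) {
      any(a$chrom == h$chrom[i] & a$insert_start <= h$pos[i] & a$insert_end >= h$pos[i])
    }, logical(1))
    if (!all(inside))
      return(paste0("hotspot outside all amplicon inserts at row(s): ",
                    paste(which(!inside), collapse = ", ")))
  }
  TRUE
})

#' Construct an AmpliconPanel
#'
#' @param amplicons data.frame of amplicon definitions (see
#'   \code{\linkS4class{AmpliconPanel}}).
#' @param hotspots data.frame of hotspot variants; defaults to none.
#' @return An \code{AmpliconPanel}.
#' @export
ampliconPanel <- function(amplicons,
                          hotspots = data.frame(chrom = character(), pos = integer(),
                                                ref = character(), alt = character(),
                                                label = character())) {
  amplicons <- as.data.frame(amplicons)
  hotspots <- as.data.frame(hotspots)
  new("AmpliconPanel", amplicons = amplicons, hotspots = hotspots)
}

#' @describeIn ampliconPanel Amplicon definition table.
#' @param panel an \code{AmpliconPanel}.
#' @export
amplicons <- function(panel) panel@amplicons

#' @describeIn ampliconPanel Hotspot variant table.
#' @export
hotspots <- function(panel) panel@hotspots

setMethod("show", "AmpliconPanel", function(object) {
  cat(sprintf("AmpliconPanel: %d amplicon(s), %d hotspot(s)\n",
              nrow(object@amplicons), nrow(object@hotspots)))
  cat(sprintf("  chrom(s): %s\n",
              paste(unique(object@amplicons$chrom), collapse = ", ")))
  cat(sprintf("  insert lengths: %s bp\n",
              paste(range(nchar(object@amplicons$ref_insert)), collapse = "-")))
})

## ---------------------------------------------------------------------------
## TaggedReads
## ---------------------------------------------------------------------------

#' Tagged amplicon reads
#'
#' Container for reads that have been structurally parsed: both unique
#' molecular tags (UMTs) excised, primers trimmed and an amplicon assigned.
#' One row per read.
#'
#' @slot reads \code{data.frame} with columns \code{read_id}, \code{sample_id},
#'   \code{amplicon_id}, \code{sequence} (insert, alphabet A/C/G/T/N),
#'   \code{qualities} (Phred+33 string, same length as sequence),
#'   \code{umt5}, \code{umt3}, \code{primer_trimmed}.
#' @slot umtLength integer, the configured UMT length per end.
#' @export
setClass("TaggedReads",
  representation(reads = "data.frame", umtLength = "integer"))

setValidity("TaggedReads", function(object) {
  r <- object@reads
  need <- c("read_id", "sample_id", "amplicon_id", "sequence", "qualities",
            "umt5", "umt3", "primer_trimmed")
  if (!all(need %in% names(r)))
    return(paste("reads must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) > 0L) {
    if (any(nchar(r$sequence) != nchar(r$qualities)))
      return("sequence and qualities must have equal lengths")
    u <- object@umtLength
    if (any(nchar(r$umt5) != u) || any(nchar(r$umt3) != u))
      return(sprintf("UMT lengths must all equal the configured length (%d)", u))
    if (any(grepl("[^ACGTN]", r$sequence)))
      return("read sequence alphabet must be {A,C,G,T,N}")
  }
  TRUE
})

#' Construct a TaggedReads object
#'
#' @param reads data.frame of parsed reads (see \code{\linkS4class{TaggedReads}}).
#' @param umtLength UMT length per end (default 6).
#' @return A \code{TaggedReads} object.
#' @export
taggedReads <- function(reads, umtLength = 6L) {
  new("TaggedReads", reads = as.data.frame(reads), umtLength = as.integer(umtLength))
}

#' @describeIn taggedReads The underlying read table.
#' @param x a \code{TaggedReads} object.
#' @export
readsTable <- function(x) x@reads

#' @describeIn taggedReads Configured UMT length.
#' @export
umtLength <- function(x) x@umtLength

setMethod("show", "TaggedReads", function(object) {
  r <- object@reads
  cat(sprintf("TaggedReads: %d read(s), UMT length %d\n", nrow(r), object@umtLength))
  if (nrow(r) > 0L)
    cat(sprintf("  samples: %s; amplicons: %d\n",
                paste(unique(r$sample_id), collapse = ", "),
                length(unique(r$amplicon_id))))
})

setMethod("length", "TaggedReads", function(x) nrow(x@reads))

## ---------------------------------------------------------------------------
## MolecularFamilies
## ---------------------------------------------------------------------------

#' Molecular families with unanimous consensus
#'
#' Result of clustering tagged reads by the family key
#' (sample, amplicon, 5' UMT, 3' UMT) and computing the per-position
#' unanimous consensus within each family. A family supports an alternate
#' allele only when every member read carries the identical allele; positions
#' where members disagree are ambiguous, contributing molecular depth but
#' supporting no allele.
#'
#' @slot families per-family statistics: \code{family_id}, \code{sample_id},
#'   \code{amplicon_id}, \code{umt5}, \code{umt3}, \code{size},
#'   \code{functional}, \code{consensus_failed}.
#' @slot members per-read family assignment (\code{read_id}, \code{family_id},
#'   plus the read fields needed to recompute consensus after merging).
#' @slot supports unanimously supported non-reference alleles, one row per
#'   (family, variant): \code{family_id}, \code{amplicon_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{variant_class}.
#' @slot ambiguities positions at which a family is not unanimous:
#'   \code{family_id}, \code{amplicon_id}, \code{chrom}, \code{pos}.
#' @slot minFamilySize minimum member count for a functional family.
#' @slot panel the \code{AmpliconPanel} the reads were assigned against.
#' @export
setClass("MolecularFamilies",
  representation(families = "data.frame", members = "data.frame",
                 supports = "data.frame", ambiguities = "data.frame",
                 minFamilySize = "integer", panel = "AmpliconPanel"))

setValidity("MolecularFamilies", function(object) {
  f <- object@families
  if (nrow(f) > 0L && any(f$size < 1L)) return("family size must be >= 1")
  if (nrow(f) > 0L && !identical(f$functional, f$size >= object@minFamilySize))
    return("functional flag inconsistent with minFamilySize")
  if (nrow(object@members) > 0L && sum(f$size) != nrow(object@members))
    return("sum of family sizes must equal number of member reads")
  TRUE
})

#' @describeIn buildFamilies Per-family statistics table.
#' @param x a \code{MolecularFamilies} object.
#' @export
familyStats <- function(x) x@families

#' @describeIn buildFamilies Unanimously supported alleles, one row per
#'   (family, variant).
#' @export
familySupports <- function(x) x@supports

#' @describeIn buildFamilies Ambiguous (non-unanimous) positions per family.
#' @export
familyAmbiguities <- function(x) x@ambiguities

setMethod("show", "MolecularFamilies", function(object) {
  f <- object@families
  cat(sprintf("MolecularFamilies: %d families from %d reads (min size %d)\n",
              nrow(f), sum(f$size), object@minFamilySize))
  if (nrow(f) > 0L)
    cat(sprintf("  functional: %d (%.1f%%); median size %d\n",
                sum(f$functional), 100 * mean(f$functional),
                as.integer(stats::median(f$size))))
})

setMethod("length", "MolecularFamilies", function(x) nrow(x@families))

## ---------------------------------------------------------------------------
## Filter configurations
## ---------------------------------------------------------------------------

#' Molecular-barcode caller filter configuration
#'
#' Thresholds of the molecular-barcode (MB) filter cascade. Defaults follow
#' the published amplicon dual-UMT workflow settings: functional families
#' require at least 2 member reads; SNV and hotspot variants require at least
#' 2 supporting functional families while insertions/deletions require 6;
#' alternate allele (molecule) count must be at least 2; the binomial
#' background-error p-value must be below 0.02; INDELs with molecular VAF
#' below 0.002 or at most 3 supporting molecules are excluded, as are
#' non-hotspot variants with at most 3 supporting molecules; in tumor context
#' a molecular VAF of at least 0.005 is additionally required.
#'
#' @slot min_family_size minimum reads per functional family (default 2).
#' @slot min_snp_supporting_families minimum supporting functional families
#'   for an SNV (default 2).
#' @slot min_hotspot_supporting_families same, for hotspot variants (default 2).
#' @slot min_indel_supporting_families same, for insertions/deletions
#'   (default 6).
#' @slot homopolymer_indel_family_size minimum size of every supporting
#'   family for a homopolymer-context INDEL (default 2).
#' @slot min_alt_allele_count minimum alternate molecule count (default 2).
#' @slot max_p_value background-error p-value threshold (default 0.02,
#'   strict \code{<}).
#' @slot min_indel_vaf minimum molecular VAF for INDELs (default 0.002).
#' @slot min_indel_alt_count minimum alternate molecule count for INDELs
#'   (default 4, i.e. counts of 3 or fewer are excluded).
#' @slot min_nonhotspot_alt_count minimum alternate molecule count for
#'   non-hotspot variants (default 4).
#' @slot tumor_vaf_cutoff molecular VAF cutoff applied in tumor context only
#'   (default 0.005).
#' @slot background_error_rate per-family per-allele background error rate
#'   for the binomial tail test; either a single rate or a named vector with
#'   elements \code{SNV}, \code{INS}, \code{DEL} (default 1e-4).
#' @slot common_snp_positions character vector of \code{"chrom:pos"} keys to
#'   exclude (the common-SNP filter); default empty.
#' @slot homopolymer_min_run minimum reference run length defining
#'   homopolymer context (default 4).
#' @export
setClass("MBFilterConfig",
  representation(
    min_family_size = "integer",
    min_snp_supporting_families = "integer",
    min_hotspot_supporting_families = "integer",
    min_indel_supporting_families = "integer",
    homopolymer_indel_family_size = "integer",
    min_alt_allele_count = "integer",
    max_p_value = "numeric",
    min_indel_vaf = "numeric",
    min_indel_alt_count = "integer",
    min_nonhotspot_alt_count = "integer",
    tumor_vaf_cutoff = "numeric",
    background_error_rate = "numeric",
    common_snp_positions = "character",
    homopolymer_min_run = "integer"),
  prototype(
    min_family_size = 2L,
    min_snp_supporting_families = 2L,
    min_hotspot_supporting_families = 2L,
    min_indel_supporting_families = 6L,
    homopolymer_indel_family_size = 2L,
    min_alt_allele_count = 2L,
    max_p_value = 0.02,
    min_indel_vaf = 0.002,
    min_indel_alt_count = 4L,
    min_nonhotspot_alt_count = 4L,
    tumor_vaf_cutoff = 0.005,
    background_error_rate = 1e-4,
    common_snp_positions = character(0),
    homopolymer_min_run = 4L))

setValidity("MBFilterConfig", function(object) {
  if (object@max_p_value <= 0 || object@max_p_value >= 1)
    return("max_p_value must be in (0,1)")
  if (any(object@background_error_rate <= 0) || any(object@background_error_rate >= 1))
    return("background_error_rate must be in (0,1)")
  thr <- c(object@min_family_size, object@min_snp_supporting_families,
           object@min_hotspot_supporting_families, object@min_indel_supporting_families,
           object@min_alt_allele_count, object@min_indel_alt_count,
           object@min_nonhotspot_alt_count, object@homopolymer_min_run)
  if (any(thr < 0L)) return("all thresholds must be >= 0")
  TRUE
})

#' Create an MB filter configuration
#'
#' @param ... named slot overrides; see \code{\linkS4class{MBFilterConfig}}
#'   for the available thresholds and their defaults.
#' @return An \code{MBFilterConfig}.
#' @examples
#' cfg <- mbFilterConfig(max_p_value = 0.01)
#' @export
mbFilterConfig <- function(...) {
  args <- list(...)
  intSlots <- c("min_family_size", "min_snp_supporting_families",
                "min_hotspot_supporting_families", "min_indel_supporting_families",
                "homopolymer_indel_family_size", "min_alt_allele_count",
                "min_indel_alt_count", "min_nonhotspot_alt_count",
                "homopolymer_min_run")
  for (s in intersect(names(args), intSlots)) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list(Class = "MBFilterConfig"), args))
}

setMethod("show", "MBFilterConfig", function(object) {
  cat("MBFilterConfig\n")
  for (s in slotNames(object))
    cat(sprintf("  %s: %s\n", s, paste(format(slot(object, s)), collapse = ",")))
})

#' Conventional (non-MB) caller filter configuration
#'
#' Read-level tumor-normal filters of the conventional amplicon pipeline:
#' at least 10 variant-supporting reads, coverage depth at least 20,
#' exclusion of common-SNP positions, and a confident-somatic requirement on
#' the matched normal (at most \code{normal_max_alt_reads} supporting reads
#' and normal VAF at most \code{normal_max_vaf}). \code{min_vaf} is an
#' optional operating floor on the tumor/plasma VAF (default 0, i.e. off);
#' a 0.05 floor reproduces the practical detection limit of conventional
#' amplicon sequencing in plasma.
#'
#' @slot min_alt_reads minimum variant-supporting reads (default 10).
#' @slot min_depth minimum read depth (default 20).
#' @slot common_snp_positions \code{"chrom:pos"} exclusion keys.
#' @slot normal_max_alt_reads maximum supporting reads allowed in the normal
#'   (default 1).
#' @slot normal_max_vaf maximum normal VAF (default 0.02).
#' @slot min_vaf VAF operating floor (default 0).
#' @export
setClass("NonMBFilterConfig",
  representation(
    min_alt_reads = "integer",
    min_depth = "integer",
    common_snp_positions = "character",
    normal_max_alt_reads = "integer",
    normal_max_vaf = "numeric",
    min_vaf = "numeric"),
  prototype(
    min_alt_reads = 10L,
    min_depth = 20L,
    common_snp_positions = character(0),
    normal_max_alt_reads = 1L,
    normal_max_vaf = 0.02,
    min_vaf = 0))

setValidity("NonMBFilterConfig", function(object) {
  if (object@min_alt_reads < 0L || object@min_depth < 0L)
    return("thresholds must be >= 0")
  TRUE
})

#' Create a non-MB filter configuration
#'
#' @param ... named slot overrides; see \code{\linkS4class{NonMBFilterConfig}}.
#' @return A \code{NonMBFilterConfig}.
#' @export
nonMBFilterConfig <- function(...) {
  args <- list(...)
  intSlots <- c("min_alt_reads", "min_depth", "normal_max_alt_reads")
  for (s in intersect(names(args), intSlots)) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list(Class = "NonMBFilterConfig"), args))
}

setMethod("show", "NonMBFilterConfig", function(object) {
  cat("NonMBFilterConfig\n")
  for (s in slotNames(object))
    cat(sprintf("  %s: %s\n", s, paste(format(slot(object, s)), collapse = ",")))
})

## ---------------------------------------------------------------------------
## RawTally
## ---------------------------------------------------------------------------

#' Read-level allele tally
#'
#' Per-locus read-level allele counts (UMTs ignored), the input to the
#' conventional caller. \code{alleles} has one row per observed non-reference
#' allele; \code{depths} gives per-amplicon read depth.
#'
#' @slot alleles data.frame: \code{amplicon_id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{variant_class}, \code{alt_reads}.
#' @slot depths data.frame: \code{amplicon_id}, \code{chrom},
#'   \code{insert_start}, \code{insert_end}, \code{read_depth}.
#' @export
setClass("RawTally",
  representation(alleles = "data.frame", depths = "data.frame"))

setMethod("show", "RawTally", function(object) {
  cat(sprintf("RawTally: %d alternate allele(s) over %d amplicon(s)\n",
              nrow(object@alleles), nrow(object@depths)))
})

## ---------------------------------------------------------------------------
## SimScenario
## ---------------------------------------------------------------------------

#' Simulation scenario
#'
#' Generative description of one amplicon sequencing experiment: the panel,
#' the true variants with their allele fractions, the DNA input, and the
#' error process. Template molecule counts per amplicon are
#' \code{round(input_mass_ng * copies_per_ng)}; the default 303 haploid
#' genome equivalents per ng corresponds to 3.3 pg per haploid genome, so the
#' 20 ng input used for reference-standard dilutions yields 6,060 molecules.
#'
#' Error model: cytosine deamination (FFPE artifact, C>T) and PCR errors are
#' drawn once per molecule and inherited by all of its reads
#' (lineage-heritable, the error class that can survive consensus);
#' sequencing errors are i.i.d. per read base, with the substituted base
#' uniform over the three non-reference bases. Each molecule emits
#' \code{k >= 1} reads with \code{k} truncated-Poisson distributed.
#'
#' @slot panel an \code{AmpliconPanel}.
#' @slot truth data.frame of true variants: \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (anchored, VCF-style), \code{vaf}, \code{label}.
#' @slot input_mass_ng DNA input mass (ng); default 20.
#' @slot copies_per_ng haploid genome equivalents per ng; default 303.
#' @slot pcr_error_rate per-base per-doubling polymerase error rate;
#'   default 1e-6.
#' @slot pcr_doublings effective number of doublings over library
#'   construction; default 25.
#' @slot seq_error_rate per-base sequencing error rate; default 1e-3.
#' @slot reads_per_molecule_mean mean of the (>=1 truncated) Poisson read
#'   count per molecule; default 6.
#' @slot ffpe_deamination_rate per-C deamination probability; default 0
#'   (FFPE preset 3e-4).
#' @slot umt_length UMT length per end; default 6.
#' @slot sample_id sample name carried into the reads.
#' @slot seed RNG seed; all randomness in a scenario derives from it.
#' @slot label free-text scenario label (e.g. the dilution level).
#' @export
setClass("SimScenario",
  representation(
    panel = "AmpliconPanel",
    truth = "data.frame",
    input_mass_ng = "numeric",
    copies_per_ng = "numeric",
    pcr_error_rate = "numeric",
    pcr_doublings = "numeric",
    seq_error_rate = "numeric",
    reads_per_molecule_mean = "numeric",
    ffpe_deamination_rate = "numeric",
    umt_length = "integer",
    sample_id = "character",
    seed = "integer",
    label = "character"),
  prototype(
    input_mass_ng = 20,
    copies_per_ng = 303,
    pcr_error_rate = 1e-6,
    pcr_doublings = 25,
    seq_error_rate = 1e-3,
    reads_per_molecule_mean = 6,
    ffpe_deamination_rate = 0,
    umt_length = 6L,
    sample_id = "S1",
    seed = 1L,
    label = ""))

setValidity("SimScenario", function(object) {
  t <- object@truth
  if (nrow(t) > 0L && (any(t$vaf < 0) || any(t$vaf > 1)))
    return("true VAFs must be in [0,1]")
  rates <- c(object@pcr_error_rate, object@seq_error_rate, object@ffpe_deamination_rate)
  if (any(rates < 0) || any(rates >= 1)) return("error rates must be in [0,1)")
  if (object@copies_per_ng <= 0) return("copies_per_ng must be > 0")
  if (nrow(t) > 0L) {
    bylocus <- tapply(t$vaf, paste(t$chrom, t$pos), sum)
    if (any(bylocus > 1)) return("true VAFs at one locus must not sum above 1")
  }
  TRUE
})

#' Create a simulation scenario
#'
#' @param panel an \code{AmpliconPanel}.
#' @param truth data.frame of true variants (\code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{vaf}, optionally \code{label}); may have
#'   zero rows for an error-only scenario.
#' @param seed RNG seed (required for reproducibility).
#' @param ... further slot overrides; see \code{\linkS4class{SimScenario}}.
#' @return A \code{SimScenario}.
#' @export
simScenario <- function(panel, truth = NULL, seed = 1L, ...) {
  if (is.null(truth))
    truth <- data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), vaf = numeric(), label = character())
  truth <- as.data.frame(truth)
  if (nrow(truth) > 0L && is.null(truth$label))
    truth$label <- paste0(truth$chrom, ":", truth$pos, truth$ref, ">", truth$alt)
  args <- list(...)
  if (!is.null(args$umt_length)) args$umt_length <- as.integer(args$umt_length)
  do.call(new, c(list(Class = "SimScenario", panel = panel, truth = truth,
                      seed = as.integer(seed)), args))
}

setMethod("show", "SimScenario", function(object) {
  cat(sprintf("SimScenario%s: %d variant(s), %.4g ng input (%d molecules/amplicon), seed %d\n",
              if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
              nrow(object@truth), object@input_mass_ng,
              as.integer(round(object@input_mass_ng * object@copies_per_ng)),
              object@seed))
})
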