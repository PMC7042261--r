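## Amplicon read simulator with ground truth: template molecule sampling,
## dual-UMT assignment, lineage-heritable PCR errors, i.i.d. sequencing
## errors and optional FFPE cytosine deamination.

# Apply one anchored variant record to a reference insert (insert-relative
# 1-based position).
.applyVariantToInsert <- function(refInsert, relPos, ref, alt) {
  obs <- substr(refInsert, relPos, relPos + nchar(ref) - 1L)
  if (obs != ref)
    .stopf("variant REF '%s' does not match reference insert at position %d (found '%s')",
           ref, relPos, obs)
  paste0(substr(refInsert, 1L, relPos - 1L), alt,
         substr(refInsert, relPos + nchar(ref), nchar(refInsert)))
}

# Substitute `nerr[i]` random positions of seqs[i] with a uniform choice
# among the three non-reference bases. Only entries with nerr > 0 are
# touched.
.ALT_MAP <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))

.mutateSeqs <- function(seqs, nerr) {
  idx <- which(nerr > 0L)
  if (length(idx) == 0L) return(seqs)
  spl <- strsplit(seqs[idx], "", fixed = TRUE)
  for (j in seq_along(idx)) {
    s <- spl[[j]]
    p <- sample.int(length(s), nerr[idx[j]])
    pick <- sample.int(3L, length(p), replace = TRUE)
    s[p] <- vapply(seq_along(p),
                   function(k) .ALT_MAP[[s[p[k]]]][pick[k]], character(1))
    spl[[j]] <- s
  }
  seqs[idx] <- vapply(spl, paste, character(1), collapse = "")
  seqs
}

# Deaminate: each C of seqs[i] flips to T independently with prob `rate`.
.deaminateSeqs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  spl <- strsplit(seqs, "", fixed = TRUE)
  for (j in seq_along(spl)) {
    s <- spl[[j]]
    cpos <- which(s == "C")
    if (length(cpos) > 0L) {
      hit <- cpos[runif(length(cpos)) < rate]
      if (length(hit) > 0L) {
        s[hit] <- "T"
        spl[[j]] <- s
      }
    }
  }
  vapply(spl, paste, character(1), collapse = "")
}

.drawMoleculesImpl <- function(scenario) {
  panel <- scenario@panel
  a <- amplicons(panel)
  truth <- scenario@truth
  N <- as.integer(round(scenario@input_mass_ng * scenario@copies_per_ng))
  parts <- list()
  truthRows <- list()
  for (i in seq_len(nrow(a))) {
    refIns <- a$ref_insert[i]
    onAmp <- which(truth$chrom == a$chrom[i] &
                     truth$pos >= a$insert_start[i] &
                     truth$pos <= a$insert_end[i])
    tmpl <- rep(refIns, N)
    lab <- rep(NA_character_, N)
    used <- 0L
    for (v in onAmp) {
      nm <- rbinom(1L, N, truth$vaf[v])
      if (used + nm > N)
        .stopf("mutant molecule counts exceed total at %s:%d", truth$chrom[v], truth$pos[v])
      if (nm > 0L) {
        mut <- .applyVariantToInsert(refIns, truth$pos[v] - a$insert_start[i] + 1L,
                                     truth$ref[v], truth$alt[v])
        sel <- seq.int(used + 1L, used + nm)
        tmpl[sel] <- mut
        lab[sel] <- truth$label[v]
        used <- used + nm
      }
      truthRows[[length(truthRows) + 1L]] <- data.table(
        chrom = truth$chrom[v], pos = truth$pos[v], ref = truth$ref[v],
        alt = truth$alt[v], label = truth$label[v], true_vaf = truth$vaf[v],
        mutant_molecules = nm, total_molecules = N)
    }
    # FFPE deamination acts on the template before any amplification, so
    # all descendant reads inherit it
    if (scenario@ffpe_deamination_rate > 0)
      tmpl <- .deaminateSeqs(tmpl, scenario@ffpe_deamination_rate)
    # lineage-heritable PCR errors: drawn once per molecule, shared by all
    # of its reads (the error class that can survive consensus)
    q <- scenario@pcr_error_rate * scenario@pcr_doublings
    if (q > 0) {
      nerr <- rbinom(N, nchar(tmpl), q)
      tmpl <- .mutateSeqs(tmpl, nerr)
    }
    parts[[i]] <- data.table(
      amplicon_id = a$amplicon_id[i],
      sequence = tmpl,
      source_label = lab,
      umt5 = .randomSeqs(N, scenario@umt_length),
      umt3 = .randomSeqs(N, scenario@umt_length))
  }
  mol <- rbindlist(parts)
  mol[, mol_id := .I]
  truthDt <- if (length(truthRows) > 0L) rbindlist(truthRows) else
    data.table(chrom = character(), pos = integer(), ref = character(),
               alt = character(), label = character(), true_vaf = numeric(),
               mutant_molecules = integer(), total_molecules = integer())
  list(molecules = as.data.frame(mol), truth = as.data.frame(truthDt))
}

#' Draw template molecules for a scenario
#'
#' Samples \code{round(input_mass_ng * copies_per_ng)} template molecules
#' per amplicon; the mutant molecule count of each true variant is
#' Binomial(total, VAF). Every molecule receives an independent random UMT
#' pair, and FFPE deamination and lineage-heritable PCR errors are applied
#' at the molecule level. Seeds the RNG from the scenario.
#'
#' @param scenario a \code{\linkS4class{SimScenario}}.
#' @return List with \code{molecules} (data.frame: \code{mol_id},
#'   \code{amplicon_id}, \code{sequence}, \code{source_label}, \code{umt5},
#'   \code{umt3}) and \code{truth} (per-variant sampled counts).
#' @export
drawMolecules <- function(scenario) {
  set.seed(scenario@seed)
  .drawMoleculesImpl(scenario)
}

.rtruncpois <- function(n, mean) {
  k <- rpois(n, mean)
  idx <- which(k == 0L)
  while (length(idx) > 0L) {
    k[idx] <- rpois(length(idx), mean)
    idx <- idx[k[idx] == 0L]
  }
  k
}

.amplifyImpl <- function(molecules, scenario) {
  mol <- as.data.table(molecules$molecules)
  n <- nrow(mol)
  k <- .rtruncpois(n, scenario@reads_per_molecule_mean)
  ridx <- rep(seq_len(n), k)
  seqs <- mol$sequence[ridx]
  nerr <- rbinom(length(seqs), nchar(seqs), scenario@seq_error_rate)
  seqs <- .mutateSeqs(seqs, nerr)
  reads <- data.frame(
    read_id = sprintf("r%08d", seq_along(ridx)),
    sample_id = scenario@sample_id,
    amplicon_id = mol$amplicon_id[ridx],
    sequence = seqs,
    qualities = strrep("I", nchar(seqs)),
    umt5 = mol$umt5[ridx],
    umt3 = mol$umt3[ridx],
    primer_trimmed = TRUE,
    mol_id = mol$mol_id[ridx],
    n_seq_errors = nerr,
    stringsAsFactors = FALSE)
  taggedReads(reads, umtLength = scenario@umt_length)
}

#' Amplify molecules and sequence them into tagged reads
#'
#' Each molecule emits \code{k >= 1} reads (truncated Poisson); each read is
#' a copy of its molecule's template with i.i.d. per-base sequencing errors
#' (substitutions uniform over the three non-reference bases). Continues the
#' current RNG stream, so \code{drawMolecules} followed by
#' \code{amplifyAndSequence} reproduces \code{\link{simulateReads}}.
#'
#' @param molecules result of \code{\link{drawMolecules}}.
#' @param scenario the \code{\linkS4class{SimScenario}}.
#' @return A \code{\linkS4class{TaggedReads}} object with per-read
#'   \code{mol_id} and \code{n_seq_errors} bookkeeping columns.
#' @export
amplifyAndSequence <- function(molecules, scenario) {
  .amplifyImpl(molecules, scenario)
}

#' Simulate a full scenario: molecules, amplification, sequencing
#'
#' Seeds the RNG from the scenario and runs
#' \code{\link{drawMolecules}} + \code{\link{amplifyAndSequence}}.
#' Identical seeds give bit-identical output.
#'
#' @param scenario a \code{\linkS4class{SimScenario}}.
#' @return List with \code{reads} (\code{TaggedReads}), \code{truth}
#'   (per-variant sampled molecule counts) and \code{molecules}.
#' @export
simulateReads <- function(scenario) {
  set.seed(scenario@seed)
  m <- .drawMoleculesImpl(scenario)
  r <- .amplifyImpl(m, scenario)
  list(reads = r, truth = m$truth, molecules = m$molecules)
}

#' Serial-dilution scenario ladder
#'
#' Builds one scenario per expected VAF level (default ladder 0.1%, 0.25%,
#' 0.5%, 1%, 2.5% and 5%), all variants at the level's VAF, constant total
#' DNA input, with seeds derived as \code{seed + i}.
#'
#' @param panel an \code{AmpliconPanel}; by default its hotspot list
#'   provides the variant set (as in \code{\link{egfrDilutionPanel}}).
#' @param variants data.frame (\code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{label}); defaults to \code{hotspots(panel)}.
#' @param vafLevels expected VAF fractions of the ladder.
#' @param inputMassNg constant DNA input per level (default 20 ng, i.e.
#'   6,060 genome equivalents at 303 copies/ng).
#' @param seed base seed.
#' @param ... further scenario slot overrides passed to
#'   \code{\link{simScenario}}.
#' @return List of \code{\linkS4class{SimScenario}}, one per level, labelled
#'   by VAF percentage.
#' @export
serialDilutionScenarios <- function(panel, variants = NULL,
                                    vafLevels = c(0.001, 0.0025, 0.005, 0.01,
                                                  0.025, 0.05),
                                    inputMassNg = 20, seed = 1L, ...) {
  if (is.null(variants)) variants <- hotspots(panel)
  if (nrow(variants) == 0L) .stopf("no variants supplied for the dilution ladder")
  lapply(seq_along(vafLevels), function(i) {
    truth <- data.frame(chrom = variants$chrom, pos = variants$pos,
                        ref = variants$ref, alt = variants$alt,
                        vaf = vafLevels[i], label = variants$label,
                        stringsAsFactors = FALSE)
    simScenario(panel, truth, seed = seed + i,
                input_mass_ng = inputMassNg,
                label = sprintf("%g%%", 100 * vafLevels[i]), ...)
  })
}

#' Synthetic EGFR-style dilution panel
#'
#' A deterministic synthetic 8-amplicon panel mirroring the composition of
#' the commercial EGFR multiplex cfDNA reference standard used for
#' serial-dilution validation: seven SNV/short-deletion variants (L858R,
#' E746_A750del-style 15-bp deletion, T790M, L861Q, G719S, C797S, S768I)
#' and one longer 9-bp insertion (V769_D770insASV-style). Reference inserts
#' and primers are synthetic sequences (no genome download is required);
#' coordinates are arbitrary but self-consistent, and all eight variants are
#' registered as hotspots. Variant records are derived in canonical
#' left-aligned anchored form against the synthetic reference.
#'
#' @param insertLength insert length in bp (default 112, the median design
#'   length of short cfDNA amplicons).
#' @param primerLength primer length in bp (default 18).
#' @return An \code{\linkS4class{AmpliconPanel}} whose hotspot table carries
#'   the 8 variants.
#' @export
egfrDilutionPanel <- function(insertLength = 112L, primerLength = 18L) {
  labels <- c("L858R", "E746_A750del", "T790M", "V769_D770insASV",
              "L861Q", "G719S", "C797S", "S768I")
  types <- c("SNV", "DEL15", "SNV", "INS9", "SNV", "SNV", "SNV", "SNV")
  .withSeed(20200225L, {
    n <- length(labels)
    inserts <- .randomSeqs(n, insertLength)
    fwd <- .randomSeqs(n, primerLength)
    rev_ <- .randomSeqs(n, primerLength)
    starts <- 55000001L + (seq_len(n) - 1L) * 10000L
    amp <- data.frame(
      amplicon_id = paste0("EGFR_", labels),
      chrom = "chr7",
      insert_start = starts,
      insert_end = starts + insertLength - 1L,
      fwd_primer = fwd,
      rev_primer = rev_,
      pool_id = rep(c(1L, 2L), length.out = n),
      ref_insert = inserts,
      stringsAsFactors = FALSE)
    hs <- lapply(seq_len(n), function(i) {
      refIns <- inserts[i]
      mid <- insertLength %/% 2L
      mut <- switch(types[i],
        SNV = {
          base <- substr(refIns, mid, mid)
          .applyVariantToInsert(refIns, mid, base,
                                .ALT_MAP[[base]][1L])
        },
        DEL15 = .applyVariantToInsert(
          refIns, mid - 7L, substr(refIns, mid - 7L, mid + 7L),
          substr(refIns, mid - 7L, mid - 7L)),
        INS9 = .applyVariantToInsert(
          refIns, mid, substr(refIns, mid, mid),
          paste0(substr(refIns, mid, mid), "GCTAGTGTA")))
      # canonical record from the same diff machinery the caller uses
      d <- .diffVariantTable(mut, refIns, "chr7", starts[i], amp$amplicon_id[i])
      v <- d$variants
      if (nrow(v) != 1L) .stopf("panel construction produced %d records for %s",
                                nrow(v), labels[i])
      data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                 label = labels[i], stringsAsFactors = FALSE)
    })
    ampliconPanel(amp, do.call(rbind, hs))
  })
}

#' Write ground truth as VCF and TSV
#'
#' The truth VCF carries a \code{TRUE_VAF} INFO key (plus sampled molecule
#' counts when available) and is sorted by (chrom, pos).
#'
#' @param truth data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{vaf} (or \code{true_vaf}), optionally
#'   \code{mutant_molecules}, \code{total_molecules}.
#' @param vcfPath output VCF path.
#' @param tsvPath optional TSV path.
#' @return Invisibly, \code{vcfPath}.
#' @export
writeTruth <- function(truth, vcfPath, tsvPath = NULL) {
  t <- as.data.frame(truth)
  if (is.null(t$vaf) && !is.null(t$true_vaf)) t$vaf <- t$true_vaf
  if (nrow(t) > 0L) t <- t[order(t$chrom, t$pos), , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=MBAmplicon(simulated ground truth)",
           '##INFO=<ID=TRUE_VAF,Number=1,Type=Float,Description="True variant allele fraction">',
           '##INFO=<ID=MUT_MOL,Number=1,Type=Integer,Description="Sampled mutant molecule count">',
           '##INFO=<ID=TOT_MOL,Number=1,Type=Integer,Description="Total template molecule count">',
           paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO"), collapse = "\t")))
  lines <- hdr
  if (nrow(t) > 0L) {
    info <- paste0("TRUE_VAF=", t$vaf)
    if (!is.null(t$mutant_molecules))
      info <- paste0(info, ";MUT_MOL=", t$mutant_molecules,
                     ";TOT_MOL=", t$total_molecules)
    id <- if (!is.null(t$label)) t$label else "."
    lines <- c(lines, paste(t$chrom, t$pos, id, t$ref, t$alt, ".", "PASS",
                            info, sep = "\t"))
  }
  writeLines(lines, vcfPath)
  if (!is.null(tsvPath)) write.table(t, tsvPath, sep = "\t", quote = FALSE,
                                     row.names = FALSE)
  invisible(vcfPath)
}

#' Write simulated reads as a raw tagged FASTQ
#'
#' Reconstructs the raw read structure
#' (5' UMT, forward primer, insert, reverse primer, 3' UMT) for each
#' simulated read and writes Phred+33 FASTQ via \pkg{Biostrings}.
#' \code{\link{parseFastqFile}} is the exact left inverse on error-free
#' reads.
#'
#' @param reads a \code{\linkS4class{TaggedReads}} object.
#' @param panel the \code{\linkS4class{AmpliconPanel}} (provides primers).
#' @param path output FASTQ path.
#' @return Invisibly, \code{path}.
#' @export
writeSimFastq <- function(reads, panel, path) {
  r <- readsTable(reads)
  a <- amplicons(panel)
  ai <- match(r$amplicon_id, a$amplicon_id)
  raw <- paste0(r$umt5, a$fwd_primer[ai], r$sequence, a$rev_primer[ai], r$umt3)
  qual <- strrep("I", nchar(raw))
  x <- Biostrings::QualityScaledDNAStringSet(Biostrings::DNAStringSet(raw),
                                             Biostrings::PhredQuality(qual))
  names(x) <- r$read_id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
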