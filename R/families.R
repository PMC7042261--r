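## Molecular family construction and unanimous per-position consensus.
##
## Reads are partitioned by the family key (sample, amplicon, 5' UMT,
## 3' UMT); each family stands for one original template molecule. A family
## supports an alternate allele only when every member read carries the
## identical allele (unanimity); positions where members disagree are
## ambiguous and contribute molecular depth only. Since errors land in a
## subset of a family's reads, unanimity removes almost all PCR/sequencing
## errors while true variants -- present in the template -- survive.

# Derive per-sequence allele records against the reference insert.
#
# Same-length sequences give per-position SNV records (N recorded
# separately, as missing data). A sequence whose length differs from the
# reference is encoded as one left-anchored composite record spanning the
# minimal unique region (the insertion/deletion plus any adjacent
# substitutions), then trimmed to canonical VCF-style minimal form, so the
# same event seen in different reads collapses to one record and the
# unanimity rule covers SNVs and INDELs alike.
.diffVariantTable <- function(seqs, refInsert, chrom, insertStart, ampliconId) {
  L <- nchar(refInsert)
  refc <- strsplit(refInsert, "", fixed = TRUE)[[1]]
  vlist <- list()
  nlist <- list()
  lens <- nchar(seqs)
  same <- which(lens == L)
  if (length(same) > 0L) {
    m <- matrix(unlist(strsplit(seqs[same], "", fixed = TRUE), use.names = FALSE),
                nrow = L)
    diffidx <- which(m != refc)
    if (length(diffidx) > 0L) {
      p0 <- ((diffidx - 1L) %% L) + 1L
      ci <- ((diffidx - 1L) %/% L) + 1L
      altb <- m[diffidx]
      isN <- altb == "N"
      if (any(!isN))
        vlist[[length(vlist) + 1L]] <- data.table(
          uid = same[ci[!isN]], pos = insertStart + p0[!isN] - 1L,
          ref = refc[p0[!isN]], alt = altb[!isN], variant_class = "SNV")
      if (any(isN))
        nlist[[length(nlist) + 1L]] <- data.table(
          uid = same[ci[isN]], pos = insertStart + p0[isN] - 1L)
    }
  }
  for (k in which(lens != L)) {
    sc <- strsplit(seqs[k], "", fixed = TRUE)[[1]]
    ns_ <- length(sc)
    nmin <- min(ns_, L)
    eqpre <- sc[seq_len(nmin)] == refc[seq_len(nmin)]
    i <- if (all(eqpre)) nmin + 1L else which(!eqpre)[1L]
    eqsuf <- rev(sc)[seq_len(nmin)] == rev(refc)[seq_len(nmin)]
    smax <- if (all(eqsuf)) nmin else which(!eqsuf)[1L] - 1L
    slen <- max(0L, min(smax, nmin - i + 1L))
    a <- max(1L, i - 1L)
    REF <- paste(refc[a:(L - slen)], collapse = "")
    ALT <- paste(sc[a:(ns_ - slen)], collapse = "")
    norm <- .normalizeAllele(insertStart + a - 1L, REF, ALT)
    vlist[[length(vlist) + 1L]] <- data.table(
      uid = k, pos = as.integer(norm$pos), ref = norm$ref, alt = norm$alt,
      variant_class = .alleleClass(norm$ref, norm$alt))
  }
  empty_v <- data.table(uid = integer(), pos = integer(), ref = character(),
                        alt = character(), variant_class = character())
  empty_n <- data.table(uid = integer(), pos = integer())
  v <- if (length(vlist) > 0L) rbindlist(vlist) else empty_v
  ns <- if (length(nlist) > 0L) rbindlist(nlist) else empty_n
  v[, `:=`(amplicon_id = ampliconId, chrom = chrom)]
  list(variants = v, ns = ns)
}

# Allele records for every unique sequence in a member table, over all
# amplicons of the panel.
.memberVariantTables <- function(members, panel) {
  a <- amplicons(panel)
  us <- unique(members[, c("amplicon_id", "sequence")])
  setDT(us)
  us[, uid := .I]
  vparts <- list()
  nparts <- list()
  for (i in seq_len(nrow(a))) {
    sub <- us[amplicon_id == a$amplicon_id[i]]
    if (nrow(sub) == 0L) next
    d <- .diffVariantTable(sub$sequence, a$ref_insert[i], a$chrom[i],
                           a$insert_start[i], a$amplicon_id[i])
    if (nrow(d$variants) > 0L) {
      d$variants[, uid := sub$uid[uid]]
      vparts[[length(vparts) + 1L]] <- d$variants
    }
    if (nrow(d$ns) > 0L) {
      d$ns[, uid := sub$uid[uid]]
      nparts[[length(nparts) + 1L]] <- d$ns
    }
  }
  V <- if (length(vparts) > 0L) rbindlist(vparts) else
    data.table(uid = integer(), pos = integer(), ref = character(),
               alt = character(), variant_class = character(),
               amplicon_id = character(), chrom = character())
  Ns <- if (length(nparts) > 0L) rbindlist(nparts) else
    data.table(uid = integer(), pos = integer())
  list(uids = us, variants = V, ns = Ns)
}

# Compute per-family supports/ambiguities from a member table that already
# carries family_id; returns the two tables.
.familyConsensus <- function(members, fam, panel) {
  mt <- .memberVariantTables(members, panel)
  m <- as.data.table(members)[, .(family_id, amplicon_id, sequence)]
  m <- merge(m, mt$uids, by = c("amplicon_id", "sequence"), sort = FALSE)
  famdt <- as.data.table(fam)[, .(family_id, amplicon_id, size)]

  emptySup <- data.table(family_id = character(), amplicon_id = character(),
                         chrom = character(), pos = integer(), ref = character(),
                         alt = character(), variant_class = character())
  emptyAmb <- data.table(family_id = character(), amplicon_id = character(),
                         chrom = character(), pos = integer())
  if (nrow(mt$variants) == 0L && nrow(mt$ns) == 0L)
    return(list(supports = emptySup, ambiguities = emptyAmb))

  mv <- merge(m[, .(family_id, uid)], mt$variants, by = "uid",
              allow.cartesian = TRUE)
  cnt <- if (nrow(mv) > 0L)
    mv[, .(nsupp = .N), by = .(family_id, amplicon_id, chrom, pos, ref, alt, variant_class)]
  else data.table(family_id = character(), amplicon_id = character(),
                  chrom = character(), pos = integer(), ref = character(),
                  alt = character(), variant_class = character(), nsupp = integer())

  mn <- merge(m[, .(family_id, uid)], mt$ns, by = "uid", allow.cartesian = TRUE)
  famN <- if (nrow(mn) > 0L) mn[, .(nN = .N), by = .(family_id, pos)] else
    data.table(family_id = character(), pos = integer(), nN = integer())

  cnt <- merge(cnt, famN, by = c("family_id", "pos"), all.x = TRUE)
  cnt[is.na(nN), nN := 0L]
  cnt <- merge(cnt, famdt[, .(family_id, size)], by = "family_id")
  # unanimity: every non-N member carries the allele; N is missing data and
  # is ignored only when at least 2 informative members remain
  cnt[, unanimous := (nN == 0L & nsupp == size) |
        (nN > 0L & nsupp == size - nN & (size - nN) >= 2L)]

  supports <- cnt[unanimous == TRUE,
                  .(family_id, amplicon_id, chrom, pos, ref, alt, variant_class)]

  bad <- cnt[unanimous == FALSE]
  ambParts <- list()
  if (nrow(bad) > 0L) {
    w <- nchar(bad$ref)
    ambParts[[1L]] <- data.table(
      family_id = rep(bad$family_id, w),
      amplicon_id = rep(bad$amplicon_id, w),
      chrom = rep(bad$chrom, w),
      pos = unlist(mapply(seq.int, bad$pos, bad$pos + w - 1L, SIMPLIFY = FALSE)))
  }
  if (nrow(famN) > 0L) {
    # positions where only N-thinned coverage remains (< 2 informative members)
    fN <- merge(famN, famdt[, .(family_id, amplicon_id, size)], by = "family_id")
    fN <- fN[(size - nN) < 2L]
    if (nrow(fN) > 0L) {
      a <- amplicons(panel)
      fN <- merge(fN, as.data.table(a)[, .(amplicon_id, chrom)], by = "amplicon_id")
      ambParts[[length(ambParts) + 1L]] <-
        fN[, .(family_id, amplicon_id, chrom, pos)]
    }
  }
  ambiguities <- if (length(ambParts) > 0L) unique(rbindlist(ambParts, use.names = TRUE))
    else emptyAmb
  list(supports = supports, ambiguities = ambiguities)
}

.assembleFamilies <- function(members, panel, minFamilySize) {
  members <- as.data.table(members)
  fam <- members[, .(size = .N), by = .(sample_id, amplicon_id, umt5, umt3)]
  setorder(fam, sample_id, amplicon_id, umt5, umt3)
  fam[, family_id := sprintf("F%07d", .I)]
  members <- merge(members, fam[, .(sample_id, amplicon_id, umt5, umt3, family_id)],
                   by = c("sample_id", "amplicon_id", "umt5", "umt3"), sort = FALSE)
  fam[, functional := size >= minFamilySize]
  fam[, consensus_failed := FALSE]
  cons <- .familyConsensus(members, fam, panel)
  setorder(fam, family_id)
  famdf <- as.data.frame(fam[, .(family_id, sample_id, amplicon_id, umt5, umt3,
                                 size, functional, consensus_failed)])
  sup <- cons$supports
  setorder(sup, family_id, chrom, pos, alt)
  amb <- cons$ambiguities
  setorder(amb, family_id, chrom, pos)
  new("MolecularFamilies",
      families = famdf,
      members = as.data.frame(members),
      supports = as.data.frame(sup),
      ambiguities = as.data.frame(amb),
      minFamilySize = as.integer(minFamilySize),
      panel = panel)
}

#' Cluster tagged reads into molecular families and compute consensus
#'
#' Partitions reads by the family key (sample, amplicon, 5' UMT, 3' UMT),
#' flags families reaching \code{minFamilySize} members as functional, and
#' computes the unanimous per-position consensus of every family. Output
#' order is deterministic (families sorted by key). The sum of family sizes
#' equals the number of input reads.
#'
#' @param reads a \code{\linkS4class{TaggedReads}} object.
#' @param panel the \code{\linkS4class{AmpliconPanel}} the reads were
#'   assigned against (provides the reference inserts the consensus is
#'   expressed against).
#' @param minFamilySize minimum member reads for a functional family
#'   (default 2, the published workflow setting).
#' @return A \code{\linkS4class{MolecularFamilies}} object.
#' @examples
#' # three reads sharing a key form one functional family
#' @export
buildFamilies <- function(reads, panel, minFamilySize = 2L) {
  r <- readsTable(reads)
  if (nrow(r) == 0L) {
    empty <- .assembleFamilies(
      data.frame(read_id = character(), sample_id = character(),
                 amplicon_id = character(), sequence = character(),
                 qualities = character(), umt5 = character(),
                 umt3 = character(), primer_trimmed = logical()),
      panel, minFamilySize)
    return(empty)
  }
  .assembleFamilies(r, panel, as.integer(minFamilySize))
}

#' Merge UMT-neighbor families
#'
#' UMT sequencing errors fragment families: a read with one miscalled tag
#' base founds a spurious singleton next to its true family. With
#' \code{maxEditDistance = 1}, a smaller family is absorbed into a family at
#' least twice its size whose concatenated UMT pair is within Hamming
#' distance 1 (same sample and amplicon); candidate absorbers are taken
#' greedily in descending size with lexicographic tie-break, and consensus
#' is recomputed after merging. With \code{maxEditDistance = 0} the input is
#' returned unchanged. Off by default in the pipeline: exact-match keys are
#' the conservative, reproducible choice.
#'
#' @param families a \code{\linkS4class{MolecularFamilies}} object.
#' @param maxEditDistance 0 (identity) or 1.
#' @return A \code{MolecularFamilies} object with merged families.
#' @export
mergeUmtNeighbors <- function(families, maxEditDistance = 1L) {
  stopifnot(maxEditDistance %in% c(0L, 1L))
  if (maxEditDistance == 0L) return(families)
  fam <- as.data.table(familyStats(families))
  members <- as.data.table(families@members)
  if (nrow(fam) <= 1L) return(families)
  fam[, key_ := paste0(umt5, umt3)]
  setorder(fam, -size, umt5, umt3)
  absorbedInto <- setNames(rep(NA_character_, nrow(fam)), fam$family_id)
  for (i in seq_len(nrow(fam))) {
    if (!is.na(absorbedInto[fam$family_id[i]])) next
    grp <- which(fam$sample_id == fam$sample_id[i] &
                   fam$amplicon_id == fam$amplicon_id[i])
    grp <- grp[grp > i]
    for (j in grp) {
      if (!is.na(absorbedInto[fam$family_id[j]])) next
      if (fam$size[i] < 2L * fam$size[j]) next
      if (.hamming(fam$key_[i], fam$key_[j]) <= 1L)
        absorbedInto[fam$family_id[j]] <- fam$family_id[i]
    }
  }
  if (all(is.na(absorbedInto))) return(families)
  for (fid in names(absorbedInto)[!is.na(absorbedInto)]) {
    target <- absorbedInto[[fid]]
    tgt <- fam[fam$family_id == target]
    members[family_id == fid, `:=`(umt5 = tgt$umt5, umt3 = tgt$umt3)]
  }
  .assembleFamilies(
    members[, .(read_id, sample_id, amplicon_id, sequence, qualities,
                umt5, umt3, primer_trimmed)],
    families@panel, families@minFamilySize)
}

#' Family size histogram
#'
#' @param families a \code{\linkS4class{MolecularFamilies}} object.
#' @return Named integer vector mapping family size to the number of
#'   families of that size; sums to the number of families.
#' @export
familySizeHistogram <- function(families) {
  f <- familyStats(families)
  if (nrow(f) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(f$size)
  setNames(as.integer(tab), names(tab))
}

#' Write per-family statistics to TSV
#'
#' Columns: sample, amplicon, umt5, umt3, size, functional, consensus_failed.
#'
#' @param families a \code{MolecularFamilies} object.
#' @param path output path.
#' @export
writeFamilyStats <- function(families, path) {
  f <- familyStats(families)
  write.table(f[, c("sample_id", "amplicon_id", "umt5", "umt3", "size",
                    "functional", "consensus_failed")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
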