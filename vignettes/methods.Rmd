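---
title: "Dual-UMT consensus calling: model, parameters and design choices"
author: "MBAmplicon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-UMT consensus calling: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Amplicon sequencing with dual molecular barcodes tags every template
molecule with a random unique molecular tag (UMT) at both the 5′ and 3′
end before amplification. All reads descending from one template share the
family key `(sample, amplicon, UMT5, UMT3)`. The method rests on three
observations:

1. **Errors are sub-family events.** A PCR or sequencing error arises in
   one lineage or one read and therefore appears in a subset of a family's
   members. A true variant is in the template and appears in all of them.
   Requiring *unanimity* — every member read carries the identical allele —
   suppresses the error classes that dominate conventional calling. For a
   family of `s` reads and per-base error rate `e`, the probability that
   all members independently agree on the same spurious base is
   `(e/3)^s`; at `e = 1e-3` and `s = 2` this is already ~1e-7 per position
   per family.

2. **Molecules are the unit of evidence.** After consensus, each family
   contributes exactly one molecular count. The molecular VAF is
   `alt_families / family_depth`, where the depth counts all functional
   families covering the locus — including families that are *ambiguous*
   (members disagree) at the position, which support no allele. This is the
   conservative denominator matching the "variant molecules : total
   molecules" arithmetic used when such results are reported.

3. **Residual background is binomial.** The surviving error process
   (chiefly first-cycle PCR errors, which are inherited by a whole family
   and *do* survive consensus) is modeled as independent per-family,
   per-allele events at a small background rate. A candidate with `k`
   supporting molecules out of `n` is tested with the one-sided exact
   binomial tail `P(X >= k), X ~ Binomial(n, p_bg)`, thresholded at
   `p < 0.02`. The statistic itself is a design choice: the published
   workflow states only the threshold, and a binomial test against a
   background error rate is the standard choice for UMI callers. The rate
   `p_bg` is configurable per variant class (default `1e-4` per family per
   allele).

The filter cascade applied to every (locus, alternate allele) candidate,
in order: (1) supporting-family minimum by class — 2 for SNVs and hotspot
variants, 6 for insertions/deletions; (2) alternate molecule count ≥ 2;
(3) common-SNP position exclusion; (4) `p < 0.02`; (5) INDELs require
molecular VAF ≥ 0.002 **and** more than 3 supporting molecules;
(6) non-hotspot variants require more than 3 supporting molecules;
(7) homopolymer-context INDELs require every supporting family to be at
least the functional size; (8) in tumor context only, molecular VAF
≥ 0.005. All verdicts are evaluated and recorded even after the first
failure, so a call row documents its full filter profile.

The comparison baseline (`callRawVariants`) is conventional read-level
tumor–normal calling: ≥ 10 alternate reads, ≥ 20× depth, common-SNP
exclusion, and a confident-somatic requirement on the matched normal.
"Confident somatic" is not publicly specified by vendor pipelines; it is
operationalized here as *normal alternate reads ≤ 1 and normal VAF ≤ 2%*,
both configurable. An optional VAF operating floor (`min_vaf`, default off)
models the practical ~5% detection limit of conventional plasma
sequencing.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_family_size` | 2 | reads | minimum members for a functional family |
| `min_snp/hotspot_supporting_families` | 2 | families | published workflow setting |
| `min_indel_supporting_families` | 6 | families | INDELs are the noisier class |
| `max_p_value` | 0.02 | — | strict `<`, published threshold |
| `background_error_rate` | 1e-4 | per family per allele | residual post-consensus error scale |
| `min_indel_vaf` / `min_indel_alt_count` | 0.002 / 4 | — / molecules | "exclude INDELs with VAF < 0.002 or ≤ 3 molecules" |
| `min_nonhotspot_alt_count` | 4 | molecules | non-hotspot variants with ≤ 3 molecules are excluded |
| `tumor_vaf_cutoff` | 0.005 | fraction | applied in tumor context only |
| `homopolymer_min_run` | 4 | bases | reference run length defining homopolymer context |
| UMT length | 6 | bases per end | typical amplicon UMI chemistry; the source workflow does not state it |
| `copies_per_ng` | 303 | genome equivalents | 3.3 pg per haploid genome |
| `pcr_error_rate` × `pcr_doublings` | 1e-6 × 25 | per base | lineage-heritable error probability per molecule |
| `seq_error_rate` | 1e-3 | per base | typical raw accuracy of amplicon sequencing |
| `reads_per_molecule_mean` | 6 | reads | truncated Poisson ≥ 1; most families functional, deep-coverage regime |

## What the simulator emulates — and what it does not

`simulateReads` reproduces the parts of the experiment that drive the
statistics of consensus calling: binomial sampling of mutant molecules at
the true VAF from `round(input_mass_ng × copies_per_ng)` templates per
amplicon, independent random UMT pairs per molecule, a truncated-Poisson
read count per molecule, **lineage-heritable** PCR errors drawn once per
molecule (the dangerous class, because they survive unanimity),
independent per-base sequencing errors with the substituted base uniform
over the three alternatives, and optional FFPE C→T deamination applied to
templates before amplification (preset `3e-4`; the wet-lab
uracil-DNA-glycosylase treatment corresponds to leaving it at 0).

It deliberately does **not** model: per-cycle PCR lineage trees (the
heritable-error shortcut reproduces the same family-level outcome at a
fraction of the complexity), sequencing indel errors (substitution-only —
homopolymer indel noise of specific platforms is therefore absent), UMT
sequencing errors by default (enable together with `mergeUmtNeighbors`),
GC/length amplification bias, cfDNA fragment-length physics, or
polymerase-specific error spectra. Passing tests therefore demonstrate the
*statistical* behavior of the method under its own assumptions — unbiased
molecular VAF, error suppression relative to read-level calling, detection
limits set by molecule sampling — not platform-specific artifact profiles
on real data.

## Numerical and algorithmic choices

- **Allele records.** Reads are compared against the amplicon reference
  insert. Equal-length reads yield per-position SNV records. A read whose
  length differs is encoded as a single left-anchored record spanning the
  minimal unique region (the indel plus any adjacent substitutions),
  trimmed to canonical VCF-style minimal form. The same unanimity rule
  then covers SNVs and INDELs. A consequence worth knowing: a sequencing
  error anywhere in an indel-carrying read changes its composite record,
  so that family becomes ambiguous rather than supporting the indel —
  conservative support loss of roughly `1 − (1−e)^(s·L)` per mutant
  family. This is why a long insertion at 0.5% true VAF can fall under the
  INDEL VAF floor while SNVs at the same level are called comfortably.
- **`N` is missing data**, not evidence: a member with `N` at a position
  abstains; unanimity is assessed over the remaining members if at least 2
  remain, otherwise the position is ambiguous.
- **Determinism.** Families are sorted by key, calls by (chrom, pos, alt);
  all simulator randomness derives from the scenario seed; identical seeds
  give bit-identical FASTQ.
- **Family keys are exact matches.** Distance-1 UMT merging
  (`mergeUmtNeighbors`: a family absorbs into one ≥ 2× larger within
  Hamming distance 1, greedy by descending size, lexicographic tie-break)
  exists but is off by default — exact matching is the conservative,
  reproducible choice, and the source workflow is silent on merging.
- **Degenerate inputs.** Zero depth gives VAF 0 (flagged `no_coverage`)
  and p-value 1; empty read sets propagate to empty families, tallies and
  calls; multi-allelic loci are filtered per alternate allele with no
  joint normalization.
- **Primer matching** is Hamming-only (no indels) with a total budget of 2
  mismatches across the primer pair; ties between amplicons reject the
  read as ambiguous. This keeps assignment exact and testable; alignment
  to a reference genome is out of scope by design.
- **VAF reporting precision**: two decimal places at ≥ 0.01%, two
  significant figures below — matching how such values are conventionally
  printed (e.g. 9/249,780 → 0.0036; 6/9,859 → 0.06).

## Choices made where the design was open

- Both UMTs enter the family key (dual-barcode reading of the chemistry);
  sample index is carried separately.
- "Alternate allele count" and "number of mutated alleles" are interpreted
  as *molecule* (functional-family) counts, not raw reads: the workflow
  counts molecules after consensus, and molecule counts match the
  published plasma worked examples.
- The ≥ 0.005 VAF cutoff applies in tumor context only; plasma calling can
  instead be restricted to loci mutated in the paired tumor
  (`restrictTo =`), and `rescueReport` mirrors the manual review step that
  inspects sub-threshold tallies at known tumor loci.
- Reads are single-ended and oriented 5′→3′ along the amplicon; strand
  handling is collapsed into the amplicon definition, and no duplex
  (strand-aware) consensus is attempted — the chemistry tags single
  strands.
- Families contribute exactly one molecular count regardless of size; no
  down-weighting or capping.

## Problem sizes used by the test suite

The packaged checks run at desk scale chosen to keep the full suite in a
few minutes while preserving the study conditions that matter: the
dilution ladder uses the full 20 ng / 6,060-molecule design over all 8
amplicons and 6 VAF levels; plasma sensitivity uses 20,000 template
molecules (functional-family depth ≈ 19,700) with replicate ladders;
parameter recovery uses 200 replicates of 6,060 molecules on one 60-bp
amplicon; error-suppression comparisons use 500-molecule error-only runs
at `e = 0.005`. The limit-of-detection criterion is replicate-based
(≥ 50% of seeded replicates detected), which is a strictly stronger claim
than single-run detection.

## Known limitations

- Long insertions are systematically under-supported (composite-record
  unanimity, above); their practical floor is set by `min_indel_vaf`
  interacting with consensus loss, not by molecule sampling alone.
- The binomial background model assumes independence across families and
  positions; clustered artifacts (e.g. FFPE deamination hotspots) are only
  captured insofar as the configured per-class background rate absorbs
  them.
- The conventional-caller comparison inherits the undocumented vendor
  semantics of "confident somatic"; results at loci where the normal
  carries sporadic errors depend on those configurable thresholds.
- Variant records at the extreme first base of an insert cannot be
  left-anchored and are encoded right-anchored; panels should place
  primers so that target positions sit inside the insert, as real designs
  do.
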