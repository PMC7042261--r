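test_that("tallyLoci separates unanimous support, ambiguity and depth", {
  p <- tinyPanel()
  mut <- subsBase(TINY_INSERT1, 20L, "G")
  mkFam <- function(i, seqs) {
    u5 <- paste0("A", paste(c("A", "C", "G", "T")[1L + (i %/% 4L^(0:4)) %% 4L],
                            collapse = ""))
    do.call(rbind, lapply(seq_along(seqs), function(m)
      readRow("AMP1", u5, "CCCCCC", seqs[[m]], id = sprintf("f%d_%d", i, m))))
  }
  rows <- c(lapply(1:7, function(i) mkFam(i, rep(TINY_INSERT1, 2L))),
            lapply(8:9, function(i) mkFam(i, rep(mut, 2L))),
            list(mkFam(10L, c(TINY_INSERT1, mut))))
  fams <- buildFamilies(taggedReads(do.call(rbind, rows)), p)
  expect_equal(sum(familyStats(fams)$functional), 10L)
  tal <- tallyLoci(fams)
  g <- tal[tal$pos == 120L & tal$alt == "G", ]
  expect_equal(g$alt_families, 2L)
  expect_equal(g$family_depth, 10L)
  expect_equal(g$ambiguous_families, 1L)
  expect_equal(g$ref_families, 7L)
  # empty input
  empty <- buildFamilies(taggedReads(readRow("AMP1", "A", "A", "x")[0, ]), p)
  expect_equal(nrow(tallyLoci(empty)), 0L)
})

test_that("molecular VAF reproduces the printed count-to-percent conversions", {
  expect_equal(formatVafPercent(molecularVaf(9, 249780)), "0.0036")
  expect_equal(formatVafPercent(molecularVaf(2145, 236446)), "0.91")
  expect_equal(formatVafPercent(molecularVaf(4, 3053)), "0.13")
  expect_equal(formatVafPercent(molecularVaf(6, 9859)), "0.06")
  expect_equal(molecularVaf(0, 1000), 0)
  v <- molecularVaf(0, 0)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "no_coverage"))
  expect_error(molecularVaf(5, 4), "altCount")
  expect_equal(formatVafPercent(readLevelVaf(100, 100)), "100.00")
})

test_that("background p-value is an exact binomial tail", {
  expect_equal(backgroundPvalue(0, 1000, 1e-4), 1)
  expect_equal(backgroundPvalue(0, 0, 1e-4), 1)   # no coverage
  expect_equal(backgroundPvalue(5, 5, 0.01), 0.01^5, tolerance = 1e-12)
  # frozen value from the independent summation oracle
  expect_equal(backgroundPvalue(4, 3053, 1e-3), 0.3646464108884409,
               tolerance = 1e-12)
  # agreement with the oracle across depths up to 1e5, relative error 1e-12
  grid <- expand.grid(n = c(10L, 313L, 3053L, 100000L),
                      e = c(1e-4, 1e-3, 0.01))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; e <- grid$e[i]
    for (k in unique(pmin(n, c(1L, 2L, 5L, 25L, as.integer(n * e) + 3L)))) {
      expect_equal(backgroundPvalue(k, n, e), binomTailOracle(k, n, e),
                   tolerance = 1e-12)
    }
  }
  # monotone non-increasing in the observed count at fixed depth
  ks <- 0:50
  ps <- backgroundPvalue(ks, 1000, 1e-3)
  expect_true(all(diff(ps) <= 0))
  expect_error(backgroundPvalue(1, 10, 0), "errorRate")
})

test_that("the MB filter cascade reproduces the published rule set", {
  draft <- function(class = "SNV", hotspot = FALSE, homopolymer = FALSE,
                    altFam = 4L, depth = 3053L, p = 1e-4, minSize = 2L) {
    data.frame(chrom = "chr1", pos = 120L, ref = "A", alt = "G",
               variant_class = class, hotspot = hotspot,
               homopolymer = homopolymer, alt_families = altFam,
               family_depth = depth, vaf = altFam / depth, p_value = p,
               min_supp_family_size = minSize)
  }
  # plasma non-hotspot SNV with 4 supporting molecules at 0.13% passes
  r1 <- applyMBFilters(draft(), context = "plasma")
  expect_equal(r1$status, "PASS")
  # non-hotspot variants with <= 3 supporting molecules are excluded
  r2 <- applyMBFilters(draft(altFam = 3L), context = "plasma")
  expect_equal(r2$status, "FAIL")
  expect_false(r2$flt_nonhotspot_alt_count)
  # INDELs need 6 supporting functional families
  r3 <- applyMBFilters(draft(class = "DEL", altFam = 5L), context = "plasma")
  expect_equal(r3$status, "FAIL")
  expect_equal(r3$filter, "supporting_families")
  r3b <- applyMBFilters(draft(class = "DEL", altFam = 6L, depth = 2000L),
                        context = "plasma")
  expect_equal(r3b$status, "PASS")
  # tumor context applies the 0.005 VAF cutoff
  r4 <- applyMBFilters(draft(hotspot = TRUE, altFam = 2L, depth = 500L,
                             p = 1e-6), context = "tumor")
  expect_equal(r4$vaf, 0.004)
  expect_equal(r4$status, "FAIL")
  expect_false(r4$flt_tumor_vaf)
  # ...but the same call passes in plasma, where no VAF cutoff applies
  expect_equal(applyMBFilters(draft(hotspot = TRUE, altFam = 2L, depth = 500L,
                                    p = 1e-6), context = "plasma")$status,
               "PASS")
  # the p-value threshold is strict
  r5 <- applyMBFilters(draft(p = 0.02), context = "plasma")
  expect_false(r5$flt_p_value)
  # common-SNP exclusion is positional
  r6 <- applyMBFilters(draft(), mbFilterConfig(common_snp_positions = "chr1:120"))
  expect_equal(r6$filter, "common_snp")
  # INDEL evidence rule: VAF >= 0.002 AND molecules > 3
  r7 <- applyMBFilters(draft(class = "INS", altFam = 6L, depth = 10000L))
  expect_false(r7$flt_indel_evidence)  # vaf 6e-4 < 0.002
  expect_error(applyMBFilters(draft(class = "XXX")), "unknown variant class")
})

test_that("hotspot variants with 2 supporting molecules pass in plasma", {
  d <- data.frame(chrom = "chr1", pos = 120L, ref = "A", alt = "G",
                  variant_class = "SNV", hotspot = TRUE, homopolymer = FALSE,
                  alt_families = 2L, family_depth = 500L, vaf = 2 / 500,
                  p_value = 1e-6, min_supp_family_size = 2L)
  expect_equal(applyMBFilters(d, context = "plasma")$status, "PASS")
})

test_that("the filter cascade is monotone in the supporting molecule count", {
  cfg <- mbFilterConfig()
  depth <- 2000L
  for (class in c("SNV", "DEL")) {
    passed <- FALSE
    for (altFam in 1:40) {
      d <- data.frame(chrom = "chr1", pos = 120L, ref = "A", alt = "G",
                      variant_class = class, hotspot = FALSE,
                      homopolymer = FALSE, alt_families = altFam,
                      family_depth = depth, vaf = altFam / depth,
                      p_value = backgroundPvalue(altFam, depth, 1e-4),
                      min_supp_family_size = 2L)
      st <- applyMBFilters(d, cfg, context = "plasma")$status
      if (passed) expect_equal(st, "PASS")
      if (st == "PASS") passed <- TRUE
    }
    expect_true(passed)
  }
})

test_that("zero-error simulation yields exactly the truth as a PASS call", {
  p <- egfrDilutionPanel()
  hs <- hotspots(p)[1L, ]
  sc <- simScenario(p, data.frame(chrom = hs$chrom, pos = hs$pos, ref = hs$ref,
                                  alt = hs$alt, vaf = 0.10),
                    seed = 9L, input_mass_ng = 1000 / 303,
                    seq_error_rate = 0, pcr_error_rate = 0)
  sim <- simulateReads(sc)
  fams <- buildFamilies(sim$reads, p)
  calls <- callVariants(fams)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$status, "PASS")
  expect_equal(calls$pos, hs$pos)
  # exactly the mutant molecules that formed functional (>= 2 read) families
  r <- readsTable(sim$reads)
  mol <- sim$molecules[sim$molecules$amplicon_id == calls$amplicon_id, ]
  readsPerMol <- table(r$mol_id)
  mutMol <- mol$mol_id[!is.na(mol$source_label)]
  expect_equal(calls$alt_families,
               sum(readsPerMol[as.character(mutMol)] >= 2L))
  expect_equal(calls$family_depth,
               sum(readsPerMol[as.character(mol$mol_id)] >= 2L))
})

test_that("error-only simulation produces no PASS calls", {
  p <- singleAmpliconPanel()
  sc <- simScenario(p, seed = 31L, input_mass_ng = 500 / 303,
                    seq_error_rate = 0.001)
  res <- runScenarioMB(sc)
  if (nrow(res$calls) > 0L) expect_equal(sum(res$calls$status == "PASS"), 0L)
  else succeed()
})

test_that("call VCF output round-trips through a standard VCF reader", {
  skip_if_not_installed("VariantAnnotation")
  p <- egfrDilutionPanel()
  hs <- hotspots(p)[c(1L, 2L), ]
  sc <- simScenario(p, data.frame(chrom = hs$chrom, pos = hs$pos, ref = hs$ref,
                                  alt = hs$alt, vaf = 0.10),
                    seed = 13L, input_mass_ng = 300 / 303,
                    seq_error_rate = 0, pcr_error_rate = 0)
  sim <- simulateReads(sc)
  fams <- buildFamilies(sim$reads, p)
  vcf <- tempfile(fileext = ".vcf")
  calls <- callVariants(fams, vcfPath = vcf)
  v <- VariantAnnotation::readVcf(vcf)
  expect_equal(nrow(v), nrow(calls))
  expect_equal(BiocGenerics::start(SummarizedExperiment::rowRanges(v)),
               calls$pos)
  expect_equal(unlist(VariantAnnotation::info(v)$FAO), calls$alt_families,
               ignore_attr = TRUE)
})

test_that("rescue reporting surfaces sub-threshold tallies at supplied loci", {
  p <- tinyPanel()
  mut <- subsBase(TINY_INSERT1, 20L, "T")   # chr1:120 A>T, not in the hotspot list
  r <- rbind(readRows(2L, "AMP1", "ACACAC", "CCCCCC", mut, prefix = "m"),
             readRows(2L, "AMP1", "GTGTGT", "CCCCCC", TINY_INSERT1, prefix = "w1"),
             readRows(2L, "AMP1", "TGTGTG", "CCCCCC", TINY_INSERT1, prefix = "w2"))
  fams <- buildFamilies(taggedReads(r), p)
  # 2 supporting molecules: fails the non-hotspot <=3 exclusion...
  calls <- callVariants(fams, context = "plasma")
  expect_equal(calls$status, "FAIL")
  expect_false(calls$flt_nonhotspot_alt_count)
  # ...but the rescue report still shows the tally at the tumor locus
  resc <- rescueReport(fams, data.frame(chrom = "chr1", pos = 120L,
                                        ref = "A", alt = "T"))
  expect_equal(resc$alt_families, 1L)
  expect_equal(resc$family_depth, 3L)
})
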