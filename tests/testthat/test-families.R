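test_that("reads partition into families by the dual-UMT key", {
  p <- tinyPanel()
  r <- rbind(readRows(3L, "AMP1", "AAAAAA", "CCCCCC", TINY_INSERT1, prefix = "a"),
             readRow("AMP1", "AAAAAA", "CCCCCG", TINY_INSERT1, id = "b1"),
             readRow("AMP1", "TTTTTT", "CCCCCC", TINY_INSERT1, id = "c1"))
  fams <- buildFamilies(taggedReads(r), p, minFamilySize = 2L)
  f <- familyStats(fams)
  expect_equal(nrow(f), 3L)
  expect_equal(sort(f$size), c(1L, 1L, 3L))
  expect_equal(f$functional, f$size >= 2L)
  expect_equal(sum(f$size), nrow(r))        # conservation
})

test_that("degenerate family inputs behave", {
  p <- tinyPanel()
  empty <- buildFamilies(taggedReads(readRow("AMP1", "A", "A", "x")[0, ]), p)
  expect_equal(length(empty), 0L)
  r <- readRows(10L, "AMP1", "GATTAC", "CATCAT", TINY_INSERT1)
  one <- buildFamilies(taggedReads(r), p)
  expect_equal(length(one), 1L)
  expect_equal(familyStats(one)$size, 10L)
  expect_true(familyStats(one)$functional)
})

test_that("family size histogram is exact and sums to the family count", {
  p <- tinyPanel()
  r <- rbind(readRows(3L, "AMP1", "AAAAAA", "CCCCCC", TINY_INSERT1, prefix = "a"),
             readRow("AMP1", "AAAAAA", "CCCCCG", TINY_INSERT1, id = "b1"),
             readRow("AMP1", "TTTTTT", "CCCCCC", TINY_INSERT1, id = "c1"))
  fams <- buildFamilies(taggedReads(r), p)
  h <- familySizeHistogram(fams)
  expect_equal(h, c("1" = 2L, "3" = 1L))
  expect_equal(sum(h), length(fams))
  expect_equal(familySizeHistogram(buildFamilies(taggedReads(r[0, ]), p)),
               setNames(integer(0), character(0)))
})

test_that("unanimous families support the shared allele; mixed families are ambiguous", {
  p <- tinyPanel()
  mut <- subsBase(TINY_INSERT1, 20L, "G")   # chr1:120 A>G
  # unanimous mutant family
  fams <- buildFamilies(taggedReads(readRows(3L, "AMP1", "AAAAAA", "CCCCCC", mut)), p)
  sup <- familySupports(fams)
  expect_equal(nrow(sup), 1L)
  expect_equal(sup$pos, 120L)
  expect_equal(sup$alt, "G")
  expect_equal(nrow(familyAmbiguities(fams)), 0L)
  # mixed family: one mutant read among refs -> ambiguous at the position
  r <- rbind(readRows(2L, "AMP1", "AAAAAA", "CCCCCC", TINY_INSERT1, prefix = "a"),
             readRow("AMP1", "AAAAAA", "CCCCCC", mut, id = "m1"))
  fams2 <- buildFamilies(taggedReads(r), p)
  expect_equal(nrow(familySupports(fams2)), 0L)
  amb <- familyAmbiguities(fams2)
  expect_equal(amb$pos, 120L)
})

test_that("a single-member family is unanimous but not functional", {
  p <- tinyPanel()
  mut <- subsBase(TINY_INSERT1, 20L, "G")
  fams <- buildFamilies(taggedReads(readRow("AMP1", "AAAAAA", "CCCCCC", mut)), p)
  expect_equal(nrow(familySupports(fams)), 1L)
  expect_false(familyStats(fams)$functional)
  # non-functional families never reach the caller's tallies
  tal <- tallyLoci(fams)
  expect_equal(nrow(tal), 0L)
})

test_that("N is missing data: ignored with >=2 informative members, ambiguous otherwise", {
  p <- tinyPanel()
  mut <- subsBase(TINY_INSERT1, 20L, "G")
  withN <- subsBase(TINY_INSERT1, 20L, "N")
  # 2 mutant + 1 N -> still unanimous for the alt
  r <- rbind(readRows(2L, "AMP1", "AAAAAA", "CCCCCC", mut, prefix = "a"),
             readRow("AMP1", "AAAAAA", "CCCCCC", withN, id = "n1"))
  fams <- buildFamilies(taggedReads(r), p)
  expect_equal(familySupports(fams)$alt, "G")
  # 1 mutant + 1 N -> fewer than 2 informative members -> ambiguous
  r2 <- rbind(readRow("AMP1", "AAAAAA", "CCCCCC", mut, id = "a1"),
              readRow("AMP1", "AAAAAA", "CCCCCC", withN, id = "n1"))
  fams2 <- buildFamilies(taggedReads(r2), p)
  expect_equal(nrow(familySupports(fams2)), 0L)
  expect_true(120L %in% familyAmbiguities(fams2)$pos)
})

test_that("indel-carrying families reach unanimous consensus on the canonical record", {
  p <- egfrDilutionPanel()
  hs <- hotspots(p)
  del <- hs[hs$label == "E746_A750del", ]
  a <- amplicons(p)[amplicons(p)$amplicon_id == "EGFR_E746_A750del", ]
  mutIns <- paste0(substr(a$ref_insert, 1L, del$pos - a$insert_start),
                   del$alt,
                   substr(a$ref_insert, del$pos - a$insert_start + nchar(del$ref) + 1L,
                          nchar(a$ref_insert)))
  fams <- buildFamilies(taggedReads(readRows(4L, a$amplicon_id, "ACACAC", "GTGTGT",
                                             mutIns)), p)
  sup <- familySupports(fams)
  expect_equal(nrow(sup), 1L)
  expect_equal(sup$variant_class, "DEL")
  expect_equal(sup$pos, del$pos)
  expect_equal(sup$ref, del$ref)
  expect_equal(sup$alt, del$alt)
})

test_that("UMT-neighbor merging follows the absorber rule", {
  p <- tinyPanel()
  big <- readRows(10L, "AMP1", "AAAAAA", "GGGGGG", TINY_INSERT1, prefix = "b")
  frag <- readRow("AMP1", "AAAAAT", "GGGGGG", TINY_INSERT1, id = "f1")
  fams <- buildFamilies(taggedReads(rbind(big, frag)), p)
  expect_equal(length(fams), 2L)
  # distance 0 is the identity
  expect_equal(familyStats(mergeUmtNeighbors(fams, 0L))$size,
               familyStats(fams)$size)
  # brute-force pairwise Hamming scan confirms a unique absorber >= 2x larger
  merged <- mergeUmtNeighbors(fams, 1L)
  expect_equal(length(merged), 1L)
  expect_equal(familyStats(merged)$size, 11L)
  expect_equal(familyStats(merged)$umt5, "AAAAAA")
  # two singletons within distance 1 but no absorber >= 2x larger: both kept
  twins <- rbind(readRow("AMP1", "CCCCCC", "GGGGGG", TINY_INSERT1, id = "t1"),
                 readRow("AMP1", "CCCCCG", "GGGGGG", TINY_INSERT1, id = "t2"))
  fams2 <- buildFamilies(taggedReads(twins), p)
  expect_equal(length(mergeUmtNeighbors(fams2, 1L)), 2L)
})

test_that("family sizes always sum to the read count on simulated data", {
  p <- egfrDilutionPanel()
  for (seed in c(2L, 5L)) {
    sc <- simScenario(p, seed = seed, input_mass_ng = 0.1)
    sim <- simulateReads(sc)
    fams <- buildFamilies(sim$reads, p)
    expect_equal(sum(familyStats(fams)$size), length(sim$reads))
  }
})

test_that("spurious unanimous support decreases with family size", {
  # fixed-size error-only families built by hand: per-base error 1%, the
  # rate at which a whole family agrees on a spurious allele must fall
  # monotonically with family size
  p <- tinyPanel()
  e <- 0.01
  nfam <- 400L
  rate <- numeric(3L)
  set.seed(424242L)
  for (si in 1:3) {
    s <- si + 1L
    rows <- vector("list", nfam * s)
    k <- 1L
    for (f in seq_len(nfam)) {
      u5 <- paste(sample(c("A", "C", "G", "T"), 6L, replace = TRUE), collapse = "")
      u3 <- paste(sample(c("A", "C", "G", "T"), 6L, replace = TRUE), collapse = "")
      for (m in seq_len(s)) {
        sq <- strsplit(TINY_INSERT1, "")[[1]]
        hit <- which(runif(length(sq)) < e)
        for (h in hit) sq[h] <- sample(setdiff(c("A", "C", "G", "T"), sq[h]), 1L)
        rows[[k]] <- readRow("AMP1", u5, u3, paste(sq, collapse = ""),
                             id = sprintf("s%d_f%d_m%d", s, f, m))
        k <- k + 1L
      }
    }
    fams <- buildFamilies(taggedReads(do.call(rbind, rows)), p)
    sup <- familySupports(fams)
    rate[si] <- length(unique(sup$family_id)) / nfam
  }
  expect_true(rate[1] >= rate[2])
  expect_true(rate[2] >= rate[3])
  expect_lt(rate[3], 0.01)
})
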