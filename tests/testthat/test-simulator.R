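test_that("template molecule counts follow the genome-equivalent arithmetic", {
  p <- singleAmpliconPanel()
  sc <- simScenario(p, seed = 1L)   # 20 ng at 303 copies/ng
  m <- drawMolecules(sc)
  expect_equal(nrow(m$molecules), 6060L)
  sc2 <- simScenario(p, seed = 1L, input_mass_ng = 1)
  expect_equal(nrow(drawMolecules(sc2)$molecules), 303L)
})

test_that("a zero VAF never produces mutant molecules", {
  p <- singleAmpliconPanel()
  hs <- hotspots(p)
  for (seed in 1:3) {
    sc <- simScenario(p, data.frame(chrom = hs$chrom, pos = hs$pos, ref = hs$ref,
                                    alt = hs$alt, vaf = 0),
                      seed = seed, input_mass_ng = 2)
    m <- drawMolecules(sc)
    expect_equal(m$truth$mutant_molecules, 0L)
    expect_true(all(is.na(m$molecules$source_label)))
  }
})

test_that("mutant molecule counts are binomial with the expected mean", {
  p <- singleAmpliconPanel()
  hs <- hotspots(p)
  nrep <- 60L
  counts <- integer(nrep)
  for (i in seq_len(nrep)) {
    sc <- simScenario(p, data.frame(chrom = hs$chrom, pos = hs$pos, ref = hs$ref,
                                    alt = hs$alt, vaf = 0.005),
                      seed = 1000L + i)
    counts[i] <- drawMolecules(sc)$truth$mutant_molecules
  }
  mu <- 0.005 * 6060
  se <- sqrt(6060 * 0.005 * 0.995 / nrep)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("with zero error rates every read equals its template", {
  p <- singleAmpliconPanel()
  hs <- hotspots(p)
  sc <- simScenario(p, data.frame(chrom = hs$chrom, pos = hs$pos, ref = hs$ref,
                                  alt = hs$alt, vaf = 0.2),
                    seed = 5L, input_mass_ng = 100 / 303,
                    seq_error_rate = 0, pcr_error_rate = 0)
  sim <- simulateReads(sc)
  r <- readsTable(sim$reads)
  tmpl <- sim$molecules$sequence[match(r$mol_id, sim$molecules$mol_id)]
  expect_equal(r$sequence, tmpl)
  expect_true(all(r$n_seq_errors == 0L))
})

test_that("full deamination converts every template cytosine", {
  p <- singleAmpliconPanel()
  # rates must be < 1; approximate the limit arbitrarily closely
  sc <- simScenario(p, seed = 2L, input_mass_ng = 10 / 303,
                    ffpe_deamination_rate = 1 - 1e-12,
                    seq_error_rate = 0, pcr_error_rate = 0)
  m <- drawMolecules(sc)
  expect_false(any(grepl("C", m$molecules$sequence)))
})

test_that("identical seeds reproduce bit-identical reads; different seeds differ", {
  p <- singleAmpliconPanel()
  sc <- simScenario(p, seed = 42L, input_mass_ng = 50 / 303)
  r1 <- readsTable(simulateReads(sc)$reads)
  r2 <- readsTable(simulateReads(sc)$reads)
  expect_identical(r1, r2)
  sc2 <- simScenario(p, seed = 43L, input_mass_ng = 50 / 303)
  r3 <- readsTable(simulateReads(sc2)$reads)
  expect_false(identical(r1$umt5, r3$umt5))
  # FASTQ output is bit-identical too
  f1 <- tempfile(); f2 <- tempfile()
  writeSimFastq(simulateReads(sc)$reads, p, f1)
  writeSimFastq(simulateReads(sc)$reads, p, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every molecule emits at least one read and UMT pairs stay distinct", {
  p <- singleAmpliconPanel()
  sc <- simScenario(p, seed = 8L, input_mass_ng = 500 / 303)
  sim <- simulateReads(sc)
  r <- readsTable(sim$reads)
  expect_equal(sort(unique(r$mol_id)), sort(sim$molecules$mol_id))
  pairs <- unique(paste(r$umt5, r$umt3))
  # collision probability is negligible at this scale; assert and thereby
  # check molecule-count conservation through the UMT key
  expect_equal(length(pairs), nrow(sim$molecules))
})

test_that("the dilution ladder matches the reference-standard design", {
  p <- egfrDilutionPanel()
  scs <- serialDilutionScenarios(p, seed = 3L)
  expect_length(scs, 6L)
  expect_equal(vapply(scs, function(s) unique(s@truth$vaf), numeric(1)),
               c(0.001, 0.0025, 0.005, 0.01, 0.025, 0.05))
  expect_true(all(vapply(scs, function(s) nrow(s@truth), integer(1)) == 8L))
  expect_true(all(vapply(scs, function(s) s@input_mass_ng, numeric(1)) == 20))
  expect_equal(vapply(scs, function(s) s@seed, integer(1)), 3L + 1:6)
})

test_that("truth VCF output is well-formed and round-trips", {
  skip_if_not_installed("VariantAnnotation")
  p <- egfrDilutionPanel()
  hs <- hotspots(p)
  truth <- data.frame(chrom = hs$chrom, pos = hs$pos, ref = hs$ref,
                      alt = hs$alt, vaf = 0.01, label = hs$label)
  f <- tempfile(fileext = ".vcf")
  writeTruth(truth, f)
  v <- VariantAnnotation::readVcf(f)
  expect_equal(nrow(v), 8L)
  expect_equal(sort(BiocGenerics::start(SummarizedExperiment::rowRanges(v))),
               sort(truth$pos))
  expect_equal(unique(unlist(VariantAnnotation::info(v)$TRUE_VAF)), 0.01)
  # empty truth -> header-only VCF
  f2 <- tempfile(fileext = ".vcf")
  writeTruth(truth[0, ], f2)
  expect_equal(nrow(VariantAnnotation::readVcf(f2)), 0L)
})

test_that("scenario validity rejects impossible settings", {
  p <- singleAmpliconPanel()
  hs <- hotspots(p)
  expect_error(simScenario(p, data.frame(chrom = hs$chrom, pos = hs$pos,
                                         ref = hs$ref, alt = hs$alt, vaf = 1.5),
                           seed = 1L), "VAF")
  expect_error(
    simScenario(p, rbind(
      data.frame(chrom = hs$chrom, pos = hs$pos, ref = hs$ref, alt = "C", vaf = 0.6),
      data.frame(chrom = hs$chrom, pos = hs$pos, ref = hs$ref, alt = "G", vaf = 0.6)),
      seed = 1L),
    "sum")
})
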