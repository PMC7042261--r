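## Evaluation: detection tables, VAF concordance, limit-of-detection
## ladders, and end-to-end pipeline conveniences.

#' Run the MB pipeline on a simulated scenario
#'
#' \code{\link{simulateReads}} then \code{\link{buildFamilies}} then
#' \code{\link{callVariants}}.
#'
#' @param scenario a \code{\linkS4class{SimScenario}}.
#' @param config an \code{\linkS4class{MBFilterConfig}}; its
#'   \code{min_family_size} is used for family construction.
#' @param context \code{"plasma"} or \code{"tumor"}.
#' @param restrictTo optional locus restriction (see
#'   \code{\link{callVariants}}).
#' @return List with \code{calls}, \code{families}, \code{truth}.
#' @export
runScenarioMB <- function(scenario, config = mbFilterConfig(),
                          context = "plasma", restrictTo = NULL) {
  sim <- simulateReads(scenario)
  fams <- buildFamilies(sim$reads, scenario@panel,
                        minFamilySize = config@min_family_size)
  calls <- callVariants(fams, config, context = context, restrictTo = restrictTo)
  list(calls = calls, families = fams, truth = sim$truth)
}

#' Run the conventional read-level pipeline on a simulated scenario
#'
#' Simulates the tumor/plasma scenario and a matched variant-free normal
#' (same panel and input, seed offset), tallies both at read level and
#' applies the conventional filter set.
#'
#' @param scenario a \code{\linkS4class{SimScenario}}.
#' @param config a \code{\linkS4class{NonMBFilterConfig}}.
#' @param normalScenario optional explicit normal scenario; by default the
#'   scenario with empty truth and seed + 500000.
#' @return List with \code{calls}, \code{tumorTally}, \code{truth}.
#' @export
runScenarioNonMB <- function(scenario, config = nonMBFilterConfig(),
                             normalScenario = NULL) {
  sim <- simulateReads(scenario)
  if (is.null(normalScenario)) {
    normalScenario <- scenario
    normalScenario@truth <- scenario@truth[0, , drop = FALSE]
    normalScenario@seed <- scenario@seed + 500000L
    normalScenario@sample_id <- paste0(scenario@sample_id, "_normal")
  }
  nsim <- simulateReads(normalScenario)
  tt <- rawTally(sim$reads, scenario@panel)
  nt <- rawTally(nsim$reads, scenario@panel)
  calls <- callRawVariants(tt, nt, config)
  list(calls = calls, tumorTally = tt, truth = sim$truth)
}

#' Detection table over a scenario ladder
#'
#' One row per truth variant, one column per expected-VAF level; cells hold
#' the observed VAF (percent, reporting precision) of the PASS call matching
#' the variant, or \code{"ND"} (not detected) when no PASS call matches.
#'
#' @param callsPerLevel named list of call data.frames (as returned by
#'   \code{\link{callVariants}}), one per ladder level; names become the
#'   column labels.
#' @param truth data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{label} -- the shared variant set of all levels.
#' @return Character matrix (variants x levels).
#' @export
detectionTable <- function(callsPerLevel, truth) {
  truth <- as.data.frame(truth)
  need <- c("chrom", "pos", "ref", "alt", "label")
  if (!all(need %in% names(truth)))
    .stopf("truth must have columns: %s", paste(need, collapse = ", "))
  if (is.null(names(callsPerLevel)))
    names(callsPerLevel) <- paste0("level", seq_along(callsPerLevel))
  tkey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt)
  if (anyDuplicated(tkey)) .stopf("duplicate variants in truth")
  out <- matrix("ND", nrow = nrow(truth), ncol = length(callsPerLevel),
                dimnames = list(truth$label, names(callsPerLevel)))
  for (j in seq_along(callsPerLevel)) {
    calls <- callsPerLevel[[j]]
    if (is.null(calls) || nrow(calls) == 0L) next
    pass <- calls[calls$status == "PASS", , drop = FALSE]
    if (nrow(pass) == 0L) next
    ckey <- paste(pass$chrom, pass$pos, pass$ref, pass$alt)
    hit <- match(tkey, ckey)
    found <- which(!is.na(hit))
    out[found, j] <- pass$vaf_percent[hit[found]]
  }
  out
}

#' VAF concordance between two methods
#'
#' Coefficient of determination R^2, computed as the squared Pearson
#' correlation of the paired VAFs of the two methods.
#'
#' @param vaf1,vaf2 paired VAF vectors (same loci, two methods).
#' @return List with \code{r2}, \code{n} and the paired data.
#' @examples
#' vafConcordance(c(0, 1), c(1, 0))$r2  # 1: perfect (negative) correlation
#' @export
vafConcordance <- function(vaf1, vaf2) {
  if (length(vaf1) != length(vaf2)) .stopf("paired VAF vectors differ in length")
  n <- length(vaf1)
  if (n < 2L) .stopf("concordance requires at least 2 pairs")
  if (stats::sd(vaf1) == 0 || stats::sd(vaf2) == 0)
    .stopf("concordance undefined for a constant VAF vector")
  r2 <- cor(vaf1, vaf2)^2
  list(r2 = r2, n = n,
       pairs = data.frame(vaf1 = vaf1, vaf2 = vaf2))
}

#' Limit-of-detection ladder
#'
#' Simulates replicate experiments of a spiked variant set at each VAF
#' level, runs the selected caller, and reports the per-level detection
#' frequency (fraction of replicates in which every truth variant has a
#' PASS call) and the limit of detection: the smallest VAF level with
#' detection frequency of at least 0.5.
#'
#' @param panel an \code{AmpliconPanel}.
#' @param variants data.frame (\code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{label}) to spike at each level.
#' @param vafLevels descending or ascending VAF fractions to test.
#' @param replicates seeded replicates per level.
#' @param seed base seed; replicate (i, j) uses \code{seed + 1000*i + j}.
#' @param caller \code{"mb"} or \code{"nonmb"}.
#' @param mbConfig,nonmbConfig filter configurations for the two callers.
#' @param context calling context for the MB caller.
#' @param ... scenario slot overrides (e.g. \code{input_mass_ng}) passed to
#'   \code{\link{simScenario}}.
#' @return List with \code{table} (data.frame \code{vaf}, \code{vaf_percent},
#'   \code{detection_frequency}) and \code{lod_percent} (NA when no level
#'   reaches 0.5).
#' @export
lodLadder <- function(panel, variants, vafLevels, replicates = 5L, seed = 1L,
                      caller = c("mb", "nonmb"), mbConfig = mbFilterConfig(),
                      nonmbConfig = nonMBFilterConfig(), context = "plasma",
                      ...) {
  caller <- match.arg(caller)
  stopifnot(replicates >= 1L)
  variants <- as.data.frame(variants)
  freq <- numeric(length(vafLevels))
  for (i in seq_along(vafLevels)) {
    hits <- logical(replicates)
    for (j in seq_len(replicates)) {
      truth <- data.frame(chrom = variants$chrom, pos = variants$pos,
                          ref = variants$ref, alt = variants$alt,
                          vaf = vafLevels[i], label = variants$label)
      sc <- simScenario(panel, truth, seed = seed + 1000L * i + j, ...)
      calls <- if (caller == "mb")
        runScenarioMB(sc, mbConfig, context = context)$calls
      else
        runScenarioNonMB(sc, nonmbConfig)$calls
      if (is.null(calls) || nrow(calls) == 0L) { hits[j] <- FALSE; next }
      pass <- calls[calls$status == "PASS", , drop = FALSE]
      ckey <- paste(pass$chrom, pass$pos, pass$ref, pass$alt)
      tkey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt)
      hits[j] <- all(tkey %in% ckey)
    }
    freq[i] <- mean(hits)
  }
  ord <- order(vafLevels)
  tab <- data.frame(vaf = vafLevels, vaf_percent = 100 * vafLevels,
                    detection_frequency = freq)[ord, ]
  rownames(tab) <- NULL
  det <- tab$vaf_percent[tab$detection_frequency >= 0.5]
  list(table = tab,
       lod_percent = if (length(det) > 0L) min(det) else NA_real_)
}

## --------------------------------------------------------------------------
## Filter configuration YAML I/O
## --------------------------------------------------------------------------

#' Read / write filter configurations as flat YAML
#'
#' The YAML mirrors the configuration slot names exactly.
#'
#' @param path YAML file path.
#' @return The configuration object.
#' @export
readMBFilterConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$common_snp_positions))
    vals$common_snp_positions <- as.character(vals$common_snp_positions)
  if (!is.null(vals$background_error_rate) &&
      is.list(vals$background_error_rate))
    vals$background_error_rate <- unlist(vals$background_error_rate)
  do.call(mbFilterConfig, vals)
}

#' @rdname readMBFilterConfig
#' @param config a configuration object.
#' @export
writeMBFilterConfig <- function(config, path) {
  vals <- lapply(slotNames(config), function(s) slot(config, s))
  names(vals) <- slotNames(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname readMBFilterConfig
#' @export
readNonMBFilterConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$common_snp_positions))
    vals$common_snp_positions <- as.character(vals$common_snp_positions)
  do.call(nonMBFilterConfig, vals)
}
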