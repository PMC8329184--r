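## Stage orchestration: each stage writes its module's TSV artifacts plus a
## JSON run manifest; runPipeline() chains them on synthetic data. The thin
## command-line front-end in inst/scripts/phewasmr maps these functions to
## subcommands with fixed exit codes.

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.writeManifest <- function(outDir, stage, params, files) {
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("phewasMR")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = params,
    outputs = lapply(files, function(f) {
      n <- tryCatch(length(readLines(f)) - 1L, error = function(e) NA_integer_)
      list(path = f, rows = n)
    }))
  path <- file.path(outDir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Chains simulate -> clump -> single-SNP PheWAS -> PRS PheWAS -> MR -> meta
#' on a synthetic dataset, writing every stage's TSV artifacts and JSON
#' manifests under `outDir`. The single master seed in `cfg` drives all
#' randomness; the cohort is split into two halves to exercise the
#' meta-analysis stage.
#'
#' @param cfg a [simConfig()].
#' @param outDir output directory (created if needed).
#' @param pSig,r2Threshold,windowKb,minCases,minCodeInstances,qSig pipeline
#'   thresholds; defaults are the conventional values (genome-wide
#'   significance 5e-8, clumping r2 < 0.05 within 1000 kb, >= 300 cases,
#'   >= 2 code instances, q < 0.05).
#' @return invisible list of the main in-memory results (cohort, scans,
#'   meta table, MR results).
#' @export
runPipeline <- function(cfg, outDir, pSig = 5e-8, r2Threshold = 0.05,
                        windowKb = 1000, minCases = 300,
                        minCodeInstances = 2, qSig = 0.05) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ## -- simulate ----------------------------------------------------------
  G <- simulateGenotypes(cfg)
  met <- simulateMetabolite(G, cfg)
  phe <- simulateDiseasesAndIcd(G, met$metabolite, met$confounder, cfg)
  ts <- simulateTwoSampleSumstats(cfg)
  .writeTsv(variantInfo(G), file.path(outDir, "variants.tsv"))
  .writeTsv(data.frame(person_id = personIds(G), t(dosages(G)),
                       check.names = FALSE),
            file.path(outDir, "dosages.tsv"))
  write.csv(phe$events, file.path(outDir, "icd_events.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(phe$pmap, file.path(outDir, "phecode_map.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(phe$demographics, file.path(outDir, "covariates.csv"),
            row.names = FALSE, quote = FALSE)
  writeSumstats(ts$exposure, file.path(outDir, "sumstats_exposure.tsv"))
  writeSumstats(ts$outcome, file.path(outDir, "sumstats_outcome.tsv"))
  .writeManifest(outDir, "simulate", list(seed = cfg$seed,
                 n_individuals = cfg$nIndividuals,
                 n_variants = cfg$nVariants, n_phecodes = cfg$nPhecodes),
                 file.path(outDir, c("dosages.tsv", "icd_events.csv",
                                     "phecode_map.csv", "covariates.csv",
                                     "sumstats_exposure.tsv",
                                     "sumstats_outcome.tsv")))
  ## -- instruments: in-cohort sumstats, significance filter, clump -------
  g <- t(dosages(G))
  assoc <- .simpleRegressions(g, met$metabolite)
  cohort_ss <- data.frame(variantInfo(G)[, c("variant_id", "chrom", "pos")],
                          ref_allele = variantInfo(G)$ref,
                          alt_allele = variantInfo(G)$alt,
                          effect_allele = variantInfo(G)$alt,
                          eaf = colMeans(g) / 2, beta = assoc$beta,
                          se = assoc$se,
                          p = pmax(assoc$p, .Machine$double.xmin),
                          n = nrow(g), info = NA_real_,
                          stringsAsFactors = FALSE)
  sig <- significanceFilter(cohort_ss, pSig)
  instruments <- if (nrow(sig)) {
    cl <- clumpVariants(sig, G, r2Threshold = r2Threshold,
                        windowKb = windowKb)
    .writeTsv(as.data.frame(cl), file.path(outDir, "clump.tsv"))
    indexVariants(cl)
  } else character(0)
  .writeManifest(outDir, "clump",
                 list(p_sig = pSig, r2 = r2Threshold, window_kb = windowKb,
                      n_significant = nrow(sig),
                      n_index = length(instruments)),
                 if (nrow(sig)) file.path(outDir, "clump.tsv") else list())
  ## -- phenome -----------------------------------------------------------
  counts <- mapEventsToPhecodes(phe$events, phe$pmap)
  cohort <- buildCohort(counts$counts, phe$pmap, phe$demographics,
                        minCases = minCases,
                        minCodeInstances = minCodeInstances)
  ## -- single-SNP PheWAS (strongest instrument, or strongest variant) ----
  snp <- if (length(instruments)) instruments[1L] else
    cohort_ss$variant_id[which.min(cohort_ss$p)]
  dose <- dosages(G)[snp, ]
  scan_snp <- addFdr(phewasScan(cohort, encodeGenotype(dose, "additive"),
                                predictorName = snp))
  .writeTsv(scan_snp, file.path(outDir, "phewas_single_snp.tsv"))
  ## -- PRS PheWAS --------------------------------------------------------
  wvars <- if (length(instruments)) instruments else cohort_ss$variant_id
  weights <- data.frame(variant_id = wvars,
                        effect_allele = cohort_ss$effect_allele[
                          match(wvars, cohort_ss$variant_id)],
                        beta = cohort_ss$beta[
                          match(wvars, cohort_ss$variant_id)],
                        stringsAsFactors = FALSE)
  prs <- computePrs(G, weights)
  scan_prs <- addFdr(phewasScan(cohort, prs$standardized,
                                predictorName = "PRS"))
  .writeTsv(scan_prs, file.path(outDir, "phewas_prs.tsv"))
  .writeManifest(outDir, "phewas",
                 list(snp = snp, n_prs_weights = nrow(weights),
                      min_cases = minCases,
                      min_code_instances = minCodeInstances,
                      n_retained = length(retainedPhecodes(cohort))),
                 file.path(outDir, c("phewas_single_snp.tsv",
                                     "phewas_prs.tsv")))
  ## -- MR on the simulated two-sample pair ------------------------------
  fwd_inst <- significanceFilter(ts$exposure, pSig)$variant_id
  rev_inst <- significanceFilter(ts$outcome, pSig)$variant_id
  mr <- bidirectionalMr(ts$exposure, ts$outcome, fwd_inst, rev_inst,
                        seed = stageSeed(cfg$seed, "mr_boot"))
  mr_tab <- do.call(rbind, Filter(Negate(is.null), mr))
  if (!is.null(mr_tab)) .writeTsv(mr_tab, file.path(outDir, "mr.tsv"))
  .writeManifest(outDir, "mr",
                 list(n_fwd_instruments = length(fwd_inst),
                      n_rev_instruments = length(rev_inst)),
                 if (!is.null(mr_tab)) file.path(outDir, "mr.tsv") else list())
  ## -- meta: split the cohort into two halves and recombine -------------
  persons <- personIds(G)
  half <- seq_len(floor(length(persons) / 2))
  mkHalf <- function(idx) {
    dem <- phe$demographics[idx, , drop = FALSE]
    ev <- phe$events[phe$events$person_id %in% dem$person_id, , drop = FALSE]
    cts <- mapEventsToPhecodes(ev, phe$pmap)
    buildCohort(cts$counts, phe$pmap, dem,
                minCases = max(1, floor(minCases / 2)),
                minCodeInstances = minCodeInstances)
  }
  ch1 <- mkHalf(half); ch2 <- mkHalf(setdiff(seq_along(persons), half))
  s1 <- phewasScan(ch1, encodeGenotype(dose, "additive"), predictorName = snp)
  s2 <- phewasScan(ch2, encodeGenotype(dose, "additive"), predictorName = snp)
  meta <- metaScan(list(cohort1 = s1, cohort2 = s2))
  if (!is.null(meta)) .writeTsv(meta, file.path(outDir, "meta.tsv"))
  .writeManifest(outDir, "meta", list(scheme = "samplesize", q_sig = qSig),
                 if (!is.null(meta)) file.path(outDir, "meta.tsv") else list())
  invisible(list(genotypes = G, cohort = cohort, instruments = instruments,
                 scan_snp = scan_snp, scan_prs = scan_prs, mr = mr,
                 meta = meta))
}
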