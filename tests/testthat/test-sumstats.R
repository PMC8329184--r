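test_that("the published kynurenine lead SNPs read back exactly as printed", {
  ss <- readSumstats(leadSnpPath())
  expect_equal(nrow(ss), 6L)
  r <- ss[ss$variant_id == "rs3184504", ]
  expect_equal(r$chrom, "12")
  expect_equal(r$pos, 111884608L)
  expect_equal(r$ref_allele, "T")
  expect_equal(r$alt_allele, "C")
  expect_equal(r$eaf, 0.48)
  expect_equal(r$beta, 0.015)
  expect_equal(r$se, 0.002)
  expect_equal(r$p, 6.046e-18)
})

test_that("reading handles column maps, empty tables, and bad rows", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  ## renamed columns resolved through the map
  raw <- read.delim(leadSnpPath())
  names(raw)[names(raw) == "variant_id"] <- "rsid"
  names(raw)[names(raw) == "p"] <- "pval"
  write.table(raw, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- readSumstats(tmp, columnMap = c(variant = "rsid", p = "pval"))
  expect_equal(ss$variant_id[3], "rs3184504")
  ## header-only file -> empty result
  writeLines(paste(names(read.delim(leadSnpPath())), collapse = "\t"), tmp)
  expect_equal(nrow(readSumstats(tmp)), 0L)
  ## missing required column -> configuration error
  write.table(raw[, setdiff(names(raw), "se")], tmp, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readSumstats(tmp, columnMap = c(variant = "rsid", p = "pval")),
               class = "phewasMR_config_error")
  ## se = 0 row -> row-level validation error naming the row
  bad <- makeSumstats(2)
  bad$se[2] <- 0
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSumstats(tmp), "snp02",
               class = "phewasMR_validation_error")
})

test_that("round-tripping a sumstats table preserves every record", {
  ss <- readSumstats(leadSnpPath())
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeSumstats(ss, tmp)
  expect_equal(readSumstats(tmp), ss)
})

test_that("flipping to the other allele negates beta and complements eaf", {
  rec <- makeSumstats(variant_id = "rs3184504", chrom = "12",
                      pos = 111884608L, ref = "T", alt = "C", effect = "T",
                      eaf = 0.48, beta = 0.015, se = 0.002, p = 6.046e-18)
  fl <- flipToEffectAllele(rec, "C")
  expect_equal(fl$beta, -0.015)
  expect_equal(fl$eaf, 0.52)
  expect_equal(fl$effect_allele, "C")
  expect_equal(fl$se, rec$se)
  expect_equal(fl$p, rec$p)
  ## identity and involution
  expect_equal(flipToEffectAllele(rec, "T"), rec)
  expect_equal(flipToEffectAllele(fl, "T"), rec)
  expect_error(flipToEffectAllele(rec, "G"), class = "phewasMR_data_error")
})

test_that("flip is an involution preserving |beta|, se and p on random records", {
  set.seed(11)
  for (i in 1:20) {
    alleles <- sample(c("A", "C", "G", "T"), 2)
    rec <- makeSumstats(ref = alleles[1], alt = alleles[2],
                        effect = sample(alleles, 1), eaf = runif(1, .05, .95),
                        beta = rnorm(1), se = runif(1, .01, 1),
                        p = runif(1, 1e-10, 1))
    other <- setdiff(alleles, rec$effect_allele)
    once <- flipToEffectAllele(rec, other)
    expect_equal(abs(once$beta), abs(rec$beta))
    expect_equal(once$se, rec$se)
    expect_equal(once$p, rec$p)
    expect_equal(flipToEffectAllele(once, rec$effect_allele), rec)
  }
})

test_that("harmonization flips, strand-recodes, intersects and drops palindromes", {
  expo <- makeSumstats(4, variant_id = c("v1", "v2", "v3", "v4"),
                       ref = c("T", "A", "A", "C"), alt = c("C", "T", "G", "G"),
                       effect = c("T", "A", "A", "C"),
                       eaf = c(0.48, 0.10, 0.30, 0.50),
                       beta = c(0.015, 0.08, 0.05, 0.03))
  ## v1: plain flip; v2: palindromic, low MAF both -> kept; v3: reported on
  ## the opposite strand (T/C complements A/G); v4: palindromic, eaf 0.50 ->
  ## dropped; v5: exposure-only
  outc <- makeSumstats(4, variant_id = c("v1", "v2", "v3", "v4"),
                       ref = c("T", "A", "T", "C"), alt = c("C", "T", "C", "G"),
                       effect = c("C", "T", "T", "C"),
                       eaf = c(0.52, 0.92, 0.70, 0.50),
                       beta = c(-0.20, -0.10, 0.07, 0.02))
  expo5 <- rbind(expo, makeSumstats(variant_id = "v5", pos = 9000L))
  h <- harmonizePair(expo5, outc)
  expect_setequal(h$pairs$variant_id, c("v1", "v2", "v3"))
  expect_false("v5" %in% c(h$pairs$variant_id, h$dropped$variant_id))
  expect_equal(h$dropped$reason[h$dropped$variant_id == "v4"],
               "palindromic_ambiguous_maf")
  p1 <- h$pairs[h$pairs$variant_id == "v1", ]
  expect_equal(p1$beta_outcome, 0.20)  # outcome was on C, flipped to T
  p2 <- h$pairs[h$pairs$variant_id == "v2", ]
  expect_equal(p2$beta_outcome, 0.10)  # outcome effect T at eaf .92 -> A at .08
  p3 <- h$pairs[h$pairs$variant_id == "v3", ]
  expect_equal(p3$beta_outcome, 0.07)  # strand recode: T->A, effect matches
  expect_true(all(h$pairs$effect_allele == "A" | h$pairs$effect_allele == "T" |
                  h$pairs$effect_allele == "C"))
})

test_that("harmonization drops palindromes with missing frequency", {
  expo <- makeSumstats(variant_id = "v1", ref = "A", alt = "T", effect = "A",
                       eaf = NA_real_)
  outc <- makeSumstats(variant_id = "v1", ref = "A", alt = "T", effect = "A",
                       eaf = 0.1)
  h <- harmonizePair(expo, outc)
  expect_equal(nrow(h$pairs), 0L)
  expect_equal(h$dropped$reason, "palindromic_missing_eaf")
  ## non-palindromic with missing eaf is kept: letters fix the orientation
  expo2 <- makeSumstats(variant_id = "v1", eaf = NA_real_)
  outc2 <- makeSumstats(variant_id = "v1", eaf = NA_real_)
  expect_equal(nrow(harmonizePair(expo2, outc2)$pairs), 1L)
})

test_that("harmonized output is bounded by the intersection with aligned alleles", {
  set.seed(4)
  expo <- makeSumstats(8, eaf = runif(8, .1, .4))
  outc <- makeSumstats(5, eaf = runif(5, .1, .4))
  ## randomly flip some outcome rows to their alt representation
  flip <- c(1, 3)
  outc[flip, ] <- flipToEffectAllele(outc[flip, ], outc$ref_allele[flip])
  h <- harmonizePair(expo, outc)
  expect_lte(nrow(h$pairs), min(nrow(expo), nrow(outc)))
  expect_equal(h$pairs$effect_allele,
               expo$effect_allele[match(h$pairs$variant_id, expo$variant_id)])
})
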