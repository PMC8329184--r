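test_that("generators are fully deterministic given the configuration", {
  cfg <- simConfig(seed = 5, nIndividuals = 300, nPhecodes = 4)
  g1 <- simulateGenotypes(cfg); g2 <- simulateGenotypes(cfg)
  expect_identical(dosages(g1), dosages(g2))
  m1 <- simulateMetabolite(g1, cfg); m2 <- simulateMetabolite(g2, cfg)
  expect_identical(m1, m2)
  d1 <- simulateDiseasesAndIcd(g1, m1$metabolite, m1$confounder, cfg)
  d2 <- simulateDiseasesAndIcd(g2, m2$metabolite, m2$confounder, cfg)
  expect_identical(d1, d2)
  t1 <- simulateTwoSampleSumstats(cfg); t2 <- simulateTwoSampleSumstats(cfg)
  expect_identical(t1, t2)
  ## a different seed changes the draw
  cfgB <- simConfig(seed = 6, nIndividuals = 300, nPhecodes = 4)
  expect_false(identical(dosages(g1), dosages(simulateGenotypes(cfgB))))
  expect_error(simConfig(), class = "phewasMR_config_error")
})

test_that("genotypes respect Hardy-Weinberg and the configured LD structure", {
  ## single variant at frequency 0.5: genotype frequencies near (.25,.5,.25)
  cfg1 <- simConfig(seed = 13, nIndividuals = 20000, nVariants = 1,
                    ldBlocks = list(c(1, 0)), alleleFreqs = 0.5,
                    metaboliteEffects = 0.1)
  d <- dosages(simulateGenotypes(cfg1))
  frq <- table(factor(d, levels = 0:2)) / length(d)
  expect_true(all(abs(frq - c(0.25, 0.5, 0.25)) < 0.015))
  ## independent variants: negligible LD
  cfg0 <- simConfig(seed = 14, nIndividuals = 20000, nVariants = 4,
                    ldBlocks = lapply(1:4, function(i) c(1, 0)),
                    alleleFreqs = c(0.2, 0.4, 0.5, 0.3),
                    metaboliteEffects = 0.1)
  d0 <- dosages(simulateGenotypes(cfg0))
  for (i in 1:3) expect_lt(ldR2(d0[i, ], d0[i + 1, ]), 0.01)
  ## near-perfect within-block correlation survives thresholding
  cfg9 <- simConfig(seed = 15, nIndividuals = 5000, nVariants = 2,
                    ldBlocks = list(c(2, 0.99)), alleleFreqs = c(0.4, 0.4),
                    metaboliteEffects = 0.1)
  d9 <- dosages(simulateGenotypes(cfg9))
  expect_gt(ldR2(d9[1, ], d9[2, ]), 0.9)
  ## monotone: higher rho gives higher r2
  cfg5 <- simConfig(seed = 15, nIndividuals = 5000, nVariants = 2,
                    ldBlocks = list(c(2, 0.5)), alleleFreqs = c(0.4, 0.4),
                    metaboliteEffects = 0.1)
  d5 <- dosages(simulateGenotypes(cfg5))
  expect_lt(ldR2(d5[1, ], d5[2, ]), ldR2(d9[1, ], d9[2, ]))
})

test_that("the metabolite model has unit variance, no-signal normality and recoverable effects", {
  ## pure noise: standard normal
  cfg0 <- simConfig(seed = 23, nIndividuals = 10000, nVariants = 2,
                    ldBlocks = list(c(2, 0)), alleleFreqs = c(0.3, 0.4),
                    metaboliteEffects = 0,
                    confounderEffect = c(metabolite = 0, disease = 0))
  G0 <- simulateGenotypes(cfg0)
  y0 <- simulateMetabolite(G0, cfg0)$metabolite
  expect_gt(stats::ks.test(y0, "pnorm")$p.value, 1e-3)
  ## single effect recovered by regression
  cfg1 <- simConfig(seed = 24, nIndividuals = 8000, nVariants = 1,
                    ldBlocks = list(c(1, 0)), alleleFreqs = 0.3,
                    metaboliteEffects = 0.2,
                    confounderEffect = c(metabolite = 0, disease = 0))
  G1 <- simulateGenotypes(cfg1)
  y1 <- simulateMetabolite(G1, cfg1)$metabolite
  fit <- linearFit(y1, cbind(1, g = dosages(G1)[1, ]))
  expect_lt(abs(fit$coefficients["g"] - 0.2), 3 * fit$se["g"])
  ## variance decomposition: empirical genetic variance matches 2f(1-f)gamma^2
  cfgV <- simConfig(seed = 25, nIndividuals = 20000, nVariants = 3,
                    ldBlocks = lapply(1:3, function(i) c(1, 0)),
                    alleleFreqs = c(0.2, 0.4, 0.5),
                    metaboliteEffects = c(0.1, 0.15, 0.2),
                    confounderEffect = c(metabolite = 0, disease = 0))
  GV <- simulateGenotypes(cfgV)
  g <- t(dosages(GV))
  genval <- drop(g %*% cfgV$metaboliteEffects)
  theo <- sum(2 * cfgV$alleleFreqs * (1 - cfgV$alleleFreqs) *
              cfgV$metaboliteEffects^2)
  expect_equal(var(genval), theo, tolerance = 0.1)
  yV <- simulateMetabolite(GV, cfgV)$metabolite
  expect_equal(var(yV), 1, tolerance = 0.05)
})

test_that("disease generation hits base rates, responds to the metabolite and writes valid events", {
  cfg <- simConfig(seed = 33, nIndividuals = 10000, nPhecodes = 3,
                   diseaseBaseRates = 0.05, causalEffect = c(0.4, 0, 0),
                   confounderEffect = c(metabolite = 0, disease = 0))
  G <- simulateGenotypes(cfg)
  met <- simulateMetabolite(G, cfg)
  phe <- simulateDiseasesAndIcd(G, met$metabolite, met$confounder, cfg)
  ## null disease at base rate 0.05: case count within binomial tolerance
  n2 <- sum(phe$disease[, 2])
  expect_lt(abs(n2 - 500), 4 * sqrt(10000 * 0.05 * 0.95))
  ## causal disease: prevalence increases monotonically with metabolite quartile
  qr <- cut(met$metabolite, quantile(met$metabolite, 0:4 / 4),
            include.lowest = TRUE, labels = FALSE)
  prev <- tapply(phe$disease[, 1], qr, mean)
  expect_true(all(diff(prev) > 0))
  ## every true case has >= 2 distinct event dates for its phecode
  counts <- mapEventsToPhecodes(phe$events, phe$pmap)$counts
  cases1 <- rownames(phe$disease)[phe$disease[, 1] == 1]
  got <- counts[counts$phecode == "10", ]
  expect_setequal(got$person_id, cases1)
  expect_true(all(got$n_instances >= 2))
  ## noise codes are unmapped and cannot create case status
  expect_true(all(mapEventsToPhecodes(phe$events,
                                      phe$pmap)$unmapped$code %in%
                  sprintf("R%02d.9", 1:20)))
})

test_that("two-sample summary statistics carry honest SEs and the configured truth", {
  cfg <- simConfig(seed = 55, nIndividuals = 2000, nVariants = 10,
                   ldBlocks = lapply(1:10, function(i) c(1, 0)),
                   alleleFreqs = rep(0.3, 10),
                   metaboliteEffects = rep(0.12, 10), causalEffect = 0.25)
  ts <- simulateTwoSampleSumstats(cfg)
  expect_equal(ts$theta, 0.25)
  validateSumstats(ts$exposure)
  validateSumstats(ts$outcome)
  ## SE calibration: mean reported SE tracks the spread of betas across reps
  reps <- lapply(1:40, function(i) {
    c2 <- simConfig(seed = 1000 + i, nIndividuals = 2000, nVariants = 10,
                    ldBlocks = lapply(1:10, function(i) c(1, 0)),
                    alleleFreqs = rep(0.3, 10),
                    metaboliteEffects = rep(0.12, 10), causalEffect = 0.25)
    simulateTwoSampleSumstats(c2)$exposure$beta
  })
  betas <- do.call(rbind, reps)
  empSd <- mean(apply(betas, 2, sd))
  expect_lt(abs(mean(ts$exposure$se) - empSd) / empSd, 0.10)
})
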