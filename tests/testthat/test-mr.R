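test_that("the Wald ratio follows its definition and orientation invariance", {
  r <- waldRatio(0.1, 0.02, 0.02, 0.01)
  expect_equal(r$estimate, 0.2)
  expect_equal(r$se, 0.1)
  expect_equal(waldRatio(0.1, 0.02, 0, 0.01)$estimate, 0)
  rf <- waldRatio(-0.1, 0.02, -0.02, 0.01)
  expect_equal(rf$estimate, r$estimate)
  expect_error(waldRatio(0, 0.02, 0.02, 0.01), class = "phewasMR_data_error")
})

test_that("IVW equals the zero-intercept WLS closed form and reduces to Wald", {
  one <- mrInput(bx = 0.1, sx = 0.02, by = 0.02, sy = 0.01)
  expect_equal(mrIvw(one)$estimate, waldRatio(0.1, 0.02, 0.02, 0.01)$estimate)
  expect_equal(mrIvw(one)$se, waldRatio(0.1, 0.02, 0.02, 0.01)$se)
  ## the three-variant fixture against the matrix-algebra oracle
  inp <- mrInput(bx = c(0.1, 0.2, 0.15), sx = rep(0.02, 3),
                 by = c(0.025, 0.038, 0.031), sy = c(0.01, 0.01, 0.02))
  res <- mrIvw(inp)
  orc <- oracleWlsNoIntercept(inp@bx, inp@by, 1 / inp@sy^2)
  expect_equal(res$estimate, orc$estimate, tolerance = 1e-10)
  expect_equal(res$se, orc$se, tolerance = 1e-10)
  ## random inputs: agreement to 1e-10
  set.seed(71)
  for (i in 1:10) {
    m <- sample(2:30, 1)
    inp <- mrInput(bx = rnorm(m, 0.1, 0.05), sx = runif(m, .01, .05),
                   by = rnorm(m, 0.02, 0.02), sy = runif(m, .005, .05))
    res <- mrIvw(inp)
    orc <- oracleWlsNoIntercept(inp@bx, inp@by, 1 / inp@sy^2)
    expect_equal(res$estimate, orc$estimate, tolerance = 1e-10)
    expect_equal(res$se, orc$se, tolerance = 1e-10)
  }
})

test_that("perfectly proportional effects give the shared ratio with zero heterogeneity", {
  bx <- c(0.1, 0.2, 0.4)
  inp <- mrInput(bx = bx, sx = rep(0.01, 3), by = 0.3 * bx,
                 sy = rep(0.01, 3))
  res <- mrIvw(inp)
  expect_equal(res$estimate, 0.3, tolerance = 1e-12)
  expect_equal(res$Q, 0, tolerance = 1e-12)
})

test_that("estimators are invariant to joint sign flips of instrument effects", {
  set.seed(72)
  m <- 8
  inp <- mrInput(bx = runif(m, 0.05, 0.2), sx = runif(m, .01, .03),
                 by = rnorm(m, 0.03, 0.01), sy = runif(m, .01, .03))
  flip <- sample(c(-1, 1), m, replace = TRUE)
  inpF <- mrInput(bx = inp@bx * flip, sx = inp@sx, by = inp@by * flip,
                  sy = inp@sy)
  expect_equal(mrIvw(inpF)$estimate, mrIvw(inp)$estimate, tolerance = 1e-12)
  expect_equal(mrEgger(inpF)$estimate, mrEgger(inp)$estimate,
               tolerance = 1e-12)
  expect_equal(mrWeightedMedian(inpF, seed = 5)$estimate,
               mrWeightedMedian(inp, seed = 5)$estimate, tolerance = 1e-12)
})

test_that("Egger recovers exact affine relationships between effect sizes", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  sy <- c(0.01, 0.012, 0.02, 0.015, 0.01)
  ## pure proportionality: slope theta, intercept 0
  pure <- mrInput(bx = bx, sx = rep(.01, 5), by = 0.25 * bx, sy = sy)
  rp <- mrEgger(pure)
  expect_equal(rp$estimate, 0.25, tolerance = 1e-10)
  expect_equal(rp$intercept, 0, tolerance = 1e-10)
  ## affine: intercept alpha, slope theta
  aff <- mrInput(bx = bx, sx = rep(.01, 5), by = 0.04 + 0.25 * bx, sy = sy)
  ra <- mrEgger(aff)
  expect_equal(ra$estimate, 0.25, tolerance = 1e-10)
  expect_equal(ra$intercept, 0.04, tolerance = 1e-10)
  expect_error(mrEgger(mrInput(bx = bx[1:2], sx = rep(.01, 2),
                               by = bx[1:2], sy = sy[1:2])),
               class = "phewasMR_data_error")
})

test_that("the weighted median reduces to the middle ratio under equal weights", {
  ## ratios 1, 2, 9 with equal weights: percentile 0.5 hits the middle
  inp <- mrInput(bx = c(0.1, 0.1, 0.1), sx = rep(.01, 3),
                 by = c(0.1, 0.2, 0.9), sy = rep(.01, 3))
  expect_equal(mrWeightedMedian(inp, seed = 2)$estimate, 2)
  ## identical ratios: estimate c with a small bootstrap SE
  c_inp <- mrInput(bx = c(0.1, 0.2, 0.3), sx = rep(.001, 3),
                   by = 0.4 * c(0.1, 0.2, 0.3), sy = rep(.001, 3))
  wm <- mrWeightedMedian(c_inp, seed = 2)
  expect_equal(wm$estimate, 0.4, tolerance = 1e-10)
  expect_lt(wm$se, 0.05)
  expect_error(mrWeightedMedian(inp, nBoot = 10), class = "phewasMR_config_error")
})

test_that("Cochran's Q is zero only for identical ratios and grows with discordance", {
  bx <- c(0.1, 0.2, 0.3)
  homog <- mrInput(bx = bx, sx = rep(.01, 3), by = 0.2 * bx, sy = rep(.01, 3))
  expect_equal(mrIvw(homog)$Q, 0, tolerance = 1e-12)
  hetero <- mrInput(bx = bx, sx = rep(.01, 3),
                    by = 0.2 * bx + c(0.05, -0.05, 0), sy = rep(.01, 3))
  expect_gt(mrIvw(hetero)$Q, 0)
})

test_that("bidirectional MR on identical studies with self-instruments is the identity", {
  ss <- makeSumstats(5, beta = runif(5, 0.05, 0.2), se = 0.01,
                     eaf = runif(5, .1, .4))
  res <- bidirectionalMr(ss, ss, ss$variant_id, ss$variant_id, seed = 3)
  expect_equal(res$forward$estimate[res$forward$method == "ivw"], 1,
               tolerance = 1e-10)
  expect_equal(res$reverse$estimate[res$reverse$method == "ivw"], 1,
               tolerance = 1e-10)
  ## empty instrument set: direction skipped with a warning
  expect_warning(r2 <- bidirectionalMr(ss, ss, character(0), ss$variant_id,
                                       seed = 3),
                 "skipped")
  expect_null(r2$forward)
})

test_that("pure forward causation yields a forward signal and a null reverse estimate", {
  cfg <- simConfig(seed = 44, nIndividuals = 4000, nVariants = 12,
                   ldBlocks = lapply(1:12, function(i) c(1, 0)),
                   alleleFreqs = rep(0.3, 12),
                   metaboliteEffects = rep(0.15, 12), causalEffect = 0.3,
                   confounderEffect = c(metabolite = 0.2, disease = 0.2))
  ts <- simulateTwoSampleSumstats(cfg)
  fwd <- significanceFilter(ts$exposure, 5e-8)$variant_id
  rev <- significanceFilter(ts$outcome, 5e-8)$variant_id
  expect_gt(length(fwd), 0)
  res <- suppressWarnings(
    bidirectionalMr(ts$exposure, ts$outcome, fwd, rev, seed = 6))
  fivw <- res$forward[res$forward$method == "ivw", ]
  expect_lt(abs(fivw$estimate - 0.3), 3 * fivw$se)
})

test_that("shared confounding alone does not move the IVW estimate off zero", {
  cfg <- simConfig(seed = 45, nIndividuals = 4000, nVariants = 12,
                   ldBlocks = lapply(1:12, function(i) c(1, 0)),
                   alleleFreqs = rep(0.3, 12),
                   metaboliteEffects = rep(0.15, 12), causalEffect = 0,
                   confounderEffect = c(metabolite = 0.4, disease = 0.4))
  ts <- simulateTwoSampleSumstats(cfg)
  fwd <- significanceFilter(ts$exposure, 5e-8)$variant_id
  res <- mrIvw(asMRInput(harmonizePair(
    ts$exposure[ts$exposure$variant_id %in% fwd, ], ts$outcome)$pairs))
  expect_lt(abs(res$estimate), 3 * res$se)
})
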