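## Synthetic-data generator: LD-block genotypes, a heritable quantitative
## metabolite, binary diseases under a configurable causal graph
## (metabolite -> disease, per-variant horizontal pleiotropy, shared
## confounding), ICD event streams consistent with case status, and
## two-sample summary statistics with a known causal effect. Every generator
## is deterministic given the configuration seed, and every pipeline stage
## has a ground truth here.

#' Simulation configuration
#'
#' Bundles every generative parameter with a mandatory seed. The defaults
#' mirror the published kynurenine instrument architecture: six variants in
#' four LD blocks at the published effect-allele frequencies, with the
#' published per-allele metabolite effects (trait SD units).
#'
#' @param seed integer seed; mandatory, all generators derive their RNG
#'   streams from it.
#' @param nIndividuals cohort size (default 5000).
#' @param nVariants number of variants (default 6).
#' @param ldBlocks list of `c(size, rho)` pairs partitioning the variants
#'   into LD blocks with AR(rho) within-block correlation between adjacent
#'   allele indicators (the haplotype-scale LD coefficient r); sizes must
#'   sum to `nVariants`.
#' @param alleleFreqs per-variant effect (alt) allele frequencies in
#'   (0.01, 0.99).
#' @param metaboliteEffects per-allele effects on the metabolite, SD units.
#' @param confounderEffect named vector `c(metabolite=, disease=)`: effect of
#'   the shared confounder on the metabolite (SD units) and on disease
#'   liability (log-odds).
#' @param causalEffect log-odds change in disease per SD metabolite
#'   (recycled across diseases; 0 = null).
#' @param pleiotropy list `(mu, sigma, fracInvalid)`: direct variant->outcome
#'   effects for the invalid fraction of instruments, drawn N(mu, sigma).
#' @param pleiotropyMatrix optional nVariants x nPhecodes matrix of direct
#'   variant->disease log-odds effects, overriding `pleiotropy` for the
#'   disease simulator.
#' @param diseaseBaseRates baseline disease probability at covariate zero
#'   (recycled across diseases, default 0.05).
#' @param nPhecodes number of diseases/phecodes in the phenome (default 20).
#' @param icdNoiseRate Poisson mean of unrelated (unmapped) noise codes
#'   emitted per person (default 1).
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(seed,
                      nIndividuals = 5000L,
                      nVariants = 6L,
                      ldBlocks = list(c(1, 0), c(1, 0), c(2, 0.5), c(2, 0.5)),
                      alleleFreqs = c(0.37, 0.02, 0.48, 0.43, 0.64, 0.21),
                      metaboliteEffects = c(-0.010, 0.081, 0.015, 0.012,
                                            0.014, 0.026),
                      confounderEffect = c(metabolite = 0.3, disease = 0.3),
                      causalEffect = 0.2,
                      pleiotropy = list(mu = 0, sigma = 0, fracInvalid = 0),
                      pleiotropyMatrix = NULL,
                      diseaseBaseRates = 0.05,
                      nPhecodes = 20L,
                      icdNoiseRate = 1) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    .configError("seed is mandatory")
  cfg <- list(seed = as.integer(seed),
              nIndividuals = as.integer(nIndividuals),
              nVariants = as.integer(nVariants),
              ldBlocks = ldBlocks,
              alleleFreqs = rep_len(alleleFreqs, nVariants),
              metaboliteEffects = rep_len(metaboliteEffects, nVariants),
              confounderEffect = confounderEffect,
              causalEffect = causalEffect,
              pleiotropy = pleiotropy,
              pleiotropyMatrix = pleiotropyMatrix,
              diseaseBaseRates = rep_len(diseaseBaseRates, nPhecodes),
              nPhecodes = as.integer(nPhecodes),
              icdNoiseRate = icdNoiseRate)
  sizes <- vapply(cfg$ldBlocks, `[`, 0, 1L)
  rhos <- vapply(cfg$ldBlocks, `[`, 0, 2L)
  if (sum(sizes) != cfg$nVariants)
    .configError("ldBlocks sizes must sum to nVariants")
  if (any(rhos < 0 | rhos >= 1))
    .configError("LD correlations must lie in [0, 1)")
  if (any(cfg$alleleFreqs <= 0.01 | cfg$alleleFreqs >= 0.99))
    .configError("allele frequencies must lie in (0.01, 0.99)")
  if (any(cfg$diseaseBaseRates <= 0 | cfg$diseaseBaseRates >= 1))
    .configError("disease base rates must lie in (0, 1)")
  if (!is.null(cfg$pleiotropyMatrix) &&
      !all(dim(cfg$pleiotropyMatrix) == c(cfg$nVariants, cfg$nPhecodes)))
    .configError("pleiotropyMatrix must be nVariants x nPhecodes")
  class(cfg) <- "SimConfig"
  cfg
}

## P(Z1 < q1, Z2 < q2) for a bivariate standard normal with correlation r,
## by 1-D quadrature (no external dependency needed at this accuracy).
.binormCdf <- function(q1, q2, r) {
  if (abs(r) < 1e-12) return(pnorm(q1) * pnorm(q2))
  f <- function(z) pnorm((q2 - r * z) / sqrt(1 - r^2)) * stats::dnorm(z)
  stats::integrate(f, -8, q1, rel.tol = 1e-10)$value
}

## Latent correlation that yields the target correlation between the two
## thresholded allele indicators (tetrachoric-style inversion). Keeping the
## configured rho on the allele scale makes the block's LD interpretable as
## genotype r.
.latentRho <- function(targetRho, f1, f2) {
  if (targetRho <= 0) return(targetRho)
  q1 <- qnorm(f1); q2 <- qnorm(f2)
  sd12 <- sqrt(f1 * (1 - f1) * f2 * (1 - f2))
  g <- function(r) (.binormCdf(q1, q2, r) - f1 * f2) / sd12 - targetRho
  if (g(0.99999) < 0) return(0.99999)
  stats::uniroot(g, c(0, 0.99999), tol = 1e-8)$root
}

## AR(rho) correlation Cholesky per block, on the latent scale
.blockChol <- function(size, rho, freqs) {
  if (size == 1L) return(matrix(1))
  rl <- .latentRho(rho, mean(freqs), mean(freqs))
  C <- rl^abs(outer(seq_len(size), seq_len(size), "-"))
  chol(C)
}

#' Simulate LD-block genotypes
#'
#' Draws two haplotypes per person by thresholding a latent multivariate
#' normal with block-diagonal AR correlation at each variant's allele
#' frequency quantile; the dosage is the haplotype sum, so every variant is
#' in Hardy-Weinberg equilibrium marginally. The latent correlation is
#' pre-adjusted by a tetrachoric-style inversion so that the configured rho
#' is realized between adjacent allele indicators after thresholding (i.e.
#' on the LD r scale). Blocks are placed 10 Mb apart on one chromosome
#' (variants 5 kb apart within a block), so default clumping windows separate
#' them.
#'
#' @param cfg a [simConfig()] object.
#' @return a [GenotypeMatrix-class].
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  n <- cfg$nIndividuals; m <- cfg$nVariants
  sizes <- vapply(cfg$ldBlocks, `[`, 0, 1L)
  rhos <- vapply(cfg$ldBlocks, `[`, 0, 2L)
  dos <- withSeed(stageSeed(cfg$seed, "genotypes"), {
    chols <- local({
      at <- 0L
      lapply(seq_along(sizes), function(b) {
        f <- cfg$alleleFreqs[(at + 1L):(at + sizes[b])]
        at <<- at + sizes[b]
        .blockChol(sizes[b], rhos[b], f)
      })
    })
    hap <- function() {
      cols <- vector("list", length(sizes))
      at <- 0L
      for (b in seq_along(sizes)) {
        L <- chols[[b]]
        Z <- matrix(rnorm(n * sizes[b]), n) %*% L
        f <- cfg$alleleFreqs[(at + 1L):(at + sizes[b])]
        cols[[b]] <- sweep(Z, 2L, qnorm(f), "<") * 1
        at <- at + sizes[b]
      }
      do.call(cbind, cols)
    }
    hap() + hap()
  })
  pos <- integer(m); at <- 0L
  for (b in seq_along(sizes)) {
    pos[(at + 1L):(at + sizes[b])] <- (b - 1L) * 1e7 +
      seq_len(sizes[b]) * 5000L
    at <- at + sizes[b]
  }
  variants <- data.frame(variant_id = sprintf("var%03d", seq_len(m)),
                         chrom = "1", pos = pos, ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  colnames(dos) <- variants$variant_id
  GenotypeMatrix(dos, variants,
                 personIds = sprintf("person%05d", seq_len(n)))
}

#' Simulate the quantitative metabolite
#'
#' \eqn{y_i = \sum_j \gamma_j g_{ij} + \delta C_i + \epsilon_i} with the
#' residual variance chosen so the marginal variance is 1 (floored at 0.05
#' when the genetic plus confounder variance already exceeds 0.95).
#' The confounder \eqn{C \sim N(0,1)} is returned for the disease simulator.
#'
#' @param G a [GenotypeMatrix-class] from [simulateGenotypes()].
#' @param cfg the same [simConfig()].
#' @return list with `metabolite` (named numeric, SD units) and `confounder`.
#' @export
simulateMetabolite <- function(G, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  g <- t(dosages(G))
  gamma <- cfg$metaboliteEffects
  delta <- unname(cfg$confounderEffect["metabolite"])
  f <- cfg$alleleFreqs
  varG <- sum(2 * f * (1 - f) * gamma^2)
  sig2 <- max(1 - varG - delta^2, 0.05)
  withSeed(stageSeed(cfg$seed, "metabolite"), {
    C <- rnorm(nrow(g))
    y <- drop(g %*% gamma) + delta * C + rnorm(nrow(g), 0, sqrt(sig2))
    names(y) <- rownames(g); names(C) <- rownames(g)
    list(metabolite = y, confounder = C)
  })
}

#' Toy phecode map for simulated phenomes
#'
#' One phecode per simulated disease (numeric codes 10, 20, ...), each mapped
#' from two ICD-9-CM codes and one ICD-10 code, with an exclusion range of
#' +/- 2 around the phecode (so exclusion ranges of adjacent phecodes never
#' touch) and no sex restriction.
#'
#' @param cfg a [simConfig()].
#' @return phecode map data.frame in the [readPhecodeMap()] layout.
#' @export
simulatePhecodeMap <- function(cfg) {
  k <- seq_len(cfg$nPhecodes)
  phe <- as.character(k * 10)
  do.call(rbind, lapply(k, function(i) {
    data.frame(icd = c(sprintf("%03d.1", i), sprintf("%03d.2", i),
                       sprintf("A%02d.0", i)),
               vocabulary = c("ICD9CM", "ICD9CM", "ICD10"),
               phecode = phe[i], label = sprintf("disease_%02d", i),
               exclusion_min = i * 10 - 2, exclusion_max = i * 10 + 2,
               sex = "none", stringsAsFactors = FALSE)
  }))
}

#' Simulate diseases and their ICD event stream
#'
#' Disease liability per person and disease d:
#' \eqn{\mathrm{logit}\,P(D_d=1) = \alpha_d + \theta_d y + \sum_j \pi_{jd}
#' g_{ij} + \lambda_d C}, with \eqn{\alpha_d} anchored at the configured base
#' rate. Cases emit at least two ICD events for their phecode's codes on
#' distinct simulated dates (10-year window); every person additionally emits
#' Poisson(`icdNoiseRate`) unrelated, unmapped noise codes. True controls
#' never receive exclusion-range codes. Demographics (sex, age, 5 PCs) are
#' generated alongside.
#'
#' @param G a [GenotypeMatrix-class].
#' @param metabolite,confounder vectors from [simulateMetabolite()].
#' @param cfg the same [simConfig()].
#' @return list with `disease` (persons x phecodes 0/1 matrix), `events`
#'   (ICD event data.frame), `pmap` (phecode map), `demographics`.
#' @export
simulateDiseasesAndIcd <- function(G, metabolite, confounder, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  g <- t(dosages(G))
  n <- nrow(g); nd <- cfg$nPhecodes
  theta <- rep_len(cfg$causalEffect, nd)
  lambda <- rep_len(unname(cfg$confounderEffect["disease"]), nd)
  P <- cfg$pleiotropyMatrix
  pmap <- simulatePhecodeMap(cfg)
  phe <- as.character(seq_len(nd) * 10)
  withSeed(stageSeed(cfg$seed, "diseases"), {
    if (is.null(P)) {
      P <- matrix(0, cfg$nVariants, nd)
      nInvalid <- round(cfg$pleiotropy$fracInvalid * cfg$nVariants)
      if (nInvalid > 0)
        P[seq_len(nInvalid), ] <- rnorm(nInvalid * nd, cfg$pleiotropy$mu,
                                        cfg$pleiotropy$sigma)
    }
    alpha <- qlogis(cfg$diseaseBaseRates)
    eta <- outer(rep(1, n), alpha) +
      outer(metabolite, theta) + g %*% P + outer(confounder, lambda)
    D <- matrix(rbinom(n * nd, 1L, plogis(eta)), n, nd,
                dimnames = list(rownames(g), phe))
    events <- vector("list", nd + 1L)
    day0 <- as.Date("2010-01-01")
    for (d in seq_len(nd)) {
      cases <- which(D[, d] == 1L)
      if (!length(cases)) next
      nEv <- 2L + rpois(length(cases), 1)
      pid <- rep(rownames(g)[cases], nEv)
      start <- rep(sample.int(3000L, length(cases), replace = TRUE), nEv)
      off <- sequence(nEv) * 13L  # distinct dates within each person
      codes <- pmap$icd[pmap$phecode == phe[d]]
      events[[d]] <- data.frame(
        person_id = pid, date = day0 + start + off,
        code = sample(codes, length(pid), replace = TRUE),
        stringsAsFactors = FALSE)
      events[[d]]$vocabulary <- pmap$vocabulary[
        match(events[[d]]$code, pmap$icd)]
    }
    nNoise <- rpois(n, cfg$icdNoiseRate)
    if (sum(nNoise) > 0) {
      events[[nd + 1L]] <- data.frame(
        person_id = rep(rownames(g), nNoise),
        date = day0 + sample.int(3650L, sum(nNoise), replace = TRUE),
        code = sprintf("R%02d.9", sample.int(20L, sum(nNoise),
                                             replace = TRUE)),
        vocabulary = "ICD10", stringsAsFactors = FALSE)
    }
    ev <- do.call(rbind, events)
    demographics <- data.frame(
      person_id = rownames(g),
      sex = sample(c("F", "M"), n, replace = TRUE),
      age = sample(30:79, n, replace = TRUE),
      stringsAsFactors = FALSE)
    for (i in 1:5) demographics[[paste0("PC", i)]] <- rnorm(n)
    list(disease = D, events = ev[order(ev$person_id, ev$date), ],
         pmap = pmap, demographics = demographics)
  })
}

## vectorized simple regressions of y on each column of g
.simpleRegressions <- function(g, y) {
  n <- length(y)
  gc <- sweep(g, 2L, colMeans(g))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  beta <- drop(crossprod(gc, yc)) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  tt <- beta / se
  list(beta = beta, se = se, p = 2 * pt(-abs(tt), n - 2))
}

#' Simulate a two-sample summary-statistics pair
#'
#' Generates two non-overlapping samples of `cfg$nIndividuals` persons each
#' with independent genotypes at the configured allele frequencies. Sample 1
#' provides per-variant exposure regressions of the metabolite; sample 2
#' provides per-variant outcome regressions of an outcome generated with
#' causal effect `cfg$causalEffect` of the exposure plus the configured
#' per-variant horizontal pleiotropy and shared confounding. SEs come from
#' the simulated regressions themselves, not asymptotic formulas.
#'
#' @param cfg a [simConfig()]; `pleiotropy` (mu, sigma, fracInvalid) applies
#'   to the first `round(fracInvalid * nVariants)` variants.
#' @return list with `exposure` and `outcome` canonical sumstats data.frames,
#'   `theta` (true causal effect), `gamma` (true instrument effects) and
#'   `pleiotropy` (true per-variant direct outcome effects).
#' @export
simulateTwoSampleSumstats <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  n <- cfg$nIndividuals; m <- cfg$nVariants
  f <- cfg$alleleFreqs
  gamma <- cfg$metaboliteEffects
  delta <- unname(cfg$confounderEffect["metabolite"])
  lambda <- unname(cfg$confounderEffect["disease"])
  theta <- cfg$causalEffect[1L]
  varG <- sum(2 * f * (1 - f) * gamma^2)
  sig2x <- max(1 - varG - delta^2, 0.05)
  withSeed(stageSeed(cfg$seed, "two_sample"), {
    pi_j <- rep(0, m)
    nInvalid <- round(cfg$pleiotropy$fracInvalid * m)
    if (nInvalid > 0)
      pi_j[seq_len(nInvalid)] <- rnorm(nInvalid, cfg$pleiotropy$mu,
                                       cfg$pleiotropy$sigma)
    drawSample <- function() {
      g <- matrix(rbinom(n * m, 2L, rep(f, each = n)), n, m)
      C <- rnorm(n)
      x <- drop(g %*% gamma) + delta * C + rnorm(n, 0, sqrt(sig2x))
      list(g = g, C = C, x = x)
    }
    s1 <- drawSample()
    s2 <- drawSample()
    sig2y <- max(1 - theta^2 - lambda^2, 0.1)
    y2 <- theta * s2$x + drop(s2$g %*% pi_j) + lambda * s2$C +
      rnorm(n, 0, sqrt(sig2y))
    mk <- function(g, trait) {
      r <- .simpleRegressions(g, trait)
      data.frame(variant_id = sprintf("var%03d", seq_len(m)), chrom = "1",
                 pos = as.integer(seq_len(m) * 1e6), ref_allele = "A",
                 alt_allele = "G", effect_allele = "G",
                 eaf = colMeans(g) / 2, beta = r$beta, se = r$se,
                 p = pmax(r$p, .Machine$double.xmin), n = n, info = NA_real_,
                 stringsAsFactors = FALSE)
    }
    list(exposure = mk(s1$g, s1$x), outcome = mk(s2$g, y2),
         theta = theta, gamma = gamma, pleiotropy = pi_j)
  })
}
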