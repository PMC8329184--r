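## Shared fixtures and independent oracles for the test suite.

leadSnpPath <- function() {
  system.file("extdata", "kynurenine_lead_snps.tsv", package = "phewasMR")
}

## Minimal canonical sumstats row(s)
makeSumstats <- function(n = 1, variant_id = sprintf("snp%02d", seq_len(n)),
                         chrom = "1", pos = seq_len(n) * 1000L,
                         ref = "A", alt = "G", effect = alt,
                         eaf = 0.3, beta = 0.1, se = 0.02, p = 1e-9,
                         nsamp = NA_real_, info = NA_real_) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             ref_allele = ref, alt_allele = alt, effect_allele = effect,
             eaf = eaf, beta = beta, se = se, p = p, n = nsamp, info = info,
             stringsAsFactors = FALSE)
}

## Independent greedy-clumping oracle: operates on a precomputed r2 matrix,
## written as a direct transcription of the rule (no shared code with the
## package's implementation).
oracleClump <- function(ss, r2mat, r2t, window_kb) {
  remaining <- ss[order(ss$p, ss$chrom, ss$pos, ss$variant_id), ]
  index <- character(0)
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    index <- c(index, top$variant_id)
    linked <- vapply(seq_len(nrow(remaining)), function(i) {
      r <- remaining[i, ]
      if (r$variant_id == top$variant_id) return(TRUE)
      r$chrom == top$chrom &&
        abs(r$pos - top$pos) <= window_kb * 1000 &&
        r2mat[r$variant_id, top$variant_id] >= r2t
    }, TRUE)
    remaining <- remaining[!linked, , drop = FALSE]
  }
  index
}

## Zero-intercept weighted least squares via explicit matrix algebra
oracleWlsNoIntercept <- function(bx, by, w) {
  X <- matrix(bx, ncol = 1)
  XtWX <- t(X) %*% diag(w, length(w)) %*% X
  XtWy <- t(X) %*% diag(w, length(w)) %*% by
  est <- solve(XtWX, XtWy)
  list(estimate = drop(est), se = sqrt(drop(solve(XtWX))))
}

## GenotypeMatrix from a person x variant dosage matrix with evenly spaced
## positions on one chromosome
makeGenotypes <- function(d, spacing = 10000L, chrom = "1") {
  m <- ncol(d)
  GenotypeMatrix(d, data.frame(variant_id = sprintf("snp%02d", seq_len(m)),
                               chrom = chrom, pos = seq_len(m) * spacing,
                               ref = "A", alt = "G",
                               stringsAsFactors = FALSE),
                 personIds = sprintf("p%04d", seq_len(nrow(d))))
}

## PhenomeCohort straight from a status matrix (all phecodes retained)
makeCohort <- function(status, demographics = NULL) {
  if (is.null(rownames(status)))
    rownames(status) <- sprintf("p%04d", seq_len(nrow(status)))
  if (is.null(colnames(status)))
    colnames(status) <- sprintf("%d", seq_len(ncol(status)) * 10)
  if (is.null(demographics))
    demographics <- data.frame(person_id = rownames(status),
                               stringsAsFactors = FALSE)
  rownames(demographics) <- demographics$person_id
  info <- data.frame(phecode = colnames(status),
                     label = colnames(status),
                     n_cases = colSums(status == 1L, na.rm = TRUE),
                     n_controls = colSums(status == 0L, na.rm = TRUE),
                     n_excluded = colSums(is.na(status)),
                     retained = TRUE, drop_reason = "",
                     stringsAsFactors = FALSE)
  methods::new("PhenomeCohort", status = status,
               demographics = demographics, phecodeInfo = info)
}

## ICD events for a person: one row per (code, date)
makeEvents <- function(person_id, codes, dates, vocabulary = "ICD9CM") {
  data.frame(person_id = person_id, date = as.Date(dates), code = codes,
             vocabulary = vocabulary, stringsAsFactors = FALSE)
}
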