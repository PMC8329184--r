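## Instrument selection: significance filtering, greedy LD clumping against a
## reference genotype panel, and the cohort-level QC filters (imputation
## quality, relatedness pruning).

#' Squared Pearson correlation between two dosage vectors
#'
#' LD between two variants measured as the squared Pearson correlation of
#' their dosages over pairwise-complete observations.
#'
#' @param g1,g2 numeric dosage vectors of equal length; `NA` allowed.
#' @return r-squared in \[0, 1\].
#' @export
ldR2 <- function(g1, g2) {
  if (length(g1) != length(g2))
    .configError("dosage vectors must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) .dataError("fewer than 2 pairwise-complete observations")
  if (var(g1[ok]) == 0 || var(g2[ok]) == 0)
    .dataError("monomorphic variant: zero dosage variance")
  cor(g1[ok], g2[ok])^2
}

#' Genome-wide significance filter
#'
#' @param records canonical sumstats data.frame.
#' @param threshold p-value threshold in (0, 1); records with `p < threshold`
#'   (strict) are retained in input order. Default 5e-8, the conventional
#'   genome-wide significance level.
#' @return filtered data.frame.
#' @export
significanceFilter <- function(records, threshold = 5e-8) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    .configError("threshold must be a single value in (0, 1)")
  records[records$p < threshold, , drop = FALSE]
}

#' Greedy LD clumping of summary statistics
#'
#' Selects independent index variants by the standard greedy rule: repeatedly
#' take the remaining record with the smallest p-value as an index variant and
#' assign to it every remaining variant on the same chromosome within
#' `windowKb` (center-to-center) whose LD with the index, computed in the
#' reference panel, is at least `r2Threshold`. Ties in p are broken by
#' (chrom, pos, variant_id) so the result does not depend on row order.
#'
#' @param records canonical sumstats data.frame, typically pre-filtered with
#'   [significanceFilter()].
#' @param ref a [GenotypeMatrix-class] LD reference containing every record's
#'   variant.
#' @param r2Threshold LD threshold (default 0.05).
#' @param windowKb window in kilobases (default 1000).
#' @return A [ClumpResult-class] object.
#' @export
clumpVariants <- function(records, ref, r2Threshold = 0.05, windowKb = 1000) {
  if (!is.numeric(r2Threshold) || r2Threshold < 0 || r2Threshold > 1)
    .configError("r2Threshold must be in [0, 1]")
  if (!is.numeric(windowKb) || windowKb <= 0)
    .configError("windowKb must be positive")
  vi <- variantInfo(ref)
  missing <- setdiff(records$variant_id, vi$variant_id)
  if (length(missing))
    .dataError(paste("variant(s) absent from LD reference:",
                     paste(missing, collapse = ", ")))
  d <- dosages(ref)
  recs <- records[order(records$p, records$chrom, records$pos,
                        records$variant_id), , drop = FALSE]
  remaining <- recs$variant_id
  pos <- setNames(vi$pos[match(recs$variant_id, vi$variant_id)],
                  recs$variant_id)
  chrom <- setNames(vi$chrom[match(recs$variant_id, vi$variant_id)],
                    recs$variant_id)
  index <- character(0)
  assignments <- setNames(rep(NA_character_, length(remaining)), remaining)
  rows <- list()
  while (length(remaining)) {
    idx <- remaining[1L]
    index <- c(index, idx)
    assignments[idx] <- idx
    rows[[length(rows) + 1L]] <- data.frame(index_variant = idx,
                                            member_variant = idx,
                                            r2 = 1, distance_kb = 0,
                                            stringsAsFactors = FALSE)
    remaining <- remaining[-1L]
    if (!length(remaining)) break
    near <- remaining[chrom[remaining] == chrom[idx] &
                      abs(pos[remaining] - pos[idx]) <= windowKb * 1000]
    for (v in near) {
      r2 <- ldR2(d[idx, ], d[v, ])
      if (r2 >= r2Threshold) {
        assignments[v] <- idx
        rows[[length(rows) + 1L]] <- data.frame(
          index_variant = idx, member_variant = v, r2 = r2,
          distance_kb = abs(pos[v] - pos[idx]) / 1000,
          stringsAsFactors = FALSE)
        remaining <- setdiff(remaining, v)
      }
    }
  }
  methods::new("ClumpResult", indexVariants = index,
               assignments = assignments,
               table = do.call(rbind, rows))
}

#' Imputation-quality filter
#'
#' Drops records whose imputation quality (`info`) is strictly below
#' `infoMin`; records with missing `info` are kept (directly genotyped or
#' unscored variants) and their count is reported as an attribute.
#'
#' @param records canonical sumstats data.frame.
#' @param infoMin minimum imputation quality in \[0, 1\] (default 0.3).
#' @return filtered data.frame with attribute `missing_info_kept`.
#' @export
qcFilter <- function(records, infoMin = 0.3) {
  if (!is.numeric(infoMin) || infoMin < 0 || infoMin > 1)
    .configError("infoMin must be in [0, 1]")
  keep <- is.na(records$info) | records$info >= infoMin
  out <- records[keep, , drop = FALSE]
  n_missing <- sum(is.na(records$info))
  if (n_missing)
    message(sprintf("qcFilter: %d record(s) with missing info kept", n_missing))
  attr(out, "missing_info_kept") <- n_missing
  out
}

#' Relatedness pruning
#'
#' Resolves close relatedness by removing, from every pair exceeding the
#' pi-hat threshold, one member chosen by a seeded random draw, repeating
#' until no retained pair exceeds the threshold. Deterministic given the seed.
#'
#' @param personIds character vector of cohort members.
#' @param pihat data.frame with columns `id1`, `id2`, `pihat` (symmetric
#'   pairwise relatedness; unlisted pairs are treated as unrelated).
#' @param threshold pi-hat above which (strictly) a pair counts as related
#'   (default 0.2).
#' @param seed integer seed for the random member choice.
#' @return character vector of retained person ids (original order).
#' @export
relatednessPrune <- function(personIds, pihat, threshold = 0.2, seed = 1L) {
  if (!all(c("id1", "id2", "pihat") %in% names(pihat)))
    .configError("pihat must have columns id1, id2, pihat")
  if (threshold < 0) .configError("threshold must be >= 0")
  retained <- as.character(personIds)
  pairs <- pihat[pihat$pihat > threshold, , drop = FALSE]
  pairs <- pairs[order(pmin(pairs$id1, pairs$id2),
                       pmax(pairs$id1, pairs$id2)), , drop = FALSE]
  withSeed(seed, {
    repeat {
      live <- pairs$id1 %in% retained & pairs$id2 %in% retained
      if (!any(live)) break
      pr <- pairs[which(live)[1L], ]
      drop <- if (runif(1) < 0.5) pr$id1 else pr$id2
      retained <- setdiff(retained, drop)
    }
  })
  personIds[personIds %in% retained]
}
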