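#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' Person-by-variant dosage container
#'
#' `GenotypeMatrix` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with a single `"dosage"` assay holding expected alternate-allele counts in
#' \[0, 2\] (missing allowed). Rows are variants (with genomic coordinates as
#' `rowRanges` and `variant_id`, `ref`, `alt` metadata columns); columns are
#' persons. Variants are stored sorted by chromosome and position, so
#' window-based operations (LD clumping) can assume non-decreasing positions
#' within a chromosome.
#'
#' @slot .. inherits all RangedSummarizedExperiment slots.
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (any(d < 0 | d > 2, na.rm = TRUE))
      msg <- c(msg, "dosages must lie in [0, 2] (or be missing)")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  need <- c("variant_id", "ref", "alt")
  if (!all(need %in% colnames(S4Vectors::mcols(rr))))
    msg <- c(msg, "rowRanges must carry variant_id, ref and alt")
  else {
    chr <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    for (cc in unique(chr)) {
      if (is.unsorted(pos[chr == cc]))
        msg <- c(msg, sprintf("positions on chromosome %s are not sorted", cc))
    }
    if (anyDuplicated(S4Vectors::mcols(rr)$variant_id))
      msg <- c(msg, "variant_id values must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix of alternate-allele dosages, persons in rows
#'   and variants in columns (the orientation genotype files are usually read
#'   in), or variants x persons if `variantsInRows = TRUE`. Values in \[0, 2\],
#'   `NA` allowed.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, one row per variant, in the column order of `dosages`.
#' @param personIds character vector of person identifiers.
#' @param variantsInRows logical; set `TRUE` when `dosages` is already
#'   variants x persons.
#'
#' @return A [GenotypeMatrix-class] object with variants sorted by
#'   (chromosome, position).
#' @examples
#' g <- GenotypeMatrix(matrix(c(0, 1, 2, 2, 1, 0), nrow = 3),
#'                     data.frame(variant_id = c("v1", "v2"),
#'                                chrom = "1", pos = c(100, 200),
#'                                ref = "A", alt = "G"),
#'                     personIds = c("p1", "p2", "p3"))
#' dosages(g)
#' @export
GenotypeMatrix <- function(dosages, variants, personIds = NULL,
                           variantsInRows = FALSE) {
  dosages <- as.matrix(dosages)
  if (!variantsInRows) dosages <- t(dosages)
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    .configError(paste("variants table must have columns:",
                       paste(need, collapse = ", ")))
  if (nrow(variants) != nrow(dosages))
    .configError("number of variants does not match dosage dimensions")
  if (is.null(personIds)) {
    personIds <- colnames(dosages)
    if (is.null(personIds)) personIds <- sprintf("person%04d", seq_len(ncol(dosages)))
  }
  ord <- order(as.character(variants$chrom), variants$pos, variants$variant_id)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[ord, , drop = FALSE]
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(variants$chrom),
    ranges = IRanges::IRanges(start = variants$pos, width = 1L),
    variant_id = as.character(variants$variant_id),
    ref = as.character(variants$ref),
    alt = as.character(variants$alt))
  names(rr) <- as.character(variants$variant_id)
  dimnames(dosages) <- list(as.character(variants$variant_id), personIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosages), rowRanges = rr,
    colData = S4Vectors::DataFrame(person_id = personIds, row.names = personIds))
  methods::new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix dosage matrix, variants x persons.
#' @param x,object a `GenotypeMatrix`.
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeMatrix variant metadata as a data.frame
#'   (variant_id, chrom, pos, ref, alt).
#' @export
variantInfo <- function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(variant_id = S4Vectors::mcols(rr)$variant_id,
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = S4Vectors::mcols(rr)$ref,
             alt = S4Vectors::mcols(rr)$alt,
             stringsAsFactors = FALSE)
}

#' @describeIn GenotypeMatrix person identifiers.
#' @export
personIds <- function(x) colnames(SummarizedExperiment::assay(x, "dosage"))

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d variants x %d persons\n",
              nrow(object), ncol(object)))
  vi <- variantInfo(object)
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(vi$chrom), collapse = ", ")))
  miss <- mean(is.na(dosages(object)))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
})

#' Phecode case/control cohort
#'
#' Holds, for every person and every phecode, the case/control/excluded status
#' assigned by [buildCohort()], together with per-person demographics and
#' per-phecode bookkeeping (case counts and whether the phecode is retained
#' for scanning).
#'
#' Status coding in the `status` matrix (persons x phecodes): `1` = case,
#' `0` = control, `NA` = excluded.
#'
#' @slot status integer matrix, persons x phecodes, values in {0, 1, NA}.
#' @slot demographics data.frame keyed by `person_id` with sex, age (or
#'   birth_decade) and covariates such as principal components.
#' @slot phecodeInfo data.frame with one row per phecode: `phecode`, `label`,
#'   `n_cases`, `n_controls`, `n_excluded`, `retained`, `drop_reason`.
#' @export
setClass("PhenomeCohort",
         representation(status = "matrix",
                        demographics = "data.frame",
                        phecodeInfo = "data.frame"))

setValidity("PhenomeCohort", function(object) {
  msg <- character(0)
  s <- object@status
  if (!all(s %in% c(0L, 1L) | is.na(s)))
    msg <- c(msg, "status values must be 0, 1 or NA")
  if (nrow(s) != nrow(object@demographics))
    msg <- c(msg, "status rows must match demographics rows")
  if (!identical(rownames(s), as.character(object@demographics$person_id)))
    msg <- c(msg, "status rownames must equal demographics person_id")
  if (ncol(s) != nrow(object@phecodeInfo))
    msg <- c(msg, "status columns must match phecodeInfo rows")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhenomeCohort the persons x phecodes status matrix
#'   (1 case, 0 control, NA excluded).
#' @param x,object a `PhenomeCohort`.
#' @export
cohortStatus <- function(x) x@status

#' @describeIn PhenomeCohort per-phecode summary table.
#' @export
phecodeInfo <- function(x) x@phecodeInfo

#' @describeIn PhenomeCohort phecodes retained for scanning (enough cases,
#'   no sex restriction).
#' @export
retainedPhecodes <- function(x) x@phecodeInfo$phecode[x@phecodeInfo$retained]

#' @describeIn PhenomeCohort per-person demographics/covariate table.
#' @export
cohortDemographics <- function(x) x@demographics

setMethod("show", "PhenomeCohort", function(object) {
  pi <- object@phecodeInfo
  cat(sprintf("PhenomeCohort: %d persons, %d phecodes (%d retained)\n",
              nrow(object@status), nrow(pi), sum(pi$retained)))
  if (any(pi$retained)) {
    r <- pi[pi$retained, ]
    cat(sprintf("  cases per retained phecode: median %d [%d-%d]\n",
                as.integer(stats::median(r$n_cases)), min(r$n_cases),
                max(r$n_cases)))
  }
})

#' Harmonized two-sample MR input
#'
#' Per-variant exposure and outcome effect estimates on a shared effect
#' allele, the unit of analysis for all two-sample Mendelian randomization
#' estimators. Both betas must be expressed per the same allele of each
#' variant; [harmonizePair()] produces aligned tables and [asMRInput()]
#' converts them.
#'
#' @slot variantId character, instrument identifiers.
#' @slot bx,sx numeric, exposure (e.g. metabolite) betas and SEs.
#' @slot by,sy numeric, outcome betas and SEs.
#' @export
setClass("MRInput2S",
         representation(variantId = "character", bx = "numeric",
                        sx = "numeric", by = "numeric", sy = "numeric"))

setValidity("MRInput2S", function(object) {
  msg <- character(0)
  n <- length(object@bx)
  if (n < 1L) msg <- c(msg, "at least one variant is required")
  lens <- c(length(object@variantId), length(object@sx), length(object@by),
            length(object@sy))
  if (!all(lens == n)) msg <- c(msg, "all slots must have equal length")
  if (any(!is.finite(object@bx)) || any(!is.finite(object@by)) ||
      any(!is.finite(object@sx)) || any(!is.finite(object@sy)))
    msg <- c(msg, "all betas and SEs must be finite")
  else if (any(object@sx <= 0) || any(object@sy <= 0))
    msg <- c(msg, "all standard errors must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an MR input set
#'
#' @param bx,sx exposure betas and standard errors, one per variant.
#' @param by,sy outcome betas and standard errors.
#' @param variantId optional variant identifiers.
#' @return An [MRInput2S-class] object.
#' @examples
#' mrInput(bx = c(0.1, 0.2, 0.15), sx = c(0.02, 0.02, 0.02),
#'         by = c(0.025, 0.038, 0.031), sy = c(0.01, 0.01, 0.02))
#' @export
mrInput <- function(bx, sx, by, sy,
                    variantId = sprintf("snp%03d", seq_along(bx))) {
  methods::new("MRInput2S", variantId = as.character(variantId),
               bx = as.numeric(bx), sx = as.numeric(sx),
               by = as.numeric(by), sy = as.numeric(sy))
}

#' @describeIn mrInput number of instruments.
#' @param x,object an `MRInput2S`.
#' @export
nInstruments <- function(x) length(x@bx)

setMethod("show", "MRInput2S", function(object) {
  cat(sprintf("MRInput2S with %d instruments\n", length(object@bx)))
  cat(sprintf("  mean |bx| = %.4g, mean |by| = %.4g\n",
              mean(abs(object@bx)), mean(abs(object@by))))
})

#' LD clumping result
#'
#' Index variants selected greedily by p-value together with the assignment of
#' every clumped variant to its index.
#'
#' @slot indexVariants character, index variant ids in selection order.
#' @slot assignments named character vector mapping every input variant to its
#'   index variant (index variants map to themselves).
#' @slot table data.frame with columns `index_variant`, `member_variant`,
#'   `r2`, `distance_kb` for reporting.
#' @export
setClass("ClumpResult",
         representation(indexVariants = "character",
                        assignments = "character",
                        table = "data.frame"))

#' @describeIn ClumpResult index variant identifiers, in selection order.
#' @param x,object a `ClumpResult`.
#' @export
indexVariants <- function(x) x@indexVariants

#' @describeIn ClumpResult named map from each variant to its index variant.
#' @export
clumpAssignments <- function(x) x@assignments

setMethod("show", "ClumpResult", function(object) {
  cat(sprintf("ClumpResult: %d index variants from %d input variants\n",
              length(object@indexVariants), length(object@assignments)))
  cat(" ", paste(object@indexVariants, collapse = ", "), "\n")
})

#' @describeIn ClumpResult long-format table (index, member, r2, distance).
#' @param row.names,optional,... passed on per the generic; unused.
#' @export
setMethod("as.data.frame", "ClumpResult",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)
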