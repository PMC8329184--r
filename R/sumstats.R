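## GWAS summary-statistics I/O, validation and between-study harmonization.

## Canonical column set. `eaf`, `n` and `info` may be missing (NA).
.SUMSTAT_COLS <- c("variant_id", "chrom", "pos", "ref_allele", "alt_allele",
                   "effect_allele", "eaf", "beta", "se", "p", "n", "info")
.SUMSTAT_REQUIRED <- c("variant_id", "chrom", "pos", "ref_allele",
                       "alt_allele", "effect_allele", "beta", "se", "p")

#' Validate a summary-statistics table
#'
#' Checks the per-row contract every downstream step relies on: positive SEs,
#' p-values in (0, 1\], the effect allele being one of the two alleles, and
#' uniqueness of (variant_id, effect_allele).
#'
#' @param ss data.frame in canonical sumstats layout (see [readSumstats()]).
#' @return `ss` invisibly; signals a validation error listing offending rows
#'   otherwise.
#' @export
validateSumstats <- function(ss) {
  missing_cols <- setdiff(.SUMSTAT_REQUIRED, names(ss))
  if (length(missing_cols))
    .configError(paste("missing required sumstats column(s):",
                       paste(missing_cols, collapse = ", ")))
  bad <- rep(FALSE, nrow(ss))
  reasons <- character(nrow(ss))
  note <- function(idx, why) {
    bad[idx] <<- TRUE
    reasons[idx] <<- ifelse(nzchar(reasons[idx]),
                            paste(reasons[idx], why, sep = "; "), why)
  }
  note(which(!is.finite(ss$se) | ss$se <= 0), "se must be > 0")
  note(which(!is.finite(ss$p) | ss$p <= 0 | ss$p > 1), "p must be in (0,1]")
  note(which(ss$effect_allele != ss$ref_allele &
             ss$effect_allele != ss$alt_allele),
       "effect_allele not among ref/alt")
  note(which(!is.na(ss$eaf) & (ss$eaf <= 0 | ss$eaf >= 1)),
       "eaf must be in (0,1)")
  note(which(!is.na(ss$info) & (ss$info < 0 | ss$info > 1)),
       "info must be in [0,1]")
  note(which(duplicated(paste(ss$variant_id, ss$effect_allele))),
       "duplicate (variant_id, effect_allele)")
  if (any(bad)) {
    rows <- which(bad)
    detail <- paste(sprintf("row %d (%s): %s", rows, ss$variant_id[rows],
                            reasons[rows]), collapse = "\n  ")
    .validationError(paste0("invalid summary-statistics rows:\n  ", detail))
  }
  invisible(ss)
}

#' Read GWAS summary statistics
#'
#' Reads a delimited text table (tab or comma separated, detected from the
#' header line) into the canonical sumstats layout, mapping file column names
#' through `columnMap`, and validates every row.
#'
#' @param path file path to a delimited table with a header.
#' @param columnMap named character vector mapping canonical field names
#'   (`variant`, `chrom`, `pos`, `ref`, `alt`, `effect_allele`, `eaf`,
#'   `beta`, `se`, `p`, `n`, `info`) to the column names used in the file.
#'   Fields absent from the map are taken to use canonical names; optional
#'   fields missing from the file are filled with `NA`.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma.
#' @return data.frame with columns `variant_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `effect_allele`, `eaf`, `beta`, `se`, `p`, `n`, `info`,
#'   rows in file order.
#' @examples
#' path <- system.file("extdata", "kynurenine_lead_snps.tsv",
#'                     package = "phewasMR")
#' ss <- readSumstats(path)
#' ss[ss$variant_id == "rs3184504", c("beta", "se", "p")]
#' @export
readSumstats <- function(path, columnMap = NULL, sep = NULL) {
  if (!file.exists(path)) .dataError(paste("file not found:", path))
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  canon <- c(variant = "variant_id", chrom = "chrom", pos = "pos",
             ref = "ref_allele", alt = "alt_allele",
             effect_allele = "effect_allele", eaf = "eaf", beta = "beta",
             se = "se", p = "p", n = "n", info = "info")
  file_col <- canon  # default: file uses canonical names
  if (!is.null(columnMap)) {
    unknown <- setdiff(names(columnMap), names(canon))
    if (length(unknown))
      .configError(paste("unknown columnMap field(s):",
                         paste(unknown, collapse = ", ")))
    file_col[names(columnMap)] <- unlist(columnMap)
  }
  required_fields <- c("variant", "chrom", "pos", "ref", "alt",
                       "effect_allele", "beta", "se", "p")
  miss <- required_fields[!(file_col[required_fields] %in% names(raw))]
  if (length(miss))
    .configError(paste0("required column(s) not found in ", path, ": ",
                        paste(file_col[miss], collapse = ", ")))
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
    variant_id = as.character(raw[[file_col["variant"]]]),
    chrom = as.character(raw[[file_col["chrom"]]]),
    pos = as.integer(raw[[file_col["pos"]]]),
    ref_allele = toupper(as.character(raw[[file_col["ref"]]])),
    alt_allele = toupper(as.character(raw[[file_col["alt"]]])),
    effect_allele = toupper(as.character(raw[[file_col["effect_allele"]]])))
  opt <- function(field, as = as.numeric) {
    cn <- file_col[field]
    if (cn %in% names(raw)) as(raw[[cn]]) else rep(NA_real_, nrow(raw))
  }
  out$eaf <- opt("eaf"); out$beta <- as.numeric(raw[[file_col["beta"]]])
  out$se <- as.numeric(raw[[file_col["se"]]])
  out$p <- as.numeric(raw[[file_col["p"]]])
  out$n <- opt("n"); out$info <- opt("info")
  validateSumstats(out)
  out
}

#' Write summary statistics in canonical TSV layout
#'
#' @param ss canonical sumstats data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(ss, path) {
  validateSumstats(ss)
  write.table(ss[, .SUMSTAT_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Re-express effects on a chosen effect allele
#'
#' Flips summary-statistics rows so that `targetAllele` becomes the effect
#' allele: the beta changes sign, the effect-allele frequency becomes its
#' complement, and SE and p are untouched. Rows already on the target allele
#' are returned unchanged. The operation is an involution.
#'
#' @param ss canonical sumstats data.frame (one or more rows).
#' @param targetAllele character vector (recycled) of desired effect alleles;
#'   each must be the row's ref or alt allele.
#' @return `ss` with `beta`, `eaf`, `effect_allele` updated.
#' @examples
#' rec <- data.frame(variant_id = "rs3184504", chrom = "12", pos = 111884608L,
#'                   ref_allele = "T", alt_allele = "C", effect_allele = "T",
#'                   eaf = 0.48, beta = 0.015, se = 0.002, p = 6.046e-18,
#'                   n = NA, info = NA)
#' flipToEffectAllele(rec, "C")$beta   # -0.015
#' @export
flipToEffectAllele <- function(ss, targetAllele) {
  targetAllele <- rep_len(toupper(targetAllele), nrow(ss))
  ok <- targetAllele == ss$ref_allele | targetAllele == ss$alt_allele
  if (any(!ok))
    .dataError(paste("target allele not among the record's alleles for:",
                     paste(ss$variant_id[!ok], collapse = ", ")))
  flip <- targetAllele != ss$effect_allele
  ss$beta[flip] <- -ss$beta[flip]
  ss$eaf[flip] <- 1 - ss$eaf[flip]
  ss$effect_allele[flip] <- targetAllele[flip]
  ss
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.complement <- function(allele) {
  out <- .COMPLEMENT[allele]
  out[is.na(out)] <- NA_character_  # indels / multi-base: no complement
  unname(out)
}

## Palindromic = single-base alleles that are strand complements (A/T, C/G).
## Indels are never palindromic.
.isPalindromic <- function(ref, alt) {
  !is.na(.complement(ref)) & !is.na(.complement(alt)) & .complement(ref) == alt
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects two studies on `variant_id` and flips the outcome rows so both
#' studies report effects for the same allele of each variant. Alleles that
#' match only as strand complements (A<->T, C<->G recoding of both outcome
#' alleles) are accepted and recoded. Palindromic variants (A/T or C/G) are
#' retained only when the minor-allele frequency is below
#' `palindromeMafCutoff` in both studies and the frequencies agree in
#' orientation; otherwise they are dropped with a logged reason, as are
#' variants whose alleles cannot be reconciled.
#'
#' @param exposure,outcome canonical sumstats data.frames.
#' @param palindromeMafCutoff MAF below which a palindromic variant's strand
#'   can be inferred from allele frequency (default 0.42, the conservative
#'   community convention).
#' @return list with `pairs` (data.frame: variant_id, chrom, pos,
#'   effect_allele, other_allele, eaf_exposure, beta_exposure, se_exposure,
#'   eaf_outcome, beta_outcome, se_outcome) and `dropped` (data.frame:
#'   variant_id, reason).
#' @seealso [asMRInput()] to feed the result to the MR estimators.
#' @export
harmonizePair <- function(exposure, outcome, palindromeMafCutoff = 0.42) {
  validateSumstats(exposure); validateSumstats(outcome)
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]
  keep <- logical(length(shared))
  reason <- character(length(shared))
  for (i in seq_along(shared)) {
    e <- ex[i, ]; o <- ou[i, ]
    same <- setequal(c(e$ref_allele, e$alt_allele),
                     c(o$ref_allele, o$alt_allele)) &&
      nchar(e$ref_allele) + nchar(e$alt_allele) ==
      nchar(o$ref_allele) + nchar(o$alt_allele)
    if (!same) {
      ocr <- .complement(o$ref_allele); oca <- .complement(o$alt_allele)
      if (!is.na(ocr) && !is.na(oca) &&
          setequal(c(e$ref_allele, e$alt_allele), c(ocr, oca))) {
        # strand-complement match: recode both outcome alleles
        o$ref_allele <- ocr; o$alt_allele <- oca
        o$effect_allele <- .complement(o$effect_allele)
        same <- TRUE
      }
    }
    if (!same) { reason[i] <- "allele_mismatch"; next }
    if (.isPalindromic(e$ref_allele, e$alt_allele)) {
      if (is.na(e$eaf) || is.na(o$eaf)) {
        reason[i] <- "palindromic_missing_eaf"; next
      }
      maf_e <- min(e$eaf, 1 - e$eaf); maf_o <- min(o$eaf, 1 - o$eaf)
      if (maf_e >= palindromeMafCutoff || maf_o >= palindromeMafCutoff) {
        reason[i] <- "palindromic_ambiguous_maf"; next
      }
      # Align on the exposure effect allele by letter, then require frequency
      # agreement; on a palindrome the letters alone cannot fix the strand.
      o2 <- flipToEffectAllele(o, e$effect_allele)
      if ((o2$eaf < 0.5) != (e$eaf < 0.5)) {
        reason[i] <- "palindromic_freq_disagree"; next
      }
      ou[i, ] <- o2
      keep[i] <- TRUE
      next
    }
    ou[i, ] <- flipToEffectAllele(o, e$effect_allele)
    keep[i] <- TRUE
  }
  pairs <- data.frame(stringsAsFactors = FALSE,
    variant_id = ex$variant_id[keep], chrom = ex$chrom[keep],
    pos = ex$pos[keep], effect_allele = ex$effect_allele[keep],
    other_allele = ifelse(ex$effect_allele[keep] == ex$ref_allele[keep],
                          ex$alt_allele[keep], ex$ref_allele[keep]),
    eaf_exposure = ex$eaf[keep], beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep], p_exposure = ex$p[keep],
    eaf_outcome = ou$eaf[keep], beta_outcome = ou$beta[keep],
    se_outcome = ou$se[keep], p_outcome = ou$p[keep])
  dropped <- data.frame(variant_id = shared[!keep & nzchar(reason)],
                        reason = reason[!keep & nzchar(reason)],
                        stringsAsFactors = FALSE)
  list(pairs = pairs, dropped = dropped)
}

#' Convert harmonized pairs to MR input
#'
#' @param pairs the `pairs` element returned by [harmonizePair()].
#' @return An [MRInput2S-class] object.
#' @export
asMRInput <- function(pairs) {
  if (nrow(pairs) < 1L) .dataError("no harmonized variants to convert")
  mrInput(bx = pairs$beta_exposure, sx = pairs$se_exposure,
          by = pairs$beta_outcome, sy = pairs$se_outcome,
          variantId = pairs$variant_id)
}
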