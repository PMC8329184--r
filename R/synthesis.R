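## Cross-cohort synthesis: METAL-style sample-size-weighted z meta-analysis,
## inverse-variance effect-size meta-analysis, and Benjamini-Hochberg FDR.

#' Sample-size-weighted z-score meta-analysis
#'
#' The METAL default scheme: per-study z-scores \eqn{z_i = \beta_i/SE_i}
#' combined as \eqn{z = \sum_i z_i \sqrt{n_i} / \sqrt{\sum_i n_i}}, with a
#' two-sided normal p-value and a per-study direction string (`+`/`-`/`?`).
#'
#' @param betas,ses,ns numeric vectors, one entry per study; `ns` are
#'   (effective) sample sizes.
#' @return list with `z`, `p`, `directions`.
#' @examples
#' metaSampleWeighted(c(0.2, 0.2), c(0.1, 0.1), c(1000, 1000))$z  # sqrt(2)*2
#' @export
metaSampleWeighted <- function(betas, ses, ns) {
  if (any(ses <= 0) || any(ns <= 0))
    .validationError("ses and ns must be positive")
  z <- betas / ses
  zm <- sum(z * sqrt(ns)) / sqrt(sum(ns))
  list(z = zm, p = 2 * pnorm(-abs(zm)),
       directions = paste(ifelse(betas > 0, "+", ifelse(betas < 0, "-", "?")),
                          collapse = ""))
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' \eqn{\beta = \sum_i \beta_i/SE_i^2 \big/ \sum_i 1/SE_i^2},
#' \eqn{SE = (\sum_i 1/SE_i^2)^{-1/2}}.
#'
#' @param betas,ses numeric vectors, one entry per study.
#' @return list with `beta`, `se`, `p`.
#' @export
metaIvw <- function(betas, ses) {
  if (any(ses <= 0)) .validationError("ses must be positive")
  w <- 1 / ses^2
  beta <- sum(betas * w) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j} on the
#' sorted p-values, mapped back to input order.
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @return numeric vector of q-values in input order.
#' @export
bhFdr <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    .validationError("all p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Fill the q column of a scan result
#'
#' Applies [bhFdr()] over the scan's valid p-values (one FDR family per scan:
#' one predictor against one phenome), leaving failed rows `NA`.
#'
#' @param scan data.frame from [phewasScan()].
#' @return `scan` with `q` filled.
#' @export
addFdr <- function(scan) {
  ok <- !is.na(scan$p)
  scan$q[ok] <- bhFdr(scan$p[ok])
  scan
}

#' Meta-analyze scans from several cohorts
#'
#' Combines per-phenotype association rows across studies, by the
#' sample-size-weighted z scheme (default, as in METAL) or by
#' inverse-variance weighting of effect sizes, then applies
#' Benjamini-Hochberg FDR over the combined p-values. Only phenotypes present
#' with a valid fit in every study are combined.
#'
#' @param scans named list of [phewasScan()] data.frames, one per study.
#' @param scheme `"samplesize"` or `"ivw"`.
#' @return data.frame with one row per phenotype: per-study effects, the
#'   combined statistic, `p`, `q` and the direction string.
#' @export
metaScan <- function(scans, scheme = c("samplesize", "ivw")) {
  scheme <- match.arg(scheme)
  if (is.null(names(scans)))
    names(scans) <- paste0("study", seq_along(scans))
  usable <- lapply(scans, function(s) s[!is.na(s$p), , drop = FALSE])
  common <- Reduce(intersect, lapply(usable, function(s) s$phenotype))
  rows <- lapply(common, function(ph) {
    per <- lapply(usable, function(s) s[s$phenotype == ph, ][1L, ])
    betas <- vapply(per, function(r) r$beta, 0)
    ses <- vapply(per, function(r) r$se, 0)
    ns <- vapply(per, function(r) r$n_cases + r$n_controls, 0)
    base <- data.frame(phenotype = ph, label = per[[1L]]$label,
                       stringsAsFactors = FALSE)
    for (i in seq_along(per)) {
      base[[paste0("beta_", names(usable)[i])]] <- betas[i]
      base[[paste0("se_", names(usable)[i])]] <- ses[i]
      base[[paste0("n_", names(usable)[i])]] <- ns[i]
    }
    if (scheme == "samplesize") {
      mm <- metaSampleWeighted(betas, ses, ns)
      base$z_meta <- mm$z; base$p <- mm$p; base$directions <- mm$directions
    } else {
      mm <- metaIvw(betas, ses)
      base$beta_meta <- mm$beta; base$se_meta <- mm$se; base$p <- mm$p
      base$directions <- paste(ifelse(betas > 0, "+", "-"), collapse = "")
    }
    base
  })
  out <- do.call(rbind, rows)
  if (!is.null(out) && nrow(out)) out$q <- bhFdr(out$p)
  out
}
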