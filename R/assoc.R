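## Maximum-likelihood regression engine for genotype-phenotype scans.
## Logistic fits use iteratively reweighted least squares with Wald tests;
## linear fits use QR least squares with classical SEs. Both are written here
## rather than delegated so their numerical behaviour (convergence rules,
## separation flags) is under the package's control; the test suite checks
## them against stats::glm / stats::lm as independent references.

#' Encode genotypes under a genetic model
#'
#' @param dosages numeric vector of effect-allele dosages in \[0, 2\].
#' @param model `"additive"` (dosage as-is) or `"recessive"` (indicator of
#'   effect-allele homozygosity).
#' @param recessiveCut dosage at or above which an imputed dosage is treated
#'   as homozygous under the recessive model (default 1.5, i.e.
#'   round-to-nearest hard call).
#' @return numeric predictor vector.
#' @examples
#' encodeGenotype(c(0, 1, 2), "recessive")          # 0 0 1
#' encodeGenotype(c(0.2, 1.6), "recessive")          # 0 1
#' @export
encodeGenotype <- function(dosages, model = c("additive", "recessive"),
                           recessiveCut = 1.5) {
  model <- match.arg(model)
  out <- if (model == "additive") as.numeric(dosages)
         else as.numeric(dosages >= recessiveCut)
  names(out) <- names(dosages)
  out
}

## rank check shared by both fitters; names the collinear columns
.checkRank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    if (is.null(bad)) bad <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    .dataError(paste("design matrix is rank deficient; collinear column(s):",
                     paste(bad, collapse = ", ")))
  }
  qrX
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression with Wald z-tests. Convergence is
#' declared when the largest absolute score (gradient) component falls below
#' `tol`; quasi-separation is flagged when any |coefficient| exceeds 15 or
#' the fit fails to converge within `maxIter` iterations. A constant outcome
#' is returned as a degenerate fit (all estimates `NA`, flagged), not an
#' error.
#'
#' @param y binary response vector (0/1).
#' @param X design matrix including the intercept column.
#' @param maxIter maximum IRLS iterations (default 25).
#' @param tol score convergence tolerance (default 1e-8).
#' @return list with `coefficients`, `se`, `z`, `p` (two-sided Wald),
#'   `converged`, `separated`, `degenerate`, `n`, `iterations`.
#' @examples
#' set.seed(1)
#' x <- rbinom(200, 1, 0.5)
#' y <- rbinom(200, 1, plogis(-0.5 + 0.8 * x))
#' fit <- logisticFit(y, cbind(intercept = 1, x = x))
#' fit$coefficients
#' @export
logisticFit <- function(y, X, maxIter = 25L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) .validationError("y must be binary 0/1")
  if (length(y) != nrow(X)) .configError("length(y) must equal nrow(X)")
  if (length(y) <= ncol(X)) .dataError("more parameters than observations")
  p <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  na_fit <- list(coefficients = setNames(rep(NA_real_, p), nm),
                 se = setNames(rep(NA_real_, p), nm),
                 z = setNames(rep(NA_real_, p), nm),
                 p = setNames(rep(NA_real_, p), nm),
                 converged = FALSE, separated = TRUE, degenerate = TRUE,
                 n = length(y), iterations = 0L)
  if (var(y) == 0) return(na_fit)
  .checkRank(X)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    XtWX <- crossprod(X * w, X)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) return(na_fit)
    beta <- beta + step
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(X * w, X)
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cov)) return(na_fit)
  se <- sqrt(diag(cov))
  z <- beta / se
  separated <- !converged || any(abs(beta) > 15)
  list(coefficients = setNames(beta, nm), se = setNames(se, nm),
       z = setNames(z, nm), p = setNames(2 * pnorm(-abs(z)), nm),
       converged = converged, separated = separated, degenerate = FALSE,
       n = length(y), iterations = iter)
}

#' Ordinary least squares with classical standard errors
#'
#' @param y quantitative response vector.
#' @param X design matrix (include an intercept column for the usual model).
#' @return list with `coefficients`, `se`, `t`, `p` (two-sided, df = n - p),
#'   `sigma` (residual SE), `df_residual`, `n`.
#' @export
linearFit <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) .configError("length(y) must equal nrow(X)")
  if (length(y) <= ncol(X)) .dataError("more parameters than observations")
  qrX <- .checkRank(X)
  beta <- qr.coef(qrX, y)
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
  list(coefficients = setNames(beta, nm), se = setNames(se, nm),
       t = setNames(tstat, nm),
       p = setNames(2 * pt(-abs(tstat), df), nm),
       sigma = sqrt(sigma2), df_residual = df, n = length(y))
}

#' Polygenic score from dosages and discovery weights
#'
#' Computes the per-person weighted allele-dosage sum
#' \eqn{s_i = \sum_j g_{ij} \beta_j} after aligning every weight to the
#' dosage matrix's counted (alt) allele, and its cohort-standardized version
#' \eqn{z_i = (s_i - \bar s)/\mathrm{SD}(s)}. Missing dosages are mean-imputed
#' within the cohort by default.
#'
#' @param G a [GenotypeMatrix-class]; dosages count the alt allele.
#' @param weights data.frame with columns `variant_id`, `effect_allele`,
#'   `beta` (discovery-study per-allele effects).
#' @param missingDosage `"mean"` (impute the cohort mean dosage) or `"drop"`
#'   (drop persons with any missing weight-variant dosage; their scores are
#'   `NA`).
#' @return list with `raw`, `standardized` (both named by person),
#'   `zero_variance` flag (standardized is `NA` when the raw score does not
#'   vary).
#' @export
computePrs <- function(G, weights, missingDosage = c("mean", "drop")) {
  missingDosage <- match.arg(missingDosage)
  vi <- variantInfo(G)
  missing <- setdiff(weights$variant_id, vi$variant_id)
  if (length(missing))
    .dataError(paste("weight variant(s) missing from genotypes:",
                     paste(missing, collapse = ", ")))
  d <- dosages(G)[weights$variant_id, , drop = FALSE]
  m <- match(weights$variant_id, vi$variant_id)
  on_alt <- weights$effect_allele == vi$alt[m]
  on_ref <- weights$effect_allele == vi$ref[m]
  if (any(!on_alt & !on_ref))
    .dataError(paste("effect allele not among the variant's alleles for:",
                     paste(weights$variant_id[!on_alt & !on_ref],
                           collapse = ", ")))
  # effect on the ref allele: dosage of the effect allele is 2 - alt dosage
  d[on_ref, ] <- 2 - d[on_ref, , drop = FALSE]
  if (anyNA(d)) {
    if (missingDosage == "mean") {
      mu <- rowMeans(d, na.rm = TRUE)
      for (j in which(rowSums(is.na(d)) > 0))
        d[j, is.na(d[j, ])] <- mu[j]
    }  # "drop": NAs propagate to the person's score
  }
  raw <- drop(crossprod(d, weights$beta))
  names(raw) <- colnames(d)
  sdr <- sd(raw, na.rm = TRUE)
  zero_var <- is.na(sdr) || sdr == 0
  standardized <- if (zero_var) setNames(rep(NA_real_, length(raw)), names(raw))
                  else (raw - mean(raw, na.rm = TRUE)) / sdr
  list(raw = raw, standardized = standardized, zero_variance = zero_var)
}

#' Covariate matrix from cohort demographics
#'
#' Assembles the standard PheWAS adjustment set — sex plus age (or birth
#' decade) plus any principal-component columns — as a numeric matrix aligned
#' to the cohort's persons.
#'
#' @param cohort a [PhenomeCohort-class].
#' @return numeric matrix, one row per person.
#' @export
covariateMatrix <- function(cohort) {
  dem <- cohortDemographics(cohort)
  cols <- list()
  if ("sex" %in% names(dem))
    cols$sex <- as.numeric(factor(dem$sex)) - 1
  if ("age" %in% names(dem)) cols$age <- as.numeric(dem$age)
  else if ("birth_decade" %in% names(dem))
    cols$birth_decade <- as.numeric(dem$birth_decade)
  for (pc in grep("^PC[0-9]+$", names(dem), value = TRUE))
    cols[[pc]] <- as.numeric(dem[[pc]])
  if (!length(cols)) return(NULL)
  out <- do.call(cbind, cols)
  rownames(out) <- dem$person_id
  out
}

#' Phenome-wide association scan
#'
#' Fits, for every retained phecode in the cohort, a logistic regression of
#' case status on the predictor (an encoded genotype or a standardized PRS)
#' with the supplied covariates, dropping excluded persons. Phecodes whose
#' fit fails (e.g. a constant predictor after exclusions) are reported as
#' flagged rows; the scan never aborts. The `q` column is left `NA` for
#' [addFdr()] to fill.
#'
#' @param cohort a [PhenomeCohort-class].
#' @param predictor numeric vector named by (or aligned to) the cohort's
#'   persons: an encoded dosage or a standardized PRS.
#' @param covariates numeric matrix aligned to the cohort's persons, or
#'   `NULL` to use [covariateMatrix()].
#' @param predictorName label for the output rows (e.g. a variant id or
#'   `"PRS"`).
#' @return data.frame of scan results: `phenotype`, `label`, `predictor`,
#'   `beta`, `se`, `or`, `p`, `q`, `n_cases`, `n_controls`, `converged`.
#' @export
phewasScan <- function(cohort, predictor, covariates = NULL,
                       predictorName = "SNP") {
  status <- cohortStatus(cohort)
  persons <- rownames(status)
  if (!is.null(names(predictor))) predictor <- predictor[persons]
  if (length(predictor) != length(persons))
    .configError("predictor must align with the cohort's persons")
  if (is.null(covariates)) covariates <- covariateMatrix(cohort)
  if (!is.null(covariates) && !is.null(rownames(covariates)))
    covariates <- covariates[persons, , drop = FALSE]
  phecodes <- retainedPhecodes(cohort)
  pinfo <- phecodeInfo(cohort)
  rows <- lapply(phecodes, function(phi) {
    s <- status[, phi]
    use <- !is.na(s) & !is.na(predictor)
    y <- s[use]
    X <- cbind(intercept = 1, predictor = predictor[use])
    if (!is.null(covariates)) X <- cbind(X, covariates[use, , drop = FALSE])
    fit <- tryCatch(logisticFit(y, X), error = function(e) NULL)
    ok <- !is.null(fit) && !fit$degenerate
    data.frame(phenotype = phi,
               label = pinfo$label[match(phi, pinfo$phecode)],
               predictor = predictorName,
               beta = if (ok) unname(fit$coefficients["predictor"]) else NA_real_,
               se = if (ok) unname(fit$se["predictor"]) else NA_real_,
               or = if (ok) exp(unname(fit$coefficients["predictor"])) else NA_real_,
               p = if (ok) unname(fit$p["predictor"]) else NA_real_,
               q = NA_real_,
               n_cases = sum(y == 1), n_controls = sum(y == 0),
               converged = ok && fit$converged && !fit$separated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
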