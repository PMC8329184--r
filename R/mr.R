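## Two-sample Mendelian randomization estimators: Wald ratio, fixed-effect
## inverse-variance weighted (IVW), MR-Egger, and the weighted median, with
## Cochran's Q heterogeneity, plus a bidirectional driver.

.mrRow <- function(method, n_variants, estimate, se,
                   intercept = NA_real_, intercept_se = NA_real_,
                   intercept_p = NA_real_, Q = NA_real_, Q_df = NA_real_,
                   Q_p = NA_real_) {
  data.frame(method = method, n_variants = n_variants,
             estimate = estimate, se = se,
             p = 2 * pnorm(-abs(estimate / se)),
             intercept = intercept, intercept_se = intercept_se,
             intercept_p = intercept_p, Q = Q, Q_df = Q_df, Q_p = Q_p,
             stringsAsFactors = FALSE)
}

#' Wald ratio for a single instrument
#'
#' Causal estimate from one variant: the ratio of outcome to exposure beta,
#' with the first-order delta-method SE (`sy / |bx|`).
#'
#' @param bx,sx exposure beta and SE.
#' @param by,sy outcome beta and SE.
#' @return one-row data.frame (method `"wald"`) with estimate, se, p.
#' @export
waldRatio <- function(bx, sx, by, sy) {
  if (bx == 0) .dataError("undefined ratio: exposure beta is zero")
  .mrRow("wald", 1L, by / bx, sy / abs(bx))
}

## Cochran's Q about a fitted slope, first-order weights
.cochranQ <- function(bx, by, sy, slope) {
  Q <- sum((by - slope * bx)^2 / sy^2)
  df <- length(bx) - 1L
  list(Q = Q, df = df,
       p = if (df >= 1L) pchisq(Q, df, lower.tail = FALSE) else NA_real_)
}

#' Inverse-variance weighted estimator
#'
#' Fixed-effect IVW: \eqn{\hat\beta = \sum_j b_{Xj} b_{Yj}/s_{Yj}^2 \big/
#' \sum_j b_{Xj}^2/s_{Yj}^2}, the zero-intercept weighted least-squares slope
#' of outcome on exposure betas with first-order weights \eqn{1/s_{Yj}^2};
#' \eqn{SE = (\sum_j b_{Xj}^2/s_{Yj}^2)^{-1/2}}. Cochran's Q about the fitted
#' slope, on m - 1 degrees of freedom, accompanies the estimate; Q inflation
#' suggests horizontal pleiotropy.
#'
#' @param input an [MRInput2S-class].
#' @param overdispersion if `TRUE`, scale the SE by
#'   \eqn{\max(1, \sqrt{Q/(m-1)})} (multiplicative random effects); default
#'   `FALSE` (fixed effect).
#' @return one-row data.frame (method `"ivw"`).
#' @export
mrIvw <- function(input, overdispersion = FALSE) {
  bx <- input@bx; by <- input@by; sy <- input@sy
  if (all(bx == 0)) .dataError("degenerate instruments: all exposure betas zero")
  w <- 1 / sy^2
  est <- sum(bx * by * w) / sum(bx^2 * w)
  se <- 1 / sqrt(sum(bx^2 * w))
  q <- .cochranQ(bx, by, sy, est)
  if (overdispersion && q$df >= 1L) se <- se * max(1, sqrt(q$Q / q$df))
  .mrRow("ivw", length(bx), est, se, Q = q$Q, Q_df = q$df, Q_p = q$p)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept, weights \eqn{1/s_{Yj}^2}, after orienting every variant so its
#' exposure beta is positive. The slope estimates the causal effect under the
#' InSIDE assumption; the intercept estimates average directional pleiotropy.
#' SEs carry the usual multiplicative overdispersion factor
#' \eqn{\max(1, \sqrt{RSS_w/(m-2)})}.
#'
#' @param input an [MRInput2S-class] with at least 3 variants.
#' @return one-row data.frame (method `"egger"`) including `intercept`,
#'   `intercept_se`, `intercept_p` and Q on m - 2 df.
#' @export
mrEgger <- function(input) {
  m <- length(input@bx)
  if (m < 3L) .dataError("MR-Egger requires at least 3 instruments")
  flip <- sign(input@bx)
  flip[flip == 0] <- 1
  bx <- input@bx * flip; by <- input@by * flip; sy <- input@sy
  w <- 1 / sy^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X * w, X)
  coefs <- solve(XtWX, crossprod(X * w, by))
  res <- by - drop(X %*% coefs)
  rss <- sum(w * res^2)
  disp <- max(1, sqrt(rss / (m - 2)))
  covb <- chol2inv(chol(XtWX)) * disp^2
  se <- sqrt(diag(covb))
  out <- .mrRow("egger", m, coefs[2L], se[2L],
                intercept = coefs[1L], intercept_se = se[1L],
                intercept_p = 2 * pnorm(-abs(coefs[1L] / se[1L])),
                Q = rss, Q_df = m - 2L,
                Q_p = pchisq(rss, m - 2L, lower.tail = FALSE))
  out
}

## weighted median of ratio estimates; weights must sum to 1
.weightedMedian <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  cw <- cumsum(w)
  pj <- cw - w / 2
  if (0.5 <= pj[1L]) return(r[1L])
  if (0.5 >= pj[length(pj)]) return(r[length(r)])
  stats::approx(pj, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Consistent causal estimate when instruments carrying at least half the
#' weight are valid. Per-variant ratio estimates \eqn{r_j = b_{Yj}/b_{Xj}}
#' are weighted by \eqn{w_j \propto b_{Xj}^2/s_{Yj}^2} (normalized to sum 1);
#' the estimate is the weighted median obtained by linear interpolation of
#' the ordered ratios at cumulative percentile 0.5. The SE comes from a
#' seeded parametric bootstrap resampling \eqn{b_{Xj}^* \sim N(b_{Xj},
#' s_{Xj})}, \eqn{b_{Yj}^* \sim N(b_{Yj}, s_{Yj})}.
#'
#' @param input an [MRInput2S-class] with at least 3 variants.
#' @param nBoot bootstrap replicates for the SE (default 1000, minimum 100).
#' @param seed integer seed for the bootstrap.
#' @return one-row data.frame (method `"weighted_median"`).
#' @export
mrWeightedMedian <- function(input, nBoot = 1000L, seed = 1L) {
  m <- length(input@bx)
  if (m < 3L) .dataError("weighted median requires at least 3 instruments")
  if (nBoot < 100L) .configError("nBoot must be >= 100")
  bx <- input@bx; sx <- input@sx; by <- input@by; sy <- input@sy
  w <- bx^2 / sy^2
  est <- .weightedMedian(by / bx, w / sum(w))
  boots <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      bxs <- rnorm(m, bx, sx)
      bys <- rnorm(m, by, sy)
      ws <- bxs^2 / sy^2
      .weightedMedian(bys / bxs, ws / sum(ws))
    }, 0)
  })
  .mrRow("weighted_median", m, est, sd(boots))
}

#' Run all applicable MR estimators
#'
#' IVW always (reducing to the Wald ratio for a single instrument); MR-Egger
#' and the weighted median when at least 3 instruments are available.
#'
#' @param input an [MRInput2S-class].
#' @param nBoot,seed passed to [mrWeightedMedian()].
#' @param overdispersion passed to [mrIvw()].
#' @return data.frame, one row per method.
#' @export
mrAllMethods <- function(input, nBoot = 1000L, seed = 1L,
                         overdispersion = FALSE) {
  out <- mrIvw(input, overdispersion = overdispersion)
  if (length(input@bx) >= 3L) {
    out <- rbind(out, mrEgger(input),
                 mrWeightedMedian(input, nBoot = nBoot, seed = seed))
  } else {
    warning("fewer than 3 instruments: Egger and weighted median skipped")
  }
  out
}

#' Bi-directional two-sample Mendelian randomization
#'
#' Harmonizes each direction's instrument set against the other study and
#' runs every applicable estimator, reporting forward (exposure -> outcome)
#' and reverse (outcome -> exposure) results side by side. A direction with
#' no usable instruments is skipped with a warning.
#'
#' @param exposureSumstats,outcomeSumstats canonical sumstats data.frames for
#'   the two traits (full tables, not just instruments).
#' @param instrumentsFwd,instrumentsRev character vectors of variant ids
#'   selected as instruments in the exposure and outcome study respectively.
#' @param palindromeMafCutoff passed to [harmonizePair()].
#' @param nBoot,seed passed to [mrWeightedMedian()].
#' @return list with `forward` and `reverse` data.frames (each with a
#'   `direction` column), either possibly `NULL`.
#' @export
bidirectionalMr <- function(exposureSumstats, outcomeSumstats,
                            instrumentsFwd, instrumentsRev,
                            palindromeMafCutoff = 0.42, nBoot = 1000L,
                            seed = 1L) {
  runDir <- function(expo, outc, instruments, label) {
    ss <- expo[expo$variant_id %in% instruments, , drop = FALSE]
    if (nrow(ss) == 0L) {
      warning(sprintf("no instruments for the %s direction: skipped", label))
      return(NULL)
    }
    h <- harmonizePair(ss, outc, palindromeMafCutoff = palindromeMafCutoff)
    if (nrow(h$pairs) == 0L) {
      warning(sprintf(
        "no harmonizable instruments for the %s direction: skipped", label))
      return(NULL)
    }
    res <- mrAllMethods(asMRInput(h$pairs), nBoot = nBoot, seed = seed)
    cbind(direction = label, res, stringsAsFactors = FALSE)
  }
  list(forward = runDir(exposureSumstats, outcomeSumstats, instrumentsFwd,
                        "forward"),
       reverse = runDir(outcomeSumstats, exposureSumstats, instrumentsRev,
                        "reverse"))
}
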