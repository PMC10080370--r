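## Rubin-rule pooling across imputations, on the probability scale.
## Pooling on probabilities (not logits) keeps exact zeros representable:
## a cell estimated 0 in every imputation pools to 0 with a degenerate CI.

rubinCombine <- function(pArr, vArr, m) {
  pbar <- apply(pArr, c(1, 2), mean)
  W <- apply(vArr, c(1, 2), mean)
  B <- apply(pArr, c(1, 2), var)
  if (m == 1) stop("between-imputation variance undefined for m = 1")
  Tvar <- W + (1 + 1 / m) * B
  list(pbar = pbar, W = W, B = B, Tvar = Tvar)
}

#' Pool transition estimates across imputations by Rubin's rule
#'
#' The pooled point estimate is the mean of the per-imputation matrices;
#' total variance is W + (1 + 1/M) B with W the mean within-imputation
#' variance and B the between-imputation variance of the estimates. 95%
#' confidence intervals use the normal quantile (1.96) by default or
#' Rubin's t reference with Barnard-Rubin-style small-sample degrees of
#' freedom, and are truncated to [0, 1].
#'
#' @param estimates List of [TransitionEstimate] objects over the M
#'   imputations; all must share therapy and window, M >= 2.
#' @param ciReference `"normal"` (default) or `"t"`.
#' @return A [PooledTransitions].
#' @export
setMethod("poolRubin", "list", function(estimates, ciReference = "normal",
                                        ...) {
  m <- length(estimates)
  if (m < 2) stop("pooling requires m >= 2 imputations")
  ths <- unique(vapply(estimates, function(e) e@therapy, ""))
  ws <- unique(vapply(estimates, function(e) e@window, ""))
  if (length(ths) != 1 || length(ws) != 1)
    stop("all estimates must share therapy and window")
  pArr <- simplify2array(lapply(estimates, function(e) e@p))
  vArr <- simplify2array(lapply(estimates, function(e) e@var))
  rc <- rubinCombine(pArr, vArr, m)
  z <- ciQuantile(rc, m, ciReference)
  half <- z * sqrt(rc$Tvar)
  new("PooledTransitions", therapy = ths, window = ws,
      p = rc$pbar, within = rc$W, between = rc$B, totalVar = rc$Tvar,
      ciLo = clamp(rc$pbar - half, 0, 1),
      ciHi = clamp(rc$pbar + half, 0, 1),
      m = as.integer(m))
})

## per-cell CI quantile: 1.96 for the normal reference, else Rubin's t with
## df = (m - 1) (1 + W / ((1 + 1/m) B))^2 (infinite when B = 0)
ciQuantile <- function(rc, m, ciReference) {
  if (ciReference == "normal") return(1.959963984540054)
  r <- (1 + 1 / m) * rc$B / pmax(rc$W, .Machine$double.eps)
  df <- (m - 1) * (1 + 1 / pmax(r, .Machine$double.eps))^2
  q <- stats::qt(0.975, pmin(df, 1e8))
  q[rc$Tvar == 0] <- 0
  q
}

#' Contrast two therapies' transition matrices
#'
#' Elementwise difference of the per-imputation matrices (therapy A minus
#' therapy B), Rubin-pooled: within-imputation variance of a difference is
#' the sum of the two cell variances, the between component is the sample
#' variance of the differences. The pooled point estimate is exactly the
#' difference of the pooled per-therapy estimates. CIs are truncated to
#' [-1, 1]. Contrasting a therapy with itself gives the zero matrix with
#' zero-width intervals.
#'
#' @param estimatesA,estimatesB Lists of [TransitionEstimate] over the same
#'   M imputations and the same window.
#' @param ciReference `"normal"` (default) or `"t"`.
#' @return A [TransitionContrast].
#' @export
setMethod("contrastTherapies", signature("list", "list"),
          function(estimatesA, estimatesB, ciReference = "normal", ...) {
  m <- length(estimatesA)
  if (length(estimatesB) != m)
    stop("both therapies must be pooled over the same m")
  if (m < 2) stop("contrast requires m >= 2 imputations")
  wA <- unique(vapply(estimatesA, function(e) e@window, ""))
  wB <- unique(vapply(estimatesB, function(e) e@window, ""))
  if (length(wA) != 1 || !identical(wA, wB))
    stop("window mismatch between contrast arms")
  thA <- unique(vapply(estimatesA, function(e) e@therapy, ""))
  thB <- unique(vapply(estimatesB, function(e) e@therapy, ""))
  if (length(thA) != 1 || length(thB) != 1)
    stop("each arm must hold a single therapy")

  dArr <- simplify2array(lapply(seq_len(m), function(i)
    estimatesA[[i]]@p - estimatesB[[i]]@p))
  selfContrast <- identical(thA, thB)
  vArr <- if (selfContrast) {
    ## the same estimate differenced with itself has exactly zero variance
    array(0, dim = dim(dArr))
  } else {
    simplify2array(lapply(seq_len(m), function(i)
      estimatesA[[i]]@var + estimatesB[[i]]@var))
  }
  rc <- rubinCombine(dArr, vArr, m)
  z <- ciQuantile(rc, m, ciReference)
  half <- z * sqrt(rc$Tvar)
  new("TransitionContrast", therapyA = thA, therapyB = thB, window = wA,
      d = rc$pbar, totalVar = rc$Tvar,
      ciLo = clamp(rc$pbar - half, -1, 1),
      ciHi = clamp(rc$pbar + half, -1, 1),
      m = as.integer(m))
})
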