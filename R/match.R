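#' Mahalanobis distance between covariate vectors
#'
#' Computes `sqrt((x - y)' Sinv (x - y))` for a supplied inverse covariance
#' matrix. Symmetric in its arguments and zero iff `x == y`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param sInv Symmetric positive-definite inverse covariance matrix.
#' @return A nonnegative scalar.
#' @export
mahalanobisDist <- function(x, y, sInv) {
  if (length(x) != length(y))
    stop("x and y must have the same length")
  if (!isTRUE(all.equal(sInv, t(sInv), tolerance = 1e-8)))
    stop("sInv must be symmetric")
  ## chol() fails on non-positive-definite input, surfacing the error early
  chol(sInv)
  d <- x - y
  sqrt(max(drop(t(d) %*% sInv %*% d), 0))
}

#' Matrix of matching covariates
#'
#' Builds the numeric matching vector for every patient: the binary
#' covariates as 0/1 indicators, continuous covariates on their raw scale,
#' and the baseline IGA stage as an ordinal 1-4. BMI is carried in the
#' cohort but does not enter the matching vector.
#'
#' @param cohort A complete [PsoriasisCohort].
#' @return Numeric matrix, one row per patient, rownames = patient ids.
#' @export
matchingCovariates <- function(cohort) {
  p <- cohort@patients
  info <- covariateInfo()
  vars <- info$name[info$matching]
  if (anyNA(p[, vars]))
    stop("matching requires complete covariates; impute first")
  X <- as.matrix(p[, vars])
  X <- cbind(X, iga_stage = stageIndex(p$baseline_stage))
  rownames(X) <- p$id
  X
}

## inverse of the pooled covariance, ridge-regularized if near-singular
pooledCovInverse <- function(X) {
  S <- cov(X)
  eps <- 0
  for (k in 0:12) {
    Sr <- S + diag(eps, ncol(S))
    ok <- tryCatch({ chol(Sr); TRUE }, error = function(e) FALSE)
    if (ok && rcond(Sr) > 1e-12) return(chol2inv(chol(Sr)))
    eps <- if (eps == 0) 1e-8 * mean(diag(S)) else eps * 10
  }
  stop("pooled covariance could not be regularized to positive definite")
}

## nearest candidate (by squared Euclidean distance in the whitened space)
## for each anchor row; ties and near-ties (within 1e-8 relative) resolved
## to the lowest candidate id; candidates must be sorted by id
nearestIndex <- function(Za, Zc, chunk = 512L) {
  nc2 <- rowSums(Zc^2)
  out <- integer(nrow(Za))
  start <- 1L
  while (start <= nrow(Za)) {
    end <- min(start + chunk - 1L, nrow(Za))
    blk <- Za[start:end, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), nc2, "+") - 2 * tcrossprod(blk, Zc)
    d2 <- pmax(d2, 0)
    mins <- apply(d2, 1, min)
    tol <- 1e-8 * (1 + mins)
    for (i in seq_len(nrow(blk)))
      out[start + i - 1L] <- which(d2[i, ] <= mins[i] + tol[i])[1L]
    start <- end + 1L
  }
  out
}

#' Tri-directional nearest-neighbour matching with replacement
#'
#' For every patient (the anchor), finds the nearest unit by Mahalanobis
#' distance in each of the other two therapy arms, with replacement (a unit
#' can serve as the match for many anchors). The metric's covariance matrix
#' is estimated once on the pooled (all-arm) cohort; if singular it is
#' ridge-regularized. Each patient therefore anchors exactly one triple that
#' spans all three arms, and a unit's frequency weight is the number of
#' triples it appears in. Ties in distance are broken toward the lowest
#' patient id, making the procedure deterministic.
#'
#' @param cohort A complete [PsoriasisCohort] with all three arms present.
#' @param imputationIndex Optional index recording which imputed copy this
#'   is (bookkeeping only).
#' @return A [MatchedCohort] with `nrow(patients)` triples.
#' @export
setMethod("matchThreeGroups", "PsoriasisCohort",
          function(cohort, imputationIndex = 0L, ...) {
  p <- cohort@patients
  cnt <- table(factor(p$therapy, levels = therapyLevels()))
  if (any(cnt == 0))
    stop("empty therapy arm(s): ",
         paste(names(cnt)[cnt == 0], collapse = ", "))
  X <- matchingCovariates(cohort)
  sInv <- pooledCovInverse(X)
  U <- chol(sInv)
  ## whiten, then center: distances are translation-invariant, and
  ## centering avoids catastrophic cancellation in the cross-product
  ## nearest-neighbour search when the ridge inflates degenerate directions
  Z <- X %*% t(U)
  Z <- sweep(Z, 2, colMeans(Z))

  ids <- p$id
  byArm <- lapply(therapyLevels(), function(th) {
    sel <- which(p$therapy == th)
    sel[order(ids[sel])]       # candidates sorted by id for tie-breaking
  })
  names(byArm) <- therapyLevels()

  cols <- list()
  for (th in therapyLevels()) {
    col <- character(nrow(p))
    own <- p$therapy == th
    col[own] <- ids[own]       # anchor occupies its own-therapy slot
    cand <- byArm[[th]]
    other <- which(!own)
    nn <- nearestIndex(Z[other, , drop = FALSE],
                       Z[cand, , drop = FALSE])
    col[other] <- ids[cand][nn]
    cols[[th]] <- col
  }

  tr <- data.frame(anchor_id = ids,
                   biologic_id = cols$biologic,
                   traditional_id = cols$traditional,
                   systemic_id = cols$systemic,
                   stringsAsFactors = FALSE)
  new("MatchedCohort", triples = tr,
      imputationIndex = as.integer(imputationIndex))
})

weightedMeanVar <- function(x, w) {
  mu <- sum(w * x) / sum(w)
  v <- sum(w * (x - mu)^2) / sum(w)
  c(mean = mu, var = v)
}

smdOf <- function(x1, w1, x2, w2) {
  a <- weightedMeanVar(x1, w1); b <- weightedMeanVar(x2, w2)
  denom <- sqrt((a["var"] + b["var"]) / 2)
  if (denom == 0) return(0)
  abs(a["mean"] - b["mean"]) / denom
}

#' Covariate balance before and after matching
#'
#' For every matching covariate and every pairwise therapy contrast, reports
#' the standardized mean difference (SMD) and a two-sample test p-value,
#' before matching (raw arms) and after matching (frequency-weighted matched
#' populations, tests on the weight-expanded samples). Continuous
#' covariates use Welch t-tests, binary covariates chi-squared tests.
#'
#' @param cohort The complete [PsoriasisCohort] that was matched.
#' @param matched The [MatchedCohort] derived from it.
#' @return data.frame with columns `covariate`, `contrast`, `smd_pre`,
#'   `smd_post`, `p_pre`, `p_post`.
#' @export
setMethod("balanceDiagnostics", signature("PsoriasisCohort", "MatchedCohort"),
          function(cohort, matched, ...) {
  p <- cohort@patients
  X <- matchingCovariates(cohort)
  info <- covariateInfo()
  types <- c(setNames(info$type, info$name), iga_stage = "continuous")
  tr <- matched@triples
  armIds <- list(biologic = tr$biologic_id,
                 traditional = tr$traditional_id,
                 systemic = tr$systemic_id)
  pairs <- list(c("biologic", "traditional"),
                c("biologic", "systemic"),
                c("traditional", "systemic"))
  rowList <- list()
  for (v in colnames(X)) {
    xv <- setNames(X[, v], rownames(X))
    for (pr in pairs) {
      raw1 <- xv[p$id[p$therapy == pr[1]]]
      raw2 <- xv[p$id[p$therapy == pr[2]]]
      m1 <- xv[armIds[[pr[1]]]]   # weight-expanded matched populations
      m2 <- xv[armIds[[pr[2]]]]
      testP <- function(x1, x2) {
        if (types[[v]] == "binary") {
          tab <- rbind(c(sum(x1), length(x1) - sum(x1)),
                       c(sum(x2), length(x2) - sum(x2)))
          if (any(colSums(tab) == 0)) return(1)
          suppressWarnings(chisq.test(tab)$p.value)
        } else {
          if (sd(x1) == 0 && sd(x2) == 0) return(1)
          t.test(x1, x2)$p.value
        }
      }
      rowList[[length(rowList) + 1L]] <- data.frame(
        covariate = v, contrast = paste(pr, collapse = "_vs_"),
        smd_pre = smdOf(raw1, rep(1, length(raw1)),
                        raw2, rep(1, length(raw2))),
        smd_post = smdOf(m1, rep(1, length(m1)), m2, rep(1, length(m2))),
        p_pre = testP(raw1, raw2),
        p_post = testP(m1, m2),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rowList)
  rownames(out) <- NULL
  out
})
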