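#' @import methods
#' @importFrom stats cov plogis qlogis rnorm runif rbinom rchisq rlnorm
#'   uniroot sd var qnorm setNames complete.cases t.test chisq.test
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' IGA severity stage labels
#'
#' The four severity stages used throughout the package: IGA scores 0 and 1
#' are collapsed into a single clear/almost-clear stage (`S01`); scores 2-4
#' map to `S2`, `S3`, `S4`. Higher stages are more severe.
#'
#' @return Character vector of the 4 ordered stage labels.
#' @export
stageLevels <- function() c("S01", "S2", "S3", "S4")

#' Therapy arm labels
#'
#' @return Character vector of the 3 therapy arms: biologic (TNF-alpha and
#'   interleukin inhibitors), traditional (topical/phototherapy) and systemic
#'   (nonbiologic systemic drugs).
#' @export
therapyLevels <- function() c("biologic", "traditional", "systemic")

#' Follow-up window labels
#'
#' Two posttreatment windows: `w1` = days (0, 30] (0-1 month) and
#' `w2` = days (30, 365] (1-12 months). One month is taken as 30 days.
#'
#' @return Character vector `c("w1", "w2")`.
#' @export
windowLevels <- function() c("w1", "w2")

#' Baseline covariate metadata
#'
#' Names and types of the baseline covariates carried by a cohort, and
#' whether each enters the Mahalanobis matching vector. Binary covariates are
#' coded 0/1 (sex: 1 = male; marital: 1 = married; employment: 1 = full time;
#' education: 1 = college or higher; smoking: 1 = current; lesion sites:
#' 1 = affected; family_history/comorbidity: 1 = positive).
#'
#' @return A data.frame with columns `name`, `type` ("continuous" or
#'   "binary") and `matching` (logical).
#' @export
covariateInfo <- function() {
  data.frame(
    name = c("sex", "age", "bmi", "marital", "employment", "education",
             "smoking", "duration", "family_history", "nail", "scalp",
             "palmoplantar", "genital", "pasi", "bsa", "dlqi", "comorbidity"),
    type = c("binary", "continuous", "continuous", "binary", "binary",
             "binary", "binary", "continuous", "binary", "binary", "binary",
             "binary", "binary", "continuous", "continuous", "continuous",
             "binary"),
    # bmi is carried in the cohort but is not part of the matching vector
    matching = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## vectorized categorical draw: one draw per row of a row-stochastic matrix
rcatRows <- function(p) {
  p <- p / rowSums(p)
  cs <- p
  for (j in seq_len(ncol(p))[-1]) cs[, j] <- cs[, j - 1] + p[, j]
  u <- runif(nrow(p))
  1L + rowSums(cs < u)
}

## calibrate per-arm intercepts of a softmax model so that the average
## assignment probabilities equal the target shares (iterative proportional
## fitting on the intercepts; monotone and fast)
calibrateSoftmaxIntercepts <- function(lp, target, iter = 200, tol = 1e-12) {
  a <- log(target)
  for (k in seq_len(iter)) {
    eta <- sweep(lp, 2, a, "+")
    eta <- eta - apply(eta, 1, max)
    p <- exp(eta)
    p <- p / rowSums(p)
    shares <- colMeans(p)
    if (max(abs(shares - target)) < tol) break
    a <- a + log(target / shares)
  }
  a - a[which(colnames(lp) == "traditional")]
}

softmaxProbs <- function(lp, intercepts) {
  eta <- sweep(lp, 2, intercepts, "+")
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p / rowSums(p)
}

## calibrate the intercept of a logistic masking model so that the mean
## masking probability over the realized cohort equals `rate`
calibrateLogitIntercept <- function(offset, rate) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  f <- function(a) mean(plogis(a + offset)) - rate
  uniroot(f, c(-30, 30), tol = 1e-12)$root
}

## FNV-1a 32-bit hash of a character scalar, as 8 hex digits; used for
## pipeline manifests (stable across platforms, no external dependency)
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    ## xor touches only the low byte; keep h as a double in [0, 2^32)
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    ## 32-bit modular multiply by 16777619: split to avoid > 2^53 overflow
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * 16777619) %% 4294967296 +
          ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
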