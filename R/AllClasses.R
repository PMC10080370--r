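## Central S4 data containers: ground-truth simulation parameters, cohort,
## imputed set, matched cohort, transition estimates, pooled results and
## contrasts. Validity methods enforce the structural invariants the
## estimators rely on (4 ordered stages, 3 arms, row-stochastic kernels,
## strictly increasing visit days, covariate ranges).

checkKernels <- function(kernels, tol = 1e-12) {
  if (!setequal(names(kernels), therapyLevels()))
    return("kernels must be a named list over the 3 therapies")
  for (th in names(kernels)) {
    if (!setequal(names(kernels[[th]]), windowLevels()))
      return(sprintf("kernels[['%s']] must have elements w1 and w2", th))
    for (w in names(kernels[[th]])) {
      k <- kernels[[th]][[w]]
      if (!is.matrix(k) || !all(dim(k) == c(4, 4)))
        return("each kernel must be a 4x4 matrix")
      if (any(k < 0))
        return("kernel entries must be nonnegative")
      if (any(abs(rowSums(k) - 1) > tol))
        return(sprintf("kernel rows must sum to 1 (therapy %s, window %s)",
                       th, w))
    }
  }
  TRUE
}

#' Ground-truth parameters of the synthetic-cohort generator
#'
#' Everything that defines a simulated registry cohort: size, confounded
#' treatment-assignment model (slopes on standardized PASI, DLQI, disease
#' duration and ordinal baseline stage, plus target marginal arm shares to
#' which intercepts are calibrated), therapy- and window-specific 4x4
#' transition kernels (baseline stage to window outcome), baseline stage
#' distribution, covariate and follow-up-visit missingness rates, an
#' outcome-tilt coefficient controlling how strongly transitions are
#' modulated by within-stage severity (0 = outcomes depend on therapy and
#' baseline stage only), and the RNG seed.
#'
#' @slot n Cohort size (>= 10).
#' @slot assignmentSlopes 3x4 numeric matrix (rows = therapies, columns =
#'   `pasi_z`, `dlqi_z`, `duration_z`, `stage`).
#' @slot targetShares Named numeric of length 3 summing to 1.
#' @slot outcomeTilt Nonnegative scalar; exponential-tilting strength of the
#'   kernels by standardized PASI.
#' @slot kernels Named list `kernels[[therapy]][[window]]` of row-stochastic
#'   4x4 matrices.
#' @slot baselineStageProbs Length-4 probability vector over stages.
#' @slot covariateMissingRates Named numeric, one rate per covariate.
#' @slot visitMissingRates Named numeric `c(w1 = ..., w2 = ...)`.
#' @slot seed Integer RNG seed.
#' @export
setClass("TruthParams", representation(
  n = "integer",
  assignmentSlopes = "matrix",
  targetShares = "numeric",
  outcomeTilt = "numeric",
  kernels = "list",
  baselineStageProbs = "numeric",
  covariateMissingRates = "numeric",
  visitMissingRates = "numeric",
  seed = "integer"
))

setValidity("TruthParams", function(object) {
  msgs <- character()
  if (length(object@n) != 1 || is.na(object@n) || object@n < 10)
    msgs <- c(msgs, "n must be a single integer >= 10")
  k <- checkKernels(object@kernels)
  if (!isTRUE(k)) msgs <- c(msgs, k)
  if (length(object@baselineStageProbs) != 4 ||
      any(object@baselineStageProbs < 0) ||
      abs(sum(object@baselineStageProbs) - 1) > 1e-9)
    msgs <- c(msgs, "baselineStageProbs must be a length-4 probability vector")
  if (!setequal(names(object@targetShares), therapyLevels()) ||
      abs(sum(object@targetShares) - 1) > 1e-9)
    msgs <- c(msgs, "targetShares must be named over therapies and sum to 1")
  if (any(object@covariateMissingRates < 0 |
          object@covariateMissingRates > 1))
    msgs <- c(msgs, "covariateMissingRates must lie in [0, 1]")
  if (!setequal(names(object@visitMissingRates), windowLevels()) ||
      any(object@visitMissingRates < 0 | object@visitMissingRates > 1))
    msgs <- c(msgs, "visitMissingRates must be named (w1, w2) rates in [0, 1]")
  if (!all(rownames(object@assignmentSlopes) %in% therapyLevels()))
    msgs <- c(msgs, "assignmentSlopes rows must be named by therapy")
  if (length(object@outcomeTilt) != 1 || object@outcomeTilt < 0)
    msgs <- c(msgs, "outcomeTilt must be a single nonnegative number")
  if (length(msgs)) msgs else TRUE
})

#' Patient cohort container
#'
#' A cohort in long format: one baseline row per patient (id, therapy arm,
#' baseline IGA stage and the covariate set of [covariateInfo()]; empty
#' covariate cells are `NA`) and a visit table (id, day since enrollment,
#' raw IGA score 0-4). Baseline stage and therapy are never missing.
#'
#' @slot patients data.frame with columns `id`, `therapy`, `baseline_stage`
#'   and one column per covariate.
#' @slot visits data.frame with columns `id`, `day`, `iga`.
#' @export
setClass("PsoriasisCohort", representation(
  patients = "data.frame",
  visits = "data.frame"
))

setValidity("PsoriasisCohort", function(object) {
  msgs <- character()
  p <- object@patients
  v <- object@visits
  info <- covariateInfo()
  need <- c("id", "therapy", "baseline_stage", info$name)
  miss <- setdiff(need, names(p))
  if (length(miss))
    return(paste("patients table lacks columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(p$id)) msgs <- c(msgs, "patient ids must be unique")
  if (!all(p$therapy %in% therapyLevels()) || anyNA(p$therapy))
    msgs <- c(msgs, "therapy must be one of the 3 arms and never missing")
  if (!all(p$baseline_stage %in% stageLevels()) || anyNA(p$baseline_stage))
    msgs <- c(msgs, "baseline_stage must be a valid stage and never missing")
  rng <- list(pasi = c(0, 72), bsa = c(0, 100), dlqi = c(0, 30))
  for (nm in names(rng)) {
    x <- p[[nm]]
    if (any(!is.na(x) & (x < rng[[nm]][1] | x > rng[[nm]][2])))
      msgs <- c(msgs, sprintf("%s outside [%g, %g]", nm,
                              rng[[nm]][1], rng[[nm]][2]))
  }
  bin <- info$name[info$type == "binary"]
  for (nm in bin) {
    x <- p[[nm]]
    if (any(!is.na(x) & !(x %in% c(0, 1))))
      msgs <- c(msgs, sprintf("%s must be coded 0/1", nm))
  }
  if (nrow(v)) {
    if (!all(c("id", "day", "iga") %in% names(v)))
      return("visits table needs columns id, day, iga")
    if (any(v$day <= 0)) msgs <- c(msgs, "visit days must be > 0")
    if (any(!(v$iga %in% 0:4))) msgs <- c(msgs, "iga scores must be in 0..4")
    if (!all(v$id %in% p$id))
      msgs <- c(msgs, "visits reference unknown patient ids")
    if (nrow(v) > 1) {
      vv <- v[order(v$id, v$day), ]
      sameId <- vv$id[-1] == vv$id[-nrow(vv)]
      if (any(sameId & diff(vv$day) <= 0))
        msgs <- c(msgs,
                  "visit days must be strictly increasing within patient")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Multiply imputed cohort set
#'
#' `m` completed copies of a cohort produced by chained-equation imputation;
#' observed values are identical across copies and to the input, and visit
#' tables are untouched (follow-up IGA is handled by LOCF at estimation
#' time, not by multiple imputation).
#'
#' @slot cohorts List of `m` complete [PsoriasisCohort] objects.
#' @slot m Number of imputations (>= 2).
#' @slot cycles Chained-equation sweeps used.
#' @slot seed RNG seed used.
#' @export
setClass("ImputedCohortSet", representation(
  cohorts = "list", m = "integer", cycles = "integer", seed = "integer"
))

setValidity("ImputedCohortSet", function(object) {
  if (object@m < 2) return("m must be >= 2")
  if (length(object@cohorts) != object@m)
    return("length(cohorts) must equal m")
  TRUE
})

#' Matched cohort of therapy triples
#'
#' One triple per patient (the anchor): the anchor itself in its own-therapy
#' slot and its nearest Mahalanobis neighbour (with replacement) in each of
#' the other two arms. Frequency weights are the number of triples a unit
#' appears in.
#'
#' @slot triples data.frame with columns `anchor_id`, `biologic_id`,
#'   `traditional_id`, `systemic_id`.
#' @slot imputationIndex Which imputed copy was matched (0 for a complete
#'   cohort matched directly).
#' @export
setClass("MatchedCohort", representation(
  triples = "data.frame", imputationIndex = "integer"
))

setValidity("MatchedCohort", function(object) {
  need <- c("anchor_id", "biologic_id", "traditional_id", "systemic_id")
  if (!all(need %in% names(object@triples)))
    return(paste("triples must have columns", paste(need, collapse = ", ")))
  TRUE
})

#' Transition-probability estimate for one therapy, window and imputation
#'
#' A 4x4 matrix of transition probabilities from baseline stage (rows) to
#' window outcome (columns), the per-cell binomial sampling variance
#' p(1-p)/n, and the weighted row denominators. Rows with zero denominator
#' are undefined and carried as `NA` (never silently zeroed).
#'
#' @slot therapy One of the 3 arms or "overall".
#' @slot window "w1" or "w2".
#' @slot p,var 4x4 numeric matrices.
#' @slot nRow Length-4 weighted row denominators.
#' @export
setClass("TransitionEstimate", representation(
  therapy = "character", window = "character",
  p = "matrix", var = "matrix", nRow = "numeric"
))

setValidity("TransitionEstimate", function(object) {
  msgs <- character()
  if (!all(dim(object@p) == c(4, 4)) || !all(dim(object@var) == c(4, 4)))
    msgs <- c(msgs, "p and var must be 4x4")
  def <- object@nRow > 0
  if (any(def)) {
    rs <- rowSums(object@p[def, , drop = FALSE])
    if (any(abs(rs - 1) > 1e-9))
      msgs <- c(msgs, "defined rows of p must sum to 1 within 1e-9")
    if (any(object@p[def, ] < -1e-12 | object@p[def, ] > 1 + 1e-12))
      msgs <- c(msgs, "probabilities must lie in [0, 1]")
    if (any(object@var[def, ] < -1e-15))
      msgs <- c(msgs, "variances must be nonnegative")
  }
  if (any(!def) && !all(is.na(object@p[!def, ])))
    msgs <- c(msgs, "undefined rows (nRow = 0) must be NA")
  if (length(msgs)) msgs else TRUE
})

#' Rubin-pooled transition matrix
#'
#' Pooled point estimates across M imputations with total variance
#' W + (1 + 1/M) B (W = mean within-imputation variance, B =
#' between-imputation variance) and normal-quantile 95% CIs truncated to
#' [0, 1].
#'
#' @slot therapy,window As in [TransitionEstimate].
#' @slot p,within,between,totalVar,ciLo,ciHi 4x4 numeric matrices.
#' @slot m Number of imputations pooled.
#' @export
setClass("PooledTransitions", representation(
  therapy = "character", window = "character",
  p = "matrix", within = "matrix", between = "matrix", totalVar = "matrix",
  ciLo = "matrix", ciHi = "matrix", m = "integer"
))

setValidity("PooledTransitions", function(object) {
  msgs <- character()
  ok <- !is.na(object@p)
  if (any(object@ciLo[ok] > object@p[ok] + 1e-12) ||
      any(object@ciHi[ok] < object@p[ok] - 1e-12))
    msgs <- c(msgs, "CI bounds must bracket the point estimate")
  if (any(object@totalVar[ok] + 1e-15 < object@within[ok]))
    msgs <- c(msgs, "total variance cannot be below the within component")
  if (length(msgs)) msgs else TRUE
})

#' Between-therapy contrast of pooled transition matrices
#'
#' Elementwise difference (therapy A minus therapy B) of per-imputation
#' transition matrices, Rubin-pooled, with 95% CIs truncated to [-1, 1].
#'
#' @slot therapyA,therapyB,window Labels.
#' @slot d,ciLo,ciHi,totalVar 4x4 numeric matrices.
#' @slot m Number of imputations pooled.
#' @export
setClass("TransitionContrast", representation(
  therapyA = "character", therapyB = "character", window = "character",
  d = "matrix", totalVar = "matrix", ciLo = "matrix", ciHi = "matrix",
  m = "integer"
))

setValidity("TransitionContrast", function(object) {
  ok <- !is.na(object@d)
  if (any(abs(object@d[ok]) > 1 + 1e-12))
    return("differences must lie in [-1, 1]")
  TRUE
})

## ---- accessors ----

#' @rdname accessors
setMethod("patients", "PsoriasisCohort", function(object) object@patients)
#' @rdname accessors
setMethod("visits", "PsoriasisCohort", function(object) object@visits)
#' @rdname accessors
setMethod("triples", "MatchedCohort", function(object) object@triples)

#' @rdname accessors
setMethod("matchWeights", "MatchedCohort", function(object) {
  tr <- object@triples
  ids <- c(tr$biologic_id, tr$traditional_id, tr$systemic_id)
  tab <- table(ids)
  setNames(as.integer(tab), names(tab))
})

#' @rdname accessors
setMethod("transitionMatrix", "TransitionEstimate",
          function(object) object@p)
#' @rdname accessors
setMethod("transitionMatrix", "PooledTransitions",
          function(object) object@p)
#' @rdname accessors
setMethod("transitionVar", "TransitionEstimate",
          function(object) object@var)
#' @rdname accessors
setMethod("transitionVar", "PooledTransitions",
          function(object) object@totalVar)
#' @rdname accessors
setMethod("rowCounts", "TransitionEstimate", function(object) object@nRow)
#' @rdname accessors
setMethod("ciLower", "PooledTransitions", function(object) object@ciLo)
#' @rdname accessors
setMethod("ciUpper", "PooledTransitions", function(object) object@ciHi)
#' @rdname accessors
setMethod("ciLower", "TransitionContrast", function(object) object@ciLo)
#' @rdname accessors
setMethod("ciUpper", "TransitionContrast", function(object) object@ciHi)

## ---- show methods ----

setMethod("show", "TruthParams", function(object) {
  cat("TruthParams: n =", object@n, ", seed =", object@seed, "\n")
  cat("  target arm shares:",
      paste(sprintf("%s %.3f", names(object@targetShares),
                    object@targetShares), collapse = ", "), "\n")
  cat("  outcome tilt:", object@outcomeTilt,
      "| visit missing:", paste(sprintf("%s %.3f",
      names(object@visitMissingRates), object@visitMissingRates),
      collapse = ", "), "\n")
})

setMethod("show", "PsoriasisCohort", function(object) {
  cat("PsoriasisCohort:", nrow(object@patients), "patients,",
      nrow(object@visits), "visits\n")
  print(table(object@patients$therapy))
  nmiss <- sum(is.na(object@patients[, covariateInfo()$name]))
  cat("  missing covariate cells:", nmiss, "\n")
})

setMethod("show", "ImputedCohortSet", function(object) {
  cat("ImputedCohortSet: m =", object@m, ", cycles =", object@cycles,
      ", seed =", object@seed, "\n")
})

setMethod("show", "MatchedCohort", function(object) {
  cat("MatchedCohort:", nrow(object@triples), "triples (imputation",
      object@imputationIndex, ")\n")
})

setMethod("show", "TransitionEstimate", function(object) {
  cat("TransitionEstimate:", object@therapy, "/", object@window, "\n")
  print(round(object@p, 3))
  cat("  row denominators:", paste(round(object@nRow, 1), collapse = ", "),
      "\n")
})

setMethod("show", "PooledTransitions", function(object) {
  cat("PooledTransitions:", object@therapy, "/", object@window,
      "( m =", object@m, ")\n")
  print(round(object@p, 3))
})

setMethod("show", "TransitionContrast", function(object) {
  cat("TransitionContrast:", object@therapyA, "-", object@therapyB, "/",
      object@window, "( m =", object@m, ")\n")
  print(round(object@d, 3))
})
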