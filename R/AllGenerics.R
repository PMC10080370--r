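#' @rdname simulateCohort
#' @export
setGeneric("simulateCohort", function(truth, ...)
  standardGeneric("simulateCohort"))

#' @rdname applyMissingness
#' @export
setGeneric("applyMissingness", function(cohort, truth, ...)
  standardGeneric("applyMissingness"))

#' @rdname imputeCohort
#' @export
setGeneric("imputeCohort", function(cohort, m = 20, cycles = 10, seed = 1, ...)
  standardGeneric("imputeCohort"))

#' @rdname matchThreeGroups
#' @export
setGeneric("matchThreeGroups", function(cohort, ...)
  standardGeneric("matchThreeGroups"))

#' @rdname balanceDiagnostics
#' @export
setGeneric("balanceDiagnostics", function(cohort, matched, ...)
  standardGeneric("balanceDiagnostics"))

#' @rdname estimateTransitions
#' @export
setGeneric("estimateTransitions",
           function(cohort, matched, therapy, window, ...)
  standardGeneric("estimateTransitions"))

#' @rdname poolRubin
#' @export
setGeneric("poolRubin", function(estimates, ...)
  standardGeneric("poolRubin"))

#' @rdname contrastTherapies
#' @export
setGeneric("contrastTherapies", function(estimatesA, estimatesB, ...)
  standardGeneric("contrastTherapies"))

#' @rdname renderDiagram
#' @export
setGeneric("renderDiagram", function(pooled, threshold = 0, ...)
  standardGeneric("renderDiagram"))

#' Accessors for cohort and result objects
#'
#' `patients()` and `visits()` return the baseline and follow-up tables of a
#' [PsoriasisCohort]; `triples()` and `matchWeights()` the matched triples
#' and per-unit frequency weights of a [MatchedCohort];
#' `transitionMatrix()`, `transitionVar()` and `rowCounts()` the probability
#' matrix, per-cell variance and weighted row denominators of a
#' [TransitionEstimate] or [PooledTransitions]; `ciLower()`/`ciUpper()` the
#' 95% CI bounds of pooled or contrast results.
#'
#' @param object An object of the documented classes.
#' @return The corresponding slot contents (data.frame, matrix or vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))
#' @rdname accessors
#' @export
setGeneric("visits", function(object) standardGeneric("visits"))
#' @rdname accessors
#' @export
setGeneric("triples", function(object) standardGeneric("triples"))
#' @rdname accessors
#' @export
setGeneric("matchWeights", function(object) standardGeneric("matchWeights"))
#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object)
  standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setGeneric("transitionVar", function(object)
  standardGeneric("transitionVar"))
#' @rdname accessors
#' @export
setGeneric("rowCounts", function(object) standardGeneric("rowCounts"))
#' @rdname accessors
#' @export
setGeneric("ciLower", function(object) standardGeneric("ciLower"))
#' @rdname accessors
#' @export
setGeneric("ciUpper", function(object) standardGeneric("ciUpper"))
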