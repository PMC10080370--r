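#' Bin raw IGA scores into the four severity stages
#'
#' Scores 0 and 1 collapse into the clear/almost-clear stage `S01`; 2, 3 and
#' 4 map to `S2`, `S3`, `S4`.
#'
#' @param score Integer vector with values in 0..4.
#' @return Character vector of stage labels.
#' @export
binIga <- function(score) {
  if (any(is.na(score)) || any(!(score %in% 0:4)))
    stop("IGA scores must be integers in 0..4")
  stageLevels()[pmax(score, 1L)]
}

#' Window outcomes with last-observation-carried-forward
#'
#' For every patient and both follow-up windows, determines the outcome
#' stage: the binned IGA of the *last* visit inside the window if one
#' exists (when follow-up visits disagree, only the last is used);
#' otherwise the outcome is carried forward - for window 1 from the
#' baseline stage, for window 2 from the window-1 outcome (which may itself
#' be the carried baseline). LOCF makes the outcome total: every patient has
#' a defined stage in both windows.
#'
#' @param cohort A [PsoriasisCohort].
#' @param windowEnd1,windowEnd2 Day boundaries of the half-open windows
#'   (0, windowEnd1] and (windowEnd1, windowEnd2]; defaults 30 and 365
#'   (one month = 30 days).
#' @return data.frame with columns `id`, `window`, `stage`, `source`
#'   (`observed`, `locf_from_w1` or `locf_from_baseline`), two rows per
#'   patient.
#' @export
windowOutcomes <- function(cohort, windowEnd1 = 30, windowEnd2 = 365) {
  p <- cohort@patients
  v <- cohort@visits
  lastStage <- function(lo, hi) {
    sel <- v$day > lo & v$day <= hi
    vv <- v[sel, , drop = FALSE]
    if (!nrow(vv)) return(setNames(character(0), character(0)))
    vv <- vv[order(vv$id, vv$day), ]
    last <- !duplicated(vv$id, fromLast = TRUE)
    setNames(binIga(vv$iga[last]), vv$id[last])
  }
  w1obs <- lastStage(0, windowEnd1)
  w2obs <- lastStage(windowEnd1, windowEnd2)

  w1stage <- unname(w1obs[p$id])
  w1src <- ifelse(is.na(w1stage), "locf_from_baseline", "observed")
  w1stage[is.na(w1stage)] <- p$baseline_stage[is.na(w1stage)]

  w2stage <- unname(w2obs[p$id])
  w2src <- ifelse(is.na(w2stage),
                  ifelse(w1src == "observed", "locf_from_w1",
                         "locf_from_baseline"),
                  "observed")
  w2stage[is.na(w2stage)] <- w1stage[is.na(w2stage)]

  rbind(
    data.frame(id = p$id, window = "w1", stage = unname(w1stage),
               source = w1src, stringsAsFactors = FALSE),
    data.frame(id = p$id, window = "w2", stage = unname(w2stage),
               source = w2src, stringsAsFactors = FALSE))
}

#' Estimate a 4x4 transition matrix on a matched, completed cohort
#'
#' For the requested therapy, uses that therapy's slot of every matched
#' triple (the matched pseudo-population: exactly one representative per
#' triple, so all three therapy populations have identical size and, by
#' construction, comparable covariates). `"overall"` pools the three
#' per-therapy populations. Cell (i, j) is the frequency-weighted share of
#' units with baseline stage i whose window outcome (LOCF-completed) is
#' stage j; its sampling variance is the binomial p(1-p)/n with n the
#' weighted row denominator. Rows with zero denominator are flagged
#' undefined and reported as `NA`.
#'
#' @param cohort A complete [PsoriasisCohort] (one imputed copy).
#' @param matched The [MatchedCohort] for that copy.
#' @param therapy `"biologic"`, `"traditional"`, `"systemic"` or
#'   `"overall"`.
#' @param window `"w1"` or `"w2"`.
#' @param windowEnd1,windowEnd2 Window day boundaries, see
#'   [windowOutcomes()].
#' @return A [TransitionEstimate].
#' @export
setMethod("estimateTransitions",
          signature("PsoriasisCohort", "MatchedCohort"),
          function(cohort, matched, therapy, window,
                   windowEnd1 = 30, windowEnd2 = 365, ...) {
  therapy <- match.arg(therapy, c(therapyLevels(), "overall"))
  window <- match.arg(window, windowLevels())
  tr <- matched@triples
  ids <- switch(therapy,
                biologic = tr$biologic_id,
                traditional = tr$traditional_id,
                systemic = tr$systemic_id,
                overall = c(tr$biologic_id, tr$traditional_id,
                            tr$systemic_id))
  p <- cohort@patients
  wo <- windowOutcomes(cohort, windowEnd1, windowEnd2)
  wo <- wo[wo$window == window, ]
  outcomeBy <- setNames(wo$stage, wo$id)
  baseBy <- setNames(p$baseline_stage, p$id)

  from <- factor(baseBy[ids], levels = stageLevels())
  to <- factor(outcomeBy[ids], levels = stageLevels())
  counts <- table(from, to)
  nRow <- rowSums(counts)
  pm <- matrix(NA_real_, 4, 4,
               dimnames = list(stageLevels(), stageLevels()))
  vm <- pm
  def <- nRow > 0
  if (any(def)) {
    pm[def, ] <- counts[def, , drop = FALSE] / nRow[def]
    vm[def, ] <- pm[def, , drop = FALSE] *
      (1 - pm[def, , drop = FALSE]) / nRow[def]
  }
  if (any(!def))
    message("undefined row(s) (no units at baseline stage): ",
            paste(stageLevels()[!def], collapse = ", "))
  new("TransitionEstimate", therapy = therapy, window = window,
      p = pm, var = vm, nRow = as.numeric(nRow))
})

#' Naive (unmatched) transition estimate
#'
#' Estimates the 4x4 transition matrix on a therapy arm's raw units (weight
#' 1 each, no matching), or on the whole cohort for `"overall"`. Used as
#' the unadjusted comparator when quantifying what matching buys under
#' confounding, and for direct kernel-recovery checks on randomized
#' cohorts.
#'
#' @inheritParams estimateTransitions
#' @return A [TransitionEstimate].
#' @export
naiveTransitions <- function(cohort, therapy, window,
                             windowEnd1 = 30, windowEnd2 = 365) {
  therapy <- match.arg(therapy, c(therapyLevels(), "overall"))
  window <- match.arg(window, windowLevels())
  p <- cohort@patients
  ids <- if (therapy == "overall") p$id else p$id[p$therapy == therapy]
  wo <- windowOutcomes(cohort, windowEnd1, windowEnd2)
  wo <- wo[wo$window == window, ]
  outcomeBy <- setNames(wo$stage, wo$id)
  baseBy <- setNames(p$baseline_stage, p$id)
  from <- factor(baseBy[ids], levels = stageLevels())
  to <- factor(outcomeBy[ids], levels = stageLevels())
  counts <- table(from, to)
  nRow <- rowSums(counts)
  pm <- matrix(NA_real_, 4, 4,
               dimnames = list(stageLevels(), stageLevels()))
  vm <- pm
  def <- nRow > 0
  if (any(def)) {
    pm[def, ] <- counts[def, , drop = FALSE] / nRow[def]
    vm[def, ] <- pm[def, , drop = FALSE] *
      (1 - pm[def, , drop = FALSE]) / nRow[def]
  }
  new("TransitionEstimate", therapy = therapy, window = window,
      p = pm, var = vm, nRow = as.numeric(nRow))
}

#' Build a TransitionEstimate from a known matrix
#'
#' Wraps an existing probability matrix (for example a published table) in a
#' [TransitionEstimate], attaching binomial variances at nominal row
#' denominators. Used for table arithmetic and for feeding printed
#' estimates through the pooling and contrast machinery.
#'
#' @param p 4x4 row-stochastic matrix (rows are renormalized if printed
#'   rounding leaves them within 0.05 of 1; larger deviations error).
#' @param n Scalar or length-4 row denominators.
#' @param therapy,window Labels.
#' @param renormalize Renormalize rows to sum exactly to 1 (default TRUE).
#' @return A [TransitionEstimate].
#' @export
transitionEstimateFromMatrix <- function(p, n, therapy, window,
                                         renormalize = TRUE) {
  stopifnot(all(dim(p) == c(4, 4)))
  rs <- rowSums(p)
  if (any(abs(rs - 1) > 0.05))
    stop("rows deviate from 1 by more than printed rounding allows")
  if (renormalize) p <- p / rs
  dimnames(p) <- list(stageLevels(), stageLevels())
  nRow <- rep(n, length.out = 4)
  v <- p * (1 - p) / nRow
  new("TransitionEstimate", therapy = therapy, window = window,
      p = p, var = v, nRow = as.numeric(nRow))
}
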