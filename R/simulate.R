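#' Construct ground-truth generator parameters
#'
#' Builds a [TruthParams] object with defaults that emulate a large national
#' psoriasis registry cohort: target arm shares 32.6% biologic / 53.7%
#' traditional / 13.7% systemic, severity-increasing assignment slopes for
#' the biologic arm (so biologic patients have higher PASI, DLQI and longer
#' duration before matching), the published per-therapy transition matrices
#' as kernels, covariate missingness rates in the 1.5%-8.1% band and
#' follow-up-visit missingness of 62.1% (window 1) and 48.8% (window 2).
#'
#' @param n Cohort size (default 8767, the registry analysis size; tests and
#'   examples use much smaller n).
#' @param seed Integer RNG seed.
#' @param kernels Optional kernel list `kernels[[therapy]][[window]]`
#'   (row-stochastic 4x4); defaults to [defaultKernels()].
#' @param baselineStageProbs Length-4 baseline stage distribution.
#' @param targetShares Named arm-share targets (must sum to 1).
#' @param assignmentSlopes 3x4 slope matrix of the multinomial-logistic
#'   assignment model on (pasi_z, dlqi_z, duration_z, stage). All-zero slopes
#'   give randomized assignment at `targetShares`.
#' @param outcomeTilt Exponential-tilting strength of kernel rows by
#'   standardized PASI (0 disables covariate modulation of outcomes).
#' @param covariateMissingRates Named per-covariate missingness rates.
#' @param visitMissingRates Named `c(w1=, w2=)` per-window probabilities that
#'   a patient has no visit record in that window.
#' @return A validated [TruthParams] object.
#' @examples
#' truth <- truthParams(n = 200, seed = 1)
#' cohort <- simulateCohort(truth)
#' @export
truthParams <- function(n = 8767, seed = 1L,
                        kernels = defaultKernels(),
                        baselineStageProbs = c(0.15, 0.35, 0.35, 0.15),
                        targetShares = c(biologic = 0.326,
                                         traditional = 0.537,
                                         systemic = 0.137),
                        assignmentSlopes = defaultAssignmentSlopes(),
                        outcomeTilt = 0.3,
                        covariateMissingRates = defaultMissingRates(),
                        visitMissingRates = c(w1 = 0.621, w2 = 0.488)) {
  new("TruthParams",
      n = as.integer(n),
      assignmentSlopes = assignmentSlopes,
      targetShares = targetShares[therapyLevels()],
      outcomeTilt = outcomeTilt,
      kernels = kernels,
      baselineStageProbs = baselineStageProbs,
      covariateMissingRates = covariateMissingRates,
      visitMissingRates = visitMissingRates[windowLevels()],
      seed = as.integer(seed))
}

#' @rdname truthParams
#' @export
defaultAssignmentSlopes <- function() {
  m <- rbind(
    biologic    = c(pasi_z = 0.55, dlqi_z = 0.30, duration_z = 0.40,
                    stage = 0.25),
    traditional = c(pasi_z = 0.00, dlqi_z = 0.00, duration_z = 0.00,
                    stage = 0.00),
    systemic    = c(pasi_z = 0.20, dlqi_z = 0.10, duration_z = 0.15,
                    stage = 0.10))
  m
}

#' @rdname truthParams
#' @export
defaultMissingRates <- function() {
  info <- covariateInfo()
  ## fixed per-variable rates spanning the observed 1.5%-8.1% band
  rates <- c(sex = 0.015, age = 0.020, bmi = 0.060, marital = 0.030,
             employment = 0.035, education = 0.040, smoking = 0.045,
             duration = 0.055, family_history = 0.081, nail = 0.025,
             scalp = 0.025, palmoplantar = 0.030, genital = 0.050,
             pasi = 0.050, bsa = 0.045, dlqi = 0.065, comorbidity = 0.035)
  rates[info$name]
}

## stage index 1..4 for a stage label vector
stageIndex <- function(stage) match(stage, stageLevels())

## exponentially tilt kernel rows (one row per patient) toward more severe
## outcomes for positive tilt: p_j propto p_j * exp(tilt * s_j) with outcome
## severity scores s in {-1, -1/3, 1/3, 1}
tiltRows <- function(rows, tilt) {
  s <- (seq_len(4) - 2.5) / 1.5
  w <- exp(outer(tilt, s))
  rows <- rows * w
  rows / rowSums(rows)
}

drawIgaFromStage <- function(stageIdx) {
  ## S01 maps back to a raw IGA score of 0 or 1 with equal probability
  ifelse(stageIdx == 1L, rbinom(length(stageIdx), 1L, 0.5), stageIdx)
}

#' Generate a complete synthetic cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes: a latent severity factor correlating baseline stage with PASI,
#' BSA, DLQI and disease duration; confounded treatment assignment via a
#' multinomial-logistic model whose intercepts are calibrated so the marginal
#' arm shares hit the targets; window outcomes drawn from the therapy- and
#' window-specific kernels conditional on baseline stage (optionally tilted
#' by within-stage severity); and visits placed at uniformly random days in
#' (0, 30] and (30, 365]. The last visit in each window encodes the drawn
#' outcome stage. No missingness is applied here; see [applyMissingness()].
#' The same `truth` (including seed) always reproduces the identical cohort.
#'
#' @param truth A [TruthParams] object.
#' @return A complete [PsoriasisCohort]. The generating parameters are
#'   attached as attribute `"truth"`.
#' @seealso [applyMissingness()], [writeTruth()]
#' @export
setMethod("simulateCohort", "TruthParams", function(truth, ...) {
  validObject(truth)
  n <- truth@n
  set.seed(truth@seed)
  id <- sprintf("P%05d", seq_len(n))

  ## latent severity factor; baseline stage from a correlated standard
  ## normal cut at the quantiles of the target stage distribution
  u <- rnorm(n)
  u2 <- 0.8 * u + 0.6 * rnorm(n)
  cuts <- qnorm(cumsum(truth@baselineStageProbs))[1:3]
  stIdx <- 1L + rowSums(outer(u2, cuts, ">"))
  stC <- stIdx - 2.5

  ## covariates: continuous log-normal/normal with medians near the
  ## registry's marginals, severity-linked where the registry shows
  ## imbalance; binaries at registry proportions
  age <- clamp(rlnorm(n, log(38.6), 0.45), 18, 90)
  bmi <- clamp(rnorm(n, 24.0, 3.0), 14, 45)
  duration <- clamp(rlnorm(n, log(5.5) + 0.35 * u, 0.9), 0.1, 60)
  pasi <- clamp(rlnorm(n, log(8.5) + 0.35 * stC + 0.25 * u, 0.55), 0, 72)
  bsa <- clamp(rlnorm(n, log(14) + 0.40 * stC + 0.25 * u, 0.70), 0, 100)
  dlqi <- clamp(round(rnorm(n, 8 + 1.2 * stC + 1.5 * u, 4)), 0, 30)
  sex <- rbinom(n, 1, 0.663)
  marital <- rbinom(n, 1, 0.74)
  employment <- rbinom(n, 1, 0.57)
  education <- rbinom(n, 1, 0.30)
  smoking <- rbinom(n, 1, 0.255)
  family_history <- rbinom(n, 1, plogis(qlogis(0.16) + 0.15 * u))
  nail <- rbinom(n, 1, plogis(qlogis(0.24) + 0.20 * u))
  scalp <- rbinom(n, 1, plogis(qlogis(0.66) + 0.20 * u))
  palmoplantar <- rbinom(n, 1, plogis(qlogis(0.19) + 0.20 * u))
  genital <- rbinom(n, 1, plogis(qlogis(0.13) + 0.20 * u))
  comorbidity <- rbinom(n, 1, plogis(qlogis(0.15) + 0.20 * u))

  ## confounded assignment: softmax over arms, intercepts calibrated on the
  ## realized covariates so expected shares equal the targets exactly
  X <- cbind(pasi_z = zscore(pasi), dlqi_z = zscore(dlqi),
             duration_z = zscore(duration), stage = stC)
  slopes <- truth@assignmentSlopes[therapyLevels(), , drop = FALSE]
  lp <- X %*% t(slopes)
  colnames(lp) <- therapyLevels()
  a <- calibrateSoftmaxIntercepts(lp, truth@targetShares[therapyLevels()])
  pAssign <- softmaxProbs(lp, a)
  thIdx <- rcatRows(pAssign)
  therapy <- therapyLevels()[thIdx]

  ## window outcomes: kernel row by (therapy, baseline stage), optionally
  ## exponentially tilted by within-stage standardized PASI (centering the
  ## tilt within each baseline stage keeps every kernel row the
  ## row-conditional estimand while still letting treatment assignment,
  ## which depends on PASI, confound the per-therapy estimates)
  zw <- stats::ave(pasi, stIdx, FUN = zscore)
  tilt <- truth@outcomeTilt * zw
  outcome <- list()
  for (w in windowLevels()) {
    rows <- matrix(NA_real_, n, 4)
    for (th in therapyLevels()) {
      sel <- therapy == th
      rows[sel, ] <- truth@kernels[[th]][[w]][stIdx[sel], , drop = FALSE]
    }
    rows <- tiltRows(rows, tilt)
    outcome[[w]] <- rcatRows(rows)
  }

  ## visit schedule: one outcome-encoding visit per window at a uniform
  ## random day, preceded ~30% of the time by an extra earlier visit whose
  ## stage is an independent draw from the same kernel row
  vis <- list()
  for (w in windowLevels()) {
    lim <- if (w == "w1") c(1L, 30L) else c(31L, 365L)
    extra <- rbinom(n, 1, 0.3) == 1L
    dayFinal <- integer(n)
    dayEarly <- integer(n)
    for (i in which(extra)) {
      d <- sort(sample(seq(lim[1], lim[2]), 2L))
      dayEarly[i] <- d[1]; dayFinal[i] <- d[2]
    }
    if (any(!extra))
      dayFinal[!extra] <- sample(seq(lim[1], lim[2]), sum(!extra),
                                 replace = TRUE)
    rows <- matrix(NA_real_, n, 4)
    for (th in therapyLevels()) {
      sel <- therapy == th
      rows[sel, ] <- truth@kernels[[th]][[w]][stIdx[sel], , drop = FALSE]
    }
    rows <- tiltRows(rows, tilt)
    earlyStage <- rcatRows(rows)
    vis[[paste0(w, "_final")]] <- data.frame(
      id = id, day = dayFinal,
      iga = drawIgaFromStage(outcome[[w]]), stringsAsFactors = FALSE)
    vis[[paste0(w, "_early")]] <- data.frame(
      id = id[extra], day = dayEarly[extra],
      iga = drawIgaFromStage(earlyStage[extra]), stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, vis)
  visits <- visits[order(visits$id, visits$day), ]
  rownames(visits) <- NULL

  patientsDf <- data.frame(
    id = id, therapy = therapy, baseline_stage = stageLevels()[stIdx],
    sex = sex, age = age, bmi = bmi, marital = marital,
    employment = employment, education = education, smoking = smoking,
    duration = duration, family_history = family_history, nail = nail,
    scalp = scalp, palmoplantar = palmoplantar, genital = genital,
    pasi = pasi, bsa = bsa, dlqi = dlqi, comorbidity = comorbidity,
    stringsAsFactors = FALSE)

  cohort <- new("PsoriasisCohort", patients = patientsDf, visits = visits)
  attr(cohort, "truth") <- truth
  cohort
})

#' Mask covariates and delete follow-up visits (MAR)
#'
#' Applies the configured missingness to a complete cohort. Covariate cells
#' are masked missing-at-random: the masking probability is logistic in the
#' baseline stage and therapy arm (both always observed, never in the masked
#' column itself), with the intercept calibrated so the marginal rate equals
#' the configured per-covariate rate on the realized cohort. Visit records
#' are deleted per window the same way, emulating high follow-up
#' missingness. Baseline stage, therapy and patient id are never masked.
#'
#' @param cohort A complete [PsoriasisCohort].
#' @param truth The [TruthParams] carrying the rates (its seed, offset by 1,
#'   drives the masking draws so the operation is reproducible).
#' @return A [PsoriasisCohort] with `NA` covariate cells and thinned visits.
#' @export
setMethod("applyMissingness", signature("PsoriasisCohort", "TruthParams"),
          function(cohort, truth, ...) {
  validObject(truth)
  p <- cohort@patients
  v <- cohort@visits
  set.seed(truth@seed + 1L)
  stC <- stageIndex(p$baseline_stage) - 2.5
  bio <- as.numeric(p$therapy == "biologic")
  offset <- 0.35 * stC + 0.30 * bio

  for (nm in names(truth@covariateMissingRates)) {
    r <- truth@covariateMissingRates[[nm]]
    if (r <= 0) next
    if (r > 1) stop("missingness rate above 1 for ", nm)
    a <- calibrateLogitIntercept(offset, r)
    mask <- runif(nrow(p)) < plogis(a + offset)
    p[[nm]][mask] <- NA
  }

  keep <- rep(TRUE, nrow(v))
  for (w in windowLevels()) {
    r <- truth@visitMissingRates[[w]]
    if (r <= 0) next
    lim <- if (w == "w1") c(0, 30) else c(30, 365)
    a <- calibrateLogitIntercept(offset, r)
    drop <- runif(nrow(p)) < plogis(a + offset)
    inWin <- v$day > lim[1] & v$day <= lim[2]
    keep <- keep & !(inWin & v$id %in% p$id[drop])
  }
  v <- v[keep, ]
  rownames(v) <- NULL

  out <- new("PsoriasisCohort", patients = p, visits = v)
  attr(out, "truth") <- truth
  out
})

## ---- ground-truth serialization ----

truthToList <- function(truth) {
  list(
    n = truth@n,
    assignment_slopes = list(
      values = as.vector(truth@assignmentSlopes),
      rows = rownames(truth@assignmentSlopes),
      cols = colnames(truth@assignmentSlopes)),
    target_shares = as.list(truth@targetShares),
    outcome_tilt = truth@outcomeTilt,
    kernels = lapply(truth@kernels, function(byW)
      lapply(byW, function(k) as.vector(t(k)))),
    baseline_stage_probs = truth@baselineStageProbs,
    covariate_missing_rates = as.list(truth@covariateMissingRates),
    visit_missing_rates = as.list(truth@visitMissingRates),
    seed = truth@seed)
}

listToTruth <- function(x) {
  slopes <- matrix(unlist(x$assignment_slopes$values),
                   nrow = length(x$assignment_slopes$rows),
                   dimnames = list(unlist(x$assignment_slopes$rows),
                                   unlist(x$assignment_slopes$cols)))
  kernels <- lapply(x$kernels, function(byW)
    lapply(byW, function(v)
      matrix(unlist(v), 4, 4, byrow = TRUE,
             dimnames = list(stageLevels(), stageLevels()))))
  new("TruthParams",
      n = as.integer(x$n),
      assignmentSlopes = slopes,
      targetShares = unlist(x$target_shares)[therapyLevels()],
      outcomeTilt = as.numeric(x$outcome_tilt),
      kernels = kernels,
      baselineStageProbs = as.numeric(unlist(x$baseline_stage_probs)),
      covariateMissingRates = unlist(x$covariate_missing_rates),
      visitMissingRates = unlist(x$visit_missing_rates)[windowLevels()],
      seed = as.integer(x$seed))
}

#' Serialize / restore ground-truth parameters as JSON
#'
#' `writeTruth()` validates and writes a [TruthParams] object to JSON at full
#' numeric precision; `readTruth()` restores it losslessly, so
#' `readTruth(writeTruth(t))` equals `t`.
#'
#' @param truth A [TruthParams] object.
#' @param path File path for the JSON document.
#' @return `writeTruth()` returns `path` invisibly; `readTruth()` returns the
#'   restored [TruthParams].
#' @export
writeTruth <- function(truth, path) {
  validObject(truth)
  jsonlite::write_json(truthToList(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  truth <- listToTruth(x)
  validObject(truth)
  truth
}

## ---- cohort CSV round trip ----

#' Write / read a cohort as CSV tables
#'
#' A cohort is stored as `patients.csv` (one wide row per patient; empty cell
#' = missing) plus `visits.csv` (long: id, day, iga) inside `dir`.
#'
#' @param cohort A [PsoriasisCohort].
#' @param dir Directory to write into (created if needed).
#' @return `writeCohortCsv()` returns `dir` invisibly; `readCohortCsv()` the
#'   restored [PsoriasisCohort].
#' @export
writeCohortCsv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort@patients, file.path(dir, "patients.csv"),
            row.names = FALSE, na = "")
  write.csv(cohort@visits, file.path(dir, "visits.csv"),
            row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(dir) {
  p <- read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE,
                na.strings = "", colClasses = c(id = "character"))
  vPath <- file.path(dir, "visits.csv")
  v <- read.csv(vPath, stringsAsFactors = FALSE, na.strings = "",
                colClasses = c(id = "character"))
  new("PsoriasisCohort", patients = p, visits = v)
}
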