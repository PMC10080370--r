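# Builders for small deterministic cohorts and truth configurations used
# across the test files.

noMissingRates <- function() {
  setNames(rep(0, nrow(covariateInfo())), covariateInfo()$name)
}

# truth with confounding and missingness switched off unless asked for
cleanTruth <- function(n, seed, ...) {
  truthParams(n = n, seed = seed,
              assignmentSlopes = defaultAssignmentSlopes() * 0,
              targetShares = c(biologic = 1 / 3, traditional = 1 / 3,
                               systemic = 1 / 3),
              outcomeTilt = 0,
              covariateMissingRates = noMissingRates(),
              visitMissingRates = c(w1 = 0, w2 = 0), ...)
}

identityKernels <- function() {
  k <- diag(4)
  dimnames(k) <- list(stageLevels(), stageLevels())
  ks <- list()
  for (th in therapyLevels()) ks[[th]] <- list(w1 = k, w2 = k)
  ks
}

# hand-built cohort: one row per entry of `therapy`; covariates filled with
# deterministic values unless overridden via `covs` (a data.frame)
handCohort <- function(therapy, baseline_stage, visits = NULL, covs = NULL) {
  n <- length(therapy)
  id <- sprintf("H%03d", seq_len(n))
  info <- covariateInfo()
  p <- data.frame(id = id, therapy = therapy,
                  baseline_stage = baseline_stage,
                  stringsAsFactors = FALSE)
  defaults <- list(sex = 1, age = 40, bmi = 24, marital = 1, employment = 1,
                   education = 0, smoking = 0, duration = 5,
                   family_history = 0, nail = 0, scalp = 1,
                   palmoplantar = 0, genital = 0, pasi = 10, bsa = 15,
                   dlqi = 8, comorbidity = 0)
  for (nm in info$name) p[[nm]] <- rep(defaults[[nm]], n)
  if (!is.null(covs)) for (nm in names(covs)) p[[nm]] <- covs[[nm]]
  if (is.null(visits))
    visits <- data.frame(id = character(0), day = integer(0),
                         iga = integer(0), stringsAsFactors = FALSE)
  new("PsoriasisCohort", patients = p, visits = visits)
}

# random small cohort guaranteed to contain all 3 arms (for oracle tests)
randomSmallCohort <- function(n) {
  stopifnot(n >= 3)
  therapy <- c(therapyLevels(),
               sample(therapyLevels(), n - 3, replace = TRUE))
  stage <- sample(stageLevels(), n, replace = TRUE)
  covs <- data.frame(age = runif(n, 20, 70), pasi = runif(n, 1, 40),
                     bsa = runif(n, 1, 60), dlqi = runif(n, 0, 25),
                     duration = runif(n, 0.5, 25), bmi = runif(n, 18, 32),
                     sex = rbinom(n, 1, 0.5), smoking = rbinom(n, 1, 0.3))
  handCohort(therapy, stage, covs = covs)
}

# matched cohort listing each given unit once in its own-arm slot; used to
# feed hand-chosen populations through estimateTransitions with weight 1
manualMatched <- function(bioIds, tradIds, sysIds) {
  n <- max(length(bioIds), length(tradIds), length(sysIds))
  rec <- function(x) rep(x, length.out = n)
  new("MatchedCohort",
      triples = data.frame(anchor_id = rec(bioIds),
                           biologic_id = rec(bioIds),
                           traditional_id = rec(tradIds),
                           systemic_id = rec(sysIds),
                           stringsAsFactors = FALSE),
      imputationIndex = 0L)
}

# brute-force matching oracle: same metric definition, independent
# computation (base mahalanobis() pairwise, explicit lowest-id tie-break)
bruteForceMatch <- function(cohort) {
  p <- patients(cohort)
  X <- matchingCovariates(cohort)
  sInv <- psortransit:::pooledCovInverse(X)
  ids <- p$id
  out <- data.frame(anchor_id = ids, biologic_id = NA_character_,
                    traditional_id = NA_character_,
                    systemic_id = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    for (th in therapyLevels()) {
      col <- paste0(th, "_id")
      if (p$therapy[i] == th) { out[[col]][i] <- ids[i]; next }
      cand <- which(p$therapy == th)
      d <- vapply(cand, function(j)
        mahalanobis(X[i, ], X[j, ], cov = sInv, inverted = TRUE), 0)
      best <- min(d)
      sel <- cand[d <= best + 1e-8 * (1 + best)]
      out[[col]][i] <- sort(ids[sel])[1]
    }
  }
  out
}
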