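test_that("confounded assignment reproduces the target arm shares", {
  truth <- truthParams(n = 10000, seed = 11,
                       covariateMissingRates = noMissingRates(),
                       visitMissingRates = c(w1 = 0, w2 = 0))
  co <- simulateCohort(truth)
  shares <- prop.table(table(patients(co)$therapy))
  expect_lt(abs(shares[["biologic"]] - 0.326), 0.02)
  expect_lt(abs(shares[["traditional"]] - 0.537), 0.02)
  expect_lt(abs(shares[["systemic"]] - 0.137), 0.02)
  # confounding direction: biologic patients are more severe at baseline
  p <- patients(co)
  expect_gt(median(p$pasi[p$therapy == "biologic"]),
            median(p$pasi[p$therapy == "traditional"]))
  expect_gt(median(p$duration[p$therapy == "biologic"]),
            median(p$duration[p$therapy == "traditional"]))
})

test_that("identity kernels keep every visit at the baseline stage", {
  truth <- cleanTruth(n = 300, seed = 5, kernels = identityKernels())
  co <- simulateCohort(truth)
  p <- patients(co)
  v <- visits(co)
  stageOf <- setNames(p$baseline_stage, p$id)
  expect_true(all(binIga(v$iga) == stageOf[v$id]))
})

test_that("the generator is deterministic: same seed, byte-identical CSVs", {
  truth <- truthParams(n = 200, seed = 42)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  writeCohortCsv(applyMissingness(simulateCohort(truth), truth), d1)
  writeCohortCsv(applyMissingness(simulateCohort(truth), truth), d2)
  for (f in c("patients.csv", "visits.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("zero missingness rates leave the cohort untouched", {
  truth <- cleanTruth(n = 120, seed = 9)
  co <- simulateCohort(truth)
  out <- applyMissingness(co, truth)
  expect_identical(patients(out), patients(co))
  expect_identical(visits(out), visits(co))
})

test_that("achieved missingness matches the configured rates", {
  truth <- truthParams(n = 10000, seed = 13)
  co <- applyMissingness(simulateCohort(truth), truth)
  p <- patients(co)
  rates <- colMeans(is.na(p[, covariateInfo()$name]))
  expect_true(all(rates >= 0.005 & rates <= 0.095))
  expect_lt(max(abs(rates - defaultMissingRates())), 0.01)
  v <- visits(co)
  w1miss <- mean(!(p$id %in% v$id[v$day <= 30]))
  w2miss <- mean(!(p$id %in% v$id[v$day > 30 & v$day <= 365]))
  expect_lt(abs(w1miss - 0.621), 0.02)
  expect_lt(abs(w2miss - 0.488), 0.02)
  # baseline stage and therapy are never masked
  expect_false(anyNA(p$baseline_stage))
  expect_false(anyNA(p$therapy))
})

test_that("masking is MAR: rates depend on observed severity, not the value", {
  truth <- truthParams(n = 8000, seed = 21)
  complete <- simulateCohort(truth)
  masked <- applyMissingness(complete, truth)
  # missingness probability increases with (always observed) baseline stage
  p <- patients(masked)
  sev <- psortransit:::stageIndex(p$baseline_stage) >= 3
  expect_gt(mean(is.na(p$dlqi[sev])), mean(is.na(p$dlqi[!sev])))
})

test_that("empirical transition frequencies converge to the kernels", {
  truth <- cleanTruth(n = 20000, seed = 4,
                      baselineStageProbs = rep(0.25, 4))
  co <- simulateCohort(truth)
  K <- defaultKernels()
  for (th in therapyLevels()) for (w in windowLevels()) {
    est <- naiveTransitions(co, th, w)
    expect_lt(max(abs(transitionMatrix(est) - K[[th]][[w]])), 0.02)
  }
})

test_that("degenerate generator inputs are refused", {
  expect_error(truthParams(n = 5), "n must be")
  badK <- defaultKernels()
  badK$biologic$w1[1, 1] <- badK$biologic$w1[1, 1] - 0.01
  expect_error(truthParams(n = 100, kernels = badK), "sum to 1")
})

test_that("ground truth round-trips losslessly through JSON", {
  truth <- truthParams(n = 500, seed = 42)
  f <- tempfile(fileext = ".json")
  writeTruth(truth, f)
  back <- readTruth(f)
  for (sl in slotNames("TruthParams"))
    expect_equal(slot(back, sl), slot(truth, sl), tolerance = 1e-12,
                 info = sl)
  # seed-only change leaves every other serialized field identical
  f43 <- tempfile(fileext = ".json")
  writeTruth(truthParams(n = 500, seed = 43), f43)
  a <- jsonlite::read_json(f); b <- jsonlite::read_json(f43)
  expect_equal(as.numeric(a$seed), 42); expect_equal(as.numeric(b$seed), 43)
  a$seed <- NULL; b$seed <- NULL
  expect_identical(a, b)
})

test_that("cohort CSV tables round-trip", {
  truth <- truthParams(n = 150, seed = 3)
  co <- applyMissingness(simulateCohort(truth), truth)
  d <- file.path(tempdir(), "csvrt")
  writeCohortCsv(co, d)
  back <- readCohortCsv(d)
  expect_equal(patients(back), patients(co), tolerance = 1e-12)
  expect_equal(visits(back), visits(co))
})
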