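test_that("IGA scores bin into the four stages", {
  expect_equal(binIga(0), "S01")
  expect_equal(binIga(1), "S01")
  expect_equal(binIga(2), "S2")
  expect_equal(binIga(4), "S4")
  expect_equal(binIga(c(0, 1, 2, 3, 4)),
               c("S01", "S01", "S2", "S3", "S4"))
  expect_error(binIga(5), "0..4")
  expect_error(binIga(-1), "0..4")
})

test_that("window outcomes use the last visit and LOCF otherwise", {
  v <- data.frame(id = "H001", day = c(10, 20), iga = c(2, 3),
                  stringsAsFactors = FALSE)
  co <- handCohort("biologic", "S2", visits = v)
  wo <- windowOutcomes(co)
  w1 <- wo[wo$window == "w1", ]
  expect_equal(w1$stage, "S3")     # last of the two w1 visits wins
  expect_equal(w1$source, "observed")
  w2 <- wo[wo$window == "w2", ]
  expect_equal(w2$stage, "S3")     # no w2 visit: carried from w1
  expect_equal(w2$source, "locf_from_w1")

  # no visits at all: both windows carry the baseline stage
  co2 <- handCohort("systemic", "S4")
  wo2 <- windowOutcomes(co2)
  expect_equal(wo2$stage, c("S4", "S4"))
  expect_equal(wo2$source, rep("locf_from_baseline", 2))

  # one w1 visit at IGA 0, baseline S3: w2 carries the w1 outcome S01
  co3 <- handCohort("traditional", "S3",
                    visits = data.frame(id = "H001", day = 12, iga = 0,
                                        stringsAsFactors = FALSE))
  wo3 <- windowOutcomes(co3)
  expect_equal(wo3$stage[wo3$window == "w2"], "S01")
  expect_equal(wo3$source[wo3$window == "w2"], "locf_from_w1")
})

test_that("transition rows are hand-countable", {
  # 4 biologic units at baseline S4 with w1 outcomes S01, S01, S4, S2
  v <- data.frame(id = sprintf("H%03d", 1:4), day = c(5, 9, 14, 21),
                  iga = c(0, 1, 4, 2), stringsAsFactors = FALSE)
  co <- handCohort(rep(c("biologic", "traditional", "systemic"),
                       c(4, 1, 1)),
                   c(rep("S4", 4), "S2", "S3"), visits = v)
  mt <- manualMatched(sprintf("H%03d", 1:4), "H005", "H006")
  est <- estimateTransitions(co, mt, "biologic", "w1")
  expect_equal(unname(transitionMatrix(est)["S4", ]),
               c(0.50, 0.25, 0, 0.25))
  expect_equal(rowCounts(est), c(0, 0, 0, 4))
  # undefined rows are NA, not zero
  expect_true(all(is.na(transitionMatrix(est)["S01", ])))
})

test_that("frequency weights equal physical duplication exactly", {
  set.seed(15)
  co <- randomSmallCohort(12)
  p <- patients(co)
  bio <- p$id[p$therapy == "biologic"]
  trad <- p$id[p$therapy == "traditional"]
  sys <- p$id[p$therapy == "systemic"]
  v <- data.frame(id = p$id, day = 15L,
                  iga = sample(0:4, nrow(p), replace = TRUE),
                  stringsAsFactors = FALSE)
  co <- new("PsoriasisCohort", patients = p, visits = v)
  # weight 3 on the first biologic unit
  mtW <- manualMatched(c(rep(bio[1], 3), bio), trad, sys)
  # same multiset via an explicitly duplicated cohort
  clones <- p[match(bio[1], p$id), ][c(1, 1), ]
  clones$id <- c("C001", "C002")
  vc <- v[match(bio[1], v$id), ][c(1, 1), ]
  vc$id <- clones$id
  coDup <- new("PsoriasisCohort", patients = rbind(p, clones),
               visits = rbind(v, vc))
  mtD <- manualMatched(c(clones$id, bio[1], bio), trad, sys)
  for (w in windowLevels()) {
    a <- estimateTransitions(co, mtW, "biologic", w)
    b <- estimateTransitions(coDup, mtD, "biologic", w)
    expect_identical(transitionMatrix(a), transitionMatrix(b))
    expect_identical(rowCounts(a), rowCounts(b))
  }
})

test_that("with no follow-up visits every matrix is the identity", {
  truth <- truthParams(n = 200, seed = 33,
                       covariateMissingRates = noMissingRates(),
                       visitMissingRates = c(w1 = 1, w2 = 1))
  co <- applyMissingness(simulateCohort(truth), truth)
  expect_equal(nrow(visits(co)), 0)
  mt <- matchThreeGroups(co)
  I4 <- diag(4); dimnames(I4) <- list(stageLevels(), stageLevels())
  for (th in c(therapyLevels(), "overall")) {
    est <- estimateTransitions(co, mt, th, "w1")
    def <- rowCounts(est) > 0
    expect_equal(transitionMatrix(est)[def, ], I4[def, ])
  }
})

test_that("LOCF pulls estimates toward the identity monotonically", {
  truth <- truthParams(n = 1500, seed = 35,
                       covariateMissingRates = noMissingRates(),
                       visitMissingRates = c(w1 = 0, w2 = 0))
  co <- simulateCohort(truth)
  mt <- matchThreeGroups(co)
  v <- visits(co)
  set.seed(99)
  ord <- sample(nrow(v))            # nested deletion sets
  diagMean <- vapply(c(0, 0.3, 0.6, 1), function(f) {
    vKeep <- v[ord[seq_len(round((1 - f) * nrow(v)))], ]
    coDel <- new("PsoriasisCohort", patients = patients(co),
                 visits = vKeep[order(vKeep$id, vKeep$day), ])
    est <- estimateTransitions(coDel, mt, "overall", "w1")
    mean(diag(transitionMatrix(est)), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(diagMean) > 0))
  expect_equal(diagMean[4], 1)      # full deletion = pure LOCF identity
})

test_that("defined rows are row-stochastic and variances behave", {
  truth <- truthParams(n = 400, seed = 37,
                       covariateMissingRates = noMissingRates())
  co <- simulateCohort(truth)
  mt <- matchThreeGroups(co)
  for (th in c(therapyLevels(), "overall")) for (w in windowLevels()) {
    est <- estimateTransitions(co, mt, th, w)
    p <- transitionMatrix(est); vv <- transitionVar(est)
    def <- rowCounts(est) > 0
    expect_true(all(abs(rowSums(p[def, , drop = FALSE]) - 1) < 1e-9))
    expect_true(all(vv[def, ] >= 0))
    expect_true(all(vv[def, ][p[def, ] %in% c(0, 1)] == 0))
  }
})
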