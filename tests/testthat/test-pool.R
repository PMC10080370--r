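mkEst <- function(p, v, therapy = "biologic", window = "w1") {
  dimnames(p) <- list(stageLevels(), stageLevels())
  dimnames(v) <- list(stageLevels(), stageLevels())
  new("TransitionEstimate", therapy = therapy, window = window,
      p = p, var = v, nRow = rep(100, 4))
}

rowStoch <- function(cellTopLeft) {
  p <- matrix(0.1, 4, 4)
  diag(p) <- 0.7                     # every row sums to 1
  p[1, 1] <- cellTopLeft
  p[1, 2] <- 1 - cellTopLeft - sum(p[1, 3:4])
  p
}

test_that("Rubin pooling matches the closed form", {
  p1 <- rowStoch(0.4); p2 <- rowStoch(0.6)
  v <- matrix(0.01, 4, 4)
  pool <- poolRubin(list(mkEst(p1, v), mkEst(p2, v)))
  expect_equal(transitionMatrix(pool)[1, 1], 0.5)
  # W = 0.01, B = var(c(.4,.6)) = 0.02, total = 0.01 + 1.5 * 0.02 = 0.04
  expect_equal(transitionVar(pool)[1, 1], 0.04)
  expect_equal(ciLower(pool)[1, 1], 0.5 - 1.96 * 0.2, tolerance = 1e-4)
  expect_equal(ciUpper(pool)[1, 1], 0.5 + 1.96 * 0.2, tolerance = 1e-4)
})

test_that("identical copies pool to themselves with zero between-variance", {
  p <- rowStoch(0.55); v <- matrix(0.005, 4, 4)
  pool <- poolRubin(lapply(1:6, function(i) mkEst(p, v)))
  expect_equal(unname(transitionMatrix(pool)), unname(p))
  expect_true(all(pool@between == 0))
  expect_equal(unname(transitionVar(pool)), unname(v + 0 * v))
})

test_that("a constant zero cell pools to zero with a degenerate CI", {
  p <- diag(4); v <- matrix(0, 4, 4)
  pool <- poolRubin(lapply(1:3, function(i) mkEst(p, v)))
  expect_equal(transitionMatrix(pool)[1, 4], 0)
  expect_equal(ciLower(pool)[1, 4], 0)
  expect_equal(ciUpper(pool)[1, 4], 0)
})

test_that("pooling preconditions are enforced", {
  p <- rowStoch(0.5); v <- matrix(0.01, 4, 4)
  expect_error(poolRubin(list(mkEst(p, v))), "m >= 2")
  expect_error(poolRubin(list(mkEst(p, v, window = "w1"),
                              mkEst(p, v, window = "w2"))),
               "share therapy and window")
  expect_error(contrastTherapies(
    list(mkEst(p, v, window = "w1"), mkEst(p, v, window = "w1")),
    list(mkEst(p, v, "traditional", "w2"),
         mkEst(p, v, "traditional", "w2"))), "window mismatch")
})

test_that("self-contrast is exactly zero with zero-width intervals", {
  p <- rowStoch(0.5); v <- matrix(0.01, 4, 4)
  ests <- lapply(1:4, function(i) mkEst(p, v))
  ct <- contrastTherapies(ests, ests)
  expect_true(all(ct@d == 0))
  expect_true(all(ciLower(ct) == 0) && all(ciUpper(ct) == 0))
})

test_that("contrast point estimate equals difference of pooled points", {
  set.seed(3)
  mk <- function(th) lapply(1:5, function(i) {
    p <- matrix(runif(16), 4, 4); p <- p / rowSums(p)
    mkEst(p, matrix(0.004, 4, 4), therapy = th)
  })
  a <- mk("biologic"); b <- mk("traditional")
  ct <- contrastTherapies(a, b)
  expect_equal(ct@d,
               transitionMatrix(poolRubin(a)) -
                 transitionMatrix(poolRubin(b)),
               tolerance = 1e-12)
})

test_that("a two-imputation contrast matches the hand-derived Rubin form", {
  pA1 <- rowStoch(0.40); pA2 <- rowStoch(0.50)
  pB1 <- rowStoch(0.30); pB2 <- rowStoch(0.32)
  vA <- matrix(0.002, 4, 4); vB <- matrix(0.003, 4, 4)
  ct <- contrastTherapies(list(mkEst(pA1, vA), mkEst(pA2, vA)),
                          list(mkEst(pB1, vB, "traditional"),
                               mkEst(pB2, vB, "traditional")))
  d1 <- pA1[1, 1] - pB1[1, 1]; d2 <- pA2[1, 1] - pB2[1, 1]
  dbar <- mean(c(d1, d2))
  Tvar <- (0.002 + 0.003) + 1.5 * var(c(d1, d2))
  expect_equal(ct@d[1, 1], dbar)
  expect_equal(ct@totalVar[1, 1], Tvar)
  expect_equal(ciLower(ct)[1, 1], dbar - 1.96 * sqrt(Tvar),
               tolerance = 1e-4)
})

test_that("total variance never falls below the within component", {
  set.seed(8)
  for (k in 1:20) {
    ests <- lapply(1:4, function(i) {
      p <- matrix(runif(16), 4, 4); p <- p / rowSums(p)
      mkEst(p, matrix(runif(16, 0, 0.01), 4, 4))
    })
    pool <- poolRubin(ests)
    expect_true(all(pool@totalVar >= pool@within - 1e-15))
    expect_true(all(ciLower(pool) <= transitionMatrix(pool) + 1e-12))
    expect_true(all(ciUpper(pool) >= transitionMatrix(pool) - 1e-12))
  }
})

test_that("published contrast table is consistent with the per-therapy tables", {
  ref <- referenceTransitions(long = FALSE)
  refC <- referenceContrasts(long = FALSE)
  for (cmp in names(refC)) {
    other <- sub("biologic_vs_", "", cmp)
    for (w in windowLevels()) {
      a <- lapply(1:2, function(i) transitionEstimateFromMatrix(
        ref$biologic[[w]]$p, 2860, "biologic", w))
      b <- lapply(1:2, function(i) transitionEstimateFromMatrix(
        ref[[other]][[w]]$p, 2000, other, w))
      ct <- contrastTherapies(a, b)
      # printed inputs are rounded to 2 dp, so each difference can deviate
      # from the printed difference by up to 0.01 plus renormalization slack
      expect_lt(max(abs(ct@d - refC[[cmp]][[w]]$d)), 0.015)
    }
  }
})
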