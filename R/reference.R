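## Published transition-probability estimates from a large national psoriasis
## registry cohort (8767 patients, three therapy arms). They serve two
## purposes: (i) the per-therapy matrices are the package's default simulation
## kernels, so synthetic cohorts have clinically realistic dynamics, and
## (ii) the printed point estimates are the fixture for the arithmetic
## consistency checks between the per-therapy tables and the between-therapy
## contrast table.

refMat <- function(v) {
  m <- matrix(v, 4, 4, byrow = TRUE,
              dimnames = list(stageLevels(), stageLevels()))
  m
}

.refTransitions <- function() {
  list(
    overall = list(
      w1 = list(
        p  = refMat(c(0.80, 0.12, 0.06, 0.02,
                      0.18, 0.74, 0.06, 0.01,
                      0.18, 0.13, 0.68, 0.02,
                      0.19, 0.14, 0.07, 0.60)),
        lo = refMat(c(0.78, 0.10, 0.05, 0.01,
                      0.17, 0.73, 0.06, 0.01,
                      0.17, 0.12, 0.66, 0.02,
                      0.18, 0.13, 0.06, 0.58)),
        hi = refMat(c(0.82, 0.13, 0.08, 0.03,
                      0.19, 0.75, 0.07, 0.02,
                      0.19, 0.13, 0.68, 0.02,
                      0.21, 0.15, 0.08, 0.61))),
      w2 = list(
        p  = refMat(c(0.54, 0.26, 0.16, 0.05,
                      0.34, 0.48, 0.14, 0.04,
                      0.35, 0.24, 0.37, 0.04,
                      0.36, 0.29, 0.14, 0.22)),
        lo = refMat(c(0.51, 0.23, 0.14, 0.04,
                      0.33, 0.47, 0.13, 0.03,
                      0.34, 0.23, 0.36, 0.03,
                      0.34, 0.28, 0.12, 0.20)),
        hi = refMat(c(0.57, 0.28, 0.17, 0.06,
                      0.35, 0.50, 0.15, 0.04,
                      0.36, 0.25, 0.38, 0.04,
                      0.37, 0.31, 0.15, 0.23)))),
    traditional = list(
      w1 = list(
        p  = refMat(c(0.83, 0.10, 0.05, 0.02,
                      0.15, 0.78, 0.05, 0.01,
                      0.15, 0.10, 0.74, 0.02,
                      0.17, 0.12, 0.03, 0.67)),
        lo = refMat(c(0.80, 0.08, 0.04, 0.01,
                      0.14, 0.76, 0.05, 0.01,
                      0.13, 0.09, 0.72, 0.01,
                      0.15, 0.10, 0.02, 0.64)),
        hi = refMat(c(0.85, 0.12, 0.07, 0.03,
                      0.16, 0.80, 0.06, 0.02,
                      0.16, 0.11, 0.75, 0.02,
                      0.20, 0.14, 0.04, 0.70))),
      w2 = list(
        p  = refMat(c(0.61, 0.19, 0.15, 0.05,
                      0.31, 0.54, 0.12, 0.04,
                      0.30, 0.20, 0.47, 0.03,
                      0.33, 0.23, 0.12, 0.31)),
        lo = refMat(c(0.57, 0.16, 0.12, 0.03,
                      0.29, 0.52, 0.11, 0.03,
                      0.29, 0.19, 0.45, 0.02,
                      0.30, 0.20, 0.10, 0.28)),
        hi = refMat(c(0.65, 0.23, 0.18, 0.07,
                      0.33, 0.56, 0.13, 0.04,
                      0.32, 0.21, 0.48, 0.04,
                      0.37, 0.26, 0.14, 0.34)))),
    systemic = list(
      w1 = list(
        p  = refMat(c(0.85, 0.05, 0.07, 0.04,
                      0.25, 0.70, 0.04, 0.01,
                      0.17, 0.12, 0.70, 0.02,
                      0.16, 0.10, 0.06, 0.68)),
        lo = refMat(c(0.81, 0.03, 0.04, 0.01,
                      0.23, 0.68, 0.03, 0.00,
                      0.15, 0.11, 0.68, 0.01,
                      0.14, 0.08, 0.04, 0.65)),
        hi = refMat(c(0.89, 0.07, 0.09, 0.06,
                      0.27, 0.72, 0.05, 0.01,
                      0.18, 0.13, 0.71, 0.02,
                      0.19, 0.12, 0.07, 0.71))),
      w2 = list(
        p  = refMat(c(0.61, 0.18, 0.16, 0.05,
                      0.38, 0.47, 0.12, 0.03,
                      0.33, 0.24, 0.40, 0.03,
                      0.30, 0.27, 0.14, 0.29)),
        lo = refMat(c(0.56, 0.14, 0.12, 0.03,
                      0.36, 0.45, 0.11, 0.02,
                      0.31, 0.23, 0.38, 0.03,
                      0.28, 0.24, 0.12, 0.26)),
        hi = refMat(c(0.66, 0.22, 0.20, 0.07,
                      0.41, 0.49, 0.14, 0.03,
                      0.34, 0.26, 0.42, 0.04,
                      0.33, 0.29, 0.16, 0.32)))),
    biologic = list(
      w1 = list(
        p  = refMat(c(0.73, 0.20, 0.08, 0.00,
                      0.15, 0.73, 0.10, 0.02,
                      0.23, 0.16, 0.59, 0.03,
                      0.23, 0.18, 0.10, 0.49)),
        lo = refMat(c(0.69, 0.16, 0.05, 0.00,
                      0.13, 0.71, 0.08, 0.01,
                      0.21, 0.15, 0.57, 0.02,
                      0.21, 0.17, 0.08, 0.47)),
        hi = refMat(c(0.77, 0.23, 0.10, 0.00,
                      0.17, 0.75, 0.11, 0.03,
                      0.24, 0.17, 0.60, 0.03,
                      0.25, 0.20, 0.11, 0.51))),
      w2 = list(
        p  = refMat(c(0.41, 0.39, 0.16, 0.04,
                      0.34, 0.43, 0.18, 0.05,
                      0.42, 0.29, 0.25, 0.04,
                      0.41, 0.34, 0.14, 0.10)),
        lo = refMat(c(0.36, 0.35, 0.13, 0.02,
                      0.32, 0.41, 0.17, 0.04,
                      0.40, 0.27, 0.24, 0.04,
                      0.39, 0.32, 0.13, 0.09)),
        hi = refMat(c(0.45, 0.43, 0.19, 0.06,
                      0.36, 0.45, 0.20, 0.06,
                      0.44, 0.30, 0.27, 0.05,
                      0.44, 0.37, 0.16, 0.12))))
  )
}

.refContrasts <- function() {
  list(
    biologic_vs_traditional = list(
      w1 = list(
        d  = refMat(c(-0.10,  0.10,  0.02, -0.02,
                       0.00, -0.05,  0.04,  0.01,
                       0.08,  0.06, -0.15,  0.01,
                       0.06,  0.06,  0.06, -0.18)),
        lo = refMat(c(-0.14,  0.06, -0.01, -0.03,
                      -0.02, -0.07,  0.03,  0.00,
                       0.06,  0.04, -0.17,  0.00,
                       0.02,  0.03,  0.05, -0.22)),
        hi = refMat(c(-0.05,  0.14,  0.05, -0.01,
                       0.02, -0.02,  0.06,  0.01,
                       0.10,  0.08, -0.13,  0.01,
                       0.09,  0.09,  0.08, -0.14))),
      w2 = list(
        d  = refMat(c(-0.20,  0.20,  0.01, -0.01,
                       0.03, -0.11,  0.07,  0.02,
                       0.12,  0.09, -0.22,  0.01,
                       0.08,  0.11,  0.02, -0.21)),
        lo = refMat(c(-0.26,  0.14, -0.03, -0.03,
                       0.00, -0.14,  0.04,  0.00,
                       0.09,  0.06, -0.24,  0.00,
                       0.04,  0.07,  0.00, -0.25)),
        hi = refMat(c(-0.14,  0.25,  0.05,  0.02,
                       0.06, -0.08,  0.09,  0.03,
                       0.14,  0.11, -0.19,  0.02,
                       0.12,  0.15,  0.05, -0.18)))),
    biologic_vs_systemic = list(
      w1 = list(
        d  = refMat(c(-0.12,  0.15,  0.01, -0.04,
                      -0.10,  0.03,  0.05,  0.01,
                       0.06,  0.04, -0.11,  0.01,
                       0.06,  0.08,  0.04, -0.19)),
        lo = refMat(c(-0.17,  0.11, -0.03, -0.06,
                      -0.12,  0.01,  0.04,  0.00,
                       0.04,  0.02, -0.14,  0.00,
                       0.03,  0.06,  0.02, -0.23)),
        hi = refMat(c(-0.07,  0.19,  0.04, -0.01,
                      -0.07,  0.06,  0.07,  0.02,
                       0.08,  0.06, -0.09,  0.02,
                       0.09,  0.11,  0.06, -0.15))),
      w2 = list(
        d  = refMat(c(-0.20,  0.21,  0.00, -0.01,
                      -0.05, -0.04,  0.06,  0.03,
                       0.09,  0.04, -0.15,  0.01,
                       0.11,  0.08,  0.01, -0.19)),
        lo = refMat(c(-0.27,  0.16, -0.05, -0.04,
                      -0.08, -0.07,  0.04,  0.01,
                       0.07,  0.02, -0.17,  0.00,
                       0.07,  0.04, -0.02, -0.23)),
        hi = refMat(c(-0.14,  0.27,  0.05,  0.02,
                      -0.02, -0.01,  0.09,  0.04,
                       0.12,  0.07, -0.12,  0.02,
                       0.14,  0.11,  0.03, -0.16))))
  )
}

refToLong <- function(ref, valueNames) {
  rows <- list()
  for (pop in names(ref)) for (w in names(ref[[pop]])) {
    block <- ref[[pop]][[w]]
    g <- expand.grid(to = stageLevels(), from = stageLevels(),
                     stringsAsFactors = FALSE)
    df <- data.frame(population = pop, window = w,
                     from = g$from, to = g$to, stringsAsFactors = FALSE)
    for (k in seq_along(valueNames)) {
      df[[valueNames[k]]] <- as.vector(t(block[[k]]))
    }
    rows[[length(rows) + 1L]] <- df
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Published reference transition probabilities
#'
#' Point estimates and 95% CI bounds of the 4x4 stage-transition matrices
#' reported for a large psoriasis registry cohort, for the pooled population
#' ("overall") and each of the three therapies, in both follow-up windows.
#' These printed values are inputs to the package: the per-therapy matrices
#' are the default simulation kernels and the estimates anchor the
#' table-consistency checks.
#'
#' @param long If `TRUE` (default) return a tidy data.frame with columns
#'   `population`, `window`, `from`, `to`, `estimate`, `lo`, `hi`; otherwise
#'   the nested list of 4x4 matrices.
#' @return A data.frame or nested list, see `long`.
#' @export
referenceTransitions <- function(long = TRUE) {
  ref <- .refTransitions()
  if (!long) return(ref)
  out <- refToLong(ref, c("estimate", "lo", "hi"))
  out
}

#' Published reference between-therapy contrasts
#'
#' Printed differences in transition probability (biologic minus traditional,
#' biologic minus systemic) with 95% CI bounds, per window.
#'
#' @param long If `TRUE` (default) return a tidy data.frame with columns
#'   `population` (the comparison), `window`, `from`, `to`, `estimate`, `lo`,
#'   `hi`; otherwise the nested list of 4x4 matrices.
#' @return A data.frame or nested list, see `long`.
#' @export
referenceContrasts <- function(long = TRUE) {
  ref <- .refContrasts()
  if (!long) return(ref)
  refToLong(ref, c("estimate", "lo", "hi"))
}

#' Default therapy-specific transition kernels
#'
#' The per-therapy reference matrices, row-renormalized to sum exactly to 1
#' (printed rows can be off by up to 0.01 from rounding), for use as the
#' ground-truth kernels of the synthetic-cohort generator.
#'
#' @return Named list `kernels[[therapy]][[window]]` of row-stochastic 4x4
#'   matrices.
#' @export
defaultKernels <- function() {
  ref <- .refTransitions()
  out <- list()
  for (th in therapyLevels()) {
    out[[th]] <- list()
    for (w in windowLevels()) {
      m <- ref[[th]][[w]]$p
      out[[th]][[w]] <- m / rowSums(m)
    }
  }
  out
}
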