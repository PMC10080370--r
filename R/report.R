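nodeIdFor <- function(stage) sub("/", "", stage, fixed = TRUE)

stageDisplay <- c(S01 = "IGA 0/1", S2 = "IGA 2", S3 = "IGA 3", S4 = "IGA 4")

#' Render a pooled transition matrix as a Graphviz diagram
#'
#' Emits a deterministic Graphviz DOT digraph with one node per severity
#' stage and one labeled edge (2-decimal probability) per cell with
#' probability at or above `threshold` (default 0: all 16 edges), in
#' row-major order. A JSON twin carries the full-precision estimates and
#' 95% CI bounds.
#'
#' @param pooled A [PooledTransitions].
#' @param threshold Minimum probability for an edge to be drawn.
#' @param dotFile,jsonFile Optional output paths.
#' @return Invisibly, a list with elements `dot` (character scalar) and
#'   `json` (character scalar).
#' @export
setMethod("renderDiagram", "PooledTransitions",
          function(pooled, threshold = 0, dotFile = NULL, jsonFile = NULL,
                   ...) {
  st <- stageLevels()
  lines <- c(
    sprintf("digraph transitions_%s_%s {", pooled@therapy, pooled@window),
    "  rankdir=LR;",
    "  node [shape=circle, fontsize=11];",
    sprintf("  %s [label=\"%s\"];", nodeIdFor(st), stageDisplay[st]))
  edges <- list()
  for (i in seq_len(4)) for (j in seq_len(4)) {
    pv <- pooled@p[i, j]
    if (!is.na(pv) && pv >= threshold) {
      lines <- c(lines, sprintf("  %s -> %s [label=\"%.2f\"];",
                                nodeIdFor(st[i]), nodeIdFor(st[j]), pv))
      edges[[length(edges) + 1L]] <- list(
        from = st[i], to = st[j], probability = pv,
        ci_lo = pooled@ciLo[i, j], ci_hi = pooled@ciHi[i, j])
    }
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  json <- jsonlite::toJSON(list(
    therapy = pooled@therapy, window = pooled@window,
    m = pooled@m, threshold = threshold,
    nodes = as.list(setNames(as.vector(stageDisplay), names(stageDisplay))),
    edges = edges), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(dotFile)) writeLines(dot, dotFile)
  if (!is.null(jsonFile)) writeLines(as.character(json), jsonFile)
  invisible(list(dot = dot, json = as.character(json)))
})

#' Publication-style table of a pooled or contrast result
#'
#' Long-format table (from, to, estimate, ci_lo, ci_hi), rounded to 2
#' decimals like the printed tables; set `digits = NA` for full precision.
#'
#' @param object A [PooledTransitions] or [TransitionContrast].
#' @param digits Decimal places (default 2; `NA` = no rounding).
#' @return data.frame in row-major cell order.
#' @export
transitionTable <- function(object, digits = 2) {
  est <- if (is(object, "TransitionContrast")) object@d else object@p
  g <- expand.grid(to = stageLevels(), from = stageLevels(),
                   stringsAsFactors = FALSE)[, c("from", "to")]
  out <- data.frame(
    from = g$from, to = g$to,
    estimate = as.vector(t(est)),
    ci_lo = as.vector(t(object@ciLo)),
    ci_hi = as.vector(t(object@ciHi)),
    stringsAsFactors = FALSE)
  if (!is.na(digits))
    out[, c("estimate", "ci_lo", "ci_hi")] <-
      round(out[, c("estimate", "ci_lo", "ci_hi")], digits)
  out
}

defaultPipelineConfig <- function() {
  list(n = 1000, seed = 1, m = 5, cycles = 5, donors = 5,
       window_end1 = 30, window_end2 = 365,
       visit_missing = c(w1 = 0.621, w2 = 0.488),
       diagram_threshold = 0, out_dir = "psortransit-results",
       input_dir = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or ingest from CSV) -> apply missingness -> multiple
#' imputation -> Mahalanobis matching per imputation -> transition
#' estimation -> Rubin pooling -> contrasts -> diagrams, writing CSV/JSON/
#' DOT outputs plus a manifest (config hash, package and R versions, seed)
#' that makes re-runs exactly reproducible. The run is a pure function of
#' the configuration and input files: identical config gives identical
#' outputs.
#'
#' Configuration keys (YAML file or list): `n`, `seed`, `m`, `cycles`,
#' `donors`, `window_end1`, `window_end2`, `visit_missing` (w1/w2 rates),
#' `diagram_threshold`, `out_dir`, and optionally `input_dir` holding
#' `patients.csv`/`visits.csv` to analyse instead of simulating.
#'
#' @param config A list or the path of a YAML file.
#' @return Invisibly, a list with the pooled results (`pooled`), contrasts
#'   (`contrasts`), balance table of the first imputation (`balance`) and
#'   the manifest; side effect: files under `out_dir`.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaultPipelineConfig(), config)
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    message("[psortransit] stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cohort <- if (!is.null(cfg$input_dir)) {
    stage("ingest", readCohortCsv(cfg$input_dir))
  } else {
    stage("simulate", {
      vm <- unlist(cfg$visit_missing)
      truth <- truthParams(n = cfg$n, seed = cfg$seed,
                           visitMissingRates = c(w1 = unname(vm["w1"]),
                                                 w2 = unname(vm["w2"])))
      writeTruth(truth, file.path(outDir, "truth.json"))
      complete <- simulateCohort(truth)
      applyMissingness(complete, truth)
    })
  }
  writeCohortCsv(cohort, file.path(outDir, "cohort"))

  imputed <- stage("impute",
    imputeCohort(cohort, m = cfg$m, cycles = cfg$cycles,
                 seed = cfg$seed, donors = cfg$donors))
  matchedList <- stage("match",
    lapply(seq_len(imputed@m), function(i)
      matchThreeGroups(imputed@cohorts[[i]], imputationIndex = i)))
  balance <- stage("balance",
    balanceDiagnostics(imputed@cohorts[[1]], matchedList[[1]]))
  write.csv(balance, file.path(outDir, "balance_m1.csv"), row.names = FALSE)

  pops <- c("overall", therapyLevels())
  estimates <- stage("transitions", {
    out <- list()
    for (pop in pops) for (w in windowLevels()) {
      out[[paste(pop, w, sep = "_")]] <-
        lapply(seq_len(imputed@m), function(i)
          estimateTransitions(imputed@cohorts[[i]], matchedList[[i]],
                              therapy = pop, window = w,
                              windowEnd1 = cfg$window_end1,
                              windowEnd2 = cfg$window_end2))
    }
    out
  })

  pooled <- stage("pool",
    lapply(estimates, poolRubin))
  for (nm in names(pooled))
    write.csv(transitionTable(pooled[[nm]]),
              file.path(outDir, paste0("pooled_", nm, ".csv")),
              row.names = FALSE)

  contrastPairs <- list(c("biologic", "traditional"),
                        c("biologic", "systemic"),
                        c("traditional", "systemic"))
  contrasts <- stage("contrast", {
    out <- list()
    for (pr in contrastPairs) for (w in windowLevels()) {
      nm <- paste0(pr[1], "_vs_", pr[2], "_", w)
      out[[nm]] <- contrastTherapies(
        estimates[[paste(pr[1], w, sep = "_")]],
        estimates[[paste(pr[2], w, sep = "_")]])
      write.csv(transitionTable(out[[nm]]),
                file.path(outDir, paste0("contrast_", nm, ".csv")),
                row.names = FALSE)
    }
    out
  })

  stage("report", {
    for (nm in names(pooled))
      renderDiagram(pooled[[nm]], threshold = cfg$diagram_threshold,
                    dotFile = file.path(outDir,
                                        paste0("diagram_", nm, ".dot")),
                    jsonFile = file.path(outDir,
                                         paste0("diagram_", nm, ".json")))
    full <- lapply(pooled, function(po) transitionTable(po, digits = NA))
    jsonlite::write_json(full, file.path(outDir, "results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })

  cfgJson <- as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                           digits = NA))
  manifest <- list(
    config = cfg,
    config_hash = fnv1a32(cfgJson),
    package_version = as.character(packageVersion("psortransit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(pooled = pooled, contrasts = contrasts, balance = balance,
                 manifest = manifest))
}
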