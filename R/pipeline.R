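#' Default pipeline parameters
#'
#' The conventional analysis defaults: baseline clamp 1, minimum signal 5,
#' saturation filter off, R-squared threshold 0.9, median chip centering,
#' within-chip LFC, cutoffs (0.2, 0.3, 0.4), 2000 sampling iterations,
#' hit threshold |Z| >= 2, network depth 1.
#'
#' @return named list of parameters.
#' @export
defaultParameters <- function() {
  list(baseline = 1, minSignal = 5, detectionFraction = 1,
       saturationLimit = Inf, keepReference = FALSE, r2Min = 0.9,
       chipNorm = "median", mode = "within_chip",
       cutoffs = c(0.2, 0.3, 0.4), iterations = 2000L, seed = 123L,
       zThreshold = 2, networkDepth = 1L, workers = 1L)
}

#' Run the full kinome-array analysis pipeline
#'
#' One-command end-to-end run: read crosstab, assign groups, QC filter,
#' fit the kinetic model, compute differential phosphorylation, score
#' upstream kinase families by random sampling, grow the hit network, and
#' write every artifact (tables, QC report, log, resolved configuration)
#' into a run directory. The run directory plus the embedded config and
#' seed suffice to reproduce the run; the same config and seed give
#' bit-identical score tables.
#'
#' @param config a named list or the path of a YAML file with entries:
#'   `crosstab` (input file), `baseline`, `comparison` (group labels),
#'   `mapping` (peptide-kinase file), optional `groups` (named
#'   sample-to-label mapping; defaults to the file's Group line),
#'   optional `ppi` and `aliases` files, optional `outDir`, and any
#'   parameter of [defaultParameters()] under `params`.
#' @param outDir overrides `config$outDir` (default `tempfile("kinact_")`).
#' @return invisibly, a list with the intermediate objects: `dataset`,
#'   `qc`, `model`, `diff`, `sets`, `scores`, `hits`, `network`,
#'   `outDir`.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  for (field in c("crosstab", "baseline", "comparison", "mapping"))
    if (is.null(config[[field]]))
      stop("config validation: missing required field \"", field, "\"",
           call. = FALSE)
  params <- utils::modifyList(defaultParameters(),
                              config$params %||% list())
  outDir <- outDir %||% config$outDir %||% tempfile("kinact_")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  logFile <- file.path(outDir, "run.log")
  logLine <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logFile, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cfgOut <- config
  cfgOut$params <- lapply(params,
                          function(v) if (identical(v, Inf)) ".inf" else v)
  yaml::write_yaml(cfgOut, file.path(outDir, "config.yaml"))

  ds <- stage("read", readCrosstab(config$crosstab))
  logLine("read: ", nrow(ds@peptides), " peptides x ",
          nrow(ds@samples), " wells")
  grpSpec <- config$groups %||% "group"
  ds <- stage("groups", assignGroups(ds, grpSpec))
  for (g in c(config$baseline, config$comparison))
    if (!g %in% ds@samples$group)
      stop("config validation: group \"", g,
           "\" not present among samples", call. = FALSE)

  ds <- stage("qc", qcSteps(ds, baseline = params$baseline,
                            saturationLimit = params$saturationLimit,
                            minSignal = params$minSignal,
                            fraction = params$detectionFraction,
                            keepReference = params$keepReference))
  rep0 <- qcReport(ds)
  logLine("qc: ", rep0@nReferenceRemoved, " reference + ",
          rep0@nLowSignalRemoved, " undetectable peptides removed; ",
          length(rep0@survivingPeptides), " remain")

  ep <- stage("endpoint", extractEndpoint(ds))
  model <- stage("model", scaleModel(ep, r2Min = params$r2Min,
                                     chipNorm = params$chipNorm,
                                     baseline = params$baseline))
  nonlinear <- attr(model@fits, "nonlinearRemoved")
  ds@qc$nNonlinearRemoved <- length(nonlinear)
  ds <- subsetPeptides(ds, unique(model@fits$peptideId))
  ds <- recordThreshold(ds, r2Min = params$r2Min)
  logLine("model: ", length(nonlinear), " non-linear peptides removed; ",
          length(unique(model@fits$peptideId)), " modeled")
  writeModel(model, outDir)
  writeQcReport(qcReport(ds), file.path(outDir, "qc_report.txt"))

  diff <- stage("differential",
                computeLFC(model, baseline = config$baseline,
                           comparison = config$comparison,
                           mode = params$mode))
  writeDiff(diff, file.path(outDir, "differential.tsv"))
  sets <- stage("peptide_sets", peptideSets(diff, params$cutoffs))
  setSizes <- vapply(sets, function(s) length(s@peptides), 0L)
  logLine("differential: set sizes at cutoffs (",
          paste(params$cutoffs, collapse = ", "), "): ",
          paste(setSizes, collapse = "/"))
  writeTable(data.frame(cutoff = rep(as.numeric(names(sets)), setSizes),
                        peptideId = unlist(lapply(sets,
                                                  function(s) s@peptides),
                                           use.names = FALSE)),
             file.path(outDir, "peptide_sets.tsv"))

  pool <- sort(unique(model@normalized$peptideId))
  mapping <- stage("mapping", loadMapping(config$mapping, pool = pool))
  scores <- stage("kinase_scores",
                  scoreKinases(mapping, sets,
                               iterations = params$iterations,
                               seed = params$seed,
                               workers = params$workers))
  writeScores(scores, outDir)
  hits <- selectHits(scores, zThreshold = params$zThreshold)
  writeTable(hits, file.path(outDir, "kinase_hits.tsv"))
  logLine("kinase scores: ", nrow(hits), " hit families at |Z| >= ",
          params$zThreshold)

  network <- NULL
  if (!is.null(config$ppi)) {
    network <- stage("network",
                     buildKinaseNetwork(hits, scores, ppi = config$ppi,
                                        depth = params$networkDepth,
                                        aliases = config$aliases))
    writeNetwork(network, outDir)
    logLine("network: ", nrow(network@nodes), " nodes, ",
            nrow(network@edges), " edges")
  }

  logLine("done: artifacts in ", outDir)
  invisible(list(dataset = ds, qc = qcReport(ds), model = model,
                 diff = diff, sets = sets, scores = scores, hits = hits,
                 network = network, outDir = outDir))
}
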