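#' Run configuration for the end-to-end pipeline
#'
#' Validated bundle of every tunable the pipeline stages read; the
#' snapshot written next to the outputs suffices to reproduce a run.
#'
#' @param seed global integer seed.
#' @param nPerGroup participants per group.
#' @param outDir output directory (created if missing).
#' @param config an `EffectConfig` for the generator.
#' @param ewmaN expTRIMP horizons (default `c(3, 5, 7)`).
#' @param aucIntegrand `"difference"` or `"percent"`.
#' @param aucNormalize per-day normalization of window AUCs.
#' @param pairedTest `"wilcoxon"` or `"t"`.
#' @param corScale `"raw"` or `"log"`.
#' @param traces simulate and use 1-Hz HR traces (`FALSE`: planned loads).
#' @param writeTraces write `hr_traces.csv` (large; default `TRUE` when
#'   traces are simulated).
#' @param markers optional marker subset.
#' @param mixedModel fit the per-marker phase mixed models.
#' @param ratio run the combined-biomarker stage (needs at least one
#'   significant positive and one negative load-correlated marker, which
#'   small cohorts may not yield).
#' @param ratioTarget selection target for the combined biomarker.
#' @return a validated `RunConfig` list.
#' @export
runConfig <- function(seed = 1, nPerGroup = 10, outDir = "loadmark-run",
                      config = defaultEffectConfig(),
                      ewmaN = c(3, 5, 7),
                      aucIntegrand = "difference", aucNormalize = TRUE,
                      pairedTest = "wilcoxon", corScale = "raw",
                      traces = TRUE, writeTraces = traces,
                      markers = NULL, mixedModel = TRUE, ratio = TRUE,
                      ratioTarget = "exp_trimp_7") {
  if (!is.numeric(seed) || is.na(seed)) stop("config error: invalid seed")
  if (nPerGroup < 2) stop("config error: nPerGroup must be >= 2")
  if (!inherits(config, "EffectConfig"))
    stop("config error: config must be an EffectConfig")
  if (!all(ewmaN > 0)) stop("config error: ewmaN must be positive")
  if (!aucIntegrand %in% c("difference", "percent"))
    stop("config error: invalid aucIntegrand '", aucIntegrand, "'")
  if (!pairedTest %in% c("wilcoxon", "t"))
    stop("config error: invalid pairedTest '", pairedTest, "'")
  if (!corScale %in% c("raw", "log"))
    stop("config error: invalid corScale '", corScale, "'")
  if (writeTraces && !traces)
    stop("config error: writeTraces requires traces")
  structure(list(seed = as.integer(seed), nPerGroup = as.integer(nPerGroup),
                 outDir = outDir, config = config, ewmaN = ewmaN,
                 aucIntegrand = aucIntegrand, aucNormalize = aucNormalize,
                 pairedTest = pairedTest, corScale = corScale,
                 traces = traces, writeTraces = writeTraces,
                 markers = markers, mixedModel = mixedModel,
                 ratio = ratio, ratioTarget = ratioTarget),
            class = "RunConfig")
}

.writeCsv <- function(x, dir, name, log) {
  path <- file.path(dir, name)
  write.csv(x, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  log(sprintf("wrote %s: %d rows", name, nrow(x)))
  path
}

#' Run the full monitoring pipeline
#'
#' generate -> training load -> biomarker statistics -> correlations ->
#' combined biomarker, writing every stage's tidy CSV plus a config
#' snapshot and a log into the run directory.  Identical config and seed
#' give byte-identical outputs; any stage error aborts with the stage
#' name and cause.
#'
#' @param rc a `RunConfig` from [runConfig()].
#' @return (invisibly) list with the run directory, the written file
#'   paths and the in-memory stage results.
#' @export
#' @examples
#' \donttest{
#' rc <- runConfig(seed = 1, nPerGroup = 3, outDir = tempfile(),
#'                 traces = FALSE, mixedModel = FALSE,
#'                 markers = c("CK", "urea", "RBC", "HCT"))
#' res <- runPipeline(rc)
#' list.files(res$outDir)
#' }
runPipeline <- function(rc) {
  if (!inherits(rc, "RunConfig")) stop("rc must be a RunConfig")
  dir.create(rc$outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character()
  log <- function(msg) {
    logLines <<- c(logLines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character()

  log(sprintf("run: seed=%d nPerGroup=%d traces=%s", rc$seed,
              rc$nPerGroup, rc$traces))
  study <- stage("generate", simulateStudy(
    nPerGroup = rc$nPerGroup, seed = rc$seed, config = rc$config,
    traces = rc$traces, markers = rc$markers))
  files <- c(files,
    .writeCsv(study$participants[, c("participant_id", "group", "sex",
                                     "hr_max", "speed_at_1p5")],
              rc$outDir, "participants.csv", log),
    .writeCsv(study$sessions, rc$outDir, "sessions.csv", log),
    .writeCsv(study$petStages, rc$outDir, "pet_stages.csv", log),
    .writeCsv(longForm(study$panel)[, c("participant_id", "timepoint",
                                        "marker", "value", "unit")],
              rc$outDir, "biomarkers.csv", log),
    .writeCsv(study$selfReports, rc$outDir, "selfreports.csv", log),
    .writeCsv(study$vo2max, rc$outDir, "vo2max.csv", log))
  if (rc$writeTraces)
    files <- c(files, .writeCsv(study$hrTraces, rc$outDir,
                                "hr_traces.csv", log))

  daily <- stage("training_load", {
    if (rc$traces) {
      zms <- fitZoneModels(study$petStages, study$participants)
      sl <- computeSessionLoads(study$hrTraces, zms, study$sessions)
      files <- c(files, .writeCsv(sl, rc$outDir, "session_loads.csv", log))
      dailyLoad(sl, N = rc$ewmaN)
    } else {
      log("traces disabled: daily load from the session plan")
      study$plannedDaily
    }
  })
  files <- c(files, .writeCsv(daily, rc$outDir, "daily_load.csv", log))

  stats <- stage("biomarker_stats", {
    thr <- sdThreshold(study$panel)
    chronic <- chronicAUC(study$panel, integrand = rc$aucIntegrand,
                          normalize = rc$aucNormalize,
                          pairedTest = rc$pairedTest)
    mm <- if (rc$mixedModel) phaseMixedModel(study$panel) else NULL
    list(thr = thr, chronic = chronic, mm = mm)
  })
  files <- c(files,
    .writeCsv(stats$thr, rc$outDir, "sd_thresholds.csv", log),
    .writeCsv(stats$chronic$byGroup, rc$outDir, "chronic_changes.csv", log))
  if (!is.null(stats$mm))
    files <- c(files, .writeCsv(stats$mm$contrasts, rc$outDir,
                                "mixed_model_results.csv", log))

  corr <- stage("correlation", {
    aligned <- buildAlignedTable(study$panel, daily, study$selfReports,
                                 study$vo2max)
    cm <- pearsonMatrix(aligned, scale = rc$corScale)
    net <- buildNetwork(cm)
    list(aligned = aligned, cm = cm, net = net)
  })
  files <- c(files,
    .writeCsv(significantPairs(corr$cm), rc$outDir,
              "correlation_matrix.csv", log),
    .writeCsv(networkEdges(corr$net), rc$outDir, "network_edges.csv", log))

  ratio <- NULL
  if (rc$ratio) {
    ratio <- stage("combined_biomarker",
      combinedBiomarker(study$panel, corr$cm, corr$aligned,
                        target = rc$ratioTarget))
    rs <- ratio$series
    key <- paste(corr$aligned$participant_id, corr$aligned$timepoint)
    ri <- match(paste(rs$participant_id, rs$timepoint), key)
    rs$exp_trimp_7 <- corr$aligned$exp_trimp_7[ri]
    rs$soreness <- corr$aligned$soreness[ri]
    files <- c(files, .writeCsv(rs, rc$outDir, "ratio_biomarker.csv", log))
    log(sprintf(
      "combined biomarker: log%s-to-log%s, r(load)=%.3f, r(soreness)=%.3f",
      ratio$spec$positive, ratio$spec$negative,
      ratio$evaluation$r_load, ratio$evaluation$r_soreness))
  }

  snap <- c(
    sprintf("seed=%d", rc$seed),
    sprintf("n_per_group=%d", rc$nPerGroup),
    sprintf("ewma_n=%s", paste(rc$ewmaN, collapse = ",")),
    sprintf("auc_integrand=%s", rc$aucIntegrand),
    sprintf("auc_normalize=%s", rc$aucNormalize),
    sprintf("paired_test=%s", rc$pairedTest),
    sprintf("cor_scale=%s", rc$corScale),
    sprintf("traces=%s", rc$traces),
    sprintf("markers=%s",
            paste(if (is.null(rc$markers)) "all" else rc$markers,
                  collapse = ",")))
  writeLines(snap, file.path(rc$outDir, "config.txt"))
  writeLines(logLines, file.path(rc$outDir, "run.log"))

  invisible(list(outDir = rc$outDir, files = files, study = study,
                 daily = daily, stats = stats, corr = corr,
                 ratio = ratio))
}

## Schema registry: required columns and row-level checks.
.csvSchemas <- function() {
  list(
    participants = list(
      cols = c("participant_id", "group", "sex", "hr_max", "speed_at_1p5"),
      checks = function(d) {
        v <- list()
        dup <- which(duplicated(d$participant_id))
        if (length(dup)) v <- c(v, lapply(dup, function(i)
          list(row = i, problem = "duplicate participant_id")))
        bad <- which(!d$group %in% .GROUPS)
        v <- c(v, lapply(bad, function(i)
          list(row = i, problem = "unknown group")))
        bad <- which(d$hr_max < 160 | d$hr_max > 210)
        v <- c(v, lapply(bad, function(i)
          list(row = i, problem = "hr_max outside [160, 210]")))
        v
      }),
    biomarkers = list(
      cols = c("participant_id", "timepoint", "marker", "value"),
      checks = function(d) {
        v <- list()
        bad <- which(!is.finite(d$value) | d$value <= 0)
        v <- c(v, lapply(bad, function(i)
          list(row = i, problem = "non-positive biomarker value")))
        dup <- which(duplicated(d[, c("participant_id", "timepoint",
                                      "marker")]))
        v <- c(v, lapply(dup, function(i)
          list(row = i,
               problem = "duplicate (participant, timepoint, marker)")))
        bad <- which(!d$timepoint %in% .TP_LEVELS)
        v <- c(v, lapply(bad, function(i)
          list(row = i, problem = "unknown timepoint")))
        v
      }),
    sessions = list(
      cols = c("session_id", "participant_id", "study_day", "slot",
               "kind", "planned_minutes"),
      checks = function(d) {
        v <- list()
        bad <- which(!d$kind %in% c("HIIT", "LIT", "REGULAR"))
        v <- c(v, lapply(bad, function(i)
          list(row = i, problem = "unknown session kind")))
        bad <- which(d$planned_minutes <= 0)
        v <- c(v, lapply(bad, function(i)
          list(row = i, problem = "non-positive planned_minutes")))
        v
      }),
    hr_traces = list(
      cols = c("session_id", "t_s", "hr"),
      checks = function(d) {
        bad <- which(d$hr <= 40)
        lapply(bad, function(i) list(row = i, problem = "hr <= 40"))
      }),
    daily_load = list(
      cols = c("participant_id", "study_day", "trimp"),
      checks = function(d) {
        bad <- which(d$trimp < 0)
        lapply(bad, function(i) list(row = i, problem = "negative trimp"))
      }),
    session_loads = list(
      cols = c("session_id", "participant_id", "minutes_z1", "minutes_z2",
               "minutes_z3", "trimp"),
      checks = function(d) {
        bad <- which(d$minutes_z1 < 0 | d$minutes_z2 < 0 |
                       d$minutes_z3 < 0)
        lapply(bad, function(i)
          list(row = i, problem = "negative zone minutes"))
      }),
    selfreports = list(
      cols = c("participant_id", "study_day", "soreness", "pain",
               "wellbeing", "fatigue", "sleep"),
      checks = function(d) {
        v <- list()
        bad <- which(d$soreness < 0 | d$soreness > 100 |
                       d$pain < 0 | d$pain > 100 |
                       d$wellbeing < 0 | d$wellbeing > 100)
        v <- c(v, lapply(bad, function(i)
          list(row = i, problem = "VAS score outside [0, 100]")))
        bad <- which(d$fatigue < 1 | d$fatigue > 10)
        v <- c(v, lapply(bad, function(i)
          list(row = i, problem = "fatigue outside [1, 10]")))
        bad <- which(d$sleep < 1 | d$sleep > 7)
        v <- c(v, lapply(bad, function(i)
          list(row = i, problem = "sleep outside [1, 7]")))
        v
      }),
    vo2max = list(
      cols = c("participant_id", "timepoint", "vo2max"),
      checks = function(d) {
        bad <- which(d$vo2max < 45 | d$vo2max > 80)
        lapply(bad, function(i)
          list(row = i, problem = "vo2max outside [45, 80]"))
      }),
    correlation_matrix = list(
      cols = c("var1", "var2", "r", "p", "n", "significant", "class"),
      checks = function(d) {
        v <- list()
        bad <- which(is.finite(d$r) & abs(d$r) > 1)
        v <- c(v, lapply(bad, function(i)
          list(row = i, problem = "r outside [-1, 1]")))
        bad <- which(is.finite(d$p) & (d$p < 0 | d$p > 1))
        v <- c(v, lapply(bad, function(i)
          list(row = i, problem = "p outside [0, 1]")))
        v
      })
  )
}

#' Validate a pipeline CSV against its schema
#'
#' Checks column presence and row-level invariants (positivity, key
#' uniqueness, scale ranges) for the pipeline's tidy CSV schemas;
#' violations are reported with their row numbers.
#'
#' @param path CSV file path.
#' @param schema schema name, one of
#'   `names(loadmark:::.csvSchemas())` (e.g. `"participants"`,
#'   `"biomarkers"`, `"daily_load"`).
#' @return `data.frame` of violations (`schema`, `row`, `problem`);
#'   zero rows when the file is valid.
#' @export
validateCsv <- function(path, schema) {
  schemas <- .csvSchemas()
  if (!schema %in% names(schemas))
    stop("invalid argument: unknown schema '", schema, "'")
  sc <- schemas[[schema]]
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(sc$cols, colnames(d))
  v <- lapply(miss, function(m)
    list(row = NA_integer_, problem = paste("missing column:", m)))
  if (!length(miss)) v <- c(v, sc$checks(d))
  if (!length(v))
    return(data.frame(schema = character(), row = integer(),
                      problem = character(), stringsAsFactors = FALSE))
  out <- data.frame(schema = schema,
                    row = vapply(v, function(x) x$row, integer(1)),
                    problem = vapply(v, function(x) x$problem,
                                     character(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
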