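# Run orchestration: configuration manifests for bit-reproducible stages
# and a thin command-line front end over the package's functions.

# FNV-1a over serialized bytes; stable content hash for manifests.
# 32-bit arithmetic is emulated on doubles in 16-bit halves (R's bitwXor
# is limited to signed 32-bit integers).
.configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    # (hi*2^16 + lo) * prime mod 2^32, kept within double precision
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a run manifest
#'
#' Every pipeline stage writes a manifest (configuration, its hash, seeds,
#' package version) sufficient to re-execute the stage bit-comparably.
#'
#' @param config The stage configuration (any serializable list).
#' @param seeds Integer seed(s) the stage used.
#' @param stage Stage name.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
writeManifest <- function(config, seeds, stage, path) {
  manifest <- list(
    stage = stage,
    configHash = .configHash(config),
    config = config,
    seeds = as.integer(seeds),
    package = "rungait",
    version = as.character(utils::packageVersion("rungait"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Evaluate a trained model on a split and write a metrics report
#'
#' @param model A `DitLstmModel` or `LstmRefModel`.
#' @param data A [WindowedGaitData-class].
#' @param split Which split to evaluate.
#' @return The [computeMetrics()] report.
#' @export
evaluateModel <- function(model, data, split = "test") {
  te <- subsetSplit(data, split)
  pred <- if (inherits(model, "DitLstmModel"))
    predictDitLstm(model, te) else predictLstmReference(model, te)
  computeMetrics(te@labels, factor(pred$labels, levels = levels(te@labels)),
                 pred$probabilities)
}

#' Write a metrics report as JSON
#'
#' @param metrics Output of [computeMetrics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMetricsJson <- function(metrics, path) {
  out <- metrics
  out$confusion <- as.data.frame.matrix(metrics$confusion)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches the sub-commands `simulate` (render a windowed dataset and
#' manifest), `make-dataset` (alias of simulate), `train`, `evaluate`, and
#' `report`. Used by the `inst/cli/rungait` script; calling it in-process
#' returns the exit status instead of quitting.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 success, 1 stage error, 2 usage error).
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rungait <command> [options]",
    "commands:",
    "  simulate --out DIR [--seed N] [--config cfg.yaml]",
    "  make-dataset (alias of simulate)",
    "  train --data DIR --out DIR [--seed N]",
    "  evaluate --model FILE --data DIR --out FILE",
    "  report --runs DIR --out FILE",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(2L) }
  cmd <- args[1L]
  opts <- .parseCliOpts(args[-1L])
  known <- c("simulate", "make-dataset", "train", "evaluate", "report")
  if (!cmd %in% known) { message("unknown command: ", cmd, "\n", usage); return(2L) }
  status <- tryCatch({
    switch(cmd,
      "simulate" = ,
      "make-dataset" = .cliSimulate(opts),
      "train" = .cliTrain(opts),
      "evaluate" = .cliEvaluate(opts),
      "report" = .cliReport(opts))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}

.parseCliOpts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else { opts[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  opts
}

.cliReadConfig <- function(opts) {
  if (is.null(opts$config)) return(list())
  cfg <- yaml::read_yaml(opts$config)
  if (!is.list(cfg)) stop("config file did not parse to a mapping")
  allowed <- c("duration", "rateHz", "window", "stride", "imuNoiseSd",
               "uwbNoiseSd", "uwbRateHz", "nTrain", "nVal", "seed")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("invalid config key(s): ", paste(bad, collapse = ", "))
  cfg
}

.cliSimulate <- function(opts) {
  if (is.null(opts$out)) stop("simulate requires --out")
  seed <- as.integer(if (is.null(opts$seed)) 1L else opts$seed)
  cfg <- .cliReadConfig(opts)
  cfg$seed <- seed
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  data <- renderGaitDataset(subjects = defaultCohort(seed = seed),
                            config = cfg)
  saveWindowedDataset(data, file.path(opts$out, "dataset"))
  writeManifest(cfg, seed, "simulate", file.path(opts$out, "manifest.json"))
  message("wrote dataset (", nWindows(data), " windows) to ", opts$out)
}

.cliTrain <- function(opts) {
  if (is.null(opts$data) || is.null(opts$out))
    stop("train requires --data and --out")
  seed <- as.integer(if (is.null(opts$seed)) 1L else opts$seed)
  data <- loadWindowedDataset(file.path(opts$data, "dataset"))
  model <- trainDitLstm(data, scaledDownConfig(), seed = seed)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  saveCheckpoint(model, file.path(opts$out, "checkpoint.json"))
  writeManifest(list(config = unclass(model$config)), seed, "train",
                file.path(opts$out, "manifest.json"))
  message("checkpoint written to ", opts$out)
}

.cliEvaluate <- function(opts) {
  if (is.null(opts$model) || is.null(opts$data) || is.null(opts$out))
    stop("evaluate requires --model, --data and --out")
  model <- loadCheckpoint(opts$model)
  data <- loadWindowedDataset(file.path(opts$data, "dataset"))
  metrics <- evaluateModel(model, data, "test")
  writeMetricsJson(metrics, opts$out)
  message("metrics written to ", opts$out)
}

.cliReport <- function(opts) {
  if (is.null(opts$runs) || is.null(opts$out))
    stop("report requires --runs and --out")
  files <- list.files(opts$runs, pattern = "metrics.*\\.json$",
                      full.names = TRUE)
  if (!length(files)) stop("no metrics JSON files under ", opts$runs)
  acc <- vapply(files, function(f)
    jsonlite::read_json(f, simplifyVector = TRUE)$accuracy, numeric(1L))
  f1 <- vapply(files, function(f)
    jsonlite::read_json(f, simplifyVector = TRUE)$macroF1, numeric(1L))
  rep <- list(nRuns = length(files),
              accuracy = aggregateSeedMetrics(acc),
              macroF1 = aggregateSeedMetrics(f1))
  jsonlite::write_json(rep, opts$out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  message("aggregate report written to ", opts$out)
}

#' Save/load a windowed dataset as plain-text files
#'
#' Stores the window array as a flat CSV of values plus a CSV of per-window
#' metadata and a JSON sidecar with dimensions, channel names, and the
#' normalization statistics.
#'
#' @param data A [WindowedGaitData-class].
#' @param prefix Path prefix; three files `<prefix>_values.csv`,
#'   `<prefix>_meta.csv`, `<prefix>_info.json` are written.
#' @return `loadWindowedDataset` returns the dataset;
#'   `saveWindowedDataset` returns `prefix` invisibly.
#' @export
saveWindowedDataset <- function(data, prefix) {
  stopifnot(is(data, "WindowedGaitData"))
  d <- dim(data@windows)
  utils::write.csv(data.frame(value = as.numeric(data@windows)),
                   paste0(prefix, "_values.csv"), row.names = FALSE)
  utils::write.csv(data.frame(label = as.character(data@labels),
                              subject = data@subject,
                              split = as.character(data@split)),
                   paste0(prefix, "_meta.csv"), row.names = FALSE)
  jsonlite::write_json(list(dim = d, channels = data@channelNames,
                            classes = levels(data@labels),
                            normStats = data@normStats),
                       paste0(prefix, "_info.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname saveWindowedDataset
#' @export
loadWindowedDataset <- function(prefix) {
  info <- jsonlite::read_json(paste0(prefix, "_info.json"),
                              simplifyVector = TRUE)
  vals <- utils::read.csv(paste0(prefix, "_values.csv"))$value
  meta <- utils::read.csv(paste0(prefix, "_meta.csv"),
                          stringsAsFactors = FALSE)
  W <- array(vals, as.integer(info$dim))
  new("WindowedGaitData", windows = W,
      labels = factor(meta$label, levels = info$classes),
      subject = meta$subject,
      split = factor(meta$split, levels = c("train", "val", "test")),
      channelNames = info$channels,
      normStats = list(mean = as.numeric(info$normStats$mean),
                       sd = as.numeric(info$normStats$sd)))
}
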