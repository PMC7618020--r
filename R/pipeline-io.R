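## On-disk formats and the end-to-end pipeline: a BIDS-style cohort tree
## (participants.tsv + per-subject binary recording containers with JSON
## sidecars), marker CSVs, the analysis report, and a run manifest.

#' Write a recording container
#'
#' Stores a [MegRecording-class] as a little-endian 32-bit-float channel-major
#' binary file plus a JSON sidecar (sfreq_hz, n_channels, n_samples,
#' channel_names, channel_types, units, md5 of the payload). Values are
#' quantized to float32 on write, so a read-write-read cycle is bit-stable.
#'
#' @param recording a [MegRecording-class].
#' @param dir directory to write into (created if needed).
#' @param id file stem, e.g. \code{"sub-001_meg"}.
#' @return invisibly, the paths written.
#' @export
writeRecordingContainer <- function(recording, dir, id) {
  stopifnot(is(recording, "MegRecording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  datPath <- file.path(dir, paste0(id, ".dat"))
  jsonPath <- file.path(dir, paste0(id, ".json"))
  # channel-major: all samples of channel 1, then channel 2, ...
  con <- file(datPath, "wb")
  writeBin(as.vector(t(recording@data)), con, size = 4L, endian = "little")
  close(con)
  sidecar <- list(
    sfreq_hz = sfreq(recording),
    n_channels = nChannels(recording),
    n_samples = nSamples(recording),
    channel_names = channelNames(recording),
    channel_types = recording@channelTypes,
    units = "a.u.",
    payload_md5 = unname(tools::md5sum(datPath)))
  jsonlite::write_json(sidecar, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(datPath, jsonPath))
}

#' Read a recording container
#'
#' Validates the sidecar against the binary payload (byte count must match
#' n_channels * n_samples * 4 exactly) and returns the recording.
#'
#' @param dir directory holding the container.
#' @param id file stem.
#' @return a [MegRecording-class].
#' @export
readRecordingContainer <- function(dir, id) {
  datPath <- file.path(dir, paste0(id, ".dat"))
  jsonPath <- file.path(dir, paste0(id, ".json"))
  if (!file.exists(jsonPath))
    stop("missing sidecar: ", jsonPath)
  if (!file.exists(datPath))
    stop("missing binary payload: ", datPath)
  sc <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  expBytes <- as.numeric(sc$n_channels) * as.numeric(sc$n_samples) * 4
  gotBytes <- file.size(datPath)
  if (gotBytes != expBytes)
    stop(sprintf(
      "%s: payload is %d bytes but sidecar implies %d (%d ch x %d samples x 4)",
      datPath, gotBytes, as.integer(expBytes),
      as.integer(sc$n_channels), as.integer(sc$n_samples)))
  con <- file(datPath, "rb")
  vals <- readBin(con, "numeric", n = sc$n_channels * sc$n_samples,
                  size = 4L, endian = "little")
  close(con)
  mat <- matrix(vals, nrow = sc$n_channels, byrow = TRUE)
  megRecording(mat, sc$sfreq_hz, sc$channel_names, sc$channel_types)
}

#' Write a cohort as a BIDS-style tree
#'
#' \code{participants.tsv} (participant_id, group, age, sex, site, mmse) plus
#' \code{sub-<id>/meg/} recording containers.
#'
#' @param cohort a cohort from [generateCohort()] (recordings are regenerated
#'   from stored parameters when not kept in memory).
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$participants,
                     file.path(dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(cohort$participants))) {
    pid <- cohort$participants$participant_id[i]
    rec <- if (!is.null(cohort$recordings)) cohort$recordings[[i]]
           else subjectRecording(cohort, i)
    writeRecordingContainer(rec, file.path(dir, pid, "meg"),
                            paste0(pid, "_meg"))
  }
  invisible(dir)
}

#' Read a cohort tree
#'
#' Parses \code{participants.tsv}, validates it (unique ids, required
#' columns), reads every subject's container, and returns subjects sorted by
#' participant_id.
#'
#' @param dir cohort directory written by [writeCohort()].
#' @return list with \code{participants} and \code{recordings} (named list of
#'   [MegRecording-class]).
#' @export
readCohort <- function(dir) {
  tsv <- file.path(dir, "participants.tsv")
  if (!file.exists(tsv)) stop("no participants.tsv in ", dir)
  meta <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  needed <- c("participant_id", "group", "age", "sex", "site", "mmse")
  absent <- setdiff(needed, names(meta))
  if (length(absent))
    stop(tsv, ": missing columns ", paste(absent, collapse = ", "))
  if (anyDuplicated(meta$participant_id))
    stop(tsv, ": duplicated participant_id ",
         meta$participant_id[duplicated(meta$participant_id)][1L])
  meta <- meta[order(meta$participant_id), , drop = FALSE]
  rownames(meta) <- NULL
  recordings <- lapply(meta$participant_id, function(pid)
    readRecordingContainer(file.path(dir, pid, "meg"), paste0(pid, "_meg")))
  names(recordings) <- meta$participant_id
  list(participants = meta, recordings = recordings)
}

#' Assemble a pipeline run configuration
#'
#' Bundles the stage configurations. \code{masterSeed} deterministically
#' splits into the cohort seed and the complexity (channel-subset) seed, so
#' one integer reproduces an entire run.
#'
#' @param cohort a [CohortSpec-class].
#' @param preprocess a [PreprocessConfig-class].
#' @param complexity a [ComplexityConfig-class].
#' @param spectral a [SpectralConfig-class].
#' @param outputDir output directory.
#' @param masterSeed integer master seed.
#' @param logLevel \code{"quiet"}, \code{"info"} or \code{"debug"}.
#' @return a \code{RunConfig} (S3 list).
#' @export
runConfig <- function(cohort = cohortSpec(),
                      preprocess = preprocessConfig(),
                      complexity = complexityConfig(),
                      spectral = spectralConfig(),
                      outputDir = "megmarkers-run",
                      masterSeed = 1L, logLevel = "info") {
  cohort@seed <- deriveSeed(masterSeed, 1L)
  complexity@seed <- deriveSeed(masterSeed, 2L)
  structure(list(cohort = cohort, preprocess = preprocess,
                 complexity = complexity, spectral = spectral,
                 outputDir = outputDir, masterSeed = as.integer(masterSeed),
                 logLevel = logLevel),
            class = "RunConfig")
}

.slotList <- function(obj) {
  nm <- slotNames(class(obj))
  out <- lapply(nm, function(s) {
    v <- slot(obj, s)
    if (isVirtualClass(class(v)) || isS4(v)) .slotList(v) else v
  })
  names(out) <- nm
  out
}

#' Run the full pipeline
#'
#' Simulate (or ingest) a cohort, preprocess every subject, compute LZsum and
#' TAR, run the statistics battery, and write: \code{participants.tsv},
#' \code{markers_subject.csv}, \code{markers_epoch.csv}, per-subject
#' rejection reports (JSON), \code{analysis_report.json}, and
#' \code{manifest.json} recording every tunable, the seeds and the package
#' version, enabling exact re-runs. Given one \code{masterSeed}, two runs are
#' byte-identical.
#'
#' @param config a \code{RunConfig} from [runConfig()].
#' @param inputDir optional existing cohort tree to ingest instead of
#'   simulating.
#' @return invisibly, the \code{AnalysisReport}.
#' @examples
#' \donttest{
#' cfg <- runConfig(cohortSpec(nPerGroup = 3, nChannels = 8, duration = 16),
#'                  outputDir = tempfile(), masterSeed = 7)
#' report <- runPipeline(cfg)
#' }
#' @export
runPipeline <- function(config, inputDir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  info <- function(...) if (config$logLevel != "quiet") message(sprintf(...))

  info("[simulate] generating cohort (%d/group, %d channels, %g s)",
       config$cohort@nPerGroup, config$cohort@nChannels,
       config$cohort@duration)
  cohort <- if (is.null(inputDir)) {
    generateCohort(config$cohort, keepRecordings = FALSE)
  } else {
    info("[ingest] reading cohort from %s", inputDir)
    readCohort(inputDir)
  }
  utils::write.table(cohort$participants,
                     file.path(config$outputDir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  info("[markers] preprocessing and computing LZsum / TAR")
  rejDir <- file.path(config$outputDir, "rejection_reports")
  dir.create(rejDir, showWarnings = FALSE)
  meta <- cohort$participants
  n <- nrow(meta)
  nch <- if (!is.null(cohort$spec)) cohort$spec@nChannels
         else nChannels(cohort$recordings[[1L]])
  effK <- min(config$complexity@nSubsampleChannels, nch)
  lz <- tar <- rep(NA_real_, n)
  nKept <- nEp <- rep(NA_integer_, n)
  perEpoch <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- meta$participant_id[i]
    rec <- if (!is.null(cohort$recordings)) cohort$recordings[[i]]
           else subjectRecording(cohort, i)
    es <- preprocessRecording(rec, config$preprocess)
    jsonlite::write_json(
      list(participant_id = pid,
           threshold = config$preprocess@artifactZThreshold,
           band_hz = config$preprocess@artifactBand,
           log = rejectionLog(es)),
      file.path(rejDir, paste0(pid, "_rejection.json")),
      auto_unbox = TRUE, digits = NA)
    ccfg <- complexityConfig(
      nSubsampleChannels = effK,
      binarization = config$complexity@binarization,
      normalization = config$complexity@normalization,
      subsetPolicy = config$complexity@subsetPolicy,
      seed = deriveSeed(config$complexity@seed, i))
    lzr <- suppressWarnings(lzsumSubject(es, ccfg))
    tr <- suppressWarnings(tarSubject(es, config$spectral))
    lz[i] <- lzr$lzsum
    tar[i] <- tr$tar
    nEp[i] <- nEpochs(es); nKept[i] <- sum(keptMask(es))
    if (is.na(lz[i]) || is.na(tar[i]))
      warning(sprintf("%s: missing marker (no usable epochs), excluded", pid))
    pe <- merge(lzr$perEpoch, tr$perEpoch[, c("epoch", "valid", "tar")],
                by = "epoch")
    pe$participant_id <- pid
    perEpoch[[i]] <- pe
    if (config$logLevel == "debug")
      info("[markers] %s lzsum=%.3f tar=%.3f", pid, lz[i], tar[i])
  }
  subjects <- cbind(meta, lzsum = lz, tar = tar, nEpochs = nEp,
                    nKept = nKept,
                    binarization = config$complexity@binarization,
                    normalization = config$complexity@normalization,
                    seed = config$masterSeed)
  utils::write.csv(subjects, file.path(config$outputDir,
                                       "markers_subject.csv"),
                   row.names = FALSE)
  peTab <- do.call(rbind, perEpoch)
  peTab <- peTab[, c("participant_id", "epoch", "kept", "valid", "lzsum",
                     "tar")]
  utils::write.csv(peTab, file.path(config$outputDir, "markers_epoch.csv"),
                   row.names = FALSE)

  info("[analyze] running the statistics battery")
  report <- runBattery(subjects[, c("participant_id", "group", "age", "sex",
                                    "site", "mmse", "lzsum", "tar")])
  jsonlite::write_json(.reportToList(report),
                       file.path(config$outputDir, "analysis_report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$coefficientTable,
                   file.path(config$outputDir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(report$descriptives,
                   file.path(config$outputDir, "descriptives.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "MEGmarkers",
    version = as.character(utils::packageVersion("MEGmarkers")),
    master_seed = config$masterSeed,
    log_level = config$logLevel,
    cohort = .slotList(config$cohort),
    preprocess = .slotList(config$preprocess),
    complexity = .slotList(config$complexity),
    spectral = .slotList(config$spectral),
    input_dir = if (is.null(inputDir)) NA else inputDir,
    n_subjects = n)
  jsonlite::write_json(manifest,
                       file.path(config$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  info("[done] outputs in %s", config$outputDir)
  invisible(report)
}

# plain-list view of an AnalysisReport for JSON serialization
.reportToList <- function(report) {
  list(
    descriptives = report$descriptives,
    group_tests = lapply(report$groupTests, function(g) {
      g$groupMeans <- as.list(g$groupMeans)
      g$groupMedians <- as.list(g$groupMedians)
      g
    }),
    normality = report$normality,
    models = lapply(report$models, function(m) {
      m$coefficients <- as.list(m$coefficients)
      m$pValues <- as.list(m$pValues)
      m
    }),
    coding = report$coding)
}

#' Parse a flat key=value configuration file
#'
#' Reads the CLI's flat TOML-style configuration: one \code{key = value} pair
#' per line, \code{#} comments, bare numbers/strings/booleans and
#' comma-separated lists.
#'
#' @param path file path.
#' @return named list of parsed values.
#' @export
readKeyValueConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- unname(trimws(strsplit(val, ",", fixed = TRUE)[[1L]]))
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums
    else if (all(tolower(parts) %in% c("true", "false")))
      tolower(parts) == "true"
    else parts
  }
  out
}
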